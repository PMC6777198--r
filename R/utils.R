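# Internal helpers shared across modules.

#' Round half up to the nearest integer
#'
#' Commercial rounding as performed by the dose injector display: .5 always
#' rounds away from zero (162.5 -> 163, -2.5 -> -3), unlike [base::round()]
#' which rounds half to even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(162.97, 72.5, 36.875))
#' @export
round_half_up <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_domain <- function(...) stop(..., call. = FALSE)

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x <= 0)) {
    stop_domain(sprintf("`%s` must be strictly positive (got %s)",
                        name, paste(utils::head(x, 3), collapse = ", ")))
  }
  invisible(x)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a module sub-seed from a master seed
#'
#' Sub-seeds are derived by mixing the master seed with a 32-bit FNV-1a hash
#' of the module name, so adding a new module to the pipeline never perturbs
#' the random streams of existing modules.  The result is always a valid
#' positive 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param name character scalar naming the consuming module / stream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "cohort.standard")
#' @export
derive_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name),
            length(name) == 1L, nzchar(name))
  # FNV-1a over the UTF-8 bytes, in double arithmetic (exact below 2^53)
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(name))) {
    h <- (h %xor32% b)
    h <- (h * 16777619) %% 4294967296
  }
  mixed <- (h + 2654435761 * (as.numeric(master) %% 4294967296)) %% 4294967296
  as.integer(mixed %% (2^31 - 3) + 1)
}

# 32-bit xor for doubles holding integers in [0, 2^32)
`%xor32%` <- function(a, b) {
  r <- 0
  bit <- 1
  for (i in 1:32) {
    r <- r + bit * ((a %% 2 + b %% 2) %% 2)
    a <- a %/% 2
    b <- b %/% 2
    bit <- bit * 2
  }
  r
}

# Atomically write `lines`/data to `path`: write a sibling temp file, then
# rename.  A failed run never leaves a truncated output behind.
write_atomic <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  ok <- file.rename(tmp, path)
  if (!ok) stop_domain("could not move temporary file onto ", path)
  invisible(path)
}
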