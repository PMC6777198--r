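# Synthetic study arms: truncated-normal sampling of weight, height and heart
# rate with the published per-group demographics as defaults.

#' Truncated normal distribution helpers
#'
#' Inverse-CDF sampling (`rtnorm`) and the analytic mean and standard
#' deviation (`tnorm_mean`, `tnorm_sd`) of a normal distribution with
#' location `mean` and scale `sd`, truncated to `[lower, upper]`.  Inverse-CDF
#' sampling is used instead of rejection so that one uniform draw maps to one
#' sample: sequences are reproducible for a fixed seed regardless of the
#' truncation bounds.
#'
#' @param n number of draws.
#' @param mean,sd pre-truncation location and scale (`sd > 0`).
#' @param lower,upper truncation bounds, `lower < upper`.
#' @return `rtnorm`: numeric vector of `n` draws in `[lower, upper]`;
#'   `tnorm_mean`/`tnorm_sd`: the exact first / second moment of the
#'   truncated distribution.
#' @examples
#' set.seed(1)
#' x <- rtnorm(1000, 79.9, 14.3, 60, 109)
#' range(x)
#' tnorm_mean(79.9, 14.3, 60, 109)
#' @export
rtnorm <- function(n, mean, sd, lower, upper) {
  check_trunc(mean, sd, lower, upper)
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n)
  # map back through the normal quantile; clamp guards against u*pb rounding
  # a hair outside [pa, pb] in floating point
  clamp(stats::qnorm(pa + u * (pb - pa), mean, sd), lower, upper)
}

#' @rdname rtnorm
#' @export
tnorm_mean <- function(mean, sd, lower, upper) {
  check_trunc(mean, sd, lower, upper)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' @rdname rtnorm
#' @export
tnorm_sd <- function(mean, sd, lower, upper) {
  check_trunc(mean, sd, lower, upper)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  d <- (stats::dnorm(a) - stats::dnorm(b)) / z
  v <- 1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - d^2
  sd * sqrt(v)
}

check_trunc <- function(mean, sd, lower, upper) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0) {
    stop_domain("truncated normal needs finite mean and sd > 0")
  }
  if (!(lower < upper)) {
    stop_domain("infeasible truncation: lower (", lower,
                ") must be below upper (", upper, ")")
  }
  invisible(TRUE)
}

#' Demographics of one study arm
#'
#' Each continuous attribute is described by `(mean, sd, min, max)`: the
#' marginal is a normal with that location and scale truncated to
#' `[min, max]`.  `sex_ratio` is the fraction of male patients and
#' `pathology_mix` the (aneurysm, dissection, other) fractions; both are
#' metadata that do not enter the dose calculation.
#'
#' @param n arm size.
#' @param weight,height,heart_rate numeric length-4 vectors
#'   `c(mean, sd, min, max)` in kg, cm and bpm respectively.
#' @param sex_ratio fraction male, in `[0, 1]`.
#' @param pathology_mix length-3 fractions (aneurysm, dissection, other)
#'   summing to 1.
#' @param group arm label.
#' @return an object of class `group_demographics`.
#' @export
group_demographics <- function(n, weight, height, heart_rate,
                               sex_ratio = 0.5,
                               pathology_mix = c(0.5, 0.5, 0),
                               group = "calculator") {
  check_triple <- function(x, name) {
    if (length(x) != 4L || anyNA(x)) {
      stop_domain("`", name, "` must be c(mean, sd, min, max)")
    }
    if (!(x[3] < x[1] && x[1] < x[4])) {
      stop_domain("`", name, "`: need min < mean < max")
    }
    if (x[2] <= 0) stop_domain("`", name, "`: sd must be positive")
  }
  check_triple(weight, "weight")
  check_triple(height, "height")
  check_triple(heart_rate, "heart_rate")
  stopifnot(n >= 1, sex_ratio >= 0, sex_ratio <= 1,
            length(pathology_mix) == 3L,
            abs(sum(pathology_mix) - 1) < 1e-8)
  structure(list(n = as.integer(n), weight = weight, height = height,
                 heart_rate = heart_rate, sex_ratio = sex_ratio,
                 pathology_mix = pathology_mix, group = group),
            class = "group_demographics")
}

#' Published demographics of the three study arms
#'
#' Mean, SD and observed range of weight, height and heart rate per arm, as
#' reported for the pilot study (n = 20 per arm): the default study
#' conditions for every simulation in this package.  The printed moments
#' describe the observed (already bounded) data; they are used here as the
#' pre-truncation parameters, which slightly shrinks the simulated spread --
#' a deliberate, documented simplification.
#'
#' @return named list of three [group_demographics()]: `standard`,
#'   `calculator`, `calculator_diluted`.
#' @export
study_demographics <- function() {
  list(
    standard = group_demographics(
      n = 20,
      weight = c(74.6, 15.0, 50, 105),
      height = c(167.9, 10.0, 150, 186),
      heart_rate = c(66.8, 15.6, 39, 95),
      sex_ratio = 11 / 20,
      pathology_mix = c(9, 10, 1) / 20,
      group = "standard"),
    calculator = group_demographics(
      n = 20,
      weight = c(82.6, 14.0, 50, 115),
      height = c(172.7, 8.2, 154, 187),
      heart_rate = c(72.9, 18.4, 51, 122),
      sex_ratio = 15 / 20,
      pathology_mix = c(11, 9, 0) / 20,
      group = "calculator"),
    calculator_diluted = group_demographics(
      n = 20,
      weight = c(79.9, 14.3, 60, 109),
      height = c(172.1, 11.0, 152, 186),
      heart_rate = c(66.7, 18.5, 49, 127),
      sex_ratio = 15 / 20,
      pathology_mix = c(10, 10, 0) / 20,
      group = "calculator_diluted")
  )
}

#' Sample a synthetic study arm
#'
#' Draws `demographics$n` patients.  Weight, height and heart rate are drawn
#' from their truncated normals; heart rate is rounded to a whole bpm.  By
#' default attributes are independent; `weight_height_cor` imposes a Gaussian
#'-copula rank correlation between weight and height for more realistic BMI
#' while preserving both truncated marginals.
#'
#' @param demographics a [group_demographics()].
#' @param seed integer seed; required, so cohorts are reproducible.
#' @param concentration_mgI_ml stock contrast concentration recorded for each
#'   patient (default 350).
#' @param weight_height_cor latent normal correlation between weight and
#'   height in `(-1, 1)`; default 0 keeps the attributes independent.
#' @return data.frame with one row per patient: `id`, `weight_kg`,
#'   `height_cm`, `heart_rate_bpm`, `sex`, `pathology`, `group`,
#'   `concentration_mgI_ml`.
#' @examples
#' cohort <- sample_cohort(study_demographics()$calculator, seed = 42)
#' summary(cohort$weight_kg)
#' @export
sample_cohort <- function(demographics, seed, concentration_mgI_ml = 350,
                          weight_height_cor = 0) {
  stopifnot(inherits(demographics, "group_demographics"))
  if (missing(seed)) stop_domain("an explicit seed is required")
  stopifnot(abs(weight_height_cor) < 1)
  d <- demographics
  with_seed(seed, {
    n <- d$n
    zw <- stats::rnorm(n)
    zh <- weight_height_cor * zw +
      sqrt(1 - weight_height_cor^2) * stats::rnorm(n)
    weight <- qtnorm_from_z(zw, d$weight)
    height <- qtnorm_from_z(zh, d$height)
    hr <- round(rtnorm(n, d$heart_rate[1], d$heart_rate[2],
                       d$heart_rate[3], d$heart_rate[4]))
    sex <- ifelse(stats::runif(n) < d$sex_ratio, "male", "female")
    pathology <- sample(c("aneurysm", "dissection", "other"), n,
                        replace = TRUE, prob = d$pathology_mix)
    data.frame(
      id = sprintf("%s_%02d", d$group, seq_len(n)),
      weight_kg = weight, height_cm = height,
      heart_rate_bpm = as.integer(hr),
      sex = sex, pathology = pathology, group = d$group,
      concentration_mgI_ml = concentration_mgI_ml,
      stringsAsFactors = FALSE)
  })
}

# push a standard-normal draw through the truncated-normal quantile map
qtnorm_from_z <- function(z, par) {
  pa <- stats::pnorm(par[3], par[1], par[2])
  pb <- stats::pnorm(par[4], par[1], par[2])
  u <- stats::pnorm(z)
  clamp(stats::qnorm(pa + u * (pb - pa), par[1], par[2]), par[3], par[4])
}

#' Sample all three study arms
#'
#' @param demographics named list of three [group_demographics()] (default
#'   [study_demographics()]).
#' @param seed master seed; each arm uses a sub-seed derived with
#'   [derive_seed()] so arms are independent streams.
#' @param ... passed to [sample_cohort()].
#' @return one data.frame with all arms stacked.
#' @export
sample_study_cohorts <- function(demographics = study_demographics(), seed,
                                 ...) {
  if (missing(seed)) stop_domain("an explicit seed is required")
  do.call(rbind, lapply(names(demographics), function(g) {
    sample_cohort(demographics[[g]], seed = derive_seed(seed,
                                                        paste0("cohort.", g)),
                  ...)
  }))
}
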