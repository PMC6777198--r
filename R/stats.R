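# Study statistics written out from first principles: descriptives, the
# three t-test variants, percent differences, and the consistency /
# average-measures intraclass correlation from the two-way ANOVA
# decomposition.  Closed forms are implemented directly so tests can check
# them against independent oracles (stats::t.test, brute-force ANOVA loops).

#' Descriptive summary of one variable
#'
#' Mean, sample SD (n - 1 denominator), median (midpoint rule for even n),
#' minimum and maximum.
#'
#' @param values numeric vector, length >= 1, no NAs.
#' @param variable optional label.
#' @return one-row data.frame: `variable`, `n`, `mean`, `sd`, `median`,
#'   `min`, `max`.  `sd` is 0 for a single observation or a constant column.
#' @examples
#' describe(c(1, 2, 3))
#' @export
describe <- function(values, variable = NA_character_) {
  if (length(values) == 0L) stop_domain("cannot describe an empty vector")
  if (anyNA(values)) stop_domain("values contain NA")
  s <- if (length(values) > 1L) stats::sd(values) else 0
  data.frame(variable = variable, n = length(values), mean = mean(values),
             sd = s, median = stats::median(values), min = min(values),
             max = max(values), stringsAsFactors = FALSE)
}

#' Signed percent difference relative to a reference mean
#'
#' `100 * (other - reference) / reference`.  The study reports these to the
#' nearest whole percent (half away from zero); one decimal is kept
#' internally for the enhancement rows.
#'
#' @param reference_mean mean of the first-listed (reference) group; nonzero.
#' @param other_mean mean of the compared group.
#' @return list with `value` (full precision), `one_decimal` and `reported`
#'   (nearest integer percent).
#' @examples
#' percent_difference(120, 101.8)$reported   # -15
#' percent_difference(282.2, 191.2)$one_decimal  # -32.2
#' @export
percent_difference <- function(reference_mean, other_mean) {
  if (!is.finite(reference_mean) || reference_mean == 0) {
    stop_domain("reference mean must be nonzero and finite")
  }
  v <- 100 * (other_mean - reference_mean) / reference_mean
  list(value = v,
       one_decimal = round_half_up(v * 10) / 10,
       reported = round_half_up(v))
}

#' Two-sample / paired t-test (closed form)
#'
#' Three variants: `student_pooled` (equal-variance two-sample Student t,
#' the study default for between-arm comparisons), `welch`
#' (Satterthwaite degrees of freedom), and `paired` (one-sample t on the
#' differences, for intra-patient repeat scans).  Two-tailed p-values
#' throughout.  If both samples are constant with equal means the test is
#' degenerate and `p = 1`, `t = 0` by convention.
#'
#' @param x,y numeric samples (each n >= 2; equal lengths for `paired`).
#' @param variant `"student_pooled"`, `"welch"` or `"paired"`.
#' @param alpha significance level; the study uses 0.025
#'   (Bonferroni-corrected alpha / 2).
#' @return list: `variant`, `t`, `df`, `p`, `mean_x`, `mean_y`, `alpha`,
#'   `significant` (`p < alpha`).
#' @examples
#' two_sample_ttest(c(1, 2, 3, 4), c(2, 3, 4, 5))$t  # -1.095...
#' @export
two_sample_ttest <- function(x, y,
                             variant = c("student_pooled", "welch", "paired"),
                             alpha = 0.025) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(x), is.numeric(y), !anyNA(x), !anyNA(y))
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop_domain("need at least two values per sample")
  if (variant == "paired") {
    if (nx != ny) stop_domain("paired test requires equal-length samples")
    d <- x - y
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      tt <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    } else {
      tt <- mean(d) / (sd_d / sqrt(nx))
    }
    df <- nx - 1
  } else {
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
      md <- mean(x) - mean(y)
      tt <- if (md == 0) 0 else Inf * sign(md)
      df <- nx + ny - 2
    } else if (variant == "student_pooled") {
      sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
      tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
      df <- nx + ny - 2
    } else {
      se2 <- vx / nx + vy / ny
      tt <- (mean(x) - mean(y)) / sqrt(se2)
      df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    }
  }
  p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df)
  list(variant = variant, t = tt, df = df, p = p,
       mean_x = mean(x), mean_y = mean(y), alpha = alpha,
       significant = p < alpha)
}

#' Intraclass correlation, two-way consistency form
#'
#' ICC from the two-way (subject x rater) ANOVA decomposition without
#' interaction, in the consistency formulation, which is invariant to a
#' systematic additive offset of any rater -- the appropriate choice when one
#' reader scores consistently higher than the other.  Average measures
#' (ICC(C,k)) is the study's statistic: `(MS_rows - MS_error) / MS_rows`;
#' single measures (ICC(C,1)) is also returned.
#'
#' Inter-observer agreement uses the two readers' session-1 scores as the two
#' columns; intra-observer agreement uses reader 1's two sessions.
#'
#' @param ratings numeric matrix, subjects in rows, raters (or sessions) in
#'   columns; complete, >= 2 rows and >= 2 columns.
#' @param kind label stored in the result (`"inter_observer"` /
#'   `"intra_observer"` / anything descriptive).
#' @return list: `kind`, `model` (`"two-way consistency"`), `value`
#'   (average measures), `single` (single measures), `ms_rows`, `ms_error`,
#'   `n` subjects, `k` raters, `defined` (FALSE when between-subject
#'   variance is zero, in which case `value` is NA rather than a propagated
#'   NaN).
#' @examples
#' m <- cbind(r1 = c(4, 5, 3, 4), r2 = c(5, 5, 4, 5))
#' icc_consistency_average(m)$value
#' @export
icc_consistency_average <- function(ratings, kind = "inter_observer") {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop_domain("ratings matrix must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop_domain("need >= 2 subjects and >= 2 raters")
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  if (ms_rows <= 0) {
    return(list(kind = kind, model = "two-way consistency", value = NA_real_,
                single = NA_real_, ms_rows = ms_rows, ms_error = ms_error,
                n = n, k = k, defined = FALSE))
  }
  list(kind = kind, model = "two-way consistency",
       value = (ms_rows - ms_error) / ms_rows,
       single = (ms_rows - ms_error) / (ms_rows + (k - 1) * ms_error),
       ms_rows = ms_rows, ms_error = ms_error, n = n, k = k, defined = TRUE)
}

#' Full three-arm study analysis
#'
#' Per-arm descriptives and the three pairwise comparisons for contrast dose,
#' mean five-level enhancement, and reader-averaged visual score, plus inter-
#' and intra-observer ICC -- the full published comparison surface.  Visual
#' scores are averaged across the two readers' session-1 readings per patient
#' before summarising.  Pairwise comparisons use the pooled two-sample
#' Student t by default (`welch` reruns everything with unequal variances as
#' a sensitivity analysis) and are flagged significant at p < 0.025, the
#' study's Bonferroni-corrected level.
#'
#' @param doses dose table from [calculate_doses()] (needs `id`, `group`,
#'   `final_dose`).
#' @param enhancements table from [simulate_enhancement()] (needs `id`,
#'   `group`, `mean_hu`).
#' @param scores long table from [simulate_visual_scores()] (needs `id`,
#'   `group`, `reader`, `session`, `score`).
#' @param variant t-test variant for between-arm comparisons.
#' @param alpha significance level (default 0.025).
#' @param group_order the three arm labels, reference group first.
#' @return a `study_report`: list with `summaries` (data.frame),
#'   `comparisons` (data.frame with percent differences and p-values),
#'   `icc_inter`, `icc_intra`, `alpha`, `variant`.
#' @export
run_study_analysis <- function(doses, enhancements, scores,
                               variant = c("student_pooled", "welch"),
                               alpha = 0.025,
                               group_order = c("standard", "calculator",
                                               "calculator_diluted")) {
  variant <- match.arg(variant)
  for (g in group_order) {
    if (!any(doses$group == g)) {
      stop_domain("study arm missing from dose table: ", g)
    }
  }
  # reader-averaged session-1 score per patient
  s1 <- scores[scores$session == 1L, , drop = FALSE]
  avg_score <- stats::aggregate(score ~ id + group, data = s1, FUN = mean)
  names(avg_score)[names(avg_score) == "score"] <- "avg_score"

  vars <- list(
    dose = list(data = doses, col = "final_dose"),
    enhancement = list(data = enhancements, col = "mean_hu"),
    visual_score = list(data = avg_score, col = "avg_score"))

  summaries <- do.call(rbind, lapply(names(vars), function(v) {
    d <- vars[[v]]
    do.call(rbind, lapply(group_order, function(g) {
      x <- d$data[[d$col]][d$data$group == g]
      if (length(x) == 0L) stop_domain("study arm missing for ", v, ": ", g)
      cbind(data.frame(group = g, stringsAsFactors = FALSE),
            describe(x, variable = v))
    }))
  }))

  pairs <- utils::combn(group_order, 2, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(names(vars), function(v) {
    d <- vars[[v]]
    do.call(rbind, lapply(pairs, function(pr) {
      x <- d$data[[d$col]][d$data$group == pr[1]]
      y <- d$data[[d$col]][d$data$group == pr[2]]
      pd <- percent_difference(mean(x), mean(y))
      tt <- two_sample_ttest(x, y, variant = variant, alpha = alpha)
      data.frame(variable = v, pair = paste(pr[1], "vs", pr[2]),
                 mean_ref = mean(x), mean_other = mean(y),
                 percent_difference = pd$value,
                 percent_reported = pd$reported,
                 t = tt$t, df = tt$df, p = tt$p,
                 significant = tt$significant, stringsAsFactors = FALSE)
    }))
  }))

  icc_inter <- icc_consistency_average(
    score_matrix(scores, by = "reader"), kind = "inter_observer")
  icc_intra <- icc_consistency_average(
    score_matrix(scores, by = "session"), kind = "intra_observer")

  structure(list(summaries = summaries, comparisons = comparisons,
                 icc_inter = icc_inter, icc_intra = icc_intra,
                 alpha = alpha, variant = variant,
                 group_order = group_order),
            class = "study_report")
}

# Wide subjects x 2 matrix from the long score table: by = "reader" pairs
# the two readers' session-1 scores, by = "session" pairs reader 1's two
# sessions.
score_matrix <- function(scores, by = c("reader", "session")) {
  by <- match.arg(by)
  if (by == "reader") {
    a <- scores[scores$reader == 1L & scores$session == 1L, ]
    b <- scores[scores$reader == 2L & scores$session == 1L, ]
  } else {
    a <- scores[scores$reader == 1L & scores$session == 1L, ]
    b <- scores[scores$reader == 1L & scores$session == 2L, ]
  }
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop_domain("score table lacks the readings needed for the ", by,
                " ICC")
  }
  b <- b[match(a$id, b$id), ]
  if (anyNA(b$score)) stop_domain("incomplete score table: unmatched ids")
  cbind(first = a$score, second = b$score)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Three-arm study report (", x$variant, " t-tests, alpha = ",
      x$alpha, ")\n\n", sep = "")
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

#' Render a study report as a Markdown table
#'
#' One row per outcome variable with per-arm `mean +/- sd (median, min-max)`
#' cells and the three pairwise `percent (p ...)` columns, mirroring the
#' published summary-table layout.
#'
#' @param report a `study_report` from [run_study_analysis()].
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  go <- report$group_order
  fmt_cell <- function(s) {
    sprintf("%.1f ± %.1f (%.1f, %.1f-%.1f)",
            s$mean, s$sd, s$median, s$min, s$max)
  }
  fmt_p <- function(p) if (p < 0.01) "p < 0.01" else sprintf("p %.2f", p)
  hdr <- c("Variable", go,
           paste(go[1], "vs", go[2]), paste(go[1], "vs", go[3]),
           paste(go[2], "vs", go[3]))
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"))
  for (v in unique(report$summaries$variable)) {
    s <- report$summaries[report$summaries$variable == v, ]
    cmp <- report$comparisons[report$comparisons$variable == v, ]
    cells <- vapply(go, function(g) fmt_cell(s[s$group == g, ]), character(1))
    cmps <- sprintf("%+d%% (%s)", as.integer(cmp$percent_reported),
                    vapply(cmp$p, fmt_p, character(1)))
    lines <- c(lines, paste0("| ", paste(c(v, cells, cmps),
                                         collapse = " | "), " |"))
  }
  lines <- c(lines, "",
             sprintf("Inter-observer ICC (consistency, average measures): %.3f",
                     report$icc_inter$value),
             sprintf("Intra-observer ICC (consistency, average measures): %.3f",
                     report$icc_intra$value))
  lines
}

#' Serialise a study report to JSON
#'
#' @param report a `study_report`.
#' @param path output file; written atomically.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    alpha = report$alpha,
    variant = report$variant,
    summaries = report$summaries,
    comparisons = report$comparisons,
    icc = list(
      inter_observer = report$icc_inter[c("value", "single", "n", "k",
                                          "defined")],
      intra_observer = report$icc_intra[c("value", "single", "n", "k",
                                          "defined")]))
  write_atomic(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(path)
}
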