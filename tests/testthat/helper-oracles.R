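# Independent brute-force oracles used across tests.  These deliberately
# avoid the package's own code paths.

# Consistency / average-measures ICC from explicit double-loop ANOVA sums of
# squares (two-way, no interaction).
brute_icc_consistency_average <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) {
    ri <- 0
    for (j in seq_len(k)) ri <- ri + m[i, j]
    ss_rows <- ss_rows + k * (ri / k - grand)^2
  }
  ss_cols <- 0
  for (j in seq_len(k)) {
    cj <- 0
    for (i in seq_len(n)) cj <- cj + m[i, j]
    ss_cols <- ss_cols + n * (cj / n - grand)^2
  }
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_tot <- ss_tot + (m[i, j] - grand)^2
  }
  ms_rows <- ss_rows / (n - 1)
  ms_err <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / ms_rows
}

# ROI statistics by naive per-pixel enumeration.
brute_measure_roi <- function(slice, roi) {
  g <- slice$geometry
  sp <- g$pixel_spacing_mm
  vals <- c()
  for (i in seq_len(g$grid_size)) {
    for (j in seq_len(g$grid_size)) {
      x <- (j - 1) * sp
      y <- (i - 1) * sp
      if ((x - roi$center_mm[1])^2 + (y - roi$center_mm[2])^2 <=
            roi$radius_mm^2) {
        vals <- c(vals, slice$pixels[i, j])
      }
    }
  }
  list(mean_hu = mean(vals), sd_hu = stats::sd(vals), n_pixels = length(vals))
}

# Literal transcription of the published heart-rate correction bands, with
# the 55 bpm gap resolved into the low band (the package's documented
# reading).
literal_hr_table_lookup <- function(bpm) {
  if (bpm <= 55) -10
  else if (bpm <= 65) 0
  else if (bpm <= 75) 10
  else if (bpm <= 90) 20
  else if (bpm <= 105) 25
  else 30
}

# Tiny deterministic three-arm study tables for analysis-level tests.
make_toy_study <- function(seed = 11) {
  cfg <- study_config(group_sizes = c(standard = 8, calculator = 8,
                                      calculator_diluted = 8),
                      seed = seed)
  run_pipeline(cfg)
}
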