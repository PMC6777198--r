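# Enhancement and visual-score generators.

toy_patients <- function(n, group = "standard", pathology = "aneurysm") {
  data.frame(id = sprintf("p%02d", seq_len(n)), group = group,
             pathology = pathology, stringsAsFactors = FALSE)
}

test_that("degenerate noise gives every level exactly the group mean", {
  cfg <- simulation_config(
    enhancement = list(standard = c(282.2, 0, 282.2, 282.2)),
    level_sd = 0)
  enh <- simulate_enhancement(toy_patients(6), cfg, seed = 1)
  levels <- as.matrix(enh[, paste0("hu_", c("suprarenal", "renal",
                                            "infrarenal", "left_iliac",
                                            "right_iliac"))])
  expect_true(all(levels == 282.2))
  expect_true(all(enh$mean_hu == 282.2 & enh$min_hu == 282.2 &
                    enh$max_hu == 282.2))
})

test_that("min/mean/max summarise the five level values", {
  enh <- simulate_enhancement(toy_patients(50), seed = 2)
  levels <- as.matrix(enh[, grep("^hu_", names(enh))])
  expect_equal(enh$mean_hu, rowMeans(levels))
  expect_equal(enh$min_hu, apply(levels, 1, min))
  expect_equal(enh$max_hu, apply(levels, 1, max))
  expect_true(all(enh$min_hu <= enh$mean_hu & enh$mean_hu <= enh$max_hu))
})

test_that("the dilution-arm grand mean matches the published group mean", {
  # the generator moment-matches the truncated mean to the printed 191.2 HU
  enh <- simulate_enhancement(toy_patients(5000, "calculator_diluted"),
                              seed = 3)
  expect_equal(mean(enh$mean_hu), 191.2, tolerance = 3 / 191.2)
  expect_true(all(enh$group == "calculator_diluted"))
})

test_that("simulation is deterministic per seed and rejects unknown groups", {
  a <- simulate_enhancement(toy_patients(10), seed = 4)
  b <- simulate_enhancement(toy_patients(10), seed = 4)
  expect_identical(a, b)
  expect_error(simulate_enhancement(toy_patients(3, group = "mystery"),
                                    seed = 4),
               "no enhancement distribution")
  expect_error(simulate_enhancement(toy_patients(3)), "seed")
})

test_that("the true-lumen fraction attenuates dissection patients only", {
  cfg <- simulation_config(
    enhancement = list(standard = c(300, 0, 300, 300)),
    level_sd = 0, true_lumen_fraction = 0.5)
  pts <- toy_patients(4)
  pts$pathology <- c("aneurysm", "dissection", "dissection", "other")
  enh <- simulate_enhancement(pts, cfg, seed = 5)
  expect_equal(enh$mean_hu, c(300, 150, 150, 300))
})

test_that("latent quality is monotone in enhancement and thresholds map to
           score steps", {
  cfg <- simulation_config()
  hu <- seq(10, 600, by = 0.5)
  q <- hu_to_latent(hu, cfg)
  expect_true(all(diff(q) > 0))
  # noise-free scores step exactly at the calibrated thresholds
  s <- pmin(pmax(round_half_up(q), 1), 5)
  expect_true(all(diff(s) >= 0))
  eps <- 1e-6
  expect_identical(
    pmin(pmax(round_half_up(hu_to_latent(cfg$hu_thresholds - eps, cfg)),
              1), 5),
    c(1, 2, 3, 4))
  expect_identical(
    pmin(pmax(round_half_up(hu_to_latent(cfg$hu_thresholds + eps, cfg)),
              1), 5),
    c(2, 3, 4, 5))
})

test_that("zero noise and zero bias make the two readers identical", {
  cfg <- simulation_config(reader_noise_sd = 0, session2_sd = 0,
                           reader2_bias = c(standard = 0))
  enh <- simulate_enhancement(toy_patients(30), seed = 6)
  sc <- simulate_visual_scores(enh, cfg, seed = 6)
  r1 <- sc$score[sc$reader == 1 & sc$session == 1]
  r2 <- sc$score[sc$reader == 2 & sc$session == 1]
  s2 <- sc$score[sc$reader == 1 & sc$session == 2]
  expect_identical(r1, r2)
  expect_identical(r1, s2)
  # perfect agreement propagates to an ICC of exactly 1
  expect_identical(icc_consistency_average(cbind(r1, r2))$value, 1)
})

test_that("enhancement below the lowest threshold scores 1", {
  cfg <- simulation_config(reader_noise_sd = 0, session2_sd = 0,
                           reader2_bias = c(standard = 0),
                           enhancement = list(standard = c(50, 0, 50, 50)),
                           level_sd = 0)
  enh <- simulate_enhancement(toy_patients(5), cfg, seed = 7)
  sc <- simulate_visual_scores(enh, cfg, seed = 7)
  expect_true(all(sc$score == 1L))
})

test_that("session 2 exists only for reader 1 and scores stay in 1..5", {
  enh <- simulate_enhancement(toy_patients(40, "calculator_diluted"),
                              seed = 8)
  sc <- simulate_visual_scores(enh, seed = 8)
  expect_identical(nrow(sc[sc$reader == 2 & sc$session == 2, ]), 0L)
  expect_true(all(sc$score %in% 1:5))
  expect_identical(nrow(sc), 120L)  # 40 patients x 3 readings
})

test_that("default calibration reproduces the standard-arm mean score", {
  enh <- simulate_enhancement(toy_patients(4000), seed = 9)
  sc <- simulate_visual_scores(enh, seed = 9)
  s1 <- sc[sc$session == 1, ]
  per_patient <- tapply(s1$score, s1$id, mean)
  expect_equal(mean(per_patient), 4.5, tolerance = 0.3 / 4.5)
})

test_that("more reader noise lowers the downstream inter-observer ICC", {
  icc_at <- function(noise_sd) {
    cfg <- simulation_config(reader_noise_sd = noise_sd)
    vals <- vapply(1:5, function(s) {
      enh <- simulate_enhancement(toy_patients(120, "calculator_diluted"),
                                  cfg, seed = 100 + s)
      sc <- simulate_visual_scores(enh, cfg, seed = 200 + s)
      r1 <- sc$score[sc$reader == 1 & sc$session == 1]
      r2 <- sc$score[sc$reader == 2 & sc$session == 1]
      icc_consistency_average(cbind(r1, r2))$value
    }, numeric(1))
    mean(vals)
  }
  expect_gt(icc_at(0.1), icc_at(1.5))
})

test_that("the mechanistic kernel tracks iodine mass per BSA", {
  plans <- data.frame(final_dose = c(120, 60, 120),
                      concentration_mgI_ml = c(350, 350, 350),
                      bsa = c(1.9, 1.9, 1.9),
                      heart_rate_bpm = c(67, 67, 67))
  e <- mechanistic_enhancement(plans)
  expect_equal(e[2] / e[1], 0.5)         # half the iodine, half the signal
  expect_equal(e[1], e[3])
  # higher heart rate, lower enhancement
  plans$heart_rate_bpm <- c(67, 67, 120)
  expect_lt(mechanistic_enhancement(plans)[3], e[1])
  # cohort use: mechanistic mode flows through simulate_enhancement
  pts <- toy_patients(3)
  plans2 <- cbind(plans, id = pts$id)
  enh <- simulate_enhancement(pts, simulation_config(level_sd = 0),
                              seed = 10, mode = "mechanistic", plans = plans2)
  expect_equal(enh$mean_hu[1], mechanistic_enhancement(plans2)[1])
})
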