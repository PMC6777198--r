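# Descriptives, percent differences, t-tests, ICC, and the study report.

test_that("describe reports mean, sample sd, median and range", {
  d <- describe(c(1, 2, 3))
  expect_equal(d[, c("mean", "sd", "median", "min", "max")],
               data.frame(mean = 2, sd = 1, median = 2, min = 1, max = 3))
  # constant column (the fixed-dose arm): sd 0, degenerate range
  d2 <- describe(rep(120, 20))
  expect_equal(c(d2$mean, d2$sd, d2$min, d2$max), c(120, 0, 120, 120))
  # even n: midpoint-rule median
  expect_equal(describe(c(1, 2, 3, 10))$median, 2.5)
  set.seed(21)
  expect_equal(describe(rnorm(10000))$sd, 1, tolerance = 0.03)
  expect_error(describe(numeric(0)), "empty")
  expect_error(describe(c(1, NA)), "NA")
})

test_that("percent differences reproduce the published comparison rows", {
  expect_identical(percent_difference(120, 101.8)$reported, -15)
  expect_identical(percent_difference(120, 48.1)$reported, -60)
  expect_identical(percent_difference(101.8, 48.1)$reported, -53)
  expect_identical(percent_difference(282.2, 279.3)$reported, -1)
  expect_identical(percent_difference(282.2, 191.2)$one_decimal, -32.2)
  expect_identical(percent_difference(7, 7)$value, 0)
  expect_error(percent_difference(0, 5), "nonzero")
})

test_that("forward and reverse percent differences are reciprocal", {
  set.seed(31)
  for (i in 1:50) {
    a <- runif(1, 10, 300); b <- runif(1, 10, 300)
    d1 <- percent_difference(a, b)$value
    d2 <- percent_difference(b, a)$value
    expect_equal((1 + d1 / 100) * (1 + d2 / 100), 1, tolerance = 1e-12)
  }
})

test_that("the pooled t matches the closed-form hand computation", {
  res <- two_sample_ttest(c(1, 2, 3, 4), c(2, 3, 4, 5), "student_pooled")
  # pooled sd = 1.29099, se = 0.91287: |t| = 1.095 to 3 s.f.
  expect_equal(abs(res$t), 1.095, tolerance = 5e-4)
  expect_identical(res$df, 6)
  expect_false(res$significant)
})

test_that("all three variants agree with stats::t.test", {
  set.seed(17)
  for (i in 1:25) {
    x <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    for (v in c("student_pooled", "welch")) {
      mine <- two_sample_ttest(x, y, v)
      ref <- t.test(x, y, var.equal = v == "student_pooled")
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-8)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
    n <- min(length(x), length(y))
    mine <- two_sample_ttest(x[1:n], y[1:n], "paired")
    ref <- t.test(x[1:n], y[1:n], paired = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and edge cases follow the documented conventions", {
  r <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3), "paired")
  expect_identical(c(r$t, r$p), c(0, 1))
  r2 <- two_sample_ttest(rep(2, 5), rep(2, 7), "student_pooled")
  expect_identical(c(r2$t, r2$p), c(0, 1))
  r3 <- two_sample_ttest(rep(3, 5), rep(2, 5), "student_pooled")
  expect_identical(r3$p, 0)
  expect_error(two_sample_ttest(1:3, 1:4, "paired"), "equal-length")
  expect_error(two_sample_ttest(1, 1:5), "at least two")
})

test_that("pooled and Welch coincide for equal-size equal-variance samples", {
  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20, 0.3)
    a <- two_sample_ttest(x, y, "student_pooled")
    b <- two_sample_ttest(x, y, "welch")
    expect_equal(a$t, b$t, tolerance = 1e-12)  # identical statistic at equal n
    expect_lte(b$df, a$df)                     # Satterthwaite shrinks the df
    expect_equal(a$p, b$p, tolerance = 0.05)   # p differs only through the df
  }
})

test_that("null p-values are uniform (KS check)", {
  set.seed(23)
  p <- replicate(800, two_sample_ttest(rnorm(15), rnorm(15))$p)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("ICC equals the brute-force two-way ANOVA oracle", {
  set.seed(29)
  for (i in 1:30) {
    n <- sample(3:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
      rnorm(n)  # row effects so ms_rows > 0
    mine <- icc_consistency_average(m)
    expect_equal(mine$value, brute_icc_consistency_average(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC is 1 for duplicated raters and ~0 for independent ones", {
  x <- c(4, 5, 3, 4, 2, 5)
  expect_identical(icc_consistency_average(cbind(x, x))$value, 1)
  set.seed(37)
  r <- replicate(20, icc_consistency_average(cbind(rnorm(200), rnorm(200))))
  vals <- unlist(r["value", ])
  singles <- unlist(r["single", ])
  # null sd of the single-measures form is ~1/sqrt(n) = 0.07; the
  # average-measures form roughly doubles it
  expect_lt(sd(singles), 0.12)
  expect_lt(max(abs(singles)), 0.25)
  expect_lt(max(abs(vals)), 0.45)
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("consistency ICC is invariant to per-rater additive shifts", {
  set.seed(43)
  m <- matrix(rnorm(40), 10, 4) + rnorm(10)
  shifted <- sweep(m, 2, c(0, 0.45, 1.1, -2), "+")
  expect_equal(icc_consistency_average(shifted)$value,
               icc_consistency_average(m)$value, tolerance = 1e-12)
})

test_that("zero between-subject variance is reported as undefined", {
  m <- matrix(c(1, 1, 1, 2, 2, 2), 3, 2)  # identical rows
  r <- icc_consistency_average(m)
  expect_false(r$defined)
  expect_true(is.na(r$value))
  expect_error(icc_consistency_average(cbind(c(1, NA), c(1, 2))), "complete")
  expect_error(icc_consistency_average(matrix(1, 1, 2)), ">= 2 subjects")
})

test_that("run_study_analysis assembles the full comparison surface", {
  res <- make_toy_study()
  rep <- res$report
  expect_setequal(unique(rep$summaries$variable),
                  c("dose", "enhancement", "visual_score"))
  expect_identical(nrow(rep$comparisons), 9L)   # 3 variables x 3 pairs
  expect_true(all(rep$comparisons$p >= 0 & rep$comparisons$p <= 1))
  expect_identical(rep$comparisons$significant,
                   rep$comparisons$p < 0.025)
  expect_true(rep$icc_inter$defined)
  expect_true(rep$icc_intra$defined)
  # standard arm dose column is the fixed protocol dose
  std <- rep$summaries[rep$summaries$group == "standard" &
                         rep$summaries$variable == "dose", ]
  expect_equal(c(std$mean, std$sd, std$min, std$max), c(120, 0, 120, 120))
  # missing arm is reported by name
  expect_error(
    run_study_analysis(res$doses[res$doses$group != "calculator", ],
                       res$enhancement, res$scores),
    "missing.*calculator")
})

test_that("a zero-noise equal-mean study shows no differences", {
  cfg <- study_config(
    group_sizes = c(standard = 6, calculator = 6, calculator_diluted = 6),
    simulation = simulation_config(
      enhancement = list(standard = c(250, 0, 250, 250),
                         calculator = c(250, 0, 250, 250),
                         calculator_diluted = c(250, 0, 250, 250)),
      level_sd = 0, reader_noise_sd = 0, session2_sd = 0,
      reader2_bias = c(standard = 0, calculator = 0, calculator_diluted = 0)),
    seed = 50)
  res <- run_pipeline(cfg)
  cmp <- res$report$comparisons
  enh_cmp <- cmp[cmp$variable != "dose", ]
  expect_true(all(enh_cmp$percent_difference == 0))
  expect_true(all(!enh_cmp$significant))
})

test_that("report serialisation round-trips through JSON and Markdown", {
  rep <- make_toy_study()$report
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$icc$inter_observer$value, rep$icc_inter$value,
               tolerance = 1e-12)
  expect_equal(back$comparisons$percent_difference,
               rep$comparisons$percent_difference, tolerance = 1e-9)
  md <- report_markdown(rep)
  expect_true(any(grepl("^\\| Variable", md)))
  expect_identical(sum(grepl("^\\| (dose|enhancement|visual_score)", md)), 3L)
})
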