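# End-to-end orchestration: cohorts -> dose plans -> enhancement -> scores ->
# analysis, all under one config and one master seed.

#' Full study configuration
#'
#' Bundles group sizes, the calculator configuration, per-arm demographics
#' and the outcome-simulation configuration, plus the master seed.  Module
#' sub-seeds are derived from the master seed with [derive_seed()], so every
#' stage has an independent, reproducible random stream.
#'
#' @param group_sizes named integer vector of arm sizes (default 20 each).
#' @param calculator a [calculator_config()].
#' @param demographics named list of [group_demographics()] (default
#'   [study_demographics()]).
#' @param simulation a [simulation_config()].
#' @param seed master seed (required, no wall-clock seeding).
#' @param standard_dose fixed dose of the standard arm, ml.
#' @param concentration_mgI_ml stock concentration used for all simulated
#'   patients (default 350).
#' @return an object of class `study_config`.
#' @export
study_config <- function(group_sizes = c(standard = 20, calculator = 20,
                                         calculator_diluted = 20),
                         calculator = calculator_config(),
                         demographics = study_demographics(),
                         simulation = simulation_config(),
                         seed,
                         standard_dose = 120,
                         concentration_mgI_ml = 350) {
  if (missing(seed)) stop_domain("an explicit master seed is required")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!all(names(group_sizes) %in% names(demographics))) {
    stop_domain("group_sizes names must match demographics names")
  }
  if (any(group_sizes < 1)) {
    stop_domain("all group sizes must be at least 1")
  }
  stopifnot(inherits(calculator, "calculator_config"),
            inherits(simulation, "simulation_config"))
  demographics <- demographics[names(group_sizes)]
  for (g in names(group_sizes)) demographics[[g]]$n <-
      as.integer(group_sizes[[g]])
  structure(list(group_sizes = group_sizes, calculator = calculator,
                 demographics = demographics, simulation = simulation,
                 seed = as.integer(seed), standard_dose = standard_dose,
                 concentration_mgI_ml = concentration_mgI_ml),
            class = "study_config")
}

#' Run the full simulated study
#'
#' Samples the three arms, runs the dose calculator (with dilution in the
#' third arm), simulates enhancement and two-reader visual grading, and
#' analyses the result.  Deterministic for a fixed master seed.  When
#' `out_dir` is given, writes `cohort.csv`, `doses.csv`, `enhancement.csv`,
#' `scores.csv`, `report.json`, `report.md` and `run_log.txt`; every file is
#' written atomically (write-then-rename), so an interrupted run leaves no
#' truncated outputs.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory.
#' @return list: `cohort`, `doses`, `enhancement`, `scores`, `report`
#'   (a `study_report`).
#' @examples
#' res <- run_pipeline(study_config(seed = 1))
#' res$report$comparisons[res$report$comparisons$variable == "dose", ]
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cohort <- do.call(rbind, lapply(names(config$demographics), function(g) {
    sample_cohort(config$demographics[[g]],
                  seed = derive_seed(config$seed, paste0("cohort.", g)),
                  concentration_mgI_ml = config$concentration_mgI_ml)
  }))
  doses <- calculate_doses(cohort, config$calculator,
                           standard_dose = config$standard_dose)
  enhancement <- simulate_enhancement(
    cohort, config$simulation,
    seed = derive_seed(config$seed, "enhancement"))
  scores <- simulate_visual_scores(
    enhancement, config$simulation,
    seed = derive_seed(config$seed, "scores"))
  report <- run_study_analysis(doses, enhancement, scores)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_patient_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_patient_csv(doses, file.path(out_dir, "doses.csv"))
    write_patient_csv(enhancement, file.path(out_dir, "enhancement.csv"))
    write_patient_csv(scores, file.path(out_dir, "scores.csv"))
    write_report_json(report, file.path(out_dir, "report.json"))
    write_atomic(file.path(out_dir, "report.md"), function(tmp) {
      writeLines(report_markdown(report), tmp)
    })
    write_run_log(config,
                  files = file.path(out_dir,
                                    c("cohort.csv", "doses.csv",
                                      "enhancement.csv", "scores.csv")),
                  path = file.path(out_dir, "run_log.txt"))
  }
  list(cohort = cohort, doses = doses, enhancement = enhancement,
       scores = scores, report = report)
}

# Log every config value plus a content hash of each written table, so a run
# is fully auditable from its output directory alone.
write_run_log <- function(config, files, path) {
  lines <- c(sprintf("aortadose run, master seed %d", config$seed),
             sprintf("timestamp: %s", format(Sys.time(), tz = "UTC",
                                             usetz = TRUE)),
             "", "config:",
             utils::capture.output(utils::str(unclass_all(config))),
             "", "output hashes (FNV-1a 32-bit over file bytes):")
  for (f in files) {
    lines <- c(lines, sprintf("  %s  %s", fnv1a_file(f), basename(f)))
  }
  write_atomic(path, function(tmp) writeLines(lines, tmp))
  invisible(path)
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}

fnv1a_file <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  h <- 2166136261
  for (b in bytes) {
    h <- h %xor32% b
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Replicate the simulated study
#'
#' Runs the pipeline `n_replicates` times with per-replicate sub-seeds
#' derived from the master seed and stacks the per-arm dose / enhancement /
#' score means, for studying the sampling variability of the study's
#' summary statistics.
#'
#' @param config a [study_config()]; its seed is the master for all
#'   replicates.
#' @param n_replicates number of replicate studies.
#' @return data.frame with one row per replicate x arm: `replicate`, `group`,
#'   `mean_dose`, `mean_enhancement`, `mean_score`.
#' @export
replicate_study <- function(config, n_replicates = 100) {
  stopifnot(inherits(config, "study_config"), n_replicates >= 1)
  do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("replicate.", r))
    res <- run_pipeline(cfg)
    s <- res$report$summaries
    data.frame(replicate = r,
               group = s$group[s$variable == "dose"],
               mean_dose = s$mean[s$variable == "dose"],
               mean_enhancement = s$mean[s$variable == "enhancement"],
               mean_score = s$mean[s$variable == "visual_score"],
               stringsAsFactors = FALSE)
  }))
}

#' Write / read a study configuration as YAML
#'
#' A declarative dump of every tunable (`write_study_config`, the
#' `config --dump` of the command-line interface) and its inverse.  The
#' enhancement entries are stored as `(target_mean, sd, min, max)`; the
#' moment-matched location is recomputed on read.
#'
#' @param config a [study_config()].
#' @param path YAML file path.
#' @return `write_study_config`: the path, invisibly; `read_study_config`:
#'   a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  enh <- lapply(config$simulation$enhancement, function(e) {
    c(e$target_mean, e$sd, e$min, e$max)
  })
  payload <- list(
    seed = config$seed,
    group_sizes = as.list(config$group_sizes),
    standard_dose = config$standard_dose,
    concentration_mgI_ml = config$concentration_mgI_ml,
    calculator = list(
      dose_per_bsa = config$calculator$dose_per_bsa,
      hr_table = list(upper = config$calculator$hr_table$upper,
                      correction = config$calculator$hr_table$correction),
      reference_concentration = config$calculator$reference_concentration,
      concentration_step = config$calculator$concentration_step,
      min_dose = config$calculator$min_dose,
      max_dose = config$calculator$max_dose,
      dilution_factor = config$calculator$dilution_factor,
      dilution_floor = config$calculator$dilution_floor,
      bsa_mode = config$calculator$bsa_mode),
    demographics = lapply(config$demographics, function(d) {
      list(n = d$n, weight = d$weight, height = d$height,
           heart_rate = d$heart_rate, sex_ratio = d$sex_ratio,
           pathology_mix = d$pathology_mix, group = d$group)
    }),
    simulation = list(
      enhancement = enh,
      level_sd = config$simulation$level_sd,
      hu_thresholds = config$simulation$hu_thresholds,
      reader_noise_sd = config$simulation$reader_noise_sd,
      reader2_bias = as.list(config$simulation$reader2_bias),
      session2_sd = config$simulation$session2_sd,
      true_lumen_fraction = config$simulation$true_lumen_fraction,
      score_targets = as.list(config$simulation$score_targets)))
  write_atomic(path, function(tmp) yaml::write_yaml(payload, tmp))
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  hr_tab <- data.frame(upper = unlist(y$calculator$hr_table$upper),
                       correction = unlist(y$calculator$hr_table$correction))
  hr_tab$upper[is.na(hr_tab$upper) | hr_tab$upper == ".inf"] <- Inf
  calc <- calculator_config(
    dose_per_bsa = y$calculator$dose_per_bsa, hr_table = hr_tab,
    reference_concentration = y$calculator$reference_concentration,
    concentration_step = y$calculator$concentration_step,
    min_dose = y$calculator$min_dose, max_dose = y$calculator$max_dose,
    dilution_factor = y$calculator$dilution_factor,
    dilution_floor = y$calculator$dilution_floor,
    bsa_mode = y$calculator$bsa_mode)
  demo <- lapply(y$demographics, function(d) {
    group_demographics(n = d$n, weight = unlist(d$weight),
                       height = unlist(d$height),
                       heart_rate = unlist(d$heart_rate),
                       sex_ratio = d$sex_ratio,
                       pathology_mix = unlist(d$pathology_mix),
                       group = d$group)
  })
  sim <- simulation_config(
    enhancement = lapply(y$simulation$enhancement, unlist),
    level_sd = y$simulation$level_sd,
    hu_thresholds = unlist(y$simulation$hu_thresholds),
    reader_noise_sd = y$simulation$reader_noise_sd,
    reader2_bias = unlist(y$simulation$reader2_bias),
    session2_sd = y$simulation$session2_sd,
    true_lumen_fraction = y$simulation$true_lumen_fraction,
    score_targets = unlist(y$simulation$score_targets))
  study_config(group_sizes = unlist(y$group_sizes), calculator = calc,
               demographics = demo, simulation = sim, seed = y$seed,
               standard_dose = y$standard_dose,
               concentration_mgI_ml = y$concentration_mgI_ml)
}
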