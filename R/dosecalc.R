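# Contrast-agent dose calculator: BSA base dose + heart-rate and iodine
# concentration corrections, clamping, and the 50% dilution arm.

#' Calculator configuration
#'
#' Bundles every tunable of the injector dose algorithm.  The defaults encode
#' the published protocol: a base dose of 45 ml of contrast per m^2 of body
#' surface area, a piecewise-constant heart-rate correction
#' (<=55 bpm: -10 ml; 56-65: 0; 66-75: +10; 76-90: +20; 91-105: +25;
#' >105: +30), a concentration correction of +/-2 ml per 10 mg I/ml below/above
#' the 350 mg I/ml reference, an administered-dose window of 40-150 ml, and a
#' dilution arm that halves the clamped dose with a 20 ml floor.
#'
#' @param dose_per_bsa ml of contrast per m^2 of BSA (default 45).
#' @param hr_table data.frame with columns `upper` (inclusive upper bound of
#'   the heart-rate band, bpm, last entry `Inf`) and `correction` (ml).
#'   Bounds must be strictly increasing and corrections non-decreasing.
#' @param reference_concentration mg I/ml at which the concentration
#'   correction is zero (default 350).
#' @param concentration_step ml correction per 10 mg I/ml of deviation from
#'   the reference (default 2).
#' @param min_dose,max_dose clamp limits for the administered dose, ml
#'   (defaults 40 and 150).
#' @param dilution_factor fraction of the clamped dose given in the dilution
#'   arm (default 0.5); must lie strictly between 0 and 1.
#' @param dilution_floor minimum diluted dose, ml (default 20); must be below
#'   `min_dose`.
#' @param bsa_mode `"literal"` (default) computes BSA as
#'   `(height * weight / 3600) * 0.5`; `"mosteller"` computes
#'   `sqrt(height * weight / 3600)`.  See [compute_bsa()].
#' @param injection_rate ml/s of the contrast bolus (protocol constant, 4).
#' @param saline_flush ml of saline chaser (protocol constant, 30).
#' @return an object of class `calculator_config`.
#' @seealso [calculate_dose()], [compute_bsa()]
#' @examples
#' cfg <- calculator_config()
#' cfg$hr_table
#' @export
calculator_config <- function(dose_per_bsa = 45,
                              hr_table = default_hr_table(),
                              reference_concentration = 350,
                              concentration_step = 2,
                              min_dose = 40,
                              max_dose = 150,
                              dilution_factor = 0.5,
                              dilution_floor = 20,
                              bsa_mode = c("literal", "mosteller"),
                              injection_rate = 4,
                              saline_flush = 30) {
  bsa_mode <- match.arg(bsa_mode)
  assert_positive(dose_per_bsa, "dose_per_bsa")
  assert_positive(reference_concentration, "reference_concentration")
  stopifnot(is.data.frame(hr_table),
            all(c("upper", "correction") %in% names(hr_table)),
            nrow(hr_table) >= 1L)
  if (is.unsorted(hr_table$upper, strictly = TRUE)) {
    stop_domain("hr_table upper bounds must be strictly increasing")
  }
  if (is.unsorted(hr_table$correction)) {
    stop_domain("hr_table corrections must be non-decreasing")
  }
  if (!is.infinite(hr_table$upper[nrow(hr_table)])) {
    stop_domain("hr_table must end with an open band (upper = Inf)")
  }
  if (!(dilution_factor > 0 && dilution_factor < 1)) {
    stop_domain("dilution_factor must lie strictly between 0 and 1")
  }
  if (!(min_dose < max_dose)) stop_domain("min_dose must be below max_dose")
  if (!(dilution_floor < min_dose)) {
    stop_domain("dilution_floor must be below min_dose")
  }
  structure(
    list(dose_per_bsa = dose_per_bsa, hr_table = hr_table,
         reference_concentration = reference_concentration,
         concentration_step = concentration_step,
         min_dose = min_dose, max_dose = max_dose,
         dilution_factor = dilution_factor, dilution_floor = dilution_floor,
         bsa_mode = bsa_mode, injection_rate = injection_rate,
         saline_flush = saline_flush),
    class = "calculator_config"
  )
}

#' Default heart-rate correction table
#'
#' The published volume-correction bands.  The printed table leaves 55 bpm
#' unassigned ("<55" then "56-65"); here the low band is implemented as
#' `<= 55` so the lookup is total over positive heart rates.
#'
#' @return data.frame with columns `upper` (bpm, inclusive) and
#'   `correction` (ml).
#' @export
default_hr_table <- function() {
  data.frame(upper      = c(55, 65, 75, 90, 105, Inf),
             correction = c(-10, 0, 10, 20, 25, 30))
}

#' Body surface area from height and weight
#'
#' Two readings of the same printed formula are supported.  `"literal"`
#' computes `(height_cm * weight_kg / 3600) * 0.5` -- the arithmetic exactly
#' as printed in the device description, and the only reading that reproduces
#' the device's published worked example (163 ml for 115 kg / 185 cm /
#' 122 bpm).  `"mosteller"` computes `sqrt(height_cm * weight_kg / 3600)`,
#' the standard Mosteller BSA formula, on the view that the printed
#' "x 0.5" is a corrupted exponent.  Both modes are first-class; the package
#' default is `"literal"`.
#'
#' @param weight_kg body weight in kilograms, > 0.
#' @param height_cm body height in centimetres, > 0.
#' @param mode `"literal"` or `"mosteller"`.
#' @return BSA in m^2 (unrounded).  Vectorised over weight and height.
#' @examples
#' compute_bsa(80, 180, "mosteller")   # exactly 2
#' compute_bsa(115, 185, "literal")    # 2.9548...
#' @export
compute_bsa <- function(weight_kg, height_cm, mode = c("literal", "mosteller")) {
  mode <- match.arg(mode)
  assert_positive(weight_kg, "weight_kg")
  assert_positive(height_cm, "height_cm")
  hw <- height_cm * weight_kg / 3600
  switch(mode, literal = hw * 0.5, mosteller = sqrt(hw))
}

#' Heart-rate volume correction
#'
#' Piecewise-constant lookup in the configured correction table: the first
#' band whose inclusive upper bound is at or above the measured heart rate.
#'
#' @param heart_rate_bpm heart rate in beats per minute, > 0.  Vectorised.
#' @param config a [calculator_config()].
#' @return correction in ml.
#' @examples
#' hr_correction(c(50, 60, 122))
#' @export
hr_correction <- function(heart_rate_bpm, config = calculator_config()) {
  assert_positive(heart_rate_bpm, "heart_rate_bpm")
  idx <- findInterval(heart_rate_bpm, config$hr_table$upper,
                      left.open = TRUE) + 1L
  config$hr_table$correction[idx]
}

#' Iodine-concentration volume correction
#'
#' `((reference - concentration) / 10) * step` ml: positive below the
#' reference concentration, negative above it, scaling linearly between
#' multiples of 10 mg I/ml.
#'
#' @param concentration_mgI_ml stock iodine concentration, mg I/ml, > 0.
#' @param config a [calculator_config()].
#' @return correction in ml.
#' @examples
#' concentration_correction(c(320, 350, 370))  # +6, 0, -4
#' @export
concentration_correction <- function(concentration_mgI_ml,
                                     config = calculator_config()) {
  assert_positive(concentration_mgI_ml, "concentration_mgI_ml")
  (config$reference_concentration - concentration_mgI_ml) / 10 *
    config$concentration_step
}

#' Patient profile constructor
#'
#' @param weight_kg,height_cm,heart_rate_bpm body parameters, all > 0; the
#'   heart rate is a single pre-scan measurement and is stored as an integer.
#' @param sex `"male"` or `"female"` (metadata only).
#' @param age years (metadata only).
#' @param pathology `"aneurysm"`, `"dissection"` or `"other"` (metadata only).
#' @param group study arm: `"standard"` (fixed 120 ml), `"calculator"`, or
#'   `"calculator_diluted"`.
#' @param id optional identifier.
#' @return a one-row data.frame of class `patient_profile`.
#' @export
patient_profile <- function(weight_kg, height_cm, heart_rate_bpm,
                            sex = "male", age = NA_real_,
                            pathology = c("aneurysm", "dissection", "other"),
                            group = c("standard", "calculator",
                                      "calculator_diluted"),
                            id = NA_character_) {
  pathology <- match.arg(pathology)
  group <- match.arg(group)
  assert_positive(weight_kg, "weight_kg")
  assert_positive(height_cm, "height_cm")
  assert_positive(heart_rate_bpm, "heart_rate_bpm")
  out <- data.frame(id = id, weight_kg = weight_kg, height_cm = height_cm,
                    heart_rate_bpm = as.integer(round(heart_rate_bpm)),
                    sex = sex, age = age, pathology = pathology,
                    group = group, stringsAsFactors = FALSE)
  class(out) <- c("patient_profile", class(out))
  out
}

#' Calculate the individualized contrast dose for one patient
#'
#' The full injector algorithm: BSA x 45 ml/m^2 base dose, plus the
#' heart-rate and concentration corrections, summed exactly, rounded half-up
#' to whole ml, then clamped to the 40-150 ml administration window.  Every
#' intermediate term is recorded so the plan is a complete audit trail.
#'
#' @param weight_kg,height_cm,heart_rate_bpm patient parameters (> 0).
#' @param concentration_mgI_ml stock contrast concentration (default 350).
#' @param config a [calculator_config()]; `config$bsa_mode` selects the BSA
#'   reading.
#' @return a `dose_plan`: a list with fields `bsa`, `base_dose`,
#'   `hr_correction`, `concentration_correction`, `raw_dose` (pre-clamp,
#'   unrounded), `raw_dose_rounded`, `clamped_dose`, `final_dose`, `diluted`,
#'   `injection_rate`, `saline_flush`, plus the inputs.
#' @examples
#' plan <- calculate_dose(115, 185, 122)
#' plan$raw_dose_rounded  # 163
#' plan$final_dose        # 150 (clamped)
#' @export
calculate_dose <- function(weight_kg, height_cm, heart_rate_bpm,
                           concentration_mgI_ml = 350,
                           config = calculator_config()) {
  bsa <- compute_bsa(weight_kg, height_cm, config$bsa_mode)
  base <- bsa * config$dose_per_bsa
  hrc <- hr_correction(heart_rate_bpm, config)
  cc <- concentration_correction(concentration_mgI_ml, config)
  raw <- base + hrc + cc
  raw_rounded <- round_half_up(raw)
  clamped <- clamp(raw_rounded, config$min_dose, config$max_dose)
  structure(
    list(weight_kg = weight_kg, height_cm = height_cm,
         heart_rate_bpm = heart_rate_bpm,
         concentration_mgI_ml = concentration_mgI_ml,
         bsa_mode = config$bsa_mode,
         bsa = bsa, base_dose = base, hr_correction = hrc,
         concentration_correction = cc, raw_dose = raw,
         raw_dose_rounded = raw_rounded, clamped_dose = clamped,
         final_dose = clamped, diluted = FALSE,
         injection_rate = config$injection_rate,
         saline_flush = config$saline_flush),
    class = "dose_plan"
  )
}

#' Apply the 50% dilution arm to a dose plan
#'
#' The dilution arm administers `dilution_factor` (default one half) of the
#' clamped calculator dose, rounded half-up, but never less than the
#' `dilution_floor` (20 ml).  The clamped pre-dilution dose stays on record.
#' Diluting a plan twice is an error.
#'
#' @param plan a `dose_plan` from [calculate_dose()].
#' @param config a [calculator_config()].
#' @return the plan with `final_dose` replaced by the diluted volume and
#'   `diluted = TRUE`.
#' @examples
#' apply_dilution(calculate_dose(115, 185, 122))$final_dose  # 75
#' @export
apply_dilution <- function(plan, config = calculator_config()) {
  stopifnot(inherits(plan, "dose_plan"))
  if (isTRUE(plan$diluted)) stop_domain("plan is already diluted")
  if (any(plan$final_dose < config$min_dose |
            plan$final_dose > config$max_dose)) {
    stop_domain("plan final dose lies outside the clamp window; ",
                "dilution applies to a clamped plan")
  }
  plan$final_dose <- max(round_half_up(plan$clamped_dose *
                                         config$dilution_factor),
                         config$dilution_floor)
  plan$diluted <- TRUE
  plan
}

#' @export
print.dose_plan <- function(x, ...) {
  cat("Contrast dose plan (", x$bsa_mode, " BSA mode)\n", sep = "")
  cat(sprintf("  patient: %.1f kg, %.1f cm, %d bpm, %g mg I/ml\n",
              x$weight_kg, x$height_cm, as.integer(x$heart_rate_bpm),
              x$concentration_mgI_ml))
  cat(sprintf("  BSA:                      %.4f m^2\n", x$bsa))
  cat(sprintf("  base dose (45 ml/m^2):    %.2f ml\n", x$base_dose))
  cat(sprintf("  heart-rate correction:    %+g ml\n", x$hr_correction))
  cat(sprintf("  concentration correction: %+g ml\n",
              x$concentration_correction))
  cat(sprintf("  raw dose:                 %.2f ml -> %d ml\n",
              x$raw_dose, as.integer(x$raw_dose_rounded)))
  cat(sprintf("  clamped dose:             %d ml\n",
              as.integer(x$clamped_dose)))
  cat(sprintf("  final dose:               %d ml%s\n",
              as.integer(x$final_dose),
              if (x$diluted) " (diluted)" else ""))
  cat(sprintf("  injection: %g ml/s + %g ml saline flush\n",
              x$injection_rate, x$saline_flush))
  invisible(x)
}

#' Batch dose calculation over a patient table
#'
#' Runs [calculate_dose()] (and, for the `calculator_diluted` arm,
#' [apply_dilution()]) on every row of a cohort table.  Patients in the
#' `standard` arm receive the fixed protocol dose of 120 ml and bypass the
#' calculator entirely.
#'
#' @param patients data.frame with columns `weight_kg`, `height_cm`,
#'   `heart_rate_bpm`, and optionally `id`, `concentration_mgI_ml`
#'   (default 350) and `group` (default `"calculator"`).
#' @param config a [calculator_config()].
#' @param standard_dose fixed dose for the `standard` arm, ml (default 120).
#' @return the input columns plus one column per dose-plan field.
#' @examples
#' calculate_doses(data.frame(weight_kg = c(80, 115), height_cm = c(180, 185),
#'                            heart_rate_bpm = c(60, 122)))
#' @export
calculate_doses <- function(patients, config = calculator_config(),
                            standard_dose = 120) {
  stopifnot(is.data.frame(patients),
            all(c("weight_kg", "height_cm", "heart_rate_bpm") %in%
                  names(patients)))
  n <- nrow(patients)
  if (n == 0L) stop_domain("empty patient table")
  conc <- if ("concentration_mgI_ml" %in% names(patients)) {
    patients$concentration_mgI_ml
  } else rep(350, n)
  group <- if ("group" %in% names(patients)) as.character(patients$group) else {
    rep("calculator", n)
  }
  bad <- setdiff(unique(group),
                 c("standard", "calculator", "calculator_diluted"))
  if (length(bad)) stop_domain("unknown group(s): ", paste(bad, collapse = ", "))
  plans <- lapply(seq_len(n), function(i) {
    if (group[i] == "standard") {
      list(bsa = compute_bsa(patients$weight_kg[i], patients$height_cm[i],
                             config$bsa_mode),
           base_dose = NA_real_, hr_correction = NA_real_,
           concentration_correction = NA_real_, raw_dose = NA_real_,
           raw_dose_rounded = NA_real_, clamped_dose = NA_real_,
           final_dose = standard_dose, diluted = FALSE)
    } else {
      p <- calculate_dose(patients$weight_kg[i], patients$height_cm[i],
                          patients$heart_rate_bpm[i], conc[i], config)
      if (group[i] == "calculator_diluted") p <- apply_dilution(p, config)
      p
    }
  })
  fields <- c("bsa", "base_dose", "hr_correction", "concentration_correction",
              "raw_dose", "raw_dose_rounded", "clamped_dose", "final_dose",
              "diluted")
  out <- patients
  out$concentration_mgI_ml <- conc
  out$group <- group
  for (f in fields) out[[f]] <- vapply(plans, function(p) as.numeric(p[[f]]),
                                       numeric(1))
  out$diluted <- as.logical(out$diluted)
  out
}

#' Read / write cohort and dose tables as CSV
#'
#' The batch CSV schema has one row per patient with columns `id`,
#' `weight_kg`, `height_cm`, `heart_rate_bpm`, `concentration_mgI_ml`,
#' `group` (plus any metadata columns); dose output mirrors the input with
#' the dose-plan fields appended.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_patient_csv` returns a data.frame; `write_patient_csv`
#'   returns the path invisibly.  Writing is atomic (write-then-rename).
#' @export
read_patient_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("weight_kg", "height_cm", "heart_rate_bpm")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop_domain("patient CSV lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  x
}

#' @rdname read_patient_csv
#' @export
write_patient_csv <- function(x, path) {
  write_atomic(path, function(tmp) {
    utils::write.csv(x, tmp, row.names = FALSE)
  })
  invisible(path)
}
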