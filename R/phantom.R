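# Synthetic axial CT-like slices of an aorta and circular-ROI measurement,
# mirroring the study's quantitative measurement procedure: a circular ROI
# centred in the aorta (true lumen for dissection) and the mean HU over it.
#
# Conventions: the pixel grid is a numeric matrix in row-major order; pixel
# (i, j) is row i, column j, 0-based in the exported CSV, with the
# pixel-centre convention -- pixel (i, j) covers the physical point
# ((j - 1) * spacing, (i - 1) * spacing) at its centre.  Membership tests
# (lumen, flap, ROI) are by pixel centre; no partial-volume weighting.

#' Phantom slice geometry
#'
#' Describes one axial slice: a circular aortic lumen on a soft-tissue
#' background, an optional mural thrombus ring, and an optional dissection
#' flap.  The flap is a straight strip through the lumen; its offset from the
#' lumen centre is solved so the *true* lumen (the side measurements are
#' taken in) occupies `true_lumen_fraction` of the lumen area.
#'
#' @param grid_size pixels per side (square grid, default 128).
#' @param pixel_spacing_mm pixel size, mm (default 0.7).
#' @param center_mm lumen centre `c(x, y)` in mm; default the grid centre.
#' @param lumen_radius_mm lumen radius, mm.
#' @param thrombus_outer_mm outer radius of the thrombus ring, mm, or `NULL`
#'   for none; must exceed the lumen radius.
#' @param thrombus_hu thrombus attenuation (default 55 HU).
#' @param dissection `TRUE` adds an intimal flap.
#' @param flap_angle_deg flap orientation, degrees.
#' @param flap_thickness_mm flap thickness, mm.
#' @param flap_hu flap attenuation (default 45 HU).
#' @param true_lumen_fraction fraction of the lumen area on the true-lumen
#'   side, in (0, 1).
#' @param false_lumen_hu attenuation of the false lumen, or `NULL` to use
#'   60% of the rendered lumen enhancement.
#' @param background_hu soft-tissue background (default 40 HU).
#' @return an object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid_size = 128, pixel_spacing_mm = 0.7,
                             center_mm = NULL, lumen_radius_mm = 15,
                             thrombus_outer_mm = NULL, thrombus_hu = 55,
                             dissection = FALSE, flap_angle_deg = 30,
                             flap_thickness_mm = 1.4, flap_hu = 45,
                             true_lumen_fraction = 0.4,
                             false_lumen_hu = NULL, background_hu = 40) {
  stopifnot(grid_size >= 16, pixel_spacing_mm > 0, lumen_radius_mm > 0)
  extent <- (grid_size - 1) * pixel_spacing_mm
  if (is.null(center_mm)) center_mm <- c(extent / 2, extent / 2)
  if (!is.null(thrombus_outer_mm) && thrombus_outer_mm <= lumen_radius_mm) {
    stop_domain("thrombus outer radius must exceed the lumen radius")
  }
  if (dissection &&
      !(true_lumen_fraction > 0 && true_lumen_fraction < 1)) {
    stop_domain("true_lumen_fraction must lie strictly in (0, 1)")
  }
  outer <- if (is.null(thrombus_outer_mm)) lumen_radius_mm else {
    thrombus_outer_mm
  }
  if (center_mm[1] - outer < 0 || center_mm[2] - outer < 0 ||
      center_mm[1] + outer > extent || center_mm[2] + outer > extent) {
    stop_domain("geometry exceeds the pixel grid")
  }
  structure(list(grid_size = as.integer(grid_size),
                 pixel_spacing_mm = pixel_spacing_mm, center_mm = center_mm,
                 lumen_radius_mm = lumen_radius_mm,
                 thrombus_outer_mm = thrombus_outer_mm,
                 thrombus_hu = thrombus_hu, dissection = dissection,
                 flap_angle_deg = flap_angle_deg,
                 flap_thickness_mm = flap_thickness_mm, flap_hu = flap_hu,
                 true_lumen_fraction = true_lumen_fraction,
                 false_lumen_hu = false_lumen_hu,
                 background_hu = background_hu),
            class = "phantom_geometry")
}

# Signed offset d of the flap midline from the lumen centre such that the
# half-plane {s > d} holds `fraction` of the disc area.  Circular-segment
# area: A(d) = r^2 acos(d/r) - d sqrt(r^2 - d^2).
flap_offset <- function(radius, fraction) {
  target <- fraction * pi * radius^2
  stats::uniroot(function(d) {
    radius^2 * acos(clamp(d / radius, -1, 1)) -
      d * sqrt(pmax(radius^2 - d^2, 0)) - target
  }, interval = c(-radius, radius), tol = 1e-10)$root
}

#' Render a phantom slice
#'
#' Paints the geometry onto the pixel grid at the requested lumen
#' enhancement and adds independent Gaussian pixel noise.  In dissection
#' mode the true lumen receives `lumen_hu`, the false lumen
#' `false_lumen_hu`, and the flap strip `flap_hu`.
#'
#' @param geometry a [phantom_geometry()].
#' @param lumen_hu enhancement of the (true) lumen, HU.
#' @param noise_sd pixel noise SD, HU (0 for a noise-free slice).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @return a `phantom_slice`: list with `pixels` (matrix), `geometry`,
#'   `lumen_hu`, `noise_sd`, and logical masks `lumen_mask`,
#'   `true_lumen_mask` (equal to `lumen_mask` when not dissected).
#' @examples
#' slc <- render_slice(phantom_geometry(), lumen_hu = 200, noise_sd = 0)
#' mean(slc$pixels[slc$lumen_mask])
#' @export
render_slice <- function(geometry, lumen_hu, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(geometry, "phantom_geometry"), is.finite(lumen_hu),
            noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed)) {
    stop_domain("a seed is required when noise_sd > 0")
  }
  g <- geometry
  n <- g$grid_size
  sp <- g$pixel_spacing_mm
  xs <- ((seq_len(n)) - 1) * sp  # column centres (x), row centres (y)
  xmat <- matrix(xs, n, n, byrow = TRUE)
  ymat <- matrix(xs, n, n)
  dx <- xmat - g$center_mm[1]
  dy <- ymat - g$center_mm[2]
  r2 <- dx^2 + dy^2
  lumen <- r2 <= g$lumen_radius_mm^2
  pixels <- matrix(g$background_hu, n, n)
  if (!is.null(g$thrombus_outer_mm)) {
    ring <- r2 <= g$thrombus_outer_mm^2 & !lumen
    pixels[ring] <- g$thrombus_hu
  }
  true_mask <- lumen
  if (g$dissection) {
    theta <- g$flap_angle_deg * pi / 180
    s <- dx * cos(theta) + dy * sin(theta)   # signed distance to flap axis
    d <- flap_offset(g$lumen_radius_mm, g$true_lumen_fraction)
    flap <- lumen & abs(s - d) <= g$flap_thickness_mm / 2
    true_side <- lumen & (s - d) > g$flap_thickness_mm / 2
    false_side <- lumen & (s - d) < -g$flap_thickness_mm / 2
    fl_hu <- if (is.null(g$false_lumen_hu)) 0.6 * lumen_hu else {
      g$false_lumen_hu
    }
    pixels[false_side] <- fl_hu
    pixels[true_side] <- lumen_hu
    pixels[flap] <- g$flap_hu
    true_mask <- true_side
  } else {
    pixels[lumen] <- lumen_hu
  }
  if (noise_sd > 0) {
    pixels <- pixels + with_seed(seed, {
      matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    })
  }
  structure(list(pixels = pixels, geometry = g, lumen_hu = lumen_hu,
                 noise_sd = noise_sd, lumen_mask = lumen,
                 true_lumen_mask = true_mask),
            class = "phantom_slice")
}

#' Automatically place a circular ROI in the (true) lumen
#'
#' The ROI is centred at the centroid of the true-lumen pixel mask (the whole
#' lumen when there is no flap) with radius equal to `radius_fraction` of the
#' largest circle around that centroid that stays inside the mask --
#' deterministic given the slice, so repeated placements agree exactly.
#'
#' @param slice a `phantom_slice`.
#' @param radius_fraction fraction of the inscribed radius used (default
#'   0.6; a repo convention, the clinical ROI diameter is operator-chosen).
#' @param min_radius_mm smallest acceptable ROI radius; a true lumen too
#'   small to host it raises an error rather than silently shrinking.
#' @return a `roi_spec`: list with `center_mm` `c(x, y)`, `radius_mm`,
#'   `center_px` (0-based `c(col, row)`).
#' @export
auto_place_roi <- function(slice, radius_fraction = 0.6, min_radius_mm = 1.5) {
  stopifnot(inherits(slice, "phantom_slice"),
            radius_fraction > 0, radius_fraction <= 1)
  g <- slice$geometry
  sp <- g$pixel_spacing_mm
  mask <- slice$true_lumen_mask
  if (!any(mask)) stop_domain("true-lumen mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  cy <- (mean(idx[, "row"]) - 1) * sp
  cx <- (mean(idx[, "col"]) - 1) * sp
  # largest circle around the centroid inside the mask = distance from the
  # centroid to the nearest pixel centre outside the mask
  out_idx <- which(!mask, arr.ind = TRUE)
  d_out <- sqrt(((out_idx[, "col"] - 1) * sp - cx)^2 +
                  ((out_idx[, "row"] - 1) * sp - cy)^2)
  inscribed <- min(d_out)
  radius <- radius_fraction * inscribed
  if (radius < min_radius_mm) {
    stop_domain(sprintf(
      "true lumen too small for a %.1f mm ROI (inscribed radius %.2f mm)",
      min_radius_mm, inscribed))
  }
  structure(list(center_mm = c(cx, cy), radius_mm = radius,
                 center_px = c(cx, cy) / sp),
            class = "roi_spec")
}

#' Measure a circular ROI
#'
#' Mean, SD (n - 1) and pixel count over the pixels whose centres fall within
#' the ROI disc (boundary inclusive).
#'
#' @param slice a `phantom_slice`.
#' @param roi a `roi_spec` from [auto_place_roi()], or a list with
#'   `center_mm` and `radius_mm`.
#' @return list: `mean_hu`, `sd_hu`, `n_pixels`.
#' @examples
#' slc <- render_slice(phantom_geometry(), lumen_hu = 100, noise_sd = 0)
#' measure_roi(slc, auto_place_roi(slc))
#' @export
measure_roi <- function(slice, roi) {
  stopifnot(inherits(slice, "phantom_slice"),
            is.list(roi), !is.null(roi$center_mm), !is.null(roi$radius_mm))
  g <- slice$geometry
  n <- g$grid_size
  sp <- g$pixel_spacing_mm
  extent <- (n - 1) * sp
  if (roi$center_mm[1] - roi$radius_mm < 0 ||
      roi$center_mm[2] - roi$radius_mm < 0 ||
      roi$center_mm[1] + roi$radius_mm > extent ||
      roi$center_mm[2] + roi$radius_mm > extent) {
    stop_domain("ROI extends outside the pixel grid")
  }
  xs <- (seq_len(n) - 1) * sp
  xmat <- matrix(xs, n, n, byrow = TRUE)
  ymat <- matrix(xs, n, n)
  inside <- (xmat - roi$center_mm[1])^2 + (ymat - roi$center_mm[2])^2 <=
    roi$radius_mm^2
  vals <- slice$pixels[inside]
  if (length(vals) == 0L) stop_domain("ROI contains no pixel centres")
  list(mean_hu = mean(vals),
       sd_hu = if (length(vals) > 1L) stats::sd(vals) else 0,
       n_pixels = length(vals))
}

#' Export a slice
#'
#' `write_slice_csv` dumps the raw HU matrix (lossless, 0-based row-major
#' grid, one CSV row per pixel row).  `write_slice_png` writes a windowed
#' 8-bit grey PNG (requires the `png` package); DICOM is deliberately
#' unsupported.
#'
#' @param slice a `phantom_slice`.
#' @param path output file.
#' @param window `c(center, width)` HU display window for the PNG.
#' @return the path, invisibly.
#' @export
write_slice_csv <- function(slice, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(slice$pixels, tmp, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  })
  invisible(path)
}

#' @rdname write_slice_csv
#' @export
write_slice_png <- function(slice, path, window = c(150, 400)) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_domain("the `png` package is required for PNG export")
  }
  lo <- window[1] - window[2] / 2
  img <- clamp((slice$pixels - lo) / window[2], 0, 1)
  write_atomic(path, function(tmp) png::writePNG(img, tmp))
  invisible(path)
}
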