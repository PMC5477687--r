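#' Physical constants for radiative heat output
#'
#' Defaults are the values used throughout this method: human-skin
#' emissivity 0.98 and the Stefan-Boltzmann constant as 5.676e-8
#' W/(m^2 K^4). The latter is kept at this printed precision by default so
#' results reproduce the published arithmetic; pass the CODATA value if
#' preferred.
#'
#' @param emissivity dimensionless, in (0, 1].
#' @param sigma Stefan-Boltzmann constant, W/(m^2 K^4).
#' @return object of class `phys_constants`.
#' @export
phys_constants <- function(emissivity = 0.98, sigma = 5.676e-8) {
  if (emissivity <= 0 || emissivity > 1)
    stop("`emissivity` must be in (0, 1]", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  structure(list(emissivity = emissivity, sigma = sigma),
            class = "phys_constants")
}

#' Sequence-averaged ROI measurement
#'
#' The pair the radiative law consumes: mean ROI area in m^2 and mean ROI
#' temperature in Kelvin, each averaged across the frames of a 5 s video
#' sequence. Temperatures are validated against a physiological band
#' (300-315 K by default) to catch the classic Celsius-for-Kelvin unit bug;
#' disable with `validate = FALSE` for non-physiological inputs.
#'
#' @param side `"left"` or `"right"`.
#' @param area_m2 mean ROI area, m^2 (>= 0).
#' @param temp_k mean ROI temperature, Kelvin (> 0).
#' @param pixel_count mean ROI pixel count (optional bookkeeping).
#' @param n_frames number of frames averaged (optional bookkeeping).
#' @param validate check `temp_k` against `band`.
#' @param band plausible skin-temperature band in K.
#' @return object of class `roi_measurement`.
#' @export
roi_measurement <- function(side, area_m2, temp_k, pixel_count = NA_real_,
                            n_frames = NA_integer_, validate = TRUE,
                            band = c(300, 315)) {
  side <- match.arg(side, c("left", "right"))
  if (!is.finite(area_m2) || area_m2 < 0)
    stop("`area_m2` must be >= 0", call. = FALSE)
  if (!is.finite(temp_k) || temp_k <= 0)
    stop("`temp_k` must be positive (Kelvin)", call. = FALSE)
  if (validate && (temp_k < band[1] || temp_k > band[2]))
    stop(sprintf(paste0("`temp_k` = %.2f K is outside the physiological band ",
                        "[%g, %g] K - was a Celsius value passed where Kelvin ",
                        "is expected? (use validate = FALSE to override)"),
                 temp_k, band[1], band[2]), call. = FALSE)
  structure(list(side = side, area_m2 = area_m2, temp_k = temp_k,
                 pixel_count = pixel_count, n_frames = n_frames),
            class = "roi_measurement")
}

#' Convert Celsius to Kelvin
#'
#' @param temp_c temperature(s) in degrees C.
#' @return temperature(s) in Kelvin (`temp_c + 273.15`).
#' @export
c_to_k <- function(temp_c) temp_c + 273.15

#' Radiated heat output of one ROI (Stefan-Boltzmann law)
#'
#' `W = emissivity * sigma * A * T^4`, with `A` the mean ROI area in m^2 and
#' `T` the mean ROI temperature in Kelvin.
#'
#' @param m a [roi_measurement()].
#' @param constants a [phys_constants()].
#' @return radiated power in watts.
#' @export
heat_output <- function(m, constants = phys_constants()) {
  if (!inherits(m, "roi_measurement"))
    stop("`m` must be a roi_measurement", call. = FALSE)
  constants$emissivity * constants$sigma * m$area_m2 * m$temp_k^4
}

#' Total heat output of the left and right ROIs
#'
#' @param left_w,right_w per-side radiated power in watts (>= 0).
#' @return their sum, watts.
#' @export
total_heat <- function(left_w, right_w) {
  if (!is.finite(left_w) || !is.finite(right_w) || left_w < 0 || right_w < 0)
    stop("heat outputs must be finite and >= 0", call. = FALSE)
  left_w + right_w
}

#' Percent change in heat output from baseline
#'
#' @param baseline_w baseline power, watts (> 0).
#' @param stimulated_w stimulated power, watts.
#' @return `100 * (stimulated_w - baseline_w) / baseline_w`.
#' @export
percent_change_heat <- function(baseline_w, stimulated_w) {
  if (!is.finite(baseline_w) || baseline_w <= 0)
    stop("`baseline_w` must be positive", call. = FALSE)
  100 * (stimulated_w - baseline_w) / baseline_w
}

#' Quantify one side's heat output from a sequence, end to end
#'
#' Convenience pipeline for a single search window: segment every frame
#' ([segment_sequence()]), calibrate ([calibrate_sequence()]), convert the
#' sequence-mean ROI into metric area and Kelvin, and apply the radiative
#' law. Area is averaged per frame through the calibration (mean of
#' per-frame mask areas), matching the mean-pixel-count bookkeeping.
#'
#' Two orders of averaging are reported: `watts` applies the law to the
#' sequence-averaged (A, T) — the method's published order — while
#' `watts_per_frame_mean` averages per-frame powers. The two differ through
#' the T^4 nonlinearity; the first is the default interpretation.
#'
#' @param seq a [thermal_sequence()].
#' @param window a [search_window()].
#' @param params a [seg_params()].
#' @param layout a [fiducial_layout()].
#' @param constants a [phys_constants()].
#' @param transform optional pre-computed [estimate_transform()] result;
#'   when `NULL` the sequence is calibrated from its first frame.
#' @param mask_band fiducial band masked out of the window before
#'   segmentation (see [segment_sequence()]).
#' @return list with `side`, `measurement` (a [roi_measurement()]), `watts`,
#'   `watts_per_frame_mean`, `segmentation`, `transform`.
#' @export
quantify_sequence <- function(seq, window, params, layout = fiducial_layout(),
                              constants = phys_constants(), transform = NULL,
                              mask_band = c(28, 31)) {
  segres <- segment_sequence(seq, window, params, mask_band = mask_band)
  if (is.null(transform)) transform <- calibrate_sequence(seq, layout)
  areas <- temps <- rep(NA_real_, length(segres$frames))
  for (i in seq_along(segres$frames)) {
    f <- segres$frames[[i]]
    if (is.null(f)) next
    areas[i] <- roi_area_m2(f$mask, transform)
    temps[i] <- f$mean_temp_c
  }
  used <- which(!is.na(areas))
  mean_area <- mean(areas[used])
  mean_temp_k <- c_to_k(mean(temps[used]))
  m <- roi_measurement(window$side, mean_area, mean_temp_k,
                       pixel_count = segres$mean_pixel_count,
                       n_frames = length(used), validate = FALSE)
  w_pf <- constants$emissivity * constants$sigma *
    mean(areas[used] * c_to_k(temps[used])^4)
  list(side = window$side, measurement = m,
       watts = heat_output(m, constants),
       watts_per_frame_mean = w_pf,
       segmentation = segres, transform = transform)
}
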