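#' Specify a synthetic hotspot
#'
#' A warm elliptical plateau emulating the skin area over an active
#' supraclavicular BAT depot: flat interior at `background + delta_t_c`,
#' falling to background over a sigmoid edge of configurable width. The
#' sharp edge is deliberate — the region-growing detector keys on an abrupt
#' dermal temperature gradient, which a smooth Gaussian bump lacks.
#'
#' @param center `c(row, col)` centre in pixels (frame 1; drift moves it).
#' @param semi_axes `c(a_row, a_col)` ellipse semi-axes in pixels (> 0).
#' @param delta_t_c plateau height above background, degrees C (>= 0).
#' @param edge_width_px sigmoid edge width in pixels (smaller = sharper);
#'   `0` renders an exact step edge, the limit case in which the true
#'   plateau mask is unambiguous (used by the recovery tests).
#' @param side `"left"` or `"right"` label.
#' @return object of class `hotspot_spec`.
#' @export
hotspot_spec <- function(center, semi_axes, delta_t_c,
                         edge_width_px = 0.4, side = c("left", "right")) {
  side <- match.arg(side)
  if (any(semi_axes <= 0)) stop("`semi_axes` must be positive", call. = FALSE)
  if (delta_t_c < 0) stop("`delta_t_c` must be >= 0", call. = FALSE)
  if (edge_width_px < 0) stop("`edge_width_px` must be >= 0", call. = FALSE)
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 delta_t_c = delta_t_c, edge_width_px = edge_width_px,
                 side = side),
            class = "hotspot_spec")
}

#' Specify a synthetic thermogram scene
#'
#' Describes everything [generate_sequence()] renders: a warm skin
#' background (optionally with a linear gradient), zero or more hotspots,
#' four cool fiducial disks placed at the corners of the physical layout
#' rectangle under a known pixel-per-cm scale (so the true pixel-to-metric
#' transform is available as ground truth), Gaussian pixel noise, and slow
#' rigid pose drift.
#'
#' @param dims `c(rows, cols)` frame size in pixels.
#' @param background_c background skin temperature, degrees C (default 33).
#' @param background_gradient `c(per_row, per_col)` linear trend in degrees C
#'   per pixel (default none).
#' @param layout a [fiducial_layout()]; disk centres in cm.
#' @param px_per_cm pixels per cm (uniform frontal-view scale; default 4).
#' @param origin_px `c(row, col)` pixel position of the layout origin
#'   (cm point (0, 0)).
#' @param fiducial_temp_c disk temperature, degrees C (default 29.5,
#'   mid-band of the 28-31 C foil disks).
#' @param hotspots list of [hotspot_spec()] (may be empty).
#' @param noise_sd_c Gaussian pixel noise standard deviation, degrees C.
#' @param drift_px_per_frame `c(row, col)` rigid scene translation per frame
#'   in pixels (default none).
#' @param n_frames number of frames (>= 1; default 150, i.e. 5 s at 30 Hz).
#' @param frame_rate_hz frame rate (default 30).
#' @param seed RNG seed making generation deterministic.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(dims = c(96, 128), background_c = 33,
                       background_gradient = c(0, 0),
                       layout = fiducial_layout(), px_per_cm = 4,
                       origin_px = c(24, 24), fiducial_temp_c = 29.5,
                       hotspots = list(), noise_sd_c = 0.1,
                       drift_px_per_frame = c(0, 0), n_frames = 150L,
                       frame_rate_hz = 30, seed = 1L) {
  if (length(dims) != 2L || any(dims < 1)) stop("bad `dims`", call. = FALSE)
  if (noise_sd_c < 0) stop("`noise_sd_c` must be >= 0", call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("`n_frames` must be >= 1", call. = FALSE)
  if (!is.list(hotspots) ||
      !all(vapply(hotspots, inherits, logical(1), "hotspot_spec")))
    stop("`hotspots` must be a list of hotspot_spec", call. = FALSE)
  spec <- structure(list(dims = as.integer(dims), background_c = background_c,
                         background_gradient = as.numeric(background_gradient),
                         layout = layout, px_per_cm = px_per_cm,
                         origin_px = as.numeric(origin_px),
                         fiducial_temp_c = fiducial_temp_c,
                         hotspots = hotspots, noise_sd_c = noise_sd_c,
                         drift_px_per_frame = as.numeric(drift_px_per_frame),
                         n_frames = n_frames, frame_rate_hz = frame_rate_hz,
                         seed = as.integer(seed)),
                    class = "scene_spec")
  check_no_overlap(spec)
  spec
}

# fiducial disk centres in pixel coords (row, col) for frame 1
fiducial_centers_px <- function(spec) {
  cm <- spec$layout$points_cm
  cbind(row = spec$origin_px[1L] + cm[, "y_cm"] * spec$px_per_cm,
        col = spec$origin_px[2L] + cm[, "x_cm"] * spec$px_per_cm)
}

check_no_overlap <- function(spec) {
  ctr <- fiducial_centers_px(spec)
  r_fid <- spec$layout$disk_diameter_mm / 20 * spec$px_per_cm  # radius in px
  for (h in spec$hotspots) {
    # conservative circumscribed-circle test around the ellipse
    r_hot <- max(h$semi_axes) + 3 * h$edge_width_px
    d <- sqrt((ctr[, "row"] - h$center[1L])^2 + (ctr[, "col"] - h$center[2L])^2)
    if (any(d <= r_hot + r_fid))
      stop("hotspot overlaps a fiducial disk; this would confound calibration",
           call. = FALSE)
  }
  invisible(spec)
}

#' Generate a synthetic thermal sequence with ground truth
#'
#' Renders each frame deterministically from the scene specification and
#' seed: background plus gradient, sigmoid-edged hotspot plateaus, cool
#' fiducial disks, i.i.d. Gaussian pixel noise, and a rigid translation of
#' the whole scene by `drift_px_per_frame` per frame. Ground truth returned
#' alongside: the per-frame true plateau masks (pixel centres inside each
#' ellipse) and the exact pixel-to-cm transform per frame.
#'
#' @param spec a [scene_spec()].
#' @return list with:
#'   * `sequence`: a [thermal_sequence()];
#'   * `truth_masks`: list (frames) of lists (hotspots) of logical matrices;
#'   * `transforms`: list of true `planar_transform` objects, one per frame;
#'   * `spec`: the input spec.
#' @export
generate_sequence <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("`spec` must be a scene_spec", call. = FALSE)
  nr <- spec$dims[1L]; nc <- spec$dims[2L]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  fid_ctr0 <- fiducial_centers_px(spec)
  r_fid <- spec$layout$disk_diameter_mm / 20 * spec$px_per_cm
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  frames <- vector("list", spec$n_frames)
  truth_masks <- vector("list", spec$n_frames)
  transforms <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    shift <- spec$drift_px_per_frame * (k - 1L)
    v <- spec$background_c +
      spec$background_gradient[1L] * (rows - 1) +
      spec$background_gradient[2L] * (cols - 1)
    masks_k <- vector("list", length(spec$hotspots))
    for (j in seq_along(spec$hotspots)) {
      h <- spec$hotspots[[j]]
      cr <- h$center[1L] + shift[1L]; cc <- h$center[2L] + shift[2L]
      de <- sqrt(((rows - cr) / h$semi_axes[1L])^2 +
                 ((cols - cc) / h$semi_axes[2L])^2)
      if (h$edge_width_px == 0) {          # exact step edge
        v <- v + h$delta_t_c * (de <= 1)
      } else {
        # signed pixel distance from the ellipse boundary (outward positive)
        dpx <- (de - 1) * sqrt(prod(h$semi_axes))
        v <- v + h$delta_t_c / (1 + exp(dpx / h$edge_width_px))
      }
      masks_k[[j]] <- de <= 1
    }
    ctr <- fid_ctr0 + rep(shift, each = 4L)
    for (i in 1:4) {
      disk <- (rows - ctr[i, 1L])^2 + (cols - ctr[i, 2L])^2 <= r_fid^2
      v[disk] <- spec$fiducial_temp_c
    }
    if (spec$noise_sd_c > 0)
      v <- v + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd_c), nr, nc)
    frames[[k]] <- thermal_frame(v, frame_index = k - 1L, validate = FALSE)
    truth_masks[[k]] <- masks_k
    # true pixel (x=col, y=row) -> cm transform for this frame
    s <- spec$px_per_cm
    Ht <- matrix(c(1 / s, 0, -(spec$origin_px[2L] + shift[2L]) / s,
                   0, 1 / s, -(spec$origin_px[1L] + shift[1L]) / s,
                   0, 0, 1), 3L, 3L, byrow = TRUE)
    transforms[[k]] <- structure(list(matrix = Ht, residual_cm = 0,
                                      pixel_pts = NULL, layout = spec$layout),
                                 class = "planar_transform")
  }
  list(sequence = thermal_sequence(frames, frame_rate_hz = spec$frame_rate_hz),
       truth_masks = truth_masks, transforms = transforms, spec = spec)
}

#' Simulate a subject cohort with known responder labels
#'
#' Draws per-subject baseline total heat outputs and percent changes under
#' stimulation from a two-component mixture: non-responders (low-BAT) and
#' responders (high-BAT) whose percent change is shifted upward. Ground
#' truth labels are returned so classifier recovery can be scored. Defaults
#' emulate the study conditions: 24 subjects, a quarter of them responders,
#' baseline total heat near 1.5 W, and group mean changes back-computed from
#' the reported group-level heat deltas over that baseline.
#'
#' @param n_subjects number of subjects (>= 2; default 24).
#' @param responder_fraction fraction of responders in `[0, 1]`
#'   (default 0.25).
#' @param baseline_mean_w,baseline_sd_w baseline total heat output (W).
#' @param nonresponder_pct_mean,nonresponder_pct_sd percent-change
#'   distribution of non-responders (default 43 +/- 15).
#' @param responder_pct_mean,responder_pct_sd percent-change distribution of
#'   responders (default 85 +/- 15).
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `baseline_w`, `stimulated_w`,
#'   `pct_change`, `true_responder` (logical).
#' @export
generate_cohort <- function(n_subjects = 24L, responder_fraction = 0.25,
                            baseline_mean_w = 1.5, baseline_sd_w = 0.3,
                            nonresponder_pct_mean = 43,
                            nonresponder_pct_sd = 15,
                            responder_pct_mean = 85, responder_pct_sd = 15,
                            seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("`responder_fraction` must be in [0, 1]", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  n_resp <- round(responder_fraction * n_subjects)
  truth <- sample(rep(c(TRUE, FALSE), c(n_resp, n_subjects - n_resp)))
  baseline <- pmax(stats::rnorm(n_subjects, baseline_mean_w, baseline_sd_w), 0.1)
  pct <- ifelse(truth,
                stats::rnorm(n_subjects, responder_pct_mean, responder_pct_sd),
                stats::rnorm(n_subjects, nonresponder_pct_mean,
                             nonresponder_pct_sd))
  data.frame(subject = seq_len(n_subjects),
             baseline_w = baseline,
             stimulated_w = baseline * (1 + pct / 100),
             pct_change = pct,
             true_responder = truth)
}
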