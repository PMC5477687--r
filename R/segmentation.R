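#' Define a rectangular search window
#'
#' Designates the pre-defined image area overlying the left or right
#' cervical-supraclavicular (C-SCV) region. The hottest pixel inside the
#' window seeds the region growth, and growth is confined to the window.
#' Bounds are inclusive-exclusive: rows `r0 <= r < r1`, columns
#' `c0 <= c < c1`, 1-based.
#'
#' @param r0,r1,c0,c1 window bounds (1-based, `r1`/`c1` exclusive).
#' @param side `"left"` or `"right"`, the body side the window covers.
#' @return object of class `search_window`.
#' @export
search_window <- function(r0, r1, c0, c1, side = c("left", "right")) {
  side <- match.arg(side)
  r0 <- as.integer(r0); r1 <- as.integer(r1)
  c0 <- as.integer(c0); c1 <- as.integer(c1)
  if (r1 <= r0 || c1 <= c0 || r0 < 1L || c0 < 1L)
    stop("window must be non-empty with 1-based bounds", call. = FALSE)
  structure(list(r0 = r0, r1 = r1, c0 = c0, c1 = c1, side = side),
            class = "search_window")
}

check_window <- function(window, frame) {
  if (!inherits(window, "search_window")) stop("not a search_window", call. = FALSE)
  if (window$r1 - 1L > nrow(frame) || window$c1 - 1L > ncol(frame))
    stop("window exceeds frame bounds", call. = FALSE)
  invisible(window)
}

#' Segmentation parameters for seeded region growing
#'
#' @param t_t admission tolerance in degrees C (>= 0): growth stops once the
#'   best frontier pixel's absolute deviation from the running region mean
#'   exceeds `t_t`. The study tuned this per subject; see [auto_tolerance()]
#'   for a reproducible surrogate.
#' @param seed_region_radius Chebyshev radius (pixels, >= 0) of the initial
#'   seed neighbourhood; the default 1 gives a 3x3 patch, the smallest
#'   neighbourhood with a stable mean.
#' @param max_region_fraction cap on region size as a fraction of the pixels
#'   being searched, guarding runaway growth on low-contrast frames.
#' @return object of class `seg_params`.
#' @export
seg_params <- function(t_t, seed_region_radius = 1L, max_region_fraction = 0.5) {
  if (!is.numeric(t_t) || length(t_t) != 1L || is.na(t_t) || t_t < 0)
    stop("`t_t` must be a single number >= 0", call. = FALSE)
  seed_region_radius <- as.integer(seed_region_radius)
  if (seed_region_radius < 0L) stop("`seed_region_radius` must be >= 0", call. = FALSE)
  if (max_region_fraction <= 0 || max_region_fraction > 1)
    stop("`max_region_fraction` must be in (0, 1]", call. = FALSE)
  structure(list(t_t = t_t, seed_region_radius = seed_region_radius,
                 connectivity = 8L, max_region_fraction = max_region_fraction),
            class = "seg_params")
}

#' Select the seed pixel: hottest valid pixel in the search window
#'
#' Ties are broken deterministically in favour of the smallest `(row, col)`
#' in row-major order, so segmentation is bit-reproducible.
#'
#' @param frame a [thermal_frame()] or numeric matrix.
#' @param window a [search_window()]; `NULL` searches the whole frame.
#' @return integer vector `c(row, col)` (1-based, frame coordinates).
#' @export
select_seed <- function(frame, window = NULL) {
  if (is.null(window))
    window <- search_window(1L, nrow(frame) + 1L, 1L, ncol(frame) + 1L)
  check_window(window, frame)
  rows <- window$r0:(window$r1 - 1L)
  cols <- window$c0:(window$c1 - 1L)
  sub <- unclass(frame)[rows, cols, drop = FALSE]
  sub[!frame_valid(frame)[rows, cols, drop = FALSE]] <- -Inf
  if (all(sub == -Inf)) stop("window contains no valid pixel", call. = FALSE)
  mx <- max(sub)
  # row-major tie-break: scan candidate rows first, then columns
  hits <- which(sub == mx, arr.ind = TRUE)
  ord <- order(hits[, 1L], hits[, 2L])
  best <- hits[ord[1L], ]
  c(rows[best[1L]], cols[best[2L]])
}

# 8-neighbour offsets, row-major order
.n8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
             dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Grow a region from a seed by modified seeded region growing
#'
#' Starting from the valid pixels within Chebyshev radius
#' `seed_region_radius` of the seed, the algorithm repeatedly considers the
#' frontier `H` — all unallocated valid pixels 8-adjacent to the region —
#' computes each frontier pixel's absolute deviation
#' `delta(x) = |T(x) - mean(region)|` from the running region mean, and
#' admits the pixel with the smallest deviation, provided that deviation
#' does not exceed the tolerance `t_t`. The region mean is updated after
#' every admission, so the acceptance test always uses the current mean.
#' Growth stops when the best frontier deviation exceeds `t_t`, the
#' frontier empties, or the region reaches `max_region_fraction` of the
#' searched pixels. Equal deviations are resolved toward the smallest
#' `(row, col)` in row-major order.
#'
#' @param frame a [thermal_frame()] or numeric matrix (degrees C).
#' @param seed integer `c(row, col)` seed coordinate (1-based).
#' @param params a [seg_params()].
#' @param window optional [search_window()] confining growth; default is the
#'   whole frame.
#' @return object of class `thermo_region`: list with `pixels` (n x 2 matrix
#'   of row/col), `mask` (logical matrix, frame-sized), `mean_temp_c`,
#'   `size`, `seed`, and `stopped_by` (one of `"tolerance"`, `"frontier"`,
#'   `"cap"`).
#' @export
grow_region <- function(frame, seed, params, window = NULL) {
  vals <- unclass(frame)
  nr <- nrow(vals); nc <- ncol(vals)
  seed <- as.integer(seed)
  if (length(seed) != 2L || any(is.na(seed)) ||
      seed[1L] < 1L || seed[1L] > nr || seed[2L] < 1L || seed[2L] > nc)
    stop("seed outside frame", call. = FALSE)
  if (!inherits(params, "seg_params")) stop("`params` must be seg_params", call. = FALSE)
  valid <- frame_valid(frame)
  inside <- matrix(FALSE, nr, nc)
  if (is.null(window)) {
    inside[] <- TRUE
  } else {
    check_window(window, frame)
    inside[window$r0:(window$r1 - 1L), window$c0:(window$c1 - 1L)] <- TRUE
  }
  admissible <- valid & inside
  if (!admissible[seed[1L], seed[2L]])
    stop("seed pixel is invalid or outside the window", call. = FALSE)
  max_size <- max(1L, floor(params$max_region_fraction * sum(inside)))

  # initial seed neighbourhood: valid pixels within the Chebyshev radius
  rad <- params$seed_region_radius
  r_rng <- max(1L, seed[1L] - rad):min(nr, seed[1L] + rad)
  c_rng <- max(1L, seed[2L] - rad):min(nc, seed[2L] + rad)
  in_region <- matrix(FALSE, nr, nc)
  for (r in r_rng) for (c in c_rng)
    if (admissible[r, c]) in_region[r, c] <- TRUE
  # states: 0 free, 1 region, 2 frontier
  reg_idx <- which(in_region, arr.ind = TRUE)
  reg_sum <- sum(vals[in_region])
  reg_n <- nrow(reg_idx)

  # frontier kept as parallel vectors (row, col, temp)
  fr_r <- integer(0); fr_c <- integer(0); fr_t <- numeric(0)
  in_frontier <- matrix(FALSE, nr, nc)
  push_neighbours <- function(r0, c0) {
    for (k in 1:8) {
      r <- r0 + .n8[k, 1L]; c <- c0 + .n8[k, 2L]
      if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
          admissible[r, c] && !in_region[r, c] && !in_frontier[r, c]) {
        in_frontier[r, c] <<- TRUE
        fr_r[length(fr_r) + 1L] <<- r
        fr_c[length(fr_c) + 1L] <<- c
        fr_t[length(fr_t) + 1L] <<- vals[r, c]
      }
    }
  }
  for (i in seq_len(reg_n)) push_neighbours(reg_idx[i, 1L], reg_idx[i, 2L])

  stopped_by <- "frontier"
  while (length(fr_r) > 0L) {
    if (reg_n >= max_size) { stopped_by <- "cap"; break }
    mu <- reg_sum / reg_n
    delta <- abs(fr_t - mu)
    dmin <- min(delta)
    if (dmin > params$t_t) { stopped_by <- "tolerance"; break }
    cand <- which(delta == dmin)
    if (length(cand) > 1L) {   # row-major tie-break
      cand <- cand[order(fr_r[cand], fr_c[cand])[1L]]
    }
    zr <- fr_r[cand]; zc <- fr_c[cand]
    fr_r <- fr_r[-cand]; fr_c <- fr_c[-cand]; fr_t <- fr_t[-cand]
    in_frontier[zr, zc] <- FALSE
    in_region[zr, zc] <- TRUE
    reg_sum <- reg_sum + vals[zr, zc]
    reg_n <- reg_n + 1L
    push_neighbours(zr, zc)
  }

  pixels <- which(in_region, arr.ind = TRUE)
  dimnames(pixels) <- list(NULL, c("row", "col"))
  structure(list(pixels = pixels[order(pixels[, 1L], pixels[, 2L]), , drop = FALSE],
                 mask = in_region, mean_temp_c = reg_sum / reg_n,
                 size = reg_n, seed = seed, stopped_by = stopped_by),
            class = "thermo_region")
}

#' @export
print.thermo_region <- function(x, ...) {
  cat(sprintf("<thermo_region> %d px, mean %.3f C, seed (%d, %d), stopped by %s\n",
              x$size, x$mean_temp_c, x$seed[1L], x$seed[2L], x$stopped_by))
  invisible(x)
}

#' Threshold-segmentation baseline
#'
#' The earlier-generation detector this package's region growing improves
#' on: threshold at the median of the hottest 25% of window pixels and keep
#' every pixel at or above it. Spatial connectivity is deliberately NOT
#' enforced — the scattered clusters it yields on realistic scenes are the
#' baseline's documented weakness.
#'
#' @param frame a [thermal_frame()] or numeric matrix.
#' @param window a [search_window()]; `NULL` uses the whole frame.
#' @return list with `pixels` (n x 2 row/col matrix), `mask`, `threshold_c`.
#' @export
threshold_segment <- function(frame, window = NULL) {
  if (is.null(window))
    window <- search_window(1L, nrow(frame) + 1L, 1L, ncol(frame) + 1L)
  check_window(window, frame)
  rows <- window$r0:(window$r1 - 1L)
  cols <- window$c0:(window$c1 - 1L)
  sub <- unclass(frame)[rows, cols, drop = FALSE]
  ok <- frame_valid(frame)[rows, cols, drop = FALSE]
  v <- sub[ok]
  if (length(v) < 4L)
    stop("window must contain at least 4 valid pixels", call. = FALSE)
  k <- ceiling(0.25 * length(v))
  top <- sort(v, decreasing = TRUE)[seq_len(k)]
  thr <- stats::median(top)
  mask <- matrix(FALSE, nrow(frame), ncol(frame))
  sel <- ok & sub >= thr
  mask[rows, cols] <- sel
  pixels <- which(mask, arr.ind = TRUE)
  dimnames(pixels) <- list(NULL, c("row", "col"))
  list(pixels = pixels[order(pixels[, 1L], pixels[, 2L]), , drop = FALSE],
       mask = mask, threshold_c = thr)
}

#' Segment every frame of a sequence and average the ROI statistics
#'
#' Re-selects the seed and grows the region independently on each frame,
#' then averages the per-frame ROI pixel count and mean ROI temperature
#' arithmetically across frames — the 5 s / 150-frame averaging the video
#' protocol prescribes. Pixels inside fiducial-disk temperature band can be
#' masked out of the window beforehand via `mask_band` so the cool disks
#' never distort growth.
#'
#' @param seq a [thermal_sequence()].
#' @param window a [search_window()].
#' @param params a [seg_params()].
#' @param mask_band optional length-2 numeric; window pixels inside this
#'   temperature band (degrees C) are treated as invalid (default the
#'   fiducial band `c(28, 31)`; use `NULL` to disable).
#' @return object of class `sequence_segmentation`: list with `frames` (list
#'   of per-frame results: `mask`, `pixel_count`, `mean_temp_c`, `seed`,
#'   `t_t`, or `NULL` where a frame was unsegmentable), `mean_pixel_count`,
#'   `mean_roi_temp_c`, `n_frames_used`, `side`.
#' @export
segment_sequence <- function(seq, window, params, mask_band = c(28, 31)) {
  if (!inherits(seq, "thermal_sequence")) stop("`seq` must be a thermal_sequence", call. = FALSE)
  if (length(seq$frames) == 0L) stop("empty sequence", call. = FALSE)
  per_frame <- vector("list", length(seq$frames))
  counts <- temps <- rep(NA_real_, length(seq$frames))
  for (i in seq_along(seq$frames)) {
    fr <- seq$frames[[i]]
    if (!is.null(mask_band)) {
      v <- unclass(fr)
      inband <- is.finite(v) & v >= mask_band[1] & v <= mask_band[2]
      if (any(inband)) {
        inv <- attr(fr, "invalid") | inband
        fr <- structure(v, frame_index = attr(fr, "frame_index"),
                        invalid = inv, class = class(fr))
      }
    }
    res <- tryCatch({
      seed <- select_seed(fr, window)
      reg <- grow_region(fr, seed, params, window = window)
      list(mask = roi_mask(reg$mask, frame_index = i - 1L),
           pixel_count = reg$size, mean_temp_c = reg$mean_temp_c,
           seed = seed, t_t = params$t_t)
    }, error = function(e) {
      warning(sprintf("frame %d unsegmentable (%s); excluded from the average",
                      i, conditionMessage(e)), call. = FALSE)
      NULL
    })
    per_frame[[i]] <- res
    if (!is.null(res)) { counts[i] <- res$pixel_count; temps[i] <- res$mean_temp_c }
  }
  used <- which(!is.na(counts))
  if (length(used) == 0L) stop("no frame could be segmented", call. = FALSE)
  structure(list(frames = per_frame,
                 mean_pixel_count = mean(counts[used]),
                 mean_roi_temp_c = mean(temps[used]),
                 n_frames_used = length(used),
                 side = window$side),
            class = "sequence_segmentation")
}

#' @export
print.sequence_segmentation <- function(x, ...) {
  cat(sprintf("<sequence_segmentation> side %s: %d/%d frames, mean ROI %.1f px at %.3f C\n",
              x$side, x$n_frames_used, length(x$frames),
              x$mean_pixel_count, x$mean_roi_temp_c))
  invisible(x)
}

#' Reproducible surrogate for per-subject tolerance tuning
#'
#' The study tuned the admission tolerance by hand for each subject. As a
#' reproducible automatic surrogate, this scans a grid of tolerances,
#' records the grown region size at each, and returns the midpoint of the
#' flattest run of the size-versus-tolerance curve — the widest plateau over
#' which the segmentation is insensitive to the tolerance. An extension to
#' the original manual procedure, not a reproduction of it.
#'
#' @param frame a [thermal_frame()] or matrix.
#' @param window a [search_window()].
#' @param grid tolerance grid to scan (degrees C, increasing).
#' @param params base [seg_params()] supplying radius and cap.
#' @return list with `t_t` (chosen tolerance), `grid`, `sizes`.
#' @export
auto_tolerance <- function(frame, window, grid = seq(0.1, 3, by = 0.1),
                           params = seg_params(0)) {
  seed <- select_seed(frame, window)
  sizes <- vapply(grid, function(tt) {
    p <- seg_params(tt, params$seed_region_radius, params$max_region_fraction)
    grow_region(frame, seed, p, window = window)$size
  }, numeric(1))
  # longest run of constant size = flattest plateau; ties -> first (smallest t_t)
  r <- rle(sizes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- which.max(r$lengths)
  pick <- starts[best] + (r$lengths[best] - 1L) %/% 2L
  list(t_t = grid[pick], grid = grid, sizes = sizes)
}
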