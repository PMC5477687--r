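#' Construct a single thermal frame
#'
#' A thermal frame is one time point's grid of skin temperatures in degrees
#' Celsius, stored as a numeric matrix. Non-finite entries (NA/NaN/Inf) mark
#' invalid pixels (dead detector elements); they are excluded from seed
#' selection, region growth and all region statistics downstream. Finite
#' values outside the plausible skin-temperature band raise a warning and are
#' flagged, not altered.
#'
#' @param values numeric matrix of temperatures in degrees C.
#' @param frame_index non-negative integer position of the frame in its
#'   sequence (0-based; purely bookkeeping).
#' @param band length-2 numeric, the plausible temperature band in degrees C.
#'   Defaults to 5-45 C, generous for human skin plus cool fiducial disks.
#' @param validate logical; set `FALSE` to skip band checking (used
#'   internally on frames already validated).
#' @return an object of class `thermal_frame`: the matrix with attributes
#'   `frame_index` and `invalid` (logical matrix of non-finite or
#'   out-of-band pixels).
#' @export
thermal_frame <- function(values, frame_index = 0L, band = c(5, 45),
                          validate = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("frame must have at least one pixel", call. = FALSE)
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L)
    stop("`frame_index` must be a non-negative integer", call. = FALSE)
  invalid <- !is.finite(values)
  if (validate) {
    oob <- is.finite(values) & (values < band[1] | values > band[2])
    if (any(oob)) {
      warning(sprintf("%d pixel(s) outside the plausible band [%g, %g] C; flagged invalid",
                      sum(oob), band[1], band[2]), call. = FALSE)
      invalid <- invalid | oob
    }
  }
  structure(values, frame_index = frame_index, invalid = invalid,
            class = c("thermal_frame", "matrix", "array"))
}

#' @export
print.thermal_frame <- function(x, ...) {
  v <- x[!attr(x, "invalid")]
  cat(sprintf("<thermal_frame> %d x %d px, frame %d, %d invalid px, range %.2f-%.2f C\n",
              nrow(x), ncol(x), attr(x, "frame_index"),
              sum(attr(x, "invalid")),
              if (length(v)) min(v) else NA_real_,
              if (length(v)) max(v) else NA_real_))
  invisible(x)
}

# valid-pixel logical matrix for a frame (accepts plain matrices too)
frame_valid <- function(frame) {
  inv <- attr(frame, "invalid")
  ok <- is.finite(frame)
  if (!is.null(inv)) ok & !inv else ok
}

#' Construct a thermal sequence
#'
#' An ordered list of equally sized thermal frames plus acquisition metadata.
#' The study protocol records 30 frames per second for 5 s, i.e. 150 frames
#' per data point; any rate/duration is accepted as long as the frame count
#' is consistent with a declared duration.
#'
#' @param frames list of [thermal_frame()] objects (or numeric matrices,
#'   which are wrapped), all with identical dimensions.
#' @param frame_rate_hz positive frame rate (default 30).
#' @param duration_s optional declared duration in seconds; if given,
#'   `length(frames)` must equal `round(frame_rate_hz * duration_s)`.
#' @param scale,offset linear count-to-temperature map used when the
#'   sequence is quantized to 16-bit counts on disk:
#'   `temperature = scale * count + offset`.
#' @return object of class `thermal_sequence` (a list with elements
#'   `frames`, `frame_rate_hz`, `duration_s`, `scale`, `offset`).
#' @export
thermal_sequence <- function(frames, frame_rate_hz = 30, duration_s = NULL,
                             scale = 0.01, offset = 0) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list", call. = FALSE)
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (inherits(f, "thermal_frame")) f
    else thermal_frame(f, frame_index = i - 1L, validate = FALSE)
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share dimensions", call. = FALSE)
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be positive", call. = FALSE)
  if (!is.null(duration_s)) {
    expected <- round(frame_rate_hz * duration_s)
    if (length(frames) != expected)
      stop(sprintf("declared duration %g s at %g Hz implies %d frames, got %d",
                   duration_s, frame_rate_hz, expected, length(frames)),
           call. = FALSE)
  } else {
    duration_s <- length(frames) / frame_rate_hz
  }
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 duration_s = duration_s, scale = scale, offset = offset),
            class = "thermal_sequence")
}

#' @export
print.thermal_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<thermal_sequence> %d frames of %d x %d px, %g Hz (%g s), scale %g C/count, offset %g C\n",
              length(x$frames), d[1], d[2], x$frame_rate_hz, x$duration_s,
              x$scale, x$offset))
  invisible(x)
}

#' @export
length.thermal_sequence <- function(x) length(x$frames)

#' Construct a region-of-interest mask
#'
#' A boolean pixel mask congruent with its frame, typically the output of
#' [grow_region()] for one frame. Masks from the seeded-region-growing
#' detector are a single 8-connected component; masks from the threshold
#' baseline need not be, so connectivity is checked only when requested.
#'
#' @param mask logical matrix.
#' @param frame_index frame the mask belongs to.
#' @param check_connected logical; assert the marked pixels form one
#'   8-connected component.
#' @return object of class `roi_mask` (a logical matrix with attribute
#'   `frame_index`).
#' @export
roi_mask <- function(mask, frame_index = 0L, check_connected = FALSE) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (check_connected && sum(mask) > 0L && !is_connected8(mask))
    stop("mask pixels do not form one 8-connected component", call. = FALSE)
  structure(mask, frame_index = as.integer(frame_index),
            class = c("roi_mask", "matrix", "array"))
}

# one 8-connected component? flood fill from the first TRUE pixel
is_connected8 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(TRUE)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  stack <- matrix(idx[1L, ], ncol = 2)
  seen[idx[1L, 1L], idx[1L, 2L]] <- TRUE
  nr <- nrow(mask); nc <- ncol(mask)
  while (nrow(stack) > 0L) {
    p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r <- p[1L] + dr; c <- p[2L] + dc
      if (r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        stack <- rbind(stack, c(r, c))
      }
    }
  }
  all(seen[mask])
}
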