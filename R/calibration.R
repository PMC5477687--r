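#' Physical layout of the four fiducial disks
#'
#' Four aluminium-foil disks on the skin delineate a rectangle on the body
#' plane: two subclavicular disks spaced 18 cm apart horizontally, and two
#' more each 8 cm above them on the trapezius border. Coordinates are in cm
#' on the body plane, x rightward and y downward, so in an upright image the
#' upper disks have the smaller y.
#'
#' @param points_cm 4 x 2 numeric matrix of (x, y) disk-centre coordinates
#'   in cm, ordered upper-left, upper-right, lower-left, lower-right.
#'   Default: the 18 cm x 8 cm study rectangle.
#' @param disk_diameter_mm disk diameter (default 5 mm).
#' @return object of class `fiducial_layout`.
#' @export
fiducial_layout <- function(points_cm = rbind(c(0, 0), c(18, 0),
                                              c(0, 8), c(18, 8)),
                            disk_diameter_mm = 5) {
  points_cm <- as.matrix(points_cm)
  if (!all(dim(points_cm) == c(4L, 2L)))
    stop("`points_cm` must be a 4 x 2 matrix", call. = FALSE)
  if (anyDuplicated(points_cm))
    stop("fiducial points must be distinct", call. = FALSE)
  if (any_three_collinear(points_cm))
    stop("no three fiducial points may be collinear", call. = FALSE)
  dimnames(points_cm) <- list(c("ul", "ur", "ll", "lr"), c("x_cm", "y_cm"))
  structure(list(points_cm = points_cm, disk_diameter_mm = disk_diameter_mm),
            class = "fiducial_layout")
}

any_three_collinear <- function(p, tol = 1e-9) {
  combs <- utils::combn(nrow(p), 3L)
  for (j in seq_len(ncol(combs))) {
    a <- p[combs[1L, j], ]; b <- p[combs[2L, j], ]; c <- p[combs[3L, j], ]
    area2 <- abs((b[1L] - a[1L]) * (c[2L] - a[2L]) -
                 (c[1L] - a[1L]) * (b[2L] - a[2L]))
    scale <- max(abs(c(a, b, c)), 1)
    if (area2 <= tol * scale^2) return(TRUE)
  }
  FALSE
}

#' Detect the four cool fiducial disks in a frame
#'
#' The foil disks image at roughly 28-31 degrees C, distinctly cooler than
#' the surrounding skin. Pixels in the configured band are labelled into
#' connected blobs; blobs smaller than `min_blob_px` are discarded as noise;
#' exactly four must remain. Centroids are sub-pixel (mean of member pixel
#' coordinates) and are assigned to layout corners by geometric ordering in
#' image coordinates: the two smallest-row centroids are the upper pair,
#' ordered by column, and likewise the lower pair.
#'
#' @param frame a [thermal_frame()] or numeric matrix (degrees C).
#' @param band temperature band (degrees C) the disks occupy; default 28-31.
#' @param min_blob_px minimum blob size in pixels (default 4).
#' @return 4 x 2 numeric matrix of centroids, rows named
#'   `ul`, `ur`, `ll`, `lr`, columns `row`, `col` (1-based pixel coords).
#' @export
detect_fiducials <- function(frame, band = c(28, 31), min_blob_px = 4L) {
  v <- unclass(frame)
  inband <- frame_valid(frame) & v >= band[1] & v <= band[2]
  if (!any(inband))
    stop("no pixels in the fiducial band; cannot detect disks", call. = FALSE)
  lab <- EBImage::bwlabel(matrix(as.numeric(inband), nrow(v), ncol(v)))
  nblob <- max(lab)
  cent <- matrix(NA_real_, 0L, 2L)
  sizes <- integer(0)
  for (b in seq_len(nblob)) {
    px <- which(lab == b, arr.ind = TRUE)
    if (nrow(px) < min_blob_px) next
    cent <- rbind(cent, colMeans(px))
    sizes <- c(sizes, nrow(px))
  }
  if (nrow(cent) != 4L)
    stop(sprintf("expected 4 fiducial blobs, found %d (sizes: %s)",
                 nrow(cent),
                 if (length(sizes)) paste(sizes, collapse = ", ") else "none"),
         call. = FALSE)
  # geometric ordering: top pair = two smallest rows, each pair sorted by col
  ord <- order(cent[, 1L])
  top <- cent[ord[1:2], , drop = FALSE]
  bot <- cent[ord[3:4], , drop = FALSE]
  out <- rbind(top[order(top[, 2L]), ], bot[order(bot[, 2L]), ])
  dimnames(out) <- list(c("ul", "ur", "ll", "lr"), c("row", "col"))
  out
}

#' Estimate the pixel-to-metric planar transform from 4 correspondences
#'
#' Computes the exact 3x3 homography mapping homogeneous pixel coordinates
#' (x = column, y = row) to cm on the body plane, by direct linear transform
#' on the four point pairs (8 degrees of freedom, so the fit is exact up to
#' numerical tolerance). The matrix is normalised so its largest-magnitude
#' entry is 1.
#'
#' @param pixel_pts 4 x 2 matrix of detected disk centres, columns
#'   `row`, `col` as returned by [detect_fiducials()] (or any 4 points in
#'   the same corner order as `layout`).
#' @param layout a [fiducial_layout()].
#' @return object of class `planar_transform`: list with `matrix` (3x3,
#'   pixel (x, y, 1) -> cm), `residual_cm` (RMS reprojection residual at
#'   the 4 points), `pixel_pts`, `layout`.
#' @export
estimate_transform <- function(pixel_pts, layout = fiducial_layout()) {
  pixel_pts <- as.matrix(pixel_pts)
  if (!all(dim(pixel_pts) == c(4L, 2L)))
    stop("`pixel_pts` must be a 4 x 2 matrix", call. = FALSE)
  # pixel (x, y) convention: x = column, y = row
  src <- cbind(x = pixel_pts[, "col"], y = pixel_pts[, "row"])
  dst <- layout$points_cm
  if (any_three_collinear(src))
    stop("degenerate fiducial configuration: three detected centres are collinear",
         call. = FALSE)
  H <- dlt_homography(src, dst)
  mapped <- apply_transform_xy(H, src)
  residual <- sqrt(mean(rowSums((mapped - dst)^2)))
  structure(list(matrix = H, residual_cm = residual,
                 pixel_pts = pixel_pts, layout = layout),
            class = "planar_transform")
}

# direct linear transform: h minimises ||A h||, ||h|| = 1, via SVD
dlt_homography <- function(src, dst) {
  A <- matrix(0, 0L, 9L)
  for (i in 1:4) {
    x <- src[i, 1L]; y <- src[i, 2L]
    u <- dst[i, 1L]; v <- dst[i, 2L]
    A <- rbind(A,
               c(-x, -y, -1, 0, 0, 0, u * x, u * y, u),
               c(0, 0, 0, -x, -y, -1, v * x, v * y, v))
  }
  h <- svd(A, nu = 0, nv = 9L)$v[, 9L]
  H <- matrix(h, 3L, 3L, byrow = TRUE)
  H / h[which.max(abs(h))]
}

# apply homography to n x 2 (x, y) points
apply_transform_xy <- function(H, pts) {
  hom <- H %*% rbind(t(pts), 1)
  t(hom[1:2, , drop = FALSE] / rep(hom[3L, ], each = 2L))
}

#' Map pixel coordinates through a planar transform
#'
#' @param transform a [planar_transform()].
#' @param pixels n x 2 matrix with columns `row`, `col` (1-based).
#' @return n x 2 matrix of (x_cm, y_cm) body-plane coordinates.
#' @export
pixels_to_cm <- function(transform, pixels) {
  pixels <- as.matrix(pixels)
  out <- apply_transform_xy(transform$matrix,
                            cbind(pixels[, 2L], pixels[, 1L]))
  colnames(out) <- c("x_cm", "y_cm")
  out
}

#' @export
print.planar_transform <- function(x, ...) {
  cat("<planar_transform> pixel (x, y, 1) -> cm, RMS residual",
      format(x$residual_cm, digits = 3), "cm\n")
  print(unname(x$matrix))
  invisible(x)
}

#' Metric area of an ROI through a planar transform
#'
#' Integrates the transform's local area scale over the mask: each member
#' pixel contributes the absolute Jacobian determinant of the pixel-to-cm
#' map evaluated at its centre (for a homography `H` with third row
#' `(g, h, i)`, `|det J| = |det H| / |g x + h y + i|^3`). For an affine
#' transform this reduces exactly to pixel count times a constant cm^2 per
#' pixel. The cm^2 total is returned in m^2.
#'
#' @param mask a [roi_mask()] or logical matrix.
#' @param transform a [planar_transform()].
#' @return area in m^2 (a single number).
#' @export
roi_area_m2 <- function(mask, transform) {
  px <- which(unclass(mask), arr.ind = TRUE)
  if (nrow(px) == 0L) return(0)
  H <- transform$matrix
  detH <- det(H)
  w <- H[3L, 1L] * px[, 2L] + H[3L, 2L] * px[, 1L] + H[3L, 3L]
  if (any(abs(w) < 1e-12))
    stop("transform degenerate at an ROI pixel (zero homogeneous weight)",
         call. = FALSE)
  sum(abs(detH) / abs(w)^3) * 1e-4   # cm^2 -> m^2
}

#' Estimate the calibration for a sequence
#'
#' Detects the fiducials on one designated frame (default the first) and
#' fits the transform once, holding it fixed for the sequence — or
#' re-estimates per frame when `per_frame = TRUE` (useful under pose drift).
#'
#' @param seq a [thermal_sequence()].
#' @param layout a [fiducial_layout()].
#' @param frame which frame to calibrate from (1-based; default 1).
#' @param per_frame logical; estimate one transform per frame.
#' @param band,min_blob_px passed to [detect_fiducials()].
#' @return a [estimate_transform()] result, or a list of them when
#'   `per_frame = TRUE`.
#' @export
calibrate_sequence <- function(seq, layout = fiducial_layout(), frame = 1L,
                               per_frame = FALSE, band = c(28, 31),
                               min_blob_px = 4L) {
  if (!inherits(seq, "thermal_sequence"))
    stop("`seq` must be a thermal_sequence", call. = FALSE)
  one <- function(i) {
    ctr <- detect_fiducials(seq$frames[[i]], band = band,
                            min_blob_px = min_blob_px)
    estimate_transform(ctr, layout)
  }
  if (per_frame) lapply(seq_along(seq$frames), one) else one(frame)
}

#' Serialize / deserialize a planar transform as JSON
#'
#' @param transform a [planar_transform()].
#' @param path output (input) JSON path.
#' @return `path` invisibly; `read_transform` returns a `planar_transform`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(matrix = as.vector(t(transform$matrix)),   # row-major
         residual_cm = transform$residual_cm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(matrix = matrix(obj$matrix, 3L, 3L, byrow = TRUE),
                 residual_cm = obj$residual_cm,
                 pixel_pts = NULL, layout = NULL),
            class = "planar_transform")
}
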