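#' Write a thermal sequence to disk
#'
#' Two portable dialects are supported. `tiff-stack` writes a multi-page
#' 16-bit TIFF of integer counts plus a sidecar JSON file
#' (`<stem>.json`) carrying the linear count-to-temperature scale/offset and
#' the frame rate; per-pixel quantization error is at most `scale / 2`.
#' `csv-dir` writes one full-precision CSV matrix per frame plus
#' `metadata.json` in a directory — bulkier, but human-readable and
#' quantization-free, intended for debugging.
#'
#' Invalid (non-finite) pixels are stored as count 65535 (tiff-stack) or as
#' empty fields (csv-dir) and come back as `NA`.
#'
#' @param seq a [thermal_sequence()].
#' @param path output path: the TIFF file path for `tiff-stack`, a directory
#'   for `csv-dir`.
#' @param dialect `"tiff-stack"` or `"csv-dir"`.
#' @return `path`, invisibly.
#' @seealso [read_sequence()]
#' @export
write_sequence <- function(seq, path, dialect = c("tiff-stack", "csv-dir")) {
  dialect <- match.arg(dialect)
  if (!inherits(seq, "thermal_sequence"))
    stop("`seq` must be a thermal_sequence", call. = FALSE)
  if (length(seq$frames) == 0L) stop("empty sequence", call. = FALSE)
  meta <- list(format = "thermoroi-sequence", dialect = dialect,
               scale = seq$scale, offset = seq$offset,
               frame_rate_hz = seq$frame_rate_hz,
               duration_s = seq$duration_s,
               n_frames = length(seq$frames))
  if (dialect == "tiff-stack") {
    pages <- lapply(seq$frames, function(f) {
      count <- round((unclass(f) - seq$offset) / seq$scale)
      oor <- is.finite(count) & (count < 0 | count > 65534)
      if (any(oor))
        stop("temperatures outside the representable 16-bit range for this scale/offset",
             call. = FALSE)
      count[!is.finite(count)] <- 65535   # reserved invalid-pixel code
      count / 65535
    })
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                   error = function(e) stop("cannot write TIFF: ",
                                            conditionMessage(e), call. = FALSE))
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  } else {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
      stop("cannot create directory ", path, call. = FALSE)
    for (i in seq_along(seq$frames)) {
      utils::write.table(unclass(seq$frames[[i]]),
                         file.path(path, sprintf("frame_%04d.csv", i)),
                         sep = ",", row.names = FALSE, col.names = FALSE,
                         na = "")
    }
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(tiff_path) paste0(sub("\\.tiff?$", "", tiff_path), ".json")

#' Read a thermal sequence from disk
#'
#' Counterpart of [write_sequence()]; the round trip is the identity up to
#' the declared quantization (`scale / 2` per pixel for `tiff-stack`, exact
#' for `csv-dir`), and metadata survives exactly.
#'
#' @param path a TIFF file (`tiff-stack`) or directory (`csv-dir`).
#' @param dialect `"tiff-stack"` or `"csv-dir"`; by default inferred from
#'   whether `path` is a directory.
#' @param band plausible temperature band passed to [thermal_frame()];
#'   out-of-band pixels trigger a validation warning and are flagged.
#' @return a validated [thermal_sequence()] in degrees C.
#' @export
read_sequence <- function(path, dialect = NULL, band = c(5, 45)) {
  if (is.null(dialect))
    dialect <- if (dir.exists(path)) "csv-dir" else "tiff-stack"
  dialect <- match.arg(dialect, c("tiff-stack", "csv-dir"))
  if (dialect == "tiff-stack") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    sp <- sidecar_path(path)
    if (!file.exists(sp))
      stop("missing sidecar metadata ", sp,
           " (scale/offset/frame rate are required)", call. = FALSE)
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    meta <- check_meta(meta)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    mats <- lapply(pages, function(p) {
      count <- round(p * 65535)
      v <- meta$scale * count + meta$offset
      v[count == 65535] <- NA_real_
      v
    })
  } else {
    if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
    mp <- file.path(path, "metadata.json")
    if (!file.exists(mp)) stop("missing metadata.json in ", path, call. = FALSE)
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    meta <- check_meta(meta)
    files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no frame_*.csv files in ", path, call. = FALSE)
    mats <- lapply(files, function(f)
      as.matrix(utils::read.table(f, sep = ",", header = FALSE,
                                  colClasses = "numeric")))
    mats <- lapply(mats, function(m) { dimnames(m) <- NULL; m })
  }
  shapes <- vapply(mats, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("ragged frame shapes: ",
         paste(unique(apply(shapes, 2, paste, collapse = "x")), collapse = ", "),
         call. = FALSE)
  frames <- lapply(seq_along(mats), function(i)
    thermal_frame(mats[[i]], frame_index = i - 1L, band = band))
  thermal_sequence(frames, frame_rate_hz = meta$frame_rate_hz,
                   scale = meta$scale, offset = meta$offset)
}

check_meta <- function(meta) {
  need <- c("scale", "offset", "frame_rate_hz")
  missing <- need[!need %in% names(meta)]
  if (length(missing))
    stop("metadata is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  # JSON readers may re-type whole numbers; the fields are doubles by contract
  for (k in need) meta[[k]] <- as.numeric(meta[[k]])
  meta
}

#' Write an ROI mask as an 8-bit PNG
#'
#' Member pixels are white (255), background black; a lossless, widely
#' viewable serialization of a detected region.
#'
#' @param mask a [roi_mask()] or logical matrix.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read an ROI mask written by [write_roi_mask()]
#'
#' @param path a `.png` path.
#' @param frame_index frame index to attach.
#' @return a [roi_mask()].
#' @export
read_roi_mask <- function(path, frame_index = 0L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  roi_mask(img > 0.5, frame_index = frame_index)
}
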