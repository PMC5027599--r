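# File I/O: TIFF movies, localization tables, camera configuration and
# threshold reports.
#
# Coordinate convention for exported tables: nm, origin at the outer corner
# of pixel (0, 0), x along the column axis, y along the row axis; frame
# indices are 0-based.

#' Read a grayscale TIFF movie
#'
#' @param path Path to an 8- or 16-bit grayscale TIFF stack.
#' @return List of integer matrices (one per frame, ADU values).
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path, call. = FALSE)
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  lapply(frames, function(fr) {
    if (length(dim(fr)) == 3L) fr <- fr[, , 1]   # first channel
    fr
  })
}

#' Write a movie as a 16-bit grayscale TIFF stack
#'
#' @param frames List of integer matrices (ADU, 0..65535).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_movie <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  tiff::writeTIFF(lapply(frames, function(m) m / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Write a rendered image as 32-bit float TIFF
#'
#' @param image A `rendered_image` (see [render_superres()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rendered_tiff <- function(image, path) {
  stopifnot(inherits(image, "rendered_image"))
  v <- image$values
  # 32-bit samples are written as IEEE floats; count images legitimately
  # exceed 1, which libtiff stores faithfully despite the range warning
  suppressWarnings(tiff::writeTIFF(v, path, bits.per.sample = 32L))
  invisible(path)
}

#' Write a reliability map as a color-mapped PNG
#'
#' @param image A `rendered_image` with values in `[0, 1]`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reliability_png <- function(image, path) {
  stopifnot(inherits(image, "rendered_image"))
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  v <- pmin(pmax(image$values, 0), 1)
  pal <- grDevices::hcl.colors(256, "Inferno")
  rgb <- grDevices::col2rgb(pal[pmin(255L, floor(v * 255)) + 1L]) / 255
  arr <- array(0, c(nrow(v), ncol(v), 3))
  arr[, , 1] <- matrix(rgb[1, ], nrow(v)); arr[, , 2] <- matrix(rgb[2, ], nrow(v))
  arr[, , 3] <- matrix(rgb[3, ], nrow(v))
  png::writePNG(arr, path)
  invisible(path)
}

#' Write and read localization tables
#'
#' CSV with header `frame,x_nm,y_nm,n_psf,n_b,reliability` (missing
#' columns are allowed and written as empty). Numeric values keep enough
#' digits for a lossless round trip to at least 6 significant digits.
#'
#' @param localizations Data.frame of localizations.
#' @param path CSV path.
#' @return `write_localizations()`: invisibly, `path`;
#'   `read_localizations()`: the data.frame.
#' @export
write_localizations <- function(localizations, path) {
  cols <- intersect(c("frame", "x_nm", "y_nm", "n_psf", "n_b",
                      "reliability"), names(localizations))
  df <- localizations[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 9))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) stop("cannot read CSV: ", path, call. = FALSE)
  df <- read.csv(path)
  need <- c("frame", "x_nm", "y_nm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("localization CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read a camera/analysis configuration file
#'
#' YAML with the [camera_optics()] keys (`offset`, `gain`, `pixel_size_nm`,
#' `magnification`, `na`, `wavelength_nm`) plus optional analysis options
#' (`model`, `n_levels`, `render_pixel_nm`, `tolerance_nm`, `seed`).
#'
#' @param path YAML path.
#' @return List with `cam` (a `camera_optics`) and `options` (named list of
#'   the remaining keys).
#' @export
read_camera_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("offset", "gain", "pixel_size_nm", "magnification", "na",
            "wavelength_nm")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing required key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  cam <- camera_optics(cfg$offset, cfg$gain, cfg$pixel_size_nm,
                       cfg$magnification, cfg$na, cfg$wavelength_nm)
  list(cam = cam, options = cfg[setdiff(names(cfg), need)])
}

#' Write a threshold report as JSON
#'
#' Records the model name, the threshold (raw units and gray level), the
#' prior masses and fitted parameters of both classes, and the counts of
#' accepted/rejected emitters when an analysis is given.
#'
#' @param x A `threshold_result` or `smlm_analysis`.
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_threshold_report <- function(x, path) {
  if (inherits(x, "smlm_analysis")) {
    res <- x$threshold
    extra <- list(selection_threshold = x$selection_threshold,
                  n_accepted = nrow(x$localizations),
                  n_rejected = nrow(x$rejected),
                  n_frames = nrow(x$frame_stats))
  } else {
    stopifnot(inherits(x, "threshold_result"))
    res <- x
    extra <- NULL
  }
  rpt <- c(list(model = res$model_name, threshold = res$threshold,
                gray_level = res$T_star, p_false = res$p_false,
                p_true = res$p_true,
                theta_false = as.list(res$theta_false),
                theta_true = as.list(res$theta_true),
                n_emitters = res$total),
           extra)
  jsonlite::write_json(rpt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export the potential-emitter table with the criterion trace
#'
#' Tabulated data for custom analysis or visual checking: one CSV with the
#' per-emitter characteristic values, and one with the criterion trace
#' J(T).
#'
#' @param analysis An `smlm_analysis`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "smlm_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "localizations.csv")
  p2 <- file.path(dir, "potential_emitters.csv")
  p3 <- file.path(dir, "criterion_trace.csv")
  p4 <- file.path(dir, "threshold_report.json")
  write_localizations(analysis$localizations, p1)
  write_localizations(analysis$all_fits, p2)
  write.csv(analysis$threshold$criterion_trace, p3, row.names = FALSE)
  write_threshold_report(analysis, p4)
  invisible(c(p1, p2, p3, p4))
}
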