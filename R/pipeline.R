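# The end-to-end analysis pipeline: frames -> photoelectrons -> candidate
# spots -> PSF fits -> pooled histogram -> automatic threshold ->
# localizations with reliability.

#' Analyze all frames of a movie without selection
#'
#' Runs the per-frame algorithm (conversion, locally brightest spots,
#' background estimation, PSF fitting of every candidate, close-spot
#' pruning) on every frame and pools the retained fits. No threshold is
#' applied here: the full set of potential emitters is the input to the
#' automatic threshold determination.
#'
#' @param frames List of raw ADU matrices (or a single matrix).
#' @param cam A [camera_optics()].
#' @param verbose Print per-frame candidate counts.
#' @return List with `fits` (data.frame: `frame` 0-based, `x0`, `y0` in
#'   pixels, `x_nm`, `y_nm`, `n_psf`, `n_b`) and `frame_stats` (data.frame:
#'   `frame`, `candidates`, `failed`, `pruned`, `retained`).
#' @export
fit_movie <- function(frames, cam, verbose = FALSE) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(inherits(cam, "camera_optics"), length(frames) >= 1L)
  optics <- derive_optics(cam)
  all_fits <- vector("list", length(frames))
  stats <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    pe <- to_photoelectrons(frames[[f]], cam)
    bg <- estimate_background(pe, optics)
    cand <- find_local_maxima(pe, optics)
    cand$bg <- bg[cbind(cand$i, cand$j)]
    fits <- fit_spots(pe, cand, optics)
    ok <- fits[fits$ok, , drop = FALSE]
    kept <- prune_close_spots(ok, optics)
    stats[[f]] <- data.frame(frame = f - 1L, candidates = nrow(cand),
                             failed = nrow(fits) - nrow(ok),
                             pruned = nrow(ok) - nrow(kept),
                             retained = nrow(kept))
    if (verbose)
      message(sprintf("frame %d: %d candidates, %d failed, %d pruned, %d retained",
                      f - 1L, nrow(cand), nrow(fits) - nrow(ok),
                      nrow(ok) - nrow(kept), nrow(kept)))
    if (nrow(kept)) {
      kept$frame <- f - 1L
      kept$x_nm <- kept$x0 * optics$p_eff_nm
      kept$y_nm <- kept$y0 * optics$p_eff_nm
      all_fits[[f]] <- kept[, c("frame", "x0", "y0", "x_nm", "y_nm",
                                "n_psf", "n_b")]
    }
  }
  fits <- do.call(rbind, all_fits[!vapply(all_fits, is.null, logical(1))])
  if (is.null(fits))
    fits <- data.frame(frame = integer(), x0 = numeric(), y0 = numeric(),
                       x_nm = numeric(), y_nm = numeric(),
                       n_psf = numeric(), n_b = numeric())
  rownames(fits) <- NULL
  list(fits = fits, frame_stats = do.call(rbind, stats))
}

#' Fully automatic movie analysis
#'
#' The complete pipeline: [fit_movie()], pooled photoelectron-count
#' histogram, automatic threshold by [find_threshold()] with the chosen
#' distribution model, emitter selection, and per-emitter reliability.
#'
#' @param frames List of raw ADU matrices, or a TIFF path (read with
#'   [read_movie()]).
#' @param cam A [camera_optics()].
#' @param model `"wldm"` (default), `"ggdm"`, or a `dist_model`.
#' @param n_levels Optional histogram size (default per
#'   [build_histogram()]).
#' @param manual_threshold Optional manual override of the selection
#'   threshold in photoelectrons (e.g. 1 to export every positive fit);
#'   the automatic threshold is still computed and reported.
#' @param verbose Print per-frame progress.
#' @return Object of class `smlm_analysis`: `localizations` (accepted
#'   fits), `rejected`, `all_fits` (with a `reliability` column),
#'   `threshold` (a `threshold_result`), `selection_threshold` (number
#'   actually used), `histogram`, `frame_stats`, `cam`, `optics`.
#' @export
analyze_movie <- function(frames, cam, model = "wldm", n_levels = NULL,
                          manual_threshold = NULL, verbose = FALSE) {
  if (is.character(frames)) frames <- read_movie(frames)
  fm <- fit_movie(frames, cam, verbose = verbose)
  if (nrow(fm$fits) < 10L)
    stop("only ", nrow(fm$fits), " retained fits in the whole movie; ",
         "not enough for threshold analysis", call. = FALSE)
  hist <- build_histogram(fm$fits$n_psf, n_levels = n_levels)
  result <- find_threshold(hist, model)
  curve <- reliability_curve(result)
  fits <- fm$fits
  fits$reliability <- curve$R(fits$n_psf)
  thr <- if (is.null(manual_threshold)) result$threshold
         else as.numeric(manual_threshold)
  parts <- select_emitters(fits, thr)
  structure(
    list(localizations = parts$accepted, rejected = parts$rejected,
         all_fits = fits, threshold = result, selection_threshold = thr,
         reliability = curve, histogram = hist,
         frame_stats = fm$frame_stats, cam = cam,
         optics = derive_optics(cam)),
    class = "smlm_analysis"
  )
}

#' @export
print.smlm_analysis <- function(x, ...) {
  cat("<smlm_analysis>\n")
  cat(sprintf("  %d potential emitters in %d frames\n", nrow(x$all_fits),
              nrow(x$frame_stats)))
  cat(sprintf("  model %s, automatic threshold %.4g, selection threshold %.4g\n",
              x$threshold$model_name, x$threshold$threshold,
              x$selection_threshold))
  cat(sprintf("  %d accepted, %d rejected\n", nrow(x$localizations),
              nrow(x$rejected)))
  invisible(x)
}

#' Detection quality as a function of the selection threshold
#'
#' Sweeps the selection threshold over a grid and, for each value, matches
#' the accepted localizations against the ground truth. Used to check that
#' the automatic threshold sits near the optimum of the Jaccard index.
#'
#' @param fits Data.frame of potential emitters (columns `frame`, `x_nm`,
#'   `y_nm`, `n_psf`), e.g. `analysis$all_fits`.
#' @param ground_truth Reference table (columns `frame`, `x_nm`, `y_nm`).
#' @param tolerance_nm Matching radius in nm.
#' @param thresholds Numeric vector of thresholds to evaluate; default is
#'   an even quantile grid over the observed `n_psf` range.
#' @param n_thresholds Grid size when `thresholds` is not given.
#' @return Data.frame with columns `threshold`, `tp`, `fp`, `fn`,
#'   `jaccard`, `precision`, `recall`, `rmsd_nm`.
#' @export
jaccard_sweep <- function(fits, ground_truth, tolerance_nm,
                          thresholds = NULL, n_thresholds = 60L) {
  if (is.null(thresholds)) {
    # half the grid follows the data density (quantiles), half is spread
    # geometrically so sparse regions between the modes are still sampled
    n_half <- max(2L, n_thresholds %/% 2L)
    qs <- stats::quantile(fits$n_psf,
                          probs = seq(0, 1, length.out = n_half + 1L))
    lo <- max(min(fits$n_psf), 1e-6)
    geo <- exp(seq(log(lo), log(max(fits$n_psf)), length.out = n_half))
    thresholds <- sort(unique(as.numeric(c(qs[-length(qs)], geo))))
  }
  out <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    acc <- fits[fits$n_psf >= thresholds[k], , drop = FALSE]
    rep <- match_localizations(ground_truth, acc, tolerance_nm)
    out[[k]] <- data.frame(threshold = thresholds[k], tp = rep$tp,
                           fp = rep$fp, fn = rep$fn, jaccard = rep$jaccard,
                           precision = rep$precision, recall = rep$recall,
                           rmsd_nm = rep$rmsd_nm)
  }
  do.call(rbind, out)
}
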