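# PSF fitting of spot candidates and suppression of too-close fits.
#
# Continuous coordinates are in pixel units with the origin at the outer
# corner of the first pixel: the center of pixel (i, j) (1-based matrix
# indices) is at (x, y) = (j - 0.5, i - 0.5); x runs along columns.
# Multiplying by the effective pixel size gives nm.

#' Starting values for a PSF fit
#'
#' The position starts at the locally brightest pixel; the background starts
#' at the background-image estimate; the integrated photoelectron count
#' starts at `2 * pi * s0^2 * (peak - background)` — the value for which the
#' fixed-width Gaussian model reproduces the observed excess at the peak —
#' floored at a small positive value.
#'
#' @param peak_value Photoelectron count at the candidate peak.
#' @param bg_estimate Background estimate at the peak
#'   (see [estimate_background()]).
#' @param optics A [derive_optics()] result.
#' @param npsf_floor Lower bound for the starting integrated count
#'   (default 1).
#' @return Named list with `n_psf` and `n_b`.
#' @export
initial_guess <- function(peak_value, bg_estimate, optics, npsf_floor = 1) {
  stopifnot(inherits(optics, "optics_derived"))
  list(n_psf = max(2 * pi * optics$s0_px^2 * (peak_value - bg_estimate),
                   npsf_floor),
       n_b = bg_estimate)
}

#' Fit fixed-width 2D Gaussian PSFs to spot candidates
#'
#' Least-squares fit of the model
#' `n_psf / (2 pi s0^2) * exp(-((x - x0)^2 + (y - y0)^2) / (2 s0^2)) + n_b`
#' over the `(2 h_f + 1)` square window centered on each candidate, with the
#' width `s0` held fixed at its theoretical value. Free parameters are the
#' sub-pixel center `(x0, y0)`, the integrated photoelectron count `n_psf`
#' and the flat local background `n_b`. Minimization uses a
#' Levenberg-Marquardt iteration (unweighted residuals, analytic Jacobian).
#'
#' Fits that fail to converge, end with `n_psf <= 0`, or whose center leaves
#' the fit window are flagged `ok = FALSE` and are excluded from threshold
#' analysis downstream.
#'
#' @param frame Photoelectron matrix.
#' @param candidates Data.frame from [find_local_maxima()] with an added
#'   `bg` column (background estimate at each peak), or columns `i`, `j`,
#'   `peak`, `bg`.
#' @param optics A [derive_optics()] result.
#' @param npsf_floor Floor for the starting `n_psf` (default 1).
#' @return Data.frame with columns `x0`, `y0` (pixel units), `n_psf`, `n_b`,
#'   `rss`, `iter`, `converged`, `ok`.
#' @export
fit_spots <- function(frame, candidates, optics, npsf_floor = 1) {
  stopifnot(is.matrix(frame), inherits(optics, "optics_derived"))
  need <- c("i", "j", "peak", "bg")
  if (!all(need %in% names(candidates)))
    stop("'candidates' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(candidates) == 0L)
    return(data.frame(x0 = numeric(), y0 = numeric(), n_psf = numeric(),
                      n_b = numeric(), rss = numeric(), iter = numeric(),
                      converged = logical(), ok = logical()))
  m <- fit_spots_cpp(frame, as.integer(candidates$i),
                     as.integer(candidates$j), as.numeric(candidates$bg),
                     optics$h_f, optics$s0_px, npsf_floor)
  hf <- optics$h_f
  res <- data.frame(x0 = m[, "x0"], y0 = m[, "y0"], n_psf = m[, "n_psf"],
                    n_b = m[, "n_b"], rss = m[, "rss"], iter = m[, "iter"],
                    converged = m[, "converged"] > 0)
  inside <- abs(res$x0 - (candidates$j - 0.5)) <= hf &
    abs(res$y0 - (candidates$i - 0.5)) <= hf
  res$ok <- res$converged & res$n_psf > 0 & inside
  res
}

#' Fit one candidate spot
#'
#' Convenience wrapper around [fit_spots()] for a single candidate.
#'
#' @param frame Photoelectron matrix.
#' @param i,j 1-based row/column of the candidate peak.
#' @param bg Background estimate at the peak.
#' @param optics A [derive_optics()] result.
#' @return One-row data.frame as in [fit_spots()].
#' @export
fit_psf <- function(frame, i, j, bg, optics) {
  fit_spots(frame,
            data.frame(i = i, j = j, peak = frame[i, j], bg = bg),
            optics)
}

#' Suppress fits that are closer than the PSF width
#'
#' When several fitted centers lie within `s0_px` of each other, only the
#' fit with the largest integrated photoelectron count is retained.
#' Implemented greedily in descending `n_psf` order (ties broken by `x0`,
#' then `y0`), which makes the result deterministic and idempotent.
#'
#' @param fits Data.frame of fits from one frame (columns `x0`, `y0`,
#'   `n_psf`).
#' @param optics A [derive_optics()] result.
#' @return The surviving subset of `fits`, in the original row order.
#' @export
prune_close_spots <- function(fits, optics) {
  stopifnot(inherits(optics, "optics_derived"))
  n <- nrow(fits)
  if (is.null(n) || n <= 1L) return(fits)
  ord <- order(-fits$n_psf, fits$x0, fits$y0)
  x <- fits$x0[ord]; y <- fits$y0[ord]
  alive <- rep(TRUE, n)
  keep <- logical(n)
  r2 <- optics$s0_px^2
  for (k in seq_len(n)) {
    if (!alive[k]) next
    keep[k] <- TRUE
    if (k < n) {
      rest <- (k + 1L):n
      d2 <- (x[rest] - x[k])^2 + (y[rest] - y[k])^2
      alive[rest][d2 <= r2] <- FALSE
    }
  }
  fits[sort(ord[keep]), , drop = FALSE]
}
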