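# Histogram construction and generalized minimum-error thresholding (GMET).
#
# The characteristic (photoelectron count n_psf by default, but any scalar
# with a bimodal false/true structure) is quantized into N gray levels
# {0, ..., N-1}. For each candidate threshold T, the false side R0 = {0..T}
# and the true side R1 = {T+1..N-1} are fitted with the class densities of
# a distribution model, and the Bayes classification-error criterion
#   J(T) = -sum_i sum_{x in Ri} h(x) [log P_iT + log f_i(x | theta_iT)]
# is minimized exhaustively over T.

#' Quantize characteristic values into a gray-level histogram
#'
#' Values are mapped to levels `0..N-1` by the affine rule
#' `level = round((v - lo) / width)` (clamped), with `lo = min(0, min(v))`
#' and `width = (max(v) - lo) / (N - 1)`. When `n_levels` is not given,
#' `N = min(ceiling(max(v) - lo), length(v))`, so for photoelectron counts
#' the default quantization is rounding to integers.
#'
#' @param values Numeric vector of characteristic values (at least 10).
#' @param n_levels Number of gray levels N; default per the rule above.
#' @return Object of class `characteristic_histogram` with fields `counts`
#'   (length N), `levels` (`0:(N-1)`), `n_levels`, `lo`, `width`, `total`.
#' @export
build_histogram <- function(values, n_levels = NULL) {
  values <- as.numeric(values)
  if (anyNA(values) || !all(is.finite(values)))
    stop("'values' contains missing or non-finite entries", call. = FALSE)
  if (length(values) < 10L)
    stop("at least 10 characteristic values are required to build a ",
         "histogram (got ", length(values), ")", call. = FALSE)
  lo <- min(0, min(values))
  span <- max(values) - lo
  if (span <= 0)
    stop("characteristic values are constant; no histogram structure",
         call. = FALSE)
  if (is.null(n_levels)) {
    n_levels <- min(ceiling(span), length(values))
  }
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("'n_levels' must be at least 2", call. = FALSE)
  width <- span / (n_levels - 1)
  lev <- pmin(pmax(round((values - lo) / width), 0), n_levels - 1)
  counts <- tabulate(lev + 1L, nbins = n_levels)
  structure(
    list(counts = counts, levels = 0:(n_levels - 1L), n_levels = n_levels,
         lo = lo, width = width, total = length(values)),
    class = "characteristic_histogram"
  )
}

#' @export
print.characteristic_histogram <- function(x, ...) {
  cat(sprintf("<characteristic_histogram> %d values in %d levels (width %.4g, lo %.4g)\n",
              x$total, x$n_levels, x$width, x$lo))
  invisible(x)
}

# Map a gray level (possibly fractional) back to raw characteristic units.
level_to_raw <- function(hist, level) hist$lo + level * hist$width

# Map raw characteristic values to the continuous gray-level axis.
raw_to_level <- function(hist, v) (v - hist$lo) / hist$width

#' Minimum-error criterion at one candidate threshold
#'
#' Fits the model's false density to histogram levels `0..T` and the true
#' density to levels `T+1..N-1`, with prior masses `P_iT` equal to the
#' histogram mass fractions, and evaluates the classification-error
#' criterion (see package overview of the thresholding module). Candidates
#' where either side has fewer than `min_side` nonzero-count levels, or zero
#' variance, are reported invalid rather than raising an error.
#'
#' @param hist A [build_histogram()] result.
#' @param T Candidate threshold gray level (last level of the false side).
#' @param model A `dist_model` (see [ggdm()], [wldm()]) or model name.
#' @param min_side Minimum nonzero-count levels required per side.
#' @return List with `valid`, `J`, `theta_false`, `theta_true`, `p_false`,
#'   `p_true`.
#' @export
gmet_criterion <- function(hist, T, model, min_side = 5L) {
  stopifnot(inherits(hist, "characteristic_histogram"))
  model <- as_dist_model(model)
  lev <- hist$levels
  cnt <- hist$counts
  nz <- cnt > 0
  left <- lev <= T
  gmet_criterion_impl(lev[nz & left], cnt[nz & left],
                      lev[nz & !left], cnt[nz & !left],
                      hist$total, model, min_side)
}

# Choose the threshold level within a minimal plateau [T_lo, T_hi]: the
# level nearest the crossing of the fitted weighted class densities
# (log p1 + log f1 = log p0 + log f0), which is the minimum-error cut of
# the fitted mixture. Falls back to the plateau end on one-sided dominance.
plateau_pick <- function(fit, model, T_lo, T_hi) {
  if (T_hi <= T_lo) return(as.integer(T_lo))
  d <- function(x)
    (log(fit$p_true) + model$logpdf_true(x, fit$theta_true)) -
    (log(fit$p_false) + model$logpdf_false(x, fit$theta_false))
  lo <- T_lo + 0.5; hi <- T_hi + 0.5
  dlo <- d(lo); dhi <- d(hi)
  if (!is.finite(dlo) || !is.finite(dhi)) return(as.integer(T_lo))
  if (dlo >= 0) return(as.integer(T_lo))     # true dominates everywhere
  if (dhi <= 0) return(as.integer(T_hi))     # false dominates everywhere
  x_star <- tryCatch(uniroot(d, c(lo, hi), tol = 1e-6)$root,
                     error = function(e) lo)
  as.integer(pmin(pmax(round(x_star - 0.5), T_lo), T_hi))
}

gmet_criterion_impl <- function(lev0, cnt0, lev1, cnt1, total, model,
                                min_side) {
  m0 <- sum(cnt0); m1 <- sum(cnt1)
  p0 <- m0 / total; p1 <- m1 / total
  invalid <- list(valid = FALSE, J = Inf, theta_false = NULL,
                  theta_true = NULL, p_false = p0, p_true = p1)
  if (length(lev0) < min_side || length(lev1) < min_side) return(invalid)
  if (length(unique(lev0)) < 2L || length(unique(lev1)) < 2L) return(invalid)
  th0 <- model$fit_false(lev0, cnt0)
  th1 <- model$fit_true(lev1, cnt1)
  if (anyNA(th0) || anyNA(th1) || !all(is.finite(c(th0, th1))))
    return(invalid)
  lp0 <- model$logpdf_false(lev0, th0)
  lp1 <- model$logpdf_true(lev1, th1)
  J <- -(sum(cnt0 * (log(p0) + lp0)) + sum(cnt1 * (log(p1) + lp1)))
  if (!is.finite(J)) J <- Inf
  list(valid = TRUE, J = J, theta_false = th0, theta_true = th1,
       p_false = p0, p_true = p1)
}

#' Determine the optimal false/true emitter threshold
#'
#' Exhaustively evaluates the minimum-error criterion at every candidate
#' threshold and returns the global minimizer. The criterion is constant on
#' runs of empty gray levels, so it is evaluated once per run and the trace
#' is carried forward over empty levels. The threshold is reported in raw
#' characteristic units on the half-level convention, `T* + 0.5` gray
#' levels, so that "value >= threshold" selects exactly the true side.
#'
#' When the minimum is attained on a plateau (a run of thresholds with
#' identical side contents, e.g. across an empty gap between the two
#' modes), every plateau member carries the same fitted mixture; the
#' returned `T*` is the plateau level closest to the crossing of the fitted
#' weighted class densities — the minimum-classification-error cut of that
#' mixture. `T*` is always an exact minimizer of the criterion trace.
#'
#' @param hist A [build_histogram()] result, or a numeric vector of
#'   characteristic values (then [build_histogram()] is applied first).
#' @param model A `dist_model` or `"ggdm"`/`"wldm"`.
#' @param min_side Minimum nonzero-count levels per side (default 5).
#' @return Object of class `threshold_result`: `threshold` (raw units),
#'   `T_star` (gray level), `theta_false`, `theta_true`, `p_false`,
#'   `p_true`, `criterion_trace` (data.frame `T`, `J`, `valid`,
#'   `evaluated`), `model_name`, `model`, `hist`, `total`.
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(400, 100, 15), rnorm(600, 500, 60))
#' res <- find_threshold(build_histogram(v), ggdm())
#' res$threshold  # near the Bayes crossing of the two components
find_threshold <- function(hist, model, min_side = 5L) {
  if (is.numeric(hist)) hist <- build_histogram(hist)
  stopifnot(inherits(hist, "characteristic_histogram"))
  model <- as_dist_model(model)
  lev <- hist$levels
  cnt <- hist$counts
  nzlev <- lev[cnt > 0]
  nzcnt <- cnt[cnt > 0]
  N <- hist$n_levels
  # J(T) only changes when T crosses a nonzero level; evaluate there.
  cand <- nzlev[nzlev <= N - 2L]
  J_at <- rep(NA_real_, length(cand))
  valid_at <- logical(length(cand))
  fits_at <- vector("list", length(cand))
  best_J <- Inf
  for (k in seq_along(cand)) {
    Tk <- cand[k]
    left <- nzlev <= Tk
    r <- gmet_criterion_impl(nzlev[left], nzcnt[left], nzlev[!left],
                             nzcnt[!left], hist$total, model, min_side)
    J_at[k] <- r$J
    valid_at[k] <- r$valid
    fits_at[[k]] <- r
    if (r$valid && r$J < best_J) best_J <- r$J
  }
  if (!is.finite(best_J))
    stop("histogram is not bimodal under the '", model$name,
         "' model: no candidate threshold leaves at least ", min_side,
         " occupied levels with spread on both sides", call. = FALSE)
  # minimal plateau: run of candidates tied at the minimum (the criterion
  # is constant over empty levels, so ties across a gap are routine)
  is_min <- valid_at & abs(J_at - best_J) <= 1e-9 * (abs(best_J) + 1)
  k_first <- which(is_min)[1]
  k_last <- k_first
  while (k_last < length(cand) && is_min[k_last + 1L]) k_last <- k_last + 1L
  best <- fits_at[[k_first]]
  # the plateau extends in T-space up to just before the next evaluated
  # candidate (side contents are unchanged over the empty levels)
  T_lo <- cand[k_first]
  T_hi <- if (k_last < length(cand)) cand[k_last + 1L] - 1L else N - 2L
  best_T <- plateau_pick(best, model, T_lo, T_hi)
  # carry the evaluated values forward over empty levels for a full trace
  allT <- 0:(N - 2L)
  idx <- findInterval(allT, cand)
  trace <- data.frame(
    T = allT,
    J = ifelse(idx >= 1L, J_at[pmax(idx, 1L)], Inf),
    valid = ifelse(idx >= 1L, valid_at[pmax(idx, 1L)], FALSE),
    evaluated = allT %in% cand
  )
  structure(
    list(threshold = level_to_raw(hist, best_T + 0.5),
         T_star = best_T,
         theta_false = best$theta_false, theta_true = best$theta_true,
         p_false = best$p_false, p_true = best$p_true,
         criterion_trace = trace, model_name = model$name, model = model,
         hist = hist, total = hist$total),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> model %s, threshold %.4g (gray level %d + 0.5)\n",
              x$model_name, x$threshold, x$T_star))
  cat(sprintf("  P(false) %.3f, P(true) %.3f\n", x$p_false, x$p_true))
  cat("  theta_false:", paste(names(x$theta_false),
                              signif(x$theta_false, 4), sep = "=",
                              collapse = ", "), "\n")
  cat("  theta_true: ", paste(names(x$theta_true),
                              signif(x$theta_true, 4), sep = "=",
                              collapse = ", "), "\n")
  invisible(x)
}

#' Partition emitters by a threshold
#'
#' Splits fitted emitters into accepted (`n_psf >= threshold`) and rejected
#' sets. Both are returned: the rejected ones are still needed for
#' reliability maps. A manual threshold of 1 reproduces the "export
#' everything" convention for downstream reliability analysis.
#'
#' @param fits Data.frame with an `n_psf` column.
#' @param threshold Either a `threshold_result` or a number in raw
#'   characteristic units.
#' @return List with `accepted` and `rejected` data.frames.
#' @export
select_emitters <- function(fits, threshold) {
  thr <- if (inherits(threshold, "threshold_result")) threshold$threshold
         else as.numeric(threshold)
  sel <- fits$n_psf >= thr
  list(accepted = fits[sel, , drop = FALSE],
       rejected = fits[!sel, , drop = FALSE])
}

#' Plot a characteristic histogram with its fitted class densities
#'
#' Visual validity check for the automatic threshold: the gray-level
#' histogram, the fitted false and true densities (scaled to expected
#' counts) and the threshold line.
#'
#' @param x A `threshold_result`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.threshold_result <- function(x, main = NULL, ...) {
  h <- x$hist
  lev <- h$levels
  nf <- x$total * x$p_false * exp(x$model$logpdf_false(lev, x$theta_false))
  nt <- x$total * x$p_true * exp(x$model$logpdf_true(lev, x$theta_true))
  graphics::plot(lev, h$counts, type = "h", col = "grey60",
                 xlab = "gray level", ylab = "count",
                 main = main %||% paste("Threshold analysis,", x$model_name),
                 ...)
  graphics::lines(lev, nf, col = "red", lwd = 2)
  graphics::lines(lev, nt, col = "blue", lwd = 2)
  graphics::abline(v = x$T_star + 0.5, lty = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
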