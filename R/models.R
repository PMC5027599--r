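# Class-density models for minimum-error thresholding. A model bundles, for
# the false (low) and true (high) side of a candidate threshold, a weighted
# parameter estimator and a log-density on the gray-level axis. Gray levels
# are shifted by +0.5 before any logarithm so that level 0 stays in-support
# for the Weibull and lognormal families.

weighted_mean_sd <- function(x, w) {
  W <- sum(w)
  m <- sum(w * x) / W
  v <- sum(w * (x - m)^2) / W
  c(mean = m, sd = sqrt(v))
}

# Weighted maximum-likelihood Weibull fit via Newton iteration on the shape
# k (profile likelihood; scale has a closed form given k). Falls back to
# method of moments when Newton fails to converge in `maxit` steps.
fit_weibull_weighted <- function(x, w, maxit = 50L) {
  t <- x + 0.5
  W <- sum(w)
  lt <- log(t)
  mlog <- sum(w * lt) / W
  g <- function(k) {
    tk <- t^k
    sum(w * tk * lt) / sum(w * tk) - 1 / k - mlog
  }
  k <- 1.0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    gk <- g(k)
    h <- 1e-4 * max(k, 1e-4)
    dg <- (g(k + h) - g(k - h)) / (2 * h)
    if (!is.finite(gk) || !is.finite(dg) || dg == 0) break
    step <- gk / dg
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (k_new > 100) k_new <- 100
    if (abs(k_new - k) < 1e-9 * (1 + k)) { k <- k_new; converged <- TRUE; break }
    k <- k_new
  }
  if (!converged) {
    ms <- weighted_mean_sd(t, w)
    cv <- ms["sd"] / ms["mean"]
    if (!is.finite(cv) || cv <= 0) {
      k <- 50
    } else {
      f <- function(k) {
        m1 <- gamma(1 + 1 / k)
        sqrt(pmax(gamma(1 + 2 / k) - m1^2, 0)) / m1 - cv
      }
      k <- tryCatch(uniroot(f, c(0.05, 100), tol = 1e-8)$root,
                    error = function(e) 1.0)
    }
    lambda <- (sum(w * t^k) / W)^(1 / k)
    return(c(shape = unname(k), scale = unname(lambda)))
  }
  lambda <- (sum(w * t^k) / W)^(1 / k)
  c(shape = k, scale = lambda)
}

new_dist_model <- function(name, fit_false, fit_true, logpdf_false,
                           logpdf_true) {
  structure(list(name = name, fit_false = fit_false, fit_true = fit_true,
                 logpdf_false = logpdf_false, logpdf_true = logpdf_true),
            class = "dist_model")
}

#' @export
print.dist_model <- function(x, ...) {
  cat("<dist_model>", x$name, "\n")
  invisible(x)
}

#' Gaussian-Gaussian distribution model (GGDM)
#'
#' Both the false- and the true-emitter class densities are Gaussian, the
#' generic central-limit choice. Parameters are estimated as the weighted
#' mean and standard deviation of the histogram mass on each side of the
#' candidate threshold.
#'
#' @return A `dist_model` object for use with [find_threshold()].
#' @seealso [wldm()]
#' @export
ggdm <- function() {
  fit_g <- function(levels, counts) {
    ms <- weighted_mean_sd(levels, counts)
    c(mean = unname(ms["mean"]), sd = unname(ms["sd"]))
  }
  lp_g <- function(x, theta) dnorm(x, theta["mean"], theta["sd"], log = TRUE)
  new_dist_model("ggdm", fit_g, fit_g, lp_g, lp_g)
}

#' Weibull-Lognormal distribution model (WLDM)
#'
#' The false emitters (background fluctuations that survived fitting) follow
#' a Weibull distribution; the true single-molecule emitters follow a
#' lognormal, the empirical shape of single-fluorophore photon-count
#' distributions. Weibull parameters are estimated by weighted maximum
#' likelihood (Newton iteration on the shape, method-of-moments fallback);
#' lognormal parameters are the weighted mean and standard deviation of the
#' log gray levels. Levels are shifted by +0.5 to keep level 0 in-support.
#'
#' @return A `dist_model` object for use with [find_threshold()].
#' @seealso [ggdm()]
#' @export
wldm <- function() {
  fit_w <- function(levels, counts) fit_weibull_weighted(levels, counts)
  fit_ln <- function(levels, counts) {
    ms <- weighted_mean_sd(log(levels + 0.5), counts)
    c(meanlog = unname(ms["mean"]), sdlog = unname(ms["sd"]))
  }
  lp_w <- function(x, theta)
    dweibull(x + 0.5, shape = theta["shape"], scale = theta["scale"],
             log = TRUE)
  lp_ln <- function(x, theta)
    dlnorm(x + 0.5, meanlog = theta["meanlog"], sdlog = theta["sdlog"],
           log = TRUE)
  new_dist_model("wldm", fit_w, fit_ln, lp_w, lp_ln)
}

#' Look up a distribution model by name
#'
#' @param model A `dist_model` object or one of `"ggdm"`, `"wldm"`.
#' @return A `dist_model` object.
#' @export
as_dist_model <- function(model) {
  if (inherits(model, "dist_model")) return(model)
  switch(match.arg(tolower(model), c("ggdm", "wldm")),
         ggdm = ggdm(), wldm = wldm())
}
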