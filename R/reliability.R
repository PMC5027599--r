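# Per-emitter reliability from the fitted false/true class densities, and
# rendering of super-resolution and reliability-map images.

#' Reliability of an emitter as a function of its characteristic value
#'
#' Given the fitted class densities, the expected number of false and true
#' emitters at characteristic value `x` is `NF(x) = total * P_false *
#' f_false(x)` and `NT(x) = total * P_true * f_true(x)`; the reliability —
#' the posterior probability that an emitter with that value is true — is
#' `R(x) = NT(x) / (NF(x) + NT(x))`. Computed in log space, so `R` is
#' defined for every `x` even where both expected counts underflow.
#'
#' @param result A [find_threshold()] result.
#' @param total Number of potential emitters behind the histogram (defaults
#'   to the histogram total).
#' @return Object of class `reliability_curve`: functions `R`, `NF`, `NT`
#'   of the raw characteristic value.
#' @export
reliability_curve <- function(result, total = result$total) {
  stopifnot(inherits(result, "threshold_result"))
  hist <- result$hist
  model <- result$model
  th0 <- result$theta_false; th1 <- result$theta_true
  p0 <- result$p_false; p1 <- result$p_true
  lvl <- function(v) raw_to_level(hist, v)
  # densities per raw characteristic unit (level density / bin width)
  NF <- function(v) total * p0 * exp(model$logpdf_false(lvl(v), th0)) /
    hist$width
  NT <- function(v) total * p1 * exp(model$logpdf_true(lvl(v), th1)) /
    hist$width
  R <- function(v) {
    d <- (log(p1) + model$logpdf_true(lvl(v), th1)) -
      (log(p0) + model$logpdf_false(lvl(v), th0))
    # both log-densities -Inf cannot happen for the supported families on
    # levels >= 0; plogis handles +-Inf limits (0 and 1) directly
    plogis(d)
  }
  structure(list(R = R, NF = NF, NT = NT, total = total),
            class = "reliability_curve")
}

#' @export
print.reliability_curve <- function(x, ...) {
  cat("<reliability_curve> over", x$total, "potential emitters\n")
  invisible(x)
}

# Shared binning for the rendering functions. Half-open bins [lo, hi).
render_bins <- function(x_nm, y_nm, render_pixel_nm, extent_nm) {
  if (is.null(extent_nm)) {
    extent_nm <- c(0, max(x_nm, 0) + render_pixel_nm,
                   0, max(y_nm, 0) + render_pixel_nm)
  }
  nx <- max(1L, as.integer(ceiling((extent_nm[2] - extent_nm[1]) /
                                     render_pixel_nm)))
  ny <- max(1L, as.integer(ceiling((extent_nm[4] - extent_nm[3]) /
                                     render_pixel_nm)))
  ix <- floor((x_nm - extent_nm[1]) / render_pixel_nm) + 1L
  iy <- floor((y_nm - extent_nm[3]) / render_pixel_nm) + 1L
  inside <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  list(ix = ix, iy = iy, inside = inside, nx = nx, ny = ny,
       origin = extent_nm[c(1, 3)])
}

new_rendered_image <- function(values, render_pixel_nm, origin, kind) {
  structure(list(values = values, render_pixel_nm = render_pixel_nm,
                 origin = origin, kind = kind),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %s, %d x %d px at %g nm/px\n", x$kind,
              nrow(x$values), ncol(x$values), x$render_pixel_nm))
  invisible(x)
}

#' Render a super-resolution image from localizations
#'
#' Plain 2D histogram rendering: each localization adds one count to the
#' rendered pixel containing it (half-open bins). Optionally each
#' localization is splatted as a small Gaussian blob (sigma = half a
#' rendered pixel) for visual smoothness; the total intensity is conserved
#' either way.
#'
#' @param x_nm,y_nm Localization coordinates in nm.
#' @param render_pixel_nm Rendered pixel size in nm (default 10).
#' @param extent_nm Rendered region `c(xmin, xmax, ymin, ymax)` in nm;
#'   default covers the data starting at 0.
#' @param blobs If `TRUE`, render Gaussian blobs instead of counts.
#' @return A `rendered_image` (rows = y, columns = x).
#' @export
render_superres <- function(x_nm, y_nm, render_pixel_nm = 10,
                            extent_nm = NULL, blobs = FALSE) {
  if (length(x_nm) != length(y_nm))
    stop("'x_nm' and 'y_nm' lengths differ", call. = FALSE)
  if (length(x_nm) == 0L) {
    warning("no localizations to render; returning an all-zero image")
    b <- render_bins(numeric(), numeric(), render_pixel_nm,
                     extent_nm %||% c(0, render_pixel_nm, 0, render_pixel_nm))
    return(new_rendered_image(matrix(0, b$ny, b$nx), render_pixel_nm,
                              b$origin, "density"))
  }
  b <- render_bins(x_nm, y_nm, render_pixel_nm, extent_nm)
  img <- matrix(0, b$ny, b$nx)
  if (!blobs) {
    idx <- cbind(b$iy[b$inside], b$ix[b$inside])
    tab <- table(factor((idx[, 1] - 1L) * b$nx + idx[, 2]))
    lin <- as.integer(names(tab))
    img[cbind((lin - 1L) %/% b$nx + 1L, (lin - 1L) %% b$nx + 1L)] <-
      as.numeric(tab)
  } else {
    s <- 0.5 * render_pixel_nm
    hw <- 3L
    xs <- (x_nm - b$origin[1]) / render_pixel_nm
    ys <- (y_nm - b$origin[2]) / render_pixel_nm
    for (k in which(b$inside)) {
      cx <- b$ix[k]; cy <- b$iy[k]
      jj <- max(1L, cx - hw):min(b$nx, cx + hw)
      ii <- max(1L, cy - hw):min(b$ny, cy + hw)
      gx <- exp(-((jj - 0.5) - xs[k])^2 / (2 * (s / render_pixel_nm)^2))
      gy <- exp(-((ii - 0.5) - ys[k])^2 / (2 * (s / render_pixel_nm)^2))
      blob <- outer(gy, gx)
      img[ii, jj] <- img[ii, jj] + blob / sum(blob)
    }
  }
  new_rendered_image(img, render_pixel_nm, b$origin, "density")
}

#' Render a reliability map
#'
#' For every rendered pixel, the mean reliability `R(n_psf)` over all
#' potential emitters (accepted and rejected) falling in that pixel; the
#' map is then normalized by its maximum. Pixels containing no emitters
#' are 0.
#'
#' @param x_nm,y_nm Coordinates of all potential emitters in nm.
#' @param reliability Per-emitter reliability values in `[0, 1]` (e.g.
#'   `curve$R(fits$n_psf)`).
#' @inheritParams render_superres
#' @return A `rendered_image` with values in `[0, 1]`.
#' @export
render_reliability_map <- function(x_nm, y_nm, reliability,
                                   render_pixel_nm = 10, extent_nm = NULL) {
  if (length(x_nm) == 0L) {
    warning("no emitters to render; returning an all-zero map")
    b <- render_bins(numeric(), numeric(), render_pixel_nm,
                     extent_nm %||% c(0, render_pixel_nm, 0, render_pixel_nm))
    return(new_rendered_image(matrix(0, b$ny, b$nx), render_pixel_nm,
                              b$origin, "reliability"))
  }
  stopifnot(length(reliability) == length(x_nm))
  b <- render_bins(x_nm, y_nm, render_pixel_nm, extent_nm)
  img <- matrix(0, b$ny, b$nx)
  ii <- b$iy[b$inside]; jj <- b$ix[b$inside]
  rr <- reliability[b$inside]
  lin <- (ii - 1L) * b$nx + jj
  s <- rowsum(rr, lin)
  n <- rowsum(rep(1, length(lin)), lin)
  lin_u <- as.integer(rownames(s))
  img[cbind((lin_u - 1L) %/% b$nx + 1L, (lin_u - 1L) %% b$nx + 1L)] <-
    s[, 1] / n[, 1]
  mx <- max(img)
  if (mx > 0) img <- img / mx
  new_rendered_image(img, render_pixel_nm, b$origin, "reliability")
}
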