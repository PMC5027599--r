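# Ground-truthed synthetic SMLM movie generator. Sparse blinking emitters
# sit on filament structures; each activation deposits a fixed-width
# Gaussian PSF with a lognormal photoelectron count on a smooth structured
# background; pixelwise Poisson noise is applied to the expected
# photoelectron image, which is then converted to camera ADU.

#' Specify a synthetic SMLM scene
#'
#' @param image_shape `c(rows, cols)` of the camera frame in pixels.
#' @param structures List of polylines (matrices with columns `x_nm`,
#'   `y_nm`; a single-row matrix is an isolated point emitter site).
#' @param emitter_density Mean number of emitter sites per micrometer of
#'   filament length.
#' @param frames Number of movie frames.
#' @param on_probability Per-frame activation probability of each emitter
#'   site.
#' @param photons Distribution of true-emitter photoelectron counts per
#'   activation: `list(meanlog, sdlog)` of a lognormal.
#' @param background_rate Mean background photoelectrons per pixel. The
#'   background field is spatially smooth but not flat (a gentle diagonal
#'   ramp with this mean), so the background estimator is actually
#'   exercised.
#' @param read_noise_sd Gaussian read noise added in ADU after gain
#'   conversion (default 0).
#' @param poisson_noise Apply Poisson photon statistics (default TRUE;
#'   turning it off gives the noiseless expected image).
#' @param seed RNG seed; a fixed seed makes the movie and ground truth
#'   bit-reproducible.
#' @return Object of class `scene_spec`.
#' @seealso [standard_scene()], [simulate_movie()]
#' @export
scene_spec <- function(image_shape = c(128L, 128L), structures,
                       emitter_density = 30, frames = 200L,
                       on_probability = 0.005,
                       photons = list(meanlog = log(800), sdlog = 0.35),
                       background_rate = 10, read_noise_sd = 0,
                       poisson_noise = TRUE, seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16),
            is.list(structures), length(structures) >= 1L,
            emitter_density >= 0, frames >= 1L,
            on_probability >= 0, on_probability <= 1,
            is.list(photons), background_rate >= 0, read_noise_sd >= 0)
  structures <- lapply(structures, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 2L) stop("each structure must be an n x 2 matrix of nm",
                            " coordinates", call. = FALSE)
    colnames(s) <- c("x_nm", "y_nm")
    s
  })
  structure(
    list(image_shape = as.integer(image_shape), structures = structures,
         emitter_density = emitter_density, frames = as.integer(frames),
         on_probability = on_probability, photons = photons,
         background_rate = background_rate, read_noise_sd = read_noise_sd,
         poisson_noise = isTRUE(poisson_noise), seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px, %d frames, %d structures, seed %d\n",
              x$image_shape[1], x$image_shape[2], x$frames,
              length(x$structures), x$seed))
  invisible(x)
}

#' The canonical synthetic test scene
#'
#' Three crossing filaments in a 128 x 128 pixel field at 70 nm effective
#' pixel size (8.96 x 8.96 um), 200 frames, lognormal photoelectron counts
#' with median about 800 per activation, 10 background photoelectrons per
#' pixel. Used by the end-to-end examples and tests; different `seed`s give
#' statistically identical but independent scenes.
#'
#' @param seed RNG seed for the scene.
#' @return A [scene_spec()].
#' @export
standard_scene <- function(seed = 1L) {
  filaments <- list(
    rbind(c(400, 1200), c(8500, 7600)),
    rbind(c(600, 8300), c(8400, 900)),
    rbind(c(4500, 300), c(4650, 8700))
  )
  scene_spec(image_shape = c(128L, 128L), structures = filaments,
             emitter_density = 30, frames = 200L, on_probability = 0.005,
             photons = list(meanlog = log(800), sdlog = 0.35),
             background_rate = 10, read_noise_sd = 0, poisson_noise = TRUE,
             seed = seed)
}

# Evaluate the local RNG stream of `expr` under `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sample emitter site positions along the scene structures: a Poisson
# number of sites per polyline, uniform in arclength.
place_emitters <- function(spec) {
  out <- list()
  for (s in spec$structures) {
    if (nrow(s) == 1L) {
      out[[length(out) + 1L]] <- s
      next
    }
    seg <- diff(s)
    seg_len <- sqrt(rowSums(seg^2))
    total_um <- sum(seg_len) / 1000
    n <- rpois(1, spec$emitter_density * total_um)
    if (n == 0) next
    at <- runif(n, 0, sum(seg_len))
    cum <- c(0, cumsum(seg_len))
    k <- findInterval(at, cum, rightmost.closed = TRUE)
    k[k > nrow(seg)] <- nrow(seg)
    frac <- (at - cum[k]) / seg_len[k]
    out[[length(out) + 1L]] <- cbind(x_nm = s[k, 1] + frac * seg[k, 1],
                                     y_nm = s[k, 2] + frac * seg[k, 2])
  }
  if (length(out) == 0L)
    return(matrix(numeric(), 0, 2,
                  dimnames = list(NULL, c("x_nm", "y_nm"))))
  do.call(rbind, out)
}

# Smooth structured background field with the requested mean rate: a
# gentle diagonal ramp (85% to 115% of the mean).
background_field <- function(shape, rate) {
  ii <- (seq_len(shape[1]) - 0.5) / shape[1]
  jj <- (seq_len(shape[2]) - 0.5) / shape[2]
  rate * (0.85 + 0.3 * outer(ii, jj, function(a, b) (a + b) / 2))
}

#' Simulate a synthetic SMLM movie with ground truth
#'
#' Per frame, each emitter site activates independently with
#' `on_probability`; each activation draws a photoelectron count from the
#' photon distribution and deposits a sampled fixed-width Gaussian PSF of
#' width `s0_px` at its position. The smooth background field is added,
#' pixelwise Poisson noise is applied to the expected photoelectron image
#' (unless disabled), and the result is converted to integer ADU through
#' the camera model (`I = gain * n + offset`, plus optional Gaussian read
#' noise, clamped to the 16-bit range).
#'
#' @param spec A [scene_spec()].
#' @param cam A [camera_optics()].
#' @return List with `frames` (list of integer ADU matrices),
#'   `ground_truth` (data.frame `frame` (0-based), `x_nm`, `y_nm`,
#'   `photons`), and `emitters` (site positions in nm).
#' @export
simulate_movie <- function(spec, cam) {
  stopifnot(inherits(spec, "scene_spec"), inherits(cam, "camera_optics"))
  optics <- derive_optics(cam)
  p_eff <- optics$p_eff_nm
  shp <- spec$image_shape
  field_nm <- c(shp[2] * p_eff, shp[1] * p_eff)   # x (cols), y (rows)
  with_seed(spec$seed, {
    em <- place_emitters(spec)
    inside <- em[, 1] >= 0 & em[, 1] < field_nm[1] &
      em[, 2] >= 0 & em[, 2] < field_nm[2]
    if (any(!inside)) {
      warning(sum(!inside), " emitter site(s) outside the image were dropped")
      em <- em[inside, , drop = FALSE]
    }
    n_em <- nrow(em)
    ex_px <- em[, 1] / p_eff   # continuous pixel coords, corner origin
    ey_px <- em[, 2] / p_eff
    bg <- background_field(shp, spec$background_rate)
    s0 <- optics$s0_px
    win <- as.integer(ceiling(5 * s0))
    norm <- 1 / (2 * pi * s0^2)
    frames <- vector("list", spec$frames)
    gt <- vector("list", spec$frames)
    for (f in seq_len(spec$frames)) {
      expected <- bg
      if (n_em > 0) {
        on <- runif(n_em) < spec$on_probability
        idx_on <- which(on)
        if (length(idx_on)) {
          ph <- rlnorm(length(idx_on), spec$photons$meanlog,
                       spec$photons$sdlog)
          for (a in seq_along(idx_on)) {
            e <- idx_on[a]
            cj <- as.integer(ceiling(ex_px[e]))
            ci <- as.integer(ceiling(ey_px[e]))
            jj <- max(1L, cj - win):min(shp[2], cj + win)
            ii <- max(1L, ci - win):min(shp[1], ci + win)
            gx <- exp(-((jj - 0.5) - ex_px[e])^2 / (2 * s0^2))
            gy <- exp(-((ii - 0.5) - ey_px[e])^2 / (2 * s0^2))
            expected[ii, jj] <- expected[ii, jj] +
              ph[a] * norm * outer(gy, gx)
          }
          gt[[f]] <- data.frame(frame = f - 1L,
                                x_nm = em[idx_on, 1],
                                y_nm = em[idx_on, 2],
                                photons = ph)
        }
      }
      n_e <- if (spec$poisson_noise) {
        matrix(rpois(length(expected), expected), shp[1], shp[2])
      } else expected
      adu <- cam$gain * n_e + cam$offset
      if (spec$read_noise_sd > 0)
        adu <- adu + rnorm(length(adu), 0, spec$read_noise_sd)
      adu <- round(adu)
      adu[adu < 0] <- 0
      adu[adu > 65535] <- 65535
      frames[[f]] <- matrix(as.integer(adu), shp[1], shp[2])
    }
    gt_all <- do.call(rbind, gt[!vapply(gt, is.null, logical(1))])
    if (is.null(gt_all))
      gt_all <- data.frame(frame = integer(), x_nm = numeric(),
                           y_nm = numeric(), photons = numeric())
    rownames(gt_all) <- NULL
    list(frames = frames, ground_truth = gt_all, emitters = em)
  })
}
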