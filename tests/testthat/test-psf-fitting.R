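cam <- standard_camera()
optics <- derive_optics(cam)

test_that("initial guesses follow the amplitude-to-integral rule", {
  g <- initial_guess(peak_value = 10, bg_estimate = 10, optics = optics)
  expect_equal(g$n_psf, 1)   # zero excess floors at 1
  expect_equal(g$n_b, 10)
  g2 <- initial_guess(peak_value = 20, bg_estimate = 10, optics = optics)
  expect_equal(g2$n_psf, 2 * pi * optics$s0_px^2 * 10)
  expect_equal(g2$n_psf, 114.3, tolerance = 1e-3)
})

test_that("noiseless model spots are recovered to machine-level accuracy", {
  set.seed(21)
  for (rep in 1:10) {
    x0 <- 10 + runif(1, -0.5, 0.5); y0 <- 8 + runif(1, -0.5, 0.5)
    n_psf <- runif(1, 100, 3000); n_b <- runif(1, 0, 20)
    frame <- psf_model_frame(16, 20, x0, y0, n_psf, n_b, optics$s0_px)
    fit <- fit_psf(frame, i = 8, j = 10, bg = n_b, optics = optics)
    expect_true(fit$ok)
    expect_lt(abs(fit$x0 - x0), 1e-6)
    expect_lt(abs(fit$y0 - y0), 1e-6)
    expect_lt(abs(fit$n_psf - n_psf) / n_psf, 1e-6)
    expect_lt(abs(fit$n_b - n_b), 1e-4)
  }
})

test_that("the fit agrees with an independent LM optimizer on noisy data", {
  skip_if_not_installed("minpack.lm")
  set.seed(33)
  truth <- psf_model_frame(13, 13, 6.3, 7.1, 800, 8, optics$s0_px)
  frame <- matrix(rpois(169, truth), 13, 13)
  fit <- fit_psf(frame, i = 7, j = 7, bg = 8, optics = optics)
  s0 <- optics$s0_px
  win <- 3:11   # the (2 h_f + 1) window the package fits
  resid_fun <- function(p) {
    m <- psf_model_frame(13, 13, p[1], p[2], p[3], p[4], s0)
    as.vector((frame - m)[win, win])
  }
  alt <- minpack.lm::nls.lm(par = c(6.5, 6.5, 500, 8), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  expect_equal(fit$x0, alt$par[1], tolerance = 1e-4)
  expect_equal(fit$y0, alt$par[2], tolerance = 1e-4)
  expect_equal(fit$n_psf, alt$par[3], tolerance = 1e-4)
  expect_equal(fit$n_b, alt$par[4], tolerance = 1e-3)
})

test_that("flat windows yield no retained fit", {
  frame <- matrix(5, 15, 15)
  fit <- fit_psf(frame, i = 8, j = 8, bg = 5, optics = optics)
  # no spot: either flagged failed or the integral stays at the floor
  expect_true(!fit$ok || fit$n_psf <= 1 + 1e-6)
})

test_that("fitting is equivariant under integer translations", {
  set.seed(5)
  truth <- psf_model_frame(30, 30, 14.35, 11.72, 1200, 6, optics$s0_px)
  frame <- matrix(rpois(900, truth), 30, 30)
  f1 <- fit_psf(frame, i = 12, j = 15, bg = 6, optics = optics)
  shifted <- matrix(6, 30, 30)   # shift content by (+3, +2)
  shifted[4:30, 3:30] <- frame[1:27, 1:28]
  f2 <- fit_psf(shifted, i = 15, j = 17, bg = 6, optics = optics)
  expect_equal(f2$x0 - f1$x0, 2, tolerance = 1e-5)
  expect_equal(f2$y0 - f1$y0, 3, tolerance = 1e-5)
  expect_equal(f2$n_psf, f1$n_psf, tolerance = 1e-5)
})

test_that("close-spot pruning keeps the brightest and is idempotent", {
  fits <- data.frame(x0 = c(10, 10 + 0.5 * optics$s0_px, 20),
                     y0 = c(10, 10, 10),
                     n_psf = c(900, 700, 800))
  kept <- prune_close_spots(fits, optics)
  expect_equal(kept$n_psf, c(900, 800))
  # two fits 3 s0 apart both survive
  far <- data.frame(x0 = c(10, 10 + 3 * optics$s0_px), y0 = c(5, 5),
                    n_psf = c(900, 700))
  expect_identical(nrow(prune_close_spots(far, optics)), 2L)
  expect_equal(prune_close_spots(kept, optics), kept)
})

test_that("pruning matches the largest-first suppression oracle", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(5:40, 1)
    fits <- data.frame(x0 = runif(n, 0, 12), y0 = runif(n, 0, 12),
                       n_psf = runif(n, 10, 1000))
    got <- prune_close_spots(fits, optics)
    want <- brute_prune(fits, optics$s0_px)
    expect_equal(got, want)
    expect_lte(nrow(got), n)
  }
})
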