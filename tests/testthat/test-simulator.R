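cam <- standard_camera()

small_scene <- function(...) {
  scene_spec(image_shape = c(48L, 48L),
             structures = list(rbind(c(300, 300), c(3000, 3000))),
             emitter_density = 20, frames = 30L, on_probability = 0.05,
             background_rate = 8, seed = 9, ...)
}

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_movie(small_scene(), cam)
  b <- simulate_movie(small_scene(), cam)
  expect_identical(a$frames, b$frames)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(standard_scene(3), standard_scene(3))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(simulate_movie(small_scene(), cam))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("zero activation probability gives pure background", {
  sc <- small_scene()
  sc$on_probability <- 0
  mv <- simulate_movie(sc, cam)
  expect_identical(nrow(mv$ground_truth), 0L)
  # all frames are background only: no pixel far above the background rate
  mx <- max(unlist(mv$frames))
  expect_lt((mx - cam$offset) / cam$gain, 8 * 3 + 25)
})

test_that("a noiseless single emitter reproduces the PSF model exactly", {
  opt <- derive_optics(cam)
  sc <- scene_spec(image_shape = c(32L, 32L),
                   structures = list(matrix(c(1100, 1150), 1)),
                   frames = 1L, on_probability = 1, background_rate = 0,
                   poisson_noise = FALSE, seed = 4)
  mv <- simulate_movie(sc, cam)
  expect_identical(nrow(mv$ground_truth), 1L)
  ph <- mv$ground_truth$photons
  want <- psf_model_frame(32, 32, 1100 / 70, 1150 / 70, ph, 0, opt$s0_px)
  got <- (mv$frames[[1]] - cam$offset) / cam$gain
  # ADU rounding is the only discrepancy allowed
  expect_lt(max(abs(got - want)), 0.5 / cam$gain + 1e-9)
})

test_that("activation counts follow the binomial expectation", {
  sc <- scene_spec(image_shape = c(48L, 48L),
                   structures = list(rbind(c(200, 200), c(3100, 3100))),
                   emitter_density = 25, frames = 400L,
                   on_probability = 0.02, background_rate = 5, seed = 21)
  mv <- simulate_movie(sc, cam)
  n_em <- nrow(mv$emitters)
  expected <- n_em * 0.02 * 400
  sdev <- sqrt(400 * n_em * 0.02 * 0.98)
  expect_lt(abs(nrow(mv$ground_truth) - expected), 3 * sdev)
})

test_that("ground-truth photon counts follow the generating lognormal", {
  sc <- scene_spec(image_shape = c(48L, 48L),
                   structures = list(rbind(c(200, 200), c(3100, 3100))),
                   emitter_density = 30, frames = 300L,
                   on_probability = 0.05,
                   photons = list(meanlog = log(800), sdlog = 0.35),
                   background_rate = 5, seed = 30)
  mv <- simulate_movie(sc, cam)
  ks <- suppressWarnings(
    stats::ks.test(mv$ground_truth$photons, "plnorm", log(800), 0.35))
  expect_gt(ks$p.value, 0.01)
})

test_that("emitters outside the field are dropped with a warning", {
  sc <- scene_spec(image_shape = c(32L, 32L),
                   structures = list(matrix(c(99000, 100), 1),
                                     matrix(c(500, 500), 1)),
                   frames = 2L, on_probability = 1, background_rate = 0,
                   seed = 2)
  expect_warning(mv <- simulate_movie(sc, cam), "outside")
  expect_identical(nrow(mv$emitters), 1L)
})
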