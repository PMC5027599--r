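# A hand-built threshold result with known Gaussian class densities, for
# closed-form reliability checks.
make_gg_result <- function(mu0, sd0, mu1, sd1, p0 = 0.5, n = 1000,
                           width = 1, lo = 0) {
  model <- ggdm()
  hist <- structure(list(counts = rep(1L, 10), levels = 0:9, n_levels = 10L,
                         lo = lo, width = width, total = n),
                    class = "characteristic_histogram")
  structure(
    list(threshold = (mu0 + mu1) / 2, T_star = as.integer((mu0 + mu1) / 2),
         theta_false = c(mean = mu0, sd = sd0),
         theta_true = c(mean = mu1, sd = sd1),
         p_false = p0, p_true = 1 - p0,
         criterion_trace = data.frame(), model_name = "ggdm",
         model = model, hist = hist, total = n),
    class = "threshold_result")
}

test_that("reliability is 0.5 exactly where the class densities cross", {
  res <- make_gg_result(100, 15, 300, 15)   # equal sd, equal mass
  curve <- reliability_curve(res)
  expect_equal(curve$R(200), 0.5)           # midpoint of the means
  expect_equal(curve$NF(200), curve$NT(200))
  # R spans [0, 1] and is monotone for this likelihood-ratio-ordered pair
  xs <- seq(0, 400, by = 2)
  r <- curve$R(xs)
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(diff(r) >= -1e-12))
  expect_equal(curve$R(0), 0, tolerance = 1e-6)
  expect_equal(curve$R(400), 1, tolerance = 1e-6)
})

test_that("reliability stays defined where both densities underflow", {
  res <- make_gg_result(100, 10, 300, 10)
  curve <- reliability_curve(res)
  # 1e4 sd above both means: densities underflow but the posterior is 1
  expect_equal(curve$R(1e5), 1)
  expect_equal(curve$R(-1e5), 0)
})

test_that("reliability follows fitted results end to end", {
  set.seed(31)
  v <- c(rweibull(3000, 1.5, 40), rlnorm(5000, 6.0, 0.3))
  res <- find_threshold(build_histogram(v), wldm())
  curve <- reliability_curve(res)
  xs <- seq(1, 1200, by = 5)
  r <- curve$R(xs)
  expect_true(all(is.finite(r) & r >= 0 & r <= 1))
  # reliability at the threshold is intermediate; far tails are decisive
  expect_gt(curve$R(1100), 0.99)
  expect_lt(curve$R(5), 0.2)
})

test_that("histogram rendering conserves counts and uses half-open bins", {
  img <- render_superres(x_nm = 55, y_nm = 25, render_pixel_nm = 10,
                         extent_nm = c(0, 100, 0, 100))
  expect_equal(sum(img$values), 1)
  expect_equal(img$values[3, 6], 1)   # y in [20,30) -> row 3; x in [50,60) -> col 6
  set.seed(8)
  x <- runif(500, 0, 100); y <- runif(500, 0, 100)
  img2 <- render_superres(x, y, 10, c(0, 100, 0, 100))
  expect_equal(sum(img2$values), 500)
  # two localizations 5 nm apart may share a bin or split at a boundary
  img3 <- render_superres(c(12, 17), c(5, 5), 10, c(0, 100, 0, 100))
  expect_equal(sum(img3$values), 2)
  expect_equal(max(img3$values), 2)   # both in [10,20)
  img4 <- render_superres(c(8, 13), c(5, 5), 10, c(0, 100, 0, 100))
  expect_equal(sort(img4$values[img4$values > 0]), c(1, 1))
})

test_that("rendering is translation-consistent", {
  set.seed(12)
  x <- runif(200, 20, 80); y <- runif(200, 20, 80)
  a <- render_superres(x, y, 10, c(0, 120, 0, 120))
  b <- render_superres(x + 10, y, 10, c(0, 120, 0, 120))
  expect_equal(b$values[, 2:12], a$values[, 1:11])
})

test_that("empty rendering warns and returns a zero image", {
  expect_warning(img <- render_superres(numeric(), numeric(), 10,
                                        c(0, 50, 0, 50)), "no localizations")
  expect_true(all(img$values == 0))
})

test_that("reliability maps average per pixel and max-normalize", {
  img <- render_reliability_map(x_nm = c(5, 5, 45), y_nm = c(5, 5, 45),
                                reliability = c(0.2, 0.8, 1.0),
                                render_pixel_nm = 10,
                                extent_nm = c(0, 50, 0, 50))
  expect_equal(img$values[1, 1], 0.5)   # mean(0.2, 0.8), max already 1
  expect_equal(img$values[5, 5], 1.0)
  expect_true(all(img$values >= 0 & img$values <= 1))
  # normalization by the maximum mean
  img2 <- render_reliability_map(c(5, 45), c(5, 45), c(0.4, 0.8), 10,
                                 c(0, 50, 0, 50))
  expect_equal(img2$values[1, 1], 0.5)
  expect_equal(img2$values[5, 5], 1.0)
})
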