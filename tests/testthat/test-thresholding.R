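test_that("histogram construction follows the level-count rules", {
  expect_error(build_histogram(1:5), "at least 10")
  set.seed(3)
  v <- runif(1000, 0, 500.2); v[which.max(v)] <- 500.2
  h <- build_histogram(v)
  expect_identical(h$n_levels, 501L)
  expect_identical(sum(h$counts), 1000L)
  # never more levels than values
  h2 <- build_histogram(runif(20, 0, 3000))
  expect_identical(h2$n_levels, 20L)
  # explicit level count is honored
  h3 <- build_histogram(v, n_levels = 64)
  expect_identical(h3$n_levels, 64L)
  expect_identical(sum(h3$counts), 1000L)
})

test_that("prior masses are histogram mass fractions", {
  v <- c(rep(10, 500), rep(90, 500))   # equal-mass two-spike histogram
  h <- build_histogram(v, n_levels = 91)
  r <- gmet_criterion(h, T = 50, model = ggdm())
  expect_equal(r$p_false, 0.5)
  expect_equal(r$p_true, 0.5)
  expect_false(r$valid)   # two spikes: not enough occupied levels per side
})

test_that("empty gray levels do not change the criterion", {
  set.seed(9)
  v <- c(rnorm(300, 25, 5), rnorm(300, 75, 8))
  v <- v[v > 0 & v < 100]
  h1 <- build_histogram(v, n_levels = 101)
  # pad with trailing empty levels only: J(T) must be unchanged for T < 100
  lev_pad <- build_histogram(v, n_levels = 101)
  lev_pad$counts <- c(lev_pad$counts, rep(0L, 20))
  lev_pad$levels <- 0:120
  lev_pad$n_levels <- 121L
  for (T in c(40, 50, 60))
    expect_equal(gmet_criterion(lev_pad, T, ggdm())$J,
                 gmet_criterion(h1, T, ggdm())$J)
})

test_that("the reported threshold is an exact argmin of the criterion trace", {
  set.seed(15)
  v <- c(rnorm(2000, 40, 8), rnorm(3000, 160, 25))
  v <- v[v > 0]
  h <- build_histogram(v)
  for (model in list(ggdm(), wldm())) {
    res <- find_threshold(h, model)
    # independent exhaustive re-evaluation through the public per-T op
    J_all <- vapply(0:(h$n_levels - 2L),
                    function(T) gmet_criterion(h, T, model)$J, numeric(1))
    expect_equal(min(J_all[is.finite(J_all)]),
                 gmet_criterion(h, res$T_star, model)$J)
    expect_equal(res$threshold,
                 h$lo + (res$T_star + 0.5) * h$width)
    expect_equal(res$p_false + res$p_true, 1)
    # trace agrees with the direct evaluation everywhere it is finite
    tr <- res$criterion_trace
    expect_equal(tr$J[is.finite(J_all)], J_all[is.finite(J_all)])
  }
})

test_that("GGDM thresholds track the Bayes crossing on a naive-oracle histogram", {
  set.seed(26)
  v <- c(rnorm(1200, 30, 6), rnorm(1800, 110, 15))
  v <- v[v > 0]
  h <- build_histogram(v)
  res <- find_threshold(h, ggdm())
  # fully independent criterion written from the definition
  J_naive <- vapply(0:(h$n_levels - 2L),
                    function(T) naive_ggdm_J(h$counts, T), numeric(1))
  expect_equal(gmet_criterion(h, res$T_star, ggdm())$J,
               min(J_naive[is.finite(J_naive)]))
  cross <- uniroot(function(x) 0.4 * dnorm(x, 30, 6) - 0.6 * dnorm(x, 110, 15),
                   c(35, 100))$root
  expect_lt(abs(res$threshold - cross), 10)
})

test_that("degenerate histograms raise a not-bimodal error", {
  set.seed(2)
  v <- runif(100, 0, 4)   # too few occupied levels for two sides
  expect_error(find_threshold(build_histogram(v, n_levels = 6), ggdm()),
               "not bimodal")
})

test_that("emitter selection partitions at the threshold", {
  fits <- data.frame(n_psf = c(0.5, 1, 2, 150, 800))
  parts <- select_emitters(fits, 1)
  expect_equal(parts$accepted$n_psf, c(1, 2, 150, 800))
  expect_identical(nrow(parts$accepted) + nrow(parts$rejected), nrow(fits))
  high <- select_emitters(fits, 1e6)
  expect_identical(nrow(high$accepted), 0L)
})

test_that("weighted Weibull and lognormal estimators recover known parameters", {
  set.seed(44)
  x <- rweibull(20000, shape = 1.5, scale = 120)
  lev <- pmin(round(x), 400)
  cnt <- tabulate(lev + 1, 401)
  model <- wldm()
  th <- model$fit_false(0:400, cnt)
  expect_equal(unname(th["shape"]), 1.5, tolerance = 0.03)
  expect_equal(unname(th["scale"]), 120, tolerance = 0.03)
  y <- rlnorm(20000, 6.3, 0.35)
  levy <- round(y)
  cnty <- tabulate(levy + 1, max(levy) + 1)
  th2 <- model$fit_true(0:max(levy), cnty)
  expect_equal(unname(th2["meanlog"]), 6.3, tolerance = 0.01)
  expect_equal(unname(th2["sdlog"]), 0.35, tolerance = 0.03)
})
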