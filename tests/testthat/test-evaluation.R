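test_that("identical tables score perfectly", {
  set.seed(19)
  ref <- data.frame(frame = rep(0:4, each = 3),
                    x_nm = runif(15, 0, 5000), y_nm = runif(15, 0, 5000))
  rep_ <- match_localizations(ref, ref, tolerance_nm = 100)
  expect_equal(rep_$jaccard, 1)
  expect_equal(rep_$precision, 1)
  expect_equal(rep_$recall, 1)
  expect_equal(rep_$rmsd_nm, 0)
})

test_that("the toy 6/2/4 configuration gives the textbook ratios", {
  # 10 reference points on a line; 8 reconstructed: 6 close, 2 far off
  ref <- data.frame(frame = 0, x_nm = seq(0, 9000, by = 1000), y_nm = 0)
  rec <- data.frame(frame = 0,
                    x_nm = c(seq(0, 5000, by = 1000) + 20, 20000, 30000),
                    y_nm = 0)
  rep_ <- match_localizations(ref, rec, tolerance_nm = 100)
  expect_identical(c(rep_$tp, rep_$fp, rep_$fn), c(6L, 2L, 4L))
  expect_equal(rep_$jaccard, 0.5)
  expect_equal(rep_$precision, 0.75)
  expect_equal(rep_$recall, 0.6)
  expect_equal(rep_$rmsd_nm, 20)
})

test_that("matching equals the exhaustive maximum-matching oracle", {
  set.seed(55)
  for (rep in 1:15) {
    n_ref <- sample(1:12, 1); n_rec <- sample(1:12, 1)
    rx <- runif(n_ref, 0, 300); ry <- runif(n_ref, 0, 300)
    bx <- runif(n_rec, 0, 300); by <- runif(n_rec, 0, 300)
    tol <- runif(1, 40, 160)
    got <- match_localizations(
      data.frame(x_nm = rx, y_nm = ry),
      data.frame(x_nm = bx, y_nm = by),
      tolerance_nm = tol, per_frame = FALSE)
    want <- brute_match(rx, ry, bx, by, tol)
    expect_identical(got$tp, want$tp)
    if (got$tp > 0)
      expect_equal(sum(got$pairs$dist), want$dist, tolerance = 1e-9)
    expect_true(all(got$pairs$dist <= tol))
    # one-to-one
    expect_false(any(duplicated(got$pairs$ref)))
    expect_false(any(duplicated(got$pairs$rec)))
  }
})

test_that("metric identities and invariances hold", {
  set.seed(66)
  ref <- data.frame(frame = rep(0:2, each = 6),
                    x_nm = runif(18, 0, 2000), y_nm = runif(18, 0, 2000))
  rec <- data.frame(frame = rep(0:2, each = 5),
                    x_nm = runif(15, 0, 2000), y_nm = runif(15, 0, 2000))
  r <- match_localizations(ref, rec, 250)
  expect_identical(r$tp + r$fp, nrow(rec))
  expect_identical(r$tp + r$fn, nrow(ref))
  expect_lte(r$jaccard, min(r$precision, r$recall))
  # rigid translation of both tables changes nothing
  shift <- function(d) transform(d, x_nm = x_nm + 517, y_nm = y_nm - 202)
  r2 <- match_localizations(shift(ref), shift(rec), 250)
  expect_equal(r2[c("tp", "fp", "fn", "jaccard", "rmsd_nm")],
               r[c("tp", "fp", "fn", "jaccard", "rmsd_nm")])
  # tp is monotone in the tolerance
  tps <- vapply(c(50, 100, 200, 400, 800),
                function(tol) match_localizations(ref, rec, tol)$tp,
                integer(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("per-frame matching separates frames; global mode merges them", {
  ref <- data.frame(frame = 0, x_nm = 100, y_nm = 100)
  rec <- data.frame(frame = 1, x_nm = 100, y_nm = 100)
  expect_identical(match_localizations(ref, rec, 50)$tp, 0L)
  expect_identical(
    match_localizations(ref, rec, 50, per_frame = FALSE)$tp, 1L)
})

test_that("malformed tables are rejected", {
  ok <- data.frame(frame = 0, x_nm = 1, y_nm = 1)
  expect_error(match_localizations(ok, data.frame(frame = 0, x = 1), 50),
               "missing column")
  expect_error(match_localizations(ok, ok, -5), "positive")
  bad <- data.frame(frame = 0, x_nm = NA_real_, y_nm = 1)
  expect_error(match_localizations(ok, bad, 50), "finite")
})
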