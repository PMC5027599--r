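# Independent brute-force oracles used to validate the optimized
# implementations on small inputs.

# O(pixels x window) scan for locally brightest pixels: a pixel qualifies
# when it is >= every pixel within Euclidean distance r, and lies at least
# hf away from every border. No plateau deduplication (use frames without
# exact ties when comparing).
brute_local_maxima <- function(frame, r, hf) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- NULL
  for (i in (hf + 1):(nr - hf)) {
    for (j in (hf + 1):(nc - hf)) {
      ok <- TRUE
      for (di in -floor(r):floor(r)) {
        for (dj in -floor(r):floor(r)) {
          if (di == 0 && dj == 0) next
          if (di * di + dj * dj > r * r) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          if (frame[ii, jj] > frame[i, j]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) data.frame(i = integer(), j = integer())
  else data.frame(i = out[, 1], j = out[, 2])
}

# Exhaustive maximum matching between two point sets under a tolerance:
# enumerates all one-to-one assignments recursively and returns the best
# (max pairs, then min total distance).
brute_match <- function(rx, ry, bx, by, tol) {
  n_ref <- length(rx); n_rec <- length(bx)
  d <- sqrt(outer(rx, bx, "-")^2 + outer(ry, by, "-")^2)
  best <- list(tp = -1L, dist = Inf)
  recurse <- function(i, used, tp, total) {
    if (i > n_ref) {
      if (tp > best$tp || (tp == best$tp && total < best$dist - 1e-12))
        best <<- list(tp = tp, dist = total)
      return(invisible())
    }
    # upper bound prune: even matching every remaining ref cannot beat best
    if (tp + (n_ref - i + 1L) < best$tp) return(invisible())
    for (b in seq_len(n_rec)) {
      if (!used[b] && d[i, b] <= tol) {
        used[b] <- TRUE
        recurse(i + 1L, used, tp + 1L, total + d[i, b])
        used[b] <- FALSE
      }
    }
    recurse(i + 1L, used, tp, total)
  }
  recurse(1L, rep(FALSE, n_rec), 0L, 0)
  best
}

# Largest-first close-spot suppression, written independently: repeatedly
# take the unprocessed fit with the largest n_psf, keep it, and discard
# every other unprocessed fit within distance s0 of it.
brute_prune <- function(fits, s0) {
  remaining <- fits
  remaining$.row <- seq_len(nrow(fits))
  kept <- integer()
  while (nrow(remaining) > 0) {
    o <- order(-remaining$n_psf, remaining$x0, remaining$y0)
    top <- remaining[o[1], ]
    kept <- c(kept, top$.row)
    dd <- sqrt((remaining$x0 - top$x0)^2 + (remaining$y0 - top$y0)^2)
    remaining <- remaining[dd > s0, , drop = FALSE]
  }
  fits[sort(kept), , drop = FALSE]
}

# Independent evaluation of the minimum-error criterion for the
# Gaussian-Gaussian model at threshold T: weighted moments and dnorm,
# written from the definition.
naive_ggdm_J <- function(counts, T) {
  lev <- seq_along(counts) - 1L
  l0 <- lev[lev <= T & counts > 0]; c0 <- counts[lev <= T & counts > 0]
  l1 <- lev[lev > T & counts > 0];  c1 <- counts[lev > T & counts > 0]
  if (length(l0) < 5 || length(l1) < 5) return(Inf)
  tot <- sum(counts)
  p0 <- sum(c0) / tot; p1 <- sum(c1) / tot
  m0 <- sum(c0 * l0) / sum(c0); s0 <- sqrt(sum(c0 * (l0 - m0)^2) / sum(c0))
  m1 <- sum(c1 * l1) / sum(c1); s1 <- sqrt(sum(c1 * (l1 - m1)^2) / sum(c1))
  if (s0 <= 0 || s1 <= 0) return(Inf)
  -(sum(c0 * (log(p0) + dnorm(l0, m0, s0, log = TRUE))) +
      sum(c1 * (log(p1) + dnorm(l1, m1, s1, log = TRUE))))
}

# Evaluate the fixed-width Gaussian PSF model on a pixel grid
# (corner-origin convention: pixel (i, j) center at x = j - 0.5,
# y = i - 0.5).
psf_model_frame <- function(nr, nc, x0, y0, n_psf, n_b, s0) {
  xs <- matrix((1:nc) - 0.5, nr, nc, byrow = TRUE)
  ys <- matrix((1:nr) - 0.5, nr, nc)
  n_psf / (2 * pi * s0^2) *
    exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * s0^2)) + n_b
}
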