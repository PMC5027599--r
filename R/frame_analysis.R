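# Per-frame candidate detection (locally brightest spots) and background
# estimation. All functions operate on photoelectron-converted matrices.

# Integer offsets (di, dj) with 0 < di^2 + dj^2 <= r^2.
disk_offsets <- function(r) {
  fl <- floor(r)
  g <- expand.grid(di = -fl:fl, dj = -fl:fl)
  g <- g[g$di^2 + g$dj^2 <= r^2 & !(g$di == 0 & g$dj == 0), , drop = FALSE]
  g
}

# Shift a matrix by (di, dj) with out-of-frame cells set to `fill`.
shift_matrix <- function(m, di, dj, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 - di):min(nr, nr - di)
  cj <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(ri) && length(cj)) out[ri, cj] <- m[ri + di, cj + dj]
  out
}

#' Find locally brightest spots in a photoelectron frame
#'
#' A pixel is a spot candidate when its photoelectron count is greater than
#' or equal to every pixel within one Airy disk radius (circular, Euclidean
#' distance `<= r_airy_px`). No other pre-selection is applied: every locally
#' brightest spot goes on to PSF fitting. Candidates closer than `h_f` to any
#' image border are dropped so the square fit window fits inside the frame.
#'
#' Exact ties (plateaus) are resolved deterministically: among candidates of
#' equal value connected through overlapping Airy neighborhoods, only the
#' lexicographically first pixel (smallest row, then column) is kept. A
#' plateau that also touches equal-valued pixels which are themselves
#' dominated (some strictly brighter pixel within their Airy radius) is not
#' a local maximum as a region and is discarded entirely — so a flat
#' background around a bright spot produces no spurious candidate, while a
#' perfectly flat frame still yields exactly one.
#'
#' @param frame Numeric matrix of photoelectron counts
#'   (see [to_photoelectrons()]).
#' @param optics An [derive_optics()] result.
#' @return A data.frame with columns `i`, `j` (1-based row/column of the
#'   peak) and `peak` (photoelectron count there). Zero rows when the frame
#'   has no interior candidates.
#' @export
find_local_maxima <- function(frame, optics) {
  stopifnot(is.matrix(frame), inherits(optics, "optics_derived"))
  nr <- nrow(frame); nc <- ncol(frame)
  offs <- disk_offsets(optics$r_airy_px)
  is_max <- matrix(TRUE, nr, nc)
  for (k in seq_len(nrow(offs))) {
    is_max <- is_max &
      (frame >= shift_matrix(frame, offs$di[k], offs$dj[k], fill = -Inf))
  }
  # equal-valued neighbor that is itself dominated => the shared plateau is
  # not a regional maximum
  touches_dominated <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(offs))) {
    sh_val <- shift_matrix(frame, offs$di[k], offs$dj[k], fill = -Inf)
    sh_max <- shift_matrix(is_max + 0, offs$di[k], offs$dj[k], fill = 1)
    touches_dominated <- touches_dominated |
      (frame == sh_val & sh_max == 0)
  }
  hf <- optics$h_f
  # border exclusion: fit window (2 h_f + 1)^2 must lie inside the frame
  interior <- matrix(FALSE, nr, nc)
  if (nr >= 2 * hf + 1 && nc >= 2 * hf + 1)
    interior[(hf + 1):(nr - hf), (hf + 1):(nc - hf)] <- TRUE
  idx <- which(is_max & interior, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(i = integer(), j = integer(), peak = numeric()))
  cand <- data.frame(i = idx[, 1], j = idx[, 2],
                     peak = frame[idx],
                     dominated = touches_dominated[idx])
  cand <- cand[order(cand$i, cand$j), , drop = FALSE]
  cand <- dedup_plateaus(cand, optics$r_airy_px)
  cand <- cand[, c("i", "j", "peak")]
  rownames(cand) <- NULL
  cand
}

# Keep one candidate per plateau: candidates with identical values whose
# Airy neighborhoods overlap are merged (union-find), keeping the
# lexicographically first pixel. Input must be sorted by (i, j).
dedup_plateaus <- function(cand, r) {
  n <- nrow(cand)
  if (n <= 1L) return(cand[!cand$dominated, , drop = FALSE])
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  r2 <- r^2
  groups <- split(seq_len(n), cand$peak)
  for (g in groups) {
    if (length(g) < 2L) next
    for (a in seq_along(g)) {
      for (b in seq_len(a - 1L)) {
        ia <- g[a]; ib <- g[b]
        d2 <- (cand$i[ia] - cand$i[ib])^2 + (cand$j[ia] - cand$j[ib])^2
        if (d2 <= r2) {
          ra <- find(ia); rb <- find(ib)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # drop whole components that touch dominated equal-valued pixels
  bad_roots <- unique(roots[cand$dominated])
  keep <- setdiff(sort(unique(roots)), bad_roots)
  # the root of each component is its minimal (lexicographically first) index
  cand[keep, , drop = FALSE]
}

# 1D convolution along rows or columns with edge replication.
conv1d_axis <- function(m, kernel, hf, axis) {
  out <- matrix(0, nrow(m), ncol(m))
  n <- if (axis == 1L) nrow(m) else ncol(m)
  for (t in -hf:hf) {
    idx <- pmin(pmax(seq_len(n) + t, 1L), n)
    out <- out + kernel[t + hf + 1L] *
      (if (axis == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
  }
  out
}

# Running minimum over a clipped window of half-size w along one axis.
# Index clamping replicates the edge value, which equals the minimum over
# the border-clipped window.
minfilt_axis <- function(m, w, axis) {
  out <- NULL
  n <- if (axis == 1L) nrow(m) else ncol(m)
  for (t in -w:w) {
    idx <- pmin(pmax(seq_len(n) + t, 1L), n)
    s <- if (axis == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
    out <- if (is.null(out)) s else pmin(out, s)
  }
  out
}

#' Gaussian-smooth a photoelectron frame
#'
#' Convolution with an isotropic 2D Gaussian of standard deviation `s0_px`,
#' truncated to a `(2 h_f + 1)` square support and normalized to unit sum
#' (so constants are preserved). Image borders are handled by edge
#' replication. The truncated isotropic kernel is separable, so the
#' convolution runs as two 1D passes.
#'
#' @inheritParams find_local_maxima
#' @return Smoothed matrix, same shape.
#' @export
smooth_frame <- function(frame, optics) {
  stopifnot(is.matrix(frame), inherits(optics, "optics_derived"))
  hf <- optics$h_f
  k <- dnorm(-hf:hf, mean = 0, sd = optics$s0_px)
  k <- k / sum(k)   # each 1D factor unit-sum => 2D product kernel unit-sum
  conv1d_axis(conv1d_axis(frame, k, hf, axis = 1L), k, hf, axis = 2L)
}

#' Estimate the per-pixel background of a frame
#'
#' The background at a pixel is the minimum of the Gaussian-smoothed image
#' (see [smooth_frame()]) over the `(6 h_f + 1)` square centered on that
#' pixel, with the square clipped at the image borders. The minimum escapes
#' any single PSF-sized blob, so diffuse background is tracked while
#' emitters are not.
#'
#' @inheritParams find_local_maxima
#' @return Matrix of background photoelectron estimates, same shape.
#' @export
estimate_background <- function(frame, optics) {
  sm <- smooth_frame(frame, optics)
  w <- 3L * optics$h_f
  minfilt_axis(minfilt_axis(sm, w, axis = 1L), w, axis = 2L)
}
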