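# Scoring a reconstructed localization set against a reference set:
# tolerance-radius one-to-one matching and Jaccard / precision / recall /
# RMSD.

# Optimal one-to-one matching between two point sets restricted to pairs
# with distance <= tol: maximum cardinality, then minimum total distance.
# Solved as an assignment problem on the within-tolerance pair graph with a
# penalty cost for non-edges large enough that cardinality dominates.
# Returns a data.frame (ref, rec, dist) of matched pairs (indices into the
# input vectors).
match_points <- function(rx, ry, bx, by, tol) {
  n_ref <- length(rx); n_rec <- length(bx)
  if (n_ref == 0L || n_rec == 0L)
    return(data.frame(ref = integer(), rec = integer(), dist = numeric()))
  d2 <- outer(rx, bx, "-")^2 + outer(ry, by, "-")^2
  ok <- d2 <= tol^2
  ref_keep <- which(rowSums(ok) > 0)
  rec_keep <- which(colSums(ok) > 0)
  if (length(ref_keep) == 0L)
    return(data.frame(ref = integer(), rec = integer(), dist = numeric()))
  d <- sqrt(d2[ref_keep, rec_keep, drop = FALSE])
  okk <- ok[ref_keep, rec_keep, drop = FALSE]
  s <- max(length(ref_keep), length(rec_keep))
  big <- (s + 1) * (tol + 1)
  cost <- matrix(big, s, s)
  cost[seq_along(ref_keep), seq_along(rec_keep)] <- ifelse(okk, d, big)
  assign <- hungarian_cpp(cost)
  pairs <- data.frame(ref = integer(), rec = integer(), dist = numeric())
  for (a in seq_along(ref_keep)) {
    b <- assign[a]
    if (b <= length(rec_keep) && okk[a, b]) {
      pairs <- rbind(pairs, data.frame(ref = ref_keep[a], rec = rec_keep[b],
                                       dist = d[a, b]))
    }
  }
  pairs
}

#' Match reconstructed localizations against a reference set
#'
#' One-to-one matching of reconstructed localizations to reference
#' (ground-truth) localizations within a tolerance radius, by default per
#' frame (localizations in different frames never match). The matching is
#' solved optimally on the within-tolerance candidate-pair graph: it
#' maximizes the number of matched pairs and, among maximum matchings,
#' minimizes the total distance — deterministic and independent of input
#' order. Matched pairs are true positives (TP); unmatched reconstructed
#' points are false positives (FP); unmatched reference points are false
#' negatives (FN).
#'
#' @param reference Data.frame with columns `x_nm`, `y_nm` and (when
#'   `per_frame`) `frame`; the ground-truth set.
#' @param reconstructed Data.frame with the same columns; the localization
#'   set under evaluation.
#' @param tolerance_nm Matching radius in nm. The conventional choice is
#'   the PSF FWHM, see [psf_fwhm_nm()].
#' @param per_frame Match frame by frame (default) or globally.
#' @return Object of class `match_report`: counts `tp`, `fp`, `fn`; ratios
#'   `jaccard = tp / (tp + fp + fn)`, `precision = tp / (tp + fp)`,
#'   `recall = tp / (tp + fn)` (0/0 defined as 0); `rmsd_nm` over matched
#'   pairs (NA when there are none); `tolerance_nm`; and `pairs`, a
#'   data.frame of matched pairs with row indices into both inputs and the
#'   pair distance.
#' @export
#' @examples
#' ref <- data.frame(frame = 0, x_nm = c(0, 100), y_nm = c(0, 0))
#' rec <- data.frame(frame = 0, x_nm = c(5, 300), y_nm = c(0, 0))
#' match_localizations(ref, rec, tolerance_nm = 50)
match_localizations <- function(reference, reconstructed, tolerance_nm,
                                per_frame = TRUE) {
  need <- c("x_nm", "y_nm", if (per_frame) "frame")
  for (what in list(reference = reference, reconstructed = reconstructed)) {
    miss <- setdiff(need, names(what))
    if (length(miss))
      stop("localization table is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(tolerance_nm) || length(tolerance_nm) != 1L ||
      !is.finite(tolerance_nm) || tolerance_nm <= 0)
    stop("'tolerance_nm' must be a single positive number", call. = FALSE)
  bad <- function(d) any(!is.finite(d$x_nm)) || any(!is.finite(d$y_nm))
  if (bad(reference) || bad(reconstructed))
    stop("localization coordinates must be finite", call. = FALSE)

  n_ref <- nrow(reference); n_rec <- nrow(reconstructed)
  pairs <- data.frame(ref = integer(), rec = integer(), dist = numeric())
  if (n_ref > 0L && n_rec > 0L) {
    if (per_frame) {
      frames <- intersect(unique(reference$frame),
                          unique(reconstructed$frame))
      for (f in frames) {
        ri <- which(reference$frame == f)
        bi <- which(reconstructed$frame == f)
        p <- match_points(reference$x_nm[ri], reference$y_nm[ri],
                          reconstructed$x_nm[bi], reconstructed$y_nm[bi],
                          tolerance_nm)
        if (nrow(p)) {
          p$ref <- ri[p$ref]; p$rec <- bi[p$rec]
          pairs <- rbind(pairs, p)
        }
      }
    } else {
      pairs <- match_points(reference$x_nm, reference$y_nm,
                            reconstructed$x_nm, reconstructed$y_nm,
                            tolerance_nm)
    }
  }
  tp <- nrow(pairs)
  fp <- n_rec - tp
  fn <- n_ref - tp
  ratio <- function(num, den) if (den == 0) 0 else num / den
  structure(
    list(tp = tp, fp = fp, fn = fn,
         jaccard = ratio(tp, tp + fp + fn),
         precision = ratio(tp, tp + fp),
         recall = ratio(tp, tp + fn),
         rmsd_nm = if (tp > 0) sqrt(mean(pairs$dist^2)) else NA_real_,
         tolerance_nm = tolerance_nm, pairs = pairs),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> TP %d, FP %d, FN %d (tolerance %g nm)\n",
              x$tp, x$fp, x$fn, x$tolerance_nm))
  cat(sprintf("  Jaccard %.3f, precision %.3f, recall %.3f, RMSD %s nm\n",
              x$jaccard, x$precision, x$recall,
              if (is.na(x$rmsd_nm)) "NA" else sprintf("%.2f", x$rmsd_nm)))
  invisible(x)
}
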