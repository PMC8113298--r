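#' Jaccard similarity of two VOI masks
#'
#' `|A intersect B| / |A union B|`. When both masks are empty the value
#' is defined as 0 (with a warning), matching the convention that a
#' segmentation which captured nothing scores zero agreement.
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return Value in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  .checkSameGrid(a, b, "masks")
  u <- sum(a@membership | b@membership)
  if (u == 0L) {
    warning("both masks are empty; Jaccard defined as 0")
    return(0)
  }
  sum(a@membership & b@membership) / u
}

#' Overlap fraction of two VOI masks
#'
#' `|A intersect B| / min(|A|, |B|)`: reaches 1 when one mask contains
#' the other. If either mask is empty the value is defined as 0 with a
#' warning.
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return Value in \[0, 1\].
#' @export
overlapFraction <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  .checkSameGrid(a, b, "masks")
  na <- sum(a@membership); nb <- sum(b@membership)
  if (na == 0L || nb == 0L) {
    warning("an empty mask; overlap fraction defined as 0")
    return(0)
  }
  sum(a@membership & b@membership) / min(na, nb)
}

#' Agreement report between two segmentations
#'
#' Voxel-level agreement (Jaccard, overlap fraction) plus the MATV
#' difference and ratio between two masks of the same volume.
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return list with `jaccard`, `overlap_fraction`, `matv_a_ml`,
#'   `matv_b_ml`, `delta_matv_ml` (a - b), `matv_ratio` (a / b, NA when
#'   b is empty).
#' @export
agreementReport <- function(a, b) {
  vv <- prod(a@spacing) / 1000
  ma <- sum(a@membership) * vv
  mb <- sum(b@membership) * vv
  list(jaccard = jaccard(a, b),
       overlap_fraction = overlapFraction(a, b),
       matv_a_ml = ma, matv_b_ml = mb,
       delta_matv_ml = ma - mb,
       matv_ratio = if (mb > 0) ma / mb else NA_real_)
}

#' Pearson correlation between two MATV series
#'
#' @param x,y equal-length numeric vectors (n >= 3) with non-zero
#'   variance.
#' @return list with `r` and `r_squared`.
#' @export
pearsonR2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance in x or y")
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2)
}

#' Paired t test on log-transformed MATVs
#'
#' Tests whether two matched MATV series differ, on the log scale:
#' `d_i = log(x_i + offset) - log(y_i + offset)` with a two-sided paired
#' t test. The offset (default 1 mL) keeps patients with MATV 0 (methods
#' that segmented nothing) inside the transform; it is reported back so
#' results are self-describing. Identical series return t = 0, p = 1;
#' constant non-zero differences are degenerate (zero variance) and
#' raise an error.
#'
#' @param x,y equal-length numeric MATV vectors (mL), n >= 2.
#' @param offset value (mL) added inside the log; must make every
#'   transformed value positive.
#' @return list with `t`, `p`, `mean_delta` (log scale), `ci` (95% CI of
#'   the mean log difference), `df`, `offset`.
#' @export
pairedLogTTest <- function(x, y, offset = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  bad <- which(x + offset <= 0 | y + offset <= 0)
  if (length(bad))
    stop("non-positive value after offset at index ", bad[1],
         "; increase the offset")
  d <- log(x + offset) - log(y + offset)
  n <- length(d)
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (all(d == 0))
      return(list(t = 0, p = 1, mean_delta = 0, ci = c(0, 0),
                  df = n - 1, offset = offset))
    stop("constant non-zero log differences: paired t test is degenerate")
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_delta = unname(tt$estimate), ci = as.numeric(tt$conf.int),
       df = unname(tt$parameter), offset = offset)
}

#' Cohort-level MATV agreement between two methods
#'
#' Convenience wrapper combining Pearson correlation and the paired
#' log-scale t test over matched per-patient MATVs, plus raw-scale
#' summary differences.
#'
#' @param x,y equal-length per-patient MATV vectors (mL).
#' @param offset log-transform offset (mL), see [pairedLogTTest()].
#' @return list with `pearson` (see [pearsonR2()]), `log_t`
#'   (see [pairedLogTTest()]), `mean_delta_ml` (raw scale).
#' @export
cohortAgreement <- function(x, y, offset = 1) {
  list(pearson = pearsonR2(x, y),
       log_t = pairedLogTTest(x, y, offset),
       mean_delta_ml = mean(x - y))
}
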