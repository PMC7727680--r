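#' Pixelwise confusion counts between a predicted and a ground-truth mask
#'
#' @param pred,gt [binary_mask()]s of the same shape; `gt` is the reference.
#' @return a list with integer fields `tp`, `fp`, `tn`, `fn` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(pred, gt) {
  check_same_shape(pred, gt)
  p <- as_pixels(pred); g <- as_pixels(gt)
  list(tp = sum(p == 1L & g == 1L), fp = sum(p == 1L & g == 0L),
       tn = sum(p == 0L & g == 0L), fn = sum(p == 0L & g == 1L))
}

#' Overlap metrics from confusion counts
#'
#' Computes accuracy, sensitivity, Jaccard, Dice and the Matthews correlation
#' coefficient on the 0-1 scale:
#' \deqn{acc = (tp+tn)/n,\; sen = tp/(tp+fn),\; jaccard = tp/(tp+fp+fn),}
#' \deqn{dice = 2tp/(2tp+fp+fn),\; mcc = (tp\,tn - fp\,fn)/\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}.}
#' MCC is 0 when any factor of its denominator is 0. When both masks are
#' empty, Dice and Jaccard are 1 with a warning (perfect vacuous agreement);
#' sensitivity is `NA` when the ground truth is empty.
#'
#' @param counts result of [confusion_counts()] (or a list with `tp`, `fp`,
#'   `tn`, `fn`).
#' @return a list with fields `acc`, `sen`, `mcc`, `jaccard`, `dice`.
#' @export
overlap_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n <= 0) stop("empty confusion table", call. = FALSE)
  acc <- (tp + tn) / n
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  if (tp + fn == 0 && tp + fp == 0) {
    warning("both masks empty: Dice and Jaccard reported as vacuous 1")
    jac <- 1; dice <- 1
  } else {
    jac <- tp / (tp + fp + fn)
    dice <- 2 * tp / (2 * tp + fp + fn)
  }
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den) else 0
  list(acc = acc, sen = sen, mcc = mcc, jaccard = jac, dice = dice)
}

#' Symmetric Hausdorff distance between two mask boundaries
#'
#' The boundary of each mask is its set of foreground pixels touching the
#' background 4-connectedly (or the image border); the distance is the
#' symmetric Hausdorff distance
#' \eqn{\max(\sup_a \inf_b d(a,b), \sup_b \inf_a d(a,b))} between the two
#' boundary point sets with the Euclidean metric on pixel centres. Units are
#' pixels (no millimetre conversion is attempted).
#'
#' @param pred,gt nonempty [binary_mask()]s of the same shape.
#' @return a nonnegative distance in pixels.
#' @export
hausdorff_distance <- function(pred, gt) {
  check_same_shape(pred, gt)
  p <- as_pixels(pred); g <- as_pixels(gt)
  if (sum(p) == 0 || sum(g) == 0)
    stop("Hausdorff distance undefined for an empty mask", call. = FALSE)
  A <- which(mask_boundary(p), arr.ind = TRUE)
  B <- which(mask_boundary(g), arr.ind = TRUE)
  max(.directed_hd(A, B), .directed_hd(B, A))
}

# sup over rows of A of the distance to the nearest row of B, chunked.
.directed_hd <- function(A, B, chunk = 2048L) {
  worst <- 0
  for (start in seq(1L, nrow(A), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(A))
    d2 <- outer(A[idx, 1], B[, 1], "-")^2 + outer(A[idx, 2], B[, 2], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1L, min))))
  }
  worst
}

#' Full segmentation score for one (prediction, ground truth) pair
#'
#' Convenience wrapper returning the six pixel-level scores as a one-row data
#' frame in the conventional column order (`mcc`, `acc`, `sen`, `jaccard`,
#' `hd`, `dice`). Overlap scores are on the 0-1 scale; `hd` is in pixels and
#' `NA` when either mask is empty.
#'
#' @param pred,gt [binary_mask()]s of the same shape.
#' @return a one-row data frame.
#' @export
segmentation_metrics <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  om <- overlap_metrics(cc)
  hd <- if (sum(as_pixels(pred)) > 0 && sum(as_pixels(gt)) > 0)
    hausdorff_distance(pred, gt) else NA_real_
  data.frame(mcc = om$mcc, acc = om$acc, sen = om$sen, jaccard = om$jaccard,
             hd = hd, dice = om$dice)
}

#' Friedman rank test with Nemenyi post-hoc comparison
#'
#' Ranks the methods within every case (mid-ranks on ties) and computes the
#' untied chi-square form of the Friedman statistic
#' \deqn{\chi^2_F = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1),}
#' with `n` cases and `k` methods, and its chi-square p-value on `k - 1`
#' degrees of freedom. A fully tied table yields statistic 0. Pairwise method
#' differences are flagged by the Nemenyi critical difference
#' \eqn{CD = q_{\alpha,k} \sqrt{k(k+1)/(6n)}} on mean ranks, reported in
#' `marks` as a character matrix with the conventional circle mark for a
#' significant difference and triangle mark for equality.
#'
#' @param scores numeric matrix, cases in rows and methods in columns
#'   (column names label the methods).
#' @param alpha significance level for the Nemenyi comparison.
#' @return a list with `statistic`, `p_value`, `mean_ranks`, `critical_difference`,
#'   `different` (logical k x k matrix) and `marks` (character k x k matrix,
#'   circle = difference, triangle = equality, `""` on the diagonal).
#' @export
friedman_test <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L || ncol(scores) < 2L)
    stop("need at least 2 cases and 2 methods", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("scores must be finite (no NaN rows)", call. = FALSE)
  n <- nrow(scores); k <- ncol(scores)
  ranks <- t(apply(scores, 1L, function(r) rank(-r)))  # rank 1 = best
  Rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  stat <- max(stat, 0)
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  mean_ranks <- Rj / n
  cd <- qtukey(1 - alpha, k, Inf) / sqrt(2) * sqrt(k * (k + 1) / (6 * n))
  diff_mat <- abs(outer(mean_ranks, mean_ranks, "-")) > cd
  marks <- matrix(ifelse(diff_mat, "\u25ef", "\u0394"), k, k,
                  dimnames = list(colnames(scores), colnames(scores)))
  diag(marks) <- ""
  diag(diff_mat) <- FALSE
  list(statistic = stat, p_value = p, mean_ranks = mean_ranks,
       critical_difference = cd, different = diff_mat, marks = marks)
}

#' Aggregate a set of per-slice metric rows into a mean +/- sd report
#'
#' @param metrics data frame of per-slice rows as returned by
#'   [segmentation_metrics()].
#' @param percent report overlap metrics in percent to 2 decimals.
#' @return a data frame with one row per metric: `mean`, `sd`, and a
#'   formatted `report` column.
#' @export
aggregate_metrics <- function(metrics, percent = TRUE) {
  cols <- c("mcc", "acc", "sen", "jaccard", "hd", "dice")
  cols <- intersect(cols, names(metrics))
  out <- lapply(cols, function(cn) {
    v <- metrics[[cn]]
    scale <- if (percent && cn != "hd") 100 else 1
    m <- mean(v, na.rm = TRUE) * scale
    s <- if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) * scale else 0
    data.frame(metric = cn, mean = m, sd = s,
               report = sprintf("%.2f \u00b1 %.2f", m, s))
  })
  do.call(rbind, out)
}
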