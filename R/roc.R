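#' 2x2 diagnostic contingency table
#'
#' Pathology truth on rows, test call on columns.
#'
#' @param tn,fp,fn,tp non-negative integer counts (true negative, false
#'   positive, false negative, true positive).
#' @return object of class `contingency_2x2` (an integer matrix).
#' @export
contingency_2x2 <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("table is empty")
  m <- matrix(as.integer(counts), nrow = 2L, byrow = TRUE,
              dimnames = list(truth = c("negative", "positive"),
                              call = c("negative", "positive")))
  structure(m, class = c("contingency_2x2", "matrix", "array"))
}

#' Build a 2x2 table from per-patient binary calls
#' @param truth,call binary (0/1 or logical) vectors of equal length.
#' @return a [contingency_2x2()].
#' @export
contingency_from_calls <- function(truth, call) {
  truth <- .as_binary(truth, "truth")
  call <- .as_binary(call, "call")
  stopifnot(length(truth) == length(call))
  contingency_2x2(tn = sum(truth == 0 & call == 0),
                  fp = sum(truth == 0 & call == 1),
                  fn = sum(truth == 1 & call == 0),
                  tp = sum(truth == 1 & call == 1))
}

.as_binary <- function(x, what = "labels") {
  if (is.logical(x)) x <- as.integer(x)
  if (!all(x %in% c(0, 1)))
    stop(what, " must be binary (0/1); offending values: ",
         paste(utils::head(unique(x[!x %in% c(0, 1)]), 3), collapse = ", "))
  as.integer(x)
}

#' Pearson chi-square test of a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with 1
#' degree of freedom and upper-tail p-value — the variant whose p-values
#' match the printed diagnostic comparisons.
#'
#' @param table a [contingency_2x2()].
#' @return list with `statistic`, `df` (= 1) and `p`.
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("a margin of the 2x2 table is zero; use an exact test instead")
  ht <- suppressWarnings(chisq.test(unclass(table), correct = FALSE))
  list(statistic = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Diagnostic accuracy of a binary test
#'
#' Sensitivity and specificity in percent, and the AUC of the binary call
#' viewed as a one-cutpoint ROC curve: `(sensitivity + specificity) / 200`.
#'
#' @param table a [contingency_2x2()].
#' @return list with `sensitivity`, `specificity` (percent) and `auc`.
#' @examples
#' # PET lymph-node reading of a 95-patient cohort
#' binary_test_diagnostics(contingency_2x2(tn = 69, fp = 9, fn = 7, tp = 10))
#' @export
binary_test_diagnostics <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  tn <- table[1L, 1L]; fp <- table[1L, 2L]
  fn <- table[2L, 1L]; tp <- table[2L, 2L]
  if (tp + fn == 0 || tn + fp == 0)
    stop("both truth classes must be present")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  list(sensitivity = sens, specificity = spec, auc = (sens + spec) / 200)
}

## DeLong structural components of the oriented score x with labels y.
## V10[i] = placement of positive i among negatives; V01[j] symmetric.
.delong_components <- function(score, labels) {
  xs <- score[labels == 1L]
  ys <- score[labels == 0L]
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(V10 = rowMeans(psi), V01 = colMeans(psi), auc = mean(psi))
}

#' Empirical ROC curve of a continuous marker
#'
#' Rank-based ROC analysis: the AUC equals the Mann-Whitney U statistic
#' scaled by `n1 * n0` (ties counted one half); the operating points sweep
#' the midpoints between adjacent observed values; the reported cutoff
#' maximizes the Youden index J = sensitivity + specificity - 1, ties broken
#' toward higher specificity. The 95% CI uses the DeLong
#' structural-components variance estimator.
#'
#' Marker direction is handled explicitly: with `direction = "auto"` the
#' orientation giving AUC >= 0.5 is chosen and reported, so markers for
#' which *lower* values predict the positive class (e.g. the minimum tissue
#' diffusion coefficient Dmin) are summarized on the same AUC >= 0.5
#' convention as positively-oriented markers.
#'
#' @param marker numeric marker values.
#' @param labels binary outcome (1 = positive class).
#' @param direction `"auto"`, `"higher"` (higher marker predicts positive)
#'   or `"lower"`.
#' @return object of class `roc_result`: list with `auc`, `se`, `ci95`,
#'   `direction`, `cutoff` (original marker units; positive call is
#'   `marker >= cutoff` for direction `"higher"`, `marker <= cutoff` for
#'   `"lower"`), `youden_j`, `sensitivity`/`specificity` at the cutoff (%),
#'   `curve` (data.frame of threshold, sensitivity, specificity), and the
#'   oriented scores/labels retained for paired comparisons.
#' @export
roc_continuous <- function(marker, labels,
                           direction = c("auto", "higher", "lower")) {
  direction <- match.arg(direction)
  labels <- .as_binary(labels)
  keep <- is.finite(marker) & !is.na(labels)
  marker <- marker[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (length(unique(marker)) < 2L) stop("need >= 2 distinct marker values")

  auc_of <- function(score) {
    r <- rank(score)
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (direction == "auto")
    direction <- if (auc_of(marker) >= 0.5) "higher" else "lower"
  score <- if (direction == "higher") marker else -marker
  auc <- auc_of(score)

  ## operating points at midpoints between adjacent distinct scores,
  ## closed by sentinels below/above the observed range
  u <- sort(unique(score))
  thr <- c(u[1L] - 1, (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(thr, function(t) mean(score[labels == 1L] >= t), 0)
  spec <- vapply(thr, function(t) mean(score[labels == 0L] < t), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]   # tie -> higher specificity

  comp <- .delong_components(score, labels)
  v <- var(comp$V10) / n1 + var(comp$V01) / n0
  se <- sqrt(max(v, 0))
  ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)

  curve <- data.frame(threshold = if (direction == "higher") thr else -thr,
                      sensitivity = 100 * sens, specificity = 100 * spec)
  structure(list(auc = auc, se = se, ci95 = ci, direction = direction,
                 cutoff = if (direction == "higher") thr[best] else -thr[best],
                 youden_j = j[best],
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 curve = curve, score = score, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), ",
                     "cutoff %.4g (%s predicts positive), ",
                     "sens %.2f%%, spec %.2f%%, J = %.3f\n"),
              x$auc, x$ci95[1L], x$ci95[2L], x$cutoff,
              if (x$direction == "higher") ">= cutoff" else "<= cutoff",
              x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Paired comparison of the AUCs of two markers measured on the same
#' patients, using the structural-components covariance estimator. The
#' curves must carry identical outcome labels (patient order included).
#'
#' @param roc_a,roc_b `roc_result` objects from [roc_continuous()] on the
#'   same patients.
#' @return list with `auc_a`, `auc_b`, `diff`, `z` and two-sided `p`.
#' @export
delong_compare <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (!identical(roc_a$labels, roc_b$labels))
    stop("curves must be paired: same patients, same labels, same order")
  labels <- roc_a$labels
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  ca <- .delong_components(roc_a$score, labels)
  cb <- .delong_components(roc_b$score, labels)
  s10 <- stats::cov(cbind(ca$V10, cb$V10))
  s01 <- stats::cov(cbind(ca$V01, cb$V01))
  S <- s10 / n1 + s01 / n0
  v <- S[1L, 1L] + S[2L, 2L] - 2 * S[1L, 2L]
  d <- ca$auc - cb$auc
  if (v <= .Machine$double.eps) {
    warning("degenerate variance (identical predictions); p set to 1")
    return(list(auc_a = ca$auc, auc_b = cb$auc, diff = d, z = 0, p = 1))
  }
  z <- d / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, diff = d, z = z,
       p = 2 * pnorm(-abs(z)))
}
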