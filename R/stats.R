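#' Two-group comparison with automatic test selection
#'
#' Screens each group for normality (Shapiro-Wilk at alpha = 0.05); if both
#' groups pass, a Welch two-sample t-test is used, otherwise a two-sided
#' Mann-Whitney U (Wilcoxon rank-sum) test. The test actually applied is
#' reported. Groups too small for the normality screen (n < 3) fall back to
#' the rank test.
#'
#' @param x feature values.
#' @param g binary group labels (0/1 or logical), same length as `x`.
#' @param test `"auto"` (default), or force `"t"` / `"wilcoxon"`.
#' @return list with `test` ("t" or "wilcoxon"), `statistic`, `p`, and
#'   `degenerate` (TRUE when the feature is constant within both groups, in
#'   which case no distributional test is meaningful and `p` is `NA`).
#' @export
group_compare <- function(x, g, test = c("auto", "t", "wilcoxon")) {
  test <- match.arg(test)
  g <- .as_binary(g, "group labels")
  keep <- is.finite(x)
  x <- x[keep]; g <- g[keep]
  x0 <- x[g == 0L]; x1 <- x[g == 1L]
  if (length(x0) == 0 || length(x1) == 0) stop("both groups must be non-empty")
  if (length(unique(x0)) == 1L && length(unique(x1)) == 1L &&
      x0[1L] == x1[1L])
    return(list(test = NA_character_, statistic = NA_real_, p = NA_real_,
                degenerate = TRUE))
  if (test == "auto") {
    normal <- function(v) {
      if (length(unique(v)) < 3L || length(v) < 3L || length(v) > 5000L)
        return(FALSE)
      shapiro.test(v)$p.value >= 0.05
    }
    test <- if (normal(x0) && normal(x1)) "t" else "wilcoxon"
  }
  ht <- if (test == "t") t.test(x0, x1)
        else suppressWarnings(wilcox.test(x0, x1, exact = NULL))
  list(test = test, statistic = unname(ht$statistic),
       p = unname(ht$p.value), degenerate = FALSE)
}

#' Pairwise Spearman rank correlation matrix
#'
#' Spearman rho over all feature pairs, average ranks for ties, two-sided
#' p-values from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` with
#' n - 2 degrees of freedom. Constant columns yield `NA` (rho undefined).
#'
#' @param features data.frame or matrix of numeric features (>= 3 rows).
#' @return list with matrices `rho` (symmetric, unit diagonal) and `p`.
#' @export
spearman_matrix <- function(features) {
  features <- as.data.frame(features)
  features <- features[vapply(features, is.numeric, TRUE)]
  n <- nrow(features)
  if (n < 3L) stop("need at least 3 patients")
  ## constant columns are reported as NA below; silence cor()'s sd warning
  rho <- suppressWarnings(
    cor(features, method = "spearman", use = "pairwise.complete.obs"))
  const <- vapply(features, function(v) length(unique(v[!is.na(v)])) < 2L,
                  TRUE)
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho)[!const] <- 1
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1 & !is.na(rho)] <- 0
  diag(p) <- NA_real_
  list(rho = rho, p = p)
}

#' Two-rater intraclass correlation, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' from the mean squares of the subjects-by-raters decomposition (here
#' k = 2). Absolute agreement penalizes a systematic shift between raters,
#' which is the appropriate model when both radiologists' measurements are
#' meant to be interchangeable. Agreement of 0.8-1 is labeled "high".
#'
#' @param rater1,rater2 paired numeric ratings of the same n >= 3 subjects.
#' @return object of class `agreement_result`: list with `icc`, `band`
#'   ("high" >= 0.8, "moderate" >= 0.6, "low" otherwise), and the mean
#'   squares. `icc` is `NA` (flagged) when the total variance is zero.
#' @export
icc_two_rater <- function(rater1, rater2) {
  stopifnot(length(rater1) == length(rater2))
  keep <- is.finite(rater1) & is.finite(rater2)
  y <- cbind(rater1[keep], rater2[keep])
  n <- nrow(y); k <- 2L
  if (n < 3L) stop("need at least 3 paired ratings")
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (ss_tot <= .Machine$double.eps * n * k) {
    icc <- NA_real_
  } else {
    icc <- (msr - mse) / denom
  }
  band <- if (is.na(icc)) "undefined"
          else if (icc >= 0.8) "high"
          else if (icc >= 0.6) "moderate"
          else "low"
  structure(list(icc = icc, band = band, ms_rows = msr, ms_cols = msc,
                 ms_error = mse, n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> ICC(2,1) = %s (%s agreement, n = %d)\n",
              if (is.na(x$icc)) "NA" else sprintf("%.3f", x$icc),
              x$band, x$n))
  invisible(x)
}
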