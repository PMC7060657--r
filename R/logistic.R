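#' Binary logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares), standard errors from the observed information, and Wald
#' chi-square tests `W = (coefficient / SE)^2` with 1 df per coefficient —
#' the inference layout of the study's regression tables. Complete
#' separation is detected and flagged rather than reported as a silently
#' diverged fit; collinear predictors raise an error naming the variables.
#'
#' @param data data.frame containing response and predictors.
#' @param response name of the binary (0/1) outcome column.
#' @param predictors character vector of predictor column names.
#' @return object of class `logistic_model`: list with `coefficients`
#'   (data.frame: term, coefficient, std_error, wald, p), `fitted`
#'   (probabilities), `log_likelihood`, `null_log_likelihood`, `converged`,
#'   `separation` and the underlying `glm` fit.
#' @export
fit_logistic <- function(data, response, predictors) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  y <- .as_binary(data[[response]], "response")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (nrow(data) <= length(predictors) + 1L)
    stop("need more observations than parameters")

  X <- as.matrix(data[predictors])
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    bad <- c("(Intercept)", predictors)[qx$pivot[-seq_len(qx$rank)]]
    stop("collinear predictors: ", paste(bad, collapse = ", "))
  }

  df <- data.frame(.y = y, data[predictors], check.names = FALSE)
  form <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", predictors), collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = df,
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  separation <- sep_warn || any(abs(coef(fit)[-1L]) > 15)
  tab <- data.frame(term = rownames(sm), coefficient = sm[, 1L],
                    std_error = sm[, 2L],
                    wald = (sm[, 1L] / sm[, 2L])^2,
                    row.names = NULL)
  tab$p <- pchisq(tab$wald, df = 1L, lower.tail = FALSE)
  ll <- as.numeric(stats::logLik(fit))
  p1 <- mean(y)
  ll0 <- sum(y) * log(p1) + sum(1 - y) * log(1 - p1)
  structure(list(coefficients = tab, fitted = stats::fitted(fit),
                 log_likelihood = ll, null_log_likelihood = ll0,
                 converged = fit$converged, separation = separation,
                 glm = fit),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model> logLik", sprintf("%.3f", x$log_likelihood))
  if (x$separation) cat("  [complete separation detected]")
  cat("\n")
  tab <- x$coefficients
  tab[-1L] <- lapply(tab[-1L], signif, 5)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of candidate tests the correction spans.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 10)  # 0.005
#' bonferroni_alpha(0.05, 3)   # 0.0167
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Build the combined lymph-node prediction model
#'
#' Two-stage model building used for the metastasis prediction model:
#'
#' 1. **Univariate screen** — each candidate is fit alone against the
#'    pathology label; candidates with Wald p below
#'    `alpha_entry_univariate` (default 0.1) proceed.
#' 2. **Forward stepwise multivariate** — starting from the intercept-only
#'    model, at each step the surviving candidate with the smallest Wald p
#'    in the expanded model enters if that p is below the
#'    Bonferroni-corrected threshold `alpha / n_candidates`; selection stops
#'    when no candidate qualifies. (Entry-driven selection only, no removal
#'    step.)
#'
#' The final model's in-sample linear predictor is scored by
#' [roc_continuous()]. Comparing that ROC with single-feature ROC curves on
#' the same data mirrors the study procedure; note the optimism inherent in
#' evaluating a fitted model on its own training data.
#'
#' @param cohort data.frame with the cohort schema (see [make_cohort()]).
#' @param candidates candidate predictor columns; defaults to the ten
#'   quantitative imaging features plus the PET and MRI node calls.
#' @param alpha_entry_univariate univariate screening threshold (0.1).
#' @param alpha family-wise alpha for the multivariate entry correction.
#' @param n_candidates Bonferroni divisor. Defaults to the number of
#'   quantitative imaging features among the candidates (the published
#'   correction convention counts the feature panel, 10 in the full cohort
#'   and 3 in the PET-negative subset analysis).
#' @param response pathology label column.
#' @return list with `univariate` (screening table: term, coefficient,
#'   std_error, wald, p, selected), `model` (final `logistic_model`), `roc`
#'   (ROC of the linear predictor), `alpha_entry` (corrected threshold),
#'   `selected` (variables in entry order) and `audit` (character log of
#'   every entry decision). If nothing survives the univariate screen the
#'   best univariate model is returned with a warning.
#' @export
build_combined_model <- function(cohort,
                                 candidates = c("suv_max", "suv_mean",
                                                "mtv", "tlg", "adc_mean",
                                                "adc_min", "d_mean",
                                                "d_min", "d_star", "f",
                                                "pet_node_positive",
                                                "mri_node_positive"),
                                 alpha_entry_univariate = 0.1,
                                 alpha = 0.05,
                                 n_candidates = NULL,
                                 response = "pathology_positive") {
  stopifnot(all(candidates %in% names(cohort)))
  if (is.null(n_candidates)) {
    quant <- setdiff(candidates, c("pet_node_positive", "mri_node_positive"))
    n_candidates <- max(length(quant), 1L)
  }
  alpha_entry <- bonferroni_alpha(alpha, n_candidates)
  audit <- character()

  ## stage 1: univariate screen
  uni <- do.call(rbind, lapply(candidates, function(v) {
    m <- fit_logistic(cohort, response, v)
    cbind(m$coefficients[m$coefficients$term != "(Intercept)", ],
          separation = m$separation)
  }))
  uni$term <- candidates
  uni$selected <- uni$p < alpha_entry_univariate
  audit <- c(audit, sprintf(
    "univariate screen at p < %g: %d of %d candidates retained (%s)",
    alpha_entry_univariate, sum(uni$selected), nrow(uni),
    paste(uni$term[uni$selected], collapse = ", ")))

  survivors <- uni$term[uni$selected]
  if (length(survivors) == 0L) {
    warning("no candidate passed the univariate screen; ",
            "returning the best univariate model")
    best <- uni$term[which.min(uni$p)]
    model <- fit_logistic(cohort, response, best)
    roc <- roc_continuous(model$fitted, cohort[[response]])
    return(list(univariate = uni, model = model, roc = roc,
                alpha_entry = alpha_entry, selected = best,
                audit = c(audit, paste("fallback: best univariate =", best))))
  }

  ## stage 2: forward entry at the Bonferroni-corrected threshold
  selected <- character()
  repeat {
    pool <- setdiff(survivors, selected)
    if (length(pool) == 0L) break
    entry_p <- vapply(pool, function(v) {
      m <- tryCatch(fit_logistic(cohort, response, c(selected, v)),
                    error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      m$coefficients$p[m$coefficients$term == v]
    }, 0)
    if (all(is.na(entry_p))) break
    best <- pool[which.min(entry_p)]
    if (is.na(entry_p[best]) || entry_p[best] >= alpha_entry) {
      audit <- c(audit, sprintf(
        "stop: best remaining candidate %s has p = %.4g >= %.4g",
        best, entry_p[best], alpha_entry))
      break
    }
    selected <- c(selected, best)
    audit <- c(audit, sprintf("enter %s (p = %.4g < %.4g)",
                              best, entry_p[best], alpha_entry))
  }

  if (length(selected) == 0L) {
    warning("no candidate entered at the corrected threshold; ",
            "returning the best univariate model")
    selected <- survivors[which.min(uni$p[uni$selected])]
    audit <- c(audit, paste("fallback: best univariate =", selected))
  }
  model <- fit_logistic(cohort, response, selected)
  lp <- as.numeric(stats::predict(model$glm, type = "link"))
  roc <- roc_continuous(lp, cohort[[response]], direction = "higher")
  list(univariate = uni, model = model, roc = roc,
       alpha_entry = alpha_entry, selected = selected, audit = audit)
}
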