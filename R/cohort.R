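## Class-conditional feature summaries (mean, sd) for the default cohort:
## 78 pathology-negative and 17 pathology-positive cervical-cancer patients.
## Diffusion coefficients in 1e-3 mm^2/s, SUV in g/cm^3, MTV cm^3, TLG g.
.default_feature_means <- function() {
  list(
    negative = c(d_mean = 0.90, d_min = 0.59, adc_mean = 1.13,
                 adc_min = 0.70, d_star = 42.58, f = 0.16,
                 suv_max = 15.35, suv_mean = 9.16, mtv = 10.22,
                 tlg = 100.11),
    positive = c(d_mean = 0.81, d_min = 0.49, adc_mean = 1.16,
                 adc_min = 0.76, d_star = 42.87, f = 0.18,
                 suv_max = 19.24, suv_mean = 11.38, mtv = 16.67,
                 tlg = 183.74))
}

.default_feature_sds <- function() {
  list(
    negative = c(d_mean = 0.24, d_min = 0.18, adc_mean = 0.23,
                 adc_min = 0.14, d_star = 15.35, f = 0.06,
                 suv_max = 9.53, suv_mean = 6.03, mtv = 8.06,
                 tlg = 117.33),
    positive = c(d_mean = 0.16, d_min = 0.13, adc_mean = 0.26,
                 adc_min = 0.22, d_star = 17.70, f = 0.07,
                 suv_max = 8.69, suv_mean = 5.32, mtv = 12.99,
                 tlg = 144.08))
}

.cohort_features <- function() names(.default_feature_means()$negative)

#' Specification of a synthetic patient cohort
#'
#' Class-conditional feature distributions (mean, sd per pathology class)
#' and per-class probabilities of a positive lymph-node call on PET and on
#' MRI. The defaults reproduce the study cohort: 78 node-negative and 17
#' node-positive patients, PET node-positive rates 9/78 and 10/17, MRI rates
#' 17/78 and 9/17, and the printed per-class feature summaries.
#'
#' @param n_negative,n_positive patient counts per pathology class.
#' @param feature_means,feature_sds lists with `negative`/`positive` named
#'   vectors over the ten features `d_mean, d_min, adc_mean, adc_min,
#'   d_star, f, suv_max, suv_mean, mtv, tlg`.
#' @param pet_node_rates,mri_node_rates length-2 vectors
#'   `(negative, positive)` of P(positive node call) per class.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_negative = 78L, n_positive = 17L,
                        feature_means = .default_feature_means(),
                        feature_sds = .default_feature_sds(),
                        pet_node_rates = c(9 / 78, 10 / 17),
                        mri_node_rates = c(17 / 78, 9 / 17),
                        seed = 1L) {
  if (n_negative < 1 || n_positive < 1) stop("patient counts must be > 0")
  feats <- .cohort_features()
  for (cls in c("negative", "positive")) {
    if (!all(feats %in% names(feature_means[[cls]])))
      stop("feature_means$", cls, " is missing features")
    if (!all(feats %in% names(feature_sds[[cls]])))
      stop("feature_sds$", cls, " is missing features")
    if (any(feature_sds[[cls]][feats] < 0)) stop("sds must be >= 0")
  }
  for (r in list(pet_node_rates, mri_node_rates))
    if (length(r) != 2L || any(r < 0) || any(r > 1))
      stop("node rates must be two probabilities in [0, 1]")
  structure(list(n_negative = as.integer(n_negative),
                 n_positive = as.integer(n_positive),
                 feature_means = feature_means, feature_sds = feature_sds,
                 pet_node_rates = as.numeric(pet_node_rates),
                 mri_node_rates = as.numeric(mri_node_rates),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## Truncated-normal draw by inverse-CDF: the draw is a genuine truncated
## normal on [lower, upper], well-defined for any sd (no rejection loop).
.rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic patient cohort
#'
#' Draws each feature independently per pathology class from a truncated
#' normal (truncated at 0; perfusion fraction `f` additionally at 1) with
#' the class means/sds of the [cohort_spec()]; node calls are Bernoulli with
#' the per-class rates. TLG is then recomputed as `suv_mean * mtv` so the
#' identity TLG = SUVmean x MTV holds for every patient, replacing the
#' marginal TLG draw. No other inter-feature correlation is imposed (only
#' marginal summaries are available per class).
#'
#' @param spec a `cohort_spec`.
#' @return data.frame with columns `patient_id`, `pathology_positive`,
#'   `pet_node_positive`, `mri_node_positive`, then the ten features
#'   (`suv_max, suv_mean, mtv, tlg, adc_mean, adc_min, d_mean, d_min,
#'   d_star, f`).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  feats <- .cohort_features()
  draw_class <- function(cls, n) {
    mu <- spec$feature_means[[cls]]
    sg <- spec$feature_sds[[cls]]
    out <- as.data.frame(lapply(setNames(feats, feats), function(ft)
      .rtruncnorm(n, mu[[ft]], sg[[ft]], lower = 0,
                  upper = if (ft == "f") 1 else Inf)))
    out$tlg <- out$suv_mean * out$mtv
    k <- if (cls == "positive") 2L else 1L
    out$pet_node_positive <- rbinom(n, 1L, spec$pet_node_rates[k])
    out$mri_node_positive <- rbinom(n, 1L, spec$mri_node_rates[k])
    out$pathology_positive <- as.integer(cls == "positive")
    out
  }
  tab <- rbind(draw_class("negative", spec$n_negative),
               draw_class("positive", spec$n_positive))
  tab$patient_id <- sprintf("P%03d", seq_len(nrow(tab)))
  tab[c("patient_id", "pathology_positive", "pet_node_positive",
        "mri_node_positive", "suv_max", "suv_mean", "mtv", "tlg",
        "adc_mean", "adc_min", "d_mean", "d_min", "d_star", "f")]
}
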