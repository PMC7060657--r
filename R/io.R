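#' Read a NIfTI volume with voxel geometry
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return list with `data` (plain numeric array) and `voxel_size`
#'   (mm triple from the header pixdim).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size = as.numeric(RNifti::pixdim(img))[1:3])
}

#' Write an array as NIfTI with voxel geometry
#'
#' @param data 3-D or 4-D numeric array.
#' @param path destination `.nii.gz` path.
#' @param voxel_size mm triple stored in the header.
#' @param datatype NIfTI storage type (e.g. `"uint8"` for masks).
#' @return the path, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1),
                        datatype = "double") {
  .check_voxel_size(voxel_size)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxel_size,
                           rep(1, length(dim(data)) - 3L))[seq_along(dim(data))]
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a b-value sidecar (plain text or JSON)
#'
#' One value per entry, s/mm^2: either whitespace/newline-separated text or
#' a JSON array.
#' @param path sidecar path.
#' @return numeric b-values.
#' @export
read_bvals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  b <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.numeric(unlist(jsonlite::read_json(path)))
  else
    scan(path, what = numeric(), quiet = TRUE)
  .check_bvals(b)
}

#' Write a b-value sidecar
#' @param b_values numeric b-values.
#' @param path destination `.txt` or `.json` path.
#' @return the path, invisibly.
#' @export
write_bvals <- function(b_values, path) {
  .check_bvals(b_values)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(b_values, path, digits = NA)
  else
    writeLines(format(b_values, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Load a DWI series from NIfTI + b-value sidecar
#'
#' Validates that the 4th dimension of the volume matches the sidecar
#' length before constructing the [dwi_series()].
#' @param dwi_path 4-D NIfTI path.
#' @param bvals_path sidecar path.
#' @return a `dwi_series`.
#' @export
read_dwi_series <- function(dwi_path, bvals_path) {
  vol <- read_nifti(dwi_path)
  b <- read_bvals(bvals_path)
  if (length(dim(vol$data)) != 4L)
    stop("expected a 4-D DWI volume, got ",
         length(dim(vol$data)), "-D")
  if (dim(vol$data)[4L] != length(b))
    stop("b-value count mismatch: volume has ", dim(vol$data)[4L],
         " frames but sidecar lists ", length(b), " values")
  dwi_series(vol$data, b, vol$voxel_size)
}

.cohort_schema <- function() {
  c("patient_id", "pathology_positive", "pet_node_positive",
    "mri_node_positive", "suv_max", "suv_mean", "mtv", "tlg",
    "adc_mean", "adc_min", "d_mean", "d_min", "d_star", "f")
}

#' Read and validate a cohort CSV
#'
#' Enforces the cohort schema (see [make_cohort()]): all columns present,
#' label columns strictly binary. Missing values stay `NA` — they are never
#' zero-filled.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("cohort file is empty")
  missing_cols <- setdiff(.cohort_schema(), names(tab))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(tab), .cohort_schema())
  if (length(extra))
    stop("unknown columns: ", paste(extra, collapse = ", "))
  for (col in c("pathology_positive", "pet_node_positive",
                "mri_node_positive")) {
    v <- tab[[col]]
    bad <- which(!is.na(v) & !v %in% c(0, 1))
    if (length(bad))
      stop("column ", col, " must be binary; row ", bad[1L],
           " has value ", v[bad[1L]])
  }
  tab
}

#' Write a cohort table as CSV
#' @param cohort data.frame in cohort schema.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#' @param report named list of results.
#' @param path destination `.json` path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Read a pipeline configuration (YAML)
#'
#' Validates threshold ranges; paths are checked by the stage that uses
#' them.
#' @param path YAML config path.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$mtv_threshold_fraction) &&
      (cfg$mtv_threshold_fraction <= 0 || cfg$mtv_threshold_fraction >= 1))
    stop("mtv_threshold_fraction must lie in (0, 1)")
  if (!is.null(cfg$b_threshold) && cfg$b_threshold <= 0)
    stop("b_threshold must be positive")
  cfg
}

#' Full statistical report on a cohort
#'
#' Runs the whole diagnostic analysis on a cohort table: per-feature group
#' comparisons, PET and MRI node 2x2 diagnostics with chi-square,
#' per-feature ROC analyses, the combined logistic model with its ROC and
#' DeLong comparisons against each single feature, and the Spearman
#' correlation matrix. With `subset = "pet_negative"` the analysis is
#' restricted to patients with a negative PET node call and the candidate
#' panel reduces to MTV, TLG and Dmin (with Bonferroni divisor 3), the
#' subset analysis of the study.
#'
#' @param cohort cohort data.frame (see [make_cohort()] / [read_cohort()]).
#' @param subset `"all"` or `"pet_negative"`.
#' @return nested list ready for [write_report()].
#' @export
analyze_cohort <- function(cohort, subset = c("all", "pet_negative")) {
  subset <- match.arg(subset)
  quant <- c("suv_max", "suv_mean", "mtv", "tlg", "adc_mean", "adc_min",
             "d_mean", "d_min", "d_star", "f")
  if (subset == "pet_negative") {
    cohort <- cohort[cohort$pet_node_positive == 0, ]
    candidates <- c("mtv", "tlg", "d_min")
    n_candidates <- 3L
  } else {
    candidates <- c(quant, "pet_node_positive", "mri_node_positive")
    n_candidates <- 10L
  }
  y <- cohort$pathology_positive
  groups <- lapply(setNames(quant, quant), function(v)
    group_compare(cohort[[v]], y))
  node <- list()
  for (mod in c("pet", "mri")) {
    call_col <- paste0(mod, "_node_positive")
    if (length(unique(cohort[[call_col]])) < 2L) next
    tab <- contingency_from_calls(y, cohort[[call_col]])
    node[[mod]] <- c(list(table = as.vector(tab)),
                     binary_test_diagnostics(tab),
                     chi_square = list(chi_square_2x2(tab)))
  }
  rocs <- lapply(setNames(quant, quant), function(v) {
    r <- roc_continuous(cohort[[v]], y)
    r[c("auc", "ci95", "direction", "cutoff", "sensitivity", "specificity")]
  })
  combined <- build_combined_model(cohort, candidates = candidates,
                                   n_candidates = n_candidates)
  delong <- lapply(setNames(combined$selected, combined$selected),
                   function(v) {
    if (length(unique(cohort[[v]])) < 2L) return(NULL)
    delong_compare(combined$roc, roc_continuous(cohort[[v]], y))
  })
  sp <- spearman_matrix(cohort[quant])
  list(n = nrow(cohort),
       n_positive = sum(y), n_negative = sum(1 - y),
       subset = subset,
       group_comparisons = groups,
       node_diagnostics = node,
       feature_roc = rocs,
       combined_model = list(
         selected = combined$selected,
         alpha_entry = combined$alpha_entry,
         coefficients = combined$model$coefficients,
         auc = combined$roc$auc, ci95 = combined$roc$ci95,
         sensitivity = combined$roc$sensitivity,
         specificity = combined$roc$specificity,
         audit = combined$audit),
       delong_vs_selected = delong,
       spearman = sp)
}
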