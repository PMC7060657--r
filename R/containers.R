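#' Diffusion-weighted series container
#'
#' A 4-D signal array indexed by (x, y, z, b) together with its b-value
#' schedule and voxel geometry.
#'
#' @param signal 4-D non-negative array; 4th axis indexes b-values.
#' @param b_values ascending b-values, s/mm^2, starting at 0, no duplicates.
#' @param voxel_size mm triple.
#' @return object of class `dwi_series`.
#' @export
dwi_series <- function(signal, b_values, voxel_size = c(1, 1, 1)) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L) stop("signal must be a 4-D array")
  .check_bvals(b_values)
  if (dim(signal)[4L] != length(b_values))
    stop("4th dimension (", dim(signal)[4L], ") does not match the ",
         length(b_values), "-entry b-value schedule")
  if (any(signal < 0, na.rm = TRUE)) stop("signal must be non-negative")
  .check_voxel_size(voxel_size)
  structure(list(signal = signal, b_values = as.numeric(b_values),
                 voxel_size = as.numeric(voxel_size)),
            class = "dwi_series")
}

#' PET standardized-uptake-value volume container
#'
#' @param suv 3-D non-negative array of SUV (g/cm^3).
#' @param voxel_size mm triple with positive product.
#' @return object of class `suv_volume`.
#' @export
suv_volume <- function(suv, voxel_size = c(1, 1, 1)) {
  suv <- as.array(suv)
  if (length(dim(suv)) != 3L) stop("suv must be a 3-D array")
  if (any(suv < 0, na.rm = TRUE)) stop("SUV must be non-negative")
  .check_voxel_size(voxel_size)
  structure(list(suv = suv, voxel_size = as.numeric(voxel_size)),
            class = "suv_volume")
}

.check_voxel_size <- function(v) {
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    stop("voxel_size must be a positive mm triple")
  invisible(v)
}

#' Voxel volume of a geometry, in cm^3
#' @param voxel_size mm triple.
#' @return scalar volume of one voxel in cm^3.
#' @export
voxel_volume_cm3 <- function(voxel_size) {
  .check_voxel_size(voxel_size)
  prod(voxel_size) / 1000
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat("<dwi_series> ", paste(d[1:3], collapse = "x"), " grid, ",
      d[4L], " b-values (", x$b_values[1L], "-", max(x$b_values),
      " s/mm^2), voxel ", paste(x$voxel_size, collapse = "x"), " mm\n",
      sep = "")
  invisible(x)
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(dim(x$suv), collapse = "x"),
      " grid, voxel ", paste(x$voxel_size, collapse = "x"),
      " mm, SUV range [", signif(min(x$suv), 4), ", ",
      signif(max(x$suv), 4), "] g/cm^3\n", sep = "")
  invisible(x)
}
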