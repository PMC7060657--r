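#' Specification of a synthetic PET/DWI lesion phantom
#'
#' Describes an ellipsoidal lesion embedded in a uniform background on a
#' regular voxel grid. The PET uptake profile inside the lesion is a
#' truncated Gaussian peaking at the lesion center,
#' \deqn{SUV(\rho) = bg + (peak - bg)\, e^{-\rho^2 / (2\sigma^2)}, \quad \rho \le 1,}
#' with \eqn{\rho} the normalized ellipsoidal radius, so a fractional-SUVmax
#' threshold selects a strict, analytically known subvolume. The diffusion
#' signal of every voxel follows the IVIM forward model with the
#' tissue-class parameters in `ivim_true`.
#'
#' Default lesion parameters echo a cervical primary tumor: D = 0.90e-3
#' mm^2/s, D* = 42.58e-3 mm^2/s, f = 0.16, SUV peak 15.35 over a low
#' background; lesion radii give a volume of the order of 10 cm^3.
#'
#' @param grid_shape integer voxel triple.
#' @param voxel_size mm triple.
#' @param lesion_center mm triple (continuous coordinates; voxel centers sit
#'   at `(i - 0.5) * voxel_size`).
#' @param lesion_radii ellipsoid semi-axes, mm.
#' @param suv_peak,suv_background SUV units (g/cm^3); `suv_peak >
#'   suv_background >= 0`.
#' @param profile_sigma width of the Gaussian uptake profile in normalized
#'   radius units (default 0.5: the 40% iso-contour falls at rho ~ 0.68).
#' @param ivim_true list with elements `lesion` and `background`, each a
#'   named list `(S0, D, D_star, f)` in mm^2/s.
#' @param noise_sigma noise level as a fraction of S0 (DWI, Rician) or of
#'   `suv_peak` (PET, Gaussian); 0 disables noise.
#' @param seed integer RNG seed for reproducible noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 20L),
                         voxel_size = c(2, 2, 2),
                         lesion_center = grid_shape * voxel_size / 2,
                         lesion_radii = c(13, 13, 13),
                         suv_peak = 15.35, suv_background = 1,
                         profile_sigma = 0.5,
                         ivim_true = list(
                           lesion = list(S0 = 1000, D = 0.90e-3,
                                         D_star = 42.58e-3, f = 0.16),
                           background = list(S0 = 1000, D = 1.40e-3,
                                             D_star = 20e-3, f = 0.05)),
                         noise_sigma = 0, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  .check_voxel_size(voxel_size)
  stopifnot(length(lesion_center) == 3L, length(lesion_radii) == 3L,
            all(lesion_radii > 0))
  extent <- grid_shape * voxel_size
  if (any(lesion_center - lesion_radii < 0) ||
      any(lesion_center + lesion_radii > extent))
    stop("lesion extends outside the grid: center ",
         paste(lesion_center, collapse = ","), " mm, radii ",
         paste(lesion_radii, collapse = ","), " mm, grid extent ",
         paste(extent, collapse = ","), " mm")
  if (!(suv_peak > suv_background) || suv_background < 0)
    stop("need suv_peak > suv_background >= 0")
  if (profile_sigma <= 0) stop("profile_sigma must be positive")
  for (cls in c("lesion", "background")) {
    p <- ivim_true[[cls]]
    if (is.null(p)) stop("ivim_true must have '", cls, "'")
    if (p$f < 0 || p$f > 1) stop(cls, ": f must lie in [0, 1]")
    if (p$D <= 0) stop(cls, ": D must be positive")
    if (p$f > 0 && p$D_star <= p$D) stop(cls, ": need D* > D")
    if (p$S0 <= 0) stop(cls, ": S0 must be positive")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 lesion_center = as.numeric(lesion_center),
                 lesion_radii = as.numeric(lesion_radii),
                 suv_peak = suv_peak, suv_background = suv_background,
                 profile_sigma = profile_sigma, ivim_true = ivim_true,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

## normalized ellipsoidal radius of every voxel center, as a 3-D array
.phantom_rho <- function(spec) {
  ax <- lapply(1:3, function(k) {
    x <- (seq_len(spec$grid_shape[k]) - 0.5) * spec$voxel_size[k]
    (x - spec$lesion_center[k]) / spec$lesion_radii[k]
  })
  g <- expand.grid(u = ax[[1L]], v = ax[[2L]], w = ax[[3L]])
  array(sqrt(g$u^2 + g$v^2 + g$w^2), spec$grid_shape)
}

#' Generate a PET lesion phantom
#'
#' Builds the SUV volume and the ellipsoid VOI mask described by a
#' [phantom_spec()]. With `noise_sigma > 0`, zero-mean Gaussian noise with
#' sd `noise_sigma * suv_peak` is added and the result clipped at 0.
#'
#' @param spec a `phantom_spec`.
#' @return list with `suv` (a [suv_volume()]), `mask` (3-D 0/1 array marking
#'   the ellipsoid), and `analytic_volume_cm3`, the exact ellipsoid volume
#'   `4/3 * pi * a * b * c` for oracle checks.
#' @seealso [analytic_isocontour_volume()] for the exact volume enclosed by
#'   a fractional-SUVmax iso-surface of the same phantom.
#' @export
make_pet_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rho <- .phantom_rho(spec)
  inside <- rho <= 1
  suv <- array(spec$suv_background, spec$grid_shape)
  suv[inside] <- spec$suv_background +
    (spec$suv_peak - spec$suv_background) *
    exp(-rho[inside]^2 / (2 * spec$profile_sigma^2))
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    suv <- suv + rnorm(length(suv), sd = spec$noise_sigma * spec$suv_peak)
    suv <- pmax(suv, 0)
    suv <- array(suv, spec$grid_shape)
  }
  list(suv = suv_volume(suv, spec$voxel_size),
       mask = array(as.integer(inside), spec$grid_shape),
       analytic_volume_cm3 = 4 / 3 * pi * prod(spec$lesion_radii) / 1000)
}

#' Exact volume enclosed by a fractional-peak iso-surface of a phantom
#'
#' For the truncated-Gaussian uptake profile of [make_pet_phantom()], the
#' surface where SUV equals `fraction * suv_peak` is the ellipsoid of
#' normalized radius
#' \deqn{\rho^* = \sigma \sqrt{-2 \log\frac{frac \cdot peak - bg}{peak - bg}},}
#' so the enclosed volume is `rho*^3` times the full ellipsoid volume. Used
#' as the analytic oracle for MTV segmentation.
#'
#' @param spec a `phantom_spec`.
#' @param fraction iso-contour level as a fraction of `suv_peak` (default
#'   0.40, the MTV convention).
#' @return volume in cm^3.
#' @export
analytic_isocontour_volume <- function(spec, fraction = 0.40) {
  stopifnot(inherits(spec, "phantom_spec"))
  level <- fraction * spec$suv_peak
  if (level <= spec$suv_background)
    stop("iso-level does not rise above the background; the contour is open")
  rel <- (level - spec$suv_background) /
    (spec$suv_peak - spec$suv_background)
  rho_star <- spec$profile_sigma * sqrt(-2 * log(rel))
  if (rho_star > 1)
    stop("iso-contour falls outside the lesion ellipsoid (rho* > 1)")
  rho_star^3 * 4 / 3 * pi * prod(spec$lesion_radii) / 1000
}

#' Generate a multi-b-value DWI phantom
#'
#' Every voxel's noiseless signal follows the IVIM forward model with its
#' tissue class's true parameters (lesion inside the ellipsoid, background
#' outside). Noise is Rician, as appropriate for magnitude MR images: the
#' magnitude of the noiseless signal plus complex Gaussian noise with
#' per-channel sd `noise_sigma * S0`. True parameter maps are returned so
#' parameter-recovery tests can compare fits against ground truth.
#'
#' @param spec a `phantom_spec`.
#' @param b_values b-value schedule, s/mm^2 (default [default_b_values()]).
#' @return list with `dwi` (a [dwi_series()]), `mask` (lesion VOI, 0/1
#'   array), and `truth` (list of 3-D arrays `D`, `D_star`, `f`, `S0`).
#' @export
make_dwi_phantom <- function(spec, b_values = default_b_values()) {
  stopifnot(inherits(spec, "phantom_spec"))
  .check_bvals(b_values)
  rho <- .phantom_rho(spec)
  inside <- rho <= 1
  dims <- spec$grid_shape
  nb <- length(b_values)

  truth <- list(D = array(NA_real_, dims), D_star = array(NA_real_, dims),
                f = array(NA_real_, dims), S0 = array(NA_real_, dims))
  for (nm in names(truth)) {
    truth[[nm]][] <- spec$ivim_true$background[[nm]]
    truth[[nm]][inside] <- spec$ivim_true$lesion[[nm]]
  }

  sig <- array(NA_real_, c(dims, nb))
  flat <- matrix(NA_real_, prod(dims), nb)
  for (cls in c("lesion", "background")) {
    p <- spec$ivim_true[[cls]]
    vox <- if (cls == "lesion") which(inside) else which(!inside)
    if (length(vox))
      flat[vox, ] <- matrix(ivim_signal(b_values, p$D, p$D_star, p$f, p$S0),
                            length(vox), nb, byrow = TRUE)
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    sd0 <- matrix(spec$noise_sigma * as.vector(truth$S0), prod(dims), nb)
    n_re <- matrix(rnorm(length(flat)), nrow(flat)) * sd0
    n_im <- matrix(rnorm(length(flat)), nrow(flat)) * sd0
    flat <- sqrt((flat + n_re)^2 + n_im^2)
  }
  sig[] <- flat
  list(dwi = dwi_series(sig, b_values, spec$voxel_size),
       mask = array(as.integer(inside), dims),
       truth = truth)
}
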