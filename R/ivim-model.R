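#' IVIM bi-exponential signal model
#'
#' Relative diffusion-weighted signal under the intravoxel incoherent motion
#' (IVIM) model,
#' \deqn{S(b)/S(0) = f \exp[-b (D^* + D)] + (1 - f) \exp(-b D),}
#' where `D` is the pure (tissue) diffusion coefficient, `D_star` the
#' pseudo-diffusion coefficient of the capillary compartment and `f` the
#' perfusion fraction. Note the fast compartment decays with rate
#' `D_star + D`, so the two exponents are separated by `D_star`.
#'
#' @param b diffusion weighting(s), s/mm^2; non-negative.
#' @param D pure diffusion coefficient, mm^2/s (e.g. `0.9e-3`).
#' @param D_star pseudo-diffusion coefficient, mm^2/s. May be `NA` when
#'   `f = 0` (the fast compartment is absent).
#' @param f perfusion fraction in `[0, 1]`.
#' @param S0 signal at `b = 0`; the default 1 returns relative signal.
#' @return numeric vector of signals, same length as `b`.
#' @examples
#' ivim_signal(0, D = 1e-3, D_star = 40e-3, f = 0.2)        # exactly 1
#' ivim_signal(1000, D = 1e-3, D_star = NA, f = 0)           # exp(-1)
#' @export
ivim_signal <- function(b, D, D_star = NA_real_, f = 0, S0 = 1) {
  if (any(b < 0)) stop("b-values must be non-negative")
  if (!is.finite(D) || D <= 0) stop("D must be a positive number")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (S0 <= 0) stop("S0 must be positive")
  if (f > 0) {
    if (!is.finite(D_star) || D_star < D)
      stop("D_star must be finite and >= D when f > 0")
    fast <- f * exp(-b * (D_star + D))
  } else {
    fast <- 0
  }
  S0 * (fast + (1 - f) * exp(-b * D))
}

## Weighted log-linear fit of log(s) on b. Weights proportional to s^2
## de-bias the log transform at low signal (delta method: var[log s] ~ 1/s^2).
## Returns slope/intercept of log(s) = intercept - slope * b.
.loglinear_fit <- function(signal, b, weighted = TRUE) {
  y <- log(signal)
  w <- if (weighted) signal^2 else rep(1, length(signal))
  X <- cbind(1, -b)
  fit <- lm.wfit(X, y, w)
  list(intercept = fit$coefficients[1L], slope = fit$coefficients[2L])
}

#' Mono-exponential ADC fit for one voxel
#'
#' Apparent diffusion coefficient from a (weighted) log-linear least-squares
#' fit of `log(signal)` on `b` using all supplied b-values. Because the fit
#' spans the perfusion-sensitive low-b range, a voxel with `f > 0` yields an
#' ADC larger than its true `D` — the classic perfusion contamination of the
#' single-exponential model.
#'
#' @param signal signal values at each b-value (arbitrary units).
#' @param b_values b-values, s/mm^2, same length as `signal`.
#' @param two_point if `TRUE`, use only the first and last b-value
#'   (the conventional two-point ADC from a b = 0/800 acquisition).
#' @param weighted weight the log-domain fit by `signal^2` (default).
#' @return list with `adc` (mm^2/s), `converged` (logical: all used signals
#'   positive) and `degenerate` (logical: signal constant across b).
#' @export
fit_adc <- function(signal, b_values, two_point = FALSE, weighted = TRUE) {
  stopifnot(length(signal) == length(b_values))
  if (length(b_values) < 2L) stop("need at least 2 b-values")
  if (two_point) {
    keep <- c(1L, length(b_values))
    signal <- signal[keep]
    b_values <- b_values[keep]
  }
  if (any(!is.finite(signal)) || any(signal <= 0))
    return(list(adc = NA_real_, converged = FALSE, degenerate = FALSE))
  if (length(unique(signal)) == 1L)
    return(list(adc = 0, converged = TRUE, degenerate = TRUE))
  ft <- .loglinear_fit(signal, b_values, weighted)
  list(adc = unname(ft$slope), converged = TRUE, degenerate = FALSE)
}

#' Segmented (two-step) IVIM fit for one voxel
#'
#' The standard asymptotic IVIM fit: at high b the pseudo-diffusion signal
#' has decayed away, so a log-linear fit over `b >= b_threshold` isolates the
#' tissue coefficient `D` and an extrapolated intercept `A`; the perfusion
#' fraction follows from the gap between the measured `S(0)` and `A`,
#' `f = (S(0) - A)/S(0)`; finally `D*` is recovered by a one-dimensional
#' bounded least-squares fit of the full bi-exponential curve with `D` and
#' `f` held fixed.
#'
#' @param signal signal values at each b-value.
#' @param b_values ascending b-values, s/mm^2; must include 0.
#' @param b_threshold split between perfusion-sensitive and diffusion-only
#'   regimes, s/mm^2 (default 200; with the default 14-value schedule this
#'   leaves 8 values below and 6 at/above the split).
#' @param D_star_bounds search interval for `D*`, mm^2/s.
#' @param weighted weight the log-domain step by `signal^2`.
#' @return list with `S0`, `D`, `D_star`, `f`, `residual` (RMS of the fitted
#'   curve), `converged`, and `clamped` (character vector naming any
#'   parameter that was clamped to its physical bounds). `D_star` is `NA`
#'   and noted in `clamped` when `f` is (numerically) zero, in which case
#'   the pseudo-diffusion coefficient is unidentifiable.
#' @export
fit_ivim_segmented <- function(signal, b_values, b_threshold = 200,
                               D_star_bounds = c(3e-3, 300e-3),
                               weighted = TRUE) {
  stopifnot(length(signal) == length(b_values))
  .check_bvals(b_values)
  hi <- b_values >= b_threshold
  if (sum(hi) < 3L || sum(!hi) < 2L)
    stop("need >= 3 b-values at/above b_threshold and >= 2 below")
  bad <- list(S0 = NA_real_, D = NA_real_, D_star = NA_real_, f = NA_real_,
              residual = NA_real_, converged = FALSE, clamped = character())
  if (any(!is.finite(signal)) || any(signal <= 0)) return(bad)

  clamped <- character()
  ## step 1: D and extrapolated intercept from the diffusion-only regime
  ft <- .loglinear_fit(signal[hi], b_values[hi], weighted)
  D <- unname(ft$slope)
  if (!is.finite(D) || D <= 0) return(bad)
  A <- exp(unname(ft$intercept))

  ## step 2: perfusion fraction from the b = 0 intercept gap
  S0_obs <- signal[b_values == 0][1L]
  f <- (S0_obs - A) / S0_obs
  if (f < 0) { f <- 0; clamped <- c(clamped, "f") }
  if (f > 1) { f <- 1; clamped <- c(clamped, "f") }

  ## step 3: D* by 1-D bounded NLS on the full curve, D and f fixed
  if (f < 1e-4) {
    D_star <- NA_real_
    clamped <- c(clamped, "D_star_unidentifiable")
  } else {
    lo <- max(D_star_bounds[1L], D)
    sse <- function(ds)
      sum((signal - ivim_signal(b_values, D, ds, f, S0_obs))^2)
    opt <- optimize(sse, interval = c(lo, D_star_bounds[2L]), tol = 1e-10)
    D_star <- opt$minimum
    ## the optimum sitting hard on a search bound is a non-convergence signal
    edge <- min(D_star - lo, D_star_bounds[2L] - D_star)
    if (edge < 1e-6 * diff(D_star_bounds))
      clamped <- c(clamped, "D_star_at_bound")
  }
  fitted <- ivim_signal(b_values, D, if (is.na(D_star)) D else D_star,
                        if (is.na(D_star)) 0 else f, S0_obs)
  list(S0 = S0_obs, D = D, D_star = D_star, f = f,
       residual = sqrt(mean((signal - fitted)^2)),
       converged = TRUE, clamped = clamped)
}

#' Full (simultaneous) IVIM fit for one voxel
#'
#' Bounded nonlinear least squares over `(S0, D, D*, f)` jointly, initialized
#' from the segmented fit (or a caller-supplied start). Falls back to the
#' segmented result when the joint optimization fails to improve the
#' residual, so the full fit is never worse than its initialization.
#'
#' @inheritParams fit_ivim_segmented
#' @param init optional named list `(S0, D, D_star, f)` used as the starting
#'   point; defaults to the segmented fit.
#' @param bounds named list of `c(lower, upper)` for `D`, `D_star`, `f`.
#'   Defaults separate the slow and fast compartments: D in (0, 3e-3],
#'   D* in [3e-3, 0.3], f in [0, 0.5] (mm^2/s).
#' @return as [fit_ivim_segmented()], plus `fallback` (logical: segmented
#'   result returned).
#' @export
fit_ivim_full <- function(signal, b_values, init = NULL, b_threshold = 200,
                          bounds = list(D = c(1e-6, 3e-3),
                                        D_star = c(3e-3, 300e-3),
                                        f = c(0, 0.5))) {
  stopifnot(length(signal) == length(b_values))
  if (length(b_values) < 4L) stop("need at least 4 b-values")
  seg <- if (is.null(init)) {
    fit_ivim_segmented(signal, b_values, b_threshold = b_threshold,
                       D_star_bounds = bounds$D_star)
  } else {
    ft <- ivim_signal(b_values, init$D, init$D_star, init$f, init$S0)
    c(init, list(residual = sqrt(mean((signal - ft)^2)),
                 converged = TRUE, clamped = character()))
  }
  if (!seg$converged) return(c(seg, list(fallback = TRUE)))

  start <- c(S0 = seg$S0,
             D = min(max(seg$D, bounds$D[1L]), bounds$D[2L]),
             D_star = if (is.na(seg$D_star)) 10e-3 else seg$D_star,
             f = min(max(seg$f, bounds$f[1L]), bounds$f[2L]))
  sse <- function(p)
    sum((signal - ivim_signal(b_values, p[2L], p[3L], p[4L], p[1L]))^2)
  opt <- tryCatch(
    optim(start, sse, method = "L-BFGS-B",
          lower = c(1e-9, bounds$D[1L], bounds$D_star[1L], bounds$f[1L]),
          upper = c(Inf, bounds$D[2L], bounds$D_star[2L], bounds$f[2L]),
          control = list(factr = 1e4, maxit = 500)),
    error = function(e) NULL)

  seg_sse <- length(signal) * seg$residual^2
  if (is.null(opt) || !is.finite(opt$value) || opt$value > seg_sse)
    return(c(seg, list(fallback = TRUE)))
  p <- opt$par
  if (p["D_star"] < p["D"]) return(c(seg, list(fallback = TRUE)))
  list(S0 = unname(p["S0"]), D = unname(p["D"]),
       D_star = unname(p["D_star"]), f = unname(p["f"]),
       residual = sqrt(opt$value / length(signal)),
       converged = TRUE, clamped = seg$clamped, fallback = FALSE)
}

#' Fit parameter maps over a volume of interest
#'
#' Applies the chosen voxelwise fit to every voxel inside `mask` of a 4-D
#' diffusion series, producing 3-D maps of ADC, D, D*, f, the per-voxel RMS
#' residual, and a convergence flag. Voxels outside the mask are `NA`;
#' non-converged voxels are flagged, never silently filled.
#'
#' @param dwi a [dwi_series()] object.
#' @param mask 3-D logical/0-1 array matching the spatial grid.
#' @param method `"segmented"` (default) or `"full"`.
#' @param b_threshold passed to the voxel fit.
#' @param two_point_adc compute the ADC map from the first/last b-value only.
#' @return an object of class `ivim_maps`: list of 3-D arrays `ADC`, `D`,
#'   `D_star`, `f`, `S0`, `residual` (units mm^2/s for coefficients) and a
#'   logical array `converged`.
#' @export
fit_maps <- function(dwi, mask, method = c("segmented", "full"),
                     b_threshold = 200, two_point_adc = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "dwi_series"))
  dims <- dim(dwi$signal)[1:3]
  mask <- .as_mask(mask, dims)
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")

  b <- dwi$b_values
  flat <- matrix(dwi$signal, nrow = prod(dims))
  maps <- replicate(6, array(NA_real_, dims), simplify = FALSE)
  names(maps) <- c("ADC", "D", "D_star", "f", "S0", "residual")
  conv <- array(FALSE, dims)
  for (i in idx) {
    s <- flat[i, ]
    a <- fit_adc(s, b, two_point = two_point_adc)
    fit <- if (method == "segmented")
      fit_ivim_segmented(s, b, b_threshold = b_threshold)
    else
      fit_ivim_full(s, b, b_threshold = b_threshold)
    maps$ADC[i] <- a$adc
    maps$D[i] <- fit$D
    maps$D_star[i] <- fit$D_star
    maps$f[i] <- fit$f
    maps$S0[i] <- fit$S0
    maps$residual[i] <- fit$residual
    conv[i] <- a$converged && fit$converged
  }
  structure(c(maps, list(converged = conv, voxel_size = dwi$voxel_size,
                         method = method, b_threshold = b_threshold)),
            class = "ivim_maps")
}

#' VOI summary statistics of IVIM parameter maps
#'
#' Mean and single-voxel minimum of ADC and D over the converged voxels of a
#' volume of interest, plus VOI-mean D* and f — the six per-patient diffusion
#' features (ADCmean, ADCmin, Dmean, Dmin, D*, f). Coefficients are reported
#' in the conventional 1e-3 mm^2/s unit; f is unitless.
#'
#' @param maps an `ivim_maps` object from [fit_maps()].
#' @param mask 3-D VOI mask.
#' @return named list: `adc_mean`, `adc_min`, `d_mean`, `d_min` (1e-3
#'   mm^2/s), `d_star` (VOI mean, 1e-3 mm^2/s), `f` (VOI mean), and
#'   `n_voxels` used.
#' @export
voi_statistics <- function(maps, mask) {
  stopifnot(inherits(maps, "ivim_maps"))
  mask <- .as_mask(mask, dim(maps$converged))
  use <- mask & maps$converged
  n <- sum(use)
  if (n == 0L) stop("no converged voxels inside the mask")
  to_milli <- 1e3
  ds <- maps$D_star[use]
  list(adc_mean = mean(maps$ADC[use]) * to_milli,
       adc_min  = min(maps$ADC[use]) * to_milli,
       d_mean   = mean(maps$D[use]) * to_milli,
       d_min    = min(maps$D[use]) * to_milli,
       d_star   = if (all(is.na(ds))) NA_real_
                  else mean(ds, na.rm = TRUE) * to_milli,
       f        = mean(maps$f[use]),
       n_voxels = n)
}

.check_bvals <- function(b) {
  if (any(b < 0)) stop("b-values must be non-negative")
  if (anyDuplicated(b)) stop("duplicate b-values")
  if (is.unsorted(b, strictly = TRUE)) stop("b-values must be ascending")
  if (b[1L] != 0) stop("b-value schedule must include b = 0 first")
  invisible(b)
}

.as_mask <- function(mask, dims) {
  if (!identical(as.integer(dim(mask)), as.integer(dims)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match grid ", paste(dims, collapse = "x"))
  array(as.logical(mask != 0), dims)
}

#' Table-style b-value schedule used throughout the package
#'
#' The 14-value axial IVIM schedule (s/mm^2) the defaults assume:
#' 0, 10, 25, 50, 75, 100, 125, 150, 200, 300, 400, 600, 800, 1000.
#' @return numeric vector of 14 b-values.
#' @export
default_b_values <- function() {
  c(0, 10, 25, 50, 75, 100, 125, 150, 200, 300, 400, 600, 800, 1000)
}
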