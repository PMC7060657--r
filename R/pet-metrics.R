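#' Segment the metabolic tumor volume
#'
#' Implements the fractional-SUVmax threshold convention: SUVmax is taken as
#' the maximum SUV inside the seed ROI; the metabolic mask is the
#' 26-connected component of voxels with `SUV >= threshold_fraction *
#' SUVmax` that contains the SUVmax voxel. The connectivity constraint
#' prevents distant hot structures inside a loosely drawn ROI from inflating
#' the volume. MTV is the voxel count times the voxel volume, in cm^3.
#'
#' @param vol a [suv_volume()].
#' @param seed_roi non-empty 3-D mask delimiting the lesion region.
#' @param threshold_fraction fraction of SUVmax defining the iso-threshold,
#'   in (0, 1); default 0.40.
#' @return list with `mask` (0/1 metabolic mask), `mtv` (cm^3), `suv_max`
#'   (g/cm^3) and `threshold` (absolute SUV threshold applied).
#' @export
segment_mtv <- function(vol, seed_roi, threshold_fraction = 0.40) {
  stopifnot(inherits(vol, "suv_volume"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  dims <- dim(vol$suv)
  seed_roi <- .as_mask(seed_roi, dims)
  if (!any(seed_roi)) stop("seed ROI is empty")
  suv_max <- max(vol$suv[seed_roi])
  if (suv_max <= 0) stop("SUV is zero everywhere inside the seed ROI")
  thr <- threshold_fraction * suv_max
  above <- vol$suv >= thr
  ## seed the flood fill at the (first) SUVmax voxel inside the ROI
  peak <- which(seed_roi & vol$suv == suv_max)[1L]
  comp <- .connected_component_26(above, peak)
  list(mask = array(as.integer(comp), dims),
       mtv = sum(comp) * voxel_volume_cm3(vol$voxel_size),
       suv_max = suv_max, threshold = thr)
}

## 26-connected component of TRUE voxels containing the seed (linear index).
## Breadth-first flood fill over precomputed neighbor offsets.
.connected_component_26 <- function(above, seed) {
  dims <- dim(above)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  comp <- array(FALSE, dims)
  if (!above[seed]) return(comp)
  comp[seed] <- TRUE
  queue <- seed
  while (length(queue)) {
    cur <- queue
    queue <- integer()
    idx <- arrayInd(cur, dims)
    for (k in seq_len(nrow(off))) {
      x <- idx[, 1L] + off$dx[k]
      y <- idx[, 2L] + off$dy[k]
      z <- idx[, 3L] + off$dz[k]
      ok <- x >= 1L & x <= nx & y >= 1L & y <= ny & z >= 1L & z <= nz
      if (!any(ok)) next
      lin <- x[ok] + (y[ok] - 1L) * nx + (z[ok] - 1L) * nx * ny
      new <- lin[above[lin] & !comp[lin]]
      if (length(new)) {
        comp[new] <- TRUE
        queue <- c(queue, new)
      }
    }
    queue <- unique(queue)
  }
  comp
}

#' SUVmax and SUVmean over a mask
#'
#' @param vol a [suv_volume()].
#' @param mask non-empty 3-D mask (normally the metabolic mask from
#'   [segment_mtv()], i.e. the statistics describe the segmented tumor).
#' @return list with `suv_max` and `suv_mean` (g/cm^3).
#' @export
compute_suv_stats <- function(vol, mask) {
  stopifnot(inherits(vol, "suv_volume"))
  mask <- .as_mask(mask, dim(vol$suv))
  if (!any(mask)) stop("mask is empty")
  v <- vol$suv[mask]
  list(suv_max = max(v), suv_mean = mean(v))
}

#' Total lesion glycolysis
#'
#' TLG = SUVmean x MTV, the product of the mean uptake of the metabolic
#' volume (g/cm^3) and that volume (cm^3), in grams.
#'
#' @param suv_mean mean SUV of the metabolic volume, g/cm^3.
#' @param mtv metabolic tumor volume, cm^3.
#' @return TLG in g.
#' @examples
#' compute_tlg(9.35, 34.94)   # 326.69 g
#' compute_tlg(7.92, 10.1)    # 79.99 g
#' @export
compute_tlg <- function(suv_mean, mtv) {
  if (suv_mean < 0 || mtv < 0) stop("inputs must be non-negative")
  suv_mean * mtv
}

#' All PET metabolic metrics for one lesion
#'
#' Convenience wrapper chaining [segment_mtv()], [compute_suv_stats()] and
#' [compute_tlg()]: segments the metabolic volume inside the seed ROI and
#' returns the four PET features of a patient record.
#'
#' @inheritParams segment_mtv
#' @return list with `suv_max`, `suv_mean` (g/cm^3), `mtv` (cm^3), `tlg`
#'   (g), and `metabolic_mask`.
#' @export
tumor_metrics <- function(vol, seed_roi, threshold_fraction = 0.40) {
  seg <- segment_mtv(vol, seed_roi, threshold_fraction)
  st <- compute_suv_stats(vol, seg$mask)
  list(suv_max = st$suv_max, suv_mean = st$suv_mean, mtv = seg$mtv,
       tlg = compute_tlg(st$suv_mean, seg$mtv), metabolic_mask = seg$mask)
}
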