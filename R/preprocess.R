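# Separable truncated-Gaussian smoothing of a 3-D array. With a mask, the
# filter is renormalised over the mask (conv(a*m)/conv(m)), so constants
# are preserved exactly on the mask and edges are not darkened.
gaussian_smooth3d <- function(a, fwhm_mm, voxel_mm, mask = NULL) {
  if (fwhm_mm <= 0) return(a)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  conv_axis <- function(x, ax, kernel) {
    r <- (length(kernel) - 1L) / 2L
    out <- array(0, dim = dim(x))
    for (k in seq_along(kernel)) {
      s <- integer(3L); s[ax] <- k - r - 1L
      out <- out + kernel[k] * roll_int(x, s, fill = 0)
    }
    out
  }
  conv <- function(x) {
    for (ax in 1:3) {
      sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm[ax]
      r <- max(1L, ceiling(3 * sigma))
      kern <- exp(-((-r):r)^2 / (2 * sigma^2))
      kern <- kern / sum(kern)
      x <- conv_axis(x, ax, kern)
    }
    x
  }
  if (is.null(mask)) return(conv(a))
  m <- mask + 0
  num <- conv(a * m)
  den <- conv(m)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Estimate the coil sensitivity map from a homogeneous phantom scan
#'
#' The scan of a homogeneous reference phantom is smoothed with a
#' Gaussian kernel and divided by its maximum, giving a relative
#' reception-efficiency field in (0, 1]. Voxels below
#' `validity_fraction` of the maximum are marked invalid; corrected
#' values there would be dominated by noise amplification and are
#' excluded downstream.
#'
#' @param homogeneous_scan an [na_volume()] of the uniform phantom.
#' @param smoothing_fwhm_mm Gaussian FWHM in mm.
#' @param validity_fraction relative threshold below which the map is
#'   marked invalid.
#' @return A `sensitivity_map` list: `values` (array, NA outside the
#'   support), `valid` (logical array), `voxel_size_mm`, `reference`
#'   (the normalising maximum, a.u.).
#' @export
estimate_sensitivity_map <- function(homogeneous_scan,
                                     smoothing_fwhm_mm = 6,
                                     validity_fraction = 0.05) {
  stopifnot(inherits(homogeneous_scan, "na_volume"))
  a <- homogeneous_scan$data
  if (any(is.na(a))) stop("sensitivity scan contains absent voxels")
  if (all(a == 0)) stop("sensitivity scan is all zero")
  if (any(a < 0)) a <- pmax(a, 0)  # magnitude data; clip noise undershoot
  support <- array(TRUE, dim = dim(a))
  sm <- gaussian_smooth3d(a, smoothing_fwhm_mm,
                          homogeneous_scan$voxel_size_mm, mask = support)
  ref <- max(sm)
  values <- sm / ref
  valid <- values >= validity_fraction
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid,
                 voxel_size_mm = homogeneous_scan$voxel_size_mm,
                 origin_mm = homogeneous_scan$origin_mm,
                 reference = ref,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 validity_fraction = validity_fraction),
            class = "sensitivity_map")
}

#' Correct a volume for coil sensitivity
#'
#' Voxel-wise division by the normalised sensitivity map. Voxels where
#' the map is invalid become `NA` (absent) and are excluded from every
#' downstream ROI statistic; the count is attached as attribute
#' `n_invalid`.
#'
#' @param volume an [na_volume()] on the map's grid.
#' @param map a `sensitivity_map` from [estimate_sensitivity_map()].
#' @return The corrected [na_volume()].
#' @export
apply_sensitivity_correction <- function(volume, map) {
  stopifnot(inherits(volume, "na_volume"),
            inherits(map, "sensitivity_map"))
  if (!identical(dim(volume$data), dim(map$values)) ||
      any(abs(volume$voxel_size_mm - map$voxel_size_mm) > 1e-6))
    stop("grid mismatch between volume and sensitivity map")
  data <- volume$data / map$values
  data[!map$valid] <- NA_real_
  out <- volume
  out$data <- data
  attr(out, "n_invalid") <- sum(!map$valid)
  out
}

#' Translation-only motion correction
#'
#' Finds the integer-voxel shift (within `+/- max_shift_voxels` per
#' axis) maximising the normalised cross-correlation between the moving
#' and fixed volume over their overlap, then resamples the moving volume
#' by that shift with edge voxels marked absent. Ties are broken by the
#' smallest shift magnitude, then lexicographically.
#'
#' @param moving,fixed [na_volume()]s on the same grid.
#' @param max_shift_voxels search window half-width.
#' @return list with `shift` (integer 3-vector, the displacement that
#'   aligns `moving` onto `fixed`), `correlation`, `resampled`
#'   ([na_volume()] with NA edges) and `low_confidence` (TRUE when the
#'   best correlation is below 0.1, e.g. for pure-noise inputs; exact
#'   alignments of a sparse structure at protocol SNR sit well above
#'   this, pure-noise maxima well below).
#' @export
register_translation <- function(moving, fixed, max_shift_voxels = 3) {
  stop_if_grid_mismatch(moving, fixed)
  d <- dim(fixed$data)
  m <- as.integer(max_shift_voxels)
  if (any(2L * m + 1L > d)) stop("search window larger than the grid")
  shifts <- as.matrix(expand.grid(sx = -m:m, sy = -m:m, sz = -m:m))
  best <- NULL
  for (i in seq_len(nrow(shifts))) {
    s <- shifts[i, ]
    idx_f <- idx_m <- vector("list", 3L)
    for (ax in 1:3) {
      if (s[ax] >= 0) { idx_f[[ax]] <- (1 + s[ax]):d[ax]
                        idx_m[[ax]] <- 1:(d[ax] - s[ax]) }
      else            { idx_f[[ax]] <- 1:(d[ax] + s[ax])
                        idx_m[[ax]] <- (1 - s[ax]):d[ax] }
    }
    # hypothesis: moving is the fixed content displaced by +s, so
    # moving[x + s] lines up with fixed[x]
    fv <- moving$data[idx_f[[1]], idx_f[[2]], idx_f[[3]]]
    mv <- fixed$data[idx_m[[1]], idx_m[[2]], idx_m[[3]]]
    cc <- suppressWarnings(stats::cor(as.vector(fv), as.vector(mv)))
    if (!is.finite(cc)) cc <- 0
    cand <- list(shift = as.integer(s), cc = cc, mag = sum(s^2))
    if (is.null(best) || cc > best$cc + 1e-12 ||
        (abs(cc - best$cc) <= 1e-12 &&
         (cand$mag < best$mag ||
          (cand$mag == best$mag &&
           paste(cand$shift, collapse = ",") <
           paste(best$shift, collapse = ","))))) best <- cand
  }
  res <- moving
  res$data <- roll_int(moving$data, -best$shift, fill = NA_real_)
  low <- best$cc < 0.1
  if (low) warning("registration correlation ", signif(best$cc, 3),
                   " is near zero; shift estimate is unreliable")
  list(shift = best$shift, correlation = best$cc, resampled = res,
       low_confidence = low)
}
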