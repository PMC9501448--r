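#' 3-D scalar volume with acquisition metadata
#'
#' Container for a single 3-D image: the voxel grid, its geometry and the
#' acquisition context needed downstream (nucleus, TR, TE). All signal
#' values are in arbitrary units (a.u.), geometry in mm, times in ms.
#'
#' Voxel indices are 0-based in world-coordinate formulas:
#' world position = origin + index * voxel_size. Axis 3 is the slice axis
#' (the tendon's long axis), increasing from the calcaneal insertion
#' (distal) towards proximal.
#'
#' `NA` values mark voxels excluded from analysis (e.g. outside the valid
#' region of a sensitivity map); `NaN`/`Inf` are rejected.
#'
#' @param data 3-D numeric array.
#' @param voxel_size_mm length-3 positive numeric, voxel edge lengths.
#' @param origin_mm length-3 numeric, world position of voxel (0,0,0).
#' @param nucleus `"NA23"` or `"H1"`.
#' @param tr_ms,te_ms repetition / echo time in ms (`NA` if not applicable).
#' @return An object of class `na_volume`.
#' @export
na_volume <- function(data, voxel_size_mm, origin_mm = c(0, 0, 0),
                      nucleus = c("NA23", "H1"),
                      tr_ms = NA_real_, te_ms = NA_real_) {
  nucleus <- match.arg(nucleus)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3-D volume: data must be a 3-D array, got ",
         paste(dim(data), collapse = "x"))
  if (any(dim(data) < 1L)) stop("volume must have >= 1 voxel per axis")
  storage.mode(data) <- "double"
  if (any(is.nan(data)) || any(is.infinite(data)))
    stop("volume contains non-finite (NaN/Inf) values")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive finite numbers")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be 3 finite numbers")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm, nucleus = nucleus,
                 tr_ms = as.numeric(tr_ms)[1], te_ms = as.numeric(te_ms)[1]),
            class = "na_volume")
}

#' @export
print.na_volume <- function(x, ...) {
  cat(sprintf("<na_volume> %s  %s voxels @ %s mm  TR=%s TE=%s ms\n",
              x$nucleus, paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              format(x$tr_ms), format(x$te_ms)))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  range [%.4g, %.4g] a.u., %d NA voxels\n",
              rng[1], rng[2], sum(is.na(x$data))))
  invisible(x)
}

# Grid equality check shared by volumes and label maps.
same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "na_labelmap")) dim(a$labels) else dim(a$data)
  db <- if (inherits(b, "na_labelmap")) dim(b$labels) else dim(b$data)
  identical(da, db) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) <= tol) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("grid mismatch between ", what,
         " (shape, voxel size or origin differ beyond 1e-6 mm)")
  invisible(TRUE)
}
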