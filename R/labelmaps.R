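#' Region codes used throughout the tendon study
#'
#' Integer label codes for the anatomical and phantom regions: the three
#' tendon segments (INS = calcaneal insertion, MID = mid-portion,
#' MTJ = myotendinous junction), an undivided tendon code used before
#' segmentation, optional skin, the four reference vials by nominal
#' concentration, and the dedicated noise region.
#'
#' @format Named integer vector.
#' @export
AT_LABELS <- c(BACKGROUND = 0L, INS = 1L, MID = 2L, MTJ = 3L, SKIN = 4L,
               TENDON = 5L, VIAL_50 = 10L, VIAL_75 = 11L, VIAL_100 = 12L,
               VIAL_125 = 13L, NOISE = 99L)

#' Integer label map on a named grid
#'
#' @param labels 3-D integer array of region codes.
#' @param voxel_size_mm,origin_mm grid geometry as in [na_volume()].
#' @param legend named integer vector mapping role names to codes; every
#'   nonzero code present in `labels` must appear in it.
#' @return An object of class `na_labelmap`.
#' @export
na_labelmap <- function(labels, voxel_size_mm, origin_mm = c(0, 0, 0),
                        legend = AT_LABELS) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("not a 3-D label map")
  if (any(!is.finite(labels))) stop("label map contains non-finite values")
  if (any(labels != round(labels)))
    stop("label map contains non-integer values")
  storage.mode(labels) <- "integer"
  legend <- vapply(legend, as.integer, integer(1))
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, legend)
  if (length(unknown))
    stop("label code(s) without legend entry: ",
         paste(unknown, collapse = ", "))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive numbers")
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm), legend = legend),
            class = "na_labelmap")
}

#' @export
print.na_labelmap <- function(x, ...) {
  cat(sprintf("<na_labelmap> %s voxels @ %s mm\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  tab <- table(x$labels[x$labels != 0L])
  if (length(tab)) {
    nm <- names(x$legend)[match(as.integer(names(tab)), x$legend)]
    cat("  ", paste(sprintf("%s=%d", nm, as.integer(tab)), collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}

# Resolve region names or codes against a legend; returns integer codes.
resolve_codes <- function(mask, codes) {
  if (is.character(codes)) {
    miss <- setdiff(codes, names(mask$legend))
    if (length(miss)) stop("unknown region name(s): ",
                           paste(miss, collapse = ", "))
    codes <- mask$legend[codes]
  }
  as.integer(codes)
}

# Logical array selecting the given codes, erroring on empty selections.
mask_indicator <- function(mask, codes, allow_empty = FALSE) {
  codes <- resolve_codes(mask, codes)
  ind <- array(mask$labels %in% codes, dim = dim(mask$labels))
  if (!allow_empty && !any(ind))
    stop("region code(s) ", paste(codes, collapse = ","),
         " not present in label map")
  ind
}
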