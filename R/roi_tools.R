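#' Partition a tendon mask into INS / MID / MTJ segments
#'
#' Starting from the most distal occupied slice, consecutive half-open
#' runs of `segment_length_mm` along the slice axis are labelled INS
#' (insertion), MID (mid-portion) and MTJ (myotendinous junction); at a
#' 1-mm slice thickness and the default 30 mm this reproduces the
#' 30-slice segments of the in-vivo protocol. Slices beyond the third
#' segment stay unlabelled. Purely mask-based and idempotent.
#'
#' @param fine_mask an [na_labelmap()] whose tendon carries a single code.
#' @param tendon_code the code marking the tendon (default `TENDON`).
#' @param segment_length_mm segment length (mm).
#' @return The label map with the tendon relabelled INS/MID/MTJ.
#' @export
segment_tendon_mask <- function(fine_mask,
                                tendon_code = AT_LABELS[["TENDON"]],
                                segment_length_mm = 30) {
  stopifnot(inherits(fine_mask, "na_labelmap"))
  lab <- fine_mask$labels
  tend <- lab == tendon_code
  if (!any(tend)) stop("tendon code ", tendon_code, " not present in mask")
  dz <- fine_mask$voxel_size_mm[3]
  occ <- which(apply(tend, 3, any))
  length_mm <- (max(occ) - min(occ) + 1) * dz
  if (length_mm < 3 * segment_length_mm)
    stop(sprintf("tendon length %g mm < %g mm (three segments of %g mm)",
                 length_mm, 3 * segment_length_mm, segment_length_mm))
  z0 <- min(occ)
  # distance (mm) of each slice start from the distal tendon end
  offset_mm <- (seq_len(dim(lab)[3]) - z0) * dz
  seg <- floor(offset_mm / segment_length_mm)  # 0=INS, 1=MID, 2=MTJ
  codes <- AT_LABELS[c("INS", "MID", "MTJ")]
  out <- lab
  out[tend] <- 0L
  for (k in 0:2) {
    sl <- which(seg == k & offset_mm >= 0)
    if (length(sl)) {
      sel <- tend
      sel[, , -sl] <- FALSE
      out[sel] <- codes[[k + 1]]
    }
  }
  na_labelmap(out, fine_mask$voxel_size_mm, fine_mask$origin_mm,
              fine_mask$legend)
}

# Per-coarse-voxel fraction occupied by the given fine-mask codes.
code_fractions <- function(fine_mask, codes, factor) {
  ind <- mask_indicator(fine_mask, codes, allow_empty = TRUE)
  block_reduce(ind + 0, factor, "mean")
}

coarse_factor <- function(fine_mask, coarse_voxel_mm) {
  f <- coarse_voxel_mm / fine_mask$voxel_size_mm[1]
  if (abs(f - round(f)) > 1e-9)
    stop("coarse voxel size is not an integer multiple of the fine size")
  as.integer(round(f))
}

#' Transfer a fine label map onto a coarser grid
#'
#' For every code, the fraction of fine voxels carrying it inside each
#' coarse voxel is counted; a coarse voxel is labelled with the code of
#' largest fraction among those reaching `inclusion_threshold` (ties go
#' to the smaller code, i.e. the more distal tendon segment).
#'
#' @param fine_mask an [na_labelmap()].
#' @param coarse_voxel_mm target voxel size (integer multiple of fine).
#' @param inclusion_threshold minimum fraction for a coarse voxel to be
#'   labelled (`>=`, so a fraction exactly at the threshold is included).
#' @return Coarse [na_labelmap()].
#' @export
transfer_mask <- function(fine_mask, coarse_voxel_mm,
                          inclusion_threshold = 0.5) {
  stopifnot(inherits(fine_mask, "na_labelmap"))
  f <- coarse_factor(fine_mask, coarse_voxel_mm)
  codes <- sort(setdiff(unique(as.vector(fine_mask$labels)), 0L))
  dcoarse <- dim(fine_mask$labels) / f
  best_frac <- array(0, dim = dcoarse)
  out <- array(0L, dim = dcoarse)
  for (code in codes) {  # ascending, so ties keep the smaller code
    fr <- code_fractions(fine_mask, code, f)
    take <- fr >= inclusion_threshold & fr > best_frac
    out[take] <- code
    best_frac <- pmax(best_frac, fr)
  }
  na_labelmap(out, rep(coarse_voxel_mm, 3), fine_mask$origin_mm,
              fine_mask$legend)
}
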