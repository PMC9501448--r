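#' ROI descriptive statistics
#'
#' Mean, unbiased (n-1) standard deviation, relative SD in percent and
#' voxel count, with `NA` (absent) voxels excluded.
#'
#' @param values numeric vector of voxel values.
#' @return list `mean`, `sd`, `rel_sd_pct`, `n_voxels`.
#' @export
roi_stats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("ROI is empty after exclusions")
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else 0
  list(mean = m, sd = s,
       rel_sd_pct = if (m != 0) 100 * s / abs(m) else NA_real_,
       n_voxels = length(values))
}

#' Signal-to-noise ratio against a dedicated noise region
#'
#' Divides every ROI voxel by the unbiased standard deviation of the
#' signal-free noise region, giving a per-voxel SNR map, and summarises
#' it over the ROI.
#'
#' @param volume an [na_volume()].
#' @param mask an [na_labelmap()] on the same grid.
#' @param roi_code region code(s)/name(s) of the signal ROI.
#' @param noise_code code of the noise region (default `NOISE`).
#' @param min_noise_voxels required noise-region size.
#' @return [roi_stats()] of the SNR map over the ROI, plus `noise_sd`.
#' @export
compute_snr <- function(volume, mask, roi_code,
                        noise_code = AT_LABELS[["NOISE"]],
                        min_noise_voxels = 100) {
  stop_if_grid_mismatch(volume, mask, "volume and label map")
  noise_vals <- volume$data[mask_indicator(mask, noise_code)]
  noise_vals <- noise_vals[!is.na(noise_vals)]
  if (length(noise_vals) < min_noise_voxels)
    stop("noise region has ", length(noise_vals), " voxels; need >= ",
         min_noise_voxels)
  noise_sd <- stats::sd(noise_vals)
  if (noise_sd == 0) stop("noise region has zero standard deviation")
  roi_vals <- volume$data[mask_indicator(mask, roi_code)]
  out <- roi_stats(roi_vals / noise_sd)
  out$noise_sd <- noise_sd
  out
}

#' Linear concentration calibration over the reference vials
#'
#' Ordinary least squares of vial ROI-mean signal against nominal
#' concentration, with intercept (the intercept absorbs the additive
#' noise floor of magnitude images).
#'
#' @param vial_means ROI-mean signal per vial (a.u.).
#' @param concentrations_mM matching nominal concentrations.
#' @return A `calibration_line` list: `slope` (a.u./mM), `intercept`
#'   (a.u.), `r_squared`, and the inputs.
#' @export
fit_calibration <- function(vial_means, concentrations_mM) {
  if (length(vial_means) != length(concentrations_mM))
    stop("one mean per concentration required")
  if (length(vial_means) < 2) stop("need >= 2 reference vials")
  if (length(unique(concentrations_mM)) < 2)
    stop("vial concentrations must be distinct")
  fit <- stats::lm(vial_means ~ concentrations_mM)
  sst <- sum((vial_means - mean(vial_means))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 concentrations_mM = concentrations_mM,
                 vial_means = vial_means),
            class = "calibration_line")
}

#' Reference-vial ROI means on the sodium grid
#'
#' Transfers each vial's fine-mask region to the coarse grid keeping
#' only interior voxels (inclusion threshold 1 by default, emulating
#' manually drawn interior vial ROIs) and averages the volume there.
#'
#' @param volume the quantification [na_volume()] (coarse grid).
#' @param fine_mask fine [na_labelmap()] holding the vial codes.
#' @param vial_codes vial codes in the order of the concentration list.
#' @param inclusion_threshold transfer threshold for vial voxels.
#' @return numeric vector of vial ROI means.
#' @export
vial_roi_means <- function(volume, fine_mask,
                           vial_codes = AT_LABELS[c("VIAL_50", "VIAL_75",
                                                    "VIAL_100", "VIAL_125")],
                           inclusion_threshold = 1) {
  f <- coarse_factor(fine_mask, volume$voxel_size_mm[1])
  vapply(vial_codes, function(code) {
    fr <- code_fractions(fine_mask, code, f)
    roi <- fr >= inclusion_threshold
    if (!any(roi)) stop("vial ROI for code ", code,
                        " empty at threshold ", inclusion_threshold)
    vals <- volume$data[roi]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) stop("vial ROI empty after exclusions")
    mean(vals)
  }, numeric(1))
}

#' Relaxation-weighting factor of the acquisition
#'
#' Fraction of the fully relaxed signal retained at a given TR/TE under
#' the saturation-recovery / biexponential model:
#' `f = (1 - exp(-TR/T1)) * (ps*exp(-TE/T2s*) + (1-ps)*exp(-TE/T2l*))`.
#' Bounded in (0, 1], strictly increasing in TR and strictly decreasing
#' in TE. The ratio of the phantom factor to the tissue factor converts
#' phantom-calibrated signal into tissue concentration.
#'
#' @param relaxation a [relaxation_params()].
#' @param tr_ms,te_ms acquisition timing (ms).
#' @return scalar factor in (0, 1].
#' @export
relaxation_weighting_factor <- function(relaxation, tr_ms, te_ms) {
  ideal_signal(1, relaxation, tr_ms, te_ms, scale = 1)
}

#' Partial-volume fraction of a region on the sodium grid
#'
#' Counts the high-resolution mask voxels of the region inside each
#' low-resolution voxel. The coarse ROI consists of the voxels whose
#' fraction reaches `inclusion_threshold`; the mean fraction over that
#' ROI is the partial-volume divisor of the aTSC correction.
#'
#' @param fine_mask fine [na_labelmap()].
#' @param codes region code(s)/name(s) (a union, e.g. all three tendon
#'   segments for the whole tendon).
#' @param coarse_voxel_mm target voxel size.
#' @param inclusion_threshold minimum fraction for ROI membership.
#' @return list `mean_fraction`, `roi` (logical coarse array),
#'   `fractions` (numeric coarse array).
#' @export
partial_volume_fraction <- function(fine_mask, codes, coarse_voxel_mm,
                                    inclusion_threshold = 0.5) {
  f <- coarse_factor(fine_mask, coarse_voxel_mm)
  codes <- resolve_codes(fine_mask, codes)
  fr <- code_fractions(fine_mask, codes, f)
  roi <- fr >= inclusion_threshold
  if (!any(roi)) stop("coarse ROI empty at threshold ", inclusion_threshold)
  list(mean_fraction = mean(fr[roi]), roi = roi, fractions = fr)
}

#' Apparent tissue sodium concentration with corrections
#'
#' Assembles the full quantification chain on the (sensitivity-corrected)
#' protocol-3 volume: per-voxel inversion of the calibration line
#' `aTSC_raw = (S - intercept) / slope`, correction for the different
#' relaxation weighting of phantom and tissue
#' (`* f_phantom / f_tissue(region)`), and partial-volume correction
#' (`* 1 / mean_fraction(region)`). Region statistics use the coarse ROI
#' defined by the region's partial-volume fractions, so the signal mean
#' and the fraction mean always refer to the same voxels.
#'
#' Negative per-voxel concentrations can occur in noise and are kept
#' (they average out) but counted in the QC output.
#'
#' @param volume protocol-3 [na_volume()] on the sodium grid.
#' @param calibration a [fit_calibration()] result.
#' @param fine_mask fine [na_labelmap()] with INS/MID/MTJ codes.
#' @param tissue_relax named list of [relaxation_params()] per region
#'   (must cover every requested region).
#' @param phantom_relax [relaxation_params()] of the reference vials.
#' @param tr_ms,te_ms protocol-3 timing.
#' @param regions regions to report; `"Total"` is the union of INS, MID
#'   and MTJ.
#' @param inclusion_threshold partial-volume ROI threshold.
#' @return A `quant_result` list: per-region [roi_stats()] in mM,
#'   `factors` (tissue/phantom weighting factors), `pv_fraction`,
#'   `qc` (negative/absent voxel counts), and `table` (a data.frame,
#'   one row per region).
#' @export
compute_atsc <- function(volume, calibration, fine_mask,
                         tissue_relax = list(INS = tendon_relaxation("INS"),
                                             MID = tendon_relaxation("MID"),
                                             MTJ = tendon_relaxation("MTJ"),
                                             Total = tendon_relaxation("Total")),
                         phantom_relax = phantom_relaxation(),
                         tr_ms = 15, te_ms = 0.1,
                         regions = c("INS", "MID", "MTJ", "Total"),
                         inclusion_threshold = 0.5) {
  if (calibration$slope <= 0)
    stop("calibration slope must be positive for quantification")
  region_codes <- list(INS = "INS", MID = "MID", MTJ = "MTJ",
                       Total = c("INS", "MID", "MTJ"))
  missing_rp <- setdiff(regions, names(tissue_relax))
  if (length(missing_rp))
    stop("missing tissue relaxation parameters for region(s): ",
         paste(missing_rp, collapse = ", "))
  f_phantom <- relaxation_weighting_factor(phantom_relax, tr_ms, te_ms)
  atsc_raw <- (volume$data - calibration$intercept) / calibration$slope
  out <- list()
  rows <- list()
  for (rg in regions) {
    pv <- partial_volume_fraction(fine_mask, region_codes[[rg]],
                                  volume$voxel_size_mm[1],
                                  inclusion_threshold)
    f_tissue <- relaxation_weighting_factor(tissue_relax[[rg]], tr_ms, te_ms)
    vox <- atsc_raw[pv$roi] * (f_phantom / f_tissue) / pv$mean_fraction
    st <- roi_stats(vox)
    out[[rg]] <- list(
      atsc = st, pv_fraction = pv$mean_fraction,
      f_tissue = f_tissue,
      qc = list(n_negative = sum(vox < 0, na.rm = TRUE),
                n_absent = sum(is.na(vox))))
    rows[[rg]] <- data.frame(
      roi = rg, atsc_mM = st$mean, atsc_sd_mM = st$sd,
      atsc_rel_sd_pct = st$rel_sd_pct, n_voxels = st$n_voxels,
      pv_fraction = pv$mean_fraction, f_tissue = f_tissue,
      f_phantom = f_phantom, n_negative = sum(vox < 0, na.rm = TRUE))
  }
  structure(list(regions = out, f_phantom = f_phantom,
                 calibration = calibration,
                 table = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "quant_result")
}
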