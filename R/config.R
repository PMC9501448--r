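#' Acquisition protocol configuration
#'
#' Bundles the acquisition parameters of the three measurement protocols:
#' protocol 1 varies TR at fixed short TE for saturation-recovery T1,
#' protocol 2 samples twelve TEs (three interleaved multi-echo runs of
#' four) at fixed TR for biexponential T2*, protocol 3 is the single
#' quantification scan used for SNR and aTSC, plus the four-echo 1H
#' acquisition for voxel-wise 1H T2* mapping. Defaults reproduce the
#' surface-coil protocol of the tendon study this package models.
#'
#' @param tr_list_ms protocol-1 repetition times (ms), strictly increasing.
#' @param te_list_ms protocol-2 echo times (ms), strictly increasing.
#' @param t2_tr_ms protocol-2 repetition time (ms).
#' @param quant_tr_ms,quant_te_ms protocol-3 TR / TE (ms).
#' @param t1_te_ms protocol-1 echo time (ms).
#' @param h1_te_list_ms 1H echo times (ms).
#' @param h1_tr_ms 1H repetition time (ms).
#' @param vial_concentrations_mM reference vial concentrations, strictly
#'   increasing and positive.
#' @param sensitivity_tr_ms,sensitivity_te_ms,sensitivity_averages
#'   homogeneous-phantom sensitivity scan parameters.
#' @param segment_length_mm tendon segment length for the INS/MID/MTJ
#'   partition (mm).
#' @return A `study_config` list.
#' @export
study_config <- function(tr_list_ms = c(8, 9, 10, 15, 25),
                         te_list_ms = sort(c(0.1, 6.2, 12.3, 18.4,
                                             1.5, 7.6, 13.7, 19.8,
                                             3.0, 9.1, 15.2, 21.3)),
                         t2_tr_ms = 30,
                         quant_tr_ms = 15, quant_te_ms = 0.1,
                         t1_te_ms = 0.1,
                         h1_te_list_ms = c(0.1, 3, 6, 9), h1_tr_ms = 12,
                         vial_concentrations_mM = c(50, 75, 100, 125),
                         sensitivity_tr_ms = 15, sensitivity_te_ms = 0.3,
                         sensitivity_averages = 20,
                         segment_length_mm = 30) {
  chk_incr <- function(x, nm) {
    if (length(x) < 2L || any(diff(x) <= 0))
      stop(nm, " must be strictly increasing with >= 2 entries")
  }
  chk_incr(tr_list_ms, "tr_list_ms")
  chk_incr(te_list_ms, "te_list_ms")
  chk_incr(vial_concentrations_mM, "vial_concentrations_mM")
  if (any(vial_concentrations_mM <= 0))
    stop("vial concentrations must be positive")
  chk_incr(h1_te_list_ms, "h1_te_list_ms")
  stopifnot(quant_tr_ms > 0, quant_te_ms >= 0, segment_length_mm > 0)
  structure(list(tr_list_ms = tr_list_ms, te_list_ms = te_list_ms,
                 t2_tr_ms = t2_tr_ms, quant_tr_ms = quant_tr_ms,
                 quant_te_ms = quant_te_ms, t1_te_ms = t1_te_ms,
                 h1_te_list_ms = h1_te_list_ms, h1_tr_ms = h1_tr_ms,
                 vial_concentrations_mM = vial_concentrations_mM,
                 sensitivity_tr_ms = sensitivity_tr_ms,
                 sensitivity_te_ms = sensitivity_te_ms,
                 sensitivity_averages = sensitivity_averages,
                 segment_length_mm = segment_length_mm),
            class = "study_config")
}

#' @rdname study_config
#' @param path YAML file holding any subset of the `study_config` fields.
#' @export
load_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(study_config, vals)
}

#' @rdname study_config
#' @param config a `study_config`.
#' @export
save_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
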