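#' Compartment of the digital phantom
#'
#' Axis-aligned geometric compartment on the fine grid: a cylinder or
#' annular tube along the slice axis, a box, or the full field of view.
#' Each compartment carries a sodium concentration with its relaxation
#' quadruple and a proton signal model (proton density and mono-exponential
#' 1H T2*) for the anatomical 1H acquisitions.
#'
#' @param role region name, one of `names(AT_LABELS)`.
#' @param shape `"cylinder"`, `"tube"`, `"box"` or `"full"`.
#' @param center_mm in-plane (x, y) centre for cylinder/tube shapes.
#' @param radius_mm outer radius; `inner_radius_mm` > 0 makes a tube.
#' @param z_range_mm half-open extent `[z0, z1)` along the slice axis.
#' @param box_mm for `"box"`: list of three half-open ranges.
#' @param concentration_mM sodium concentration (>= 0).
#' @param relaxation a [relaxation_params()] (required if concentration > 0).
#' @param h1_pd,h1_t2star_ms proton density (a.u.) and 1H T2* (ms).
#' @return A `compartment_spec` list.
#' @export
compartment_spec <- function(role, shape = c("cylinder", "tube", "box", "full"),
                             center_mm = NULL, radius_mm = NULL,
                             inner_radius_mm = 0, z_range_mm = NULL,
                             box_mm = NULL, concentration_mM = 0,
                             relaxation = NULL, h1_pd = 0,
                             h1_t2star_ms = NA_real_) {
  shape <- match.arg(shape)
  if (!role %in% names(AT_LABELS)) stop("unknown role: ", role)
  stopifnot(is.finite(concentration_mM), concentration_mM >= 0)
  if (concentration_mM > 0 && !inherits(relaxation, "relaxation_params"))
    stop("a compartment with sodium signal needs relaxation parameters")
  if (shape %in% c("cylinder", "tube")) {
    stopifnot(length(center_mm) == 2, radius_mm > 0,
              inner_radius_mm >= 0, inner_radius_mm < radius_mm,
              length(z_range_mm) == 2, z_range_mm[2] > z_range_mm[1])
  }
  if (shape == "box") stopifnot(is.list(box_mm), length(box_mm) == 3)
  structure(list(role = role, code = AT_LABELS[[role]], shape = shape,
                 center_mm = center_mm, radius_mm = radius_mm,
                 inner_radius_mm = inner_radius_mm, z_range_mm = z_range_mm,
                 box_mm = box_mm, concentration_mM = concentration_mM,
                 relaxation = relaxation, h1_pd = h1_pd,
                 h1_t2star_ms = h1_t2star_ms),
            class = "compartment_spec")
}

#' Default phantom compartments
#'
#' A tendon-like tube of three stacked 3-cm segments (INS, MID, MTJ from
#' the distal end), four reference vials behind the tendon, a
#' signal-free noise box inside the field of view, and optionally a skin
#' shell around the tendon. Segment concentrations default to the healthy
#' control region means; vials share the pooled agarose relaxation so a
#' single relaxation-weighting factor describes them.
#'
#' @param tendon_concentration_mM either a named vector
#'   `c(INS=, MID=, MTJ=)` or a single value used for an unsegmented
#'   tendon (role TENDON) with the pooled `Total` relaxation.
#' @param tendon_radius_mm tube radius.
#' @param tendon_z_mm distal start of the tendon along the slice axis.
#' @param tendon_length_mm total tendon length.
#' @param vial_concentrations_mM reference vial concentrations.
#' @param skin add a 30-60 mM skin shell hugging the tendon (off by
#'   default so the exact partial-volume inversion holds).
#' @param h1_t2star_ms per-region 1H T2* used by the proton signal model.
#' @return list of [compartment_spec()].
#' @export
default_compartments <- function(tendon_concentration_mM =
                                   c(INS = 112.9, MID = 77.3, MTJ = 55.3),
                                 tendon_radius_mm = 4,
                                 tendon_z_mm = 20, tendon_length_mm = 90,
                                 vial_concentrations_mM = c(50, 75, 100, 125),
                                 skin = FALSE,
                                 h1_t2star_ms = c(INS = 1.9, MID = 2.0,
                                                  MTJ = 2.3)) {
  comps <- list()
  # deliberately off the 2-mm sodium lattice: the tube rim then spans
  # fractional voxels, as the tendon does in vivo
  centre <- c(91, 61)
  if (length(tendon_concentration_mM) == 1L &&
      is.null(names(tendon_concentration_mM))) {
    comps$TENDON <- compartment_spec(
      "TENDON", "cylinder", center_mm = centre, radius_mm = tendon_radius_mm,
      z_range_mm = c(tendon_z_mm, tendon_z_mm + tendon_length_mm),
      concentration_mM = tendon_concentration_mM,
      relaxation = tendon_relaxation("Total"),
      h1_pd = 100, h1_t2star_ms = 2.1)
  } else {
    seg_len <- tendon_length_mm / 3
    regions <- c("INS", "MID", "MTJ")
    for (i in seq_along(regions)) {
      r <- regions[i]
      comps[[r]] <- compartment_spec(
        r, "cylinder", center_mm = centre, radius_mm = tendon_radius_mm,
        z_range_mm = tendon_z_mm + c(i - 1, i) * seg_len,
        concentration_mM = tendon_concentration_mM[[r]],
        relaxation = tendon_relaxation(r),
        h1_pd = 100, h1_t2star_ms = h1_t2star_ms[[r]])
    }
  }
  if (skin) {
    comps$SKIN <- compartment_spec(
      "SKIN", "tube", center_mm = centre, radius_mm = tendon_radius_mm + 2,
      inner_radius_mm = tendon_radius_mm,
      z_range_mm = c(tendon_z_mm, tendon_z_mm + tendon_length_mm),
      concentration_mM = 45, relaxation = relaxation_params(25, 3, 15, 0.4),
      h1_pd = 120, h1_t2star_ms = 8)
  }
  vial_x <- c(40, 70, 110, 140)
  for (i in seq_along(vial_concentrations_mM)) {
    role <- paste0("VIAL_", c(50, 75, 100, 125)[i])
    comps[[role]] <- compartment_spec(
      role, "cylinder", center_mm = c(vial_x[i], 140), radius_mm = 5,
      z_range_mm = c(60, 95),
      concentration_mM = vial_concentrations_mM[i],
      relaxation = phantom_relaxation(), h1_pd = 100, h1_t2star_ms = 30)
  }
  comps$NOISE <- compartment_spec(
    "NOISE", "box", box_mm = list(c(10, 40), c(10, 40), c(130, 160)),
    concentration_mM = 0, h1_pd = 0)
  comps
}

#' Synthetic study definition
#'
#' Everything needed to render a complete surface-coil tendon study on a
#' 1-mm proton grid and 2-mm sodium grid: geometry, signal scale, coil
#' sensitivity model, noise model and level, downsampling mode and
#' optional inter-acquisition motion.
#'
#' The noise level can be given directly (`noise_sigma`, coarse-grid
#' a.u.) or via `target_snr`: the Gaussian sigma is then set so that the
#' noise-free protocol-3 tendon ROI mean divided by sigma equals
#' `target_snr` exactly.
#'
#' @param fov_mm field of view (isotropic, mm).
#' @param fine_voxel_mm,coarse_voxel_mm 1H / 23Na voxel size; the coarse
#'   size must be an integer multiple of the fine size.
#' @param compartments list of [compartment_spec()].
#' @param sensitivity_model `"EXP_FALLOFF"` (multiplicative
#'   `exp(-depth / sensitivity_depth_mm)` from the coil face at the
#'   distal end of the slice axis) or `"UNIFORM"`.
#' @param sensitivity_depth_mm falloff depth constant (mm).
#' @param noise_model `"GAUSSIAN"` (additive, matching the additive noise
#'   term of the fitted signal equations) or `"RICIAN"` (magnitude).
#' @param noise_sigma noise standard deviation on the 23Na grid (a.u.);
#'   overrides `target_snr` when non-NULL.
#' @param target_snr requested true whole-tendon SNR of the protocol-3
#'   scan; `0` or `NULL` for noise-free studies.
#' @param h1_noise_sigma Gaussian noise sigma on the 1H grid (a.u.).
#' @param psf_mode `"BLOCK_AVERAGE"` (mean over the fine voxels in each
#'   coarse voxel) or `"GAUSSIAN_PSF"` (Gaussian blur of `psf_fwhm_mm`
#'   then block averaging).
#' @param psf_fwhm_mm PSF width for `"GAUSSIAN_PSF"`.
#' @param shift_voxels optional named list of integer fine-grid shift
#'   3-vectors keyed by acquisition id (e.g. `"p2_05"`), emulating
#'   between-acquisition motion.
#' @param scale_au_per_mM signal amplitude per mM of fully relaxed sodium.
#' @param seed base RNG seed for the study.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(fov_mm = c(180, 180, 180),
                         fine_voxel_mm = 1, coarse_voxel_mm = 2,
                         compartments = default_compartments(),
                         sensitivity_model = c("EXP_FALLOFF", "UNIFORM"),
                         sensitivity_depth_mm = 100,
                         noise_model = c("GAUSSIAN", "RICIAN"),
                         noise_sigma = NULL, target_snr = 11.7,
                         h1_noise_sigma = 2,
                         psf_mode = c("BLOCK_AVERAGE", "GAUSSIAN_PSF"),
                         psf_fwhm_mm = 3,
                         shift_voxels = NULL,
                         scale_au_per_mM = 1, seed = 1L) {
  sensitivity_model <- match.arg(sensitivity_model)
  noise_model <- match.arg(noise_model)
  psf_mode <- match.arg(psf_mode)
  if (length(fov_mm) == 1L) fov_mm <- rep(fov_mm, 3L)
  f <- coarse_voxel_mm / fine_voxel_mm
  if (abs(f - round(f)) > 1e-9)
    stop("coarse_voxel_mm must be an integer multiple of fine_voxel_mm")
  if (any(abs(fov_mm / fine_voxel_mm -
              round(fov_mm / fine_voxel_mm)) > 1e-9) ||
      any(abs(fov_mm / coarse_voxel_mm -
              round(fov_mm / coarse_voxel_mm)) > 1e-9))
    stop("field of view must be divisible by both voxel sizes")
  if (!is.null(noise_sigma) && noise_sigma < 0)
    stop("noise_sigma must be >= 0")
  structure(list(fov_mm = fov_mm, fine_voxel_mm = fine_voxel_mm,
                 coarse_voxel_mm = coarse_voxel_mm,
                 compartments = compartments,
                 sensitivity_model = sensitivity_model,
                 sensitivity_depth_mm = sensitivity_depth_mm,
                 noise_model = noise_model, noise_sigma = noise_sigma,
                 target_snr = target_snr, h1_noise_sigma = h1_noise_sigma,
                 psf_mode = psf_mode, psf_fwhm_mm = psf_fwhm_mm,
                 shift_voxels = shift_voxels,
                 scale_au_per_mM = scale_au_per_mM,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Fine-grid membership mask of one compartment (voxel-centre rule).
compartment_mask <- function(comp, dims, h) {
  cx <- (seq_len(dims[1]) - 0.5) * h
  cy <- (seq_len(dims[2]) - 0.5) * h
  cz <- (seq_len(dims[3]) - 0.5) * h
  if (comp$shape == "full")
    return(array(TRUE, dim = dims))
  if (comp$shape == "box") {
    inx <- cx >= comp$box_mm[[1]][1] & cx < comp$box_mm[[1]][2]
    iny <- cy >= comp$box_mm[[2]][1] & cy < comp$box_mm[[2]][2]
    inz <- cz >= comp$box_mm[[3]][1] & cz < comp$box_mm[[3]][2]
    return(outer(outer(inx, iny, "&"), inz, "&"))
  }
  r2 <- outer((cx - comp$center_mm[1])^2, (cy - comp$center_mm[2])^2, "+")
  plane <- r2 <= comp$radius_mm^2
  if (comp$inner_radius_mm > 0)
    plane <- plane & r2 > comp$inner_radius_mm^2
  inz <- cz >= comp$z_range_mm[1] & cz < comp$z_range_mm[2]
  outer(plane, inz, "&")
}

#' Rasterise a phantom onto its fine grid
#'
#' Computes the per-compartment fine membership masks, the fine label
#' map (later compartments overwrite earlier ones where they overlap)
#' and the fine coil-sensitivity field. Rendering many acquisitions from
#' one geometry reuses this object, which keeps repeated rendering cheap.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_geometry` list.
#' @export
phantom_geometry <- function(spec) {
  h <- spec$fine_voxel_mm
  dims <- as.integer(round(spec$fov_mm / h))
  masks <- lapply(spec$compartments, compartment_mask, dims = dims, h = h)
  labels <- array(0L, dim = dims)
  for (i in seq_along(masks)) {
    code <- spec$compartments[[i]]$code
    if (code != 0L) labels[masks[[i]]] <- code
  }
  cz <- (seq_len(dims[3]) - 0.5) * h
  sens_profile <- if (spec$sensitivity_model == "EXP_FALLOFF")
    exp(-cz / spec$sensitivity_depth_mm) else rep(1, dims[3])
  structure(list(dims = dims, fine_voxel_mm = h,
                 factor = as.integer(round(spec$coarse_voxel_mm / h)),
                 masks = masks, labels = labels,
                 sens_profile = sens_profile),
            class = "phantom_geometry")
}

#' Ideal relaxation-weighted 23Na signal
#'
#' Closed-form noise-free signal of the combined saturation-recovery /
#' biexponential model:
#' `scale * C * (1 - exp(-TR/T1)) * (ps*exp(-TE/T2s*) + (1-ps)*exp(-TE/T2l*))`.
#' Vectorised over `tr_ms` / `te_ms`.
#'
#' @param concentration_mM sodium concentration (>= 0).
#' @param relaxation a [relaxation_params()].
#' @param tr_ms,te_ms repetition / echo time, ms (`tr_ms > 0`, `te_ms >= 0`).
#' @param scale a.u. per mM of fully relaxed signal.
#' @return Signal in a.u.
#' @export
ideal_signal <- function(concentration_mM, relaxation, tr_ms, te_ms,
                         scale = 1) {
  stopifnot(inherits(relaxation, "relaxation_params"),
            concentration_mM >= 0, all(tr_ms > 0), all(te_ms >= 0))
  scale * concentration_mM * (1 - exp(-tr_ms / relaxation$t1_ms)) *
    (relaxation$ps * exp(-te_ms / relaxation$t2s_ms) +
     (1 - relaxation$ps) * exp(-te_ms / relaxation$t2l_ms))
}

# Noise-free fine-grid image for one acquisition (before sensitivity).
ideal_fine_image <- function(spec, geometry, nucleus, tr_ms, te_ms) {
  img <- array(0, dim = geometry$dims)
  for (i in seq_along(spec$compartments)) {
    comp <- spec$compartments[[i]]
    s <- if (nucleus == "NA23") {
      if (comp$concentration_mM > 0)
        ideal_signal(comp$concentration_mM, comp$relaxation, tr_ms, te_ms,
                     spec$scale_au_per_mM) else 0
    } else {
      if (comp$h1_pd > 0)
        comp$h1_pd * exp(-te_ms / comp$h1_t2star_ms) else 0
    }
    if (s != 0) img[geometry$masks[[i]]] <- s
  }
  img
}

#' Render one synthetic acquisition
#'
#' Builds the compartment-wise ideal image on the fine grid, applies the
#' coil sensitivity (23Na only; the 1H resonator is modelled as uniform),
#' applies the optional integer-voxel motion shift, downsamples to the
#' target grid and adds noise. Identical `(spec, seed)` give identical
#' volumes.
#'
#' @param spec a [phantom_spec()].
#' @param nucleus `"NA23"` (rendered on the coarse grid) or `"H1"`
#'   (stays on the fine grid).
#' @param tr_ms,te_ms acquisition timing.
#' @param seed RNG seed for the noise realisation.
#' @param shift integer fine-grid shift 3-vector.
#' @param averages number of signal averages (noise sigma scales with
#'   `1/sqrt(averages)`).
#' @param geometry optional precomputed [phantom_geometry()].
#' @param noise_sigma override for the coarse-grid noise sigma; defaults
#'   to the spec's resolved value.
#' @return An [na_volume()].
#' @export
render_acquisition <- function(spec, nucleus = c("NA23", "H1"),
                               tr_ms, te_ms, seed = spec$seed,
                               shift = c(0L, 0L, 0L), averages = 1,
                               geometry = NULL, noise_sigma = NULL) {
  nucleus <- match.arg(nucleus)
  if (is.null(geometry)) geometry <- phantom_geometry(spec)
  img <- ideal_fine_image(spec, geometry, nucleus, tr_ms, te_ms)
  if (nucleus == "NA23")
    img <- img * slice_profile_array(geometry$sens_profile, geometry$dims)
  if (any(shift != 0L)) img <- roll_int(img, shift, fill = 0)
  if (nucleus == "NA23") {
    if (spec$psf_mode == "GAUSSIAN_PSF")
      img <- gaussian_smooth3d(img, spec$psf_fwhm_mm, geometry$fine_voxel_mm)
    img <- block_reduce(img, geometry$factor, "mean")
    sigma <- if (!is.null(noise_sigma)) noise_sigma
             else resolve_noise_sigma(spec, geometry = geometry)
    vox <- spec$coarse_voxel_mm
  } else {
    sigma <- spec$h1_noise_sigma
    vox <- spec$fine_voxel_mm
  }
  sigma <- sigma / sqrt(averages)
  if (sigma > 0) {
    img <- with_seed(seed, {
      n <- length(img)
      if (spec$noise_model == "RICIAN" && nucleus == "NA23") {
        sqrt((img + stats::rnorm(n, 0, sigma))^2 +
             stats::rnorm(n, 0, sigma)^2)
      } else {
        img + stats::rnorm(n, 0, sigma)
      }
    })
    dim(img) <- if (nucleus == "NA23") geometry$dims / geometry$factor
                else geometry$dims
  }
  na_volume(img, voxel_size_mm = rep(vox, 3), nucleus = nucleus,
            tr_ms = tr_ms, te_ms = te_ms)
}

# Resolve the coarse-grid noise sigma: explicit sigma wins, otherwise the
# target-SNR rule sigma = (noise-free protocol-3 tendon ROI mean) / SNR.
resolve_noise_sigma <- function(spec, config = study_config(),
                                geometry = NULL) {
  if (!is.null(spec$noise_sigma)) return(spec$noise_sigma)
  if (is.null(spec$target_snr) || spec$target_snr <= 0) return(0)
  if (is.null(geometry)) geometry <- phantom_geometry(spec)
  true_tendon_mean(spec, config, geometry) / spec$target_snr
}

# Noise-free protocol-3 coarse tendon ROI mean (ROI = coarse voxels with
# tendon fraction >= 0.5), the reference quantity for true SNR.
true_tendon_mean <- function(spec, config, geometry) {
  img <- ideal_fine_image(spec, geometry, "NA23",
                          config$quant_tr_ms, config$quant_te_ms)
  img <- img * slice_profile_array(geometry$sens_profile, geometry$dims)
  coarse <- block_reduce(img, geometry$factor, "mean")
  frac <- tendon_fraction_array(geometry)
  roi <- frac >= 0.5
  if (!any(roi)) stop("tendon ROI empty at the coarse resolution")
  mean(coarse[roi])
}

# Per-coarse-voxel tendon fraction (union of tendon segment codes).
tendon_fraction_array <- function(geometry) {
  codes <- AT_LABELS[c("INS", "MID", "MTJ", "TENDON")]
  ind <- array(geometry$labels %in% codes, dim = geometry$dims)
  block_reduce(ind + 0, geometry$factor, "mean")
}

#' Generate a complete synthetic study
#'
#' Renders every acquisition of the three-protocol study design from one
#' phantom specification: the five protocol-1 TR volumes, the twelve
#' protocol-2 TE volumes, the protocol-3 quantification volume, the four
#' 1H echo volumes, and the homogeneous 154 mM sensitivity scan, plus
#' fine and coarse label maps and the generator ground truth.
#'
#' Per-acquisition noise seeds are `seed + k`, with `k` the position in
#' the manifest order (protocol 1, protocol 2, protocol 3, 1H echoes,
#' sensitivity scan).
#'
#' @param spec a [phantom_spec()].
#' @param config a [study_config()].
#' @param seed base seed; defaults to `spec$seed`.
#' @param include which acquisition groups to render; per-acquisition
#'   seeds are derived from the full manifest order, so a volume is
#'   identical whether or not the other groups are rendered.
#' @return A `sodium_study` list with elements `volumes` (`p1`, `p2`,
#'   `p3`, `h1`, `sensitivity`; excluded groups are NULL), `fine_mask`,
#'   `coarse_mask`, `ground_truth`, `manifest`, `config`, `spec`.
#' @export
generate_study <- function(spec, config = study_config(), seed = spec$seed,
                           include = c("p1", "p2", "p3", "h1", "sens")) {
  geometry <- phantom_geometry(spec)
  sigma <- resolve_noise_sigma(spec, config, geometry)

  fine_mask <- na_labelmap(geometry$labels, spec$fine_voxel_mm)
  if (AT_LABELS[["TENDON"]] %in% fine_mask$labels)
    fine_mask <- segment_tendon_mask(fine_mask,
                                     segment_length_mm = config$segment_length_mm)
  geometry$labels <- fine_mask$labels
  coarse_mask <- transfer_mask(fine_mask, spec$coarse_voxel_mm,
                               inclusion_threshold = 0.5)

  ids <- c(paste0("p1_", seq_along(config$tr_list_ms)),
           sprintf("p2_%02d", seq_along(config$te_list_ms)),
           "p3", paste0("h1_", seq_along(config$h1_te_list_ms)), "sens")
  seeds <- stats::setNames(seed + seq_along(ids), ids)
  shift_of <- function(id) {
    s <- spec$shift_voxels[[id]]
    if (is.null(s)) c(0L, 0L, 0L) else as.integer(s)
  }
  rend <- function(id, nucleus, tr, te, averages = 1)
    render_acquisition(spec, nucleus, tr, te, seed = seeds[[id]],
                       shift = shift_of(id), averages = averages,
                       geometry = geometry,
                       noise_sigma = if (nucleus == "NA23") sigma else NULL)

  p1 <- p2 <- h1 <- p3 <- sensitivity <- NULL
  if ("p1" %in% include)
    p1 <- lapply(seq_along(config$tr_list_ms), function(i)
      rend(paste0("p1_", i), "NA23", config$tr_list_ms[i], config$t1_te_ms))
  if ("p2" %in% include)
    p2 <- lapply(seq_along(config$te_list_ms), function(i)
      rend(sprintf("p2_%02d", i), "NA23", config$t2_tr_ms,
           config$te_list_ms[i]))
  if ("p3" %in% include)
    p3 <- rend("p3", "NA23", config$quant_tr_ms, config$quant_te_ms)
  if ("h1" %in% include)
    h1 <- lapply(seq_along(config$h1_te_list_ms), function(i)
      rend(paste0("h1_", i), "H1", config$h1_tr_ms, config$h1_te_list_ms[i]))

  if ("sens" %in% include) {
    sens_spec <- spec
    sens_spec$compartments <- list(HOMOG = compartment_spec(
      "BACKGROUND", "full", concentration_mM = 154,
      relaxation = phantom_relaxation(), h1_pd = 0))
    sens_geom <- phantom_geometry(sens_spec)
    sensitivity <- render_acquisition(
      sens_spec, "NA23", config$sensitivity_tr_ms, config$sensitivity_te_ms,
      seed = seeds[["sens"]], averages = config$sensitivity_averages,
      geometry = sens_geom, noise_sigma = sigma)
  }

  frac <- tendon_fraction_array(geometry)
  comp_truth <- lapply(spec$compartments, function(cmp)
    list(role = cmp$role, concentration_mM = cmp$concentration_mM,
         relaxation = cmp$relaxation))
  truth <- list(
    compartments = comp_truth, scale_au_per_mM = spec$scale_au_per_mM,
    noise_sigma = sigma,
    true_snr = if (sigma > 0)
      true_tendon_mean(spec, config, geometry) / sigma else Inf,
    tendon_fraction = frac,
    sensitivity_profile = geometry$sens_profile)

  rendered <- c(
    if ("p1" %in% include) paste0("p1_", seq_along(config$tr_list_ms)),
    if ("p2" %in% include) sprintf("p2_%02d", seq_along(config$te_list_ms)),
    if ("p3" %in% include) "p3",
    if ("h1" %in% include) paste0("h1_", seq_along(config$h1_te_list_ms)),
    if ("sens" %in% include) "sens")
  manifest <- list(
    seed = seed, acquisitions = rendered, noise_sigma = sigma,
    n_volumes = length(rendered),
    tr_list_ms = config$tr_list_ms, te_list_ms = config$te_list_ms,
    quant_tr_ms = config$quant_tr_ms, quant_te_ms = config$quant_te_ms,
    h1_te_list_ms = config$h1_te_list_ms)

  structure(list(volumes = list(p1 = p1, p2 = p2, p3 = p3, h1 = h1,
                                sensitivity = sensitivity),
                 fine_mask = fine_mask, coarse_mask = coarse_mask,
                 ground_truth = truth, manifest = manifest,
                 config = config, spec = spec, seed = seed),
            class = "sodium_study")
}

#' Write / read a study bundle on disk
#'
#' NIfTI volumes with JSON sidecars, label maps, a YAML manifest and the
#' ground truth as JSON.
#'
#' @param study a `sodium_study`.
#' @param dir output directory (created if missing).
#' @export
save_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  ids <- study$manifest$acquisitions
  vols <- c(study$volumes$p1, study$volumes$p2,
            if (!is.null(study$volumes$p3)) list(study$volumes$p3),
            study$volumes$h1,
            if (!is.null(study$volumes$sensitivity))
              list(study$volumes$sensitivity))
  stopifnot(length(vols) == length(ids))
  for (i in seq_along(ids))
    save_volume(vols[[i]], file.path(dir, paste0(ids[i], ".nii.gz")))
  save_label_map(study$fine_mask, file.path(dir, "mask_fine.nii.gz"))
  save_label_map(study$coarse_mask, file.path(dir, "mask_coarse.nii.gz"))
  yaml::write_yaml(study$manifest, file.path(dir, "manifest.yaml"))
  truth <- study$ground_truth
  truth$tendon_fraction <- NULL  # array ground truth stays in memory
  truth$compartments <- lapply(truth$compartments, function(x)
    list(role = x$role, concentration_mM = x$concentration_mM,
         relaxation = if (is.null(x$relaxation)) NULL
                      else unclass(x$relaxation)))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  save_study_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname save_study
#' @export
load_study <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  config <- load_study_config(file.path(dir, "config.yaml"))
  ids <- unlist(manifest$acquisitions)
  vols <- lapply(ids, function(id)
    load_volume(file.path(dir, paste0(id, ".nii.gz"))))
  names(vols) <- ids
  pick <- function(prefix) {
    sel <- vols[startsWith(ids, prefix)]
    if (length(sel)) unname(sel) else NULL
  }
  structure(list(
    volumes = list(p1 = pick("p1_"), p2 = pick("p2_"),
                   p3 = vols[["p3"]], h1 = pick("h1_"),
                   sensitivity = vols[["sens"]]),
    fine_mask = load_label_map(file.path(dir, "mask_fine.nii.gz")),
    coarse_mask = load_label_map(file.path(dir, "mask_coarse.nii.gz")),
    ground_truth = jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                       simplifyVector = TRUE),
    manifest = manifest, config = config, seed = manifest$seed),
    class = "sodium_study")
}
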