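test_that("SNR is ROI signal over noise-region SD with guard rails", {
  d <- c(8, 8, 8)
  a <- array(0, dim = d)
  lab <- array(0L, dim = d)
  lab[1:2, 1:2, ] <- 1L
  lab[5:8, 5:8, ] <- 99L
  a[lab == 1L] <- 117
  set.seed(12)
  noise <- rnorm(sum(lab == 99L), 0, 10)
  a[lab == 99L] <- noise
  vol <- na_volume(a, 2)
  mask <- na_labelmap(lab, 2)
  got <- compute_snr(vol, mask, 1, min_noise_voxels = 50)
  expect_equal(got$mean, 117 / sd(noise), tolerance = 1e-12)
  expect_equal(got$n_voxels, sum(lab == 1L))

  expect_error(compute_snr(vol, mask, 1, min_noise_voxels = 1e5),
               "noise region")
  flat <- vol; flat$data[lab == 99L] <- 1
  expect_error(compute_snr(flat, mask, 1, min_noise_voxels = 50),
               "zero standard deviation")
})

test_that("the SNR estimator recovers the generator's true SNR within 2%", {
  spec <- small_spec(sensitivity_model = "UNIFORM", target_snr = 11.7)
  geom <- phantom_geometry(spec)
  sigma <- sodiumAT:::resolve_noise_sigma(spec, study_config(), geom)
  fm <- na_labelmap(geom$labels, spec$fine_voxel_mm)
  cm <- transfer_mask(fm, spec$coarse_voxel_mm)
  est <- vapply(1:20, function(s) {
    v <- render_acquisition(spec, "NA23", 15, 0.1, seed = s,
                            geometry = geom, noise_sigma = sigma)
    compute_snr(v, cm, c("INS", "MID", "MTJ"))$mean
  }, numeric(1))
  expect_lt(abs(mean(est) / 11.7 - 1), 0.02)
})

test_that("calibration fitting is exact, affine-equivariant and OLS-consistent", {
  cal <- fit_calibration(c(100, 150, 200, 250), c(50, 75, 100, 125))
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  cal2 <- fit_calibration(c(100, 150, 200, 250) + 13, c(50, 75, 100, 125))
  expect_equal(cal2$slope, cal$slope, tolerance = 1e-12)
  expect_equal(cal2$intercept, 13, tolerance = 1e-10)

  set.seed(5)
  y <- 2 * c(50, 75, 100, 125) + rnorm(4, 0, 5)
  x <- c(50, 75, 100, 125)
  cal3 <- fit_calibration(y, x)
  # closed-form normal equations
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(cal3$slope, b, tolerance = 1e-12)
  expect_equal(cal3$intercept, a, tolerance = 1e-12)

  expect_error(fit_calibration(1, 50), ">= 2")
  expect_error(fit_calibration(c(1, 2), c(50, 50)), "distinct")
})

test_that("relaxation weighting factor has the right limits and ordering", {
  rx <- tendon_relaxation("Total")
  expect_equal(relaxation_weighting_factor(rx, 1e9 * rx$t1_ms, 0), 1,
               tolerance = 1e-12)
  # monoexponential limit: ps irrelevant when both components coincide
  rx_mono <- relaxation_params(30, 8, 8, 0.999)
  want <- (1 - exp(-15 / 30)) * exp(-0.1 / 8)
  expect_equal(relaxation_weighting_factor(rx_mono, 15, 0.1), want,
               tolerance = 1e-6)

  # tissue factor exceeds the phantom factor at the quantification TR/TE
  # (tendon T1 is much shorter than agarose T1); verified by hand
  f_t <- relaxation_weighting_factor(tendon_relaxation("Total"), 15, 0.1)
  f_p <- relaxation_weighting_factor(phantom_relaxation(), 15, 0.1)
  hand_t <- (1 - exp(-15 / 20.4)) *
    (0.316 * exp(-0.1 / 1.4) + 0.684 * exp(-0.1 / 13.9))
  hand_p <- (1 - exp(-15 / 38.5)) *
    (0.602 * exp(-0.1 / 6.0) + 0.398 * exp(-0.1 / 13.0))
  expect_equal(f_t, hand_t, tolerance = 1e-12)
  expect_equal(f_p, hand_p, tolerance = 1e-12)
  expect_gt(f_t, f_p)
})

test_that("weighting factor is bounded and monotone over random parameters", {
  set.seed(41)
  for (i in 1:1000) {
    t2s <- runif(1, 0.1, 20)
    rx <- relaxation_params(runif(1, 5, 80), t2s,
                            t2s + runif(1, 0, 30), runif(1, 0.05, 0.95))
    tr <- runif(2, 1, 100); te <- runif(2, 0, 25)
    f <- relaxation_weighting_factor(rx, tr, min(te))
    expect_true(all(f > 0 & f <= 1))
    expect_gt(f[which.max(tr)], f[which.min(tr)] - 1e-15)
    g <- relaxation_weighting_factor(rx, tr[1], te)
    expect_gt(g[which.min(te)], g[which.max(te)] - 1e-15)
  }
})

test_that("partial-volume fractions count fine voxels exactly", {
  # half-filled coarse voxel: 4 of 8 fine voxels carry the code
  lab <- array(0L, dim = c(2, 2, 2))
  lab[, , 1] <- 1L
  pv <- partial_volume_fraction(na_labelmap(lab, 1), 1L, 2,
                                inclusion_threshold = 0.5)
  expect_equal(pv$mean_fraction, 0.5)
  expect_equal(dim(pv$fractions), c(1, 1, 1))

  # exact tiling gives fractions of exactly 1
  lab2 <- array(1L, dim = c(4, 4, 4))
  pv2 <- partial_volume_fraction(na_labelmap(lab2, 1), 1L, 2)
  expect_true(all(pv2$fractions == 1))
  expect_equal(pv2$mean_fraction, 1)

  # arbitrary tubes against the brute-force counting oracle
  set.seed(9)
  for (i in 1:3) {
    spec <- noise_free(small_uniform_spec, concentration = 50,
                       center = runif(2, 15, 30),
                       radius = runif(1, 2.5, 5),
                       z_range = c(2, 112))
    geom <- phantom_geometry(spec)
    fm <- na_labelmap(geom$labels, 1)
    pv <- partial_volume_fraction(fm, AT_LABELS[["TENDON"]], 2)
    want <- oracle_fractions(geom$labels, AT_LABELS[["TENDON"]], 2)
    expect_identical(pv$fractions, want)
    expect_lte(pv$mean_fraction, 1)
  }

  expect_error(partial_volume_fraction(na_labelmap(lab2, 1), 1L, 3),
               "not divisible")
  expect_error(partial_volume_fraction(na_labelmap(lab2, 1), 2L, 2),
               "empty")
})

test_that("the quantification chain inverts exactly for arbitrary tubes", {
  set.seed(14)
  for (i in 1:3) {
    conc <- runif(1, 40, 120)
    # 90-mm tube at an arbitrary (odd-mm allowed) offset, so the
    # INS/MID/MTJ partition covers the tube exactly
    spec <- noise_free(small_uniform_spec, concentration = conc,
                       center = runif(2, 18, 30),
                       radius = runif(1, 3, 5),
                       z_range = c(2, 92) + round(runif(1, 0, 10)))
    study <- generate_study(spec, seed = i, include = "p3")
    vm <- vial_roi_means(study$volumes$p3, study$fine_mask)
    cal <- fit_calibration(vm, spec_concs <- c(50, 75, 100, 125))
    q <- compute_atsc(study$volumes$p3, cal, study$fine_mask)
    expect_equal(q$regions$Total$atsc$mean, conc, tolerance = 1e-6 * conc)
    expect_equal(q$regions$Total$qc$n_negative, 0)
  }
})

test_that("zero tendon concentration quantifies to zero", {
  spec <- noise_free(small_uniform_spec, concentration = 0)
  # a zero-concentration compartment carries no relaxation params; give
  # the tube a tiny placeholder so the mask still exists
  spec$compartments$TENDON$concentration_mM <- 0
  study <- generate_study(spec, seed = 1, include = "p3")
  vm <- vial_roi_means(study$volumes$p3, study$fine_mask)
  cal <- fit_calibration(vm, c(50, 75, 100, 125))
  q <- compute_atsc(study$volumes$p3, cal, study$fine_mask)
  expect_lt(abs(q$regions$Total$atsc$mean), 1e-9)
})

test_that("sensitivity-corrected falloff studies recover concentration within 2%", {
  spec <- small_uniform_spec(concentration = 82.2,
                             sensitivity_model = "EXP_FALLOFF",
                             target_snr = NULL, h1_noise_sigma = 0)
  study <- generate_study(spec, seed = 6, include = c("p3", "sens"))
  smap <- estimate_sensitivity_map(study$volumes$sensitivity)
  p3c <- apply_sensitivity_correction(study$volumes$p3, smap)
  vm <- vial_roi_means(p3c, study$fine_mask)
  cal <- fit_calibration(vm, c(50, 75, 100, 125))
  q <- compute_atsc(p3c, cal, study$fine_mask)
  expect_lt(abs(q$regions$Total$atsc$mean / 82.2 - 1), 0.02)
})

test_that("quantification contracts reject invalid inputs", {
  spec <- noise_free(small_uniform_spec)
  study <- generate_study(spec, seed = 2, include = "p3")
  cal <- fit_calibration(c(4, 3, 2, 1), c(50, 75, 100, 125))
  expect_error(compute_atsc(study$volumes$p3, cal, study$fine_mask),
               "slope")
  cal_ok <- fit_calibration(c(1, 2, 3, 4), c(50, 75, 100, 125))
  expect_error(
    compute_atsc(study$volumes$p3, cal_ok, study$fine_mask,
                 tissue_relax = list(INS = tendon_relaxation("INS"))),
    "missing tissue relaxation")
})
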