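test_that("strictly ordered regional values give a decisive Friedman test", {
  set.seed(2)
  vals <- cbind(INS = 110 + rnorm(10, 0, 8), MID = 77 + rnorm(10, 0, 6),
                MTJ = 55 + rnorm(10, 0, 6))
  # enforce strict ordering per subject
  vals <- t(apply(vals, 1, sort, decreasing = TRUE))
  fr <- friedman_test(vals)
  expect_lt(fr$p_value, 0.001)
  expect_equal(fr$statistic, 20, tolerance = 1e-12)  # perfect ranks, n=10
  expect_equal(unname(fr$mean_ranks), c(3, 2, 1))
})

test_that("identical columns give a zero statistic and p of 1", {
  vals <- matrix(rep(c(3, 1, 4, 1, 5), 3), ncol = 3)
  fr <- friedman_test(vals)
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p_value, 1)
})

test_that("asymptotic p matches stats::friedman.test and exact matches enumeration", {
  set.seed(23)
  vals <- matrix(rnorm(9), nrow = 3)
  fr <- friedman_test(vals)
  expect_equal(fr$p_value, stats::friedman.test(vals)$p.value,
               tolerance = 1e-12)
  ex <- friedman_test(vals, method = "exact")
  expect_equal(ex$p_value, oracle_friedman_exact(vals), tolerance = 1e-12)
})

test_that("ten same-sign paired differences print a corrected p of 0.015", {
  set.seed(11)
  ins <- 110 + rnorm(10, 0, 10)
  mid <- ins - runif(10, 5, 40)   # all differences one sign
  mtj <- mid - runif(10, 5, 30)
  pw <- pairwise_wilcoxon_bonferroni(cbind(INS = ins, MID = mid, MTJ = mtj))
  expect_equal(round(pw$p_corrected, 3), rep(0.015, 3))
  expect_true(all(pw$significant))
})

test_that("zero-difference pairs report p = 1", {
  x <- c(1, 2, 3, 4, 5)
  pw <- pairwise_wilcoxon_bonferroni(cbind(A = x, B = x, C = x + 1))
  expect_equal(pw$p_corrected[1], 1)
})

test_that("the normal approximation tracks the exact sign-enumeration null", {
  # sweep every attainable sign pattern at n = 6 (magnitudes = ranks
  # 1..6): the asymptotic two-sided p without continuity correction
  # stays within 0.1 of the exact enumeration everywhere, the
  # worst-case approximation error documented for this cohort size
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  worst <- 0
  for (i in seq_len(nrow(signs))) {
    d <- signs[i, ] * (1:6)
    p_exact <- oracle_signed_rank_exact(d)
    pw <- pairwise_wilcoxon_bonferroni(
      cbind(A = d, B = rep(0, 6), C = seq(0.1, 0.6, 0.1)))
    worst <- max(worst, abs(pw$p_raw[1] - p_exact))
  }
  expect_lt(worst, 0.1)
})

test_that("Bonferroni never decreases a p-value and never exceeds 1", {
  set.seed(5)
  for (i in 1:10) {
    vals <- matrix(rnorm(18), ncol = 3)
    colnames(vals) <- c("INS", "MID", "MTJ")
    pw <- pairwise_wilcoxon_bonferroni(vals)
    expect_true(all(pw$p_corrected >= pw$p_raw - 1e-15))
    expect_true(all(pw$p_corrected <= 1))
  }
})

test_that("the paired test depends only on signs and ranks of differences", {
  set.seed(13)
  base <- rnorm(8)
  d <- rnorm(8)
  a <- cbind(INS = base + d, MID = base, MTJ = rnorm(8))
  # monotone rescaling of |d| preserving order and signs
  d2 <- sign(d) * rank(abs(d))^3
  b <- cbind(INS = base + d2, MID = base, MTJ = a[, "MTJ"])
  pa <- pairwise_wilcoxon_bonferroni(a)
  pb <- pairwise_wilcoxon_bonferroni(b)
  expect_equal(pa$p_raw[1], pb$p_raw[1], tolerance = 1e-12)
})

test_that("pairwise tests are gated on the Friedman result", {
  set.seed(40)
  vals <- matrix(rnorm(30), ncol = 3)  # exchangeable: Friedman ns
  colnames(vals) <- c("INS", "MID", "MTJ")
  rc <- regional_comparison(vals, "noise")
  if (rc$friedman_p >= 0.05) {
    expect_true(is.na(rc$p_INS_MID))
  } else {
    expect_false(is.na(rc$p_INS_MID))
  }
  # strongly ordered data always reports pairwise values
  ordered <- t(apply(matrix(rnorm(30), ncol = 3), 1, sort))
  colnames(ordered) <- c("INS", "MID", "MTJ")
  rc2 <- regional_comparison(ordered, "ordered")
  expect_false(is.na(rc2$p_INS_MID))
})

test_that("report tables summarise cohorts and validate their inputs", {
  mk_quant <- function(n_subj) {
    do.call(rbind, lapply(seq_len(n_subj), function(s)
      data.frame(subject = s, roi = rep(c("INS", "MID", "MTJ", "Total"), 3),
                 parameter = rep(c("aTSC", "SNR", "H1_T2star"), each = 4),
                 mean = c(113, 77, 55, 82, 14, 11, 9, 12, 1.9, 2, 2.3, 2.1) +
                   s / 2,
                 rel_sd_pct = 25 + s)))
  }
  rep1 <- build_report(mk_quant(1))
  expect_true(all(is.na(rep1$parameters$between_subject_sd)))
  expect_null(rep1$stats)

  rep10 <- build_report(mk_quant(10))
  expect_true(all(rep10$parameters$between_subject_sd > 0))
  expect_equal(nrow(rep10$stats), 6)  # mean and SD rows for 3 parameters
  expect_true(all(c("friedman_p", "p_INS_MID") %in% names(rep10$stats)))

  bad <- mk_quant(2)
  bad <- bad[bad$roi != "MTJ", ]
  expect_error(build_report(bad), "missing region")
})

test_that("ordered synthetic cohorts flag all three aTSC pairs significant", {
  # protocol-level cohorts through the real quantification chain: each
  # subject's protocol-3 scan is rendered (with measurement noise at the
  # study's true SNR) on a compact phantom whose geometry is shared
  # across subjects, then calibrated, corrected and tested regionally
  spec <- phantom_spec(
    fov_mm = c(48, 48, 96),
    compartments = c(
      tendon_segments(center = c(24, 14), z0 = 3),
      local({
        v <- list()
        xs <- c(8, 19, 30, 41)
        for (i in 1:4) {
          role <- paste0("VIAL_", c(50, 75, 100, 125)[i])
          v[[role]] <- compartment_spec(
            role, "cylinder", center_mm = c(xs[i], 36), radius_mm = 5,
            z_range_mm = c(20, 56), concentration_mM = c(50, 75, 100, 125)[i],
            relaxation = phantom_relaxation())
        }
        v
      })),
    sensitivity_model = "UNIFORM", target_snr = 11.7)
  geom <- phantom_geometry(spec)
  fine_mask <- na_labelmap(geom$labels, 1)
  sigma <- sodiumAT:::resolve_noise_sigma(spec, study_config(), geom)
  conc0 <- c(INS = 112.9, MID = 77.3, MTJ = 55.3)

  measure_subject <- function(seed) {
    sp <- spec
    with_seed_concs <- local({
      set.seed(seed)
      subj <- exp(rnorm(1, 0, 0.15))
      conc0 * subj * exp(rnorm(3, 0, 0.05))
    })
    for (r in names(conc0))
      sp$compartments[[r]]$concentration_mM <- with_seed_concs[[r]]
    v <- render_acquisition(sp, "NA23", 15, 0.1, seed = seed + 7,
                            geometry = phantom_geometry(sp),
                            noise_sigma = sigma)
    cal <- fit_calibration(vial_roi_means(v, fine_mask),
                           c(50, 75, 100, 125))
    q <- compute_atsc(v, cal, fine_mask, regions = c("INS", "MID", "MTJ"))
    vapply(q$regions, function(r) r$atsc$mean, numeric(1))
  }

  n_cohorts <- 50
  hits <- 0L
  for (co in seq_len(n_cohorts)) {
    vals <- t(vapply(1:10, function(s) measure_subject(co * 1000 + s),
                     numeric(3)))
    colnames(vals) <- c("INS", "MID", "MTJ")
    rc <- regional_comparison(vals, "aTSC")
    ps <- unlist(rc[, c("p_INS_MID", "p_INS_MTJ", "p_MID_MTJ")])
    if (!any(is.na(ps)) && all(ps <= 0.05)) hits <- hits + 1L
  }
  expect_gte(hits / n_cohorts, 0.95)
})
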