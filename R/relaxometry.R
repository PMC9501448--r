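#' ROI-mean signal series across an acquisition set
#'
#' Averages each volume over the (non-absent) voxels of a region and
#' pairs the means with the varying acquisition time (TR for the
#' saturation-recovery series, TE for the decay series; auto-detected
#' from the metadata). Fitting region means instead of single voxels is
#' what makes the in-vivo relaxometry stable.
#'
#' @param volumes list of [na_volume()]s sharing the mask's grid.
#' @param mask an [na_labelmap()].
#' @param code region code(s) or name(s).
#' @return list with `times_ms` (ascending), `signals`, `time_type`
#'   (`"tr"` or `"te"`), `n_voxels`.
#' @export
roi_mean_series <- function(volumes, mask, code) {
  stopifnot(length(volumes) >= 1, inherits(mask, "na_labelmap"))
  for (v in volumes) stop_if_grid_mismatch(v, mask, "volume and label map")
  ind <- mask_indicator(mask, code)
  trs <- vapply(volumes, function(v) v$tr_ms, numeric(1))
  tes <- vapply(volumes, function(v) v$te_ms, numeric(1))
  tr_varies <- length(unique(trs[!is.na(trs)])) > 1L
  te_varies <- length(unique(tes[!is.na(tes)])) > 1L
  if (tr_varies && te_varies)
    stop("both TR and TE vary across the series; split the acquisitions")
  if (!tr_varies && !te_varies)
    stop("neither TR nor TE varies across the series")
  times <- if (tr_varies) trs else tes
  means <- vapply(volumes, function(v) {
    vals <- v$data[ind]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) stop("ROI is empty after exclusions")
    mean(vals)
  }, numeric(1))
  o <- order(times)
  list(times_ms = times[o], signals = means[o],
       time_type = if (tr_varies) "tr" else "te",
       n_voxels = sum(ind))
}

# Shared scaffolding: run minpack.lm from several starts within bounds,
# keep the lowest-SSE converged fit.
multistart_lm <- function(residual_fn, starts, lower, upper) {
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = residual_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse,
                   converged = fit$info %in% 1:4)
  }
  best
}

fit_result <- function(params, s0, offset, fitted, signals, converged,
                       degenerate = FALSE) {
  res <- signals - fitted
  sst <- sum((signals - mean(signals))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  list(params = params, s0 = s0, offset = offset, fitted = fitted,
       residuals = res, r_squared = r2, converged = converged,
       degenerate = degenerate)
}

#' Saturation-recovery T1 fit
#'
#' Bounded least-squares fit of `S(TR) = S0 * (1 - exp(-TR/T1)) + offset`
#' to an ROI-mean series, with `S0 >= 0` and `T1` in `[0.1, 500]` ms and
#' the additive noise floor as a free offset. Deterministic multi-start:
#' a two-point log estimate of T1 plus fixed alternatives.
#'
#' @param times_ms repetition times, >= 3 distinct values.
#' @param signals ROI-mean signals (a.u.).
#' @return A fit-result list: `params$t1_ms`, `s0`, `offset`,
#'   `r_squared`, `residuals`, `converged`, `degenerate`.
#' @export
fit_t1_saturation_recovery <- function(times_ms, signals) {
  stopifnot(length(times_ms) == length(signals))
  if (length(unique(times_ms)) < 3)
    stop("need >= 3 distinct repetition times")
  if (stats::sd(signals) == 0)
    return(fit_result(list(t1_ms = NA_real_), NA_real_, signals[1],
                      rep(signals[1], length(signals)), signals,
                      converged = FALSE, degenerate = TRUE))
  resid_fn <- function(p)
    signals - (p[1] * (1 - exp(-times_ms / p[2])) + p[3])
  s0_0 <- max(signals)
  # two-point log estimate from the earliest TR, offset assumed small
  frac <- 1 - signals[1] / (1.05 * s0_0)
  t1_0 <- if (frac > 0 && frac < 1) -times_ms[1] / log(frac) else 20
  starts <- lapply(c(t1_0, 5, 20, 50),
                   function(t1) c(s0 = s0_0, t1 = t1, off = min(signals)))
  best <- multistart_lm(resid_fn, starts,
                        lower = c(0, 0.1, -Inf), upper = c(Inf, 500, Inf))
  if (is.null(best)) stop("T1 fit failed from every initialisation")
  p <- best$par
  fit_result(list(t1_ms = unname(p[2])), unname(p[1]), unname(p[3]),
             signals - resid_fn(p), signals, best$converged)
}

#' Biexponential T2* fit for spin-3/2 sodium
#'
#' Bounded least-squares fit of
#' `S(TE) = S0 * (ps*exp(-TE/T2s*) + (1-ps)*exp(-TE/T2l*)) + offset`
#' with `0 < ps < 1` and both components in `[0.05, 200]` ms. Five
#' deterministic initialisations (ps in 0.3/0.6 crossed with T2s in
#' 1/5 ms at T2l = 15 ms, plus a tail-slope data-driven start) are run
#' and the lowest SSE wins; the component ordering `T2s* <= T2l*` is
#' restored afterwards by the model's label symmetry (swap components
#' and ps <-> 1-ps). If the two components coincide within 1e-3 ms the
#' decay is effectively monoexponential and `ps` is unidentifiable: the
#' fit is flagged degenerate.
#'
#' @param times_ms echo times, >= 5 distinct values.
#' @param signals ROI-mean signals (a.u.).
#' @return A fit-result list: `params$t2s_ms`, `params$t2l_ms`,
#'   `params$ps`, plus the shared fit-result fields.
#' @export
fit_t2star_biexponential <- function(times_ms, signals) {
  stopifnot(length(times_ms) == length(signals))
  if (length(unique(times_ms)) < 5)
    stop("need >= 5 distinct echo times")
  resid_fn <- function(p)
    signals - (p[1] * (p[2] * exp(-times_ms / p[3]) +
                       (1 - p[2]) * exp(-times_ms / p[4])) + p[5])
  off0 <- min(signals)
  s0_0 <- max(signals) - off0
  # data-driven start: long component from the tail log-slope
  tail_idx <- times_ms >= stats::median(times_ms)
  tail_y <- signals[tail_idx] - off0
  t2l_0 <- if (all(tail_y > 0) && sum(tail_idx) >= 2) {
    sl <- stats::coef(stats::lm(log(tail_y) ~ times_ms[tail_idx]))[2]
    if (is.finite(sl) && sl < 0) min(max(-1 / sl, 1), 200) else 15
  } else 15
  starts <- c(
    lapply(expand_grid_list(ps = c(0.3, 0.6), t2s = c(1, 5)),
           function(g) c(s0_0, g$ps, g$t2s, 15, off0)),
    list(c(s0_0, 0.5, max(0.05, t2l_0 / 10), t2l_0, off0)))
  eps <- 1e-6
  best <- multistart_lm(resid_fn, starts,
                        lower = c(0, eps, 0.05, 0.05, -Inf),
                        upper = c(Inf, 1 - eps, 200, 200, Inf))
  if (is.null(best)) stop("biexponential fit failed from every start")
  p <- best$par
  if (p[3] > p[4]) p <- c(p[1], 1 - p[2], p[4], p[3], p[5])
  degenerate <- abs(p[4] - p[3]) < 1e-3
  fit_result(list(t2s_ms = unname(p[3]), t2l_ms = unname(p[4]),
                  ps = unname(p[2])),
             unname(p[1]), unname(p[5]),
             signals - resid_fn(p), signals, best$converged, degenerate)
}

expand_grid_list <- function(...) {
  g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# Monoexponential decay fit with free offset (used voxel-wise for 1H).
fit_t2star_monoexponential <- function(times_ms, signals) {
  if (stats::sd(signals) == 0) return(NULL)
  resid_fn <- function(p) signals - (p[1] * exp(-times_ms / p[2]) + p[3])
  off0 <- min(signals)
  s0_0 <- max(signals) - off0
  y2 <- signals[2] - off0
  t2_0 <- if (s0_0 > 0 && y2 > 0 && y2 < s0_0)
    -(times_ms[2] - times_ms[1]) / log(y2 / s0_0) else 3
  starts <- lapply(c(t2_0, 1, 5), function(t2) c(s0_0, t2, off0))
  best <- multistart_lm(resid_fn, starts,
                        lower = c(0, 0.05, -Inf), upper = c(Inf, 200, Inf))
  if (is.null(best) || !best$converged) return(NULL)
  p <- best$par
  list(s0 = p[1], t2_ms = p[2], offset = p[3])
}

#' Voxel-wise monoexponential 1H T2* map
#'
#' Fits `S(TE) = S0 * exp(-TE/T2*) + offset` in every masked voxel of a
#' multi-echo 1H series. Voxels whose fit does not converge (e.g.
#' constant signal) are marked absent and tallied.
#'
#' @param echo_volumes list of [na_volume()]s at >= 3 echoes.
#' @param mask an [na_labelmap()] on the same grid.
#' @param code region code(s) or name(s) to fit.
#' @return list with `map` (an [na_volume()] of T2* in ms, NA outside
#'   the region and in failed voxels), `stats` (ROI mean/SD/relative SD
#'   of the map), `n_failed`.
#' @export
fit_t2star_mono_map <- function(echo_volumes, mask, code) {
  stopifnot(length(echo_volumes) >= 3)
  for (v in echo_volumes)
    stop_if_grid_mismatch(v, mask, "echo volume and label map")
  tes <- vapply(echo_volumes, function(v) v$te_ms, numeric(1))
  o <- order(tes)
  tes <- tes[o]
  echo_volumes <- echo_volumes[o]
  ind <- which(mask_indicator(mask, code))
  series <- vapply(echo_volumes, function(v) v$data[ind],
                   numeric(length(ind)))
  map <- array(NA_real_, dim = dim(mask$labels))
  n_failed <- 0L
  for (j in seq_along(ind)) {
    fit <- fit_t2star_monoexponential(tes, series[j, ])
    if (is.null(fit)) n_failed <- n_failed + 1L
    else map[ind[j]] <- fit$t2_ms
  }
  vals <- map[ind]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no voxel in the region produced a usable fit")
  vol <- na_volume(map, echo_volumes[[1]]$voxel_size_mm,
                   mask$origin_mm, nucleus = "H1")
  list(map = vol, stats = roi_stats(vals), n_failed = n_failed)
}
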