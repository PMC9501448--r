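# Friedman chi-square with mid-ranks and tie correction (matches
# stats::friedman.test); kept as a plain statistic function so the exact
# permutation null can reuse it.
friedman_statistic <- function(values) {
  n <- nrow(values); k <- ncol(values)
  r <- t(apply(values, 1, rank))
  stat <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  ties <- sum(apply(r, 1, function(ri) {
    tab <- table(ri)
    sum(tab^3 - tab)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  if (corr == 0) return(0)  # every row fully tied: no evidence, stat 0
  stat / corr
}

#' Friedman test across the three tendon regions
#'
#' Nonparametric repeated-measures comparison of a parameter across INS,
#' MID and MTJ (one row per subject, ties mid-ranked). The default
#' asymptotic p-value comes from the chi-square distribution with
#' `k - 1` degrees of freedom via [stats::friedman.test()]; for small
#' cohorts an exact permutation p-value enumerating every within-subject
#' ordering is available.
#'
#' @param values numeric matrix, subjects x conditions (no missing cells).
#' @param method `"asymptotic"` or `"exact"` (enumeration of all
#'   `k!^n` within-row permutations; limited to small n).
#' @return list `p_value`, `statistic`, `df`, `mean_ranks`, `method`.
#' @export
friedman_test <- function(values, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("missing cells in the value table")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  ranks <- t(apply(values, 1, rank))
  mean_ranks <- colMeans(ranks)
  stat <- friedman_statistic(values)
  if (method == "asymptotic") {
    p <- stats::friedman.test(values)$p.value
    # fully-tied tables make the tie correction degenerate upstream
    if (!is.finite(p)) p <- if (stat == 0) 1 else NA_real_
  } else {
    if (factorial(k)^n > 2e6)
      stop("exact enumeration infeasible for this table size")
    perms <- all_permutations(k)
    total <- factorial(k)^n
    count <- 0L
    grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
    for (g in seq_len(nrow(grid))) {
      vv <- values
      for (i in seq_len(n)) vv[i, ] <- values[i, perms[grid[g, i], ]]
      if (friedman_statistic(vv) >= stat - 1e-12) count <- count + 1L
    }
    p <- count / total
  }
  list(p_value = p, statistic = stat, df = k - 1,
       mean_ranks = mean_ranks, method = method)
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- NULL
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, pos - 1 + seq_len(k - pos), drop = FALSE])
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}

#' Pairwise paired Wilcoxon tests with Bonferroni correction
#'
#' Tests each region pair (INS-MID, INS-MTJ, MID-MTJ) with the paired
#' signed-rank test, two-sided, using the normal approximation without
#' continuity correction, and multiplies the p-values by three (capped
#' at 1). The design is paired because the same subjects contribute all
#' three regions; with n = 10 subjects whose differences all share one
#' sign this yields a corrected p of 0.015. A pair whose differences are
#' all zero is reported as p = 1.
#'
#' @param values numeric matrix, subjects x 3 regions, columns named.
#' @param method `"normal"` (asymptotic, no continuity correction) or
#'   `"exact"` (exact signed-rank distribution, no zeros/ties allowed).
#' @return data.frame with `pair`, `p_raw`, `p_corrected`, `significant`.
#' @export
pairwise_wilcoxon_bonferroni <- function(values, method = c("normal",
                                                            "exact")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (ncol(values) != 3) stop("expected three regions")
  if (is.null(colnames(values))) colnames(values) <- c("INS", "MID", "MTJ")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  rows <- lapply(pairs, function(pr) {
    x <- values[, pr[1]]; y <- values[, pr[2]]
    d <- x - y
    if (all(d == 0)) {
      p <- 1
    } else {
      p <- suppressWarnings(stats::wilcox.test(
        x, y, paired = TRUE, exact = (method == "exact"),
        correct = FALSE)$p.value)
    }
    data.frame(pair = paste(colnames(values)[pr], collapse = "-"),
               p_raw = p, p_corrected = min(3 * p, 1))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_corrected <= 0.05
  out
}

#' Regional comparison of one parameter
#'
#' Friedman test first; the pairwise Bonferroni-corrected Wilcoxon tests
#' are only run (and reported) when the Friedman p-value is below 0.05,
#' mirroring the study's gatekeeping procedure.
#'
#' @param values subjects x 3 matrix (INS, MID, MTJ).
#' @param parameter label for the output row.
#' @return one-row data.frame with the Friedman p and the three
#'   corrected pairwise p-values (NA when not performed).
#' @export
regional_comparison <- function(values, parameter = "parameter") {
  fr <- friedman_test(values)
  if (fr$p_value < 0.05) {
    pw <- pairwise_wilcoxon_bonferroni(values)
    p_pair <- pw$p_corrected
  } else {
    p_pair <- rep(NA_real_, 3)
  }
  data.frame(parameter = parameter, friedman_p = fr$p_value,
             p_INS_MID = p_pair[1], p_INS_MTJ = p_pair[2],
             p_MID_MTJ = p_pair[3])
}

#' Assemble the study report tables
#'
#' Builds the three summary tables of the analysis from per-subject
#' inputs: a relaxometry table (per-region mean +/- SD of T1, T2s*,
#' T2l*, ps and fit R-squared), a quantification table (per-region,
#' per-parameter mean of subject means +/- between-subject SD plus the
#' mean within-ROI SD%), and a statistics table (Friedman p and
#' corrected pairwise p-values for each parameter mean and its SD%).
#'
#' @param relaxometry data.frame with columns `subject`, `roi`, `t1_ms`,
#'   `r2_t1`, `t2s_ms`, `t2l_ms`, `ps_pct`, `r2_t2` (or NULL to skip).
#' @param quant data.frame with columns `subject`, `roi`, `parameter`,
#'   `mean`, `rel_sd_pct`.
#' @return list of data.frames `relaxometry`, `parameters`, `stats`.
#' @export
build_report <- function(quant, relaxometry = NULL) {
  need <- c("subject", "roi", "parameter", "mean", "rel_sd_pct")
  if (!all(need %in% names(quant)))
    stop("quant must have columns ", paste(need, collapse = ", "))
  regions <- c("INS", "MID", "MTJ", "Total")
  have <- unique(quant$roi)
  if (!all(c("INS", "MID", "MTJ") %in% have))
    stop("missing region(s): ",
         paste(setdiff(c("INS", "MID", "MTJ"), have), collapse = ", "))

  msd <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  param_tab <- do.call(rbind, lapply(
    split(quant, list(quant$parameter, quant$roi), drop = TRUE),
    function(d) data.frame(
      parameter = d$parameter[1], roi = d$roi[1],
      mean = mean(d$mean), between_subject_sd = msd(d$mean),
      within_roi_sd_pct = mean(d$rel_sd_pct),
      n_subjects = length(unique(d$subject)))))
  param_tab <- param_tab[order(param_tab$parameter,
                               match(param_tab$roi, regions)), ]
  rownames(param_tab) <- NULL

  stats_tab <- NULL
  n_subj <- length(unique(quant$subject))
  if (n_subj >= 2) {
    stats_rows <- list()
    for (par in unique(quant$parameter)) {
      d <- quant[quant$parameter == par & quant$roi != "Total", ]
      wide_mean <- stats::reshape(
        d[, c("subject", "roi", "mean")], idvar = "subject",
        timevar = "roi", direction = "wide")
      m <- as.matrix(wide_mean[, paste0("mean.", c("INS", "MID", "MTJ"))])
      colnames(m) <- c("INS", "MID", "MTJ")
      stats_rows[[paste0("mean ", par)]] <-
        regional_comparison(m, paste0("mean ", par))
      wide_sd <- stats::reshape(
        d[, c("subject", "roi", "rel_sd_pct")], idvar = "subject",
        timevar = "roi", direction = "wide")
      ms <- as.matrix(wide_sd[, paste0("rel_sd_pct.",
                                       c("INS", "MID", "MTJ"))])
      colnames(ms) <- c("INS", "MID", "MTJ")
      stats_rows[[paste0("SD ", par)]] <-
        regional_comparison(ms, paste0("SD ", par))
    }
    stats_tab <- do.call(rbind, c(stats_rows, make.row.names = FALSE))
  }

  relax_tab <- NULL
  if (!is.null(relaxometry)) {
    relax_tab <- do.call(rbind, lapply(
      split(relaxometry, relaxometry$roi),
      function(d) data.frame(
        roi = d$roi[1],
        t1_ms = mean(d$t1_ms), t1_sd_ms = msd(d$t1_ms),
        r2_t1 = mean(d$r2_t1),
        t2s_ms = mean(d$t2s_ms), t2s_sd_ms = msd(d$t2s_ms),
        t2l_ms = mean(d$t2l_ms), t2l_sd_ms = msd(d$t2l_ms),
        ps_pct = mean(d$ps_pct), ps_sd_pct = msd(d$ps_pct),
        r2_t2 = mean(d$r2_t2))))
    relax_tab <- relax_tab[order(match(relax_tab$roi, regions)), ]
    rownames(relax_tab) <- NULL
  }
  list(relaxometry = relax_tab, parameters = param_tab, stats = stats_tab)
}
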