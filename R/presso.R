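# MR-PRESSO: simulation-based residual-sum-of-squares diagnostics for
# horizontally pleiotropic outlier instruments — global test, per-SNP
# outlier test, and distortion test.

# Leave-one-out IVW slopes for each row, given weights w = 1/se_Y^2.
# The slope of the zero-intercept weighted regression equals the IVW
# estimate, so dropping SNP j is a rank-one update of the two sums.
loo_ivw_slopes <- function(bx, by, w) {
  Swxx <- sum(w * bx^2)
  Swxy <- sum(w * bx * by)
  (Swxy - w * bx * by) / (Swxx - w * bx^2)
}

#' MR-PRESSO pleiotropy residual sum and outlier test
#'
#' Three steps. Global: the observed residual sum of squares around
#' leave-one-out IVW fits is compared with `n_sim` parametric
#' simulations (`bx* ~ N(bx, se_X)`, `by* ~ N(b_loo * bx, se_Y)`).
#' Outlier: each SNP's observed squared residual is compared with its
#' simulated distribution, Bonferroni-adjusted across SNPs. Distortion:
#' the percent change of the IVW estimate after removing the detected
#' outliers is compared with removing random subsets of the same size.
#' Empirical p-values carry the +1 correction; the raw fractions are
#' reported alongside.
#'
#' @param instruments Harmonized instrument table (>= 4 rows).
#' @param n_sim Simulation replicates.
#' @param outlier_alpha Significance level applied to the
#'   Bonferroni-adjusted per-SNP p-values.
#' @param seed RNG seed.
#' @return A `presso_result` list: `global_rss_observed`, `global_p`,
#'   `global_p_raw`, `outlier_pvalues` (adjusted, named by rsid),
#'   `outliers`, `estimate_all`, `estimate_outlier_corrected` (NULL if
#'   every SNP is flagged), `distortion_coefficient` (percent),
#'   `distortion_p`, `n_sim`, `seed`, `all_outliers` flag.
#' @export
mr_presso <- function(instruments, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 1) {
  d <- mr_columns(instruments)
  n <- length(d$bx)
  if (n < 4) stopf("MR-PRESSO requires at least 4 instruments")
  if (any(d$bx == 0))
    stopf("zero exposure effect for instrument(s): %s",
          paste(d$rsid[d$bx == 0], collapse = ", "))
  w <- 1 / d$sy^2
  b_loo <- loo_ivw_slopes(d$bx, d$by, w)
  resid2_obs <- (d$by - b_loo * d$bx)^2
  rss_obs <- sum(resid2_obs)

  sim <- with_seed(seed, {
    bx_s <- matrix(stats::rnorm(n_sim * n, rep(d$bx, each = n_sim),
                                rep(d$sx, each = n_sim)), n_sim, n)
    by_s <- matrix(stats::rnorm(n_sim * n, rep(b_loo * d$bx, each = n_sim),
                                rep(d$sy, each = n_sim)), n_sim, n)
    W <- matrix(w, n_sim, n, byrow = TRUE)
    Swxx <- rowSums(W * bx_s^2)
    Swxy <- rowSums(W * bx_s * by_s)
    slopes <- (Swxy - W * bx_s * by_s) / (Swxx - W * bx_s^2)
    res2 <- (by_s - slopes * bx_s)^2
    list(res2 = res2, rss = rowSums(res2))
  })
  n_ge <- sum(sim$rss >= rss_obs)
  global_p <- (1 + n_ge) / (1 + n_sim)
  global_p_raw <- n_ge / n_sim

  exceed <- colSums(sim$res2 >= matrix(resid2_obs, n_sim, n, byrow = TRUE))
  p_out_raw <- (1 + exceed) / (1 + n_sim)
  p_out_adj <- pmin(1, p_out_raw * n)
  names(p_out_adj) <- d$rsid
  outliers <- d$rsid[p_out_adj < outlier_alpha]

  est_all <- mr_ivw(instruments)
  est_all$method <- "presso_raw"
  keep <- !(d$rsid %in% outliers)
  all_flagged <- !any(keep)
  est_corr <- NULL
  distortion <- NA_real_
  distortion_p <- NA_real_
  if (length(outliers) > 0 && !all_flagged) {
    est_corr <- mr_ivw(instruments[keep, , drop = FALSE])
    est_corr$method <- "presso_outlier_corrected"
    distortion <- 100 * (est_all$estimate - est_corr$estimate) /
      abs(est_corr$estimate)
    # Random same-size subsets, drawn without replacement.
    d_rand <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(n, length(outliers))
        b_sub <- mr_ivw(instruments[-drop_idx, , drop = FALSE])$estimate
        100 * (est_all$estimate - b_sub) / abs(b_sub)
      }, numeric(1))
    })
    distortion_p <- mean(abs(d_rand) >= abs(distortion))
  } else if (!all_flagged) {
    # No outliers: corrected estimate is the all-SNP estimate; the
    # distortion test is skipped.
    est_corr <- est_all
    est_corr$method <- "presso_outlier_corrected"
  }
  if (all_flagged)
    warnf("every instrument flagged as an outlier; corrected estimate undefined")

  structure(list(
    global_rss_observed = rss_obs, global_p = global_p,
    global_p_raw = global_p_raw, n_sim = n_sim,
    outlier_pvalues = p_out_adj, outlier_pvalues_raw = p_out_raw,
    outliers = outliers,
    estimate_all = est_all, estimate_outlier_corrected = est_corr,
    distortion_coefficient = distortion, distortion_p = distortion_p,
    all_outliers = all_flagged, seed = seed), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.4g, p = %.3g (%d sims)\n",
              x$global_rss_observed, x$global_p, x$n_sim))
  cat(sprintf("  outliers: %s\n",
              if (length(x$outliers)) paste(x$outliers, collapse = ", ")
              else "none"))
  if (!is.na(x$distortion_coefficient))
    cat(sprintf("  distortion: %.2f%% (p = %.3g)\n",
                x$distortion_coefficient, x$distortion_p))
  invisible(x)
}
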