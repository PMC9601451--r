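# Summary-data-based MR (SMR) linking expression to trait through the
# top cis-eQTL SNP, and the HEIDI heterogeneity test separating one
# shared causal variant (pleiotropy) from linkage of distinct variants.

#' SMR test at a single SNP
#'
#' With z1 = beta_GWAS/se_GWAS and z2 = beta_eQTL/se_eQTL, the statistic
#' is `T_smr = z1^2 z2^2 / (z1^2 + z2^2)`, referred to chi-square on one
#' df. The effect of expression on trait is `b_xy = beta_GWAS/beta_eQTL`
#' with `se_bxy = |b_xy| / sqrt(T_smr)` (so that the Wald chi-square of
#' b_xy equals T_smr).
#'
#' @param beta_gwas,se_gwas SNP-trait effect and SE.
#' @param beta_eqtl,se_eqtl SNP-expression effect and SE.
#' @return List: `b_xy`, `se_bxy`, `T_smr`, `p_smr`.
#' @export
smr_test <- function(beta_gwas, se_gwas, beta_eqtl, se_eqtl) {
  if (se_gwas <= 0 || se_eqtl <= 0) stopf("standard errors must be positive")
  if (beta_eqtl == 0) stopf("zero eQTL effect: b_xy undefined")
  z1 <- beta_gwas / se_gwas
  z2 <- beta_eqtl / se_eqtl
  T_smr <- z1^2 * z2^2 / (z1^2 + z2^2)
  p_smr <- stats::pchisq(T_smr, df = 1, lower.tail = FALSE)
  b_xy <- beta_gwas / beta_eqtl
  se_bxy <- if (T_smr > 0) abs(b_xy) / sqrt(T_smr) else Inf
  list(b_xy = b_xy, se_bxy = se_bxy, T_smr = T_smr, p_smr = p_smr)
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Tests whether every SNP in the cis region implies the same
#' expression-on-trait effect `b_xy` as the top eQTL SNP. SNPs with
#' `|z_eQTL| >= z_eqtl_min` and r-squared to the top SNP inside
#' `r2_band` are eligible (at most `max_snps`, ranked by eQTL
#' significance). For each the difference `d_i = b_xy(i) - b_xy(top)` is
#' standardized using first-order error propagation with
#' `cov(beta_i, beta_j) = r_ij se_i se_j` within each study; the
#' statistic `T_heidi = sum(z_d^2)` follows a correlated chi-square
#' mixture under the null, evaluated by Satterthwaite moment matching
#' (default) or by Monte-Carlo simulation of the multivariate-normal
#' z-differences.
#'
#' @param region Data.frame with columns `rsid`, `beta_gwas`, `se_gwas`,
#'   `beta_eqtl`, `se_eqtl` for the cis region (top SNP included).
#' @param ld An `ld_panel` covering the region.
#' @param top_snp rsid of the top eQTL SNP.
#' @param z_eqtl_min Minimum |z| in the eQTL study for eligibility.
#' @param r2_band Eligible r-squared range to the top SNP.
#' @param max_snps Cap on SNPs entering the statistic.
#' @param method `"satterthwaite"` or `"montecarlo"`.
#' @param n_mc Monte-Carlo draws when `method = "montecarlo"`.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return List: `T_heidi`, `p_heidi`, `n_snps`, `method`, `snps`;
#'   `p_heidi` is NA with `method = "insufficient_snps"` when fewer than
#'   3 SNPs are eligible.
#' @export
heidi_test <- function(region, ld, top_snp, z_eqtl_min = 3.16,
                       r2_band = c(0.05, 0.9), max_snps = 20,
                       method = c("satterthwaite", "montecarlo"),
                       n_mc = 100000, seed = 1) {
  method <- match.arg(method)
  if (!top_snp %in% region$rsid) stopf("top SNP not in region table")
  reg <- region[!duplicated(region$rsid), , drop = FALSE]
  top <- reg[reg$rsid == top_snp, , drop = FALSE]
  others <- reg[reg$rsid != top_snp, , drop = FALSE]
  z_eqtl <- abs(others$beta_eqtl / others$se_eqtl)
  r2 <- suppressWarnings(ld_r2(ld, top_snp, others$rsid))
  r2[is.na(r2)] <- 0
  elig <- z_eqtl >= z_eqtl_min & r2 >= r2_band[[1]] & r2 <= r2_band[[2]] &
    others$beta_eqtl != 0
  cand <- others[elig, , drop = FALSE]
  if (nrow(cand) > max_snps)
    cand <- cand[order(-abs(cand$beta_eqtl / cand$se_eqtl)), ,
                 drop = FALSE][seq_len(max_snps), ]
  m <- nrow(cand)
  if (m < 3)
    return(list(T_heidi = NA_real_, p_heidi = NA_real_, n_snps = m,
                method = "insufficient_snps", snps = cand$rsid))

  snps <- c(cand$rsid, top_snp)
  bg <- c(cand$beta_gwas, top$beta_gwas)
  sg <- c(cand$se_gwas, top$se_gwas)
  be <- c(cand$beta_eqtl, top$beta_eqtl)
  se <- c(cand$se_eqtl, top$se_eqtl)
  R_snp <- ld_matrix(ld, snps, missing_as_zero = TRUE)
  b <- bg / be
  # First-order covariance of the b_xy estimates: GWAS and eQTL studies
  # are independent samples, SNP effect estimates within a study are
  # correlated through LD.
  Cb <- R_snp * (outer(sg, sg) / outer(be, be)) +
    R_snp * (outer(se, se) * outer(bg, bg) / outer(be^2, be^2))
  t_idx <- m + 1
  d <- b[seq_len(m)] - b[[t_idx]]
  V <- Cb[seq_len(m), seq_len(m), drop = FALSE] -
    outer(Cb[seq_len(m), t_idx], rep(1, m)) -
    outer(rep(1, m), Cb[seq_len(m), t_idx]) + Cb[t_idx, t_idx]
  vd <- diag(V)
  if (any(vd <= 0)) stopf("non-positive variance in HEIDI propagation")
  zd <- d / sqrt(vd)
  T_heidi <- sum(zd^2)
  R <- V / sqrt(outer(vd, vd))
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  if (method == "satterthwaite") {
    s <- sum(lambda^2) / sum(lambda)
    df <- sum(lambda)^2 / sum(lambda^2)
    p <- stats::pchisq(T_heidi / s, df = df, lower.tail = FALSE)
  } else {
    ev <- eigen(R, symmetric = TRUE)
    A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m)
    p <- with_seed(seed, {
      Z <- matrix(stats::rnorm(n_mc * m), n_mc, m) %*% t(A)
      mean(rowSums(Z^2) >= T_heidi)
    })
  }
  list(T_heidi = T_heidi, p_heidi = p, n_snps = m, method = method,
       snps = cand$rsid)
}

#' Scan all eQTL targets with SMR and HEIDI
#'
#' Per target: the top cis-eQTL SNP (smallest eQTL p-value) must pass
#' `p_eqtl_top`, the SMR test is run on that SNP, and HEIDI on the cis
#' region around the target TSS. `pass_smr` uses a strict
#' `p_smr < p_smr_threshold` gate; `pass_heidi` a strict
#' `p_heidi > heidi_gate` gate.
#'
#' @param gwas Association table for the trait.
#' @param eqtl QTL table (see [read_qtl()]) grouped by `target_id`.
#' @param ld An `ld_panel`.
#' @param p_eqtl_top Minimum top-eQTL significance (strict).
#' @param p_smr_threshold SMR significance threshold (strict).
#' @param heidi_gate HEIDI pass threshold (strict greater-than).
#' @param cis_window_kb cis region half-width around the target TSS.
#' @param ... Passed to [heidi_test()].
#' @return Data.frame, one row per target x tissue, with SMR/HEIDI
#'   statistics and pass flags; skipped targets are absent (logged via
#'   message).
#' @export
smr_scan <- function(gwas, eqtl, ld, p_eqtl_top = 5e-8,
                     p_smr_threshold = 5e-6, heidi_gate = 0.05,
                     cis_window_kb = 1000, ...) {
  rows <- list()
  groups <- split(eqtl, paste(eqtl$target_id, eqtl$tissue_or_study,
                              sep = "\r"))
  for (grp in groups) {
    target <- grp$target_id[[1]]
    tissue <- grp$tissue_or_study[[1]]
    merged <- merge(grp, gwas, by = "rsid", suffixes = c("_eqtl", "_gwas"))
    if (nrow(merged) == 0) next
    tss <- merged$target_tss[[1]]
    if (!is.na(tss)) {
      keep <- !is.na(merged$pos) &
        abs(merged$pos - tss) <= cis_window_kb * 1000 &
        (is.na(merged$target_chrom[[1]]) |
           merged$chrom == merged$target_chrom[[1]])
      merged <- merged[keep, , drop = FALSE]
    }
    if (nrow(merged) == 0) next
    top_i <- which.min(merged$pvalue_eqtl)
    if (!(merged$pvalue_eqtl[[top_i]] < p_eqtl_top)) {
      message(sprintf("target %s (%s): no eQTL passes p < %g; skipped",
                      target, tissue, p_eqtl_top))
      next
    }
    top <- merged[top_i, ]
    smr <- smr_test(top$beta_gwas, top$se_gwas, top$beta_eqtl, top$se_eqtl)
    region <- data.frame(rsid = merged$rsid,
                         beta_gwas = merged$beta_gwas,
                         se_gwas = merged$se_gwas,
                         beta_eqtl = merged$beta_eqtl,
                         se_eqtl = merged$se_eqtl,
                         stringsAsFactors = FALSE)
    heidi <- heidi_test(region, ld, top$rsid, ...)
    rows[[length(rows) + 1]] <- data.frame(
      target_id = target, tissue_or_study = tissue, top_snp = top$rsid,
      p_eqtl_top = top$pvalue_eqtl,
      b_xy = smr$b_xy, se_bxy = smr$se_bxy,
      T_smr = smr$T_smr, p_smr = smr$p_smr,
      T_heidi = heidi$T_heidi, p_heidi = heidi$p_heidi,
      n_heidi_snps = heidi$n_snps, heidi_method = heidi$method,
      pass_smr = smr$p_smr < p_smr_threshold,
      pass_heidi = !is.na(heidi$p_heidi) && heidi$p_heidi > heidi_gate,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(0), tissue_or_study = character(0),
               top_snp = character(0), p_eqtl_top = numeric(0),
               b_xy = numeric(0), se_bxy = numeric(0), T_smr = numeric(0),
               p_smr = numeric(0), T_heidi = numeric(0),
               p_heidi = numeric(0), n_heidi_snps = integer(0),
               heidi_method = character(0), pass_smr = logical(0),
               pass_heidi = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
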