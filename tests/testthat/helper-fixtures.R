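# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from packaged data.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A standard-dialect GWAS file (SNP CHR BP A1 A2 FRQ BETA SE P header).
gwas_fixture_path <- function() {
  write_lines_tmp(c(
    "SNP\tCHR\tBP\tA1\tA2\tFRQ\tBETA\tSE\tP",
    "rs1\t1\t1000\tA\tG\t0.20\t0.10\t0.02\t5.7e-7",
    "rs2\t1\t2000\tC\tT\t0.45\t-0.05\t0.01\t6.0e-7",
    "rs3\t2\t3000\tG\tA\t0.33\t0.01\t0.03\t0.74"))
}

# Association table built directly in memory.
make_assoc <- function(rsid, pvalue, beta = NULL, se = NULL,
                       chrom = "1", pos = NULL,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3) {
  n <- length(rsid)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  se <- if (is.null(se)) rep(0.02, n) else rep_len(se, n)
  beta <- if (is.null(beta))
    se * stats::qnorm(pvalue / 2, lower.tail = FALSE) else rep_len(beta, n)
  data.frame(rsid = rsid, chrom = rep_len(chrom, n), pos = pos,
             effect_allele = rep_len(effect_allele, n),
             other_allele = rep_len(other_allele, n),
             eaf = rep_len(eaf, n), beta = beta, se = se, pvalue = pvalue,
             n = 10000L, stringsAsFactors = FALSE)
}

# Instrument table from raw vectors.
make_instruments <- function(bx, by, sx, sy, rsid = NULL) {
  n <- length(bx)
  data.frame(rsid = rsid %||% paste0("rs", seq_len(n)),
             beta_exposure = bx, se_exposure = rep_len(sx, n),
             beta_outcome = by, se_outcome = rep_len(sy, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Summary-level two-sample MR draw: n_snp instruments with true gamma,
# causal effect b, optional per-SNP direct effects alpha.
sim_summary_instruments <- function(n_snp, b = 0, gamma_mean = 0.15,
                                    sx = 0.01, sy = 0.01, alpha = 0) {
  gamma <- stats::rnorm(n_snp, gamma_mean, 0.03)
  alpha <- rep_len(alpha, n_snp)
  bx <- stats::rnorm(n_snp, gamma, sx)
  by <- stats::rnorm(n_snp, b * gamma + alpha, sy)
  make_instruments(bx, by, sx, sy)
}

# Small per-target cis scenario on individual-level data: one LD block,
# expression driven by one variant; returns gwas, eqtl, panel.
sim_cis_scenario <- function(seed, n = 50000, n_snps = 12, rho = 0.9,
                             h2_expr = 0.05, b_outcome = 0.3,
                             linkage = FALSE) {
  cfg <- sim_config(n_individuals = n, n_blocks = 1,
                    snps_per_block = n_snps, rho = rho, n_causal = 1,
                    heritability_x = h2_expr, beta_causal = b_outcome,
                    seed = seed)
  panel <- gen_ld_panel(cfg)
  ss <- gen_summary_stats(panel, cfg)
  if (!linkage) {
    expr_tab <- ss$exposure
    gwas_tab <- ss$outcome
  } else {
    # Distinct causal variants: expression from the generated causal
    # SNP, outcome directly from a correlated neighbour (no mediation).
    G <- panel$dosages
    causal <- which(ss$truth$causal)[[1]]
    neighbour <- if (causal < n_snps) causal + 1L else causal - 1L
    g <- G[, neighbour]
    y <- 0.15 * (g - mean(g)) / stats::sd(g) + stats::rnorm(n)
    expr_tab <- ss$exposure
    gwas_tab <- assoc_scan(panel, y)
  }
  tss <- panel$snp_info$pos[[1]]
  eqtl <- data.frame(rsid = expr_tab$rsid, target_id = "GENE_T",
                     target_chrom = expr_tab$chrom, target_tss = tss,
                     beta = expr_tab$beta, se = expr_tab$se,
                     pvalue = expr_tab$pvalue, tissue_or_study = "sim",
                     stringsAsFactors = FALSE)
  list(gwas = gwas_tab, eqtl = eqtl, panel = panel, truth = ss$truth)
}
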