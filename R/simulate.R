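# Synthetic-data generator. Individual-level genotypes with block-wise
# AR(1) LD are drawn from a latent-Gaussian model, an exposure and an
# outcome are built from the structural model
#     X = G %*% gamma + eps_x        (gamma scaled to heritability_x)
#     Y = beta * X + G %*% alpha + eps_y
# and per-SNP marginal OLS regressions of X and Y on each dosage column
# give the summary statistics every downstream stage consumes. The truth
# record (per-SNP gamma, alpha, causal and RNAm flags, true beta, seed)
# makes parameter-recovery tests possible.

#' Simulation configuration
#'
#' Collects every knob of the generative model. Defaults describe the
#' reference scenario used throughout the package's tests: 50,000
#' individuals, 50 LD blocks of 4 SNPs (AR(1) latent correlation 0.8),
#' 50 causal SNPs explaining 30% of exposure variance, a true causal
#' effect of 0.1 of exposure on outcome, no pleiotropy, and an RNAm flag
#' base rate of 5% enriched 5-fold at causal SNPs.
#'
#' @param n_individuals Sample size of the simulated cohort.
#' @param n_blocks Number of independent LD blocks.
#' @param snps_per_block SNPs per block (>= 1).
#' @param rho Within-block AR(1) latent correlation, in [0, 1).
#' @param maf_range Minor-allele-frequency range, subset of (0, 0.5].
#' @param n_causal Number of SNPs with nonzero exposure effect.
#' @param heritability_x Variance fraction of exposure explained by
#'   genetics, in [0, 1).
#' @param beta_causal True causal effect of exposure on outcome.
#' @param pleiotropy_fraction Share of causal SNPs with a direct
#'   (horizontally pleiotropic) outcome effect.
#' @param alpha_scale SD of the direct outcome effects alpha_j.
#' @param rnam_base_rate Probability a non-causal SNP carries an RNAm flag.
#' @param rnam_enrichment Multiplier on the flag rate at causal SNPs
#'   (capped so the rate never exceeds 1).
#' @param seed Base RNG seed; every generator derives its stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 50000,
                       n_blocks = 50,
                       snps_per_block = 4,
                       rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_causal = 50,
                       heritability_x = 0.3,
                       beta_causal = 0.1,
                       pleiotropy_fraction = 0,
                       alpha_scale = 0.1,
                       rnam_base_rate = 0.05,
                       rnam_enrichment = 5,
                       seed = 20221018) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_blocks = as.integer(n_blocks),
              snps_per_block = as.integer(snps_per_block),
              rho = rho, maf_range = maf_range,
              n_causal = as.integer(n_causal),
              heritability_x = heritability_x,
              beta_causal = beta_causal,
              pleiotropy_fraction = pleiotropy_fraction,
              alpha_scale = alpha_scale,
              rnam_base_rate = rnam_base_rate,
              rnam_enrichment = rnam_enrichment,
              seed = as.integer(seed))
  if (cfg$n_individuals < 2) stopf("n_individuals must be >= 2")
  if (cfg$snps_per_block < 1) stopf("snps_per_block must be >= 1")
  if (cfg$n_blocks < 1) stopf("n_blocks must be >= 1")
  if (!is.numeric(cfg$rho) || cfg$rho < 0 || cfg$rho >= 1)
    stopf("rho must lie in [0, 1)")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stopf("maf_range must be [low, high] within (0, 0.5]")
  if (cfg$heritability_x < 0 || cfg$heritability_x >= 1)
    stopf("heritability_x must lie in [0, 1)")
  if (cfg$pleiotropy_fraction < 0 || cfg$pleiotropy_fraction > 1)
    stopf("pleiotropy_fraction must lie in [0, 1]")
  if (cfg$rnam_base_rate <= 0 || cfg$rnam_base_rate >= 1)
    stopf("rnam_base_rate must lie in (0, 1)")
  if (cfg$rnam_enrichment < 1) stopf("rnam_enrichment must be >= 1")
  structure(cfg, class = "sim_config")
}

sim_snp_map <- function(config) {
  m <- config$n_blocks * config$snps_per_block
  block <- rep(seq_len(config$n_blocks), each = config$snps_per_block)
  within <- rep(seq_len(config$snps_per_block), config$n_blocks)
  chrom <- as.character(((block - 1) %% 22) + 1)
  block_on_chrom <- (block - 1) %/% 22
  pos <- as.integer(block_on_chrom * 2e7 + 1e5 + (within - 1) * 5000)
  data.frame(rsid = paste0("rs", seq_len(m)), chrom = chrom, pos = pos,
             block = block, stringsAsFactors = FALSE)
}

#' Generate an LD panel of dosage genotypes
#'
#' Per block, two latent-Gaussian haplotypes per individual follow an
#' AR(1) process (lag-k latent correlation `rho^k`); dosages are the
#' number of haplotypes below the MAF-determined threshold. Blocks are
#' mutually independent. MAFs are drawn uniformly from `maf_range`.
#'
#' @param config A [sim_config()].
#' @param keep_latent Keep the latent haplotype matrices (used by tests
#'   that verify the generating correlation directly).
#' @return An `ld_panel` whose `snp_info` carries rsid/chrom/pos/block/maf.
#' @export
gen_ld_panel <- function(config, keep_latent = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  snp_map <- sim_snp_map(config)
  n <- config$n_individuals
  m <- nrow(snp_map)
  with_seed(config$seed, {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    thr <- stats::qnorm(maf)
    G <- matrix(0L, n, m)
    latent <- if (keep_latent) vector("list", 2) else NULL
    if (keep_latent) latent <- list(h1 = matrix(0, n, m), h2 = matrix(0, n, m))
    for (b in seq_len(config$n_blocks)) {
      idx <- which(snp_map$block == b)
      for (h in 1:2) {
        z <- matrix(0, n, length(idx))
        z[, 1] <- stats::rnorm(n)
        if (length(idx) > 1) {
          sd_innov <- sqrt(1 - config$rho^2)
          for (k in 2:length(idx))
            z[, k] <- config$rho * z[, k - 1] + sd_innov * stats::rnorm(n)
        }
        G[, idx] <- G[, idx] + (z < matrix(thr[idx], n, length(idx),
                                           byrow = TRUE))
        if (keep_latent) latent[[h]][, idx] <- z
      }
    }
    colnames(G) <- snp_map$rsid
    snp_map$maf <- maf
    panel <- ld_panel_from_dosages(G, snp_map)
    if (keep_latent) panel$latent <- latent
    panel
  })
}

select_causal <- function(snp_map, n_causal) {
  # Spread causal SNPs across blocks (cycling) so default instruments are
  # quasi-independent; within a block the slot is drawn at random.
  n_blocks <- max(snp_map$block)
  chosen <- integer(0)
  pool <- split(seq_len(nrow(snp_map)), snp_map$block)
  b <- 1
  while (length(chosen) < n_causal) {
    avail <- setdiff(pool[[b]], chosen)
    if (length(avail))
      chosen <- c(chosen, if (length(avail) == 1) avail else sample(avail, 1))
    b <- b %% n_blocks + 1
  }
  sort(chosen)
}

#' Generate exposure and outcome summary statistics
#'
#' Simulates the structural model on the panel's individuals and returns
#' per-SNP marginal OLS association statistics for exposure and outcome,
#' plus the truth record. The genetic exposure component is rescaled so
#' the realized sample heritability equals `heritability_x` exactly (up
#' to the sampling correlation between genetic and noise components).
#'
#' @param panel An `ld_panel` from [gen_ld_panel()].
#' @param config The same [sim_config()].
#' @return List with `exposure` and `outcome` association tables,
#'   `truth` (per-SNP gamma and alpha, causal/pleiotropy flags, true
#'   beta, seed) and `phenotypes` (the individual-level x and y, kept
#'   in memory only).
#' @export
gen_summary_stats <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"), panel$type == "dosage")
  G <- panel$dosages
  n <- nrow(G)
  m <- ncol(G)
  if (config$n_causal > m)
    stopf("n_causal (%d) exceeds total SNPs (%d)", config$n_causal, m)
  snp_map <- panel$snp_info
  with_seed(config$seed + 1L, {
    causal <- select_causal(snp_map, config$n_causal)
    gamma_raw <- stats::rnorm(config$n_causal)
    h2 <- config$heritability_x
    gamma <- numeric(m)
    if (h2 > 0 && config$n_causal > 0) {
      u <- as.vector(G[, causal, drop = FALSE] %*% gamma_raw)
      sd_u <- stats::sd(u)
      if (sd_u == 0) stopf("degenerate genetic component (monomorphic SNPs?)")
      gamma[causal] <- gamma_raw * sqrt(h2) / sd_u
      g_comp <- (u - mean(u)) / sd_u * sqrt(h2)
    } else {
      g_comp <- numeric(n)
    }
    eps_x <- stats::rnorm(n)
    eps_x <- (eps_x - mean(eps_x)) / stats::sd(eps_x) * sqrt(1 - h2)
    X <- g_comp + eps_x

    alpha <- numeric(m)
    n_pleio <- round(config$pleiotropy_fraction * config$n_causal)
    pleio <- if (n_pleio > 0) sort(sample(causal, n_pleio)) else integer(0)
    if (n_pleio > 0)
      alpha[pleio] <- stats::rnorm(n_pleio, 0, config$alpha_scale)
    Y <- config$beta_causal * X +
      as.vector(G[, pleio, drop = FALSE] %*% alpha[pleio]) + stats::rnorm(n)

    # Allele labels: effect allele is the counted (dosage) allele.
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1), character(1))

    stats_x <- marginal_ols(G, X)
    stats_y <- marginal_ols(G, Y)
    mono <- stats_x$mono
    if (any(mono))
      warnf("%d monomorphic SNP(s) dropped from summary tables", sum(mono))
    keep <- !mono
    mk <- function(st) data.frame(
      rsid = snp_map$rsid[keep], chrom = snp_map$chrom[keep],
      pos = snp_map$pos[keep], effect_allele = ea[keep],
      other_allele = oa[keep], eaf = colMeans(G)[keep] / 2,
      beta = st$beta[keep], se = st$se[keep], pvalue = st$p[keep],
      n = n, stringsAsFactors = FALSE, row.names = NULL)
    truth <- list(rsid = snp_map$rsid, gamma = gamma, alpha = alpha,
                  causal = seq_len(m) %in% causal,
                  pleiotropic = seq_len(m) %in% pleio,
                  beta = config$beta_causal, seed = config$seed)
    list(exposure = mk(stats_x), outcome = mk(stats_y), truth = truth,
         phenotypes = list(x = X, y = Y))
  })
}

# Exact per-SNP simple OLS of y on each (centred) dosage column.
marginal_ols <- function(G, y) {
  n <- nrow(G)
  yc <- y - mean(y)
  gm <- colMeans(G)
  ss_g <- colSums(G^2) - n * gm^2
  mono <- ss_g <= 0
  ss_g[mono] <- NA_real_
  b <- (crossprod(G, yc)[, 1]) / ss_g
  rss <- sum(yc^2) - b^2 * ss_g
  sigma2 <- pmax(rss, 0) / (n - 2)
  se <- sqrt(sigma2 / ss_g)
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  p[p == 0] <- 1e-300
  list(beta = b, se = se, p = p, mono = mono)
}

#' Per-SNP association scan of an arbitrary phenotype
#'
#' Marginal OLS of a phenotype vector on every dosage column of a panel,
#' returning a canonical association table. Useful for composing custom
#' scenarios (e.g. a linkage scenario where expression and outcome are
#' driven by different variants) on top of a generated panel.
#'
#' @param panel A dosage-backed `ld_panel`.
#' @param y Phenotype vector, one value per panel individual.
#' @return Association table (monomorphic SNPs dropped with a warning).
#' @export
assoc_scan <- function(panel, y) {
  stopifnot(panel$type == "dosage", length(y) == nrow(panel$dosages))
  G <- panel$dosages
  st <- marginal_ols(G, y)
  keep <- !st$mono
  if (any(st$mono))
    warnf("%d monomorphic SNP(s) dropped", sum(st$mono))
  info <- panel$snp_info
  data.frame(
    rsid = colnames(G)[keep],
    chrom = if (!is.null(info)) info$chrom[keep] else NA_character_,
    pos = if (!is.null(info)) info$pos[keep] else NA_integer_,
    effect_allele = "A", other_allele = "G",
    eaf = colMeans(G)[keep] / 2,
    beta = st$beta[keep], se = st$se[keep], pvalue = st$p[keep],
    n = nrow(G), stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate an RNAm catalogue with enrichment at causal SNPs
#'
#' Flags each SNP as RNA-modification-related with probability
#' `rnam_base_rate`, multiplied by `rnam_enrichment` at causal SNPs
#' (capped at 1). Modification type, confidence, gain/loss and region are
#' drawn from fixed categorical distributions (m6A-dominated, mirroring
#' the composition of public RNAm-SNP catalogues).
#'
#' @param snp_list Character vector of rsids in the universe.
#' @param truth Truth record from [gen_summary_stats()] (aligned to
#'   `snp_list` via its `rsid` field); its `causal` flags receive the
#'   enriched rate.
#' @param config A [sim_config()].
#' @return Catalogue data.frame; attribute `rnam_flags` is the logical
#'   flag vector aligned to `snp_list`, attribute `probs` the categorical
#'   distributions used.
#' @export
gen_rnam_catalogue <- function(snp_list, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  causal <- truth$causal[match(snp_list, truth$rsid)]
  causal[is.na(causal)] <- FALSE
  rate <- ifelse(causal,
                 pmin(1, config$rnam_base_rate * config$rnam_enrichment),
                 config$rnam_base_rate)
  probs <- list(
    mod_type = c(m6A = 0.85, m1A = 0.06, `A-to-I` = 0.04, m7G = 0.02,
                 m5C = 0.015, m5U = 0.005, m6Am = 0.005, `2'-O-Me` = 0.003,
                 pseudouridine = 0.002),
    confidence = c(high = 0.42, medium = 0.25, low = 0.33),
    effect = c(gain = 0.14, loss = 0.86),
    gene_type = c(protein_coding = 0.85, noncoding = 0.15),
    region = c(exonic = 0.29, `3'UTR` = 0.20, `5'UTR` = 0.05,
               intronic = 0.46)
  )
  with_seed(config$seed + 2L, {
    flags <- stats::runif(length(snp_list)) < rate
    k <- sum(flags)
    draw <- function(p, k) sample(names(p), k, replace = TRUE, prob = p)
    cat <- data.frame(
      rsid = snp_list[flags],
      mod_type = draw(probs$mod_type, k),
      confidence = draw(probs$confidence, k),
      effect = draw(probs$effect, k),
      gene = paste0("GENE", which(flags)),
      gene_type = draw(probs$gene_type, k),
      region = draw(probs$region, k),
      stringsAsFactors = FALSE)
    attr(cat, "rnam_flags") <- flags
    attr(cat, "probs") <- probs
    cat
  })
}

#' Generate a cis-QTL summary table for one target
#'
#' Reuses the structural-model machinery with the exposure playing the
#' role of expression or protein level; the target's TSS is placed at the
#' causal block so simulated signals are cis.
#'
#' @param panel An `ld_panel`.
#' @param config A [sim_config()].
#' @param target_id Gene or protein identifier.
#' @param tissue_or_study Label for the QTL study/tissue column.
#' @return List with `qtl` (QTL table) and `truth`.
#' @export
gen_qtl_table <- function(panel, config, target_id = "GENE1",
                          tissue_or_study = "synthetic") {
  ss <- gen_summary_stats(panel, config)
  causal_idx <- which(ss$truth$causal)
  info <- panel$snp_info
  anchor <- if (length(causal_idx)) causal_idx[[1]] else 1L
  qtl <- data.frame(
    rsid = ss$exposure$rsid,
    target_id = target_id,
    target_chrom = info$chrom[[anchor]],
    target_tss = info$pos[[anchor]],
    beta = ss$exposure$beta,
    se = ss$exposure$se,
    pvalue = ss$exposure$pvalue,
    tissue_or_study = tissue_or_study,
    stringsAsFactors = FALSE)
  list(qtl = qtl, truth = ss$truth)
}

#' Simulate and write a complete input bundle
#'
#' Writes every file the pipeline reads: outcome GWAS, exposure summary
#' statistics, a cis-QTL table, the RNAm catalogue, the LD dosage matrix
#' and a JSON truth record.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
simulate_bundle <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- gen_ld_panel(config)
  ss <- gen_summary_stats(panel, config)
  cat <- gen_rnam_catalogue(ss$truth$rsid, ss$truth, config)
  qtl <- gen_qtl_table(panel, config)
  paths <- c(
    gwas = file.path(out_dir, "gwas.tsv"),
    exposure = file.path(out_dir, "exposure.tsv"),
    qtl = file.path(out_dir, "qtl.tsv"),
    catalogue = file.path(out_dir, "catalogue.tsv"),
    ld_panel = file.path(out_dir, "ld_panel.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_tsv(ss$outcome, paths[["gwas"]])
  write_tsv(ss$exposure, paths[["exposure"]])
  write_tsv(qtl$qtl, paths[["qtl"]])
  write_tsv(cat, paths[["catalogue"]])
  write_ld_panel(panel, paths[["ld_panel"]])
  truth <- ss$truth
  truth$rnam_flags <- as.logical(attr(cat, "rnam_flags"))
  truth$config <- unclass(config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
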