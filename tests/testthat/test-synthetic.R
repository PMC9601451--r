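test_that("generators are deterministic under a fixed config and seed", {
  cfg <- sim_config(n_individuals = 200, n_blocks = 3, snps_per_block = 4,
                    n_causal = 3, seed = 11)
  p1 <- gen_ld_panel(cfg)
  p2 <- gen_ld_panel(cfg)
  expect_identical(p1$dosages, p2$dosages)
  s1 <- gen_summary_stats(p1, cfg)
  s2 <- gen_summary_stats(p2, cfg)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$truth$gamma, s2$truth$gamma)
  c1 <- gen_rnam_catalogue(s1$truth$rsid, s1$truth, cfg)
  c2 <- gen_rnam_catalogue(s2$truth$rsid, s2$truth, cfg)
  expect_identical(c1, c2)
})

test_that("rho = 0 gives independent adjacent SNPs, rho = 0.9 is recovered", {
  cfg0 <- sim_config(n_individuals = 2000, n_blocks = 10,
                     snps_per_block = 4, rho = 0, n_causal = 5, seed = 3)
  panel0 <- gen_ld_panel(cfg0)
  adj_r <- sapply(seq_len(10), function(b) {
    i <- (b - 1) * 4 + 1
    cor(panel0$dosages[, i], panel0$dosages[, i + 1])
  })
  expect_lt(mean(abs(adj_r)), 0.05)

  cfg9 <- sim_config(n_individuals = 5000, n_blocks = 4, snps_per_block = 5,
                     rho = 0.9, n_causal = 4, seed = 5)
  panel9 <- gen_ld_panel(cfg9, keep_latent = TRUE)
  lat <- panel9$latent$h1
  adj <- sapply(seq_len(4), function(b) {
    i <- (b - 1) * 5 + 1
    mean(sapply(1:4, function(k) cor(lat[, i + k - 1], lat[, i + k])))
  })
  expect_true(all(abs(adj - 0.9) < 0.05))
  # cross-block latent correlation is zero in expectation
  expect_lt(abs(cor(lat[, 5], lat[, 6])), 0.05)
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(heritability_x = 1), "heritability_x")
  expect_error(sim_config(rnam_enrichment = 0.5), "rnam_enrichment")
  cfg <- sim_config(n_individuals = 100, n_blocks = 2, snps_per_block = 2,
                    n_causal = 10, seed = 1)
  expect_error(gen_summary_stats(gen_ld_panel(cfg), cfg), "n_causal")
})

test_that("null SNP z-scores are standard normal and null exposure has no hits", {
  # heritability 0: the exposure is pure noise, so every SNP is null.
  cfg <- sim_config(n_individuals = 2000, n_blocks = 250,
                    snps_per_block = 4, rho = 0.5, n_causal = 10,
                    heritability_x = 0, beta_causal = 0.3, seed = 8)
  panel <- gen_ld_panel(cfg)
  ss <- gen_summary_stats(panel, cfg)
  expect_equal(sum(ss$exposure$pvalue < 5e-8), 0)
  z <- ss$exposure$beta / ss$exposure$se
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("realized exposure heritability matches the configured value", {
  cfg <- sim_config(n_individuals = 50000, n_blocks = 20,
                    snps_per_block = 2, n_causal = 20,
                    heritability_x = 0.3, seed = 13)
  panel <- gen_ld_panel(cfg)
  ss <- gen_summary_stats(panel, cfg)
  u <- as.vector(panel$dosages %*% ss$truth$gamma)
  # the genetic component's sample variance is h2 exactly by the scaling
  expect_equal(stats::var(u), 0.3, tolerance = 1e-9)
  # realized R^2 of the genetic component against the exposure
  r2 <- stats::cor(u, ss$phenotypes$x)^2
  expect_equal(r2, 0.3, tolerance = 0.02)
})

test_that("catalogue flag rates respect base rate and enrichment", {
  truth <- list(rsid = paste0("rs", 1:10000),
                causal = c(rep(TRUE, 3000), rep(FALSE, 7000)))
  cfg <- sim_config(rnam_base_rate = 0.01, rnam_enrichment = 5, seed = 21)
  cat_tab <- gen_rnam_catalogue(truth$rsid, truth, cfg)
  flags <- attr(cat_tab, "rnam_flags")
  rate_causal <- mean(flags[1:3000])
  rate_null <- mean(flags[3001:10000])
  # binomial 99.9% bands around 0.05 and 0.01
  expect_lt(abs(rate_causal - 0.05), 3.3 * sqrt(0.05 * 0.95 / 3000))
  expect_lt(abs(rate_null - 0.01), 3.3 * sqrt(0.01 * 0.99 / 7000))
  expect_true(all(cat_tab$mod_type %in% rnamodmr:::MOD_TYPES))
  expect_equal(nrow(cat_tab), sum(flags))
})

test_that("enrichment = 1 leaves causal and non-causal flag rates equal", {
  n_reject <- 0
  for (seed in 1:40) {
    truth <- list(rsid = paste0("rs", 1:4000),
                  causal = rep(c(TRUE, FALSE), c(1000, 3000)))
    cfg <- sim_config(rnam_base_rate = 0.1, rnam_enrichment = 1, seed = seed)
    flags <- attr(gen_rnam_catalogue(truth$rsid, truth, cfg), "rnam_flags")
    p <- stats::prop.test(c(sum(flags[1:1000]), sum(flags[1001:4000])),
                          c(1000, 3000))$p.value
    if (p < 0.01) n_reject <- n_reject + 1
  }
  expect_lte(n_reject, 4)
})

test_that("under a null causal effect the downstream IVW CI covers zero", {
  covered <- vapply(1:100, function(s) {
    cfg <- sim_config(n_individuals = 10000, n_blocks = 30,
                      snps_per_block = 1, n_causal = 30,
                      heritability_x = 0.3, beta_causal = 0,
                      pleiotropy_fraction = 0, seed = 3000 + s)
    panel <- gen_ld_panel(cfg)
    ss <- gen_summary_stats(panel, cfg)
    cand <- suppressWarnings(select_instruments(ss$exposure, 5e-4))
    instr <- instrument_subset(harmonize(cand, ss$outcome))
    iv <- mr_ivw(instr)
    iv$ci95[[1]] <= 0 && iv$ci95[[2]] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.88)
})

test_that("simulate_bundle writes a readable, internally consistent bundle", {
  cfg <- sim_config(n_individuals = 500, n_blocks = 5, snps_per_block = 3,
                    n_causal = 5, rnam_base_rate = 0.3, seed = 20221018)
  dir <- tempfile()
  paths <- suppressWarnings(simulate_bundle(cfg, dir))
  expect_true(all(file.exists(paths)))
  g <- suppressWarnings(read_gwas(paths[["gwas"]]))
  e <- suppressWarnings(read_gwas(paths[["exposure"]]))
  expect_equal(g$rsid, e$rsid)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(length(truth$gamma), 15)
  expect_equal(truth$beta, cfg$beta_causal)
  cat_tab <- read_rnam_catalogue(paths[["catalogue"]])
  expect_equal(sort(unique(cat_tab$rsid)),
               sort(unique(truth$rsid[truth$rnam_flags])))
  panel <- read_ld_panel(paths[["ld_panel"]])
  expect_equal(ncol(panel$dosages), 15)
})
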