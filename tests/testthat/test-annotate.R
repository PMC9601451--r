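make_catalogue <- function(rsid, mod_type = "m6A", confidence = "high",
                           effect = "loss", gene = "GENE1",
                           gene_type = "protein_coding", region = "exonic") {
  n <- length(rsid)
  data.frame(rsid = rsid, mod_type = rep_len(mod_type, n),
             confidence = rep_len(confidence, n),
             effect = rep_len(effect, n), gene = rep_len(gene, n),
             gene_type = rep_len(gene_type, n),
             region = rep_len(region, n), stringsAsFactors = FALSE)
}

test_that("annotation is an inner join with a strict significance gate", {
  gwas <- make_assoc(c("rs1", "rs2", "rs3"), c(1e-9, 5e-8, 0.2))
  cat_tab <- make_catalogue(c("rs1", "rs2", "rs4"))
  ann <- annotate_gwas(gwas, cat_tab)
  expect_equal(sort(ann$rsid), c("rs1", "rs2"))  # rs4 not in GWAS
  expect_true(ann$significant[ann$rsid == "rs1"])
  expect_false(ann$significant[ann$rsid == "rs2"])  # p exactly 5e-8
  expect_warning(annotate_gwas(gwas, make_catalogue("rs99")), "no rsids")
})

test_that("a multi-type SNP contributes one row per modification type", {
  gwas <- make_assoc("rs1", 1e-9)
  cat_tab <- rbind(make_catalogue("rs1", "m6A"), make_catalogue("rs1", "m5C"))
  ann <- annotate_gwas(gwas, cat_tab)
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$mod_type, c("m6A", "m5C"))
})

test_that("per-type summary formats counts and half-up percentages", {
  ann <- data.frame(
    mod_type = rep("m6A", 400),
    significant = rep(c(TRUE, FALSE), c(5, 395)))
  s <- summarize_by_type(ann)
  expect_equal(s$n_total, 400)
  expect_equal(s$n_significant, 5)
  expect_equal(s$pct_significant, 1.25)
  expect_equal(s$label, "5 (1.25%)")
  # zero significant
  ann0 <- data.frame(mod_type = "m7G", significant = FALSE)
  expect_equal(summarize_by_type(ann0)$label, "0 (0.00%)")
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-1.25, 1), -1.3)
  expect_equal(round_half_up(2.675, 2), 2.68)
})

test_that("classification tallies count SNPs once and regions on coding genes", {
  gwas <- make_assoc(paste0("rs", 1:10), rep(1e-9, 10))
  cat_tab <- rbind(
    make_catalogue(paste0("rs", 1:4), effect = "gain", confidence = "high",
                   region = "exonic"),
    make_catalogue(paste0("rs", 5:8), effect = "loss", confidence = "low",
                   region = "intronic"),
    make_catalogue(paste0("rs", 9:10), effect = "loss",
                   confidence = "medium", gene_type = "noncoding",
                   region = "other"),
    make_catalogue("rs1", mod_type = "m5C", effect = "gain",
                   confidence = "high"))  # second type: not double-counted
  ann <- annotate_gwas(gwas, cat_tab)
  tl <- tally_classifications(ann)
  expect_equal(attr(tl, "n_snps"), 10)
  gain <- tl[tl$dimension == "effect" & tl$level == "gain", ]
  expect_equal(gain$count, 4)
  expect_equal(gain$denominator, 10)
  expect_equal(gain$pct, 40)
  # regions restricted to protein-coding genes (8 of 10 SNPs)
  exonic <- tl[tl$dimension == "region_protein_coding" &
                 tl$level == "exonic", ]
  expect_equal(exonic$denominator, 8)
  expect_equal(exonic$count, 4)
  expect_equal(exonic$pct, 50)
})

test_that("locus chaining matches a brute-force transitive closure", {
  brute_force_loci <- function(pos, window_bp) {
    # transitive closure of the pairwise <= window relation on sorted SNPs
    n <- length(pos)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (abs(pos[i] - pos[j]) <= window_bp && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    comp
  }
  set.seed(99)
  for (rep in 1:5) {
    pos <- sort(sample.int(5e6, 20))
    snps <- make_assoc(paste0("rs", 1:20), rep(1e-9, 20), pos = pos)
    loci <- cluster_loci(snps, window_kb = 500)
    comp <- brute_force_loci(pos, 5e5)
    expect_equal(nrow(loci), length(unique(comp)))
    # membership partition matches
    got <- lapply(strsplit(loci$members, ","), sort)
    want <- lapply(split(paste0("rs", 1:20), comp), sort)
    expect_setequal(got, unname(want))
    # every significant SNP in exactly one locus
    expect_equal(sort(unlist(strsplit(loci$members, ","))),
                 sort(paste0("rs", 1:20)))
  }
})

test_that("locus windows and lead-SNP tie-breaks behave", {
  one <- cluster_loci(make_assoc("rs1", 1e-9, pos = 100))
  expect_equal(nrow(one), 1)
  two <- cluster_loci(make_assoc(c("rs1", "rs2"), rep(1e-9, 2),
                                 pos = c(1e6, 3e6)), window_kb = 1000)
  expect_equal(nrow(two), 2)
  tie <- cluster_loci(make_assoc(c("rs1", "rs2"), c(1e-9, 1e-9),
                                 pos = c(2000, 1000)))
  expect_equal(tie$lead_rsid, "rs2")  # equal p: smaller position leads
})

test_that("QTL linking applies the signal gate and cis/trans window", {
  ann <- data.frame(rsid = c("rs1", "rs2", "rs3"), chrom = c("1", "1", "2"),
                    pos = c(1e6, 2e6, 1e6), stringsAsFactors = FALSE)
  qtl <- data.frame(
    rsid = c("rs1", "rs1", "rs2", "rs3"),
    target_id = c("G1", "G2", "G3", "G4"),
    target_chrom = c("1", "2", "1", "1"),
    target_tss = c(1.5e6, 1e6, NA, 1e6),
    beta = 0.1, se = 0.02,
    pvalue = c(1e-6, 1e-6, 1e-6, 0.5),
    tissue_or_study = "blood", stringsAsFactors = FALSE)
  expect_warning(links <- link_qtl(ann, qtl, cis_window_kb = 1000,
                                   p_signal = 5e-5), "unknown")
  expect_equal(nrow(links), 3)  # rs3's QTL fails the signal gate
  expect_equal(links$cis_trans[links$target_id == "G1"], "cis")    # 500 kb
  expect_equal(links$cis_trans[links$target_id == "G2"], "trans")  # other chrom
  expect_equal(links$cis_trans[links$target_id == "G3"], "unknown")
})

test_that("manual filter oracle on a 12-row QTL fixture", {
  set.seed(7)
  pvals <- 10^stats::runif(12, -8, 0)
  ann <- data.frame(rsid = paste0("rs", 1:12), chrom = "1",
                    pos = seq_len(12) * 1e5, stringsAsFactors = FALSE)
  qtl <- data.frame(rsid = paste0("rs", 1:12), target_id = "G",
                    target_chrom = "1", target_tss = 1e5, beta = 0.1,
                    se = 0.02, pvalue = pvals, tissue_or_study = "s",
                    stringsAsFactors = FALSE)
  links <- link_qtl(ann, qtl, p_signal = 5e-5)
  expect_equal(nrow(links), sum(pvals < 5e-5))
})
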