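# Annotation stage: join GWAS summary statistics with the RNAm-SNP
# catalogue, gate at genome-wide significance, tabulate by modification
# type / confidence / gain-loss / region, chain significant SNPs into
# loci, and link annotated SNPs to QTL signals.

#' Annotate GWAS summary statistics with the RNAm catalogue
#'
#' Inner join on rsid: one output row per (rsid, mod_type) pair, carrying
#' both the association statistics and the catalogue fields, plus a
#' `significant` flag set by strict comparison `pvalue < p_threshold`.
#'
#' @param gwas Association table (see [read_gwas()]).
#' @param catalogue Catalogue table (see [read_rnam_catalogue()]).
#' @param p_threshold Genome-wide significance level; the gate is strict.
#' @return Annotated data.frame; empty (with a warning) if the tables
#'   share no rsids.
#' @export
annotate_gwas <- function(gwas, catalogue, p_threshold = 5e-8) {
  assert_prob(p_threshold, "p_threshold", open_lower = TRUE)
  out <- merge(gwas, catalogue, by = "rsid", sort = FALSE)
  if (nrow(out) == 0) {
    warnf("no rsids shared between GWAS and catalogue")
  }
  out$significant <- out$pvalue < p_threshold
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos, out$rsid,
                   out$mod_type), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Per-modification-type summary of significant RNAm-SNPs
#'
#' For each modification type: the number of catalogue SNPs found in the
#' GWAS, the number significant, and the percentage (rounded half-up to
#' two decimals) formatted `"N (P%)"`.
#'
#' @param annotated Output of [annotate_gwas()].
#' @return Data.frame with columns `mod_type`, `n_total`, `n_significant`,
#'   `pct_significant`, `label`.
#' @export
summarize_by_type <- function(annotated) {
  types <- unique(annotated$mod_type)
  rows <- lapply(types, function(tp) {
    sub <- annotated[annotated$mod_type == tp, , drop = FALSE]
    n_tot <- nrow(sub)
    n_sig <- sum(sub$significant)
    pct <- if (n_tot > 0) round_half_up(100 * n_sig / n_tot, 2) else NA_real_
    data.frame(mod_type = tp, n_total = n_tot, n_significant = n_sig,
               pct_significant = pct,
               label = sprintf("%d (%.2f%%)", n_sig, pct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_total), , drop = FALSE]
  rownames(out) <- NULL
  check_summary_consistency(out$n_significant, out$n_total,
                            out$pct_significant, 2)
  out
}

# Internal consistency check run on every printed summary: percentages
# must recompute exactly from their counts.
check_summary_consistency <- function(k, n, pct, digits) {
  recompute <- ifelse(n > 0, round_half_up(100 * k / n, digits), NA_real_)
  bad <- !is.na(pct) & !is.na(recompute) & abs(pct - recompute) > 1e-9
  if (any(bad))
    stopf("internal error: summary percentage does not recompute from counts")
  invisible(TRUE)
}

#' Tally gain/loss, confidence, and region classifications
#'
#' Counts and percentages (one decimal, half-up) for functional
#' gain/loss, the three confidence tiers and — restricted to SNPs in
#' protein-coding genes — the region classes. A SNP carrying several
#' modification types is counted once per classification (deduplicated
#' on rsid, keeping the first record); the per-type view is
#' [summarize_by_type()]'s job.
#'
#' @param annotated Output of [annotate_gwas()].
#' @param significant_only Restrict to genome-wide-significant rows.
#' @return Data.frame with `dimension`, `level`, `count`, `denominator`,
#'   `pct`.
#' @export
tally_classifications <- function(annotated, significant_only = TRUE) {
  df <- annotated
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  dedup <- df[!duplicated(df$rsid), , drop = FALSE]
  n_all <- nrow(dedup)

  tally_one <- function(values, levels, dimension, denom) {
    counts <- vapply(levels, function(l) sum(values == l, na.rm = TRUE),
                     integer(1))
    pct <- if (denom > 0) round_half_up(100 * counts / denom, 1) else
      rep(NA_real_, length(levels))
    data.frame(dimension = dimension, level = levels,
               count = as.integer(counts), denominator = denom, pct = pct,
               stringsAsFactors = FALSE)
  }
  pc <- dedup[!is.na(dedup$gene_type) & dedup$gene_type == "protein_coding", ,
              drop = FALSE]
  out <- rbind(
    tally_one(dedup$effect, EFFECT_LEVELS, "effect", n_all),
    tally_one(dedup$confidence, CONFIDENCE_LEVELS, "confidence", n_all),
    tally_one(pc$region, REGION_LEVELS, "region_protein_coding", nrow(pc)))
  rownames(out) <- NULL
  check_summary_consistency(out$count, out$denominator, out$pct, 1)
  attr(out, "n_snps") <- n_all
  attr(out, "n_rows") <- nrow(df)
  out
}

#' Chain significant SNPs into loci
#'
#' Single-linkage chaining per chromosome: consecutive significant SNPs
#' at most `window_kb` apart join the same locus. The lead SNP is the
#' smallest p-value (ties broken by smaller position).
#'
#' @param snps Data.frame with `rsid`, `chrom`, `pos`, `pvalue` (usually
#'   the significant subset of an annotated table); duplicated rsids
#'   (multi-type SNPs) are collapsed first.
#' @param window_kb Chaining window in kilobases.
#' @return Data.frame of loci: `chrom`, `start`, `end`, `n_snps`,
#'   `lead_rsid`, `lead_pvalue`, `members` (comma-separated, position
#'   order).
#' @export
cluster_loci <- function(snps, window_kb = 1000) {
  df <- snps[!duplicated(snps$rsid), c("rsid", "chrom", "pos", "pvalue")]
  if (nrow(df) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      lead_rsid = character(0), lead_pvalue = numeric(0),
                      members = character(0), stringsAsFactors = FALSE))
  window_bp <- window_kb * 1000
  res <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos, sub$rsid), , drop = FALSE]
    gap <- c(FALSE, diff(sub$pos) > window_bp)
    sub$locus <- cumsum(gap)
    for (lid in unique(sub$locus)) {
      mem <- sub[sub$locus == lid, , drop = FALSE]
      lead <- mem[order(mem$pvalue, mem$pos), , drop = FALSE][1, ]
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = min(mem$pos), end = max(mem$pos),
        n_snps = nrow(mem), lead_rsid = lead$rsid,
        lead_pvalue = lead$pvalue,
        members = paste(mem$rsid, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Link annotated SNPs to QTL signals with cis/trans labels
#'
#' Joins on rsid, keeps QTL rows with `pvalue < p_signal` (strict), and
#' labels each surviving pair cis if SNP and target share a chromosome
#' and lie within `cis_window_kb` of the target TSS, trans otherwise.
#' Rows lacking a target TSS (or SNP position) are labelled `"unknown"`
#' with a warning.
#'
#' @param annotated Output of [annotate_gwas()] (deduplicated on rsid
#'   before joining).
#' @param qtl QTL table (see [read_qtl()]).
#' @param cis_window_kb Window around the target TSS, kilobases.
#' @param p_signal QTL signal threshold (strict).
#' @return Data.frame of linked signals with a `cis_trans` column.
#' @export
link_qtl <- function(annotated, qtl, cis_window_kb = 1000, p_signal = 5e-5) {
  assert_prob(p_signal, "p_signal", open_lower = TRUE)
  snps <- annotated[!duplicated(annotated$rsid),
                    c("rsid", "chrom", "pos"), drop = FALSE]
  hits <- qtl[qtl$pvalue < p_signal, , drop = FALSE]
  out <- merge(snps, hits, by = "rsid", sort = FALSE)
  if (nrow(out) == 0) {
    out$cis_trans <- character(0)
    return(out)
  }
  window_bp <- cis_window_kb * 1000
  known <- !is.na(out$target_tss) & !is.na(out$pos) &
    !is.na(out$target_chrom) & !is.na(out$chrom)
  if (any(!known))
    warnf("%d QTL link(s) lack positions; labelled 'unknown'", sum(!known))
  cis <- known & out$chrom == out$target_chrom &
    abs(out$pos - out$target_tss) <= window_bp
  out$cis_trans <- ifelse(known, ifelse(cis, "cis", "trans"), "unknown")
  out <- out[order(out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
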