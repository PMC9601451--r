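# Instrument construction for two-sample MR: p-value selection of
# candidate instruments, exposure/outcome allele harmonization, and
# greedy LD clumping to quasi-independence.

#' Select candidate instruments by exposure p-value
#'
#' @param exposure Association table.
#' @param p_instrument Inclusion threshold (strict: `pvalue <
#'   p_instrument`).
#' @return Subset of the exposure table (warning if empty).
#' @export
select_instruments <- function(exposure, p_instrument = 5e-4) {
  assert_prob(p_instrument, "p_instrument", open_lower = TRUE)
  out <- exposure[exposure$pvalue < p_instrument, , drop = FALSE]
  if (nrow(out) == 0) warnf("no SNP passes the instrument p-value threshold")
  rownames(out) <- NULL
  out
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two studies to a common effect allele per SNP. Matching
#' orientations are kept; swapped alleles flip the outcome beta's sign
#' and complement its allele frequency; strand flips (complemented
#' alleles) are resolved the same way. Palindromic SNPs (A/T or C/G)
#' whose allele frequency lies within `0.5 +/- palindromic_eaf_band` in
#' either study — or is missing — are dropped as strand-ambiguous;
#' `strict_palindromic = TRUE` drops every palindromic SNP. Irreconcilable
#' allele sets are dropped as mismatches. Drops are recorded, never
#' raised.
#'
#' @param exposure,outcome Association tables sharing rsids.
#' @param palindromic_eaf_band Half-width of the ambiguous frequency band
#'   around 0.5.
#' @param strict_palindromic Drop all palindromic SNPs regardless of
#'   frequency.
#' @return Instrument table: `rsid`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `pvalue_exposure`, `beta_outcome`,
#'   `se_outcome`, `pvalue_outcome`, `eaf`, `chrom`, `pos`,
#'   `harmonization_action`. Dropped rows stay in the table with their
#'   action label; [instrument_subset()] extracts the usable rows.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_band = 0.08,
                      strict_palindromic = FALSE) {
  exp_df <- exposure[!duplicated(exposure$rsid), , drop = FALSE]
  out_df <- outcome[!duplicated(outcome$rsid), , drop = FALSE]
  shared <- intersect(exp_df$rsid, out_df$rsid)
  e <- exp_df[match(shared, exp_df$rsid), , drop = FALSE]
  o <- out_df[match(shared, out_df$rsid), , drop = FALSE]
  n <- length(shared)
  action <- character(n)
  beta_o <- o$beta
  eaf_o <- o$eaf
  for (i in seq_len(n)) {
    ea_e <- e$effect_allele[[i]]; oa_e <- e$other_allele[[i]]
    ea_o <- o$effect_allele[[i]]; oa_o <- o$other_allele[[i]]
    pal <- is_palindromic(ea_e, oa_e)
    if (pal) {
      ambiguous <- strict_palindromic ||
        is.na(e$eaf[[i]]) || is.na(o$eaf[[i]]) ||
        abs(e$eaf[[i]] - 0.5) <= palindromic_eaf_band ||
        abs(o$eaf[[i]] - 0.5) <= palindromic_eaf_band
      if (ambiguous) {
        action[[i]] <- "dropped_palindromic"
        next
      }
      # Allele labels cannot orient a palindrome; use frequency concordance.
      same_side <- (e$eaf[[i]] - 0.5) * (o$eaf[[i]] - 0.5) > 0
      action[[i]] <- if (same_side) "kept" else "flipped"
      if (action[[i]] == "flipped") {
        beta_o[[i]] <- -beta_o[[i]]
        if (!is.na(eaf_o[[i]])) eaf_o[[i]] <- 1 - eaf_o[[i]]
      }
      next
    }
    # Try direct, swapped, strand-complemented, and complemented-swapped.
    if (ea_o == ea_e && oa_o == oa_e) {
      action[[i]] <- "kept"
    } else if (ea_o == oa_e && oa_o == ea_e) {
      action[[i]] <- "flipped"
    } else if (!pal && COMPLEMENT[[ea_o]] == ea_e &&
               COMPLEMENT[[oa_o]] == oa_e) {
      action[[i]] <- "kept"
    } else if (!pal && COMPLEMENT[[ea_o]] == oa_e &&
               COMPLEMENT[[oa_o]] == ea_e) {
      action[[i]] <- "flipped"
    } else {
      action[[i]] <- "dropped_mismatch"
      next
    }
    if (action[[i]] == "flipped") {
      beta_o[[i]] <- -beta_o[[i]]
      if (!is.na(eaf_o[[i]])) eaf_o[[i]] <- 1 - eaf_o[[i]]
    }
  }
  res <- data.frame(
    rsid = shared,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    beta_exposure = e$beta, se_exposure = e$se, pvalue_exposure = e$pvalue,
    beta_outcome = beta_o, se_outcome = o$se, pvalue_outcome = o$pvalue,
    eaf = e$eaf,
    chrom = if ("chrom" %in% names(e)) e$chrom else NA_character_,
    pos = if ("pos" %in% names(e)) e$pos else NA_integer_,
    harmonization_action = action,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Usable rows of a harmonized instrument table
#' @param harmonized Output of [harmonize()].
#' @return Rows with action `kept` or `flipped`.
#' @export
instrument_subset <- function(harmonized) {
  out <- harmonized[harmonized$harmonization_action %in%
                      c("kept", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clumping configuration
#'
#' @param r2_threshold Pairwise r-squared above which SNPs are considered
#'   dependent.
#' @param window_kb Distance window (kb) within which r-squared is
#'   checked; SNPs further apart are treated as independent.
#' @param p_instrument Instrument inclusion threshold carried alongside.
#' @return List of class `clump_config`.
#' @export
clump_config <- function(r2_threshold = 0.001, window_kb = 10000,
                         p_instrument = 5e-4) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stopf("r2_threshold must lie in (0, 1]")
  if (window_kb <= 0) stopf("window_kb must be positive")
  structure(list(r2_threshold = r2_threshold,
                 window_kb = as.integer(window_kb),
                 p_instrument = p_instrument), class = "clump_config")
}

#' Greedy LD clumping of candidate instruments
#'
#' Sorts candidates by p-value (ties by position, then rsid), keeps the
#' head, removes every SNP within `window_kb` of a kept SNP with
#' r-squared at or above `r2_threshold`, and repeats. SNP pairs missing
#' from the LD panel are treated as uncorrelated with a warning.
#'
#' @param candidates Data.frame with `rsid`, `chrom`, `pos` and a
#'   p-value column (`pvalue` or `pvalue_exposure`).
#' @param ld An `ld_panel`.
#' @param config A [clump_config()].
#' @return The independent subset, in kept order.
#' @export
ld_clump <- function(candidates, ld, config = clump_config()) {
  pcol <- if ("pvalue" %in% names(candidates)) "pvalue" else "pvalue_exposure"
  if (!pcol %in% names(candidates))
    stopf("candidates need a `pvalue` or `pvalue_exposure` column")
  df <- candidates[!duplicated(candidates$rsid), , drop = FALSE]
  df <- df[order(df[[pcol]], df$pos, df$rsid), , drop = FALSE]
  window_bp <- config$window_kb * 1000
  kept <- logical(nrow(df))
  removed <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (removed[[i]]) next
    kept[[i]] <- TRUE
    if (i == nrow(df)) break
    rest <- which(!kept & !removed)
    rest <- rest[rest > i]
    if (!length(rest)) next
    same_chr <- df$chrom[rest] == df$chrom[[i]]
    near <- same_chr & abs(df$pos[rest] - df$pos[[i]]) <= window_bp
    if (any(near)) {
      r2 <- suppressWarnings(
        ld_r2(ld, df$rsid[[i]], df$rsid[rest[near]]))
      miss <- is.na(r2)
      if (any(miss)) {
        warnf("%d SNP pair(s) missing from LD panel treated as r2 = 0",
              sum(miss))
        r2[miss] <- 0
      }
      removed[rest[near][r2 >= config$r2_threshold]] <- TRUE
    }
  }
  out <- df[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}
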