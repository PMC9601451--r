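# Readers and writers for every delimited table the pipeline touches.
#
# Canonical in-memory representations are plain data.frames:
#   association table: rsid, chrom, pos, effect_allele, other_allele,
#                      eaf, beta, se, pvalue, n
#   catalogue table:   rsid, mod_type, confidence, effect, gene,
#                      gene_type, region
#   qtl table:         rsid, target_id, target_chrom, target_tss,
#                      beta, se, pvalue, tissue_or_study

GWAS_CANONICAL <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pvalue", "n")

# Common summary-statistic header dialects, tried when no column_map entry
# names the source column.
GWAS_ALIASES <- list(
  rsid = c("rsid", "SNP", "snp", "RSID", "MarkerName", "variant_id"),
  chrom = c("chrom", "CHR", "chr", "chromosome"),
  pos = c("pos", "BP", "bp", "position", "POS"),
  effect_allele = c("effect_allele", "A1", "a1", "EA", "allele1"),
  other_allele = c("other_allele", "A2", "a2", "OA", "NEA", "allele2"),
  eaf = c("eaf", "FRQ", "frq", "EAF", "freq", "af"),
  beta = c("beta", "BETA", "b", "effect"),
  se = c("se", "SE", "stderr", "standard_error"),
  pvalue = c("pvalue", "P", "p", "pval", "p_value", "PVAL"),
  n = c("n", "N", "samplesize")
)

read_delim_table <- function(path, delim = "\t") {
  utils::read.table(path, header = TRUE, sep = delim, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

resolve_columns <- function(header, column_map, aliases, mandatory) {
  out <- list()
  for (field in names(aliases)) {
    src <- column_map[[field]]
    if (is.null(src)) {
      hit <- aliases[[field]][aliases[[field]] %in% header]
      src <- if (length(hit)) hit[[1]] else NA_character_
    }
    if (!is.na(src) && !src %in% header) src <- NA_character_
    out[[field]] <- src
  }
  missing <- mandatory[vapply(out[mandatory], is.na, logical(1))]
  if (length(missing))
    stopf("missing mandatory column(s): %s", paste(missing, collapse = ", "))
  out
}

#' Read GWAS (or any association) summary statistics
#'
#' Parses a delimited summary-statistics file into the canonical
#' association table. Rows violating hard invariants (non-positive
#' standard error, identical or non-ACGT alleles, p-value outside (0, 1])
#' are rejected with row-numbered diagnostics; a p-value of exactly 0 is
#' clamped to 1e-300 with a warning rather than rejected. Allele strings
#' are uppercased. Rows whose |beta/se| z-score disagrees with the stated
#' p-value by more than a factor of 10 trigger a warning, not rejection.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named list/character vector mapping canonical field
#'   names (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n`) to source column names. Unmapped
#'   fields are resolved against common header dialects (SNP/CHR/BP/...).
#' @param delim Field delimiter, tab by default.
#' @return A data.frame with the canonical columns; attribute `n_rejected`
#'   holds the rejected-row count and attribute `rejections` a character
#'   vector of row-numbered reasons.
#' @export
read_gwas <- function(path, column_map = list(), delim = "\t") {
  raw <- read_delim_table(path, delim)
  cols <- resolve_columns(names(raw), column_map, GWAS_ALIASES,
                          mandatory = c("rsid", "beta", "se", "pvalue"))
  n_in <- nrow(raw)
  df <- data.frame(
    rsid = as.character(raw[[cols$rsid]]),
    chrom = if (!is.na(cols$chrom)) as.character(raw[[cols$chrom]]) else NA_character_,
    pos = if (!is.na(cols$pos)) as.integer(raw[[cols$pos]]) else NA_integer_,
    effect_allele = if (!is.na(cols$effect_allele))
      toupper(as.character(raw[[cols$effect_allele]])) else NA_character_,
    other_allele = if (!is.na(cols$other_allele))
      toupper(as.character(raw[[cols$other_allele]])) else NA_character_,
    eaf = if (!is.na(cols$eaf)) as.numeric(raw[[cols$eaf]]) else NA_real_,
    beta = as.numeric(raw[[cols$beta]]),
    se = as.numeric(raw[[cols$se]]),
    pvalue = as.numeric(raw[[cols$pvalue]]),
    n = if (!is.na(cols$n)) as.integer(raw[[cols$n]]) else NA_integer_,
    stringsAsFactors = FALSE
  )
  validate_association(df, n_input = n_in)
}

#' Validate an association table
#'
#' Applies the hard row invariants of the canonical association schema to
#' an already-assembled data.frame (used by [read_gwas()] and accepted
#' anywhere the pipeline takes association input).
#'
#' @param df Data.frame with at least rsid, beta, se, pvalue.
#' @param n_input Input row count used for the bookkeeping identity.
#' @return The validated table with rejection attributes (see [read_gwas()]).
#' @export
validate_association <- function(df, n_input = nrow(df)) {
  for (col in GWAS_CANONICAL)
    if (!col %in% names(df)) df[[col]] <- NA
  df <- df[GWAS_CANONICAL]
  if (any(df$pvalue == 0, na.rm = TRUE)) {
    warnf("%d p-value(s) of exactly 0 clamped to 1e-300",
          sum(df$pvalue == 0, na.rm = TRUE))
    df$pvalue[!is.na(df$pvalue) & df$pvalue == 0] <- 1e-300
  }
  reasons <- character(0)
  bad <- rep(FALSE, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    if (any(cond))
      reasons <<- c(reasons, sprintf("row %d: %s", which(cond), why))
    bad <<- bad | cond
  }
  flag(is.na(df$rsid) | df$rsid == "", "missing rsid")
  flag(is.na(df$se) | df$se <= 0, "non-positive se")
  flag(is.na(df$beta), "missing beta")
  flag(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
       "p-value outside (0, 1]")
  has_alleles <- !is.na(df$effect_allele) & !is.na(df$other_allele)
  flag(has_alleles & df$effect_allele == df$other_allele,
       "effect and other allele identical")
  flag(has_alleles & !(df$effect_allele %in% c("A", "C", "G", "T") &
                         df$other_allele %in% c("A", "C", "G", "T")),
       "allele not a single A/C/G/T base")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0, 1]")

  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  # Soft consistency check: |z| implied by p vs beta/se within a factor 10.
  ok <- !is.na(out$beta) & !is.na(out$se) & out$se > 0 & out$pvalue < 1
  if (any(ok)) {
    z_obs <- abs(out$beta[ok] / out$se[ok])
    z_imp <- stats::qnorm(out$pvalue[ok] / 2, lower.tail = FALSE)
    off <- z_obs > 0 & z_imp > 0 & (z_obs / z_imp > 10 | z_imp / z_obs > 10)
    if (any(off))
      warnf("%d row(s) with p-value inconsistent with beta/se (factor > 10)",
            sum(off))
  }
  attr(out, "n_rejected") <- n_input - nrow(out)
  attr(out, "rejections") <- reasons
  out
}

#' Read an RNA-modification SNP catalogue
#'
#' Parses an RMVar-style dump of RNA-modification-related SNPs. The
#' canonical dump schema has seven named columns: `rsid`, `mod_type`,
#' `confidence`, `effect`, `gene`, `gene_type`, `region`; extra columns
#' are tolerated and a `column_map` permits other dialects. Rows with a
#' modification type outside the nine-type vocabulary are rejected;
#' duplicates on (rsid, mod_type) are collapsed keeping the highest
#' confidence tier.
#'
#' @param path Delimited text file with header.
#' @param column_map Optional mapping of canonical field to source column.
#' @param delim Field delimiter.
#' @return Data.frame of catalogue records with rejection attributes.
#' @export
read_rnam_catalogue <- function(path, column_map = list(), delim = "\t") {
  raw <- read_delim_table(path, delim)
  fields <- c("rsid", "mod_type", "confidence", "effect", "gene",
              "gene_type", "region")
  aliases <- stats::setNames(as.list(fields), fields)
  cols <- resolve_columns(names(raw), column_map, aliases,
                          mandatory = c("rsid", "mod_type", "confidence",
                                        "effect"))
  df <- data.frame(
    rsid = as.character(raw[[cols$rsid]]),
    mod_type = as.character(raw[[cols$mod_type]]),
    confidence = tolower(as.character(raw[[cols$confidence]])),
    effect = tolower(as.character(raw[[cols$effect]])),
    gene = if (!is.na(cols$gene)) as.character(raw[[cols$gene]]) else NA_character_,
    gene_type = if (!is.na(cols$gene_type))
      as.character(raw[[cols$gene_type]]) else NA_character_,
    region = if (!is.na(cols$region)) as.character(raw[[cols$region]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  n_in <- nrow(df)
  reasons <- character(0)
  bad <- !(df$mod_type %in% MOD_TYPES)
  if (any(bad))
    reasons <- c(reasons, sprintf(
      "row %d: unknown mod_type '%s' (allowed: %s)",
      which(bad), df$mod_type[bad], paste(MOD_TYPES, collapse = ", ")))
  bad2 <- !(df$confidence %in% CONFIDENCE_LEVELS)
  if (any(bad2 & !bad))
    reasons <- c(reasons, sprintf("row %d: unknown confidence '%s'",
                                  which(bad2 & !bad), df$confidence[bad2 & !bad]))
  bad3 <- !(df$effect %in% EFFECT_LEVELS)
  if (any(bad3 & !bad & !bad2))
    reasons <- c(reasons, sprintf("row %d: unknown effect '%s'",
                                  which(bad3 & !bad & !bad2),
                                  df$effect[bad3 & !bad & !bad2]))
  df <- df[!(bad | bad2 | bad3), , drop = FALSE]
  df$gene_type[!is.na(df$gene_type) &
                 !df$gene_type %in% GENE_TYPES] <- NA_character_
  df$region[!is.na(df$region) & !df$region %in% REGION_LEVELS] <- "other"

  # Collapse duplicates on (rsid, mod_type), keeping highest confidence.
  conf_rank <- match(df$confidence, CONFIDENCE_LEVELS)  # 1 = high
  ord <- order(df$rsid, df$mod_type, conf_rank)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df[c("rsid", "mod_type")]), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n_in - sum(!(bad | bad2 | bad3))
  attr(df, "rejections") <- reasons
  df
}

#' Read QTL (eQTL/pQTL) summary statistics
#'
#' @param path Delimited text file with header; canonical columns `rsid`,
#'   `target_id`, `target_chrom`, `target_tss`, `beta`, `se`, `pvalue`,
#'   `tissue_or_study`.
#' @param column_map Optional canonical-to-source column mapping.
#' @param delim Field delimiter.
#' @return Data.frame of QTL records with rejection attributes.
#' @export
read_qtl <- function(path, column_map = list(), delim = "\t") {
  raw <- read_delim_table(path, delim)
  fields <- c("rsid", "target_id", "target_chrom", "target_tss",
              "beta", "se", "pvalue", "tissue_or_study")
  aliases <- stats::setNames(as.list(fields), fields)
  aliases$beta <- c("beta", "BETA", "b")
  aliases$se <- c("se", "SE")
  aliases$pvalue <- c("pvalue", "P", "p", "pval")
  cols <- resolve_columns(names(raw), column_map, aliases,
                          mandatory = c("rsid", "target_id", "beta", "se",
                                        "pvalue"))
  df <- data.frame(
    rsid = as.character(raw[[cols$rsid]]),
    target_id = as.character(raw[[cols$target_id]]),
    target_chrom = if (!is.na(cols$target_chrom))
      as.character(raw[[cols$target_chrom]]) else NA_character_,
    target_tss = if (!is.na(cols$target_tss))
      as.integer(raw[[cols$target_tss]]) else NA_integer_,
    beta = as.numeric(raw[[cols$beta]]),
    se = as.numeric(raw[[cols$se]]),
    pvalue = as.numeric(raw[[cols$pvalue]]),
    tissue_or_study = if (!is.na(cols$tissue_or_study))
      as.character(raw[[cols$tissue_or_study]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  n_in <- nrow(df)
  bad <- is.na(df$se) | df$se <= 0 | is.na(df$beta) |
    is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  reasons <- if (any(bad))
    sprintf("row %d: invalid se/beta/pvalue", which(bad)) else character(0)
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n_in - nrow(df)
  attr(df, "rejections") <- reasons
  df
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines with
#' fewer than three fields are skipped with a warning. Gene symbols are
#' uppercased and deduplicated within a set.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors), `descriptions`, and `universe` (NULL unless set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character(0)
  n_bad <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      n_bad <- n_bad + 1L
      next
    }
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    sets[[parts[[1]]]] <- genes
    descriptions[parts[[1]]] <- parts[[2]]
  }
  if (n_bad > 0)
    warnf("%d GMT line(s) with fewer than 3 fields skipped", n_bad)
  if (anyDuplicated(names(sets)))
    warnf("duplicate gene-set names; later definitions replaced earlier ones")
  structure(list(sets = sets, descriptions = descriptions, universe = NULL),
            class = "gene_set_collection")
}

#' Write gene sets in GMT format
#'
#' @param collection A `gene_set_collection` as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- collection$descriptions[nm]
    if (is.na(desc)) desc <- ""
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' All pipeline outputs are tab-separated with a header and no quoting;
#' reals keep 15 significant digits so a write/read round trip is stable
#' to 12 significant digits.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.double(out[[col]]))
      out[[col]] <- vapply(out[[col]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 15), character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return Data.frame.
#' @export
read_tsv <- function(path) read_delim_table(path, "\t")

#' Write a named list of result tables into a directory
#'
#' @param tables Named list of data.frames; each becomes `<name>.tsv`.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }, character(1))
  invisible(paths)
}
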