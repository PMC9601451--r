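# LD reference panel: either individual-level dosages (from which pairwise
# allelic correlation is computed on demand) or a precomputed sparse
# correlation table. Both present the same r/r2 lookup surface.

#' Construct an LD panel from a dosage matrix
#'
#' @param dosages Numeric matrix, individuals x SNPs, entries 0/1/2
#'   (fractional dosages accepted); column names are rsids.
#' @param snp_info Optional data.frame with columns `rsid`, `chrom`, `pos`
#'   (and anything else) aligned to the panel's SNPs.
#' @return An object of class `ld_panel`.
#' @export
ld_panel_from_dosages <- function(dosages, snp_info = NULL) {
  if (is.null(colnames(dosages)))
    stopf("dosage matrix must have rsid column names")
  if (!is.null(snp_info)) {
    if (!all(colnames(dosages) %in% snp_info$rsid))
      stopf("snp_info does not cover all panel SNPs")
    snp_info <- snp_info[match(colnames(dosages), snp_info$rsid), ,
                         drop = FALSE]
    rownames(snp_info) <- NULL
  }
  structure(list(type = "dosage", dosages = dosages,
                 rsids = colnames(dosages), snp_info = snp_info),
            class = "ld_panel")
}

#' Construct an LD panel from a pairwise correlation table
#'
#' @param cor_table Data.frame with columns `rsid_a`, `rsid_b`, `r`
#'   (allelic correlation). Symmetry and unit diagonal are implied; pairs
#'   absent from the table are treated as uncorrelated by consumers that
#'   opt into that behaviour.
#' @param snp_info Optional SNP metadata as in [ld_panel_from_dosages()].
#' @return An object of class `ld_panel`.
#' @export
ld_panel_from_cor <- function(cor_table, snp_info = NULL) {
  need <- c("rsid_a", "rsid_b", "r")
  if (!all(need %in% names(cor_table)))
    stopf("correlation table needs columns %s", paste(need, collapse = ", "))
  if (any(abs(cor_table$r) > 1 + 1e-12))
    stopf("correlation values must lie in [-1, 1]")
  rsids <- unique(c(cor_table$rsid_a, cor_table$rsid_b))
  key <- c(paste(cor_table$rsid_a, cor_table$rsid_b, sep = "\r"),
           paste(cor_table$rsid_b, cor_table$rsid_a, sep = "\r"))
  val <- c(cor_table$r, cor_table$r)
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(key)) assign(key[[i]], val[[i]], envir = lookup)
  structure(list(type = "cor", lookup = lookup, rsids = rsids,
                 snp_info = snp_info),
            class = "ld_panel")
}

#' Read an LD panel from disk
#'
#' Accepts either a dosage matrix TSV (header = rsids, one row per
#' individual) or a 3-column correlation table (`rsid_a`, `rsid_b`, `r`).
#' The format is inferred from the header.
#'
#' @param path TSV file.
#' @return An `ld_panel`.
#' @export
read_ld_panel <- function(path) {
  df <- read_delim_table(path, "\t")
  if (all(c("rsid_a", "rsid_b", "r") %in% names(df)))
    return(ld_panel_from_cor(df))
  ld_panel_from_dosages(as.matrix(df))
}

#' Write an LD panel's dosages to TSV
#' @param panel A dosage-backed `ld_panel`.
#' @param path Output path.
#' @export
write_ld_panel <- function(panel, path) {
  if (panel$type != "dosage")
    stopf("only dosage-backed panels can be written as a dosage TSV")
  utils::write.table(panel$dosages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pairwise allelic correlation from an LD panel
#'
#' @param panel An `ld_panel`.
#' @param a,b rsids (vectorised; recycled to common length).
#' @param missing_as_zero For correlation-table panels, treat absent pairs
#'   as r = 0 (with one warning) instead of NA.
#' @return Numeric vector of correlations.
#' @export
ld_r <- function(panel, a, b, missing_as_zero = FALSE) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- numeric(n)
  if (panel$type == "dosage") {
    known <- a %in% panel$rsids & b %in% panel$rsids
    if (any(known)) {
      ga <- panel$dosages[, a[known], drop = FALSE]
      gb <- panel$dosages[, b[known], drop = FALSE]
      out[known] <- vapply(seq_len(sum(known)), function(i) {
        if (stats::sd(ga[, i]) == 0 || stats::sd(gb[, i]) == 0) return(0)
        stats::cor(ga[, i], gb[, i])
      }, numeric(1))
    }
    out[!known] <- NA_real_
  } else {
    for (i in seq_len(n)) {
      if (a[[i]] == b[[i]]) {
        out[[i]] <- 1
      } else {
        v <- get0(paste(a[[i]], b[[i]], sep = "\r"), envir = panel$lookup)
        out[[i]] <- if (is.null(v)) NA_real_ else v
      }
    }
  }
  if (missing_as_zero && anyNA(out)) {
    warnf("%d SNP pair(s) absent from LD panel treated as r = 0",
          sum(is.na(out)))
    out[is.na(out)] <- 0
  }
  out
}

#' Pairwise r-squared from an LD panel
#' @inheritParams ld_r
#' @return Numeric vector of squared correlations.
#' @export
ld_r2 <- function(panel, a, b, missing_as_zero = FALSE)
  ld_r(panel, a, b, missing_as_zero = missing_as_zero)^2

#' Correlation matrix for a set of SNPs
#'
#' @param panel An `ld_panel`.
#' @param rsids SNPs to include, in order.
#' @param missing_as_zero Treat pairs absent from a correlation-table
#'   panel as uncorrelated.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(panel, rsids, missing_as_zero = FALSE) {
  m <- length(rsids)
  if (panel$type == "dosage") {
    if (!all(rsids %in% panel$rsids))
      stopf("LD panel does not cover: %s",
            paste(setdiff(rsids, panel$rsids), collapse = ", "))
    g <- panel$dosages[, rsids, drop = FALSE]
    sds <- apply(g, 2, stats::sd)
    if (any(sds == 0)) {
      R <- diag(m)
      ok <- sds > 0
      if (sum(ok) > 1) R[ok, ok] <- stats::cor(g[, ok, drop = FALSE])
    } else {
      R <- stats::cor(g)
    }
    dimnames(R) <- list(rsids, rsids)
    return(R)
  }
  R <- diag(m)
  dimnames(R) <- list(rsids, rsids)
  n_missing <- 0L
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    v <- get0(paste(rsids[[i]], rsids[[j]], sep = "\r"), envir = panel$lookup)
    if (is.null(v)) {
      n_missing <- n_missing + 1L
      v <- if (missing_as_zero) 0 else NA_real_
    }
    R[i, j] <- R[j, i] <- v
  }
  if (missing_as_zero && n_missing > 0)
    warnf("%d SNP pair(s) absent from LD panel treated as r = 0", n_missing)
  R
}
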