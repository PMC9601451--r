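# End-to-end pipeline driver: annotate -> enrich -> QTL links ->
# instruments -> MR, with the SMR/HEIDI branch on the eQTL table and ORA
# on the genes of significant annotated SNPs. Every stage writes its
# table as soon as it finishes, so an aborted run keeps partial outputs.

#' Pipeline configuration
#'
#' Collects all input paths and analysis thresholds in one validated
#' object. Threshold defaults are the conventional gates of this kind of
#' analysis: genome-wide significance 5e-8, instrument selection 5e-4,
#' QTL signal 5e-5, SMR significance 5e-6, HEIDI gate 0.05, clumping
#' r-squared 0.001 within 10,000 kb.
#'
#' @param gwas,exposure,qtl,catalogue,ld_panel Input file paths (`qtl`,
#'   `ld_panel` optional for a reduced run; `gmt` optional).
#' @param gmt Optional gene-set GMT path for the ORA stage.
#' @param out_dir Output directory.
#' @param p_gwas,p_instrument,p_qtl_signal,p_smr,heidi_gate Analysis
#'   thresholds.
#' @param clump_r2,clump_window_kb Clumping parameters.
#' @param B Permutation replicates for enrichment.
#' @param n_sim MR-PRESSO simulation replicates.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param seed RNG seed for all stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gwas, exposure = NULL, qtl = NULL,
                            catalogue, ld_panel = NULL, gmt = NULL,
                            out_dir = "pipeline_out",
                            p_gwas = 5e-8, p_instrument = 5e-4,
                            p_qtl_signal = 5e-5, p_smr = 5e-6,
                            heidi_gate = 0.05, clump_r2 = 0.001,
                            clump_window_kb = 10000, B = 1000,
                            n_sim = 1000, n_boot = 1000, seed = 1) {
  cfg <- list(gwas = gwas, exposure = exposure, qtl = qtl,
              catalogue = catalogue, ld_panel = ld_panel, gmt = gmt,
              out_dir = out_dir, p_gwas = p_gwas,
              p_instrument = p_instrument, p_qtl_signal = p_qtl_signal,
              p_smr = p_smr, heidi_gate = heidi_gate, clump_r2 = clump_r2,
              clump_window_kb = clump_window_kb, B = as.integer(B),
              n_sim = as.integer(n_sim), n_boot = as.integer(n_boot),
              seed = as.integer(seed))
  for (nm in c("p_gwas", "p_instrument", "p_qtl_signal", "p_smr",
               "heidi_gate"))
    assert_prob(cfg[[nm]], nm, open_lower = TRUE)
  for (nm in c("gwas", "catalogue"))
    if (!file.exists(cfg[[nm]])) stopf("input file not found: %s", cfg[[nm]])
  for (nm in c("exposure", "qtl", "ld_panel", "gmt"))
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stopf("input file not found: %s", cfg[[nm]])
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML (or JSON)
#'
#' Keys mirror the arguments of [pipeline_config()]; `overrides` (e.g.
#' from command-line flags) take precedence.
#'
#' @param path YAML or JSON file.
#' @param overrides Named list of values overriding file keys.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_file <- function(path, overrides = list()) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
  else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: annotation and significance
#' gating, per-type summaries and classification tallies, locus
#' clustering, permutation enrichment, QTL linking, instrument
#' construction (selection, harmonization, clumping), the MR suite, the
#' SMR/HEIDI scan, and ORA. Writes one TSV per stage plus
#' `manifest.json` (package version, seed, config echo, per-stage row
#' counts) and `run.log`. A stage error aborts with the stage name;
#' tables written so far are kept.
#'
#' @param config A [pipeline_config()].
#' @return The output directory path, invisibly; the manifest is also
#'   returned as attribute `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg),
               log_con)
    message(msg)
  }
  counts <- list()
  stage <- function(name, expr) {
    say("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    if (is.data.frame(res)) {
      counts[[name]] <<- nrow(res)
      write_tsv(res, file.path(config$out_dir, paste0(name, ".tsv")))
    }
    say("stage %s: done (%s rows)", name,
        if (is.data.frame(res)) nrow(res) else "-")
    res
  }

  gwas <- stage("gwas_input", suppressWarnings(read_gwas(config$gwas)))
  catalogue <- stage("catalogue_input",
                     suppressWarnings(read_rnam_catalogue(config$catalogue)))
  annotated <- stage("annotated",
                     annotate_gwas(gwas, catalogue, config$p_gwas))
  stage("summary_by_type", summarize_by_type(annotated))
  stage("classifications", tally_classifications(annotated))
  sig <- annotated[annotated$significant, , drop = FALSE]
  stage("loci", cluster_loci(sig))
  stage("enrichment",
        enrichment_by_type(gwas, annotated, config$p_gwas, config$B,
                           config$seed))

  qtl <- NULL
  if (!is.null(config$qtl)) {
    qtl <- suppressWarnings(read_qtl(config$qtl))
    stage("qtl_links",
          link_qtl(annotated, qtl, p_signal = config$p_qtl_signal))
  }

  ld <- if (!is.null(config$ld_panel)) read_ld_panel(config$ld_panel)

  mr_table <- NULL
  if (!is.null(config$exposure)) {
    exposure <- suppressWarnings(read_gwas(config$exposure))
    cand <- suppressWarnings(select_instruments(exposure,
                                                config$p_instrument))
    harmonized <- stage("harmonized", harmonize(cand, gwas))
    usable <- instrument_subset(harmonized)
    clumped <- if (!is.null(ld) && nrow(usable) > 0)
      stage("instruments",
            ld_clump(usable, ld,
                     clump_config(config$clump_r2, config$clump_window_kb,
                                  config$p_instrument)))
    else stage("instruments", usable)
    if (nrow(clumped) >= 1) {
      mr <- mr_all(clumped, n_boot = config$n_boot, n_sim = config$n_sim,
                   seed = config$seed)
      mr_table <- stage("mr_results", mr$table)
    } else {
      say("no instruments after clumping; MR skipped")
      mr_table <- stage("mr_results", data.frame(
        method = character(0), estimate = numeric(0), se = numeric(0),
        pvalue = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
        n_snps = integer(0)))
    }
  }

  if (!is.null(qtl) && !is.null(ld)) {
    stage("smr_results",
          smr_scan(gwas, qtl, ld, p_smr_threshold = config$p_smr,
                   heidi_gate = config$heidi_gate))
  }

  if (!is.null(config$gmt)) {
    sets <- suppressWarnings(read_gmt(config$gmt))
    genes <- unique(toupper(sig$gene[!is.na(sig$gene)]))
    if (length(genes) > 0) {
      universe <- unique(toupper(c(unlist(sets$sets, use.names = FALSE),
                                   catalogue$gene[!is.na(catalogue$gene)])))
      stage("ora_results",
            suppressWarnings(ora_test(genes, sets, universe = universe)))
    } else say("no significant annotated genes; ORA skipped")
  }

  manifest <- list(
    package = "rnamodmr",
    version = as.character(utils::packageVersion("rnamodmr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    row_counts = counts,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("pipeline complete")
  out <- config$out_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}
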