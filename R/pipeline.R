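#' Pipeline configuration: thresholds, toggles and the simulation design
#'
#' Centralises every analysis threshold: per-site alpha 0.05, merge gap
#' 200 bp, minimum 5 CpGs per region, region-level slk alpha 1e-4, SNP MAF
#' filter 0.05, CPM filter 1, pair correlation alpha 0.05, 1000 matched null
#' draws.
#'
#' @param sim a [sim_config()] describing the cohort to simulate.
#' @param site_alpha,max_gap,min_cpgs,region_alpha DMR-calling thresholds.
#' @param maf SNP minor-allele-frequency exclusion threshold.
#' @param min_cpm expression inclusion threshold (mean CPM).
#' @param pair_alpha Spearman significance cutoff for DMR-gene pairs.
#' @param n_draws matched null draws for enrichment.
#' @param association "two_track" (default: smoothed levels locate candidate
#'   regions, raw-level statistics score them), "smoothed" or "raw" (single
#'   track used for both).
#' @param stages character vector of stages to run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), site_alpha = 0.05,
                            max_gap = 200, min_cpgs = 5, region_alpha = 1e-4,
                            maf = 0.05, min_cpm = 1, pair_alpha = 0.05,
                            n_draws = 1000,
                            association = c("two_track", "smoothed", "raw"),
                            stages = c("methylation", "dmr", "enrichment",
                                       "expression", "integration",
                                       "cytokines")) {
  association <- match.arg(association)
  stopifnot(site_alpha > 0, site_alpha <= 1, region_alpha > 0,
            region_alpha <= 1, min_cpgs >= 1, max_gap > 0, n_draws >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes the stages in dependency order (methylation -> DMR -> enrichment;
#' expression; integration; cytokines), writes every stage output as TSV into
#' `outdir` when given, and records a JSON manifest (seed, thresholds,
#' per-stage row counts). Re-running with the same configuration reproduces
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created); NULL to skip writing files.
#' @param cohort optionally a pre-built [simulate_cohort()] result (must match
#'   `config$sim`); simulated when NULL.
#' @return list with per-stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         cohort = NULL) {
  t0 <- Sys.time()
  if (is.null(cohort)) cohort <- simulate_cohort(config$sim)
  res <- list(config = config, cohort = cohort)
  manifest <- list(seed = config$sim$seed,
                   thresholds = config[c("site_alpha", "max_gap", "min_cpgs",
                                         "region_alpha", "maf", "min_cpm",
                                         "pair_alpha", "n_draws",
                                         "association")],
                   stages = list())
  want <- function(s) s %in% config$stages
  if (want("methylation")) {
    mc <- filter_snp_overlap(cohort$meth$counts, cohort$genome$snps,
                             maf_threshold = config$maf)
    n_removed <- attr(mc, "n_removed")
    smoothed <- smooth_profiles(mc)
    raw <- methylation_level(mc$meth, mc$unmeth)
    bulk <- raw
    rownames(bulk) <- paste(mc$sites$chrom, mc$sites$pos, sep = ":")
    cell_props <- estimate_cell_proportions(bulk, cohort$genome$cell_reference)
    need_sm <- config$association %in% c("two_track", "smoothed")
    need_raw <- config$association %in% c("two_track", "raw")
    stats_sm <- if (need_sm)
      site_association(smoothed, cohort$meth$sheet, cell_props)
    stats_raw <- if (need_raw)
      site_association(raw, cohort$meth$sheet, cell_props)
    track <- switch(config$association,
                    two_track = pvalue_track(mc, stats_raw),
                    smoothed = pvalue_track(mc, stats_sm),
                    raw = pvalue_track(mc, stats_raw))
    sel_track <- if (config$association == "two_track")
      pvalue_track(mc, stats_sm)
    res$methylation <- list(counts = mc, smoothed = smoothed, raw = raw,
                            cell_props = cell_props,
                            stats = if (need_raw) stats_raw else stats_sm,
                            track = track, selection_track = sel_track)
    manifest$stages$methylation <- list(
      n_sites = nrow(mc$sites), n_snp_removed = n_removed,
      n_samples = ncol(mc$meth))
  }
  if (want("dmr")) {
    acf <- estimate_acf(res$methylation$track)
    dmrs <- call_dmrs(res$methylation$track, acf,
                      region_alpha = config$region_alpha,
                      site_alpha = config$site_alpha,
                      max_gap = config$max_gap, min_cpgs = config$min_cpgs,
                      selection_track = res$methylation$selection_track)
    res$dmr <- list(acf = acf, dmrs = dmrs)
    manifest$stages$dmr <- list(
      n_dmrs = nrow(dmrs), n_hyper = sum(dmrs$direction == "hyper"),
      n_hypo = sum(dmrs$direction == "hypo"))
  }
  if (want("enrichment")) {
    if (nrow(res$dmr$dmrs) > 0) {
      g <- cohort$genome
      promoters <- build_promoters(g$genes, g$layout)
      cgi_ctx <- build_cgi_context(g$cgis, g$layout)
      gt <- gene_feature_tracks(g$genes)
      tracks <- c(list(promoter = promoters[, c("chrom", "start", "end")]),
                  gt[c("utr5", "utr3", "exon", "intron")],
                  cgi_ctx, state_feature_tracks(g$states))
      set.seed(child_seed(config$sim, 505))
      enr <- enrich(res$dmr$dmrs, tracks, g$cpgs, n_draws = config$n_draws)
    } else {
      enr <- data.frame(stratum = character(), feature = character(),
                        observed = integer(), null_mean = numeric(),
                        null_sd = numeric(), fold = numeric(),
                        log2fold = numeric(), emp_p_enriched = numeric(),
                        emp_p_depleted = numeric(), direction = character(),
                        n_extreme = integer(), n_draws = integer())
    }
    res$enrichment <- enr
    manifest$stages$enrichment <- list(n_rows = nrow(enr))
  }
  if (want("expression")) {
    kept <- cpm_filter(cohort$expr$counts, min_cpm = config$min_cpm)
    sheet <- cohort$expr$sheet
    X <- cbind(1, as.numeric(sheet$group == "smoker"), sheet$age, sheet$bmi,
               as.numeric(sheet$miner))
    vw <- mean_variance_weights(kept, design = X)
    deg <- deg_test(vw$logcpm, vw$weights, sheet)
    res$expression <- list(counts = kept, logcpm = vw$logcpm,
                           weights = vw$weights, deg = deg)
    manifest$stages$expression <- list(
      n_kept = nrow(kept), n_removed = attr(kept, "n_removed"),
      n_deg_fdr05 = sum(deg$q < 0.05))
  }
  if (want("integration")) {
    g <- cohort$genome
    promoters <- build_promoters(g$genes, g$layout)
    dmrs <- res$dmr$dmrs
    links <- rbind(annotate_dmr_genes(dmrs, g$genes),
                   map_regulatory_dmrs(dmrs, promoters, g$enhancers))
    dmr_meth <- dmr_mean_methylation(dmrs, res$methylation$counts$sites,
                                     res$methylation$smoothed)
    overlap <- intersect(colnames(dmr_meth), colnames(res$expression$logcpm))
    pairs <- correlate_pairs(links[links$link_class != "body", , drop = FALSE],
                             dmr_meth, res$expression$logcpm,
                             res$expression$deg, dmrs, samples = overlap,
                             alpha = config$pair_alpha)
    res$integration <- list(links = links, dmr_meth = dmr_meth, pairs = pairs,
                            overlap_samples = overlap)
    sig <- pairs[pairs$significant, , drop = FALSE]
    manifest$stages$integration <- list(
      n_links = nrow(links), n_pairs_tested = nrow(pairs),
      n_pairs_significant = nrow(sig),
      quadrants = as.list(table(sig$quadrant)))
  }
  if (want("cytokines")) {
    cyt <- cytokine_diff(cohort$cyto$panel, cohort$cyto$sheet)
    res$cytokines <- cyt
    manifest$stages$cytokines <- list(
      n_analytes = nrow(cyt), n_nominal = sum(cyt$p < 0.05))
  }
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res$manifest <- manifest
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' @keywords internal
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  if (!is.null(res$methylation)) {
    st <- res$methylation$counts$sites
    tsv_write(cbind(st[, c("chrom", "pos")], res$methylation$stats),
              p("site_stats.tsv"))
  }
  if (!is.null(res$dmr)) {
    tsv_write(res$dmr$dmrs, p("dmrs.tsv"))
    write_dmr_bed(res$dmr$dmrs, p("dmrs.bed"))
  }
  if (!is.null(res$enrichment)) tsv_write(res$enrichment, p("enrichment.tsv"))
  if (!is.null(res$expression)) tsv_write(res$expression$deg, p("degs.tsv"))
  if (!is.null(res$integration)) {
    pr <- res$integration$pairs
    out <- data.frame(block = ifelse(pr$link_class == "promoter", "Promoter",
                                     "Promoter/enhancer"),
                      region = pr$region, enhancer_id = pr$enhancer_id,
                      meth_direction = pr$meth_direction,
                      target_gene = pr$gene,
                      expr_direction = pr$expr_direction,
                      rho = pr$rho, p = pr$p,
                      significant = pr$significant)
    tsv_write(out, p("pairs.tsv"))
  }
  if (!is.null(res$cytokines)) tsv_write(res$cytokines, p("cytokines.tsv"))
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Write a simulated cohort's inputs as plain-text files
#'
#' Emits every downstream input dialect: methylation counts TSV, sample
#' sheets, expression counts TSV, cytokine TSV, BED tracks (CpG islands,
#' enhancers, chromatin states), gene-model and SNP TSVs, and a ground-truth
#' ledger JSON.
#'
#' @param cohort from [simulate_cohort()]. @param outdir directory.
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_methylation_tsv(cohort$meth$counts, p("methylation_counts.tsv"))
  tsv_write(cohort$meth$sheet, p("sample_sheet_wgbs.tsv"))
  write_counts_tsv(cohort$expr$counts, p("expression_counts.tsv"))
  tsv_write(cohort$expr$sheet, p("sample_sheet_rna.tsv"))
  tsv_write(data.frame(analyte = rownames(cohort$cyto$panel),
                       cohort$cyto$panel, check.names = FALSE),
            p("cytokines.tsv"))
  tsv_write(cohort$cyto$sheet, p("sample_sheet_cytokine.tsv"))
  write_bed(cohort$genome$cgis, p("cgi.bed"))
  tsv_write(cohort$genome$snps, p("snps.tsv"))
  write_gene_models_tsv(cohort$genome$genes, p("gene_models.tsv"))
  tsv_write(cohort$genome$enhancers, p("enhancers.tsv"))
  tsv_write(cohort$genome$states, p("chromatin_states.tsv"))
  tsv_write(cohort$genome$cpgs, p("cpg_positions.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(dmrs = truth$dmrs, degs = truth$degs,
         coupled_links = truth$coupled_links,
         cytokine_shifts = as.list(truth$cytokine_shifts)),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
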