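# Shared fixtures: a reduced cohort for unit tests (cached per session) and
# small constructors used across files.

tiny_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed, n_smokers = 12, n_nonsmokers = 12,
                   n_rna_smokers = 14, n_rna_nonsmokers = 13,
                   n_overlap_smokers = 6, n_overlap_nonsmokers = 8,
                   n_cyto_smokers = 5, n_cyto_nonsmokers = 6,
                   n_chroms = 2, chrom_length = 4e5, n_cpgs = 8000,
                   n_cgis_per_chrom = 15, n_dmrs = 12, n_genes = 60,
                   n_transcripts = 300, n_degs = 15, n_enhancers = 40,
                   n_coupled_enhancers = 6, n_snps = 800,
                   n_cell_ref_sites = 150)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.cache <- new.env()

tiny_cohort <- function() {
  if (is.null(.cache$tiny)) .cache$tiny <- simulate_cohort(tiny_config())
  .cache$tiny
}

# minimal gene model set reused by annotation tests
toy_genes <- function() {
  gene_models(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
    strand = c("+", "-"), tx_start = c(10000, 40000), tx_end = c(20000, 50000),
    exons = c("10000-12000;15000-17000;19000-20000",
              "40000-42000;48000-50000"),
    cds = c("11000-12000;15000-17000;19000-19500", NA))
}

toy_layout <- function() genome_layout(c(chr1 = 1e6, chr2 = 5e5))

# reciprocal-overlap DMR recovery counter used by dmr and acceptance tests
count_recovered <- function(called, truth, min_recip = 0.5) {
  rec <- 0L
  for (i in seq_len(nrow(truth))) {
    cand <- called[called$chrom == truth$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmin(cand$end, truth$end[i]) - pmax(cand$start, truth$start[i])
    hit <- ov >= min_recip * (truth$end[i] - truth$start[i]) &
      ov >= min_recip * (cand$end - cand$start) &
      cand$direction == truth$direction[i]
    if (any(hit)) rec <- rec + 1L
  }
  rec
}

run_methylation_tracks <- function(co) {
  mc <- filter_snp_overlap(co$meth$counts, co$genome$snps)
  smn <- smooth_profiles(mc)
  raw <- methylation_level(mc$meth, mc$unmeth)
  bulk <- raw
  rownames(bulk) <- paste(mc$sites$chrom, mc$sites$pos, sep = ":")
  cp <- estimate_cell_proportions(bulk, co$genome$cell_reference)
  list(mc = mc, smoothed = smn, raw = raw, cell_props = cp,
       sel = pvalue_track(mc, site_association(smn, co$meth$sheet, cp)),
       inf = pvalue_track(mc, site_association(raw, co$meth$sheet, cp)))
}
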