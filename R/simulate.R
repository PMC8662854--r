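#' Simulation configuration for a synthetic smoking cohort
#'
#' Defaults emulate the study design the pipeline targets: 36 + 36 WGBS
#' samples at ~12.5x mean depth, a bimodal baseline methylation landscape
#' (peaks near 0-0.1 and 0.9-1.0), planted DMRs with mean |delta| ~ 3.4%
#' ranging 0.3-20% at ~3:1 hyper:hypo, 38 + 37 RNA samples overlapping WGBS
#' in 12 + 18 subjects, planted log2 fold changes up to 2.25, a 27-analyte
#' cytokine panel on 9 + 13 subjects, and covariate plus cell-composition
#' confounding.
#'
#' @param seed master RNG seed; per-stage child seeds are derived from it so
#'   toggling one stage never perturbs another's draws.
#' @param n_smokers,n_nonsmokers WGBS group sizes.
#' @param n_rna_smokers,n_rna_nonsmokers RNA-seq group sizes.
#' @param n_overlap_smokers,n_overlap_nonsmokers subjects with both assays.
#' @param n_cyto_smokers,n_cyto_nonsmokers cytokine subset sizes (from WGBS).
#' @param n_chroms,chrom_length genome geometry.
#' @param n_cpgs total simulated CpG sites.
#' @param n_cgis_per_chrom,cgi_width_range,cgi_cpg_fraction CpG island layout;
#'   `cgi_cpg_fraction` of CpGs are placed inside islands (CpG-rich areas).
#' @param mean_depth mean sequencing depth (Poisson, truncated >= 1).
#' @param overdispersion beta-binomial within-group overdispersion rho.
#' @param baseline_low_beta,baseline_high_beta shape pairs of the two
#'   baseline mixture components.
#' @param p_low_island,p_low_open probability a site draws the low component,
#'   inside and outside islands.
#' @param n_dmrs,dmr_delta_range,dmr_delta_mean,hyper_fraction planted DMR
#'   count, |delta| range and mean, and hypermethylated fraction.
#' @param dmr_cpg_range CpGs per planted DMR.
#' @param dmr_min_span minimum planted DMR span in bp.
#' @param dmr_sample_sd per-subject regional methylation variability (sd).
#' @param n_snps simulated SNP count (MAFs spanning the 5% threshold).
#' @param n_genes gene models placed on the genome.
#' @param n_transcripts expression matrix rows (genomic genes + unplaced
#'   transcripts).
#' @param n_degs,deg_log2fc_range planted DEG count and |log2FC| spread; the
#'   largest magnitude is planted upregulated at the range maximum.
#' @param nb_size negative-binomial size (1/dispersion) for counts.
#' @param n_enhancers,enhancer_targets_max enhancer map geometry.
#' @param n_coupled_enhancers enhancers placed directly on planted DMRs with
#'   methylation-coupled targets.
#' @param enhancer_coupling_strength log2 expression units per unit of
#'   regional methylation (negative coupling; 0 disables).
#' @param age_mean,age_sd,bmi_mean,bmi_sd covariate distributions.
#' @param beta_age,beta_bmi,beta_miner covariate effects on methylation.
#' @param cell_types,cell_mean_smoker,cell_mean_nonsmoker,cell_concentration
#'   Dirichlet cell-composition model (granulocyte-dominant, group-shifted).
#' @param cell_effect_fraction,cell_effect_sd fraction of sites carrying a
#'   granulocyte-loading effect, and its sd.
#' @param n_cell_ref_sites designated deconvolution reference sites.
#' @param n_cytokines panel size.
#' @param cytokine_sd residual sd of log2 intensities (0.28 reproduces the
#'   confidence-interval width typical of 27-plex panels at n ~ 22).
#' @param cytokine_shifts named numeric vector of planted smoker shifts
#'   (log2 scale).
#' @param n_state_celltypes,state_mean_seglen chromatin-state simulation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_smokers = 36, n_nonsmokers = 36,
                       n_rna_smokers = 38, n_rna_nonsmokers = 37,
                       n_overlap_smokers = 12, n_overlap_nonsmokers = 18,
                       n_cyto_smokers = 9, n_cyto_nonsmokers = 13,
                       n_chroms = 2, chrom_length = 1.5e6, n_cpgs = 30000,
                       n_cgis_per_chrom = 40, cgi_width_range = c(500, 1500),
                       cgi_cpg_fraction = 0.2,
                       mean_depth = 12.5, overdispersion = 0.02,
                       baseline_low_beta = c(1.2, 28),
                       baseline_high_beta = c(28, 1.2),
                       p_low_island = 0.9, p_low_open = 0.25,
                       n_dmrs = 60, dmr_delta_range = c(0.003, 0.20),
                       dmr_delta_mean = 0.034, hyper_fraction = 0.75,
                       dmr_cpg_range = c(10, 15), dmr_min_span = 1000,
                       dmr_sample_sd = 0.05,
                       n_snps = 3000,
                       n_genes = 300, n_transcripts = 1200, n_degs = 40,
                       deg_log2fc_range = c(0.25, 2.25), nb_size = 10,
                       n_enhancers = 150, enhancer_targets_max = 3,
                       n_coupled_enhancers = 15,
                       enhancer_coupling_strength = 10,
                       age_mean = 41, age_sd = 2.3,
                       bmi_mean = 24.7, bmi_sd = 3.4,
                       beta_age = 0.001, beta_bmi = 0.001, beta_miner = 0.01,
                       cell_types = c("B", "NK", "CD4T", "CD8T", "Mono", "Gran"),
                       cell_mean_smoker = c(0.05, 0.06, 0.13, 0.09, 0.07, 0.60),
                       cell_mean_nonsmoker = c(0.07, 0.08, 0.16, 0.11, 0.08, 0.50),
                       cell_concentration = 150,
                       cell_effect_fraction = 0.15, cell_effect_sd = 0.03,
                       n_cell_ref_sites = 300,
                       n_cytokines = 27, cytokine_sd = 0.28,
                       cytokine_shifts = c(VEGF = 0.26, FGF_basic = 0.165),
                       n_state_celltypes = 3, state_mean_seglen = 2000) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_smokers, cfg$n_nonsmokers, cfg$n_chroms, cfg$chrom_length,
              cfg$n_cpgs, cfg$n_genes, cfg$n_transcripts, cfg$n_cytokines)
  if (any(counts <= 0)) stop("counts must be > 0")
  fr <- c(cfg$cgi_cpg_fraction, cfg$hyper_fraction, cfg$p_low_island,
          cfg$p_low_open, cfg$overdispersion)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (any(cfg$dmr_delta_range < 0 | cfg$dmr_delta_range > 1) ||
      diff(cfg$dmr_delta_range) <= 0)
    stop("dmr_delta_range must be an increasing range within [0, 1]")
  if (cfg$n_cpgs * 2 > cfg$n_chroms * cfg$chrom_length / 10)
    stop("infeasible geometry: too many CpGs for the chromosome length")
  if (cfg$n_overlap_smokers > min(cfg$n_smokers, cfg$n_rna_smokers) ||
      cfg$n_overlap_nonsmokers > min(cfg$n_nonsmokers, cfg$n_rna_nonsmokers))
    stop("assay overlap larger than an assay group")
  if (cfg$n_cyto_smokers > cfg$n_smokers ||
      cfg$n_cyto_nonsmokers > cfg$n_nonsmokers)
    stop("cytokine subset larger than the WGBS group it is drawn from")
  structure(cfg, class = "sim_config")
}

#' @keywords internal
child_seed <- function(config, k) as.integer((config$seed %% 1000000000) + k)

#' @keywords internal
rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Beta-binomial sampler (mean p, overdispersion rho), elementwise
#' @keywords internal
rbetabinom_mat <- function(depth, p, rho) {
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  pp <- stats::rbeta(length(p), a, b)
  m <- stats::rbinom(length(p), size = as.vector(depth), prob = pp)
  dim(m) <- dim(depth)
  m
}

#' @keywords internal
truncexp_quantiles <- function(n, lo, hi, mean_target) {
  b <- hi - lo
  mu <- mean_target - lo
  stopifnot(mu > 0, mu < b / 2 + lo)
  f <- function(lam) 1 / lam - b * exp(-lam * b) / (1 - exp(-lam * b)) - mu
  lam <- stats::uniroot(f, c(1e-6, 1e4))$root
  q <- (seq_len(n) - 0.5) / n
  lo + (-log(1 - q * (1 - exp(-lam * b))) / lam)
}

#' Simulate the genome: layout, CpGs, tracks and planted-DMR ground truth
#'
#' CpGs are clustered (a configurable fraction inside CpG islands); planted
#' DMRs are runs of 10-15 CpGs with pairwise gaps <= 200 bp spanning at
#' least `dmr_min_span` bp; |delta| magnitudes follow a truncated-exponential
#' quantile grid with the configured mean and range, signed hyper with
#' probability `hyper_fraction`. SNP MAFs span the 5% filter threshold.
#'
#' @param config a [sim_config()].
#' @return list: layout, cpgs, cgis, genes, snps, enhancers, states,
#'   cell_reference, site_base (baseline level per CpG), truth (planted DMRs,
#'   coupled links, reference-site index).
#' @export
simulate_genome <- function(config) {
  set.seed(child_seed(config, 101))
  ct <- config
  chroms <- paste0("chr", seq_len(ct$n_chroms))
  layout <- genome_layout(stats::setNames(rep(ct$chrom_length, ct$n_chroms),
                                          chroms))
  ## CpG islands, non-overlapping per chromosome
  cgi <- list()
  for (ch in chroms) {
    w <- round(stats::runif(ct$n_cgis_per_chrom, ct$cgi_width_range[1],
                            ct$cgi_width_range[2]))
    slots <- sort(sample.int(ct$chrom_length - max(w) - 1,
                             ct$n_cgis_per_chrom))
    keep <- c(TRUE, diff(slots) > max(w) + 4000)
    cgi[[ch]] <- data.frame(chrom = ch, start = slots[keep],
                            end = slots[keep] + w[keep])
  }
  cgis <- do.call(rbind, cgi); rownames(cgis) <- NULL
  ## CpG positions: a fraction inside islands, the rest genome-wide
  n_isl <- round(ct$cgi_cpg_fraction * ct$n_cpgs)
  wts <- cgis$end - cgis$start
  pick <- sample.int(nrow(cgis), round(n_isl * 1.4), replace = TRUE,
                     prob = wts)
  pos_isl <- floor(cgis$start[pick] +
                     stats::runif(length(pick)) * (wts[pick] - 2))
  chrom_isl <- cgis$chrom[pick]
  n_open <- ct$n_cpgs - n_isl
  chrom_open <- sample(chroms, round(n_open * 1.25), replace = TRUE)
  pos_open <- floor(stats::runif(length(chrom_open), 0, ct$chrom_length - 2))
  cp <- data.frame(chrom = c(chrom_isl, chrom_open),
                   pos = c(pos_isl, pos_open),
                   island = rep(c(TRUE, FALSE),
                                c(length(pos_isl), length(pos_open))))
  cp <- cp[order(cp$chrom, cp$pos), , drop = FALSE]
  ok <- !duplicated(paste(cp$chrom, cp$pos)) &
    c(TRUE, !(diff(cp$pos) == 1 & cp$chrom[-1] == cp$chrom[-nrow(cp)]))
  cp <- cp[ok, , drop = FALSE]
  want_isl <- sort(sample(which(cp$island), min(n_isl, sum(cp$island))))
  want_open <- which(!cp$island)
  if (length(want_open) < n_open) stop("infeasible geometry: CpG placement")
  want_open <- sort(sample(want_open, n_open))
  cp <- cp[sort(c(want_isl, want_open)), , drop = FALSE]
  rownames(cp) <- NULL
  ## gene models tiled along the chromosomes
  genes <- list()
  gid <- 0L
  for (ch in chroms) {
    at <- round(stats::runif(1, 1000, 4000))
    while (gid < ct$n_genes && at < ct$chrom_length - 10000) {
      gid <- gid + 1L
      w <- round(stats::runif(1, 4000, 8000))
      txs <- at; txe <- min(at + w, ct$chrom_length - 1)
      k <- sample(3:6, 1)
      bnd <- sort(round(stats::runif(2 * k - 2, txs + 50, txe - 50)))
      bnd <- unique(bnd)
      while (length(bnd) %% 2 != 0) bnd <- bnd[-length(bnd)]
      es <- c(txs, bnd[seq_along(bnd) %% 2 == 0])
      ee <- c(bnd[seq_along(bnd) %% 2 == 1], txe)
      okx <- es < ee
      es <- es[okx]; ee <- ee[okx]
      cs <- es[1] + round((ee[1] - es[1]) / 2)
      ce <- es[length(es)] + round((ee[length(es)] - es[length(es)]) / 2)
      cds_s <- pmax(es, cs); cds_e <- pmin(ee, ce)
      okc <- cds_s < cds_e
      genes[[gid]] <- data.frame(
        gene_id = sprintf("G%04d", gid), chrom = ch,
        strand = sample(c("+", "-"), 1), tx_start = txs, tx_end = txe,
        exons = pack_intervals(es, ee),
        cds = if (any(okc)) pack_intervals(cds_s[okc], cds_e[okc]) else
          NA_character_)
      at <- txe + round(stats::runif(1, 500, 3000))
    }
    if (gid >= ct$n_genes) break
  }
  genes <- do.call(rbind, genes)
  genes <- gene_models(genes$gene_id, genes$chrom, genes$strand,
                       genes$tx_start, genes$tx_end, genes$exons, genes$cds)
  ## SNPs with MAFs spanning the 5% threshold
  snps <- snp_set(data.frame(
    chrom = sample(chroms, ct$n_snps, replace = TRUE),
    pos = floor(stats::runif(ct$n_snps, 0, ct$chrom_length - 1)),
    maf = stats::rbeta(ct$n_snps, 1, 3) * 0.5))
  ## baseline methylation: bimodal mixture, low component favoured in islands
  p_low <- ifelse(cp$island, ct$p_low_island, ct$p_low_open)
  low <- stats::rbinom(nrow(cp), 1, p_low) == 1
  base <- numeric(nrow(cp))
  base[low] <- stats::rbeta(sum(low), ct$baseline_low_beta[1],
                            ct$baseline_low_beta[2])
  base[!low] <- stats::rbeta(sum(!low), ct$baseline_high_beta[1],
                             ct$baseline_high_beta[2])
  ## plant DMRs on CpG runs with gaps <= 200 bp
  gap_prev <- c(Inf, ifelse(cp$chrom[-1] == cp$chrom[-nrow(cp)],
                            diff(cp$pos), Inf))
  taken <- logical(nrow(cp))
  sizes <- sample(seq(ct$dmr_cpg_range[1], ct$dmr_cpg_range[2]),
                  ct$n_dmrs, replace = TRUE)
  mags <- sample(truncexp_quantiles(ct$n_dmrs, ct$dmr_delta_range[1],
                                    ct$dmr_delta_range[2], ct$dmr_delta_mean))
  signs <- ifelse(stats::runif(ct$n_dmrs) < ct$hyper_fraction, 1, -1)
  dmr_rows <- list()
  dmr_sites <- list()
  starts_pool <- sample.int(nrow(cp))
  di <- 0L
  for (s0 in starts_pool) {
    if (di >= ct$n_dmrs) break
    k <- sizes[di + 1L]
    if (s0 + k - 1 > nrow(cp)) next
    idx <- s0:(s0 + k - 1)
    if (any(taken[idx])) next
    if (any(gap_prev[idx[-1]] > 200)) next
    span <- cp$pos[idx[k]] + 1 - cp$pos[idx[1]]
    if (span < ct$dmr_min_span) next
    di <- di + 1L
    taken[idx] <- TRUE
    dmr_sites[[di]] <- idx
    dmr_rows[[di]] <- data.frame(
      dmr_id = sprintf("true_dmr_%03d", di), chrom = cp$chrom[idx[1]],
      start = cp$pos[idx[1]], end = cp$pos[idx[k]] + 1, n_cpg = k,
      delta = mags[di] * signs[di],
      direction = ifelse(signs[di] > 0, "hyper", "hypo"))
  }
  if (di < ct$n_dmrs)
    warning("only ", di, " of ", ct$n_dmrs, " DMRs could be planted")
  true_dmrs <- if (di > 0) do.call(rbind, dmr_rows) else
    data.frame(dmr_id = character(), chrom = character(), start = numeric(),
               end = numeric(), n_cpg = integer(), delta = numeric(),
               direction = character())
  rownames(true_dmrs) <- NULL
  ## rebase DMR sites so the planted shift stays inside (0, 1)
  for (j in seq_len(di)) {
    d <- true_dmrs$delta[j]
    lo <- max(0.05, 0.05 - d); hi <- min(0.93, 0.93 - d)
    base[dmr_sites[[j]]] <- stats::runif(length(dmr_sites[[j]]), lo, hi)
  }
  ## cell-composition machinery: reference sites + granulocyte loadings
  free <- which(!taken)
  ref_idx <- sort(sample(free, ct$n_cell_ref_sites))
  cell_ref <- matrix(stats::rbeta(ct$n_cell_ref_sites * length(ct$cell_types),
                                  0.5, 0.5),
                     ct$n_cell_ref_sites, length(ct$cell_types),
                     dimnames = list(paste(cp$chrom[ref_idx], cp$pos[ref_idx],
                                           sep = ":"), ct$cell_types))
  n_eff <- round(ct$cell_effect_fraction * nrow(cp))
  cell_eff_idx <- sort(sample(setdiff(free, ref_idx), n_eff))
  cell_eff <- stats::rnorm(n_eff, 0, ct$cell_effect_sd)
  ## enhancer map: coupled enhancers sit on planted DMRs
  enh <- list()
  n_coupled <- min(ct$n_coupled_enhancers, di)
  coupled_dmr <- if (n_coupled > 0) sort(sample.int(di, n_coupled)) else
    integer(0)
  eid <- 0L
  coupled <- list()
  for (j in coupled_dmr) {
    eid <- eid + 1L
    tg <- sample(genes$gene_id, sample(1:2, 1))
    id <- sprintf("ENH%04d", eid)
    enh[[eid]] <- data.frame(enhancer_id = id,
                             chrom = true_dmrs$chrom[j],
                             start = max(true_dmrs$start[j] - 100, 0),
                             end = true_dmrs$end[j] + 100,
                             target_gene = tg)
    coupled[[eid]] <- data.frame(enhancer_id = id,
                                 dmr_id = true_dmrs$dmr_id[j],
                                 target_gene = tg)
  }
  while (eid < ct$n_enhancers) {
    eid <- eid + 1L
    ch <- sample(chroms, 1)
    st <- floor(stats::runif(1, 0, ct$chrom_length - 2000))
    tg <- sample(genes$gene_id, sample(seq_len(ct$enhancer_targets_max), 1))
    enh[[eid]] <- data.frame(enhancer_id = sprintf("ENH%04d", eid), chrom = ch,
                             start = st,
                             end = st + round(stats::runif(1, 500, 1500)),
                             target_gene = tg)
  }
  enhancers <- enhancer_map(do.call(rbind, enh))
  coupled_links <- if (length(coupled)) do.call(rbind, coupled) else
    data.frame(enhancer_id = character(), dmr_id = character(),
               target_gene = character())
  ## chromatin-state segmentations
  state_probs <- stats::setNames(rep(0.2 / 11, 15), CHROMATIN_STATES)
  state_probs[c("Quies", "TxWk", "Tx", "Enh", "TssA")] <-
    c(0.50, 0.12, 0.06, 0.06, 0.06)
  states <- list()
  for (ctype in paste0("CT", seq_len(ct$n_state_celltypes))) {
    for (ch in chroms) {
      at <- 0
      seg <- list()
      while (at < ct$chrom_length) {
        w <- min(round(stats::rexp(1, 1 / ct$state_mean_seglen)) + 200,
                 ct$chrom_length - at)
        seg[[length(seg) + 1L]] <- data.frame(
          chrom = ch, start = at, end = at + w,
          state = sample(CHROMATIN_STATES, 1, prob = state_probs),
          cell_type = ctype)
        at <- at + w
      }
      states[[length(states) + 1L]] <- do.call(rbind, seg)
    }
  }
  states <- chromatin_states(do.call(rbind, states))
  list(layout = layout, cpgs = cp[, c("chrom", "pos", "island")],
       cgis = cgis, genes = genes, snps = snps, enhancers = enhancers,
       states = states, cell_reference = cell_ref, site_base = base,
       truth = list(dmrs = true_dmrs, dmr_sites = dmr_sites,
                    ref_idx = ref_idx, cell_eff_idx = cell_eff_idx,
                    cell_eff = cell_eff, coupled_links = coupled_links))
}

#' @keywords internal
make_subjects <- function(config) {
  ct <- config
  n_wg <- c(ct$n_smokers, ct$n_nonsmokers)
  n_rna <- c(ct$n_rna_smokers, ct$n_rna_nonsmokers)
  n_ov <- c(ct$n_overlap_smokers, ct$n_overlap_nonsmokers)
  groups <- c("smoker", "nonsmoker")
  subj <- list()
  for (g in 1:2) {
    total <- n_wg[g] + n_rna[g] - n_ov[g]
    wgbs <- c(rep(TRUE, n_wg[g]), rep(FALSE, total - n_wg[g]))
    rna <- c(rep(TRUE, n_ov[g]), rep(FALSE, n_wg[g] - n_ov[g]),
             rep(TRUE, total - n_wg[g]))
    miner <- sample(rep(c(TRUE, FALSE), length.out = total))
    subj[[g]] <- data.frame(
      group = groups[g],
      age = round(stats::rnorm(total, ct$age_mean, ct$age_sd), 1),
      bmi = round(stats::rnorm(total, ct$bmi_mean, ct$bmi_sd), 1),
      miner = miner, wgbs = wgbs, rna = rna)
  }
  out <- do.call(rbind, subj)
  out$sample_id <- sprintf("S%03d", seq_len(nrow(out)))
  ## cytokine subset drawn from WGBS subjects
  out$cyto <- FALSE
  for (g in 1:2) {
    idx <- which(out$group == groups[g] & out$wgbs)
    n_cy <- if (g == 1) ct$n_cyto_smokers else ct$n_cyto_nonsmokers
    out$cyto[sample(idx, n_cy)] <- TRUE
  }
  ## group-specific Dirichlet cell composition
  props <- matrix(NA_real_, nrow(out), length(ct$cell_types),
                  dimnames = list(out$sample_id, ct$cell_types))
  for (i in seq_len(nrow(out))) {
    mu <- if (out$group[i] == "smoker") ct$cell_mean_smoker else
      ct$cell_mean_nonsmoker
    props[i, ] <- rdirichlet_one(mu * ct$cell_concentration)
  }
  rownames(out) <- NULL
  list(sheet = out[, c("sample_id", "group", "age", "bmi", "miner",
                       "wgbs", "rna", "cyto")],
       cell_props = props)
}

#' Simulate per-CpG methylation counts for the WGBS subset
#'
#' True level per site and subject = baseline + planted group effect inside
#' DMRs + per-subject regional deviation + covariate effects + granulocyte
#' loading (reference sites instead mix the cell reference profiles by the
#' subject's true composition), bounded to (0, 1); reads are beta-binomial
#' around the truth at truncated-Poisson depth.
#'
#' @param config [sim_config()]. @param genome from [simulate_genome()].
#' @param subjects from the cohort builder (sheet + cell_props).
#' @param dmr_dev planted-DMR x subject matrix of regional deviations.
#' @return list(counts = methylation_counts, sheet = WGBS sample sheet,
#'   true_levels = sites x samples matrix).
#' @export
simulate_methylation <- function(config, genome, subjects, dmr_dev) {
  set.seed(child_seed(config, 202))
  ct <- config
  sheet <- subjects$sheet[subjects$sheet$wgbs, , drop = FALSE]
  ids <- sheet$sample_id
  ns <- nrow(genome$cpgs); np <- length(ids)
  L <- matrix(genome$site_base, ns, np)
  smoker <- as.numeric(sheet$group == "smoker")
  tr <- genome$truth
  for (j in seq_len(nrow(tr$dmrs))) {
    idx <- tr$dmr_sites[[j]]
    shift <- tr$dmrs$delta[j] * smoker + dmr_dev[j, ids]
    L[idx, ] <- L[idx, ] + rep(shift, each = length(idx))
  }
  xb <- ct$beta_age * (sheet$age - ct$age_mean) +
    ct$beta_bmi * (sheet$bmi - ct$bmi_mean) +
    ct$beta_miner * (sheet$miner - 0.5)
  L <- L + rep(xb, each = ns)
  gran <- subjects$cell_props[ids, "Gran"]
  L[tr$cell_eff_idx, ] <- L[tr$cell_eff_idx, ] +
    outer(tr$cell_eff, gran - mean(gran))
  L[tr$ref_idx, ] <- genome$cell_reference %*%
    t(subjects$cell_props[ids, , drop = FALSE])
  L <- pmin(pmax(L, 0.005), 0.995)
  depth <- matrix(stats::rpois(ns * np, ct$mean_depth), ns, np)
  depth[depth == 0] <- 1L
  meth <- rbetabinom_mat(depth, L, ct$overdispersion)
  unmeth <- depth - meth
  dimnames(meth) <- dimnames(unmeth) <- list(NULL, ids)
  sites <- genome$cpgs[, c("chrom", "pos")]
  sites$strand <- "+"
  list(counts = methylation_counts(sites, meth, unmeth),
       sheet = sample_sheet(sheet[, c("sample_id", "group", "age", "bmi",
                                      "miner")]),
       true_levels = structure(L, dimnames = list(NULL, ids)))
}

#' Simulate the expression count matrix for the RNA subset
#'
#' Negative-binomial counts around gene baselines; planted DEGs carry the
#' configured log2 fold changes; targets of enhancers sitting on planted
#' DMRs are shifted by -coupling_strength x (subject's regional methylation
#' - cohort mean), yielding recoverable negative methylation-expression
#' correlations.
#'
#' @param config,genome,subjects as in [simulate_methylation()].
#' @param dmr_latent planted-DMR x all-subjects latent regional methylation.
#' @return list(counts = transcripts x samples matrix, sheet, truth_degs).
#' @export
simulate_expression <- function(config, genome, subjects, dmr_latent) {
  set.seed(child_seed(config, 303))
  ct <- config
  sheet <- subjects$sheet[subjects$sheet$rna, , drop = FALSE]
  ids <- sheet$sample_id
  tx <- c(genome$genes$gene_id,
          sprintf("TX%04d", seq_len(ct$n_transcripts - nrow(genome$genes))))
  ng <- length(tx); np <- length(ids)
  base <- stats::rlnorm(ng, log(150), 1.2)
  low <- stats::runif(ng) < 0.15  # lowly expressed tail, mostly CPM-filtered
  low[tx %in% genome$truth$coupled_links$target_gene] <- FALSE
  base[low] <- stats::rlnorm(sum(low), log(0.15), 1)
  coupled_genes <- unique(genome$truth$coupled_links$target_gene)
  eligible <- setdiff(tx[!low], coupled_genes)
  deg_ids <- sample(eligible, ct$n_degs)
  mags <- seq(ct$deg_log2fc_range[1], ct$deg_log2fc_range[2],
              length.out = ct$n_degs)
  sgn <- sample(c(-1, 1), ct$n_degs, replace = TRUE)
  sgn[which.max(mags)] <- 1  # headline DEG planted upregulated at the max
  lfc <- stats::setNames(mags * sgn, deg_ids)
  smoker <- as.numeric(sheet$group == "smoker")
  shift <- matrix(0, ng, np, dimnames = list(tx, ids))
  shift[deg_ids, ] <- outer(lfc, smoker)
  cl <- genome$truth$coupled_links
  for (i in seq_len(nrow(cl))) {
    lat <- dmr_latent[cl$dmr_id[i], ids]
    shift[cl$target_gene[i], ] <- shift[cl$target_gene[i], ] -
      ct$enhancer_coupling_strength * (lat - mean(dmr_latent[cl$dmr_id[i], ]))
  }
  xb <- 0.005 * (sheet$age - ct$age_mean) + 0.005 * (sheet$bmi - ct$bmi_mean) +
    0.05 * (sheet$miner - 0.5)
  libf <- stats::rlnorm(np, 0, 0.15)
  mu <- base * 2^(shift + rep(xb, each = ng)) * rep(libf, each = ng)
  counts <- matrix(stats::rnbinom(ng * np, mu = mu, size = ct$nb_size),
                   ng, np, dimnames = list(tx, ids))
  list(counts = counts,
       sheet = sample_sheet(sheet[, c("sample_id", "group", "age", "bmi",
                                      "miner")]),
       truth_degs = data.frame(transcript = deg_ids, log2fc = unname(lfc)))
}

#' Simulate the 27-analyte cytokine panel for the plasma subset
#'
#' Gaussian log2 intensities with analyte-specific baselines, planted smoker
#' shifts for the named analytes, and a small age leakage.
#'
#' @param config,subjects as above.
#' @return list(panel = analyte x sample matrix, sheet, truth_shifts).
#' @export
simulate_cytokines <- function(config, subjects) {
  set.seed(child_seed(config, 404))
  ct <- config
  sheet <- subjects$sheet[subjects$sheet$cyto, , drop = FALSE]
  ids <- sheet$sample_id
  shifts <- ct$cytokine_shifts
  extra <- ct$n_cytokines - length(shifts)
  analytes <- c(names(shifts), sprintf("CYT%02d", seq_len(extra)))
  shift_vec <- stats::setNames(c(shifts, rep(0, extra)), analytes)
  baseline <- stats::runif(ct$n_cytokines, 6, 14)
  smoker <- as.numeric(sheet$group == "smoker")
  mu <- outer(baseline, rep(1, length(ids))) +
    outer(shift_vec, smoker) +
    0.01 * rep(sheet$age - ct$age_mean, each = ct$n_cytokines)
  panel <- mu + stats::rnorm(length(mu), 0, ct$cytokine_sd)
  dimnames(panel) <- list(analytes, ids)
  list(panel = panel,
       sheet = sample_sheet(sheet[, c("sample_id", "group", "age", "bmi",
                                      "miner")]),
       truth_shifts = shift_vec)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Orchestrates the genome, subject, methylation, expression and cytokine
#' simulators under per-stage child seeds and assembles the ground-truth
#' ledger (planted DMRs, DEGs, coupled enhancer links, covariates, true cell
#' proportions, cytokine shifts).
#'
#' @param config a [sim_config()].
#' @return list: config, genome, subjects, meth (counts/sheet/true_levels),
#'   expr (counts/sheet), cyto (panel/sheet), truth.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(child_seed(config, 1))
  subjects <- make_subjects(config)
  genome <- simulate_genome(config)
  set.seed(child_seed(config, 151))
  tr <- genome$truth
  n_d <- nrow(tr$dmrs)
  all_ids <- subjects$sheet$sample_id
  dmr_dev <- matrix(stats::rnorm(n_d * length(all_ids), 0,
                                 config$dmr_sample_sd),
                    n_d, length(all_ids),
                    dimnames = list(tr$dmrs$dmr_id, all_ids))
  smoker <- as.numeric(subjects$sheet$group == "smoker")
  base_mean <- vapply(tr$dmr_sites, function(ix) mean(genome$site_base[ix]),
                      1.0)
  dmr_latent <- matrix(base_mean, n_d, length(all_ids)) +
    tr$dmrs$delta %o% smoker + dmr_dev
  dmr_latent <- pmin(pmax(dmr_latent, 0.01), 0.99)
  dimnames(dmr_latent) <- dimnames(dmr_dev)
  meth <- simulate_methylation(config, genome, subjects, dmr_dev)
  expr <- simulate_expression(config, genome, subjects, dmr_latent)
  cyto <- simulate_cytokines(config, subjects)
  truth <- list(dmrs = tr$dmrs, degs = expr$truth_degs,
                coupled_links = tr$coupled_links,
                cell_props = subjects$cell_props,
                dmr_latent = dmr_latent,
                cytokine_shifts = cyto$truth_shifts,
                ref_idx = tr$ref_idx, dmr_sites = tr$dmr_sites)
  list(config = config, genome = genome, subjects = subjects,
       meth = meth, expr = expr, cyto = cyto, truth = truth)
}
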