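test_that("cohort simulation is fully deterministic under a fixed seed", {
  a <- simulate_cohort(tiny_config(seed = 11))
  b <- simulate_cohort(tiny_config(seed = 11))
  expect_identical(a$meth$counts$meth, b$meth$counts$meth)
  expect_identical(a$expr$counts, b$expr$counts)
  expect_identical(a$cyto$panel, b$cyto$panel)
  expect_identical(a$truth$dmrs, b$truth$dmrs)
  c <- simulate_cohort(tiny_config(seed = 12))
  expect_false(identical(a$meth$counts$meth, c$meth$counts$meth))
})

test_that("planted DMRs satisfy the merge-rule geometry", {
  co <- tiny_cohort()
  tr <- co$truth$dmrs
  expect_true(nrow(tr) > 0)
  expect_true(all(tr$n_cpg >= 5))
  for (j in seq_len(nrow(tr))) {
    idx <- co$truth$dmr_sites[[j]]
    pos <- co$genome$cpgs$pos[idx]
    expect_true(all(co$genome$cpgs$chrom[idx] == tr$chrom[j]))
    expect_true(all(diff(pos) <= 200))
    expect_gte(length(pos), 5)
  }
  # planted regions are non-overlapping
  expect_equal(anyDuplicated(unlist(co$truth$dmr_sites)), 0L)
})

test_that("config with zero planted DMRs leaves the truth ledger empty", {
  co <- simulate_cohort(tiny_config(seed = 5, n_dmrs = 0,
                                    n_coupled_enhancers = 0))
  expect_equal(nrow(co$truth$dmrs), 0L)
  expect_equal(nrow(co$truth$coupled_links), 0L)
})

test_that("infeasible geometry is rejected", {
  expect_error(sim_config(n_cpgs = 1e6, chrom_length = 1e5, n_chroms = 1),
               "infeasible")
})

test_that("baseline methylation is bimodal with modes at the extremes", {
  co <- tiny_cohort()
  lv <- methylation_level(co$meth$counts$meth, co$meth$counts$unmeth)
  lv <- as.vector(lv)
  lv <- lv[!is.na(lv)]
  h <- hist(lv, breaks = seq(0, 1, 0.1), plot = FALSE)
  d <- h$counts / length(lv)
  expect_gt(d[1], 0.2)   # mode in [0, 0.1]
  expect_gt(d[10], 0.2)  # mode in [0.9, 1.0]
  expect_true(all(d[1] > d[2:9]))
  expect_true(all(d[10] > d[2:9]))
  # about a fifth of CpGs sit in CpG-rich areas
  expect_gt(mean(co$genome$cpgs$island), 0.15)
  expect_lt(mean(co$genome$cpgs$island), 0.25)
})

test_that("planted group differences are recoverable by direct averaging", {
  co <- tiny_cohort()
  raw <- methylation_level(co$meth$counts$meth, co$meth$counts$unmeth)
  sm <- co$meth$sheet$group == "smoker"
  tr <- co$truth$dmrs
  big <- which(abs(tr$delta) >= 0.08)
  expect_true(length(big) > 0)
  for (j in big) {
    idx <- co$truth$dmr_sites[[j]]
    d <- mean(rowMeans(raw[idx, sm, drop = FALSE]) -
                rowMeans(raw[idx, !sm, drop = FALSE]))
    expect_lt(abs(d - tr$delta[j]), 0.05)
  }
})

test_that("hyper:hypo planted ratio tracks the configured fraction", {
  signs <- unlist(lapply(1:4, function(s) {
    co <- simulate_cohort(tiny_config(seed = 100 + s))
    co$truth$dmrs$direction == "hyper"
  }))
  phat <- mean(signs)
  se <- sqrt(0.75 * 0.25 / length(signs))
  expect_lt(abs(phat - 0.75), 4 * se)
})

test_that("null methylation simulation shows no group difference", {
  # planted delta ~ 0 everywhere: group means differ only by sampling noise
  pvals <- vapply(1:6, function(s) {
    co <- simulate_cohort(tiny_config(seed = 200 + s, n_dmrs = 1,
                                      dmr_delta_range = c(1e-6, 2e-6),
                                      dmr_delta_mean = 1.4e-6,
                                      cell_mean_smoker =
                                        c(0.07, 0.08, 0.16, 0.11, 0.08, 0.50),
                                      cell_effect_fraction = 1e-4,
                                      beta_age = 0, beta_bmi = 0,
                                      beta_miner = 0))
    raw <- methylation_level(co$meth$counts$meth, co$meth$counts$unmeth)
    sm <- co$meth$sheet$group == "smoker"
    stats::t.test(colMeans(raw[, sm]), colMeans(raw[, !sm]))$p.value
  }, 1.0)
  expect_gte(mean(pvals > 0.01), 5 / 6)
})

test_that("planted expression fold changes appear in the group count ratio", {
  # sparse toy genome: partial DMR planting is expected and irrelevant here
  co <- suppressWarnings(
    simulate_cohort(sim_config(seed = 33, n_cpgs = 4000,
                               chrom_length = 4e5, n_genes = 80,
                               n_transcripts = 400, n_cgis_per_chrom = 10,
                               n_dmrs = 10, n_snps = 400,
                               n_cell_ref_sites = 150)))
  tr <- co$truth$degs
  top <- tr[which.max(abs(tr$log2fc)), ]
  expect_equal(top$log2fc, 2.25)
  cnt <- co$expr$counts
  lib <- colSums(cnt)
  cpm <- t(t(cnt) / lib) * 1e6
  sm <- co$expr$sheet$group == "smoker"
  ratio <- mean(cpm[top$transcript, sm]) / mean(cpm[top$transcript, !sm])
  expect_gt(ratio, 2^1.75)
  expect_lt(ratio, 2^2.75)
})

test_that("enhancer coupling creates negative methylation-expression association", {
  co <- tiny_cohort()
  cl <- co$truth$coupled_links
  expect_true(nrow(cl) > 0)
  ids <- intersect(colnames(co$expr$counts),
                   colnames(co$truth$dmr_latent))
  rhos <- vapply(seq_len(nrow(cl)), function(i) {
    x <- co$truth$dmr_latent[cl$dmr_id[i], ids]
    y <- log2(co$expr$counts[cl$target_gene[i], ids] + 0.5)
    stats::cor(x, y, method = "spearman")
  }, 1.0)
  expect_lt(median(rhos), -0.3)
  # coupling off: correlations centred on zero
  co0 <- simulate_cohort(tiny_config(seed = 42,
                                     enhancer_coupling_strength = 0))
  cl0 <- co0$truth$coupled_links
  ids0 <- intersect(colnames(co0$expr$counts), colnames(co0$truth$dmr_latent))
  rhos0 <- vapply(seq_len(nrow(cl0)), function(i) {
    x <- co0$truth$dmr_latent[cl0$dmr_id[i], ids0]
    y <- log2(co0$expr$counts[cl0$target_gene[i], ids0] + 0.5)
    stats::cor(x, y, method = "spearman")
  }, 1.0)
  expect_lt(abs(median(rhos0)), 0.3)
})

test_that("cytokine panel has the configured shape and null analytes are null", {
  co <- tiny_cohort()
  expect_equal(dim(co$cyto$panel),
               c(27, sum(co$subjects$sheet$cyto)))
  expect_true(all(c("VEGF", "FGF_basic") %in% rownames(co$cyto$panel)))
  # unshifted analytes: two-group t-test p-values roughly uniform
  ps <- unlist(lapply(1:5, function(s) {
    cc <- simulate_cohort(tiny_config(seed = 300 + s,
                                      cytokine_shifts = c(VEGF = 0)))
    smv <- cc$cyto$sheet$group == "smoker"
    apply(cc$cyto$panel, 1, function(y)
      stats::t.test(y[smv], y[!smv])$p.value)
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cohort writers produce readable round-trip files", {
  co <- tiny_cohort()
  td <- withr::local_tempdir()
  write_cohort(co, td)
  mc2 <- read_methylation_tsv(file.path(td, "methylation_counts.tsv"))
  expect_equal(mc2$meth, co$meth$counts$meth, ignore_attr = TRUE)
  cnt2 <- read_counts_tsv(file.path(td, "expression_counts.tsv"))
  expect_equal(unname(cnt2), unname(co$expr$counts))
  genes2 <- read_gene_models_tsv(file.path(td, "gene_models.tsv"))
  expect_equal(genes2$gene_id, co$genome$genes$gene_id)
  truth <- jsonlite::read_json(file.path(td, "truth.json"))
  expect_equal(length(truth$dmrs), nrow(co$truth$dmrs))
})
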