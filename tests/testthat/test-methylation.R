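test_that("methylation level is the methylated-read fraction, guarded at 0/0", {
  expect_equal(methylation_level(3, 1), 0.75)
  expect_equal(methylation_level(0, 7), 0)
  expect_true(is.na(methylation_level(0, 0)))
  # scale-free: (k*Nmc, k*Nnmc) gives the same level
  set.seed(1)
  m <- rpois(1000, 5); u <- rpois(1000, 5)
  ok <- m + u > 0
  for (k in c(2L, 7L))
    expect_equal(methylation_level(k * m[ok], k * u[ok]),
                 methylation_level(m[ok], u[ok]))
  # matrix form agrees with elementwise division oracle
  M <- matrix(rpois(60, 4), 10); U <- matrix(rpois(60, 4), 10)
  lv <- methylation_level(M, U)
  for (i in seq_len(10)) for (j in seq_len(6)) {
    tot <- M[i, j] + U[i, j]
    expect_equal(lv[i, j], if (tot == 0) NA_real_ else M[i, j] / tot)
  }
})

test_that("common-SNP filtering covers both bases of the dinucleotide", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400))
  snps <- snp_set(data.frame(chrom = "chr1", pos = c(100, 201, 300, 401),
                             maf = c(0.10, 0.30, 0.01, 0.04)))
  kept <- filter_snp_overlap(sites, snps)
  # pos 100: SNP on first base, MAF 10% -> removed
  # pos 200: SNP at 201 = second base, MAF 30% -> removed
  # pos 300: MAF 1% below threshold -> retained
  # pos 400: SNP at 401 but MAF 4% -> retained
  expect_equal(kept$pos, c(300, 400))
  expect_equal(attr(kept, "n_removed"), 2L)
  # idempotent and order-independent
  again <- filter_snp_overlap(kept, snps)
  expect_equal(again$pos, kept$pos)
  shuf <- filter_snp_overlap(sites[c(3, 1, 4, 2), ], snps)
  expect_setequal(shuf$pos, kept$pos)
})

make_counts <- function(pos, levels_mat, depth = 12, chrom = "chr1") {
  n <- length(pos); s <- ncol(levels_mat)
  meth <- round(levels_mat * depth)
  unmeth <- depth - meth
  colnames(meth) <- colnames(unmeth) <- sprintf("S%02d", seq_len(s))
  methylation_counts(data.frame(chrom = chrom, pos = pos), meth, unmeth)
}

test_that("smoothing preserves constants and respects block boundaries", {
  pos <- sort(c(seq(0, 4900, by = 100), seq(10000, 14900, by = 100)))
  lv <- matrix(0.5, length(pos), 4)
  x <- make_counts(pos, lv)
  sm <- smooth_profiles(x)
  expect_true(all(abs(sm - 0.5) < 1e-12))
  # two blocks: perturbing cluster 1 leaves cluster 2 untouched
  lv2 <- lv; lv2[1:10, ] <- 0.9
  sm2 <- smooth_profiles(make_counts(pos, lv2))
  second <- pos >= 10000
  expect_equal(sm2[second, ], sm[second, ])
  expect_false(isTRUE(all.equal(sm2[!second, ], sm[!second, ])))
  expect_error(smooth_profiles(
    methylation_counts(data.frame(chrom = "chr1", pos = c(200, 100)),
                       matrix(1, 2, 1, dimnames = list(NULL, "a")),
                       matrix(1, 2, 1, dimnames = list(NULL, "a")))),
    NA) # constructor sorts; smoothing accepts sorted output
})

test_that("smoothing reduces error on a noisy step profile", {
  set.seed(99)
  pos <- seq(0, 9900, by = 100)
  truth <- rep(c(0.2, 0.8), each = 50)
  depth <- matrix(rpois(100 * 20, 12), 100, 20)
  depth[depth == 0] <- 1
  meth <- matrix(rbinom(100 * 20, as.vector(depth), rep(truth, 20)), 100, 20)
  colnames(meth) <- sprintf("S%02d", 1:20)
  unmeth <- depth - meth
  colnames(unmeth) <- colnames(meth)
  x <- methylation_counts(data.frame(chrom = "chr1", pos = pos), meth, unmeth)
  raw <- methylation_level(x$meth, x$unmeth)
  sm <- smooth_profiles(x)
  mae_raw <- mean(abs(raw - truth))
  mae_sm <- mean(abs(sm - truth))
  expect_lt(mae_sm, mae_raw)
})

test_that("cell deconvolution recovers exact and noisy mixtures", {
  set.seed(7)
  types <- c("B", "NK", "CD4T", "CD8T", "Mono", "Gran")
  ref <- matrix(rbeta(200 * 6, 0.5, 0.5), 200, 6,
                dimnames = list(sprintf("chr1:%d", 1:200), types))
  # identity mixture
  bulk <- ref[, "Gran", drop = FALSE]
  colnames(bulk) <- "s1"
  pr <- estimate_cell_proportions(bulk, ref)
  expect_equal(unname(pr["s1", ]), c(0, 0, 0, 0, 0, 1), tolerance = 1e-8)
  # exact 50/50 mixture
  bulk2 <- cbind(s2 = 0.5 * ref[, "B"] + 0.5 * ref[, "NK"])
  pr2 <- estimate_cell_proportions(bulk2, ref)
  expect_equal(unname(pr2["s2", ]), c(0.5, 0.5, 0, 0, 0, 0), tolerance = 1e-8)
  # noisy mixtures: RMSE below 0.05
  true_p <- t(vapply(1:10, function(i) {
    g <- rgamma(6, c(2, 2, 4, 3, 2, 12)); g / sum(g)
  }, numeric(6)))
  noisy <- ref %*% t(true_p) + matrix(rnorm(200 * 10, 0, 0.02), 200)
  colnames(noisy) <- sprintf("n%02d", 1:10)
  prn <- estimate_cell_proportions(noisy, ref)
  expect_lt(sqrt(mean((prn - true_p)^2)), 0.05)
  # proportions are a simplex
  expect_true(all(prn >= 0))
  expect_equal(unname(rowSums(prn)), rep(1, 10))
  expect_error(estimate_cell_proportions(bulk, ref[, c(1, 1, 2:5)]),
               "rank")
})

test_that("site association recovers planted effects and guards degenerates", {
  co <- tiny_cohort()
  tk <- run_methylation_tracks(co)
  # planted large-delta DMRs: smoothed-track estimate near truth
  tr <- co$truth$dmrs
  st <- site_association(tk$raw, co$meth$sheet, tk$cell_props)
  for (j in which(abs(tr$delta) >= 0.09)) {
    idx <- which(tk$mc$sites$chrom == tr$chrom[j] &
                   tk$mc$sites$pos >= tr$start[j] &
                   tk$mc$sites$pos < tr$end[j])
    est <- mean(st$delta[idx], na.rm = TRUE)
    # ~3 standard errors at n = 12 + 12 with regional variability
    expect_lt(abs(est - tr$delta[j]), 0.075)
  }
  # identical groups, constant covariates: delta 0, p 1
  lv <- matrix(0.4, 5, 8, dimnames = list(NULL, sprintf("P%d", 1:8)))
  sheet <- sample_sheet(data.frame(
    sample_id = sprintf("P%d", 1:8),
    group = rep(c("smoker", "nonsmoker"), each = 4),
    age = 40, bmi = 24, miner = rep(c(TRUE, FALSE), 4)))
  st0 <- site_association(lv, sheet, NULL)
  expect_equal(st0$delta, rep(0, 5))
  expect_equal(st0$p, rep(1, 5))
})

test_that("adjustment for cell composition is what keeps the test calibrated", {
  # under a between-group composition shift with no direct smoking effect,
  # the adjusted analysis is calibrated and the unadjusted one inflates
  co <- simulate_cohort(tiny_config(seed = 77, n_dmrs = 1,
                                    dmr_delta_range = c(1e-6, 2e-6),
                                    dmr_delta_mean = 1.4e-6,
                                    cell_mean_smoker =
                                      c(0.04, 0.05, 0.10, 0.07, 0.04, 0.70),
                                    cell_mean_nonsmoker =
                                      c(0.08, 0.09, 0.18, 0.12, 0.08, 0.45),
                                    cell_effect_fraction = 0.6,
                                    cell_effect_sd = 0.25))
  tkc <- run_methylation_tracks(co)
  lv <- tkc$raw
  adj <- site_association(lv, co$meth$sheet, tkc$cell_props)
  unadj <- site_association(lv, co$meth$sheet, NULL)
  frac_adj <- mean(adj$p < 0.05, na.rm = TRUE)
  frac_unadj <- mean(unadj$p < 0.05, na.rm = TRUE)
  expect_gt(frac_unadj, frac_adj * 1.5)
  expect_lt(frac_adj, 0.10)
})
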