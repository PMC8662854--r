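test_that("gene-body linking applies the asymmetric extension", {
  genes <- toy_genes()  # gA: 10000-20000, gB: 40000-50000
  dmr <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                   name = "d")
  # DMR ending 1500 bp before gA: inside the 2000 bp upstream extension
  expect_equal(annotate_dmr_genes(dmr(8000, 8500), genes)$gene, "gA")
  # 2500 bp away: not linked
  expect_equal(nrow(annotate_dmr_genes(dmr(7000, 7500), genes)), 0L)
  # intronic DMR is linked
  expect_equal(annotate_dmr_genes(dmr(13000, 13400), genes)$gene, "gA")
  # downstream side only extends 1000 bp
  expect_equal(annotate_dmr_genes(dmr(20500, 20900), genes)$gene, "gA")
  expect_equal(nrow(annotate_dmr_genes(dmr(21100, 21500), genes)), 0L)
  # with zero extensions this reduces to plain overlap
  expect_equal(nrow(annotate_dmr_genes(dmr(8000, 9999), genes,
                                       up_ext = 0, down_ext = 0)), 0L)
  expect_equal(annotate_dmr_genes(dmr(8000, 10001), genes, up_ext = 0,
                                  down_ext = 0)$gene, "gA")
})

test_that("regulatory mapping produces promoter and one-to-many enhancer links", {
  genes <- toy_genes()
  prom <- build_promoters(genes, toy_layout())
  enh <- enhancer_map(data.frame(
    enhancer_id = c("E1", "E1", "E2"), chrom = "chr1",
    start = c(30000, 30000, 60000), end = c(31000, 31000, 61000),
    target_gene = c("gA", "gB", "gA")))
  dmrs <- data.frame(chrom = "chr1", start = c(9000, 30500, 70000),
                     end = c(9500, 30800, 70500),
                     name = c("d_prom", "d_enh", "d_none"))
  links <- map_regulatory_dmrs(dmrs, prom, enh)
  expect_equal(links$gene[links$dmr == "d_prom" &
                            links$link_class == "promoter"], "gA")
  enh_links <- links[links$dmr == "d_enh", ]
  expect_setequal(enh_links$gene, c("gA", "gB"))
  expect_true(all(enh_links$enhancer_id == "E1"))
  expect_false("d_none" %in% links$dmr)
})

test_that("DMR mean methylation averages covered CpGs per sample", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400, 500))
  lv <- cbind(s1 = c(0.2, 0.4, 0.6, 0.8, 1.0),
              s2 = c(0.5, 0.5, 0.5, 0.5, 0.5),
              s3 = c(NA, NA, NA, NA, NA))
  dmrs <- data.frame(chrom = "chr1", start = 100, end = 501, name = "d1")
  mm <- dmr_mean_methylation(dmrs, sites, lv)
  expect_equal(mm["d1", "s1"], 0.6)
  expect_equal(mm["d1", "s2"], 0.5)
  expect_true(is.na(mm["d1", "s3"]))
  # invariant to CpG ordering
  o <- c(3, 1, 5, 2, 4)
  mm2 <- dmr_mean_methylation(dmrs, sites[o, ], lv[o, ])
  expect_equal(mm2["d1", "s1"], 0.6)
})

test_that("Spearman test handles monotone, tied and transformed data", {
  x <- 1:10
  y <- 10:1
  st <- spearman_test(x, y)
  expect_equal(st$rho, -1)
  expect_lt(st$p, 0.001)
  # agreement with cor.test on untied data
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(15); b <- 0.5 * a + rnorm(15)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman"))
    st2 <- spearman_test(a, b)
    expect_equal(st2$rho, unname(ref$estimate), tolerance = 1e-12)
  }
  # rank property: invariant under strictly monotone transforms
  a <- rexp(12); b <- a + rnorm(12, 0, 0.2)
  expect_equal(spearman_test(exp(a), b)$rho, spearman_test(a, b)$rho)
  expect_equal(spearman_test(a, log(b + 10))$rho, spearman_test(a, b)$rho)
  # average-rank ties
  expect_equal(spearman_test(c(1, 1, 2, 3), c(4, 4, 5, 6))$rho, 1,
               tolerance = 1e-12)
  # degenerate input
  expect_true(is.na(spearman_test(rep(1, 6), rnorm(6))$rho))
  # exact permutation p agrees with the t approximation in direction
  ex <- spearman_test(1:6, c(2, 1, 4, 3, 6, 5), method = "exact")
  expect_gt(ex$rho, 0.5)
  expect_lt(ex$p, 0.2)
})

test_that("quadrant classification is the stated bijection", {
  expect_equal(classify_quadrant("hyper", "up"), "Hyper-Up")
  expect_equal(classify_quadrant("hyper", "down"), "Hyper-Down")
  expect_equal(classify_quadrant("hypo", "up"), "Hypo-Up")
  expect_equal(classify_quadrant("hypo", "down"), "Hypo-Down")
  all4 <- classify_quadrant(c("hyper", "hyper", "hypo", "hypo"),
                            c("up", "down", "up", "down"))
  expect_equal(length(unique(all4)), 4L)
  expect_error(classify_quadrant("high", "up"))
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  # N=20, K=5, n=5, k=5 -> 1/choose(20,5)
  u <- sprintf("g%02d", 1:20)
  expect_equal(hypergeom_geneset_test(u[1:5], u[1:5], u),
               1 / choose(20, 5), tolerance = 1e-12)
  # query = set = universe -> 1
  expect_equal(hypergeom_geneset_test(u, u, u), 1)
  # k = 0 -> P(X >= 0) = 1
  expect_equal(hypergeom_geneset_test(u[1:5], u[6:10], u), 1)
  # random instances against a dhyper-summation oracle
  set.seed(10)
  for (i in 1:1000) {
    N <- sample(5:40, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    uu <- sprintf("x%03d", seq_len(N))
    gs <- sample(uu, K); qq <- sample(uu, n)
    k <- length(intersect(gs, qq))
    oracle <- sum(dhyper(k:min(K, n), K, N - K, n))
    expect_equal(hypergeom_geneset_test(qq, gs, uu), oracle,
                 tolerance = 1e-10)
  }
  expect_error(hypergeom_geneset_test("a", "b", character(0)), "universe")
})

test_that("gene-set scan orders by p and adjusts with BH", {
  u <- sprintf("g%02d", 1:50)
  sets <- list(hit = u[1:10], miss = u[41:50], half = u[c(1:5, 30:34)])
  res <- geneset_enrichment(u[1:10], sets, u)
  expect_equal(res$set[1], "hit")
  expect_true(all(diff(res$p) >= 0))
  expect_equal(res$q, p.adjust(res$p[order(res$p)], "BH")[rank(res$p)])
})

test_that("pair correlation recovers planted enhancer coupling", {
  co <- tiny_cohort()
  tk <- run_methylation_tracks(co)
  dmrs <- call_dmrs(tk$inf, estimate_acf(tk$inf), selection_track = tk$sel)
  kept <- cpm_filter(co$expr$counts)
  sheet <- co$expr$sheet
  X <- cbind(1, as.numeric(sheet$group == "smoker"), sheet$age, sheet$bmi,
             as.numeric(sheet$miner))
  vw <- mean_variance_weights(kept, X)
  deg <- deg_test(vw$logcpm, vw$weights, sheet)
  prom <- build_promoters(co$genome$genes, co$genome$layout)
  links <- map_regulatory_dmrs(dmrs, prom, co$genome$enhancers)
  sm <- smooth_profiles(tk$mc)
  dmr_meth <- dmr_mean_methylation(dmrs, tk$mc$sites, sm)
  overlap <- intersect(colnames(dmr_meth), colnames(vw$logcpm))
  pairs <- correlate_pairs(links[links$link_class == "enhancer", ],
                           dmr_meth, vw$logcpm, deg, dmrs,
                           samples = overlap)
  # links to planted coupled enhancers that survive the filters should be
  # significantly negatively correlated
  cl <- co$truth$coupled_links
  planted <- pairs[pairs$enhancer_id %in% cl$enhancer_id &
                     paste(pairs$enhancer_id, pairs$gene) %in%
                     paste(cl$enhancer_id, cl$target_gene), ]
  if (nrow(planted) > 0) {
    expect_gte(mean(planted$significant), 0.5)
    expect_lt(median(planted$rho), 0)
  }
  expect_true(all(pairs$quadrant %in%
                    c("Hyper-Up", "Hyper-Down", "Hypo-Up", "Hypo-Down")))
})

test_that("the shipped regulatory-pair example table reproduces its counts", {
  path <- system.file("extdata", "regulatory_pair_examples.tsv",
                      package = "dmrkit")
  pairs <- read_pair_table(path)
  s <- pair_table_summary(pairs)
  expect_equal(unname(s$block_counts["Promoter"]), 1)
  expect_equal(unname(s$block_counts["Promoter/enhancer"]), 22)
  expect_equal(s$n_pairs, 23)
  expect_gte(s$opposite_fraction, 0.70)
  expect_equal(round(s$opposite_fraction, 3), round(16 / 22, 3))
})
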