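#' Per-site methylation level
#'
#' Level = methylated reads / total reads at the site, as a fraction in
#' \[0, 1\]. Sites with zero total reads get NA (never 0/0). Works on vectors
#' or matrices elementwise.
#'
#' @param n_meth,n_unmeth methylated / unmethylated read counts.
#' @return numeric of the same shape; NA where uncovered.
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  tot <- n_meth + n_unmeth
  out <- n_meth / tot
  out[tot == 0] <- NA_real_
  out
}

#' Remove CpGs overlapping common SNPs
#'
#' A CpG is dropped when a SNP with MAF above the threshold falls on either
#' base of the CpG dinucleotide (pos or pos + 1). Genotype at such sites can
#' mimic methylation differences.
#'
#' @param x methylation_counts, or a site data.frame with chrom/pos.
#' @param snps SNP table (chrom, pos 0-based, maf), see [snp_set()].
#' @param maf_threshold drop SNP-overlapping CpGs when maf > this (default 0.05).
#' @return object of the same kind as `x`, restricted to retained sites, with
#'   attribute `n_removed`.
#' @export
filter_snp_overlap <- function(x, snps, maf_threshold = 0.05) {
  sites <- if (inherits(x, "methylation_counts")) x$sites else x
  common <- snps[snps$maf > maf_threshold, , drop = FALSE]
  key <- function(ch, p) paste(ch, p, sep = ":")
  bad <- key(sites$chrom, sites$pos) %in% key(common$chrom, common$pos) |
    key(sites$chrom, sites$pos + 1) %in% key(common$chrom, common$pos)
  out <- if (inherits(x, "methylation_counts")) {
    subset_counts(x, which(!bad))
  } else {
    x[!bad, , drop = FALSE]
  }
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Smooth per-sample methylation profiles
#'
#' Chromosomes are split into blocks wherever the gap between adjacent CpGs
#' exceeds `max_gap`; smoothing never crosses a block boundary. Within a block,
#' each site's smoothed level is a depth-weighted, tricube-weighted local
#' linear fit over the smallest symmetric window containing at least
#' `min_cpgs` CpGs and spanning at least `min_width` bp (truncated at block
#' edges). Blocks with fewer than `min_cpgs` sites pass through unsmoothed.
#'
#' @param x methylation_counts (sites must be position-sorted per chromosome).
#' @param min_width minimum window width in bp (default 1000).
#' @param min_cpgs minimum CpGs per window (default 11).
#' @param max_gap gap in bp that discontinues smoothing (default 2000).
#' @return sites x samples matrix of smoothed levels, with attributes
#'   `blocks` (block id per site) and `unsmoothed_blocks` (count).
#' @export
smooth_profiles <- function(x, min_width = 1000, min_cpgs = 11,
                            max_gap = 2000) {
  sites <- x$sites
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) stop("sites must be sorted")
  raw <- methylation_level(x$meth, x$unmeth)
  depth <- x$meth + x$unmeth
  out <- raw
  gap_break <- c(TRUE, diff(sites$pos) > max_gap |
                   sites$chrom[-1] != sites$chrom[-nrow(sites)])
  block <- cumsum(gap_break)
  n_passthrough <- 0L
  for (b in unique(block)) {
    idx <- which(block == b)
    m <- length(idx)
    if (m < min_cpgs) { n_passthrough <- n_passthrough + 1L; next }
    pos <- sites$pos[idx]
    for (k in seq_len(m)) {
      lo <- hi <- k
      repeat {
        n_in <- hi - lo + 1
        if (n_in >= min_cpgs && (pos[hi] - pos[lo]) >= min_width) break
        can_l <- lo > 1; can_r <- hi < m
        if (!can_l && !can_r) break
        dl <- if (can_l) pos[k] - pos[lo - 1] else Inf
        dr <- if (can_r) pos[hi + 1] - pos[k] else Inf
        if (dl <= dr) lo <- lo - 1 else hi <- hi + 1
      }
      j <- lo:hi
      dx <- pos[j] - pos[k]
      h <- max(abs(dx)) + 1
      tri <- (1 - (abs(dx) / h)^3)^3
      w <- tri * depth[idx[j], , drop = FALSE]
      y <- raw[idx[j], , drop = FALSE]
      wy <- w * y; wx <- w * dx
      s0 <- colSums(w); s1 <- colSums(wx); s2 <- colSums(w * dx * dx)
      sy <- colSums(wy, na.rm = TRUE); sxy <- colSums(wx * y, na.rm = TRUE)
      den <- s0 * s2 - s1 * s1
      b0 <- ifelse(abs(den) > 1e-12, (s2 * sy - s1 * sxy) / den,
                   sy / pmax(s0, 1e-12))
      out[idx[k], ] <- pmin(pmax(b0, 0), 1)
    }
  }
  attr(out, "blocks") <- block
  attr(out, "unsmoothed_blocks") <- n_passthrough
  out
}

#' Reference-based cell-type deconvolution
#'
#' Per sample, solves non-negative least squares of the bulk methylation
#' levels at reference sites on the six leukocyte reference profiles
#' (B, NK, CD4T, CD8T, Mono, Gran), then rescales the coefficients to sum
#' to one.
#'
#' @param bulk sites x samples matrix of levels; rownames are site keys
#'   matching the reference.
#' @param reference sites x cell-types matrix of reference levels in \[0,1\].
#' @return samples x cell-types matrix of proportions (rows sum to 1).
#' @export
estimate_cell_proportions <- function(bulk, reference) {
  common <- intersect(rownames(bulk), rownames(reference))
  if (length(common) < ncol(reference))
    stop("need at least as many shared reference sites as cell types")
  R <- as.matrix(reference[common, , drop = FALSE])
  if (qr(R)$rank < ncol(R)) stop("reference matrix is rank deficient")
  B <- as.matrix(bulk[common, , drop = FALSE])
  props <- t(apply(B, 2, function(y) {
    ok <- !is.na(y)
    f <- pracma::lsqnonneg(R[ok, , drop = FALSE], y[ok])$x
    if (sum(f) <= 0) rep(1 / ncol(R), ncol(R)) else f / sum(f)
  }))
  dimnames(props) <- list(colnames(bulk), colnames(reference))
  props
}

#' Per-site association of methylation with smoking status
#'
#' Ordinary least squares of the (smoothed) methylation level on smoking
#' status, age, BMI, working condition (miner) and estimated cell proportions
#' (one component dropped to avoid the sum-to-one collinearity). The smoking
#' coefficient is the adjusted smoker-minus-nonsmoker difference on the
#' methylation-fraction scale; its two-sided t-test gives the per-site p.
#'
#' @param levels sites x samples matrix (smoothed or raw levels).
#' @param sheet sample sheet (see [sample_sheet()]); rows matched to columns
#'   of `levels` by sample_id.
#' @param cell_props samples x cell-types proportion matrix, or NULL to omit
#'   the cell-composition adjustment.
#' @param drop_cell cell type excluded from the design (default "Gran").
#' @param min_per_group minimum covered samples per group at a site (default 3).
#' @return data.frame with delta, p, n_used per site (NA where the
#'   precondition fails).
#' @export
site_association <- function(levels, sheet, cell_props = NULL,
                             drop_cell = "Gran", min_per_group = 3) {
  sheet <- sheet[match(colnames(levels), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("levels columns missing from sample sheet")
  X <- cbind(intercept = 1,
             smoker = as.numeric(sheet$group == "smoker"),
             age = sheet$age, bmi = sheet$bmi,
             miner = as.numeric(sheet$miner))
  if (!is.null(cell_props)) {
    cp <- cell_props[match(colnames(levels), rownames(cell_props)), ,
                     drop = FALSE]
    keep <- setdiff(colnames(cp), drop_cell)
    X <- cbind(X, cp[, keep, drop = FALSE])
  }
  # constant nuisance covariates carry no information; keep the fit defined
  const <- apply(X[, -(1:2), drop = FALSE], 2, function(v) stats::var(v) == 0)
  if (any(const)) X <- X[, c(TRUE, TRUE, !const)]
  n <- nrow(X); p <- ncol(X)
  smoker <- X[, "smoker"]
  full <- rowSums(is.na(levels)) == 0
  delta <- pval <- rep(NA_real_, nrow(levels))
  n_used <- integer(nrow(levels))
  fit_block <- function(Xs, Y) {
    # Y: samples x sites; shared design -> one QR
    qx <- qr(Xs)
    if (qx$rank < ncol(Xs)) return(NULL)
    cf <- qr.coef(qx, Y)
    res <- qr.resid(qx, Y)
    df_res <- nrow(Xs) - ncol(Xs)
    s2 <- colSums(res^2) / df_res
    xtxinv <- chol2inv(qr.R(qx))
    se <- sqrt(pmax(s2 * xtxinv[2, 2], 0))
    b <- cf[2, ]
    degen <- s2 < 1e-20  # numerically perfect fit (e.g. constant response)
    b[degen & abs(b) < 1e-8] <- 0
    t <- ifelse(se > 0 & !degen, b / se, ifelse(abs(b) < 1e-8, 0, Inf))
    pv <- 2 * stats::pt(-abs(t), df_res)
    pv[t == 0 & (degen | se == 0)] <- 1
    list(delta = b, p = pmin(pmax(pv, .Machine$double.xmin), 1))
  }
  idx_full <- which(full)
  if (length(idx_full)) {
    fb <- fit_block(X, t(levels[idx_full, , drop = FALSE]))
    if (is.null(fb)) stop("collinear design matrix")
    delta[idx_full] <- fb$delta
    pval[idx_full] <- fb$p
    n_used[idx_full] <- n
  }
  for (i in which(!full)) {
    ok <- !is.na(levels[i, ])
    n_used[i] <- sum(ok)
    if (sum(ok & smoker == 1) < min_per_group ||
        sum(ok & smoker == 0) < min_per_group) next
    Xs <- X[ok, , drop = FALSE]
    if (qr(Xs)$rank < ncol(Xs)) { warning("collinear design at site ", i); next }
    fb <- fit_block(Xs, cbind(levels[i, ok]))
    delta[i] <- fb$delta[1]; pval[i] <- fb$p[1]
  }
  data.frame(delta = delta, p = pval, n_used = n_used)
}

#' Build a per-site p-value track from counts + association stats
#'
#' @param x methylation_counts. @param stats output of [site_association()].
#' @return data.frame chrom, pos, delta, p sorted by position, with sites
#'   lacking stats removed.
#' @export
pvalue_track <- function(x, stats) {
  df <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                   delta = stats$delta, p = stats$p)
  df <- df[!is.na(df$p), , drop = FALSE]
  df[order(df$chrom, df$pos), , drop = FALSE]
}
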