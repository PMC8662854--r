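#' Estimate the distance autocorrelation of probit-transformed p-values
#'
#' For each genomic distance bin, the Pearson correlation of
#' z = qnorm(1 - p) over all same-chromosome site pairs whose distance falls
#' in the bin. Negative estimates are truncated to zero so the downstream
#' variance inflation stays conservative and the implied covariance positive.
#'
#' @param track p-value track (chrom, pos, p), position-sorted.
#' @param bin_upper upper edges (bp) of the distance bins; the first bin
#'   starts at 1 bp. The default extends past the 200 bp merge gap because
#'   profile smoothing correlates sites over roughly the smoothing window.
#' @param min_pairs bins with fewer pairs than this are flagged unstable.
#' @return data.frame lo, hi, cor, n_pairs, stable; class `acf_estimate`.
#' @export
estimate_acf <- function(track,
                         bin_upper = c(50, 100, 150, 200, 300, 400, 500, 750, 1000),
                         min_pairs = 100) {
  if (nrow(track) < 2) stop("need at least 2 sites to estimate the ACF")
  lo <- c(1, bin_upper[-length(bin_upper)] + 1)
  z <- stats::qnorm(1 - pmin(pmax(track$p, 1e-15), 1 - 1e-15))
  maxd <- max(bin_upper)
  d_all <- z1 <- z2 <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    pos <- track$pos[idx]
    zz <- z[idx]
    off <- 1L
    while (off < length(idx)) {
      d <- pos[-seq_len(off)] - pos[seq_len(length(idx) - off)]
      keep <- d <= maxd
      if (!any(keep)) break
      d_all[[length(d_all) + 1L]] <- d[keep]
      z1[[length(z1) + 1L]] <- zz[seq_len(length(idx) - off)][keep]
      z2[[length(z2) + 1L]] <- zz[-seq_len(off)][keep]
      off <- off + 1L
    }
  }
  d_all <- unlist(d_all); z1 <- unlist(z1); z2 <- unlist(z2)
  cors <- n_pairs <- numeric(length(bin_upper))
  for (k in seq_along(bin_upper)) {
    sel <- which(d_all >= lo[k] & d_all <= bin_upper[k])
    n_pairs[k] <- length(sel)
    cors[k] <- if (length(sel) >= 2) {
      suppressWarnings(stats::cor(z1[sel], z2[sel]))
    } else NA_real_
  }
  cors[is.na(cors)] <- 0
  cors <- pmax(cors, 0)
  structure(data.frame(lo = lo, hi = bin_upper, cor = cors,
                       n_pairs = n_pairs, stable = n_pairs >= min_pairs),
            class = c("acf_estimate", "data.frame"))
}

#' Look up the estimated correlation at given distances
#' @param acf acf_estimate. @param d numeric distances in bp.
#' @return correlation per distance; 1 at d = 0, 0 beyond the last bin.
#' @export
acf_at <- function(acf, d) {
  out <- numeric(length(d))
  out[d == 0] <- 1
  k <- findInterval(d, c(acf$lo[1], acf$hi + 0.5))
  inside <- d > 0 & k >= 1 & k <= nrow(acf)
  out[inside] <- acf$cor[k[inside]]
  out
}

#' Stouffer-Liptak-Kechris combination of correlated p-values
#'
#' Each p becomes z = qnorm(1 - p); the combined statistic is
#' sum(z) / sqrt(sum(Sigma)) where Sigma is the pairwise correlation matrix
#' of the z's, and the combined p is its upper normal tail. With the identity
#' Sigma this is the textbook Stouffer combination; positive correlations
#' inflate the variance and make the combination conservative.
#'
#' @param p p-values in (0, 1].
#' @param sigma correlation matrix (projected to PSD if needed).
#' @return combined p-value in (0, 1].
#' @export
slk_combine <- function(p, sigma = diag(length(p))) {
  if (length(p) == 0) stop("empty p-value window")
  stopifnot(all(p > 0 & p <= 1), all(dim(sigma) == length(p)))
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    lam <- pmax(ev$values, 0)
    sigma <- ev$vectors %*% (lam * t(ev$vectors))
  }
  z <- stats::qnorm(1 - pmin(pmax(p, 1e-300), 1 - 1e-16))
  denom <- sqrt(sum(sigma))
  zc <- sum(z) / denom
  max(stats::pnorm(zc, lower.tail = FALSE), .Machine$double.xmin)
}

#' Merge adjacent significant sites into candidate regions
#'
#' A candidate is a maximal run of consecutive track sites all with
#' p < `site_alpha` and consecutive positions at most `max_gap` bp apart;
#' runs with fewer than `min_cpgs` sites are discarded. The region span is
#' \[first site, last site + 1).
#'
#' @param track p-value track (chrom, pos, p, delta), sorted.
#' @param site_alpha per-site significance threshold (default 0.05).
#' @param max_gap maximum gap between adjacent member CpGs in bp (default 200).
#' @param min_cpgs minimum member CpGs (default 5).
#' @return data.frame chrom, start, end, n_cpg plus list-column site_idx of
#'   row indices into `track`.
#' @export
find_candidate_regions <- function(track, site_alpha = 0.05, max_gap = 200,
                                   min_cpgs = 5) {
  n <- nrow(track)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_cpg = integer())
  if (n == 0) { empty$site_idx <- list(); return(empty) }
  sig <- track$p < site_alpha
  newrun <- c(TRUE, diff(track$pos) > max_gap |
                track$chrom[-1] != track$chrom[-n] |
                !sig[-1] | !sig[-n])
  run <- cumsum(newrun)
  out <- list()
  for (r in unique(run[sig])) {
    idx <- which(run == r & sig)
    if (length(idx) < min_cpgs) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = track$chrom[idx[1]], start = track$pos[idx[1]],
      end = track$pos[idx[length(idx)]] + 1, n_cpg = length(idx))
    attr(out[[length(out)]], "site_idx") <- idx
  }
  if (!length(out)) { empty$site_idx <- list(); return(empty) }
  res <- do.call(rbind, out)
  res$site_idx <- lapply(out, attr, "site_idx")
  rownames(res) <- NULL
  res
}

#' Call differentially methylated regions
#'
#' Candidate regions from [find_candidate_regions()] are scored with the
#' slk-combined p-value using the distance ACF for the pairwise correlations,
#' and kept when slk_p <= `region_alpha` (ties kept). mean_delta is the
#' unweighted mean of member-site deltas; direction is hyper when smokers are
#' higher (mean_delta > 0), hypo when lower.
#'
#' When a `selection_track` is supplied, candidate runs are located on it
#' (typically the smoothed-level association, which borrows strength from
#' neighbouring CpGs) while the slk score, deltas and ACF come from `track`
#' (typically the raw-level association, whose site z-scores are close to
#' independent). Locating on a smoothed track and scoring on the raw track
#' keeps the regional test calibrated under the spatial correlation that
#' smoothing induces, while retaining the smoothing power for discovery.
#'
#' @param track inference p-value track (chrom, pos, p, delta), sorted.
#' @param acf acf_estimate from `track` (estimated when NULL).
#' @param region_alpha region-level slk threshold (default 1e-4).
#' @param site_alpha,max_gap,min_cpgs passed to [find_candidate_regions()].
#' @param selection_track optional p-value track used only to locate
#'   candidate runs; sites are matched to `track` by (chrom, pos).
#' @return DMR data.frame: chrom, start, end, name, n_cpg, slk_p, mean_delta,
#'   direction.
#' @export
call_dmrs <- function(track, acf = NULL, region_alpha = 1e-4,
                      site_alpha = 0.05, max_gap = 200, min_cpgs = 5,
                      selection_track = NULL) {
  if (is.null(acf)) acf <- estimate_acf(track)
  sel <- if (is.null(selection_track)) track else selection_track
  cand <- find_candidate_regions(sel, site_alpha, max_gap, min_cpgs)
  if (nrow(cand) > 0 && !is.null(selection_track)) {
    key <- paste(track$chrom, track$pos)
    cand$site_idx <- lapply(cand$site_idx, function(ix)
      stats::na.omit(match(paste(sel$chrom[ix], sel$pos[ix]), key)))
    cand <- cand[lengths(cand$site_idx) >= min_cpgs, , drop = FALSE]
  }
  if (nrow(cand) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), n_cpg = integer(), slk_p = numeric(),
                      mean_delta = numeric(), direction = character()))
  slk <- md <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    idx <- cand$site_idx[[i]]
    pos <- track$pos[idx]
    sigma <- acf_at(acf, abs(outer(pos, pos, "-")))
    dim(sigma) <- c(length(pos), length(pos))
    diag(sigma) <- 1
    slk[i] <- slk_combine(track$p[idx], sigma)
    md[i] <- mean(track$delta[idx])
  }
  keep <- slk <= region_alpha
  zero <- keep & md == 0
  if (any(zero)) {
    warning(sum(zero), " zero-delta region(s) dropped")
    keep <- keep & md != 0
  }
  res <- cand[keep, c("chrom", "start", "end", "n_cpg"), drop = FALSE]
  res$slk_p <- slk[keep]
  res$mean_delta <- md[keep]
  res$direction <- ifelse(res$mean_delta > 0, "hyper", "hypo")
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$name <- sprintf("dmr_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "name", "n_cpg", "slk_p", "mean_delta",
          "direction")]
}

#' Write called DMRs as BED6+ (name, slk_p score column, extras)
#' @param dmrs DMR table from [call_dmrs()]. @param path file path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  df <- dmrs
  df$score <- df$slk_p
  write_bed(df, path, extra = c("n_cpg", "mean_delta", "direction"))
}
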