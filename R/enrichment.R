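#' Draw CpG-count- and length-matched random regions
#'
#' For every query DMR and draw, a surrogate region anchored on a random
#' genome CpG is extended rightwards to contain exactly the query's CpG
#' count; anchors whose resulting span lies within +/-5% of the query length
#' are eligible, and one is drawn uniformly (equivalent to rejection sampling
#' on a uniform anchor). When no anchor satisfies the length band, the
#' nearest-length anchor is used and the relaxation is counted.
#'
#' @param dmrs DMR table (chrom, start, end, n_cpg).
#' @param cpgs genome-wide CpG table (chrom, pos), position-sorted.
#' @param n_draws number of matched null sets (default 1000).
#' @param length_tol relative length tolerance (default 0.05).
#' @param seed optional integer seed for reproducible draws.
#' @return data.frame draw, query, chrom, start, end, n_cpg with attribute
#'   `n_relaxed` (queries for which the length band was relaxed).
#' @export
sample_matched_regions <- function(dmrs, cpgs, n_draws = 1000,
                                   length_tol = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
  pos_by_chrom <- split(cpgs$pos, cpgs$chrom)
  n_by_chrom <- vapply(pos_by_chrom, length, 1L)
  if (nrow(dmrs) && max(dmrs$n_cpg) > max(n_by_chrom))
    stop("genome has fewer CpGs than the largest query region")
  n_relaxed <- 0L
  out <- vector("list", nrow(dmrs))
  span_cache <- list()
  spans_for <- function(cc) {
    key <- as.character(cc)
    if (!is.null(span_cache[[key]])) return(span_cache[[key]])
    res <- lapply(names(pos_by_chrom), function(ch) {
      p <- pos_by_chrom[[ch]]
      n <- length(p)
      if (n < cc) return(NULL)
      j <- seq_len(n - cc + 1)
      data.frame(chrom = ch, j = j, start = p[j],
                 end = p[j + cc - 1] + 1)
    })
    res <- do.call(rbind, res)
    span_cache[[key]] <<- res
    res
  }
  for (i in seq_len(nrow(dmrs))) {
    cc <- dmrs$n_cpg[i]
    L <- dmrs$end[i] - dmrs$start[i]
    cand <- spans_for(cc)
    len <- cand$end - cand$start
    valid <- which(abs(len - L) <= length_tol * L)
    if (!length(valid)) {
      valid <- which.min(abs(len - L))
      n_relaxed <- n_relaxed + 1L
    }
    pick <- valid[sample.int(length(valid), n_draws, replace = TRUE)]
    out[[i]] <- data.frame(draw = seq_len(n_draws), query = i,
                           chrom = cand$chrom[pick], start = cand$start[pick],
                           end = cand$end[pick], n_cpg = cc)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(draw = integer(), query = integer(), chrom = character(),
                      start = numeric(), end = numeric(), n_cpg = integer())
  attr(res, "n_relaxed") <- n_relaxed
  res
}

#' Permutation-style empirical p-value with the add-one rule
#'
#' p = (r + 1) / (n + 1), where n is the number of null draws and r the
#' number of draws at least as extreme as the observed statistic. Never
#' returns 0.
#'
#' @param r number of at-least-as-extreme null draws (0 <= r <= n).
#' @param n number of null draws (>= 1).
#' @return empirical p-value in (0, 1].
#' @export
empirical_p <- function(r, n) {
  if (any(n < 1)) stop("need at least one null draw")
  if (any(r < 0 | r > n)) stop("r must lie in [0, n]")
  (r + 1) / (n + 1)
}

#' Enrichment fold change against a matched null
#'
#' Observed overlap count divided by the mean null overlap count. Degenerate
#' cases are flagged, not raised: +Inf when the null mean is 0 with a positive
#' observation, NaN when both are 0.
#'
#' @param observed observed overlap count.
#' @param null_counts vector of null overlap counts.
#' @return numeric fold (possibly Inf or NaN).
#' @export
fold_change <- function(observed, null_counts) {
  if (!length(null_counts)) stop("null_counts must be non-empty")
  m <- mean(null_counts)
  if (m == 0) {
    if (observed == 0) return(NaN)
    return(Inf)
  }
  observed / m
}

#' Matched-null enrichment of DMRs in feature tracks
#'
#' DMRs are stratified by direction (hyper/hypo); per stratum one set of
#' matched null draws is shared across all features. For each feature the
#' observed overlapping-region count is compared with the null distribution:
#' two one-sided empirical p-values (enrichment: null >= observed; depletion:
#' null <= observed) and the fold change are reported, with the direction set
#' to the smaller side.
#'
#' @param dmrs DMR table with a `direction` column (or all in one stratum).
#' @param feature_tracks named list of region data.frames.
#' @param cpgs genome-wide CpG table (chrom, pos).
#' @param n_draws matched null draws (default 1000).
#' @param seed optional seed for the null sampler.
#' @param log2_cap cap for log2 fold on degenerate folds (default 10).
#' @return data.frame: stratum, feature, observed, null_mean, null_sd, fold,
#'   log2fold, emp_p_enriched, emp_p_depleted, direction, n_extreme, n_draws.
#' @export
enrich <- function(dmrs, feature_tracks, cpgs, n_draws = 1000, seed = NULL,
                   log2_cap = 10) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.list(feature_tracks), length(names(feature_tracks)) ==
              length(feature_tracks))
  strata <- if ("direction" %in% names(dmrs)) unique(dmrs$direction) else "all"
  res <- list()
  for (st in strata) {
    sub <- if (identical(st, "all")) dmrs else
      dmrs[dmrs$direction == st, , drop = FALSE]
    if (nrow(sub) == 0) { warning("empty stratum ", st, " skipped"); next }
    draws <- sample_matched_regions(sub, cpgs, n_draws = n_draws)
    for (feat in names(feature_tracks)) {
      track <- feature_tracks[[feat]]
      obs <- count_overlaps(sub, track)
      hit <- overlaps_any(draws, track)
      null_counts <- as.vector(table(factor(draws$draw[hit],
                                            levels = seq_len(n_draws))))
      r_enr <- sum(null_counts >= obs)
      r_dep <- sum(null_counts <= obs)
      p_enr <- empirical_p(r_enr, n_draws)
      p_dep <- empirical_p(r_dep, n_draws)
      fold <- fold_change(obs, null_counts)
      l2 <- if (is.nan(fold)) NA_real_ else
        max(min(log2(max(fold, 2^-log2_cap)), log2_cap), -log2_cap)
      dirn <- if (p_enr <= p_dep) "enriched" else "depleted"
      res[[length(res) + 1L]] <- data.frame(
        stratum = st, feature = feat, observed = obs,
        null_mean = mean(null_counts), null_sd = stats::sd(null_counts),
        fold = fold, log2fold = l2, emp_p_enriched = p_enr,
        emp_p_depleted = p_dep, direction = dirn,
        n_extreme = if (dirn == "enriched") r_enr else r_dep,
        n_draws = n_draws)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Split a chromatin-state segmentation into per (cell type, state) tracks
#' @param states chromatin-state table (see [chromatin_states()]).
#' @return named list of region data.frames ("cell|state").
#' @export
state_feature_tracks <- function(states) {
  sp <- split(states, paste(states$cell_type, states$state, sep = "|"))
  lapply(sp, function(df) df[, c("chrom", "start", "end")])
}
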