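#' Link DMRs to genes by extended overlap (gene-body class)
#'
#' A DMR is linked to every gene it overlaps after allowing an upstream
#' 2 kb / downstream 1 kb margin. "Upstream" is only well defined for a
#' stranded feature, so the default reads the margin on the gene: a DMR
#' links to a gene when it overlaps the gene's span extended 2 kb upstream
#' of the TSS and 1 kb past the transcript end (strand-aware). The
#' alternative `"dmr_extension"` mode instead extends the unstranded DMR
#' span as \[start - up_ext, end + down_ext).
#'
#' @param dmrs DMR table (chrom, start, end, name).
#' @param genes gene model table.
#' @param up_ext,down_ext margin in bp (defaults 2000/1000).
#' @param mode "gene_flank" (default) or "dmr_extension".
#' @return data.frame dmr, gene, link_class ("body"), enhancer_id (NA).
#' @export
annotate_dmr_genes <- function(dmrs, genes, up_ext = 2000, down_ext = 1000,
                               mode = c("gene_flank", "dmr_extension")) {
  mode <- match.arg(mode)
  if (nrow(dmrs) == 0)
    return(data.frame(dmr = character(), gene = character(),
                      link_class = character(), enhancer_id = character()))
  if (mode == "dmr_extension") {
    ext <- data.frame(chrom = dmrs$chrom,
                      start = pmax(dmrs$start - up_ext, 0),
                      end = dmrs$end + down_ext)
    gb <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                     end = genes$tx_end)
  } else {
    ext <- dmrs[, c("chrom", "start", "end")]
    plus <- genes$strand != "-"
    gb <- data.frame(chrom = genes$chrom,
                     start = pmax(genes$tx_start -
                                    ifelse(plus, up_ext, down_ext), 0),
                     end = genes$tx_end + ifelse(plus, down_ext, up_ext))
  }
  lv <- union(unique(ext$chrom), unique(gb$chrom))
  hits <- GenomicRanges::findOverlaps(regions_to_gr(ext, lv),
                                      regions_to_gr(gb, lv))
  if (length(hits) == 0)
    return(data.frame(dmr = character(), gene = character(),
                      link_class = character(), enhancer_id = character()))
  data.frame(dmr = dmrs$name[S4Vectors::queryHits(hits)],
             gene = genes$gene_id[S4Vectors::subjectHits(hits)],
             link_class = "body", enhancer_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Link DMRs to genes through promoters and enhancers
#'
#' A promoter link is made when a DMR overlaps a gene's promoter window; an
#' enhancer link when it overlaps an enhancer region, one link per target
#' gene of that enhancer (one-to-many "commuting" enhancers supported).
#'
#' @param dmrs DMR table. @param promoters promoter regions named by gene.
#' @param enhancers enhancer interaction table (see [enhancer_map()]).
#' @return data.frame dmr, gene, link_class, enhancer_id.
#' @export
map_regulatory_dmrs <- function(dmrs, promoters, enhancers) {
  empty <- data.frame(dmr = character(), gene = character(),
                      link_class = character(), enhancer_id = character())
  if (nrow(dmrs) == 0) return(empty)
  out <- list(empty)
  if (nrow(promoters)) {
    lv <- union(unique(dmrs$chrom), unique(promoters$chrom))
    h <- GenomicRanges::findOverlaps(regions_to_gr(dmrs, lv),
                                     regions_to_gr(promoters, lv))
    if (length(h))
      out[[length(out) + 1L]] <- data.frame(
        dmr = dmrs$name[S4Vectors::queryHits(h)],
        gene = promoters$name[S4Vectors::subjectHits(h)],
        link_class = "promoter", enhancer_id = NA_character_)
  }
  if (nrow(enhancers)) {
    lv <- union(unique(dmrs$chrom), unique(enhancers$chrom))
    h <- GenomicRanges::findOverlaps(regions_to_gr(dmrs, lv),
                                     regions_to_gr(enhancers, lv))
    if (length(h))
      out[[length(out) + 1L]] <- data.frame(
        dmr = dmrs$name[S4Vectors::queryHits(h)],
        gene = enhancers$target_gene[S4Vectors::subjectHits(h)],
        link_class = "enhancer",
        enhancer_id = enhancers$enhancer_id[S4Vectors::subjectHits(h)])
  }
  res <- do.call(rbind, out)
  unique(res)
}

#' Per-sample mean methylation over each DMR
#'
#' Unweighted mean of the (smoothed) levels of the CpGs inside each DMR span,
#' per sample; NA for samples with no covered CpG in the region.
#'
#' @param dmrs DMR table. @param sites CpG site table (chrom, pos).
#' @param levels sites x samples level matrix aligned with `sites`.
#' @return DMRs x samples matrix, rownames = DMR names.
#' @export
dmr_mean_methylation <- function(dmrs, sites, levels) {
  out <- matrix(NA_real_, nrow(dmrs), ncol(levels),
                dimnames = list(dmrs$name, colnames(levels)))
  for (i in seq_len(nrow(dmrs))) {
    idx <- which(sites$chrom == dmrs$chrom[i] & sites$pos >= dmrs$start[i] &
                   sites$pos < dmrs$end[i])
    if (!length(idx)) next
    sub <- levels[idx, , drop = FALSE]
    mm <- colMeans(sub, na.rm = TRUE)
    mm[colSums(!is.na(sub)) == 0] <- NA_real_
    out[i, ] <- mm
  }
  out
}

#' Spearman correlation with average-rank ties
#'
#' rho is the Pearson correlation of average ranks; the p-value uses the
#' t approximation with n - 2 df, or full enumeration of rank permutations
#' when `method = "exact"` (n <= 9).
#'
#' @param x,y numeric vectors of equal length.
#' @param method "t" (default) or "exact".
#' @return list(rho, p, n).
#' @export
spearman_test <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 9) stop("exact permutation p only supported for n <= 9")
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- .Machine$double.xmin
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), n - 2)
    }
  }
  list(rho = rho, p = max(p, .Machine$double.xmin), n = n)
}

#' @keywords internal
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
  }
  out
}

#' Quadrant label from methylation and expression directions
#'
#' Total bijection \{hyper,hypo\} x \{up,down\} -> \{Hyper-Up, Hyper-Down,
#' Hypo-Up, Hypo-Down\} (directions relative to nonsmokers).
#'
#' @param meth_direction "hyper" or "hypo" (vectorised).
#' @param expr_direction "up" or "down" (vectorised).
#' @return character vector of quadrant labels.
#' @export
classify_quadrant <- function(meth_direction, expr_direction) {
  stopifnot(all(meth_direction %in% c("hyper", "hypo")),
            all(expr_direction %in% c("up", "down")))
  m <- ifelse(meth_direction == "hyper", "Hyper", "Hypo")
  e <- ifelse(expr_direction == "up", "Up", "Down")
  paste(m, e, sep = "-")
}

#' Correlate DMR methylation with target-gene expression
#'
#' Keeps links whose DMR is in the supplied (slk-thresholded) DMR set and
#' whose gene passes the relaxed expression threshold (raw p < `deg_alpha`),
#' then computes the Spearman correlation between per-sample DMR mean
#' methylation and log2 expression over the samples present in both assays.
#' Pairs with fewer than `min_n` complete sample pairs are skipped with a
#' warning.
#'
#' @param links DMR-gene link table (dmr, gene, link_class, enhancer_id).
#' @param dmr_meth DMRs x samples mean methylation matrix.
#' @param logcpm transcripts x samples log2 expression matrix.
#' @param deg DEG table with transcript, p, direction.
#' @param dmrs DMR table with name, direction.
#' @param samples optional sample ids to use (default: columns shared by both
#'   matrices).
#' @param alpha correlation significance cutoff (default 0.05).
#' @param deg_alpha relaxed expression p cutoff for inclusion (default 0.05).
#' @param min_n minimum complete pairs (default 5).
#' @return data.frame dmr, gene, link_class, enhancer_id, region,
#'   meth_direction, expr_direction, quadrant, rho, p, n, significant.
#' @export
correlate_pairs <- function(links, dmr_meth, logcpm, deg, dmrs,
                            samples = NULL, alpha = 0.05, deg_alpha = 0.05,
                            min_n = 5) {
  if (is.null(samples))
    samples <- intersect(colnames(dmr_meth), colnames(logcpm))
  deg_ok <- deg[deg$p < deg_alpha, , drop = FALSE]
  keep <- links$dmr %in% dmrs$name & links$gene %in% deg_ok$transcript
  links <- links[keep, , drop = FALSE]
  if (nrow(links) == 0)
    return(data.frame(dmr = character(), gene = character(),
                      link_class = character(), enhancer_id = character(),
                      region = character(), meth_direction = character(),
                      expr_direction = character(), quadrant = character(),
                      rho = numeric(), p = numeric(), n = integer(),
                      significant = logical()))
  didx <- match(links$dmr, dmrs$name)
  gidx <- match(links$gene, rownames(logcpm))
  out <- links
  out$region <- format_region_string(dmrs[didx, , drop = FALSE])
  out$meth_direction <- dmrs$direction[didx]
  out$expr_direction <- deg$direction[match(links$gene, deg$transcript)]
  out$quadrant <- classify_quadrant(out$meth_direction, out$expr_direction)
  out$rho <- out$p <- NA_real_; out$n <- NA_integer_
  skipped <- 0L
  for (i in seq_len(nrow(out))) {
    x <- dmr_meth[links$dmr[i], samples]
    y <- logcpm[gidx[i], samples]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_n) { skipped <- skipped + 1L; next }
    st <- spearman_test(x[ok], y[ok])
    out$rho[i] <- st$rho; out$p[i] <- st$p; out$n[i] <- st$n
  }
  if (skipped) warning(skipped, " pair(s) skipped: fewer than ", min_n,
                       " complete sample pairs")
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set over-representation test
#'
#' p = P(X >= k) for X ~ Hypergeometric(N = |universe|, K = |set|,
#' n = |query|) with k = |query intersect set|.
#'
#' @param query_genes character vector of query gene ids.
#' @param gene_set character vector, the annotated set.
#' @param universe character vector of all considered genes.
#' @return upper-tail p-value.
#' @export
hypergeom_geneset_test <- function(query_genes, gene_set, universe) {
  if (!length(universe)) stop("empty gene universe")
  query_genes <- intersect(unique(query_genes), universe)
  gene_set <- intersect(unique(gene_set), universe)
  k <- length(intersect(query_genes, gene_set))
  stats::phyper(k - 1, length(gene_set),
                length(universe) - length(gene_set),
                length(query_genes), lower.tail = FALSE)
}

#' Test many gene sets hypergeometrically with BH correction
#'
#' @param query_genes query gene ids.
#' @param gene_sets named list of character vectors.
#' @param universe all considered genes.
#' @return data.frame set, k, set_size, p, q ordered by p.
#' @export
geneset_enrichment <- function(query_genes, gene_sets, universe) {
  p <- vapply(gene_sets, hypergeom_geneset_test, 1.0,
              query_genes = query_genes, universe = universe)
  k <- vapply(gene_sets, function(s)
    length(intersect(intersect(unique(query_genes), universe),
                     intersect(unique(s), universe))), 1L)
  out <- data.frame(set = names(gene_sets), k = k,
                    set_size = vapply(gene_sets, function(s)
                      length(intersect(unique(s), universe)), 1L),
                    p = p, q = stats::p.adjust(p, "BH"))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a regulatory pair table
#'
#' Given pair records with a regulatory block label, methylation and
#' expression directions, returns per-block pair counts, quadrant counts,
#' and the opposite-direction fraction (hyper-down or hypo-up) among
#' enhancer-block pairs.
#'
#' @param pairs data.frame with columns block, meth_direction, expr_direction.
#' @return list(block_counts, quadrant_counts, n_pairs, opposite_fraction).
#' @export
pair_table_summary <- function(pairs) {
  quad <- classify_quadrant(pairs$meth_direction, pairs$expr_direction)
  opposite <- quad %in% c("Hyper-Down", "Hypo-Up")
  enh <- grepl("enhancer", pairs$block, ignore.case = TRUE)
  list(block_counts = table(pairs$block),
       quadrant_counts = table(factor(quad, levels = c("Hyper-Up",
                                                       "Hyper-Down", "Hypo-Up", "Hypo-Down"))),
       n_pairs = nrow(pairs),
       opposite_fraction = if (any(enh)) mean(opposite[enh]) else NA_real_)
}

#' Read a regulatory pair table TSV (block, region, enhancer_id, directions, p)
#' @param path file path.
#' @return data.frame.
#' @export
read_pair_table <- function(path) {
  df <- tsv_read(path)
  need <- c("block", "region", "enhancer_id", "meth_direction",
            "target_gene", "expr_direction", "p")
  stopifnot(all(need %in% names(df)))
  df$meth_direction <- tolower(df$meth_direction)
  df$expr_direction <- tolower(df$expr_direction)
  df
}
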