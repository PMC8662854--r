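#' Gene model table
#'
#' Minimal gene model dialect: one row per gene with exon (and optionally CDS)
#' intervals packed as "start-end;start-end" strings in 0-based half-open
#' coordinates. UTR-aware feature classification needs the CDS column.
#'
#' @param gene_id,chrom,strand,tx_start,tx_end vectors, one entry per gene.
#' @param exons character vector, ";"-separated "start-end" intervals.
#' @param cds like `exons`, or NA when unknown.
#' @return validated data.frame of class columns (plain data.frame).
#' @export
gene_models <- function(gene_id, chrom, strand, tx_start, tx_end,
                        exons, cds = NA_character_) {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = as.character(strand),
                   tx_start = as.numeric(tx_start), tx_end = as.numeric(tx_end),
                   exons = as.character(exons), cds = as.character(cds),
                   stringsAsFactors = FALSE)
  if (any(df$tx_start >= df$tx_end)) stop("tx_start must be < tx_end")
  if (anyDuplicated(df$gene_id)) stop("gene ids must be unique")
  ex <- unpack_intervals(df$exons, df$gene_id)
  bad <- ex$start < df$tx_start[match(ex$id, df$gene_id)] |
    ex$end > df$tx_end[match(ex$id, df$gene_id)]
  if (any(bad)) stop("exons must lie within [tx_start, tx_end)")
  df
}

#' @keywords internal
pack_intervals <- function(start, end) paste(start, end, sep = "-", collapse = ";")

#' @keywords internal
unpack_intervals <- function(packed, id = seq_along(packed)) {
  keep <- !is.na(packed) & nzchar(packed)
  if (!any(keep))
    return(data.frame(id = character(), start = numeric(), end = numeric()))
  parts <- strsplit(packed[keep], ";", fixed = TRUE)
  n <- lengths(parts)
  flat <- unlist(parts)
  se <- strsplit(flat, "-", fixed = TRUE)
  data.frame(id = rep(as.character(id[keep]), n),
             start = as.numeric(vapply(se, `[`, "", 1L)),
             end = as.numeric(vapply(se, `[`, "", 2L)))
}

#' Strand-aware promoter windows around transcription start sites
#'
#' The promoter of a gene is the window from `upstream` bp before to
#' `downstream` bp after its TSS (tx_start on "+", tx_end on "-"), clipped to
#' the chromosome. Records with unknown strand are dropped with a warning.
#'
#' @param genes gene model table (see [gene_models()]).
#' @param layout [genome_layout()] for end clipping.
#' @param upstream,downstream window extents in bp (defaults 1500/500).
#' @return region data.frame named by gene_id.
#' @export
build_promoters <- function(genes, layout, upstream = 1500, downstream = 500) {
  known <- genes$strand %in% c("+", "-")
  if (any(!known)) {
    warning(sum(!known), " gene(s) with unknown strand dropped from promoters")
    genes <- genes[known, , drop = FALSE]
  }
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  start <- ifelse(genes$strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(genes$strand == "+", tss + downstream, tss + upstream)
  start <- pmax(start, 0)
  end <- pmin(end, layout[genes$chrom])
  keep <- start < end
  regions(genes$chrom[keep], start[keep], end[keep], name = genes$gene_id[keep],
          strand = genes$strand[keep], layout = layout)
}

#' CpG-island context partition: island / shore / shelf / open sea
#'
#' Islands are merged first; shores are the 2 kb flanks minus islands; shelves
#' the next 2 kb minus islands and shores; open sea is the remainder. The four
#' classes tile every chromosome disjointly.
#'
#' @param cgis region data.frame of CpG islands.
#' @param layout [genome_layout()].
#' @param flank flank width in bp for each of shore and shelf (default 2000).
#' @return named list of region data.frames: island, shore, shelf, open_sea.
#' @export
build_cgi_context <- function(cgis, layout, flank = 2000) {
  if (nrow(cgis) == 0) {
    empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
    return(list(island = empty, shore = empty, shelf = empty,
                open_sea = data.frame(chrom = names(layout), start = 0,
                                      end = as.numeric(layout))))
  }
  island <- merge_regions(cgis)
  clip <- function(df) {
    df$start <- pmax(df$start, 0)
    df$end <- pmin(df$end, layout[df$chrom])
    df[df$start < df$end, , drop = FALSE]
  }
  flank1 <- clip(data.frame(chrom = rep(island$chrom, 2),
                            start = c(island$start - flank, island$end),
                            end = c(island$start, island$end + flank)))
  shore <- setdiff_regions(merge_regions(flank1), island)
  flank2 <- clip(data.frame(chrom = rep(island$chrom, 2),
                            start = c(island$start - 2 * flank, island$end + flank),
                            end = c(island$start - flank, island$end + 2 * flank)))
  shelf <- setdiff_regions(setdiff_regions(merge_regions(flank2), island), shore)
  open_sea <- complement_regions(rbind(island, shore, shelf), layout)
  list(island = island, shore = shore, shelf = shelf, open_sea = open_sea)
}

#' Derive exon/intron/UTR tracks from gene models
#'
#' When a gene has no CDS, UTR classes are not emitted for it (its exons stay
#' plain exons).
#'
#' @param genes gene model table.
#' @return named list of region data.frames: utr5, utr3, exon, intron, body.
#' @export
gene_feature_tracks <- function(genes) {
  ex <- unpack_intervals(genes$exons, genes$gene_id)
  cds <- unpack_intervals(genes$cds, genes$gene_id)
  idx <- match(ex$id, genes$gene_id)
  ex$chrom <- genes$chrom[idx]
  ex$strand <- genes$strand[idx]
  exon <- data.frame(chrom = ex$chrom, start = ex$start, end = ex$end)
  body <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                     end = genes$tx_end)
  intron <- setdiff_regions(body, exon)
  utr5 <- utr3 <- data.frame(chrom = character(), start = numeric(),
                             end = numeric())
  if (nrow(cds)) {
    cs <- tapply(cds$start, cds$id, min)
    ce <- tapply(cds$end, cds$id, max)
    has <- ex$id %in% names(cs)
    exh <- ex[has, , drop = FALSE]
    cstart <- as.numeric(cs[exh$id]); cend <- as.numeric(ce[exh$id])
    left <- data.frame(chrom = exh$chrom, start = exh$start,
                       end = pmin(exh$end, cstart), strand = exh$strand)
    left <- left[left$start < left$end, , drop = FALSE]
    right <- data.frame(chrom = exh$chrom, start = pmax(exh$start, cend),
                        end = exh$end, strand = exh$strand)
    right <- right[right$start < right$end, , drop = FALSE]
    utr5 <- rbind(left[left$strand == "+", c("chrom", "start", "end")],
                  right[right$strand == "-", c("chrom", "start", "end")])
    utr3 <- rbind(right[right$strand == "+", c("chrom", "start", "end")],
                  left[left$strand == "-", c("chrom", "start", "end")])
  }
  list(utr5 = utr5, utr3 = utr3, exon = exon, intron = intron, body = body)
}

#' Classify regions into genomic feature classes
#'
#' Fixed precedence: promoter > 5'UTR > 3'UTR > exon > intron > intergenic.
#' A region qualifies for a class when it overlaps it by >= 1 bp.
#'
#' @param query region data.frame to classify.
#' @param genes gene model table.
#' @param promoters promoter regions from [build_promoters()].
#' @param layout optional [genome_layout()]; when supplied, regions on unknown
#'   chromosomes raise an error.
#' @return character vector of labels, one per query row.
#' @export
classify_genomic_feature <- function(query, genes, promoters, layout = NULL) {
  if (!is.null(layout)) validate_regions(query, layout)
  tracks <- gene_feature_tracks(genes)
  out <- rep("intergenic", nrow(query))
  order_ <- list(promoter = promoters, `5'UTR` = tracks$utr5,
                 `3'UTR` = tracks$utr3, exon = tracks$exon,
                 intron = tracks$intron)
  for (lab in rev(names(order_))) {
    hit <- overlaps_any(query, order_[[lab]])
    out[hit] <- lab
  }
  out
}

#' The 15 chromatin-state labels of the core joint epigenome model
#' @export
CHROMATIN_STATES <- c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG",
                      "Enh", "ZNF/Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv",
                      "ReprPC", "ReprPCWk", "Quies")

#' Validate a chromatin-state segmentation table
#'
#' @param df data.frame with chrom, start, end, state, cell_type.
#' @return the validated data.frame.
#' @export
chromatin_states <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "state", "cell_type") %in% names(df)))
  validate_regions(df)
  bad <- !df$state %in% CHROMATIN_STATES
  if (any(bad)) stop("unknown chromatin state label: ", df$state[bad][1])
  for (ct in unique(df$cell_type)) {
    sub <- df[df$cell_type == ct, , drop = FALSE]
    for (ch in unique(sub$chrom)) {
      s <- sub[sub$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping segments within cell type ", ct)
    }
  }
  df
}

#' Validate a SNP table (chrom, pos 0-based, maf)
#' @param df data.frame with chrom, pos, maf.
#' @return the validated data.frame.
#' @export
snp_set <- function(df) {
  stopifnot(all(c("chrom", "pos", "maf") %in% names(df)))
  if (any(df$maf < 0 | df$maf > 0.5)) stop("maf must lie in [0, 0.5]")
  df
}

#' Validate an enhancer-to-target interaction table
#'
#' One row per (enhancer, target gene) pair; an enhancer targeting k genes
#' occupies k rows sharing its enhancer_id and coordinates.
#'
#' @param df data.frame with enhancer_id, chrom, start, end, target_gene.
#' @return the validated data.frame.
#' @export
enhancer_map <- function(df) {
  stopifnot(all(c("enhancer_id", "chrom", "start", "end", "target_gene") %in%
                  names(df)))
  validate_regions(df)
  if (anyDuplicated(df[, c("enhancer_id", "target_gene")]))
    stop("duplicate (enhancer, target) pairs")
  df
}
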