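#' Per-CpG methylation count container
#'
#' Holds the site table (chrom, pos, strand; 0-based positions, strand-combined
#' CpG dinucleotides) and two sites-by-samples integer matrices of methylated
#' and unmethylated read counts. A site is covered in a sample when
#' meth + unmeth >= 1.
#'
#' @param sites data.frame with chrom, pos (0-based) and optionally strand.
#' @param meth,unmeth numeric matrices, sites x samples, same dimnames.
#' @return object of class `methylation_counts`.
#' @export
methylation_counts <- function(sites, meth, unmeth) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)),
            nrow(meth) == nrow(sites), all(dim(meth) == dim(unmeth)))
  if (is.null(colnames(meth))) stop("count matrices need sample column names")
  if (!identical(colnames(meth), colnames(unmeth)))
    stop("meth/unmeth sample columns differ")
  if (any(meth < 0) || any(unmeth < 0)) stop("counts must be >= 0")
  o <- order(sites$chrom, sites$pos)
  structure(list(sites = sites[o, , drop = FALSE],
                 meth = meth[o, , drop = FALSE],
                 unmeth = unmeth[o, , drop = FALSE]),
            class = "methylation_counts")
}

#' @export
print.methylation_counts <- function(x, ...) {
  cat("methylation_counts:", nrow(x$sites), "CpG sites x",
      ncol(x$meth), "samples on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.methylation_counts <- function(x) c(nrow(x$sites), ncol(x$meth))

#' Subset a methylation_counts object by site index and/or samples
#' @param x methylation_counts.
#' @param i site row index. @param samples sample names or index.
#' @return methylation_counts.
#' @export
subset_counts <- function(x, i = NULL, samples = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x$sites))
  if (is.null(samples)) samples <- colnames(x$meth)
  methylation_counts(x$sites[i, , drop = FALSE],
                     x$meth[i, samples, drop = FALSE],
                     x$unmeth[i, samples, drop = FALSE])
}

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

tsv_read <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write/read methylation counts as TSV
#'
#' Layout: chrom, pos, strand, then paired per-sample columns
#' `<id>_meth`, `<id>_unmeth`.
#' @param x methylation_counts. @param path file path.
#' @export
write_methylation_tsv <- function(x, path) {
  samp <- colnames(x$meth)
  out <- x$sites[, intersect(c("chrom", "pos", "strand"), names(x$sites)),
                 drop = FALSE]
  for (s in samp) {
    out[[paste0(s, "_meth")]] <- x$meth[, s]
    out[[paste0(s, "_unmeth")]] <- x$unmeth[, s]
  }
  tsv_write(out, path)
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(path) {
  df <- tsv_read(path)
  mcols <- grep("_meth$", names(df), value = TRUE)
  samp <- sub("_meth$", "", mcols)
  meth <- as.matrix(df[, paste0(samp, "_meth"), drop = FALSE])
  unmeth <- as.matrix(df[, paste0(samp, "_unmeth"), drop = FALSE])
  colnames(meth) <- colnames(unmeth) <- samp
  sites <- df[, intersect(c("chrom", "pos", "strand"), names(df)), drop = FALSE]
  methylation_counts(sites, meth, unmeth)
}

#' Validate a sample sheet
#'
#' @param df data.frame with sample_id, group ("smoker"/"nonsmoker"),
#'   age, bmi, miner (logical).
#' @return the validated data.frame.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "group", "age", "bmi", "miner")
  stopifnot(all(need %in% names(df)))
  if (!all(df$group %in% c("smoker", "nonsmoker")))
    stop("group must be smoker/nonsmoker")
  if (length(unique(df$group)) < 2) stop("both groups must be present")
  if (anyNA(df[, need])) stop("missing covariates in sample sheet")
  df$miner <- as.logical(df$miner)
  df
}

#' Write a region table as BED (0-based half-open)
#'
#' @param df region data.frame; name/score/strand columns used when present.
#' @param path file path. @param extra extra column names to append (BED6+).
#' @export
write_bed <- function(df, path, extra = character()) {
  n <- nrow(df)
  out <- data.frame(chrom = df$chrom, start = as.integer(df$start),
                    end = as.integer(df$end),
                    name = if ("name" %in% names(df)) df$name else
                      rep(".", n),
                    score = if ("score" %in% names(df)) df$score else
                      rep(0, n),
                    strand = if ("strand" %in% names(df)) df$strand else
                      rep(".", n))
  for (cn in extra) out[[cn]] <- df[[cn]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Read a BED3+ file into a region table
#' @param path file path.
#' @param col_names names for columns beyond chrom/start/end.
#' @export
read_bed <- function(path, col_names = c("name", "score", "strand")) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  k <- min(ncol(df) - 3, length(col_names))
  if (k > 0) names(df)[4:(3 + k)] <- col_names[1:k]
  df
}

#' Write/read the minimal gene model TSV dialect
#' @param genes gene model table. @param path file path.
#' @export
write_gene_models_tsv <- function(genes, path) tsv_write(genes, path)

#' @rdname write_gene_models_tsv
#' @export
read_gene_models_tsv <- function(path) {
  df <- tsv_read(path)
  gene_models(df$gene_id, df$chrom, df$strand, df$tx_start, df$tx_end,
              df$exons, df$cds)
}

#' Write/read an expression count matrix TSV (transcript x sample)
#' @param counts integer matrix with dimnames. @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  tsv_write(data.frame(transcript = rownames(counts), counts,
                       check.names = FALSE), path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- tsv_read(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
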