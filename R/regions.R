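#' Genome layout
#'
#' A genome layout is a named integer vector of chromosome lengths (bp).
#' All intervals in dmrkit are 0-based half-open (BED convention).
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length in bp.
#' @return validated named integer-ish vector of class `genome_layout`.
#' @export
genome_layout <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (anyDuplicated(names(chrom_sizes)))
    stop("chromosome names must be unique")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  structure(as.numeric(chrom_sizes), names = names(chrom_sizes),
            class = "genome_layout")
}

#' Construct a region table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param name optional region names.
#' @param strand optional strand ("+", "-" or ".").
#' @param layout optional [genome_layout()] used to check bounds.
#' @return data.frame with columns chrom, start, end (and name/strand if given).
#' @export
regions <- function(chrom, start, end, name = NULL, strand = NULL,
                    layout = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_regions(df, layout)
}

#' @keywords internal
validate_regions <- function(df, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start >= df$end)) stop("regions must satisfy start < end")
  if (any(df$start < 0)) stop("regions must satisfy start >= 0")
  if (!is.null(layout)) {
    unknown <- setdiff(unique(df$chrom), names(layout))
    if (length(unknown))
      stop("regions on unknown chromosomes: ", paste(unknown, collapse = ", "))
    if (any(df$end > layout[df$chrom]))
      stop("regions extend beyond chromosome ends")
  }
  df
}

#' Convert a region table to GRanges
#'
#' Internal bridge to the GenomicRanges interval machinery. dmrkit coordinates
#' are 0-based half-open; GRanges are 1-based closed, hence start + 1.
#' @keywords internal
regions_to_gr <- function(df, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom,
                      levels = union(seqlevels, unique(df$chrom))),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' Parse "chr:start-end" region strings (1-based inclusive) to 0-based half-open
#'
#' Report-style coordinates such as `chr12:108733790-108734067` are 1-based
#' inclusive; internally they become `[start-1, end)`.
#'
#' @param x character vector of region strings.
#' @return data.frame with chrom, start, end.
#' @export
parse_region_string <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)[-–]([0-9,]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable region string: ", x[bad][1])
  chrom <- vapply(m, `[`, "", 2L)
  s <- as.numeric(gsub(",", "", vapply(m, `[`, "", 3L)))
  e <- as.numeric(gsub(",", "", vapply(m, `[`, "", 4L)))
  regions(chrom, s - 1, e)
}

#' Format 0-based half-open regions as 1-based inclusive strings
#' @param df region data.frame.
#' @return character vector like "chr1:101-200".
#' @export
format_region_string <- function(df) {
  sprintf("%s:%d-%d", df$chrom, as.integer(df$start + 1), as.integer(df$end))
}

#' Number of query regions overlapping a feature track
#'
#' Counts query regions that overlap at least one feature interval by >= 1 bp;
#' each query region is counted once regardless of how many features it hits.
#'
#' @param query,features region data.frames (chrom, start, end).
#' @return integer count.
#' @export
count_overlaps <- function(query, features) {
  if (nrow(query) == 0 || nrow(features) == 0) return(0L)
  lv <- union(unique(query$chrom), unique(features$chrom))
  hits <- GenomicRanges::countOverlaps(regions_to_gr(query, lv),
                                       regions_to_gr(features, lv))
  sum(hits > 0L)
}

#' Logical overlap indicator per query region
#' @keywords internal
overlaps_any <- function(query, features) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(features) == 0) return(rep(FALSE, nrow(query)))
  lv <- union(unique(query$chrom), unique(features$chrom))
  GenomicRanges::countOverlaps(regions_to_gr(query, lv),
                               regions_to_gr(features, lv)) > 0L
}

#' Complement of a region set within a genome
#' @keywords internal
complement_regions <- function(df, layout) {
  out <- list()
  for (ch in names(layout)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) {
      out[[ch]] <- data.frame(chrom = ch, start = 0, end = layout[[ch]])
      next
    }
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1, sub$end))
    gap <- IRanges::gaps(ir, start = 1, end = layout[[ch]])
    if (length(gap))
      out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(gap) - 1,
                              end = IRanges::end(gap))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
  rownames(out) <- NULL
  out
}

#' Merge overlapping/adjacent regions
#' @keywords internal
merge_regions <- function(df) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(sub) {
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1, sub$end))
    data.frame(chrom = sub$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Set difference of region sets (a minus b), per chromosome
#' @keywords internal
setdiff_regions <- function(a, b) {
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end")])
  out <- list()
  for (ch in unique(a$chrom)) {
    sa <- a[a$chrom == ch, , drop = FALSE]
    sb <- b[b$chrom == ch, , drop = FALSE]
    ia <- IRanges::reduce(IRanges::IRanges(sa$start + 1, sa$end))
    if (nrow(sb) == 0) {
      res <- ia
    } else {
      ib <- IRanges::reduce(IRanges::IRanges(sb$start + 1, sb$end))
      res <- IRanges::setdiff(ia, ib)
    }
    if (length(res))
      out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(res) - 1,
                              end = IRanges::end(res))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
  rownames(out) <- NULL
  out
}
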