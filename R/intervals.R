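#' Construct a set of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based start,
#' exclusive end, so that \code{length = end - start}. Strand is one of
#' \code{"+"}, \code{"-"} or \code{"*"} (unstranded).
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions (bp).
#' @param end exclusive end positions (bp); must satisfy \code{end > start}.
#' @param strand strand labels, recycled; defaults to unstranded.
#' @param ... further equal-length columns (e.g. \code{name}, \code{score})
#'   carried along untouched.
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand} plus any extras.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", ...) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (n > 0) {
    chrom <- rep_len(chrom, n)
    start <- rep_len(start, n)
    end <- rep_len(end, n)
  }
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  extras <- list(...)
  for (nm in names(extras)) df[[nm]] <- extras[[nm]]
  df
}

empty_intervals <- function() {
  genomic_intervals(character(), numeric(), numeric())[0, ]
}

#' @noRd
iv_length <- function(iv) iv$end - iv$start

# 0-based half-open -> 1-based closed GRanges
iv_to_gr <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end),
    strand = ifelse(iv$strand == "*", "*", iv$strand)
  )
}

gr_to_iv <- function(gr) {
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Merge intervals closer than a gap
#'
#' Intervals whose edge-to-edge gap is at most \code{max_gap} bp are merged,
#' per chromosome and ignoring strand. Output is sorted and any two adjacent
#' output intervals are separated by more than \code{max_gap} bp.
#'
#' @param iv interval data.frame (see [genomic_intervals()]).
#' @param max_gap maximum gap (bp) bridged by a merge; 0 merges only
#'   overlapping or touching intervals.
#' @return merged, sorted interval data.frame (unstranded).
#' @export
merge_intervals <- function(iv, max_gap = 0) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || is.na(max_gap) ||
      max_gap < 0) {
    stop("max_gap must be a single non-negative number")
  }
  if (nrow(iv) == 0) return(empty_intervals())
  red <- GenomicRanges::reduce(iv_to_gr(iv), min.gapwidth = max_gap + 1,
                               ignore.strand = TRUE)
  out <- gr_to_iv(GenomicRanges::sort(red, ignore.strand = TRUE))
  out$strand <- "*"
  out
}

#' Drop intervals shorter than a minimum length
#'
#' Implements the sub-nucleosomal peak filter: intervals strictly shorter
#' than \code{min_len} are removed; an interval of exactly \code{min_len} bp
#' is kept.
#'
#' @inheritParams merge_intervals
#' @param min_len minimum length (bp), at least 1.
#' @export
filter_min_length <- function(iv, min_len) {
  if (!is.numeric(min_len) || length(min_len) != 1 || min_len < 1) {
    stop("min_len must be a single number >= 1")
  }
  iv[iv_length(iv) >= min_len, , drop = FALSE]
}

#' Signed distance to the nearest gene
#'
#' For each query interval, finds the nearest gene body on the same
#' chromosome. Distance is 0 on overlap, otherwise the edge-to-edge gap in
#' bp, signed positive when the gene lies downstream (to the right) of the
#' query and negative when upstream. Ties are broken by smaller gene start,
#' then lexicographic gene id. Queries on chromosomes with no gene are
#' reported with \code{NA} (a reportable no-neighbor state, not an error).
#'
#' @param query interval data.frame.
#' @param genes gene model data.frame (see [gene_models()]).
#' @return data.frame with one row per query: \code{gene_id},
#'   \code{distance}.
#' @export
distance_to_nearest <- function(query, genes) {
  n <- nrow(query)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0 || nrow(genes) == 0) return(out)
  qgr <- iv_to_gr(query)
  ggr <- iv_to_gr(genes)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(qgr, ggr, select = "all",
                                     ignore.strand = TRUE))
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # resolve ties deterministically: smaller gene start, then gene_id
  ord <- order(qh, genes$start[sh], genes$gene_id[sh])
  keep <- ord[!duplicated(qh[ord])]
  qi <- qh[keep]; gi <- sh[keep]
  gap <- S4Vectors::mcols(hits)$distance[keep]
  sign <- ifelse(genes$start[gi] >= query$end[qi], 1,
                 ifelse(genes$end[gi] <= query$start[qi], -1, 0))
  out$gene_id[qi] <- genes$gene_id[gi]
  out$distance[qi] <- sign * gap
  out
}

#' Which query intervals overlap any subject interval
#'
#' @param query,subject interval data.frames.
#' @return logical vector along \code{query}.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(iv_to_gr(query), iv_to_gr(subject),
                       ignore.strand = TRUE)
}

#' Construct gene models
#'
#' The transcription start site is the strand-aware 5' end of the gene body:
#' \code{start} on the plus strand, \code{end - 1} on the minus strand.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom,start,end,strand gene body coordinates (0-based half-open);
#'   strand must be \code{"+"} or \code{"-"}.
#' @param name display names (default \code{gene_id}).
#' @param biotype e.g. \code{"protein_coding"} or an ncRNA class.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        name = gene_id, biotype = "protein_coding") {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  iv <- genomic_intervals(chrom, start, end, strand)
  iv$gene_id <- as.character(gene_id)
  iv$name <- rep_len(as.character(name), nrow(iv))
  iv$biotype <- rep_len(as.character(biotype), nrow(iv))
  iv$tss <- ifelse(iv$strand == "+", iv$start, iv$end - 1)
  iv
}
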