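# Center-anchored metaprofiles of feature density (counts per million) and
# IUPAC consensus motif scanning.

#' Metaprofile of feature midpoints around anchor centers
#'
#' Each feature midpoint falling within \code{[-window, window)} of an
#' anchor center increments the bin of its offset; a feature near several
#' centers is counted at each. Counts are normalised to counts per million:
#' \code{cpm = count * 1e6 / total feature count}.
#'
#' @param features interval data.frame (e.g. histone peaks, motif hits);
#'   the feature location is its interval midpoint (floor).
#' @param centers data.frame with \code{chrom}, \code{center} (bp), e.g.
#'   TAPE centers.
#' @param window half-window in bp (default 5000).
#' @param bin bin width in bp (default 50); must divide \code{window}.
#' @return data.frame \code{offset} (bin left edge relative to center),
#'   \code{count}, \code{cpm}.
#' @export
metaprofile <- function(features, centers, window = 5000, bin = 50) {
  if (window %% bin != 0) stop("window must be divisible by bin")
  nb <- 2 * window / bin
  offs <- seq(-window, window - bin, by = bin)
  count <- rep(0L, nb)
  total <- nrow(features)
  if (total > 0 && nrow(centers) > 0) {
    mid <- floor((features$start + features$end) / 2)
    for (ch in unique(centers$chrom)) {
      cc <- centers$center[centers$chrom == ch]
      mm <- mid[features$chrom == ch]
      if (length(cc) == 0 || length(mm) == 0) next
      for (c0 in cc) {
        d <- mm - c0
        d <- d[d >= -window & d < window]
        if (length(d)) {
          idx <- floor((d + window) / bin) + 1
          t <- tabulate(idx, nbins = nb)
          count <- count + t
        }
      }
    }
  }
  data.frame(offset = offs, count = count,
             cpm = if (total > 0) count * 1e6 / total else rep(0, nb))
}

IUPAC_CLASSES <- c(A = "A", C = "C", G = "G", T = "T",
                   R = "AG", Y = "CT", S = "CG", W = "AT",
                   K = "GT", M = "AC", B = "CGT", D = "AGT",
                   H = "ACT", V = "ACG", N = "ACGT")

#' Scan a sequence for an IUPAC consensus motif
#'
#' Exact degenerate matching: every window of motif length whose bases all
#' satisfy the corresponding IUPAC classes is reported, on the forward
#' strand and (as hits to the reverse-complement pattern) on the reverse
#' strand. Overlapping hits are allowed. Degenerate codes in the subject
#' sequence are not treated as wildcards.
#'
#' @param sequence a character string or \code{Biostrings::DNAString}.
#' @param motif IUPAC consensus string (e.g. the CTCF consensus
#'   \code{"CCGCGNGGNGGCAG"}).
#' @param chrom chromosome name recorded in the hit intervals.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return interval data.frame of hits (0-based half-open, forward-strand
#'   coordinates) with \code{strand} and \code{matched} (the hit sequence as
#'   read on its strand).
#' @export
iupac_scan <- function(sequence, motif, chrom = "chr", both_strands = TRUE) {
  motif <- toupper(motif)
  codes <- strsplit(motif, "")[[1]]
  if (!all(codes %in% names(IUPAC_CLASSES))) {
    stop("invalid IUPAC code in motif: ",
         paste(setdiff(codes, names(IUPAC_CLASSES)), collapse = ", "))
  }
  subj <- if (inherits(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  pat <- Biostrings::DNAString(motif)
  hits_one <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
    if (length(m) == 0) return(NULL)
    st <- BiocGenerics::start(m) - 1
    en <- BiocGenerics::end(m)
    seqs <- as.character(m)
    if (strand == "-") {
      seqs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs)))
    }
    genomic_intervals(chrom, st, en, strand = strand, matched = seqs)
  }
  out <- list(hits_one(pat, "+"))
  if (both_strands) {
    out <- c(out, list(hits_one(Biostrings::reverseComplement(pat), "-")))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    res <- empty_intervals()
    res$matched <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
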