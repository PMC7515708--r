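# The filter cascade from ATAC-seq peaks to transcriptionally active
# putative enhancers (TAPEs):
#   peaks -> merge(<=1 kb)/length(>=146 bp) per region -> additive set
#         -> +/-500 bp regions of open chromatin (ROCs)
#         -> intergenic ROCs (iROCs): >1 kb from genes, clear of ncRNAs and
#            contiguously transcribed blocks
#         -> TAPEs: pooled forward-strand fraction within [5%, 95%].

#' Merge and length-filter peaks per region, then build the additive set
#'
#' Within each region, peaks with edge gaps at most \code{merge_gap} bp are
#' merged and merged peaks shorter than \code{min_len} bp (sub-nucleosomal)
#' are removed. Survivors from all regions are then unioned (gap 0) into one
#' additive peak set.
#'
#' @param peaks_by_region named list of interval data.frames, one per region.
#' @param merge_gap merge gap in bp (default 1000).
#' @param min_len minimum peak length in bp (default 146, one nucleosome).
#' @return list with \code{per_region} (filtered peak sets) and
#'   \code{additive} (cross-region union).
#' @export
preprocess_peaks <- function(peaks_by_region, merge_gap = 1000,
                             min_len = 146) {
  if (length(peaks_by_region) == 0 ||
      all(vapply(peaks_by_region, nrow, integer(1)) == 0)) {
    warning("no peaks supplied; additive peak set is empty")
    return(list(per_region = lapply(peaks_by_region, function(x)
      empty_intervals()), additive = empty_intervals()))
  }
  per_region <- lapply(peaks_by_region, function(p) {
    if (nrow(p) == 0) return(empty_intervals())
    filter_min_length(merge_intervals(p, merge_gap), min_len)
  })
  additive <- merge_intervals(do.call(rbind, lapply(per_region, function(p)
    p[, c("chrom", "start", "end", "strand")])), 0)
  list(per_region = per_region, additive = additive)
}

#' Expand peaks into regions of open chromatin (ROCs)
#'
#' Default rule anchors a fixed window on the peak center:
#' \code{[center - flank, center + flank)} with
#' \code{center = floor((start + end) / 2)}, clipped to chromosome bounds.
#' The alternative \code{"edges"} rule expands each peak edge outward by
#' \code{flank} bp, giving variable-width ROCs.
#'
#' @param peaks additive peak set (interval data.frame).
#' @param chrom_sizes named chromosome length vector; peaks on chromosomes
#'   outside this whitelist are dropped (count reported as an attribute).
#' @param flank half-window in bp (default 500).
#' @param expansion \code{"center"} (default) or \code{"edges"}.
#' @return interval data.frame of ROCs with \code{roc_id} and \code{center}.
#' @export
build_rocs <- function(peaks, chrom_sizes, flank = 500,
                       expansion = c("center", "edges")) {
  expansion <- match.arg(expansion)
  on_wl <- peaks$chrom %in% names(chrom_sizes)
  dropped <- sum(!on_wl)
  peaks <- peaks[on_wl, , drop = FALSE]
  if (nrow(peaks) == 0) {
    out <- empty_intervals()
    out$roc_id <- character(0)
    out$center <- numeric(0)
    attr(out, "dropped_off_whitelist") <- dropped
    return(out)
  }
  center <- floor((peaks$start + peaks$end) / 2)
  if (expansion == "center") {
    start <- center - flank
    end <- center + flank
  } else {
    start <- peaks$start - flank
    end <- peaks$end + flank
  }
  lim <- unname(chrom_sizes[peaks$chrom])
  start <- pmax(start, 0)
  end <- pmin(end, lim)
  out <- genomic_intervals(peaks$chrom, start, end)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$roc_id <- sprintf("ROC%05d", seq_len(nrow(out)))
  out$center <- floor((out$start + out$end) / 2)
  rownames(out) <- NULL
  attr(out, "dropped_off_whitelist") <- dropped
  out
}

#' Contiguously transcribed blocks from pooled unstranded coverage
#'
#' Maximal runs of pooled per-base signal at or above \code{min_cov} are
#' found, runs with edge gaps at most \code{block_merge_gap} bp are merged,
#' and merged blocks must be strictly longer than \code{min_block_len} bp
#' to survive.
#'
#' @param pooled_cov pooled unstranded \code{coverage_track}.
#' @param min_cov per-base signal threshold (> 0).
#' @param min_block_len minimum block length, strict (default 100 bp).
#' @param block_merge_gap merge gap between runs (default 1000 bp).
#' @return interval data.frame of transcribed blocks.
#' @export
find_transcribed_blocks <- function(pooled_cov, min_cov,
                                    min_block_len = 100,
                                    block_merge_gap = 1000) {
  stopifnot(min_cov > 0)
  runs <- coverage_runs(pooled_cov, min_cov)
  if (nrow(runs) == 0) return(runs)
  merged <- merge_intervals(runs, block_merge_gap)
  merged[iv_length(merged) > min_block_len, , drop = FALSE]
}

#' Filter ROCs to intergenic ROCs (iROCs)
#'
#' A ROC survives iff its distance to every gene body exceeds
#' \code{min_gene_dist} bp, it overlaps no ncRNA annotation, and it overlaps
#' no contiguously transcribed block. With \code{anchor = "tss"} the gene
#' distance is measured to annotated TSS points instead of gene bodies.
#'
#' @param rocs ROC data.frame from [build_rocs()].
#' @param genes gene model data.frame (protein-coding universe).
#' @param ncrnas interval data.frame of small ncRNA annotations (may be
#'   empty).
#' @param blocks transcribed-block data.frame (may be empty).
#' @param min_gene_dist minimum distance to genes in bp, strict (default
#'   1000).
#' @param anchor \code{"body"} (default) or \code{"tss"}.
#' @return the surviving rows of \code{rocs}.
#' @export
filter_intergenic <- function(rocs, genes, ncrnas = empty_intervals(),
                              blocks = empty_intervals(),
                              min_gene_dist = 1000,
                              anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0) stop("gene set must be non-empty")
  if (nrow(rocs) == 0) return(rocs)
  gene_iv <- if (anchor == "body") genes else
    genomic_intervals(genes$chrom, genes$tss, genes$tss + 1,
                      gene_id = genes$gene_id)
  if (anchor == "tss") gene_iv$gene_id <- genes$gene_id
  nd <- distance_to_nearest(rocs, gene_iv)
  far <- is.na(nd$distance) | abs(nd$distance) > min_gene_dist
  clear_nc <- !overlaps_any(rocs, ncrnas)
  clear_blk <- !overlaps_any(rocs, blocks)
  rocs[far & clear_nc & clear_blk, , drop = FALSE]
}

#' Call TAPEs from iROCs and stranded coverage
#'
#' Pools forward- and reverse-strand signal across all samples within each
#' iROC and computes the forward fraction \eqn{f = fwd / (fwd + rev)}. An
#' iROC is classified bidirectional - a TAPE - when \code{lower <= f <=
#' upper} (bounds inclusive by default; set the \code{*_inclusive} flags for
#' strict semantics) and pooled signal is at least \code{min_total_signal}.
#'
#' @param irocs iROC data.frame from [filter_intergenic()].
#' @param coverage list of \code{stranded_coverage}, one per sample (named
#'   by sample id).
#' @param lower,upper bidirectionality bounds on f (defaults 0.05, 0.95).
#' @param min_total_signal minimum pooled signal (default 10; 0 emulates the
#'   unguarded rule).
#' @param inclusive logical: treat the bounds as inclusive (default TRUE).
#' @return a \code{tape_set}: data.frame of all iROCs with pooled
#'   \code{fwd}, \code{rev}, forward fraction \code{f}, classification
#'   \code{bidirectional} and \code{flag} ("ok" or "no signal"); per-sample
#'   signal matrices in attributes \code{fwd_by_sample},
#'   \code{rev_by_sample}. TAPE ids are assigned to bidirectional rows.
#' @export
call_tapes <- function(irocs, coverage, lower = 0.05, upper = 0.95,
                       min_total_signal = 10, inclusive = TRUE) {
  stopifnot(length(coverage) >= 1)
  n <- nrow(irocs)
  ids <- names(coverage)
  if (is.null(ids)) ids <- sprintf("sample%02d", seq_along(coverage))
  fwd_m <- matrix(0, n, length(coverage), dimnames = list(NULL, ids))
  rev_m <- fwd_m
  for (j in seq_along(coverage)) {
    fwd_m[, j] <- signal_in_intervals(coverage[[j]]$fwd, irocs)
    rev_m[, j] <- signal_in_intervals(coverage[[j]]$rev, irocs)
  }
  fwd <- rowSums(fwd_m)
  rev <- rowSums(rev_m)
  total <- fwd + rev
  f <- ifelse(total > 0, fwd / total, NA_real_)
  in_bounds <- if (inclusive) !is.na(f) & f >= lower & f <= upper else
    !is.na(f) & f > lower & f < upper
  bidir <- in_bounds & total >= min_total_signal & total > 0
  out <- irocs
  out$fwd <- fwd
  out$rev <- rev
  out$f <- f
  out$bidirectional <- bidir
  out$flag <- ifelse(total > 0, "ok", "no signal")
  out$tape_id <- rep(NA_character_, n)
  out$tape_id[bidir] <- sprintf("TAPE%05d", seq_len(sum(bidir)))
  rownames(out) <- NULL
  attr(out, "fwd_by_sample") <- fwd_m
  attr(out, "rev_by_sample") <- rev_m
  class(out) <- c("tape_set", "data.frame")
  out
}

#' Extract the TAPE rows of a tape_set
#' @param x a \code{tape_set} from [call_tapes()].
#' @return data.frame of bidirectional iROCs with per-sample count matrix in
#'   attribute \code{counts} (fwd + rev per sample).
#' @export
tapes <- function(x) {
  stopifnot(inherits(x, "tape_set"))
  keep <- x$bidirectional
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  cnt <- attr(x, "fwd_by_sample")[keep, , drop = FALSE] +
    attr(x, "rev_by_sample")[keep, , drop = FALSE]
  rownames(cnt) <- out$tape_id
  attr(out, "counts") <- cnt
  out
}

#' @export
print.tape_set <- function(x, ...) {
  cat(sprintf("tape_set: %d iROCs scored, %d bidirectional (TAPEs)\n",
              nrow(x), sum(x$bidirectional)))
  if (any(x$bidirectional)) {
    f <- x$f[x$bidirectional]
    cat(sprintf("  forward fraction of TAPEs: median %.3f [%.3f, %.3f]\n",
                stats::median(f), min(f), max(f)))
  }
  invisible(x)
}

#' @export
summary.tape_set <- function(object, ...) {
  print(object)
  cat(sprintf("  no-signal iROCs: %d\n", sum(object$flag == "no signal")))
  invisible(object)
}
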