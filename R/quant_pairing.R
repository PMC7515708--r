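# CPKM quantification and correlation-based enhancer-gene pairing: every
# protein-coding gene whose TSS lies within 1 Mb of a TAPE center is a
# candidate partner; partners are scored by Pearson correlation of CPKM
# across samples, globally and within each region.

#' Counts per kilobase per million (CPKM)
#'
#' \code{cpkm = raw / (length_kb * library_size_millions)}.
#'
#' @param raw numeric features-by-samples matrix of raw signal.
#' @param lengths feature lengths in bp, along rows (all > 0).
#' @param library_sizes per-sample total mapped signal, along columns
#'   (all > 0).
#' @return CPKM matrix with attribute \code{unit = "CPKM"}.
#' @export
cpkm <- function(raw, lengths, library_sizes) {
  stopifnot(length(lengths) == nrow(raw),
            length(library_sizes) == ncol(raw))
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  out <- raw / (lengths / 1e3) /
    matrix(library_sizes / 1e6, nrow(raw), ncol(raw), byrow = TRUE)
  attr(out, "unit") <- "CPKM"
  out
}

#' Candidate TAPE-gene pairs within a distance window
#'
#' One pair per (TAPE, protein-coding gene) with \code{|TSS - center| <=
#' window}. Signed distance is \code{TSS - center} (positive when the TSS
#' lies downstream of the TAPE center). \code{distance_rank} is 1 for the
#' closest candidate gene of each TAPE, ranking by \code{|distance|} with
#' ties broken by gene id.
#'
#' @param tape_df data.frame with \code{tape_id}, \code{chrom},
#'   \code{center}.
#' @param genes gene model data.frame; only rows with biotype
#'   \code{"protein_coding"} are candidate partners.
#' @param window maximum |distance| in bp (default 1e6).
#' @return data.frame of pairs: \code{tape_id}, \code{gene_id},
#'   \code{distance}, \code{distance_rank}.
#' @export
candidate_pairs <- function(tape_df, genes, window = 1e6) {
  genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  if (nrow(tape_df) == 0 || nrow(genes) == 0) {
    return(data.frame(tape_id = character(), gene_id = character(),
                      distance = numeric(), distance_rank = integer(),
                      stringsAsFactors = FALSE))
  }
  pieces <- lapply(seq_len(nrow(tape_df)), function(i) {
    g <- genes[genes$chrom == tape_df$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    d <- g$tss - tape_df$center[i]
    keep <- abs(d) <= window
    if (!any(keep)) return(NULL)
    g <- g[keep, , drop = FALSE]
    d <- d[keep]
    ord <- order(abs(d), g$gene_id)
    data.frame(tape_id = tape_df$tape_id[i], gene_id = g$gene_id[ord],
               distance = d[ord], distance_rank = seq_along(ord),
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) {
    return(data.frame(tape_id = character(), gene_id = character(),
                      distance = numeric(), distance_rank = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation with an undefined flag
#'
#' Returns \code{NA} (rather than erroring or propagating NaN) when either
#' vector has zero variance, the state the pairing stage uses to drop pairs
#' whose gene never varies (e.g. all-zero counts).
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return correlation in [-1, 1], or \code{NA} if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Score candidate pairs by expression correlation
#'
#' Fills \code{r_global} (all samples) and one \code{r_<region>} column per
#' region (that region's samples only). Pairs with undefined global
#' correlation are removed; undefined region entries are kept as \code{NA}.
#' \code{high_confidence} marks pairs with \code{r_global > 0.5} (strict).
#'
#' @param pairs data.frame from [candidate_pairs()].
#' @param expr features-by-samples expression matrix (CPKM) containing every
#'   paired TAPE and gene.
#' @param sample_info sample metadata with \code{sample_id}, \code{region}.
#' @param r_high high-confidence threshold on \code{r_global} (default 0.5,
#'   strict).
#' @param treatments which treatments enter the global correlation
#'   (default both).
#' @return a \code{tape_pairs} data.frame.
#' @export
correlate_pairs <- function(pairs, expr, sample_info, r_high = 0.5,
                            treatments = c("Veh", "KCl")) {
  miss <- setdiff(unique(c(pairs$tape_id, pairs$gene_id)), rownames(expr))
  if (length(miss)) {
    stop("expression matrix lacks features: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  use <- sample_info$sample_id[sample_info$treatment %in% treatments]
  use <- intersect(colnames(expr), use)
  regions <- sort(unique(sample_info$region))
  out <- pairs
  out$r_global <- vapply(seq_len(nrow(pairs)), function(i) {
    pearson_r(expr[pairs$tape_id[i], use], expr[pairs$gene_id[i], use])
  }, numeric(1))
  for (rg in regions) {
    rs <- intersect(use,
                    sample_info$sample_id[sample_info$region == rg])
    out[[paste0("r_", rg)]] <- vapply(seq_len(nrow(pairs)), function(i) {
      if (stats::sd(expr[pairs$tape_id[i], rs]) == 0 ||
          stats::sd(expr[pairs$gene_id[i], rs]) == 0) return(NA_real_)
      stats::cor(expr[pairs$tape_id[i], rs], expr[pairs$gene_id[i], rs])
    }, numeric(1))
  }
  out <- out[!is.na(out$r_global), , drop = FALSE]
  out$high_confidence <- out$r_global > r_high
  rownames(out) <- NULL
  class(out) <- c("tape_pairs", "data.frame")
  out
}

#' @export
print.tape_pairs <- function(x, ...) {
  cat(sprintf(
    "tape_pairs: %d pairs (%d TAPEs), %d high-confidence (r > 0.5)\n",
    nrow(x), length(unique(x$tape_id)), sum(x$high_confidence)))
  invisible(x)
}

# argmax r_global per TAPE; ties -> smaller distance_rank, then gene_id
best_pair_per_tape <- function(pairs) {
  ord <- order(pairs$tape_id, -pairs$r_global, pairs$distance_rank,
               pairs$gene_id)
  p <- pairs[ord, , drop = FALSE]
  p[!duplicated(p$tape_id), , drop = FALSE]
}

#' Where does each TAPE's best-correlated gene rank by distance?
#'
#' For each TAPE the candidate gene with maximal \code{r_global} is found
#' (ties to the smaller distance rank, then gene id); the histogram of the
#' winning distance ranks and the fraction of TAPEs whose winner is the
#' closest gene (rank 1) are reported.
#'
#' @param pairs scored pair data.frame (typically the high-confidence
#'   subset).
#' @return list with \code{rank_counts} (data.frame rank/count) and
#'   \code{fraction_rank1}.
#' @export
rank_position_summary <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(list(rank_counts = data.frame(distance_rank = integer(),
                                         count = integer()),
                fraction_rank1 = NA_real_))
  }
  best <- best_pair_per_tape(pairs)
  tab <- table(best$distance_rank)
  list(
    rank_counts = data.frame(distance_rank = as.integer(names(tab)),
                             count = as.integer(tab)),
    fraction_rank1 = mean(best$distance_rank == 1)
  )
}

#' Mean correlation as a function of TAPE-gene distance
#'
#' Bins pairs by \code{|distance|} and reports per-bin pair count and mean
#' \code{r_global}; empty bins are flagged rather than reported as zero.
#' Also returns the per-TAPE best pair (max r) with its distance for
#' distance-vs-strength analyses.
#'
#' @param pairs scored pair data.frame.
#' @param bin_width bin width in bp (default 1e5).
#' @param window distance span covered by the bins (default 1e6).
#' @return list with \code{bins} (data.frame bin_start, bin_end, n, mean_r,
#'   empty) and \code{best} (per-TAPE max-r pair).
#' @export
distance_correlation_summary <- function(pairs, bin_width = 1e5,
                                         window = 1e6) {
  edges <- seq(0, window, by = bin_width)
  nb <- length(edges) - 1
  idx <- pmin(pmax(findInterval(abs(pairs$distance), edges,
                                rightmost.closed = TRUE), 1), nb)
  n <- tabulate(idx, nbins = nb)
  mean_r <- rep(NA_real_, nb)
  for (b in which(n > 0)) mean_r[b] <- mean(pairs$r_global[idx == b])
  bins <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                     n = n, mean_r = mean_r, empty = n == 0)
  list(bins = bins, best = best_pair_per_tape(pairs))
}
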