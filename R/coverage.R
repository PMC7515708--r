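# Per-base signal as a sparse step function: one data.frame per chromosome
# with columns start, end, value (0-based half-open, value > 0, segments
# sorted and non-overlapping). Bases not covered by a segment have signal 0.

#' Construct a coverage track
#'
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{value}; zero-value segments are dropped.
#' @param chrom_sizes named numeric vector of chromosome lengths declaring
#'   the coordinate universe.
#' @return object of class \code{coverage_track}.
#' @export
coverage_track <- function(segments, chrom_sizes) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  if (nrow(segments) > 0) {
    if (any(segments$value < 0)) stop("coverage values must be >= 0")
    bad <- !segments$chrom %in% names(chrom_sizes)
    if (any(bad)) {
      segments <- segments[!bad, , drop = FALSE]
    }
    segments <- segments[segments$value > 0, , drop = FALSE]
    segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  }
  by_chrom <- split(segments[, c("start", "end", "value")], segments$chrom)
  structure(list(by_chrom = by_chrom, chrom_sizes = chrom_sizes),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  nseg <- sum(vapply(x$by_chrom, nrow, integer(1)))
  cat("coverage_track:", length(x$chrom_sizes), "chromosomes,",
      nseg, "segments\n")
  invisible(x)
}

empty_track <- function(chrom_sizes) {
  coverage_track(data.frame(chrom = character(), start = numeric(),
                            end = numeric(), value = numeric()), chrom_sizes)
}

track_segments <- function(cov) {
  segs <- lapply(names(cov$by_chrom), function(ch) {
    s <- cov$by_chrom[[ch]]
    if (nrow(s) == 0) return(NULL)
    cbind(data.frame(chrom = ch, stringsAsFactors = FALSE), s)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  }
  do.call(rbind, segs)
}

#' Total signal within an interval
#'
#' Sums per-base signal over \code{[start, end)}. The chromosome must be in
#' the track's declared chromosome-size table.
#'
#' @param cov a \code{coverage_track}.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return non-negative total signal (base-pairs times per-base value).
#' @export
signal_in_interval <- function(cov, chrom, start, end) {
  if (!chrom %in% names(cov$chrom_sizes)) {
    stop("unknown chromosome: ", chrom)
  }
  segs <- cov$by_chrom[[chrom]]
  if (is.null(segs) || nrow(segs) == 0) return(0)
  hit <- segs$end > start & segs$start < end
  if (!any(hit)) return(0)
  s <- segs[hit, , drop = FALSE]
  sum(s$value * (pmin(s$end, end) - pmax(s$start, start)))
}

#' Vectorised [signal_in_interval()] over an interval data.frame
#' @param cov a \code{coverage_track}.
#' @param iv interval data.frame.
#' @return numeric vector of totals along \code{iv}.
#' @export
signal_in_intervals <- function(cov, iv) {
  vapply(seq_len(nrow(iv)), function(i) {
    signal_in_interval(cov, iv$chrom[i], iv$start[i], iv$end[i])
  }, numeric(1))
}

#' Sum several coverage tracks into one pooled track
#'
#' @param tracks list of \code{coverage_track} objects sharing a chromosome
#'   universe.
#' @return pooled \code{coverage_track}.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  sizes <- tracks[[1]]$chrom_sizes
  chroms <- unique(unlist(lapply(tracks, function(t) names(t$by_chrom))))
  segs <- lapply(chroms, function(ch) {
    evs <- lapply(tracks, function(t) {
      s <- t$by_chrom[[ch]]
      if (is.null(s) || nrow(s) == 0) return(NULL)
      data.frame(pos = c(s$start, s$end), delta = c(s$value, -s$value))
    })
    evs <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
    if (is.null(evs) || nrow(evs) == 0) return(NULL)
    ev <- stats::aggregate(delta ~ pos, data = evs, FUN = sum)
    ev <- ev[order(ev$pos), , drop = FALSE]
    val <- cumsum(ev$delta)
    k <- seq_len(nrow(ev) - 1)
    out <- data.frame(chrom = ch, start = ev$pos[k], end = ev$pos[k + 1],
                      value = val[k], stringsAsFactors = FALSE)
    out[out$value > 1e-12, , drop = FALSE]
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  all <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               value = numeric())
  coverage_track(all, sizes)
}

#' Maximal runs of coverage at or above a threshold
#'
#' @param cov a \code{coverage_track}.
#' @param min_cov minimum per-base signal (> 0).
#' @return interval data.frame of maximal runs with signal \code{>= min_cov}.
#' @export
coverage_runs <- function(cov, min_cov) {
  stopifnot(min_cov > 0)
  segs <- track_segments(cov)
  segs <- segs[segs$value >= min_cov, , drop = FALSE]
  if (nrow(segs) == 0) return(empty_intervals())
  merge_intervals(genomic_intervals(segs$chrom, segs$start, segs$end), 0)
}

#' A pair of strand-specific coverage tracks for one sample
#' @param fwd,rev \code{coverage_track}s for forward and reverse strand.
#' @export
stranded_coverage <- function(fwd, rev) {
  stopifnot(inherits(fwd, "coverage_track"), inherits(rev, "coverage_track"))
  structure(list(fwd = fwd, rev = rev), class = "stranded_coverage")
}
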