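# Independent brute-force oracles. These deliberately avoid the package's
# own interval/coverage machinery: merging is a quadratic fixpoint scan,
# coverage sums are per-base array paints, motif matching is a
# position-by-position IUPAC class check.

random_intervals <- function(n, chroms = "chr1", max_pos = 10000,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len)
}

# quadratic fixpoint merge: join any two intervals on the same chromosome
# whose edge gap is <= max_gap, until stable
oracle_merge <- function(iv, max_gap) {
  df <- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end)
  repeat {
    done <- TRUE
    dead <- rep(FALSE, nrow(df))
    for (i in seq_len(nrow(df))) {
      if (dead[i]) next
      for (j in seq_len(nrow(df))) {
        if (i == j || dead[i] || dead[j]) next
        if (df$chrom[i] != df$chrom[j]) next
        gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
        if (gap <= max_gap) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          dead[j] <- TRUE
          done <- FALSE
        }
      }
    }
    df <- df[!dead, , drop = FALSE]
    if (done) break
  }
  out <- df
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

iv_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(sprintf("%s:%d-%d", df$chrom, as.integer(df$start),
               as.integer(df$end)))
}

# all-pairs nearest gene with the package's documented tie-break
oracle_nearest <- function(q_chrom, q_start, q_end, genes) {
  g <- genes[genes$chrom == q_chrom, , drop = FALSE]
  if (nrow(g) == 0) return(list(gene_id = NA_character_, dist = NA_real_))
  gap <- pmax(g$start - q_end, q_start - g$end, 0)
  ord <- order(gap, g$start, g$gene_id)
  k <- ord[1]
  sign <- if (g$start[k] >= q_end) 1 else if (g$end[k] <= q_start) -1 else 0
  list(gene_id = g$gene_id[k], dist = sign * gap[k])
}

# paint a per-base signal array for one chromosome from (start,end,value)
# segments (0-based half-open; array index b+1 is base b)
paint_array <- function(segments, len) {
  arr <- numeric(len)
  if (nrow(segments) > 0) {
    for (i in seq_len(nrow(segments))) {
      s <- segments$start[i]; e <- min(segments$end[i], len)
      if (e > s) arr[(s + 1):e] <- arr[(s + 1):e] + segments$value[i]
    }
  }
  arr
}

# maximal runs with arr >= threshold, as 0-based half-open intervals
array_runs <- function(arr, threshold) {
  r <- rle(arr >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    i <- ord[k]
    val <- min(p[i] * n / k, prev)
    q[i] <- val
    prev <- val
  }
  q
}

IUPAC_ORACLE <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracle_iupac_hits <- function(sequence, motif) {
  seq_ch <- strsplit(sequence, "")[[1]]
  mot <- strsplit(motif, "")[[1]]
  m <- length(mot)
  hits <- integer(0)
  if (length(seq_ch) >= m) {
    for (s in 0:(length(seq_ch) - m)) {
      ok <- TRUE
      for (k in seq_len(m)) {
        if (!seq_ch[s + k] %in% IUPAC_ORACLE[[mot[k]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  hits
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# tiny coverage track from segment triples on one chromosome
make_track <- function(chrom, start, end, value, sizes) {
  coverage_track(data.frame(chrom = chrom, start = start, end = end,
                            value = value), sizes)
}

empty_track_for_tests <- function(sizes) {
  coverage_track(data.frame(chrom = character(), start = numeric(),
                            end = numeric(), value = numeric()), sizes)
}
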