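# Readers and writers for the plain-text formats the pipeline touches.
# BED/narrowPeak/bedGraph are 0-based half-open (kept as-is); GTF is 1-based
# inclusive and converted to the internal convention at the boundary.

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

parse_error <- function(path, line_no, msg) {
  stop(sprintf("%s:%d: %s", path, line_no, msg), call. = FALSE)
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a BED file (BED3 or BED6)
#'
#' @param path BED file path.
#' @return interval data.frame; BED6 name/score columns carried along.
#' @export
read_bed <- function(path) {
  lines <- read_lines_checked(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) return(empty_intervals())
  fields <- split_fields(lines[idx])
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad)) parse_error(path, idx[bad[1]], "BED line has < 3 fields")
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  badnum <- which(is.na(start) | is.na(end))
  if (length(badnum)) {
    parse_error(path, idx[badnum[1]], "non-numeric BED coordinates")
  }
  iv <- genomic_intervals(chrom, start, end)
  if (all(nf >= 6)) {
    iv$name <- vapply(fields, `[`, "", 4)
    iv$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
    iv$strand <- vapply(fields, `[`, "", 6)
    iv$strand[!iv$strand %in% c("+", "-")] <- "*"
  } else if (all(nf >= 4)) {
    iv$name <- vapply(fields, `[`, "", 4)
  }
  iv
}

#' Write intervals as BED
#'
#' Writes BED6 when \code{name} is present (score defaults to 0), else BED3.
#' @param iv interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  if (nrow(iv) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (!is.null(iv$name)) {
    score <- if (is.null(iv$score)) rep(0, nrow(iv)) else iv$score
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", iv$chrom, as.integer(iv$start),
                     as.integer(iv$end), iv$name, format_num(score),
                     ifelse(iv$strand == "*", ".", iv$strand))
  } else {
    lines <- sprintf("%s\t%d\t%d", iv$chrom, as.integer(iv$start),
                     as.integer(iv$end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a MACS2 narrowPeak file (BED6+4)
#' @param path narrowPeak file path.
#' @return interval data.frame with name, score, signal, pval, qval, summit.
#' @export
read_narrowpeak <- function(path) {
  lines <- read_lines_checked(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) return(empty_intervals())
  fields <- split_fields(lines[idx])
  bad <- which(lengths(fields) < 10)
  if (length(bad)) {
    parse_error(path, idx[bad[1]], "narrowPeak line has < 10 fields")
  }
  num <- function(k) suppressWarnings(as.numeric(vapply(fields, `[`, "", k)))
  iv <- genomic_intervals(vapply(fields, `[`, "", 1), num(2), num(3))
  iv$name <- vapply(fields, `[`, "", 4)
  iv$score <- num(5)
  iv$signal <- num(7)
  iv$pval <- num(8)
  iv$qval <- num(9)
  iv$summit <- num(10)
  iv
}

#' Read gene models from GTF gene lines
#'
#' Only lines whose feature column is \code{gene} are used. GTF 1-based
#' inclusive coordinates are converted to 0-based half-open. Requires
#' \code{gene_id} in the attributes column; \code{gene_name} and
#' \code{gene_biotype} are used when present.
#'
#' @param path GTF file path.
#' @return gene model data.frame (see [gene_models()]).
#' @export
read_gtf_genes <- function(path) {
  lines <- read_lines_checked(path)
  idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(idx) == 0) {
    return(gene_models(character(), character(), numeric(), numeric(),
                       character()))
  }
  fields <- split_fields(lines[idx])
  bad <- which(lengths(fields) < 9)
  if (length(bad)) parse_error(path, idx[bad[1]], "GTF line has < 9 fields")
  feat <- vapply(fields, `[`, "", 3)
  gidx <- which(feat == "gene")
  if (length(gidx) == 0) {
    return(gene_models(character(), character(), numeric(), numeric(),
                       character()))
  }
  f <- fields[gidx]
  start1 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 4)))
  end1 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 5)))
  badnum <- which(is.na(start1) | is.na(end1))
  if (length(badnum)) {
    parse_error(path, idx[gidx[badnum[1]]], "non-numeric GTF coordinates")
  }
  attrs <- vapply(f, `[`, "", 9)
  get_attr <- function(key) {
    out <- rep(NA_character_, length(attrs))
    hit <- grepl(paste0(key, ' "'), attrs)
    out[hit] <- sub(paste0(key, ' "([^"]*)".*'), "\\1",
                    regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs)))
    out
  }
  gene_id <- get_attr("gene_id")
  miss <- which(is.na(gene_id))
  if (length(miss)) {
    parse_error(path, idx[gidx[miss[1]]], "GTF gene line lacks gene_id")
  }
  name <- get_attr("gene_name")
  biotype <- get_attr("gene_biotype")
  gene_models(
    gene_id = gene_id,
    chrom = vapply(f, `[`, "", 1),
    start = start1 - 1,   # 1-based inclusive -> 0-based half-open
    end = end1,
    strand = vapply(f, `[`, "", 7),
    name = ifelse(is.na(name), gene_id, name),
    biotype = ifelse(is.na(biotype), "protein_coding", biotype)
  )
}

#' Write gene models as GTF gene lines
#' @param genes gene model data.frame.
#' @param path output path.
#' @param source source field (column 2).
#' @export
write_gtf_genes <- function(genes, path, source = "tapecall") {
  lines <- sprintf(
    '%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s";',
    genes$chrom, source, as.integer(genes$start + 1), as.integer(genes$end),
    genes$strand, genes$gene_id, genes$name, genes$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#' @param path bedGraph file path.
#' @param chrom_sizes named chromosome length vector.
#' @return a \code{coverage_track}.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  lines <- read_lines_checked(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) return(empty_track(chrom_sizes))
  fields <- split_fields(lines[idx])
  bad <- which(lengths(fields) < 4)
  if (length(bad)) {
    parse_error(path, idx[bad[1]], "bedGraph line has < 4 fields")
  }
  num <- function(k) suppressWarnings(as.numeric(vapply(fields, `[`, "", k)))
  start <- num(2); end <- num(3); value <- num(4)
  badnum <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(badnum)) {
    parse_error(path, idx[badnum[1]], "non-numeric bedGraph fields")
  }
  coverage_track(data.frame(chrom = vapply(fields, `[`, "", 1),
                            start = start, end = end, value = value,
                            stringsAsFactors = FALSE), chrom_sizes)
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 10)
  trimws(out)
}

#' Write a coverage track as bedGraph
#' @param cov a \code{coverage_track}.
#' @param path output path.
#' @export
write_bedgraph <- function(cov, path) {
  segs <- track_segments(cov)
  if (nrow(segs) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s", segs$chrom, as.integer(segs$start),
                     as.integer(segs$end), format_num(segs$value)), path)
  invisible(path)
}

#' Read a chrom.sizes file
#' @param path two-column (name, length) tab-separated file.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  lines <- read_lines_checked(path)
  idx <- which(nzchar(lines))
  fields <- split_fields(lines[idx])
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    parse_error(path, idx[bad[1]], "chrom.sizes line has < 2 fields")
  }
  len <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  badnum <- which(is.na(len))
  if (length(badnum)) {
    parse_error(path, idx[badnum[1]], "non-numeric chromosome length")
  }
  stats::setNames(len, vapply(fields, `[`, "", 1))
}

#' @rdname read_chrom_sizes
#' @param sizes named numeric vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' Read a features-by-samples TSV matrix
#'
#' First column holds feature ids, header row holds sample ids.
#' @param path TSV file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  lines <- read_lines_checked(path)
  if (length(lines) == 0) parse_error(path, 1, "empty matrix file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1) {
    m <- matrix(numeric(), nrow = 0, ncol = length(header) - 1,
                dimnames = list(NULL, header[-1]))
    return(m)
  }
  fields <- split_fields(lines[-1])
  bad <- which(lengths(fields) != length(header))
  if (length(bad)) {
    parse_error(path, bad[1] + 1, "matrix row width differs from header")
  }
  vals <- lapply(fields, function(f) suppressWarnings(as.numeric(f[-1])))
  badnum <- which(vapply(vals, anyNA, logical(1)))
  if (length(badnum)) {
    parse_error(path, badnum[1] + 1, "non-numeric matrix value")
  }
  m <- do.call(rbind, vals)
  rownames(m) <- vapply(fields, `[`, "", 1)
  colnames(m) <- header[-1]
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with dimnames.
#' @param id_col name for the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  if (nrow(m) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format_num(m[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read or write the sample metadata table
#'
#' Columns: \code{sample_id}, \code{region} (cortex/hippocampus/striatum),
#' \code{treatment} (Veh/KCl), \code{replicate}; \code{library_size} added
#' downstream once signal is quantified.
#' @param path TSV file path.
#' @export
read_sample_info <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "region", "treatment", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": sample table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop(path, ": duplicate sample_id")
  df
}

#' @rdname read_sample_info
#' @param info sample metadata data.frame.
#' @export
write_sample_info <- function(info, path) {
  utils::write.table(info, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
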