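# End-to-end orchestration: resolved configuration, staged runs with
# atomic outputs, and a manifest recording the record-count funnel
# |peaks| -> |ROCs| -> |iROCs| -> |TAPEs| -> |pairs| -> |high-confidence|.

pipeline_defaults <- function() {
  list(
    seed = 1,
    merge_gap = 1000, min_peak_len = 146,
    roc_flank = 500, roc_expansion = "center",
    min_gene_dist = 1000, gene_anchor = "body",
    block_min_cov = 1, block_min_len = 100, block_merge_gap = 1000,
    bidir_lower = 0.05, bidir_upper = 0.95, bidir_inclusive = TRUE,
    min_total_signal = 10,
    pairing_window = 1e6, r_high = 0.5,
    global_treatments = c("Veh", "KCl"),
    q_threshold = 0.05, z_margin = 0.5,
    distance_bin = 1e5,
    profile_window = 5000, profile_bin = 50,
    paths = list()
  )
}

#' Pipeline configuration
#'
#' All thresholds default to the method's stated values (1 kb peak merge,
#' 146 bp minimum peak, +/-500 bp ROC windows, >1 kb intergenic distance,
#' >100 bp transcribed blocks merged within 1 kb, 5-95% inclusive
#' bidirectionality bounds, 1 Mb pairing window, r > 0.5 high confidence,
#' FDR 0.05). \code{paths} must name the external inputs for non-simulated
#' runs: \code{peaks} (named per region), \code{gtf}, \code{ncrna},
#' \code{chrom_sizes}, \code{sample_info}, \code{coverage} (per sample:
#' \code{fwd}, \code{rev}), optionally \code{rna_counts},
#' \code{atac_counts}, \code{truth}.
#'
#' @param ... overrides of the defaults; unknown keys are an error listing
#'   the valid keys.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("invalid config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(defaults), collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a resolved pipeline configuration
#' @param cfg a \code{pipeline_config}.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

fixture_paths <- function(dir) {
  si <- read_sample_info(file.path(dir, "sample_info.tsv"))
  regions <- sort(unique(si$region))
  list(
    peaks = stats::setNames(
      file.path(dir, "peaks", paste0(regions, ".narrowPeak")), regions),
    gtf = file.path(dir, "genes.gtf"),
    ncrna = file.path(dir, "ncrna.bed"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    sample_info = file.path(dir, "sample_info.tsv"),
    coverage = stats::setNames(lapply(si$sample_id, function(s) list(
      fwd = file.path(dir, "coverage", paste0(s, "_fwd.bedGraph")),
      rev = file.path(dir, "coverage", paste0(s, "_rev.bedGraph")))),
      si$sample_id),
    rna_counts = file.path(dir, "rna_counts.tsv"),
    atac_counts = file.path(dir, "atac_counts.tsv"),
    truth = file.path(dir, "truth.tsv"))
}

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

require_inputs <- function(paths) {
  flat <- unlist(paths, use.names = TRUE)
  miss <- flat[!file.exists(flat)]
  if (length(miss)) {
    stop("missing input file(s): ", paste(miss, collapse = ", "))
  }
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " INFO [", stage, "] ",
          ...)
}

load_coverage <- function(paths, sizes) {
  covs <- lapply(paths, function(p) {
    stranded_coverage(read_bedgraph(p$fwd, sizes),
                      read_bedgraph(p$rev, sizes))
  })
  names(covs) <- names(paths)
  covs
}

read_peaks_file <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  nf <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (length(first) && nf >= 10) read_narrowpeak(path) else read_bed(path)
}

#' Run the pipeline
#'
#' Stages: \code{simulate} (generate the synthetic fixture under
#' \code{outdir/fixture} and point the config at it), \code{call-tapes}
#' (peaks to TAPEs), \code{pair} (CPKM quantification and correlation
#' pairing), \code{diff} (region-selective and activity-dependent calls
#' plus linked-response summaries), \code{profile} (ATAC metaprofile around
#' TAPE centers), \code{evaluate} (recovery metrics against planted truth)
#' or \code{all}. Later stages read the earlier stages' outputs from
#' \code{outdir}; outputs are written atomically and a manifest with the
#' resolved-config hash, input checksums and per-stage record counts is
#' refreshed after every run.
#'
#' @param stage one of simulate, call-tapes, pair, diff, profile, evaluate,
#'   all.
#' @param config a [pipeline_config()]; for \code{simulate}, \code{sim}
#'   must be a [sim_config()].
#' @param outdir output directory.
#' @param sim a [sim_config()] for the simulate stage.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "call-tapes", "pair",
                                   "diff", "profile", "evaluate"),
                         config = pipeline_config(), outdir, sim = NULL) {
  stage <- match.arg(stage)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c(if (!is.null(sim)) "simulate", "call-tapes", "pair", "diff",
      "profile", if (!is.null(sim)) "evaluate")
  } else stage
  counts <- list()
  for (st in stages) {
    counts <- c(counts, switch(
      st,
      "simulate" = {
        if (is.null(sim)) stop("simulate stage needs a sim_config")
        fx <- simulate_fixture(sim, file.path(outdir, "fixture"))
        config$paths <- fixture_paths(fx$dir)
        stage_log(st, "fixture written to ", fx$dir)
        list(planted_enhancers = sim$n_enhancers)
      },
      "call-tapes" = run_stage_tapes(config, outdir),
      "pair" = run_stage_pair(config, outdir),
      "diff" = run_stage_diff(config, outdir),
      "profile" = run_stage_profile(config, outdir),
      "evaluate" = run_stage_evaluate(config, outdir),
      stop("unknown stage: ", st)))
  }
  # refresh manifest: resolved config + input checksums + funnel counts
  cfg_path <- file.path(outdir, "config_resolved.yaml")
  atomic_write(function(p) write_config(config, p), cfg_path)
  inputs <- unlist(config$paths, use.names = TRUE)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    tool = "tapecall",
    version = as.character(utils::packageVersion("tapecall")),
    config_hash = unname(tools::md5sum(cfg_path)),
    input_checksums = as.list(tools::md5sum(unname(inputs))),
    record_counts = counts)
  prev <- file.path(outdir, "manifest.yaml")
  old_counts <- if (file.exists(prev)) {
    yaml::read_yaml(prev)$record_counts
  } else NULL
  if (!is.null(old_counts)) {
    manifest$record_counts <- utils::modifyList(old_counts, counts)
  }
  atomic_write(function(p) yaml::write_yaml(manifest, p), prev)
  invisible(manifest)
}

run_stage_tapes <- function(config, outdir) {
  p <- config$paths
  require_inputs(p[c("peaks", "gtf", "ncrna", "chrom_sizes",
                     "sample_info", "coverage")])
  sizes <- read_chrom_sizes(p$chrom_sizes)
  peaks <- lapply(p$peaks, read_peaks_file)
  genes <- read_gtf_genes(p$gtf)
  ncrna <- read_bed(p$ncrna)
  covs <- load_coverage(p$coverage, sizes)
  pre <- preprocess_peaks(peaks, config$merge_gap, config$min_peak_len)
  rocs <- build_rocs(pre$additive, sizes, config$roc_flank,
                     config$roc_expansion)
  pooled <- pool_tracks(unlist(lapply(covs, function(sc)
    list(sc$fwd, sc$rev)), recursive = FALSE))
  blocks <- find_transcribed_blocks(pooled, config$block_min_cov,
                                    config$block_min_len,
                                    config$block_merge_gap)
  coding <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  irocs <- filter_intergenic(rocs, coding, ncrna, blocks,
                             config$min_gene_dist, config$gene_anchor)
  ts <- call_tapes(irocs, covs, config$bidir_lower, config$bidir_upper,
                   config$min_total_signal, config$bidir_inclusive)
  tp <- tapes(ts)
  stage_log("call-tapes", sprintf(
    "peaks=%d ROCs=%d iROCs=%d TAPEs=%d",
    nrow(pre$additive), nrow(rocs), nrow(irocs), nrow(tp)))
  atomic_write(function(f) {
    x <- rocs; x$name <- x$roc_id
    write_bed(x, f)
  }, file.path(outdir, "rocs.bed"))
  atomic_write(function(f) {
    x <- irocs; x$name <- x$roc_id
    write_bed(x, f)
  }, file.path(outdir, "irocs.bed"))
  atomic_write(function(f) {
    x <- tp; x$name <- x$tape_id; x$score <- round(1000 * x$f)
    write_bed(x, f)
  }, file.path(outdir, "tapes.bed"))
  atomic_write(function(f) {
    utils::write.table(
      tp[, c("tape_id", "chrom", "start", "end", "center", "fwd", "rev",
             "f", "flag")],
      f, sep = "\t", quote = FALSE, row.names = FALSE)
  }, file.path(outdir, "tapes.tsv"))
  atomic_write(function(f) write_matrix_tsv(attr(tp, "counts"), f,
                                            "tape_id"),
               file.path(outdir, "tape_counts.tsv"))
  list(peaks = nrow(pre$additive), rocs = nrow(rocs),
       irocs = nrow(irocs), tapes = nrow(tp))
}

# quantify gene counts per sample from the coverage tracks
quantify_genes <- function(genes, covs) {
  m <- matrix(0, nrow(genes), length(covs),
              dimnames = list(genes$gene_id, names(covs)))
  for (j in seq_along(covs)) {
    m[, j] <- signal_in_intervals(covs[[j]]$fwd, genes) +
      signal_in_intervals(covs[[j]]$rev, genes)
  }
  m
}

read_tapes_tsv <- function(outdir) {
  f <- file.path(outdir, "tapes.tsv")
  if (!file.exists(f)) {
    stop("missing ", f, "; run the call-tapes stage first")
  }
  utils::read.delim(f, stringsAsFactors = FALSE)
}

run_stage_pair <- function(config, outdir) {
  p <- config$paths
  require_inputs(p[c("gtf", "chrom_sizes", "sample_info", "coverage")])
  tp <- read_tapes_tsv(outdir)
  tape_counts <- read_matrix_tsv(file.path(outdir, "tape_counts.tsv"))
  sizes <- read_chrom_sizes(p$chrom_sizes)
  genes <- read_gtf_genes(p$gtf)
  si <- read_sample_info(p$sample_info)
  covs <- load_coverage(p$coverage, sizes)
  gene_counts <- quantify_genes(genes, covs)
  counts <- rbind(tape_counts, gene_counts[, colnames(tape_counts),
                                           drop = FALSE])
  lib <- colSums(counts)
  lens <- c(tp$end - tp$start,
            genes$end - genes$start)
  expr <- cpkm(counts, lens, lib)
  pairs0 <- candidate_pairs(tp, genes, config$pairing_window)
  pairs <- correlate_pairs(pairs0, expr, si, config$r_high,
                           config$global_treatments)
  hc <- pairs[pairs$high_confidence, , drop = FALSE]
  rk <- rank_position_summary(hc)
  db <- distance_correlation_summary(pairs, config$distance_bin,
                                     config$pairing_window)
  stage_log("pair", sprintf(
    "candidates=%d scored=%d high_confidence=%d rank1_fraction=%.3f",
    nrow(pairs0), nrow(pairs), nrow(hc), rk$fraction_rank1))
  atomic_write(function(f) utils::write.table(
    pairs, f, sep = "\t", quote = FALSE, row.names = FALSE),
    file.path(outdir, "pairs.tsv"))
  atomic_write(function(f) utils::write.table(
    rk$rank_counts, f, sep = "\t", quote = FALSE, row.names = FALSE),
    file.path(outdir, "rank_summary.tsv"))
  atomic_write(function(f) utils::write.table(
    db$bins, f, sep = "\t", quote = FALSE, row.names = FALSE),
    file.path(outdir, "distance_bins.tsv"))
  list(candidate_pairs = nrow(pairs0), scored_pairs = nrow(pairs),
       high_confidence = nrow(hc))
}

run_stage_diff <- function(config, outdir) {
  p <- config$paths
  require_inputs(p[c("sample_info")])
  tape_counts <- round(read_matrix_tsv(file.path(outdir,
                                                 "tape_counts.tsv")))
  si <- read_sample_info(p$sample_info)
  si <- si[match(colnames(tape_counts), si$sample_id), ]
  rs <- region_selective(tape_counts, si$region, config$q_threshold,
                         config$z_margin)
  act <- activity_dependent(tape_counts, si, config$q_threshold)
  pairs_f <- file.path(outdir, "pairs.tsv")
  lr <- NULL
  if (file.exists(pairs_f) && !is.null(p$rna_counts) &&
      file.exists(p$rna_counts)) {
    pairs <- utils::read.delim(pairs_f, stringsAsFactors = FALSE)
    rna <- round(read_matrix_tsv(p$rna_counts))
    trt <- factor(si$treatment, levels = c("Veh", "KCl"))
    gene_ids <- unique(pairs$gene_id)
    gene_ids <- intersect(gene_ids, rownames(rna))
    gene_de <- nb_test(rna[gene_ids, si$sample_id, drop = FALSE], trt,
                       mode = "wald")
    gene_lfc <- stats::setNames(gene_de$log2fc, gene_de$feature_id)
    tape_lfc <- prom_lfc <- NULL
    if (!is.null(p$atac_counts) && file.exists(p$atac_counts)) {
      atac <- round(read_matrix_tsv(p$atac_counts))
      atac_de <- nb_test(atac[, si$sample_id, drop = FALSE], trt,
                         mode = "wald")
      alfc <- stats::setNames(atac_de$log2fc, atac_de$feature_id)
      # translate planted-element ATAC features to TAPE ids by position
      tp <- read_tapes_tsv(outdir)
      if (!is.null(p$truth) && file.exists(p$truth)) {
        truth <- utils::read.delim(p$truth, stringsAsFactors = FALSE)
        hit <- vapply(seq_len(nrow(truth)), function(i) {
          j <- which(tp$chrom == truth$chrom[i] &
                       tp$start <= truth$center[i] &
                       tp$end > truth$center[i])
          if (length(j)) tp$tape_id[j[1]] else NA_character_
        }, "")
        ok <- !is.na(hit) & truth$id %in% names(alfc)
        tape_lfc <- stats::setNames(alfc[truth$id[ok]], hit[ok])
        pn <- paste0("prom_", gene_ids)
        pn <- pn[pn %in% names(alfc)]
        prom_lfc <- stats::setNames(alfc[pn], sub("^prom_", "", pn))
      }
    }
    lr <- linked_response_summary(act$significant, pairs, gene_lfc,
                                  tape_lfc, prom_lfc)
    atomic_write(function(f) utils::write.table(
      lr, f, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(outdir, "linked_response.tsv"))
  }
  stage_log("diff", sprintf(
    "region_selective=%d (assigned=%d) activity=%d",
    nrow(rs$assignment), sum(!is.na(rs$assignment$region)),
    length(act$union)))
  atomic_write(function(f) utils::write.table(
    rs$assignment, f, sep = "\t", quote = FALSE, row.names = FALSE),
    file.path(outdir, "region_selective.tsv"))
  atomic_write(function(f) utils::write.table(
    act$significant, f, sep = "\t", quote = FALSE, row.names = FALSE),
    file.path(outdir, "activity_tapes.tsv"))
  list(region_selective = nrow(rs$assignment),
       region_assigned = sum(!is.na(rs$assignment$region)),
       activity_tapes = length(act$union))
}

run_stage_profile <- function(config, outdir) {
  p <- config$paths
  require_inputs(p["peaks"])
  tp <- read_tapes_tsv(outdir)
  peaks <- do.call(rbind, lapply(p$peaks, function(f) {
    read_peaks_file(f)[, c("chrom", "start", "end", "strand")]
  }))
  prof <- metaprofile(peaks, tp, config$profile_window,
                      config$profile_bin)
  stage_log("profile", sprintf("features=%d centers=%d", nrow(peaks),
                               nrow(tp)))
  atomic_write(function(f) utils::write.table(
    prof, f, sep = "\t", quote = FALSE, row.names = FALSE),
    file.path(outdir, "profile.tsv"))
  list(profile_features = nrow(peaks))
}

run_stage_evaluate <- function(config, outdir) {
  p <- config$paths
  if (is.null(p$truth) || !file.exists(p$truth)) {
    stop("evaluate stage needs paths$truth")
  }
  truth <- utils::read.delim(p$truth, stringsAsFactors = FALSE)
  tp <- read_tapes_tsv(outdir)
  ts <- tp
  ts$bidirectional <- TRUE
  ts$tape_id <- tp$tape_id
  outputs <- list(tape_set = ts)
  pf <- file.path(outdir, "pairs.tsv")
  if (file.exists(pf)) {
    outputs$pairs <- utils::read.delim(pf, stringsAsFactors = FALSE)
  }
  rf <- file.path(outdir, "region_selective.tsv")
  if (file.exists(rf)) {
    outputs$assignment <- utils::read.delim(rf, stringsAsFactors = FALSE)
  }
  af <- file.path(outdir, "activity_tapes.tsv")
  if (file.exists(af)) {
    sig <- utils::read.delim(af, stringsAsFactors = FALSE)
    outputs$activity <- list(significant = sig,
                             union = unique(sig$feature_id))
  }
  metrics <- evaluate_recovery(outputs, truth)
  stage_log("evaluate", sprintf(
    "sensitivity=%.3f specificity=%.3f",
    metrics$sensitivity, metrics$specificity))
  atomic_write(function(f) jsonlite::write_json(metrics, f,
                                                auto_unbox = TRUE,
                                                digits = NA),
               file.path(outdir, "metrics.json"))
  list(evaluated = 1)
}
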