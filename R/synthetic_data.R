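# Seeded synthetic fixture generator with planted ground truth. The
# generator emulates the statistical structure the pipeline assumes: a
# small annotated genome; intergenic enhancers emitting bidirectional RNA
# whose latent activity is correlated (Gaussian copula on the log scale)
# with a linked gene; unidirectional and silent decoys; strongly
# transcribed unannotated regions for the contiguous-transcription filter;
# NB replicate noise; region-selective and depolarisation-responsive
# effects. Every quantity is drawn under the config seed, so identical
# configs give byte-identical fixture files.

#' Simulation configuration
#'
#' Defaults define the packaged study conditions: 3 chromosomes of 2 Mb, 60
#' genes, 40 planted enhancers (12 region-selective, 9 KCl-up, 3 KCl-down,
#' 16 plain), 20 unidirectional decoys, 15 silent accessible sites, 5
#' unannotated transcripts, and 3 regions x 2 treatments x 4 replicates.
#'
#' @param seed integer seed (mandatory; all stages derive their streams
#'   from it).
#' @param chrom_sizes named chromosome lengths (bp).
#' @param n_genes,n_ncrna,n_enhancers,n_decoys,n_inert,n_unannot element
#'   counts.
#' @param n_region_selective enhancers planted region-selective (split
#'   evenly across regions).
#' @param n_kcl_up,n_kcl_down enhancers planted KCl-responsive.
#' @param regions,treatments,replicates experimental design.
#' @param nb_dispersion NB dispersion of replicate counts.
#' @param r_true generative enhancer-gene log-scale correlation.
#' @param f_range planted forward-fraction range for true enhancers.
#' @param sigma_batch SD of the latent log expression shared by the
#'   vehicle/KCl sister cultures of one region x replicate batch; it
#'   carries enhancer-gene correlation (shared with the linked gene at
#'   \code{r_true}) but cancels exactly in the treatment contrast, the
#'   way split-batch designs behave.
#' @param sigma_rep SD of the fully independent per-sample latent; also
#'   shared with the linked gene at \code{r_true}. Together with
#'   \code{sigma_batch} this sets the cross-sample variation the
#'   correlation stage exploits; alone it sets the replicate noise the
#'   treatment contrasts must overcome.
#' @param sigma_cell optional SD of a latent component shared by all
#'   replicates of a region x treatment cell (default 0). Nonzero values
#'   lower the effective sample size of the correlation stage.
#' @param enhancer_mean,gene_mean,unannot_mean,atac_mean mean counts per
#'   sample.
#' @param region_fold,kcl_fold planted effect sizes (fold change).
#' @param gene_effect_share fraction (log scale) of a planted enhancer
#'   effect inherited by its linked gene.
#' @param atac_kcl_log2fc planted ATAC log2 shift at KCl-responsive TAPEs
#'   and their linked promoters (negative: accessibility drops on
#'   depolarisation).
#' @param margin minimum bp between any two planted elements.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed,
                       chrom_sizes = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                       n_genes = 60, n_ncrna = 12, n_enhancers = 40,
                       n_decoys = 20, n_inert = 15, n_unannot = 5,
                       n_region_selective = 12, n_kcl_up = 9,
                       n_kcl_down = 3,
                       regions = c("cortex", "hippocampus", "striatum"),
                       treatments = c("Veh", "KCl"), replicates = 4,
                       nb_dispersion = 0.02, r_true = 0.8,
                       f_range = c(0.3, 0.7), sigma_cell = 0,
                       sigma_batch = 0.35, sigma_rep = 0.28,
                       enhancer_mean = 12, gene_mean = 1000,
                       unannot_mean = 3000, atac_mean = 500,
                       region_fold = 8, kcl_fold = 4,
                       gene_effect_share = 0.25, atac_kcl_log2fc = -0.4,
                       margin = 3000) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_region_selective + n_kcl_up + n_kcl_down > n_enhancers) {
    stop("planted effect counts exceed n_enhancers")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# place n elements of given widths on [0, L) with pairwise gaps >= margin
place_on_chrom <- function(widths, L, margin) {
  n <- length(widths)
  slack <- L - sum(widths) - (n + 1) * margin
  if (slack < 0) stop("infeasible packing: elements do not fit with margin")
  cuts <- c(0, sort(stats::runif(n)), 1)
  extra <- diff(cuts) * slack
  starts <- numeric(n)
  pos <- 0
  for (i in seq_len(n)) {
    pos <- pos + margin + extra[i]
    starts[i] <- floor(pos)
    pos <- pos + widths[i]
  }
  starts
}

# lay out all planted elements; deterministic under cfg$seed
sim_layout <- function(cfg) {
  set.seed(cfg$seed)
  classes <- c(rep("gene", cfg$n_genes), rep("ncrna", cfg$n_ncrna),
               rep("enhancer", cfg$n_enhancers),
               rep("decoy", cfg$n_decoys), rep("inert", cfg$n_inert),
               rep("unannot", cfg$n_unannot))
  widths <- numeric(length(classes))
  widths[classes == "gene"] <- round(stats::runif(cfg$n_genes, 3000, 8000))
  widths[classes == "ncrna"] <- round(stats::runif(cfg$n_ncrna, 100, 300))
  widths[classes == "enhancer"] <- round(stats::runif(cfg$n_enhancers,
                                                      250, 450))
  widths[classes == "decoy"] <- round(stats::runif(cfg$n_decoys, 250, 450))
  widths[classes == "inert"] <- round(stats::runif(cfg$n_inert, 250, 450))
  widths[classes == "unannot"] <- round(stats::runif(cfg$n_unannot,
                                                     1500, 2500))
  # shuffle, then deal to chromosomes proportionally to length
  ord <- sample(length(classes))
  classes <- classes[ord]; widths <- widths[ord]
  chrom_of <- rep(names(cfg$chrom_sizes), length.out = length(classes))
  out <- NULL
  for (ch in names(cfg$chrom_sizes)) {
    sel <- which(chrom_of == ch)
    if (length(sel) == 0) next
    starts <- place_on_chrom(widths[sel], cfg$chrom_sizes[[ch]],
                             cfg$margin)
    out <- rbind(out, data.frame(
      chrom = ch, start = starts, end = starts + widths[sel],
      class = classes[sel], stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$strand <- sample(c("+", "-"), nrow(out), replace = TRUE)
  out$id <- NA_character_
  for (cl in unique(out$class)) {
    k <- which(out$class == cl)
    out$id[k] <- sprintf("%s%03d", toupper(substr(cl, 1, 3)), seq_along(k))
  }
  out$center <- floor((out$start + out$end) / 2)
  rownames(out) <- NULL
  out
}

#' Simulate the genome annotation
#'
#' Writes \code{genes.gtf} (gene lines, 1-based), \code{ncrna.bed} and
#' \code{chrom.sizes} under \code{dir}, all deterministic under the config
#' seed, and returns the full element layout (genes, ncRNAs, enhancers,
#' decoys, silent sites, unannotated transcripts) used by the later stages.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with \code{layout}, \code{genes} (gene
#'   models) and the written \code{paths}.
#' @export
simulate_annotation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layout <- sim_layout(cfg)
  gl <- layout[layout$class == "gene", ]
  genes <- gene_models(gl$id, gl$chrom, gl$start, gl$end, gl$strand)
  nc <- layout[layout$class == "ncrna", ]
  ncrna <- genomic_intervals(nc$chrom, nc$start, nc$end, nc$strand,
                             name = nc$id)
  paths <- list(gtf = file.path(dir, "genes.gtf"),
                ncrna = file.path(dir, "ncrna.bed"),
                chrom_sizes = file.path(dir, "chrom.sizes"))
  write_gtf_genes(genes, paths$gtf)
  write_bed(ncrna, paths$ncrna)
  write_chrom_sizes(unlist(cfg$chrom_sizes), paths$chrom_sizes)
  invisible(list(layout = layout, genes = genes, ncrna = ncrna,
                 paths = paths))
}

#' Build the planted truth table
#'
#' Assigns each planted enhancer a forward fraction, a linked gene (the
#' nearest-window random partner, generative correlation \code{r_true}),
#' and a region-selectivity or KCl-response label; decoys get extreme
#' forward fractions; silent sites and unannotated transcripts are recorded
#' as negatives.
#'
#' @param cfg a [sim_config()].
#' @param ann result of [simulate_annotation()].
#' @return truth data.frame, one row per planted element.
#' @export
build_truth <- function(cfg, ann) {
  set.seed(cfg$seed + 1L)
  lay <- ann$layout
  genes <- ann$genes
  el <- lay[lay$class %in% c("enhancer", "decoy", "inert", "unannot"), ]
  truth <- data.frame(
    id = el$id, class = el$class, chrom = el$chrom, start = el$start,
    end = el$end, center = el$center, f_true = NA_real_,
    linked_gene = NA_character_, r_true = 0, region_label = "none",
    kcl_log2fc = 0, stringsAsFactors = FALSE)
  enh <- which(truth$class == "enhancer")
  truth$f_true[enh] <- stats::runif(length(enh), cfg$f_range[1],
                                    cfg$f_range[2])
  dec <- which(truth$class == "decoy")
  truth$f_true[dec] <- sample(c(0.01, 0.99), length(dec), replace = TRUE)
  una <- which(truth$class == "unannot")
  truth$f_true[una] <- sample(c(0.01, 0.99), length(una), replace = TRUE)
  # linked genes: uniform pick among genes within 0.9 Mb of the center,
  # preferring genes not yet linked so each partner is distinct
  used <- character(0)
  for (i in enh) {
    cand <- genes[genes$chrom == truth$chrom[i] &
                    abs(genes$tss - truth$center[i]) <= 9e5, ]
    fresh <- cand[!cand$gene_id %in% used, ]
    if (nrow(fresh) > 0) cand <- fresh
    if (nrow(cand) > 0) {
      pick <- if (nrow(cand) == 1) cand$gene_id else
        sample(cand$gene_id, 1)
      truth$linked_gene[i] <- pick
      truth$r_true[i] <- cfg$r_true
      used <- c(used, pick)
    }
  }
  # planted effects: disjoint subsets of enhancers, in layout order
  stopifnot(cfg$n_region_selective %% length(cfg$regions) == 0)
  pool <- sample(enh)   # random but seeded assignment
  rs <- pool[seq_len(cfg$n_region_selective)]
  truth$region_label[rs] <- rep(cfg$regions,
                                length.out = length(rs))
  kc <- pool[cfg$n_region_selective +
               seq_len(cfg$n_kcl_up + cfg$n_kcl_down)]
  truth$kcl_log2fc[kc] <- c(rep(log2(cfg$kcl_fold), cfg$n_kcl_up),
                            rep(-log2(cfg$kcl_fold), cfg$n_kcl_down))
  truth
}

sim_samples <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      treatment = cfg$treatments, region = cfg$regions,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("region", "treatment", "replicate")]
  grid$sample_id <- sprintf("%s_%s_%d", grid$region, grid$treatment,
                            grid$replicate)
  grid
}

# per-element, per-sample multiplier encoding planted effects
effect_multiplier <- function(truth_row, samples, cfg, share = 1) {
  mult <- rep(1, nrow(samples))
  if (truth_row$region_label != "none") {
    # geometrically centred fold-change: selected region is boosted
    # fold^(2/3), the others suppressed fold^(-1/3), preserving the
    # planted contrast while keeping off-region signal quantifiable
    on <- samples$region == truth_row$region_label
    mult[on] <- mult[on] * cfg$region_fold^(2 / 3 * share)
    mult[!on] <- mult[!on] / cfg$region_fold^(1 / 3 * share)
  }
  if (truth_row$kcl_log2fc != 0) {
    kcl <- samples$treatment == "KCl"
    mult[kcl] <- mult[kcl] * 2^(truth_row$kcl_log2fc * share)
  }
  mult
}

#' Simulate stranded transcription, ATAC peaks and count matrices
#'
#' Per sample, gene bodies emit coverage on their annotated strand
#' proportional to a latent log-normal expression value; planted enhancers
#' emit coverage on both strands split at their true forward fraction, with
#' the latent value correlated at \code{r_true} with the linked gene's
#' latent (Gaussian copula on the log scale); decoys emit unidirectional
#' signal and silent sites none. Replicate counts are negative binomial.
#' ATAC peaks are written per region at every planted accessible element,
#' and ATAC counts (peaks and gene promoters) carry the planted
#' depolarisation shift.
#'
#' @param cfg a [sim_config()].
#' @param ann result of [simulate_annotation()].
#' @param truth truth table from [build_truth()].
#' @param dir output directory.
#' @return invisibly, list of written paths plus in-memory matrices.
#' @export
simulate_transcription <- function(cfg, ann, truth, dir) {
  set.seed(cfg$seed + 2L)
  dir.create(file.path(dir, "coverage"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  samples <- sim_samples(cfg)
  S <- nrow(samples)
  genes <- ann$genes
  sizes <- unlist(cfg$chrom_sizes)
  sc <- cfg$sigma_cell
  sb <- cfg$sigma_batch
  sr <- cfg$sigma_rep
  adj <- exp(-(sc^2 + sb^2 + sr^2) / 2)  # keep the mean at nominal count
  cell <- interaction(samples$region, samples$treatment, drop = TRUE)
  ncell <- nlevels(cell)
  cell_i <- as.integer(cell)
  batch <- interaction(samples$region, samples$replicate, drop = TRUE)
  nbatch <- nlevels(batch)
  batch_i <- as.integer(batch)

  # latent log expression = optional cell component + batch component
  # (shared by the Veh/KCl sister cultures of one region x replicate)
  # + independent per-sample residual; an enhancer shares every
  # component with its linked gene via a Gaussian copula
  draw_latent <- function() {
    list(cell = stats::rnorm(ncell), batch = stats::rnorm(nbatch),
         samp = stats::rnorm(S))
  }
  mix <- function(a, b, r) {
    list(cell = r * a$cell + sqrt(1 - r^2) * b$cell,
         batch = r * a$batch + sqrt(1 - r^2) * b$batch,
         samp = r * a$samp + sqrt(1 - r^2) * b$samp)
  }
  latent_log <- function(l) {
    sc * l$cell[cell_i] + sb * l$batch[batch_i] + sr * l$samp
  }

  enh <- truth[truth$class == "enhancer", ]
  lat_enh <- lapply(seq_len(nrow(enh)), function(i) draw_latent())
  lat_gene <- lapply(seq_len(nrow(genes)), function(i) draw_latent())
  for (i in seq_len(nrow(enh))) {
    if (!is.na(enh$linked_gene[i])) {
      gi <- match(enh$linked_gene[i], genes$gene_id)
      lat_gene[[gi]] <- mix(lat_enh[[i]], lat_gene[[gi]], enh$r_true[i])
    }
  }
  z_enh <- t(vapply(lat_enh, latent_log, numeric(S)))
  z_gene <- t(vapply(lat_gene, latent_log, numeric(S)))
  if (nrow(enh) == 1) z_enh <- matrix(z_enh, 1)
  if (nrow(genes) == 1) z_gene <- matrix(z_gene, 1)

  nb <- function(mu) stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$nb_dispersion)

  # enhancer counts and strand split
  enh_counts <- matrix(0, nrow(enh), S,
                       dimnames = list(enh$id, samples$sample_id))
  enh_fwd <- enh_counts
  for (i in seq_len(nrow(enh))) {
    mult <- effect_multiplier(enh[i, ], samples, cfg)
    mu <- cfg$enhancer_mean * mult * exp(z_enh[i, ]) * adj
    tot <- nb(mu)
    enh_counts[i, ] <- tot
    enh_fwd[i, ] <- stats::rbinom(S, size = tot, prob = enh$f_true[i])
  }

  # gene counts (linked genes inherit a share of the planted effects)
  gene_counts <- matrix(0, nrow(genes), S,
                        dimnames = list(genes$gene_id, samples$sample_id))
  share_of <- stats::setNames(rep(NA_integer_, nrow(genes)),
                              genes$gene_id)
  share_of[stats::na.omit(enh$linked_gene)] <-
    which(!is.na(enh$linked_gene))
  for (gi in seq_len(nrow(genes))) {
    mult <- rep(1, S)
    ei <- share_of[genes$gene_id[gi]]
    if (!is.na(ei)) {
      mult <- effect_multiplier(enh[ei, ], samples, cfg,
                                share = cfg$gene_effect_share)
    }
    mu <- cfg$gene_mean * mult * exp(z_gene[gi, ]) * adj
    gene_counts[gi, ] <- nb(mu)
  }

  # decoys and unannotated transcripts: unidirectional
  dec <- truth[truth$class %in% c("decoy", "unannot"), ]
  dec_counts <- matrix(0, nrow(dec), S,
                       dimnames = list(dec$id, samples$sample_id))
  dec_fwd <- dec_counts
  for (i in seq_len(nrow(dec))) {
    base <- if (dec$class[i] == "unannot") cfg$unannot_mean else
      cfg$enhancer_mean
    mu <- base * exp(latent_log(draw_latent())) * adj
    tot <- nb(mu)
    dec_counts[i, ] <- tot
    dec_fwd[i, ] <- stats::rbinom(S, size = tot, prob = dec$f_true[i])
  }

  # coverage tracks per sample: uniform density over the emission window
  emit_window <- function(tr) {
    data.frame(chrom = tr$chrom, start = pmax(tr$center - 500, 0),
               end = pmin(tr$center + 500, sizes[tr$chrom]),
               stringsAsFactors = FALSE)
  }
  enh_win <- emit_window(enh)
  dec_win <- data.frame(chrom = dec$chrom, start = dec$start,
                        end = dec$end)
  cov_paths <- list()
  for (s in seq_len(S)) {
    sid <- samples$sample_id[s]
    seg <- function(win, val) {
      data.frame(chrom = win$chrom, start = win$start, end = win$end,
                 value = val / (win$end - win$start))
    }
    fwd_segs <- rbind(
      seg(enh_win, enh_fwd[, s]),
      seg(dec_win, dec_fwd[, s]),
      seg(genes[genes$strand == "+", c("chrom", "start", "end")],
          gene_counts[genes$strand == "+", s]))
    rev_segs <- rbind(
      seg(enh_win, enh_counts[, s] - enh_fwd[, s]),
      seg(dec_win, dec_counts[, s] - dec_fwd[, s]),
      seg(genes[genes$strand == "-", c("chrom", "start", "end")],
          gene_counts[genes$strand == "-", s]))
    fp <- file.path(dir, "coverage", paste0(sid, "_fwd.bedGraph"))
    rp <- file.path(dir, "coverage", paste0(sid, "_rev.bedGraph"))
    write_bedgraph(coverage_track(fwd_segs, sizes), fp)
    write_bedgraph(coverage_track(rev_segs, sizes), rp)
    cov_paths[[sid]] <- c(fwd = fp, rev = rp)
  }

  # ATAC peaks per region: every accessible element, +/-20 bp jitter
  acc <- truth   # all planted elements are accessible
  peak_paths <- list()
  for (rg in cfg$regions) {
    jit <- round(stats::runif(nrow(acc), -20, 20))
    pk <- genomic_intervals(acc$chrom, pmax(acc$start + jit, 0),
                            acc$end + jit, name = acc$id)
    pk$score <- 100
    np <- file.path(dir, "peaks", paste0(rg, ".narrowPeak"))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.2f\t%.2f\t%.2f\t%d",
                     pk$chrom, as.integer(pk$start), as.integer(pk$end),
                     paste0(rg, "_", pk$name), as.integer(pk$score),
                     5.0, 10.0, 8.0,
                     as.integer(floor((pk$end - pk$start) / 2)))
    writeLines(lines, np)
    peak_paths[[rg]] <- np
  }

  # ATAC counts at peaks and promoters, with planted KCl accessibility
  # shift at KCl-responsive enhancers and their linked promoters
  kcl_lfc <- stats::setNames(rep(0, nrow(acc)), acc$id)
  kcl_lfc[acc$class == "enhancer" & acc$kcl_log2fc != 0] <-
    cfg$atac_kcl_log2fc
  prom_lfc <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  up_linked <- acc$linked_gene[acc$class == "enhancer" &
                                 acc$kcl_log2fc > 0]
  prom_lfc[stats::na.omit(up_linked)] <- cfg$atac_kcl_log2fc
  atac_ids <- c(acc$id, paste0("prom_", genes$gene_id))
  atac_lfc <- c(kcl_lfc, stats::setNames(prom_lfc,
                                         paste0("prom_", genes$gene_id)))
  atac_counts <- matrix(0, length(atac_ids), S,
                        dimnames = list(atac_ids, samples$sample_id))
  kcl_col <- samples$treatment == "KCl"
  for (i in seq_along(atac_ids)) {
    mult <- rep(1, S)
    mult[kcl_col] <- 2^atac_lfc[i]
    mu <- cfg$atac_mean * mult * exp(0.3 * stats::rnorm(S)) * exp(-0.045)
    atac_counts[i, ] <- nb(mu)
  }

  rna_counts <- rbind(enh_counts, dec_counts, gene_counts)
  paths <- list(
    rna_counts = file.path(dir, "rna_counts.tsv"),
    atac_counts = file.path(dir, "atac_counts.tsv"),
    sample_info = file.path(dir, "sample_info.tsv"),
    truth = file.path(dir, "truth.tsv"),
    coverage = cov_paths, peaks = peak_paths)
  write_matrix_tsv(rna_counts, paths$rna_counts)
  write_matrix_tsv(atac_counts, paths$atac_counts)
  write_sample_info(samples, paths$sample_info)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, samples = samples,
                 rna_counts = rna_counts, atac_counts = atac_counts))
}

#' Generate the complete packaged fixture
#'
#' Runs [simulate_annotation()], [build_truth()] and
#' [simulate_transcription()] under one config and returns everything the
#' pipeline needs.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @return list with \code{ann}, \code{truth}, \code{tx} (transcription
#'   outputs) and \code{dir}.
#' @export
simulate_fixture <- function(cfg, dir) {
  ann <- simulate_annotation(cfg, dir)
  truth <- build_truth(cfg, ann)
  tx <- simulate_transcription(cfg, ann, truth, dir)
  list(ann = ann, truth = truth, tx = tx, dir = dir)
}

#' Score pipeline outputs against the planted truth
#'
#' @param outputs list with elements \code{tape_set} (from [call_tapes()]),
#'   and optionally \code{pairs} (scored pairs), \code{assignment} (from
#'   [region_selective()]) and \code{activity} (from
#'   [activity_dependent()]). TAPEs are matched to planted elements by
#'   their planted center falling inside the TAPE interval.
#' @param truth truth table from [build_truth()].
#' @return list of recovery metrics: TAPE \code{sensitivity} and
#'   \code{specificity}; \code{top1_recovery} among high-confidence TAPEs
#'   with a planted link; per-region and macro \code{region_f1};
#'   \code{activity_precision}/\code{activity_recall}.
#' @export
evaluate_recovery <- function(outputs, truth) {
  ts <- outputs$tape_set
  tape_rows <- ts[ts$bidirectional, , drop = FALSE]
  # map planted elements to TAPE ids by center containment
  map_tape <- function(tr) {
    hit <- which(tape_rows$chrom == tr["chrom"] &
                   tape_rows$start <= as.numeric(tr["center"]) &
                   tape_rows$end > as.numeric(tr["center"]))
    if (length(hit)) tape_rows$tape_id[hit[1]] else NA_character_
  }
  truth$tape_id <- apply(truth[, c("chrom", "center")], 1, function(r)
    map_tape(c(chrom = r[["chrom"]], center = r[["center"]])))
  pos <- truth$class == "enhancer"
  neg <- !pos
  metrics <- list(
    sensitivity = mean(!is.na(truth$tape_id[pos])),
    specificity = mean(is.na(truth$tape_id[neg])),
    n_enhancers = sum(pos), n_negatives = sum(neg))

  if (!is.null(outputs$pairs)) {
    hc <- outputs$pairs[outputs$pairs$high_confidence, , drop = FALSE]
    best <- best_pair_per_tape(hc)
    linked <- truth[pos & !is.na(truth$linked_gene) &
                      !is.na(truth$tape_id), ]
    best_gene <- best$gene_id[match(linked$tape_id, best$tape_id)]
    scored <- !is.na(best_gene)
    metrics$top1_recovery <- if (any(scored))
      mean(best_gene[scored] == linked$linked_gene[scored]) else NA_real_
    metrics$n_high_confidence_linked <- sum(scored)
  }

  if (!is.null(outputs$assignment)) {
    asg <- outputs$assignment
    pred <- stats::setNames(asg$region, asg$feature_id)
    regions <- sort(unique(truth$region_label[truth$region_label != "none"]))
    f1s <- numeric(0)
    for (rg in regions) {
      truth_ids <- truth$tape_id[truth$region_label == rg &
                                   !is.na(truth$tape_id)]
      pred_ids <- names(pred)[!is.na(pred) & pred == rg]
      tp <- length(intersect(truth_ids, pred_ids))
      prec <- if (length(pred_ids)) tp / length(pred_ids) else NA
      rec <- if (length(truth_ids)) tp / length(truth_ids) else NA
      f1s[rg] <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
        2 * prec * rec / (prec + rec) else 0
    }
    metrics$region_f1 <- stats::setNames(as.numeric(f1s), regions)
    metrics$region_f1_macro <- if (length(f1s)) mean(f1s) else NA_real_
  }

  if (!is.null(outputs$activity)) {
    det <- outputs$activity$union
    truth_ids <- truth$tape_id[truth$kcl_log2fc != 0 &
                                 !is.na(truth$tape_id)]
    tp <- length(intersect(det, truth_ids))
    metrics$activity_recall <- if (length(truth_ids))
      tp / length(truth_ids) else NA_real_
    metrics$activity_precision <- if (length(det))
      tp / length(det) else NA_real_
  }
  metrics
}
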