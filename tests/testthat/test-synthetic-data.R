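small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, chrom_sizes = c(chr1 = 1e6, chr2 = 1e6),
             n_genes = 14, n_ncrna = 4, n_enhancers = 8, n_decoys = 4,
             n_inert = 3, n_unannot = 2, n_region_selective = 3,
             n_kcl_up = 2, n_kcl_down = 1, replicates = 2, ...)
}

test_that("simulated annotation packs non-overlapping elements", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 3, chrom_sizes = c(chr1 = 1e6), n_genes = 10,
                    n_ncrna = 2, n_enhancers = 4, n_decoys = 2,
                    n_inert = 2, n_unannot = 1, n_region_selective = 3,
                    n_kcl_up = 1, n_kcl_down = 0)
  ann <- simulate_annotation(cfg, d)
  expect_equal(nrow(ann$genes), 10)
  lay <- ann$layout[order(ann$layout$chrom, ann$layout$start), ]
  gaps <- lay$start[-1] - lay$end[-nrow(lay)]
  same <- lay$chrom[-1] == lay$chrom[-nrow(lay)]
  expect_true(all(gaps[same] >= cfg$margin))

  # packing that cannot fit errors out
  toobig <- sim_config(seed = 3, chrom_sizes = c(chr1 = 5e4),
                       n_genes = 20, n_enhancers = 0, n_decoys = 0,
                       n_inert = 0, n_unannot = 0, n_ncrna = 0,
                       n_region_selective = 0, n_kcl_up = 0,
                       n_kcl_down = 0)
  expect_error(simulate_annotation(toobig, withr::local_tempdir()),
               "infeasible")
})

test_that("random layouts never violate the spacing invariant", {
  set.seed(95)
  for (i in 1:25) {
    cfg <- sim_config(seed = sample.int(1e6, 1),
                      chrom_sizes = c(chr1 = 5e5, chr2 = 5e5),
                      n_genes = sample(5:12, 1), n_ncrna = sample(0:3, 1),
                      n_enhancers = sample(2:6, 1),
                      n_decoys = sample(0:4, 1), n_inert = sample(0:3, 1),
                      n_unannot = sample(0:2, 1), n_region_selective = 0,
                      n_kcl_up = 0, n_kcl_down = 0)
    lay <- tapecall:::sim_layout(cfg)
    lay <- lay[order(lay$chrom, lay$start), ]
    same <- lay$chrom[-1] == lay$chrom[-nrow(lay)]
    expect_true(all((lay$start[-1] - lay$end[-nrow(lay)])[same] > 0))
  }
})

test_that("identical configs give byte-identical fixture files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fx1 <- simulate_fixture(small_cfg(), d1)
  fx2 <- simulate_fixture(small_cfg(), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("deep coverage recovers the planted forward fraction", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(seed = 11, enhancer_mean = 2000, sigma_rep = 0.1)
  fx <- simulate_fixture(cfg, d)
  sizes <- unlist(cfg$chrom_sizes)
  enh <- fx$truth[fx$truth$class == "enhancer", ]
  covs <- lapply(fx$tx$paths$coverage, function(p)
    stranded_coverage(read_bedgraph(p[["fwd"]], sizes),
                      read_bedgraph(p[["rev"]], sizes)))
  iv <- genomic_intervals(enh$chrom, enh$center - 500, enh$center + 500)
  fwd <- rowSums(sapply(covs, function(sc) signal_in_intervals(sc$fwd, iv)))
  rev <- rowSums(sapply(covs, function(sc) signal_in_intervals(sc$rev, iv)))
  expect_true(all(abs(fwd / (fwd + rev) - enh$f_true) <= 0.03))
})

test_that("null pairs rarely exceed |r| = 0.6 and planted r converges", {
  set.seed(96)
  # null: independent features, n = 12 samples, 200 replicates
  exceed <- mean(replicate(200, {
    abs(stats::cor(stats::rnorm(12), stats::rnorm(12))) >= 0.6
  }))
  expect_lte(exceed, 0.05)

  # planted: near-noiseless config, many samples -> r close to r_true
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 13, chrom_sizes = c(chr1 = 1e6),
                    n_genes = 6, n_ncrna = 0, n_enhancers = 2,
                    n_decoys = 0, n_inert = 0, n_unannot = 0,
                    n_region_selective = 0, n_kcl_up = 0, n_kcl_down = 0,
                    replicates = 34, enhancer_mean = 5000,
                    nb_dispersion = 1e-4, sigma_batch = 0,
                    sigma_rep = 0.3)
  fx <- simulate_fixture(cfg, d)
  enh <- fx$truth[fx$truth$class == "enhancer" &
                    !is.na(fx$truth$linked_gene), ]
  cnt <- fx$tx$rna_counts
  for (i in seq_len(nrow(enh))) {
    r <- stats::cor(cnt[enh$id[i], ], cnt[enh$linked_gene[i], ])
    expect_lt(abs(r - cfg$r_true), 0.05)
  }
})

test_that("zero-depth config yields all-zero tracks and zero TAPEs", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(seed = 17, enhancer_mean = 0, gene_mean = 0,
                   unannot_mean = 0)
  fx <- simulate_fixture(cfg, d)
  sizes <- unlist(cfg$chrom_sizes)
  cov1 <- read_bedgraph(fx$tx$paths$coverage[[1]][["fwd"]], sizes)
  expect_equal(nrow(tapecall:::track_segments(cov1)), 0)
  enh <- fx$truth[fx$truth$class == "enhancer", ]
  iv <- genomic_intervals(enh$chrom, enh$center - 500, enh$center + 500)
  covs <- lapply(fx$tx$paths$coverage, function(p)
    stranded_coverage(read_bedgraph(p[["fwd"]], sizes),
                      read_bedgraph(p[["rev"]], sizes)))
  ts <- call_tapes(iv, covs)
  expect_equal(sum(ts$bidirectional), 0)
})

test_that("evaluate_recovery scores perfect and empty outputs correctly", {
  truth <- data.frame(
    id = c("E1", "E2", "D1"), class = c("enhancer", "enhancer", "decoy"),
    chrom = "chr1", start = c(1000, 5000, 9000),
    end = c(1400, 5400, 9400), center = c(1200, 5200, 9200),
    f_true = c(0.5, 0.5, 0.01), linked_gene = c("g1", "g2", NA),
    r_true = c(0.8, 0.8, 0), region_label = "none", kcl_log2fc = 0)
  ts <- data.frame(chrom = "chr1", start = c(700, 4700),
                   end = c(1700, 5700), bidirectional = TRUE,
                   tape_id = c("T1", "T2"))
  pairs <- data.frame(tape_id = c("T1", "T2"),
                      gene_id = c("g1", "g2"), distance = 1e4,
                      distance_rank = 1L, r_global = 0.9,
                      high_confidence = TRUE)
  m <- evaluate_recovery(list(tape_set = ts, pairs = pairs), truth)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$top1_recovery, 1)

  m0 <- evaluate_recovery(list(tape_set = ts[0, ]), truth)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 1)
})
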