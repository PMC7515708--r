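sizes2 <- c(chr1 = 50000)

test_that("preprocess_peaks merges within regions then unions across", {
  pk <- list(A = genomic_intervals("chr1", 0, 200),
             B = genomic_intervals("chr1", 150, 400))
  out <- preprocess_peaks(pk)
  expect_equal(iv_key(out$additive), "chr1:0-400")

  one <- list(A = genomic_intervals(c("chr1", "chr1"), c(0, 150),
                                    c(100, 300)))
  out <- preprocess_peaks(one, merge_gap = 1000, min_len = 146)
  expect_equal(iv_key(out$per_region$A), "chr1:0-300")

  expect_warning(res <- preprocess_peaks(list(A = empty_intervals())),
                 "no peaks")
  expect_equal(nrow(res$additive), 0)
})

test_that("additive peak set equals brute-force union on random regions", {
  set.seed(61)
  for (rep in 1:5) {
    pk <- lapply(1:3, function(i) random_intervals(8, max_pos = 20000))
    names(pk) <- c("cx", "hpc", "str")
    out <- preprocess_peaks(pk)
    surv <- do.call(rbind, lapply(pk, function(p)
      oracle_merge(p, 1000)))
    surv <- surv[surv$end - surv$start >= 146, , drop = FALSE]
    expect_equal(iv_key(out$additive), iv_key(oracle_merge(surv, 0)))
  }
})

test_that("build_rocs anchors fixed windows on peak centers and clips", {
  pk <- genomic_intervals("chr1", 1000, 1800)
  roc <- build_rocs(pk, sizes2)
  expect_equal(c(roc$start, roc$end), c(900, 1900))

  edge <- build_rocs(genomic_intervals("chr1", 0, 100), c(chr1 = 600))
  expect_equal(c(edge$start, edge$end), c(0, 550))

  alt <- build_rocs(pk, sizes2, expansion = "edges")
  expect_equal(c(alt$start, alt$end), c(500, 2300))

  off <- build_rocs(genomic_intervals(c("chr1", "chrUn"), c(1000, 1000),
                                      c(1800, 1800)), sizes2)
  expect_equal(nrow(off), 1)
  expect_equal(attr(off, "dropped_off_whitelist"), 1)
})

test_that("transcribed blocks: threshold runs, merge, strict length", {
  tr <- make_track("chr1", 1000, 1150, 3, sizes2)
  b <- find_transcribed_blocks(tr, min_cov = 1)
  expect_equal(iv_key(b), "chr1:1000-1150")

  two <- pool_tracks(list(make_track("chr1", 1000, 1060, 2, sizes2),
                          make_track("chr1", 1860, 1930, 2, sizes2)))
  b <- find_transcribed_blocks(two, min_cov = 1)
  expect_equal(iv_key(b), "chr1:1000-1930")  # gap 800 merged, length 930

  exact <- make_track("chr1", 1000, 1100, 5, sizes2)
  expect_equal(nrow(find_transcribed_blocks(exact, min_cov = 1)), 0)
})

test_that("filter_intergenic applies distance, ncRNA and block rules", {
  genes <- gene_models("g1", "chr1", 10000, 20000, "+")
  rocs <- build_rocs(genomic_intervals("chr1", c(8500, 30000, 40000),
                                       c(8900, 30400, 40400)), sizes2)
  # ROC centered at 8700: window (8200, 9200), 800 bp from gene -> removed
  ncr <- genomic_intervals("chr1", 40100, 40200)
  out <- filter_intergenic(rocs, genes, ncr)
  expect_equal(nrow(out), 1)
  expect_equal(out$center, 30200)

  blocks <- genomic_intervals("chr1", 30100, 30300)
  out2 <- filter_intergenic(rocs, genes, ncr, blocks)
  expect_equal(nrow(out2), 0)
  expect_error(filter_intergenic(rocs, genes[0, ]), "non-empty")
})

test_that("intergenic survivors match brute-force all-pairs checks", {
  set.seed(62)
  for (rep in 1:6) {
    ng <- 4
    gs <- sample.int(40000, ng)
    genes <- gene_models(sprintf("g%d", 1:ng), "chr1", gs - 1, gs + 2000,
                         sample(c("+", "-"), ng, replace = TRUE))
    rocs <- build_rocs(random_intervals(25, max_pos = 45000), sizes2)
    ncr <- random_intervals(3, max_pos = 45000, max_len = 200)
    blk <- random_intervals(3, max_pos = 45000, max_len = 2000)
    out <- filter_intergenic(rocs, genes, ncr, blk)
    for (i in seq_len(nrow(rocs))) {
      o <- oracle_nearest("chr1", rocs$start[i], rocs$end[i], genes)
      ovl <- function(s) any(s$start < rocs$end[i] & s$end > rocs$start[i])
      keep <- (abs(o$dist) > 1000) && !ovl(ncr) && !ovl(blk)
      expect_equal(rocs$roc_id[i] %in% out$roc_id, keep)
    }
  }
})

make_stranded <- function(fwd_val, rev_val, s = 1000, e = 2000,
                          sz = sizes2) {
  stranded_coverage(
    if (fwd_val > 0) make_track("chr1", s, e, fwd_val / (e - s), sz) else
      empty_track_for_tests(sz),
    if (rev_val > 0) make_track("chr1", s, e, rev_val / (e - s), sz) else
      empty_track_for_tests(sz))
}

test_that("call_tapes classifies by inclusive forward-fraction bounds", {
  iroc <- build_rocs(genomic_intervals("chr1", 1200, 1800), sizes2)
  f_of <- function(fwd, rev, ...) {
    ts <- call_tapes(iroc, list(s1 = make_stranded(fwd, rev)), ...)
    list(f = ts$f, bid = ts$bidirectional, flag = ts$flag)
  }
  expect_equal(f_of(50, 50)$f, 0.5, tolerance = 1e-9)
  expect_true(f_of(50, 50)$bid)
  r <- f_of(4, 96)
  expect_equal(r$f, 0.04, tolerance = 1e-9)
  expect_false(r$bid)
  r <- f_of(5, 95)
  expect_equal(r$f, 0.05, tolerance = 1e-9)
  expect_true(r$bid)                               # inclusive bounds
  expect_false(f_of(5, 95, inclusive = FALSE)$bid) # strict variant
  z <- f_of(0, 0, min_total_signal = 0)
  expect_false(z$bid)
  expect_equal(z$flag, "no signal")
  expect_false(f_of(3, 4)$bid)  # below min_total_signal = 10
})

test_that("strand swap maps f to 1 - f and preserves classification", {
  set.seed(63)
  iroc <- build_rocs(genomic_intervals("chr1", c(1200, 5200, 9200),
                                       c(1800, 5800, 9800)), sizes2)
  covs <- lapply(1:3, function(i) {
    s <- c(1200, 5200, 9200)[i]
    make_stranded(stats::runif(1, 0, 60), stats::runif(1, 0, 60),
                  s - 200, s + 800)
  })
  a <- call_tapes(iroc, covs)
  swapped <- lapply(covs, function(sc) stranded_coverage(sc$rev, sc$fwd))
  b <- call_tapes(iroc, swapped)
  ok <- !is.na(a$f)
  expect_equal(b$f[ok], 1 - a$f[ok], tolerance = 1e-9)
  expect_identical(a$bidirectional, b$bidirectional)
})

test_that("cascade counts never increase and empty coverage yields none", {
  set.seed(64)
  genes <- gene_models("g1", "chr1", 20000, 25000, "+")
  pk <- list(A = random_intervals(15, max_pos = 45000))
  pre <- preprocess_peaks(pk)
  rocs <- build_rocs(pre$additive, sizes2)
  irocs <- filter_intergenic(rocs, genes)
  ts <- call_tapes(irocs, list(s1 = make_stranded(0, 0)))
  expect_lte(nrow(irocs), nrow(rocs))
  expect_lte(sum(ts$bidirectional), nrow(irocs))
  expect_equal(sum(ts$bidirectional), 0)
})
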