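test_that("size factors recover known scaling and match DESeq2", {
  m <- matrix(c(10, 20, 5, 10, 20, 5), 3, 2,
              dimnames = list(NULL, c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 5), s2 = c(20, 40, 10))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  set.seed(81)
  nb <- matrix(stats::rnbinom(200 * 6, mu = 100, size = 10), 200, 6)
  true_sf <- c(0.5, 0.8, 1, 1.25, 1.6, 2)
  nb <- round(sweep(nb, 2, true_sf, "*"))
  colnames(nb) <- paste0("s", 1:6)
  sf <- size_factors(nb)
  ref <- DESeq2::estimateSizeFactorsForMatrix(nb)
  expect_equal(unname(sf / exp(mean(log(sf)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 0.05)

  zeroy <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(size_factors(zeroy), "pseudo_reference")
  expect_silent(size_factors(zeroy, pseudo_reference = TRUE))
})

test_that("nb_test is null on identical groups and sign-flips on relabel", {
  counts <- matrix(rep(c(40, 100, 7), each = 8), 3, 8, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), paste0("s", 1:8)))
  g <- rep(c("x", "y"), each = 4)
  res <- nb_test(counts, g, mode = "wald")
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-8)
  expect_true(all(res$p > 0.99))

  set.seed(82)
  counts <- matrix(stats::rnbinom(50 * 8, mu = 80, size = 10), 50, 8)
  colnames(counts) <- paste0("s", 1:8)
  a <- nb_test(counts, factor(g, levels = c("x", "y")), mode = "wald")
  b <- nb_test(counts, factor(g, levels = c("y", "x")), mode = "wald")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-6)

  expect_error(nb_test(counts, rep("x", 8)), "2 groups")
  expect_error(nb_test(counts[, 1:3], c("x", "x", "y")), "< 2 samples")
  expect_silent(nb_test(counts[, 1:3], c("x", "x", "y"),
                        pool_dispersion = TRUE))
})

test_that("nb_test detects a planted 4-fold change with high power", {
  set.seed(83)
  n <- 300
  mu <- matrix(100, n, 8)
  mu[, 5:8] <- 400
  counts <- matrix(stats::rnbinom(n * 8, mu = mu, size = 10), n, 8)
  colnames(counts) <- paste0("s", 1:8)
  res <- nb_test(counts, rep(c("veh", "kcl"), each = 4), mode = "wald",
                 sf = rep(1, 8))
  expect_gte(mean(res$q < 0.05, na.rm = TRUE), 0.9)
  expect_gt(stats::median(abs(res$log2fc)), 1.5)
})

test_that("bh_adjust reproduces the step-up adjustment", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(84)
  p <- stats::runif(1000)
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  perm <- sample(1000)
  expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
})

test_that("region z-scores and margin rules behave as documented", {
  # means [10, 1, 1] -> z = [1.1547, -0.5774, -0.5774]
  m <- c(10, 1, 1)
  z <- (m - mean(m)) / stats::sd(m)
  expect_equal(z, c(1.1547005, -0.5773503, -0.5773503), tolerance = 1e-6)

  set.seed(85)
  reg <- rep(c("cortex", "hippocampus", "striatum"), each = 4)
  mu <- matrix(50, 30, 12)
  mu[1:10, reg == "cortex"] <- 400         # cortex-selective block
  counts <- matrix(stats::rnbinom(30 * 12, mu = mu, size = 20), 30, 12,
                   dimnames = list(sprintf("t%02d", 1:30), NULL))
  colnames(counts) <- paste0("s", 1:12)
  rs <- region_selective(counts, reg)
  asg <- rs$assignment
  expect_true(all(asg$region[asg$feature_id %in% sprintf("t%02d", 1:10)]
                  == "cortex", na.rm = TRUE))
  sel <- asg$feature_id[!is.na(asg$region)]
  expect_true(all(sprintf("t%02d", 1:10) %in% sel))

  # infinite margin assigns nothing; zero margin assigns all clustered
  rs_inf <- region_selective(counts, reg, z_margin = Inf)
  expect_true(all(is.na(rs_inf$assignment$region)))
  rs_zero <- region_selective(counts, reg, z_margin = 0)
  clustered <- !is.na(rs_zero$assignment$node)
  expect_true(all(!is.na(rs_zero$assignment$region[clustered])))

  # flat feature: zero SD across regions stays unassigned
  flat <- matrix(rep(c(5, 5, 5), each = 4), 1, 12, byrow = TRUE)
  means <- tapply(flat[1, ], reg, mean)
  expect_equal(stats::sd(means), 0)
})

test_that("region assignment recovers planted selectivity with F1 >= 0.9", {
  set.seed(86)
  reg <- rep(c("cortex", "hippocampus", "striatum"), each = 4)
  nsel <- 100; nnull <- 300
  mu <- matrix(60, 3 * nsel + nnull, 12)
  for (k in 1:3) {
    rows <- ((k - 1) * nsel + 1):(k * nsel)
    mu[rows, reg == c("cortex", "hippocampus", "striatum")[k]] <- 60 * 8
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 10),
                   nrow(mu), 12)
  rownames(counts) <- sprintf("t%03d", seq_len(nrow(mu)))
  colnames(counts) <- paste0("s", 1:12)
  truth_reg <- rep(c("cortex", "hippocampus", "striatum", NA),
                   c(nsel, nsel, nsel, nnull))
  rs <- region_selective(counts, reg)
  pred <- stats::setNames(rs$assignment$region, rs$assignment$feature_id)
  f1 <- sapply(c("cortex", "hippocampus", "striatum"), function(rg) {
    tr <- rownames(counts)[!is.na(truth_reg) & truth_reg == rg]
    pd <- names(pred)[!is.na(pred) & pred == rg]
    tp <- length(intersect(tr, pd))
    2 * tp / (length(tr) + length(pd))
  })
  expect_gte(mean(f1), 0.9)
})

test_that("activity calls are per-region with direction labels", {
  set.seed(87)
  si <- data.frame(
    sample_id = sprintf("s%02d", 1:24),
    region = rep(c("cortex", "hippocampus", "striatum"), each = 8),
    treatment = rep(rep(c("Veh", "KCl"), each = 4), 3),
    replicate = rep(1:4, 6))
  mu <- matrix(80, 20, 24)
  kcl_str <- si$treatment == "KCl" & si$region == "striatum"
  mu[1, kcl_str] <- 320                      # striatum-only induction
  counts <- matrix(stats::rnbinom(20 * 24, mu = mu, size = 30), 20, 24,
                   dimnames = list(sprintf("t%02d", 1:20), si$sample_id))
  act <- activity_dependent(counts, si)
  hit <- act$significant[act$significant$feature_id == "t01", ]
  expect_equal(hit$region, "striatum")
  expect_equal(hit$direction, "up")
  expect_false("t01" %in%
                 act$significant$feature_id[act$significant$region !=
                                              "striatum"])

  # same matrix for Veh and KCl -> no calls
  flat <- counts
  for (rg in unique(si$region)) {
    j <- which(si$region == rg)
    veh <- j[si$treatment[j] == "Veh"]
    kcl <- j[si$treatment[j] == "KCl"]
    flat[, kcl] <- flat[, veh]
  }
  act0 <- activity_dependent(flat, si)
  expect_equal(length(act0$union), 0)
})

test_that("null activity calls stay within binomial bounds of alpha", {
  set.seed(88)
  si <- data.frame(
    sample_id = sprintf("s%02d", 1:24),
    region = rep(c("cortex", "hippocampus", "striatum"), each = 8),
    treatment = rep(rep(c("Veh", "KCl"), each = 4), 3),
    replicate = rep(1:4, 6))
  counts <- matrix(stats::rnbinom(400 * 24, mu = 100, size = 10), 400, 24,
                   dimnames = list(sprintf("t%03d", 1:400), si$sample_id))
  act <- activity_dependent(counts, si, q_threshold = 0.05)
  # BH at q < 0.05 under a global null controls the expected number of
  # false positives near zero; allow a generous binomial-style ceiling
  expect_lte(length(act$union), 20)
})

test_that("signed-rank summaries report exact and approximate p-values", {
  sig <- data.frame(feature_id = sprintf("T%d", 1:8),
                    region = "cortex",
                    log2fc = c(rep(1, 6), rep(-1, 2)),
                    q = 0.01,
                    direction = c(rep("up", 6), rep("down", 2)))
  pairs <- data.frame(tape_id = sprintf("T%d", 1:8),
                      gene_id = sprintf("g%d", 1:8),
                      distance = 1e4, distance_rank = 1L,
                      r_global = 0.9, high_confidence = TRUE)
  glfc <- stats::setNames(c(0.4, 0.9, 1.3, 0.2, 0.8, 0.5, -0.7, -0.3),
                          sprintf("g%d", 1:8))
  out <- linked_response_summary(sig, pairs, glfc)
  up <- out[out$class == "up" & out$metric == "gene_mrna", ]
  expect_equal(up$n, 6)
  expect_equal(up$p, 0.03125)   # exact two-sided: 2 / 2^6

  sym <- stats::setNames(c(-1, 1, -2, 2, -3, 3), sprintf("g%d", 1:6))
  out2 <- linked_response_summary(sig[1:6, ], pairs, sym)
  expect_gte(out2$p[out2$class == "up"], 0.99)

  # n = 40 normal approximation tracks the exact test at n = 15
  set.seed(89)
  x <- stats::rnorm(15, 0.3)
  p_exact <- stats::wilcox.test(x, mu = 0, exact = TRUE)$p.value
  p_approx <- stats::wilcox.test(x, mu = 0, exact = FALSE,
                                 correct = TRUE)$p.value
  expect_lt(abs(p_exact - p_approx), 0.01)
})
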