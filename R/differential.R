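# Negative-binomial differential testing for region-selective and
# activity-dependent TAPEs. Deliberately a compact reimplementation of the
# median-of-ratios / NB-GLM workflow (size factors, method-of-moments
# dispersion, Wald or likelihood-ratio test, BH adjustment): directional and
# rank agreement with the reference machinery is the goal, not numerical
# parity.

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median, over features with no zero count, of
#' the ratio of its count to the per-feature geometric mean. With
#' \code{pseudo_reference = TRUE} the geometric mean is taken over positive
#' counts only (usable when no feature is all-positive).
#'
#' @param counts features-by-samples count matrix (>= 2 samples).
#' @param pseudo_reference use the positive-count geometric-mean fallback.
#' @return named per-sample size factors (geometric mean 1).
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  stopifnot(ncol(counts) >= 2)
  if (pseudo_reference) {
    logref <- apply(counts, 1, function(r) {
      pos <- r > 0
      if (!any(pos)) return(NA_real_)
      mean(log(r[pos]))
    })
    use <- !is.na(logref) & rowSums(counts > 0) > 0
  } else {
    use <- rowSums(counts > 0) == ncol(counts)
    if (!any(use)) {
      stop("no feature has all-positive counts; ",
           "set pseudo_reference = TRUE to use the positive-count fallback")
    }
    logref <- rowMeans(log(counts))
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    r <- log(col[col > 0]) - logref[use][col > 0]
    exp(stats::median(r))
  })
  sf / exp(mean(log(sf)))
}

# pooled within-group method-of-moments NB dispersion per feature
mom_dispersion <- function(norm, group, min_disp = 1e-8,
                           trend_blend = FALSE) {
  g <- as.factor(group)
  n <- ncol(norm)
  df <- n - nlevels(g)
  mu <- rowMeans(norm)
  fitted <- matrix(0, nrow(norm), n)
  for (lv in levels(g)) {
    j <- which(g == lv)
    fitted[, j] <- rowMeans(norm[, j, drop = FALSE])
  }
  s2 <- rowSums((norm - fitted)^2) / max(df, 1)
  disp <- pmax((s2 - mu) / mu^2, min_disp)
  disp[!is.finite(disp)] <- min_disp
  if (trend_blend) {
    ok <- mu > 0 & is.finite(disp)
    if (sum(ok) >= 10) {
      fit <- stats::lm(disp[ok] ~ I(1 / mu[ok]))
      trend <- pmax(stats::coef(fit)[1] + stats::coef(fit)[2] / mu,
                    min_disp)
      disp <- pmax(0.5 * disp + 0.5 * trend, min_disp)
    }
  }
  disp
}

#' Negative-binomial differential test
#'
#' Per-feature NB generalized linear model with log link and size-factor
#' offsets. Dispersion is a gene-wise method-of-moments estimate (pooled
#' within-group variance), floored at \code{min_disp}; an optional
#' parametric-trend blend (\code{a/mean + b}, 50/50) can stabilise it.
#' \code{mode = "wald"} compares exactly two groups and reports a Wald
#' statistic on the log2 fold change (second level vs first), referred to a
#' t distribution on the residual degrees of freedom (samples - groups) to
#' keep the test calibrated when the dispersion is itself estimated from
#' few replicates; \code{mode = "lrt"} is an omnibus likelihood-ratio
#' chi-square with (groups - 1) df.
#'
#' @param counts features-by-samples count matrix.
#' @param group group label per sample (2 levels for \code{"wald"}).
#' @param mode \code{"wald"} or \code{"lrt"}.
#' @param sf size factors (computed via [size_factors()] when NULL, with
#'   pseudo-reference fallback).
#' @param min_disp dispersion floor (default 1e-8).
#' @param trend_blend blend gene-wise dispersions with a fitted a/mean + b
#'   trend (default FALSE).
#' @param pool_dispersion allow groups with a single sample by pooling the
#'   dispersion estimate across all samples (default FALSE: such groups are
#'   an error).
#' @param dispersion optional fixed per-feature dispersion vector (e.g.
#'   estimated once from a larger design and shared across contrasts, the
#'   usual multi-factor workflow); when supplied, \code{disp_df} should
#'   give the residual df of that estimate for the t reference.
#' @param disp_df residual degrees of freedom behind \code{dispersion}.
#' @return an \code{nb_result} data.frame: \code{feature_id},
#'   \code{baseMean}, \code{log2fc}, \code{statistic}, \code{p}, \code{q}.
#' @export
nb_test <- function(counts, group, mode = c("wald", "lrt"), sf = NULL,
                    min_disp = 1e-8, trend_blend = FALSE,
                    pool_dispersion = FALSE, dispersion = NULL,
                    disp_df = NULL) {
  mode <- match.arg(mode)
  g <- droplevels(as.factor(group))
  stopifnot(ncol(counts) == length(g))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (mode == "wald" && nlevels(g) != 2) {
    stop("wald mode compares exactly 2 groups")
  }
  small <- table(g) < 2
  if (any(small) && !pool_dispersion) {
    stop("group(s) with < 2 samples: ",
         paste(names(which(small)), collapse = ", "),
         "; set pool_dispersion = TRUE to pool the dispersion estimate")
  }
  if (is.null(sf)) {
    sf <- tryCatch(size_factors(counts),
                   error = function(e) size_factors(counts,
                                                    pseudo_reference = TRUE))
  }
  norm <- sweep(counts, 2, sf, "/")
  if (is.null(dispersion)) {
    disp_group <- if (any(small)) rep(1, length(g)) else g
    disp <- mom_dispersion(norm, disp_group, min_disp = min_disp,
                           trend_blend = trend_blend)
    tdf <- max(length(g) - nlevels(g), 1)
  } else {
    stopifnot(length(dispersion) == nrow(counts))
    disp <- pmax(dispersion, min_disp)
    tdf <- if (is.null(disp_df)) max(length(g) - nlevels(g), 1) else disp_df
  }
  off <- log(sf)
  nfeat <- nrow(counts)
  log2fc <- statistic <- p <- rep(NA_real_, nfeat)
  for (i in seq_len(nfeat)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    fam <- MASS::negative.binomial(theta = 1 / disp[i], link = "log")
    fit <- tryCatch(
      stats::glm(y ~ g + offset(off), family = fam,
                 control = stats::glm.control(maxit = 100)),
      error = function(e) NULL)
    if (mode == "wald") {
      if (!is.null(fit)) {
        cf <- summary(fit)$coefficients
        if (nrow(cf) >= 2 && is.finite(cf[2, 2]) && cf[2, 2] > 0) {
          b <- cf[2, 1]
          if (abs(b) < 1e-10) {
            # perfect fit: effect below numeric resolution
            log2fc[i] <- 0; statistic[i] <- 0; p[i] <- 1
          } else {
            log2fc[i] <- b / log(2)
            statistic[i] <- b / cf[2, 2]
            p[i] <- 2 * stats::pt(-abs(statistic[i]), df = tdf)
          }
          next
        }
      }
      # fallback: moment estimate with pseudocount, delta-method Wald
      m <- tapply(norm[i, ] + 0.125, g, mean)
      nn <- table(g)
      se2 <- sum(1 / nn * (1 / m + disp[i]))
      b <- log(m[2] / m[1])
      log2fc[i] <- b / log(2)
      statistic[i] <- b / sqrt(se2)
      p[i] <- 2 * stats::pt(-abs(statistic[i]), df = tdf)
    } else {
      fit0 <- tryCatch(
        stats::glm(y ~ 1 + offset(off), family = fam,
                   control = stats::glm.control(maxit = 100)),
        error = function(e) NULL)
      if (is.null(fit) || is.null(fit0)) next
      stat <- as.numeric(stats::deviance(fit0) - stats::deviance(fit))
      stat <- max(stat, 0)
      statistic[i] <- stat
      p[i] <- stats::pchisq(stat, df = nlevels(g) - 1, lower.tail = FALSE)
      m <- tapply(norm[i, ], g, mean)
      log2fc[i] <- log2((max(m) + 0.125) / (min(m) + 0.125))
    }
  }
  zero <- rowSums(counts != 0) == 0
  log2fc[zero] <- 0
  out <- data.frame(
    feature_id = if (is.null(rownames(counts)))
      sprintf("f%05d", seq_len(nfeat)) else rownames(counts),
    baseMean = rowMeans(norm),
    log2fc = log2fc,
    statistic = statistic,
    p = p,
    q = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("nb_result", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "dispersion") <- disp
  attr(out, "size_factors") <- sf
  out
}

#' @export
print.nb_result <- function(x, ...) {
  cat(sprintf("nb_result (%s): %d features, %d at q < 0.05\n",
              attr(x, "mode"), nrow(x), sum(x$q < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; \code{NA} p-values
#' are preserved as \code{NA} and excluded from the adjustment.
#'
#' @param p p-values in [0, 1] (NA allowed).
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Region-selective TAPE assignment
#'
#' Stage 1: three-region omnibus NB likelihood-ratio test; features with
#' \code{q < q_threshold} proceed. Stage 2: each significant feature's
#' per-region mean normalized count is z-scored across the regions
#' (mean 0, unit sample SD); features are clustered on their z-vectors
#' (Euclidean distance, complete linkage) and the dendrogram is cut at the
#' number of clusters with the largest merge-height gap (at least 3 where
#' possible, admitting extra noise nodes). A node is assigned to a region
#' when its mean z for that region exceeds both other regions' mean z by at
#' least \code{z_margin}; features in unassignable nodes (including
#' two-region-high patterns) stay unassigned.
#'
#' @param counts TAPE count matrix (features by samples).
#' @param regions region label per sample (3 levels).
#' @param q_threshold FDR threshold (default 0.05).
#' @param z_margin required z separation in SD units (default 0.5).
#' @param sf optional size factors.
#' @return list with \code{test} (the omnibus \code{nb_result}) and
#'   \code{assignment}: data.frame of significant features with per-region
#'   z-scores, cluster node and assigned region (\code{NA} = unassigned).
#' @export
region_selective <- function(counts, regions, q_threshold = 0.05,
                             z_margin = 0.5, sf = NULL) {
  g <- droplevels(as.factor(regions))
  if (nlevels(g) != 3) stop("region_selective expects exactly 3 regions")
  res <- nb_test(counts, g, mode = "lrt", sf = sf)
  sf <- attr(res, "size_factors")
  sig <- which(!is.na(res$q) & res$q < q_threshold)
  reg_names <- levels(g)
  assignment <- data.frame(feature_id = res$feature_id[sig],
                           q = res$q[sig], stringsAsFactors = FALSE)
  if (length(sig) == 0) {
    for (rg in reg_names) assignment[[paste0("z_", rg)]] <- numeric(0)
    assignment$node <- integer(0)
    assignment$region <- character(0)
    return(list(test = res, assignment = assignment))
  }
  norm <- sweep(counts[sig, , drop = FALSE], 2, sf, "/")
  means <- sapply(reg_names, function(rg)
    rowMeans(norm[, g == rg, drop = FALSE]))
  means <- matrix(means, ncol = length(reg_names),
                  dimnames = list(NULL, reg_names))
  mu <- rowMeans(means)
  sd_ <- apply(means, 1, stats::sd)
  z <- (means - mu) / ifelse(sd_ > 0, sd_, NA)
  for (rg in reg_names) assignment[[paste0("z_", rg)]] <- z[, rg]
  # cluster z-vectors; zero-SD rows cannot be clustered or assigned
  usable <- which(!is.na(z[, 1]))
  node <- rep(NA_integer_, length(sig))
  if (length(usable) >= 2) {
    hc <- stats::hclust(stats::dist(z[usable, , drop = FALSE]),
                        method = "complete")
    h <- hc$height
    kmax <- min(10, length(usable) - 1)
    if (kmax >= 2 && length(h) >= 2) {
      gaps <- rev(diff(h))          # gaps[k-1] = gap opened by cutting at k
      krange <- 2:(kmax)
      k <- krange[which.max(gaps[krange - 1])]
      k <- max(k, min(3, length(usable)))
    } else k <- length(usable)
    node[usable] <- stats::cutree(hc, k = k)
  } else if (length(usable) == 1) {
    node[usable] <- 1L
  }
  assignment$node <- node
  assignment$region <- NA_character_
  for (nd in unique(stats::na.omit(node))) {
    rows <- which(!is.na(node) & node == nd)
    zbar <- colMeans(z[rows, , drop = FALSE])
    ord <- order(zbar, decreasing = TRUE)
    if (is.finite(z_margin) && zbar[ord[1]] - zbar[ord[2]] >= z_margin) {
      assignment$region[rows] <- reg_names[ord[1]]
    }
  }
  rownames(assignment) <- NULL
  list(test = res, assignment = assignment)
}

#' Activity-dependent TAPEs (vehicle vs depolarisation, per region)
#'
#' Runs a two-group NB Wald test (KCl vs Veh) within each region, collects
#' features significant at \code{q < q_threshold} in at least one region,
#' and labels each significant (feature, region) up or down by the log2
#' fold-change sign. The per-feature dispersion is estimated once from the
#' full region x treatment design and shared across the per-region
#' contrasts, so each contrast borrows the whole dataset's replicate
#' information.
#'
#' @param counts TAPE count matrix.
#' @param sample_info sample metadata with \code{sample_id}, \code{region},
#'   \code{treatment} (Veh/KCl); columns of \code{counts} must be sample
#'   ids.
#' @param q_threshold FDR threshold (default 0.05).
#' @return list with \code{per_region} (\code{nb_result} per region),
#'   \code{significant} (feature, region, log2fc, q, direction) and
#'   \code{union} (feature ids significant anywhere).
#' @export
activity_dependent <- function(counts, sample_info, q_threshold = 0.05) {
  stopifnot(all(colnames(counts) %in% sample_info$sample_id))
  si <- sample_info[match(colnames(counts), sample_info$sample_id), ]
  regions <- sort(unique(si$region))
  # one dispersion per feature, estimated across the full region x
  # treatment design and shared by every per-region contrast
  sf_all <- tryCatch(size_factors(counts), error = function(e)
    size_factors(counts, pseudo_reference = TRUE))
  cells <- interaction(si$region, si$treatment, drop = TRUE)
  disp_all <- mom_dispersion(sweep(counts, 2, sf_all, "/"), cells)
  disp_df <- max(ncol(counts) - nlevels(cells), 1)
  per_region <- list()
  sig_rows <- list()
  for (rg in regions) {
    j <- which(si$region == rg)
    trt <- factor(si$treatment[j], levels = c("Veh", "KCl"))
    res <- nb_test(counts[, j, drop = FALSE], trt, mode = "wald",
                   dispersion = disp_all, disp_df = disp_df)
    per_region[[rg]] <- res
    hit <- which(!is.na(res$q) & res$q < q_threshold)
    if (length(hit)) {
      sig_rows[[rg]] <- data.frame(
        feature_id = res$feature_id[hit], region = rg,
        log2fc = res$log2fc[hit], q = res$q[hit],
        direction = ifelse(res$log2fc[hit] >= 0, "up", "down"),
        stringsAsFactors = FALSE)
    }
  }
  significant <- if (length(sig_rows)) do.call(rbind, sig_rows) else
    data.frame(feature_id = character(), region = character(),
               log2fc = numeric(), q = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  rownames(significant) <- NULL
  list(per_region = per_region, significant = significant,
       union = unique(significant$feature_id))
}

# two-sided one-sample signed-rank p against median 0; exact for n <= 25
# (after zero removal), normal approximation with continuity correction
# above
signed_rank_p <- function(x, exact_max = 25) {
  x <- x[!is.na(x) & x != 0]
  if (length(x) == 0) return(NA_real_)
  suppressWarnings(
    stats::wilcox.test(x, mu = 0, alternative = "two.sided",
                       exact = length(x) <= exact_max,
                       correct = TRUE)$p.value)
}

#' Linked-gene and chromatin responses at activity-dependent TAPEs
#'
#' Splits significant TAPEs into up- and downregulated classes (a TAPE
#' significant in several regions takes the direction of its most
#' significant region), links each to its top-correlated gene, and for each
#' class summarises the linked-gene mRNA log2 fold changes and the ATAC
#' log2 fold changes at TAPEs and at linked-gene promoters with a two-sided
#' Wilcoxon signed-rank test against a theoretical median of zero.
#'
#' @param significant the \code{significant} table from
#'   [activity_dependent()].
#' @param pairs scored pair data.frame (the top \code{r_global} gene per
#'   TAPE is used).
#' @param gene_log2fc named vector: mRNA log2 fold change per gene id.
#' @param tape_atac_log2fc named vector: ATAC log2 fold change per TAPE id
#'   (optional).
#' @param promoter_atac_log2fc named vector: promoter ATAC log2 fold change
#'   per gene id (optional).
#' @return data.frame with one row per (class, metric): n, median, signed-
#'   rank p (empty classes reported with n = 0 and no test).
#' @export
linked_response_summary <- function(significant, pairs, gene_log2fc,
                                    tape_atac_log2fc = NULL,
                                    promoter_atac_log2fc = NULL) {
  if (nrow(significant) > 0) {
    ord <- order(significant$feature_id, significant$q)
    top <- significant[ord, ][!duplicated(significant$feature_id[ord]), ]
  } else top <- significant
  best <- best_pair_per_tape(pairs)
  link <- best$gene_id[match(top$feature_id, best$tape_id)]
  rows <- list()
  for (cls in c("up", "down")) {
    in_cls <- which(top$direction == cls)
    tapes_c <- top$feature_id[in_cls]
    genes_c <- link[in_cls]
    metrics <- list(gene_mrna = gene_log2fc[genes_c[!is.na(genes_c)]])
    if (!is.null(tape_atac_log2fc)) {
      metrics$tape_atac <- tape_atac_log2fc[tapes_c]
    }
    if (!is.null(promoter_atac_log2fc)) {
      metrics$promoter_atac <- promoter_atac_log2fc[genes_c[!is.na(genes_c)]]
    }
    for (mn in names(metrics)) {
      v <- metrics[[mn]][!is.na(metrics[[mn]])]
      rows[[paste(cls, mn)]] <- data.frame(
        class = cls, metric = mn, n = length(v),
        median = if (length(v)) stats::median(v) else NA_real_,
        p = if (length(v)) signed_rank_p(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
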