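test_that("CPM filter applies the retention rule and is idempotent", {
  counts <- rbind(g1 = c(4, 4, 4), g2 = c(6, 6, 0), g3 = c(0, 0, 0),
                  g4 = c(100, 100, 100))
  # library sizes ~1e6 via a filler gene
  counts <- rbind(counts, filler = c(1e6, 1e6, 1e6) - colSums(counts))
  cm <- structure(list(counts = counts,
                       gene_ids = rownames(counts),
                       sample_groups = factor(c("tract", "tumor", "normal")),
                       truth_fc = rep(1, 5)),
                  class = "counts_matrix")
  f <- cpm_filter(cm, min_cpm = 5, min_samples = 2)
  expect_false("g1" %in% f$gene_ids)   # CPM 4 everywhere
  expect_true("g2" %in% f$gene_ids)    # CPM >= 5 in 2 samples
  expect_false("g3" %in% f$gene_ids)
  f2 <- cpm_filter(f, min_cpm = 5, min_samples = 2)
  expect_identical(f$gene_ids, f2$gene_ids)

  # retained set equals brute-force application of the rule
  cm2 <- simulate_counts(400, c(tract = 4, tumor = 4), de_fraction = 0,
                         seed = 9)
  got <- cpm_filter(cm2)$gene_ids
  cpm <- sweep(cm2$counts, 2, colSums(cm2$counts), "/") * 1e6
  want <- cm2$gene_ids[rowSums(cpm >= 5) >= 2]
  expect_identical(got, want)
})

test_that("hierarchical clustering separates shifted groups", {
  set.seed(4)
  base <- matrix(rnorm(200 * 9, mean = 8, sd = 0.3), 200, 9)
  base[, 4:6] <- base[, 4:6] + 6
  base[, 7:9] <- base[, 7:9] - 6
  hc <- hier_cluster(base, k = 3)
  truth <- rep(1:3, each = 3)
  # adjusted Rand index = 1 <=> identical partitions up to relabeling
  tab <- table(hc$labels, truth)
  expect_equal(sum(tab > 0), 3)
  # duplicated sample merges at height zero
  dup <- cbind(base, base[, 1])
  hcd <- hier_cluster(dup)
  expect_equal(min(hcd$hclust$height), 0)
  # permutation invariance up to relabeling
  perm <- sample(9)
  hcp <- hier_cluster(base[, perm], k = 3)
  tab2 <- table(hcp$labels, truth[perm])
  expect_equal(sum(tab2 > 0), 3)
})

test_that("voom DE is calibrated under the null and finds true signals", {
  cm <- simulate_counts(5000, de_fraction = 0, dispersion = 0.1, seed = 21)
  cmf <- cpm_filter(cm, min_cpm = 1, min_samples = 2)
  de <- voom_de(cmf)
  expect_gt(stats::ks.test(de$p_value, "punif")$p.value, 0.01)

  # 2-fold effects: detected true-DE genes have positive log2FC
  cm2 <- simulate_counts(3000, de_fraction = 0.15, fold_change = 2,
                         dispersion = 0.05, seed = 22)
  cmf2 <- cpm_filter(cm2, min_cpm = 1, min_samples = 2)
  de2 <- voom_de(cmf2)
  hit <- de2$q_value < 0.05 & cmf2$truth_fc > 1
  expect_gt(sum(hit), 20)
  expect_gte(mean(de2$log2fc[hit] > 0), 0.95)

  # a gene constant across samples (equal library sizes) has log2FC = 0
  set.seed(10)
  counts <- matrix(rnbinom(200 * 8, mu = 100, size = 10), 200, 8)
  counts[1, ] <- 500L
  counts <- rbind(counts, 120000L - colSums(counts))   # equalize libraries
  cmc <- structure(list(counts = counts,
                        gene_ids = sprintf("g%03d", 1:201),
                        sample_groups = factor(rep(c("tract", "tumor"),
                                                   each = 4)),
                        truth_fc = rep(1, 201)),
                   class = "counts_matrix")
  dec <- voom_de(cmc)
  expect_lt(abs(dec$log2fc[1]), 1e-8)

  expect_error(voom_de(structure(list(counts = cmf2$counts,
                                      gene_ids = cmf2$gene_ids,
                                      sample_groups = factor(rep("tumor",
                                                                 13)),
                                      truth_fc = NULL),
                                 class = "counts_matrix")), "tract")
})

test_that("voom weights are positive and finite", {
  cm <- simulate_counts(500, de_fraction = 0, seed = 5)
  cmf <- cpm_filter(cm, min_cpm = 1)
  design <- cbind(1, as.numeric(cmf$sample_groups == "tract"))
  v <- limma::voom(cmf$counts, design)
  expect_true(all(is.finite(v$weights)) && all(v$weights > 0))
})

test_that("BH adjustment matches the step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # oracle: direct step-up evaluation on random vectors
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    oracle <- numeric(m)
    oracle[o] <- pmin(1, q_sorted)
    expect_equal(bh_adjust(p), oracle, tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p - 1e-12))
  }
})

test_that("DE calls respect the 2-fold and FDR thresholds", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(0.9, 1.5, -2, 3),
                    ave_log_cpm = 5, t = 1,
                    p_value = c(0.001, 0.01, 0.2, 0.001),
                    q_value = c(0.001, 0.01, 0.2, 0.001))
  out <- de_call(tab)
  expect_false("a" %in% out$gene_id)   # below 2-fold despite tiny q
  expect_true(all(c("b", "d") %in% out$gene_id))
  expect_false("c" %in% out$gene_id)   # fails FDR
  expect_equal(out$direction[out$gene_id == "b"], "up")
  # brute-force row scan oracle on a random table
  set.seed(9)
  rt <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   log2fc = rnorm(200, sd = 1.5),
                   ave_log_cpm = 5, t = 0,
                   p_value = runif(200), q_value = runif(200))
  want <- rt$gene_id[abs(rt$log2fc) >= 1 & rt$q_value < 0.05]
  expect_setequal(de_call(rt)$gene_id, want)
})

test_that("over-representation test equals the hypergeometric tail sum", {
  universe <- sprintf("g%03d", 1:100)
  ann <- universe[1:20]
  de <- c(universe[1:8], universe[90:91])
  r <- ora_fisher(de, ann, universe)
  tail_sum <- sum(vapply(8:10, function(k)
    choose(20, k) * choose(80, 10 - k) / choose(100, 10), numeric(1)))
  expect_equal(r$p_value, tail_sum, tolerance = 1e-12)
  expect_equal(r$overlap, 8)
  # overlap at the independence expectation: not significant
  de2 <- c(universe[1:2], universe[30:37])   # overlap 2 = 10*20/100
  expect_gt(ora_fisher(de2, ann, universe)$p_value, 0.3)
  # de_set == annotation_set: maximal overlap, minimal p for these margins
  r3 <- ora_fisher(ann, ann, universe)
  expect_equal(r3$overlap, 20)
  expect_equal(r3$p_value,
               1 / choose(100, 20) * choose(20, 20) * choose(80, 0),
               tolerance = 1e-12)
  expect_error(ora_fisher(de, ann, character(0)), "universe")
  expect_error(ora_fisher("zzz", ann, universe), "subsets")
})

test_that("null-simulation FDR of the DE call is controlled", {
  fdp <- vapply(1:50, function(s) {
    cm <- simulate_counts(2000, de_fraction = 0, dispersion = 0.1, seed = s)
    cmf <- cpm_filter(cm, min_cpm = 1, min_samples = 2)
    de <- voom_de(cmf)
    called <- de_call(de, fc_threshold = 1, q_threshold = 0.05)
    nrow(called) > 0   # all calls are false under the null
  }, logical(1))
  margin <- 2 * sqrt(0.05 * 0.95 / 50)
  expect_lte(mean(fdp), 0.05 + margin)
})

test_that("tract-motility enrichment is recovered from simulation", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    cm <- simulate_counts(2000, de_fraction = 0.1, fold_change = 3,
                          dispersion = 0.05, seed = s)
    cmf <- cpm_filter(cm, min_cpm = 1, min_samples = 2)
    true_de <- cmf$gene_ids[cmf$truth_fc > 1]
    n_mot <- round(0.6 * length(true_de))
    motility <- c(sample(true_de, n_mot),
                  sample(setdiff(cmf$gene_ids, true_de),
                         max(0, 200 - n_mot)))
    de <- voom_de(cmf)
    called <- de_call(de, fc_threshold = 2, q_threshold = 0.05)$gene_id
    if (length(called) < 3) return(NA)
    ora_fisher(called, motility, cmf$gene_ids)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})
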