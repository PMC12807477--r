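lfq_toy <- function(seed = 71, n = 40, effect = 0, frac_shifted = 0.3) {
  set.seed(seed)
  groups <- setNames(rep(c("disease", "healthy"), c(4, 4)),
                     paste0("s", 1:8))
  base <- rnorm(n, 20, 2)
  shifted <- seq_len(floor(n * frac_shifted))  # first rows carry the effect
  delta <- ifelse(seq_len(n) %in% shifted, effect, 0)
  m <- sapply(seq_len(8), function(j)
    2^(base + if (j <= 4) delta else 0) * 2^rnorm(n, 0, 0.3))
  dimnames(m) <- list(sprintf("P%02d", 1:n), names(groups))
  list(m = m, groups = groups, shifted = rownames(m)[shifted])
}

test_that("preprocessing filters absent proteins and centers columns", {
  toy <- lfq_toy()
  lm <- preprocess_lfq(toy$m, toy$groups)
  expect_identical(dim(lm), dim(toy$m))
  expect_equal(unname(apply(lm, 2, median)), rep(0, 8))
  m2 <- toy$m
  m2["P01", ] <- NA
  expect_false("P01" %in% rownames(preprocess_lfq(m2, toy$groups)))
})

test_that("Welch differential test matches the oracle on a 3v3 toy", {
  groups <- setNames(rep(c("disease", "healthy"), each = 3), paste0("s", 1:6))
  set.seed(72)
  for (i in 1:20) {
    m <- matrix(rnorm(6, 10, 1), 1, dimnames = list("P1", names(groups)))
    de <- differential_proteins(m, groups)
    ora <- oracle_welch(m[1, 1:3], m[1, 4:6])
    expect_equal(de$t, ora$t, tolerance = 1e-9)
    expect_equal(de$p_value, ora$p, tolerance = 1e-9)
    expect_equal(de$log2fc, mean(m[1, 1:3]) - mean(m[1, 4:6]),
                 tolerance = 1e-12)
  }
  # identical groups: FC 0, p = 1
  m0 <- matrix(rep(c(1, 2, 3), 2), 1,
               dimnames = list("P1", names(groups)))
  de0 <- differential_proteins(m0, groups)
  expect_equal(de0$log2fc, 0)
  expect_equal(de0$p_value, 1)
  # < 2 values in a group: skipped with reason
  m1 <- matrix(c(1, NA, NA, 1, 2, 3), 1,
               dimnames = list("P1", names(groups)))
  expect_true(differential_proteins(m1, groups)$skipped)
})

test_that("planted abundance shifts are detected as significant", {
  toy <- lfq_toy(seed = 73, effect = -1.5)
  lm <- preprocess_lfq(toy$m, toy$groups)
  de <- differential_proteins(lm, toy$groups)
  hit <- de$significant[de$protein_id %in% toy$shifted]
  expect_gt(mean(hit), 0.9)
  expect_lt(median(de$log2fc[de$protein_id %in% toy$shifted]), -1)
  expect_lt(mean(de$significant[!de$protein_id %in% toy$shifted]), 0.2)
})

test_that("BH q-values match the step-up oracle on random p vectors", {
  set.seed(74)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(ubnexus:::bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("top-variable PCA selects the configured fraction and separates groups", {
  toy <- lfq_toy(seed = 75)
  pca <- top_variable_pca(toy$m, fraction = 0.5)
  expect_length(pca$selected, 20)
  expect_lte(sum(pca$var_explained), 1 + 1e-9)
  # two planted sample clusters separate on PC1
  toy2 <- lfq_toy(seed = 76, effect = -3, frac_shifted = 0.4)
  lm <- preprocess_lfq(toy2$m, toy2$groups)
  pca2 <- top_variable_pca(lm, fraction = 0.5)
  pc1 <- pca2$scores[, 1]
  g <- toy2$groups[rownames(pca2$scores)]
  expect_true(max(pc1[g == "disease"]) < min(pc1[g == "healthy"]) ||
                min(pc1[g == "disease"]) > max(pc1[g == "healthy"]))
})

test_that("average-linkage dendrogram matches naive agglomeration", {
  set.seed(77)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("p", 1:10),
                                                paste0("s", 1:4)))
  cl <- hierarchical_cluster(m, de = NULL, top_n = 10, k_rows = 2)
  zs <- t(scale(t(m)))
  d <- as.dist(1 - cor(zs))
  expect_equal(sort(cl$sample_hclust$height),
               oracle_average_linkage_heights(d), tolerance = 1e-9)
  # duplicate samples merge at height ~0
  m2 <- cbind(m, s5 = m[, "s4"])
  cl2 <- hierarchical_cluster(m2, de = NULL, top_n = 10)
  expect_lt(min(cl2$sample_hclust$height), 1e-12)
})

test_that("two-block matrices split into the two planted sample clusters", {
  toy <- lfq_toy(seed = 78, effect = -2)
  lm <- preprocess_lfq(toy$m, toy$groups)
  de <- differential_proteins(lm, toy$groups)
  cl <- hierarchical_cluster(lm, de, top_n = 20)
  expect_equal(length(unique(cl$sample_clusters[toy$groups == "disease"])), 1)
  expect_equal(length(unique(cl$sample_clusters[toy$groups == "healthy"])), 1)
  expect_false(cl$sample_clusters[["s1"]] == cl$sample_clusters[["s8"]])
})

test_that("network projection attaches fold changes and flags missing nodes", {
  g <- igraph::make_ring(3)
  igraph::V(g)$name <- c("A", "B", "C")
  de <- data.frame(protein_id = c("A", "B"), log2fc = c(0, 0))
  pr <- project_onto_network(de, g)
  expect_equal(pr$mean_log2fc, 0)
  expect_equal(pr$n_missing, 1)
  expect_false(igraph::V(pr$network)$measured[3])
  de2 <- data.frame(protein_id = c("A", "B", "C"), log2fc = c(-1, -2, -3))
  expect_equal(project_onto_network(de2, g)$mean_log2fc, -2)
})

test_that("fold-change correlation joins on ids", {
  x <- setNames(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  self <- fc_correlation(x, x)
  expect_equal(self$pearson, 1)
  expect_equal(self$n_matched, 4)
  y <- setNames(c(1, 2, 3), c("b", "c", "e"))
  expect_equal(fc_correlation(x, y)$n_matched, 2)
  set.seed(79)
  a <- setNames(rnorm(2000), paste0("g", 1:2000))
  b <- setNames(rnorm(2000), paste0("g", 1:2000))
  r <- fc_correlation(a, b)$pearson
  expect_lt(abs(r), 3 / sqrt(2000))
})
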