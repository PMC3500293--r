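test_that("pearson correlation handles exact dependence, hand values and degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_equal(pearson_r(c(1, 2), c(3, 4))$flag, "insufficient_n")
  expect_equal(pearson_r(c(1, 1, 1), c(1, 2, 3))$flag, "zero_variance")
  # missing values drop pairwise
  pr <- pearson_r(c(1, 2, 3, NA, 5), c(2, 4, 6, 8, NA))
  expect_equal(pr$n, 3)
  expect_equal(pr$r, 1)
})

test_that("Fisher transform round-trips, matches closed form and clamps the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-7)
  r <- seq(-0.999, 0.999, by = 0.037)
  expect_equal(inverse_fisher_z(fisher_z(r)), r, tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-6))
  expect_error(fisher_z(1.2), "domain")
})

test_that("gene-set correlation integrates member correlations through weighted Fisher z", {
  # members with exactly known correlations to the anchor
  anchor <- c(3.1, 5.2, 4.4, 6.0, 2.2, 7.5, 5.9, 4.1, 6.6, 3.8)
  m <- rbind(ANCH = anchor,
             G1 = vector_with_exact_cor(anchor, 0.0, seed = 1) + 5,
             G2 = vector_with_exact_cor(anchor, 0.5, seed = 2) + 5,
             G3 = vector_with_exact_cor(anchor, 0.6, seed = 3) + 5)
  colnames(m) <- sprintf("s%02d", 1:10)
  se <- make_se(m)

  gs <- gene_set_correlation("ANCH", c("G1", "G2"), se, set_label = "pair")
  expect_equal(gs$z_bar, (0 + atanh(0.5)) / 2, tolerance = 1e-10)
  expect_equal(gs$r_bar, tanh(0.2746531), tolerance = 1e-6)
  expect_equal(gs$se_z, 1 / sqrt(10 - 3))

  # single-member set: r_bar is that member's r
  g1 <- gene_set_correlation("ANCH", "G3", se)
  expect_equal(g1$r_bar, 0.6, tolerance = 1e-10)

  # identical inputs: all members at r -> r_bar = r
  g_same <- gene_set_correlation("ANCH", c("G3", "G3"), se)
  expect_equal(g_same$r_bar, 0.6, tolerance = 1e-10)

  # set monotonicity: adding a member whose r equals the current r_bar
  # leaves r_bar unchanged
  rbar <- gs$r_bar
  m2 <- rbind(m, G4 = vector_with_exact_cor(anchor, rbar, seed = 4) + 5)
  gs2 <- gene_set_correlation("ANCH", c("G1", "G2", "G4"), make_se(m2))
  expect_equal(gs2$r_bar, rbar, tolerance = 1e-10)

  # independent mode pools member information
  gi <- gene_set_correlation("ANCH", c("G1", "G2"), se,
                             se_mode = "independent")
  expect_equal(gi$se_z, 1 / sqrt(2 * (10 - 3)))
  expect_equal(gi$z_bar, gs$z_bar)

  # zero-variance members are excluded; empty usable set errors
  m3 <- rbind(m, FLAT = rep(2, 10))
  gs3 <- gene_set_correlation("ANCH", c("G2", "FLAT"), make_se(m3))
  expect_equal(gs3$n_used, 1)
  expect_error(gene_set_correlation("ANCH", "FLAT", make_se(m3)), "usable")
  expect_error(gene_set_correlation("ANCH", "ANCH", se), "empty")
})

test_that("the two-set Z-test matches closed-form arithmetic and is antisymmetric", {
  mk <- function(z, se, label) {
    structure(list(anchor = "A", set_label = label, z_bar = z,
                   r_bar = tanh(z), se_z = se, se_mode = "conservative",
                   samples = paste0("s", 1:13)),
              class = "gene_set_correlation")
  }
  a <- mk(atanh(0.9), 1 / sqrt(10), "beige")
  b <- mk(atanh(0.1), 1 / sqrt(10), "classical")
  v <- compare_set_correlations(a, b)
  expect_equal(v$Z, (atanh(0.9) - atanh(0.1)) / sqrt(0.2))
  expect_equal(v$Z, 3.068, tolerance = 1e-3)
  expect_equal(v$p, 0.00215, tolerance = 1e-2)
  expect_equal(v$winner, "beige")

  v_swap <- compare_set_correlations(b, a)
  expect_equal(v_swap$Z, -v$Z)
  expect_equal(v_swap$p, v$p)
  expect_equal(v_swap$winner, "beige")

  v_eq <- compare_set_correlations(a, a)
  expect_equal(v_eq$Z, 0)
  expect_equal(v_eq$p, 1)

  b_short <- mk(0, 1 / sqrt(10), "classical")
  b_short$samples <- paste0("s", 1:12)
  expect_error(compare_set_correlations(a, b_short), "panel")
})

test_that("whisker rule flags points beyond quartile +/- 1.5 IQR", {
  o <- detect_outliers(c(1:9, 100))
  expect_equal(o$outliers, 10L)
  expect_equal(o$q1, 3.25)
  expect_equal(o$q3, 7.75)
  expect_equal(o$whisker_high, 9)  # outermost point inside the fence
  expect_equal(o$whisker_low, 1)

  expect_equal(detect_outliers(rep(5, 6))$outliers, integer(0))
  expect_equal(detect_outliers(c(2, 4, 6, 8, 10, 12))$outliers, integer(0))
  expect_equal(detect_outliers(c(1, 2, 3))$flag, "insufficient_n")

  # named vectors report sample ids
  v <- c(a = 1, b = 2, c = 3, d = 4, e = 50)
  expect_equal(detect_outliers(v)$outliers, "e")
})

test_that("whisker rule agrees with a brute-force oracle on random small vectors", {
  set.seed(2024)
  for (i in 1:200) {
    v <- sample(0:10, sample(4:8, 1), replace = TRUE)
    expect_equal(sort(detect_outliers(v)$outliers), sort(oracle_outliers(v)),
                 info = paste(v, collapse = ","))
  }
})

test_that("outlier screening drops genes with excessive outlier burden", {
  m <- rbind(clean = 1:12,
             spiky = c(rep(2, 9), 100, 110, 120))
  colnames(m) <- paste0("s", 1:12)
  res <- filter_genes_by_outliers(make_se(m), max_outlier_fraction = 0.2)
  expect_equal(res$report$excluded, c(FALSE, TRUE))
  expect_equal(rownames(exprs_of(res$matrix)), "clean")
  # vacuous threshold keeps everything
  res1 <- filter_genes_by_outliers(make_se(m), max_outlier_fraction = 1)
  expect_true(all(!res1$report$excluded))
})

test_that("correlation matrix is symmetric with unit diagonal and null-level off-terms", {
  set.seed(5)
  m <- matrix(rnorm(5 * 500), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:500)))
  m <- m + 10  # keep expression non-negative
  cm <- correlation_matrix(make_se(m))
  expect_identical(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 5))
  expect_true(all(abs(cm$r[upper.tri(cm$r)]) < 0.15))  # ~3/sqrt(n) bound
  expect_true(all(cm$n[upper.tri(cm$n)] == 500))

  dup <- rbind(m[1:2, ], twin = m[2, ])
  cmd <- correlation_matrix(make_se(dup))
  expect_equal(cmd$r["g2", "twin"], 1)
})

test_that("average-linkage clustering on 1 - r matches hand execution and a brute-force oracle", {
  r <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.1,
                0.1, 0.1, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(r)
  expect_equal(hc$height, c(0.1, 0.9))
  expect_equal(sort(hc$labels[hc$merge[1, ] * -1]), c("A", "B"))

  # perfectly correlated duplicates merge at height 0
  r0 <- matrix(c(1, 1, 0.2, 1, 1, 0.2, 0.2, 0.2, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(hierarchical_cluster(r0)$height[1], 0)

  # oracle equivalence on random instances of up to 6 items
  set.seed(99)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    x <- matrix(rnorm(k * 12), nrow = k,
                dimnames = list(LETTERS[1:k], paste0("s", 1:12)))
    r_mat <- cor(t(x))
    hc_i <- hierarchical_cluster(r_mat)
    coph <- as.matrix(stats::cophenetic(hc_i))
    oracle <- oracle_upgma_cophenetic(1 - r_mat)
    expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-12)
  }

  cm_na <- structure(list(r = matrix(c(1, NA, NA, 1), 2, 2,
                                     dimnames = list(c("A", "B"),
                                                     c("A", "B"))),
                          n = matrix(2L, 2, 2)),
                     class = "correlation_matrix")
  expect_error(hierarchical_cluster(cm_na), "filter")
})

test_that("dendrograms export to Newick and read back with the same tips", {
  set.seed(7)
  x <- matrix(rnorm(4 * 10), nrow = 4,
              dimnames = list(c("W", "X", "Y", "Z"), paste0("s", 1:10)))
  hc <- hierarchical_cluster(cor(t(x)))
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("W", "X", "Y", "Z"))
})
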