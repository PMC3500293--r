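test_that("unpaired t-test matches hand values, stats::t.test, and degenerate conventions", {
  expect_equal(unpaired_t_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # frozen hand computation: t = -3.674, df = 4
  expect_equal(unpaired_t_test(c(1, 2, 3), c(4, 5, 6)), 0.02131164,
               tolerance = 1e-6)
  expect_equal(unpaired_t_test(c(0, 0), c(0, 0)), 1)
  expect_equal(unpaired_t_test(c(0, 0), c(1, 1)), 0)
  expect_error(unpaired_t_test(c(1), c(1, 2)), "2 finite")

  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    expect_equal(unpaired_t_test(x, y, "student"),
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(unpaired_t_test(x, y, "welch"),
                 t.test(x, y)$p.value, tolerance = 1e-12)
  }
})

test_that("fold change is plain linear ratio with positivity guard", {
  expect_equal(fold_change(10, 5), 2)
  expect_equal(fold_change(5, 10), 0.5)
  expect_equal(fold_change(3.3, 3.3), 1)
  expect_error(fold_change(0, 1), "positive")
  expect_error(fold_change(1, -2), "positive")
})

test_that("gene classification follows the conjunctive enrichment rule", {
  th <- de_thresholds()
  p_all <- c(beige_white = 0.01, brown_white = 0.01, beige_brown = 0.01)
  expect_equal(classify_gene(c(white = 1, beige = 10, brown = 1), p_all, th),
               "BEIGE_ONLY")
  expect_equal(classify_gene(c(white = 1, beige = 8, brown = 9), p_all, th),
               "COMMON_BROWN")  # 9/8 < 2: neither cell type dominates
  # beige is enriched over white only; brown dominates both -> classical
  expect_equal(classify_gene(c(white = 1, beige = 3, brown = 9), p_all, th),
               "CLASSICAL_ONLY")
  expect_equal(classify_gene(c(white = 10, beige = 1, brown = 1), p_all, th),
               "WHITE")
  # significance gate: folds alone are not enough
  p_ns <- c(beige_white = 0.5, brown_white = 0.01, beige_brown = 0.01)
  expect_equal(classify_gene(c(white = 1, beige = 10, brown = 1), p_ns, th),
               "UNCLASSIFIED")
  # ties at exactly min_fold are included
  expect_equal(classify_gene(c(white = 1, beige = 2, brown = 1), p_all, th),
               "BEIGE_ONLY")
})

test_that("condition relabeling permutes group labels consistently", {
  th <- de_thresholds()
  p_all <- c(beige_white = 0.01, brown_white = 0.01, beige_brown = 0.01)
  swap <- function(means) c(white = means[["white"]],
                            beige = means[["brown"]],
                            brown = means[["beige"]])
  cases <- list(c(white = 1, beige = 9, brown = 1),
                c(white = 1, beige = 1, brown = 9),
                c(white = 1, beige = 8, brown = 9),
                c(white = 9, beige = 1, brown = 1))
  mapping <- c(BEIGE_ONLY = "CLASSICAL_ONLY", CLASSICAL_ONLY = "BEIGE_ONLY",
               COMMON_BROWN = "COMMON_BROWN", WHITE = "WHITE",
               UNCLASSIFIED = "UNCLASSIFIED")
  for (m in cases) {
    expect_equal(unname(mapping[classify_gene(m, p_all, th)]),
                 classify_gene(swap(m), p_all, th))
  }
})

test_that("noise-free planted matrices are recovered exactly; null matrices yield nothing", {
  cfg <- cell_type_sim_config(
    n_genes = 60, n_replicates = 3,
    planted_groups = c(WHITE = 5, BEIGE_ONLY = 10, COMMON_BROWN = 5,
                       CLASSICAL_ONLY = 10),
    fold_effect = 10, noise_cv = 0, seed = 1
  )
  sim <- generate_cell_type_profiles(cfg)
  mg <- discover_marker_groups(sim$matrix)
  expect_equal(as.integer(mg$counts[c("WHITE", "BEIGE_ONLY", "COMMON_BROWN",
                                      "CLASSICAL_ONLY")]),
               c(5L, 10L, 5L, 10L))
  a <- mg$assignments
  expect_equal(stats::setNames(a$label, a$gene), sim$truth$gene_labels)

  # all-equal means: no DE genes at all
  null_cfg <- cell_type_sim_config(n_genes = 20,
                                   planted_groups = c(BEIGE_ONLY = 0),
                                   noise_cv = 0, seed = 1)
  mg0 <- discover_marker_groups(generate_cell_type_profiles(null_cfg)$matrix)
  expect_equal(mg0$n_de, 0)
  expect_true(all(mg0$counts == 0))
})

test_that("label recovery is high under realistic noise and monotone in effect and replication", {
  recovery <- function(fold, reps, seed = 7) {
    cfg <- cell_type_sim_config(
      n_genes = 120, n_replicates = reps,
      planted_groups = c(WHITE = 25, BEIGE_ONLY = 25, COMMON_BROWN = 25,
                         CLASSICAL_ONLY = 25),
      fold_effect = fold, noise_cv = 0.2, seed = seed
    )
    sim <- generate_cell_type_profiles(cfg)
    mg <- discover_marker_groups(sim$matrix)
    lab <- stats::setNames(mg$assignments$label, mg$assignments$gene)
    planted <- sim$truth$gene_labels != "UNCLASSIFIED"
    mean(lab[planted] == sim$truth$gene_labels[planted])
  }
  expect_gte(recovery(4, 4), 0.9)
  # monotone non-decreasing over a small grid (fixed seeds)
  expect_lte(recovery(2, 3), recovery(4, 3) + 1e-9)
  expect_lte(recovery(4, 3), recovery(4, 6) + 1e-9)
})

test_that("assignments partition the DE genes and agree with a brute-force oracle", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    n <- 15
    m <- matrix(rlnorm(n * 9, meanlog = 3, sdlog = 1.2), nrow = n,
                dimnames = list(sprintf("g%02d", 1:n),
                                sprintf("s%d", 1:9)))
    # plant a couple of strong patterns amid noise
    m[1, 4:6] <- m[1, 4:6] * 20
    m[2, 7:9] <- m[2, 7:9] * 20
    cond <- rep(c("white", "beige", "brown"), each = 3)
    se <- make_se(m, data.frame(condition = cond))
    mg <- discover_marker_groups(se)

    expect_equal(sum(mg$counts), mg$n_de)
    expect_equal(oracle_discover(m, cond),
                 stats::setNames(mg$assignments$label, mg$assignments$gene))
  }
})

test_that("overlap fractions reproduce the shared-marker arithmetic", {
  cls <- overlap_fraction(29, 323)
  expect_equal(cls$percent, 100 * 29 / 323)
  expect_equal(cls$label, "9%")
  beige <- overlap_fraction(29, 170)
  expect_equal(beige$rounded, 17)
  expect_equal(overlap_fraction(0, 50)$percent, 0)
  expect_error(overlap_fraction(1, 0), "total")
  expect_error(overlap_fraction(5, 4), "common")
})
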