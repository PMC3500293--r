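# Seeded generators emulating the two experimental designs the pipeline
# consumes: (1) three adipocyte culture conditions with planted marker
# groups, (2) a human-like multi-depot tissue panel driven by one latent
# "beige activity" factor. Ground-truth labels ride along so recovery is
# testable. RNG state of the caller is always restored.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-gene sub-stream seed: deterministic in (top seed, gene index) so that
# growing a simulation does not reshuffle the genes already present.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + index * 10007) %% 2147483563 + 1
}

# cv of a log-normal -> sd on the natural-log scale
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

MARKER_LABELS <- c("WHITE", "BEIGE_ONLY", "COMMON_BROWN", "CLASSICAL_ONLY",
                   "UNCLASSIFIED")
CONDITIONS <- c("white", "beige", "brown")

#' Configuration for the three-condition cell-type simulation
#'
#' Describes a synthetic genes-by-samples experiment with three fully
#' differentiated adipocyte conditions — inguinal white, rosiglitazone-induced
#' beige, and classical (interscapular) brown — and marker groups planted at a
#' known enrichment fold. Replicate noise is multiplicative log-normal;
#' `noise_cv` is the replicate coefficient of variation on the linear scale
#' and is converted internally to a log-sd via `sqrt(log(1 + cv^2))`.
#'
#' @param n_genes Total number of genes.
#' @param n_replicates Replicates per condition (the culture experiments this
#'   emulates typically run 3).
#' @param planted_groups Named integer vector of planted gene counts; names
#'   from `WHITE`, `BEIGE_ONLY`, `COMMON_BROWN`, `CLASSICAL_ONLY`. Remaining
#'   genes are background (`UNCLASSIFIED`).
#' @param fold_effect Linear-scale enrichment fold of a planted gene in the
#'   condition(s) its group implies; must exceed 1.
#' @param noise_cv Replicate coefficient of variation (>= 0; 0 gives
#'   noise-free means).
#' @param baseline_mean Linear-scale expression floor/baseline.
#' @param floor_frac Detection floor as a fraction of `baseline_mean`;
#'   values are clipped from below at `floor_frac * baseline_mean`.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `cell_type_sim_config`.
#' @export
cell_type_sim_config <- function(n_genes = 2000,
                                 n_replicates = 3,
                                 planted_groups = c(WHITE = 30,
                                                    BEIGE_ONLY = 140,
                                                    COMMON_BROWN = 30,
                                                    CLASSICAL_ONLY = 290),
                                 fold_effect = 4,
                                 noise_cv = 0.2,
                                 baseline_mean = 100,
                                 floor_frac = 1e-3,
                                 seed = 1L) {
  bad <- setdiff(names(planted_groups), setdiff(MARKER_LABELS, "UNCLASSIFIED"))
  if (length(bad) > 0) {
    stop("unknown planted group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (sum(planted_groups) > n_genes) {
    stop("planted group counts exceed n_genes", call. = FALSE)
  }
  if (fold_effect <= 1) stop("fold_effect must be > 1", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (baseline_mean <= 0) stop("baseline_mean must be > 0", call. = FALSE)
  if (n_replicates < 2) stop("need >= 2 replicates per condition", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 planted_groups = planted_groups,
                 fold_effect = fold_effect,
                 noise_cv = noise_cv,
                 baseline_mean = baseline_mean,
                 floor_frac = floor_frac,
                 seed = as.integer(seed)),
            class = "cell_type_sim_config")
}

#' Simulate three-condition adipocyte expression profiles
#'
#' Generates a linear-scale expression matrix over the conditions `white`,
#' `beige` and `brown`. A gene planted in group `BEIGE_ONLY` has its mean
#' multiplied by `fold_effect` in the beige condition only; `CLASSICAL_ONLY`
#' in brown only; `COMMON_BROWN` in beige and brown; `WHITE` in white.
#' Background genes sit at `baseline_mean` everywhere. Replicate noise is
#' log-normal with unit mean, so condition means equal their targets in
#' expectation (exactly, at `noise_cv = 0`).
#'
#' @param config A [cell_type_sim_config()].
#' @return A list with elements `matrix` (a `SummarizedExperiment`, colData
#'   column `condition`) and `truth` (list with `gene_labels`, a named
#'   character vector of true group labels).
#' @export
generate_cell_type_profiles <- function(config) {
  stopifnot(inherits(config, "cell_type_sim_config"))
  labels <- rep("UNCLASSIFIED", config$n_genes)
  i <- 1L
  for (g in names(config$planted_groups)) {
    k <- config$planted_groups[[g]]
    if (k > 0) {
      labels[i:(i + k - 1L)] <- g
      i <- i + k
    }
  }
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  names(labels) <- genes

  samples <- as.vector(t(outer(CONDITIONS, seq_len(config$n_replicates),
                               function(c, r) paste0(c, "_", r))))
  cond <- rep(CONDITIONS, each = config$n_replicates)

  # condition-specific fold multiplier per group label
  enriched_in <- list(WHITE = "white",
                      BEIGE_ONLY = "beige",
                      COMMON_BROWN = c("beige", "brown"),
                      CLASSICAL_ONLY = "brown",
                      UNCLASSIFIED = character(0))
  sdlog <- lognormal_sdlog(config$noise_cv)
  floor_val <- config$floor_frac * config$baseline_mean
  n_col <- length(samples)

  m <- matrix(NA_real_, nrow = config$n_genes, ncol = n_col,
              dimnames = list(genes, samples))
  for (gi in seq_len(config$n_genes)) {
    mult <- ifelse(cond %in% enriched_in[[labels[gi]]], config$fold_effect, 1)
    mu <- config$baseline_mean * mult
    noise <- if (sdlog == 0) rep(1, n_col) else
      with_seed(derive_seed(config$seed, gi),
                stats::rlnorm(n_col, meanlog = -sdlog^2 / 2, sdlog = sdlog))
    m[gi, ] <- pmax(mu * noise, floor_val)
  }

  meta <- data.frame(sample_id = samples, condition = cond,
                     stringsAsFactors = FALSE)
  list(matrix = expression_matrix(m, meta),
       truth = list(gene_labels = labels))
}

#' Configuration for the latent-factor tissue-panel simulation
#'
#' Describes a human-like multi-depot panel in which a single latent "beige
#' activity" factor (standard normal across tissues) drives beige-selective
#' genes and the common brown anchor genes, while classical-brown-selective
#' genes sit near the detection floor, independent of the factor. On the
#' log2 scale a factor-driven gene is
#' `baseline_log2 + beige_loading * factor + N(0, noise_sd)`, so the
#' population correlation between any two factor-driven genes is
#' `beige_loading^2 / (beige_loading^2 + noise_sd^2)`.
#'
#' @param n_tissues Number of tissue samples.
#' @param marker_sets Named list of disjoint gene-id vectors (the competing
#'   marker sets).
#' @param anchor_genes Common brown-fat anchor genes (PRDM16/PGC1A role);
#'   must not appear inside any marker set.
#' @param factor_sets Names of the marker sets whose genes load on the latent
#'   factor; defaults to every set except one named `"classical"`.
#' @param beige_loading Loading of the factor on factor-driven genes and (by
#'   default) anchors, in `[0, 1]`.
#' @param anchor_loading Loading for the anchor genes; defaults to
#'   `beige_loading`. Set to 0 for null panels in which the anchor is
#'   independent of every set.
#' @param classical_level Log2 mean of non-factor ("floor") genes; default
#'   `baseline_log2 - 7`, i.e. under 1% of baseline, emulating
#'   near-undetectable expression.
#' @param noise_sd Residual sd on the log2 scale (> 0).
#' @param baseline_log2 Log2 mean of factor-driven genes and anchors.
#' @param floor_frac Detection floor as a fraction of `2^baseline_log2`.
#' @param seed Integer seed.
#' @return A list of class `tissue_panel_sim_config`.
#' @export
tissue_panel_sim_config <- function(n_tissues = 15,
                                    marker_sets = list(
                                      beige = sprintf("BG%02d", 1:8),
                                      classical = sprintf("CL%02d", 1:8)),
                                    anchor_genes = c("ANCH1", "ANCH2"),
                                    factor_sets = NULL,
                                    beige_loading = 0.9,
                                    anchor_loading = NULL,
                                    classical_level = NULL,
                                    noise_sd = 0.3,
                                    baseline_log2 = 4,
                                    floor_frac = 1e-3,
                                    seed = 1L) {
  stopifnot(is.list(marker_sets), !is.null(names(marker_sets)))
  all_members <- unlist(marker_sets, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("marker sets must be disjoint", call. = FALSE)
  }
  if (length(intersect(anchor_genes, all_members)) > 0) {
    stop("anchor genes must not belong to a marker set", call. = FALSE)
  }
  if (beige_loading < 0 || beige_loading > 1) {
    stop("beige_loading must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (is.null(factor_sets)) factor_sets <- setdiff(names(marker_sets), "classical")
  if (!all(factor_sets %in% names(marker_sets))) {
    stop("factor_sets must name elements of marker_sets", call. = FALSE)
  }
  if (is.null(anchor_loading)) anchor_loading <- beige_loading
  if (is.null(classical_level)) classical_level <- baseline_log2 - 7
  structure(list(n_tissues = as.integer(n_tissues),
                 marker_sets = marker_sets,
                 anchor_genes = anchor_genes,
                 factor_sets = factor_sets,
                 beige_loading = beige_loading,
                 anchor_loading = anchor_loading,
                 classical_level = classical_level,
                 noise_sd = noise_sd,
                 baseline_log2 = baseline_log2,
                 floor_frac = floor_frac,
                 seed = as.integer(seed)),
            class = "tissue_panel_sim_config")
}

#' Simulate a multi-depot tissue panel with one latent beige-activity factor
#'
#' @param config A [tissue_panel_sim_config()].
#' @return A list with `matrix` (a `SummarizedExperiment`; colData columns
#'   `tissue` and `patient`) and `truth` (list with `gene_labels` — anchors
#'   `COMMON_BROWN`, factor-set genes `BEIGE_ONLY`, floor genes
#'   `CLASSICAL_ONLY` — and `tissue_factor`, the latent factor values).
#' @export
generate_tissue_panel <- function(config) {
  stopifnot(inherits(config, "tissue_panel_sim_config"))
  n <- config$n_tissues
  tissues <- sprintf("tissue_%02d", seq_len(n))
  f <- with_seed(config$seed, stats::rnorm(n))
  names(f) <- tissues

  genes <- c(config$anchor_genes, unlist(config$marker_sets, use.names = FALSE))
  set_of <- rep(names(config$marker_sets),
                lengths(config$marker_sets))
  names(set_of) <- unlist(config$marker_sets, use.names = FALSE)

  labels <- vapply(genes, function(g) {
    if (g %in% config$anchor_genes) return("COMMON_BROWN")
    if (set_of[[g]] %in% config$factor_sets) "BEIGE_ONLY" else "CLASSICAL_ONLY"
  }, character(1))

  floor_val <- config$floor_frac * 2^config$baseline_log2
  m <- matrix(NA_real_, nrow = length(genes), ncol = n,
              dimnames = list(genes, tissues))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    if (g %in% config$anchor_genes) {
      lambda <- config$anchor_loading
      mu <- config$baseline_log2
    } else if (set_of[[g]] %in% config$factor_sets) {
      lambda <- config$beige_loading
      mu <- config$baseline_log2
    } else {
      lambda <- 0
      mu <- config$classical_level
    }
    eps <- with_seed(derive_seed(config$seed, gi),
                     stats::rnorm(n, sd = config$noise_sd))
    m[gi, ] <- pmax(2^(mu + lambda * f + eps), floor_val)
  }

  meta <- data.frame(sample_id = tissues, tissue = tissues,
                     patient = rep_len(LETTERS, n),
                     stringsAsFactors = FALSE)
  list(matrix = expression_matrix(m, meta),
       truth = list(gene_labels = labels, tissue_factor = f))
}

#' Simulate a qPCR cycle-threshold table
#'
#' Produces target and reference (endogenous-control) Ct values consistent
#' with perfect amplification efficiency: the target Ct sits
#' `log2(true relative expression)` cycles below the reference Ct, plus
#' optional Gaussian measurement noise on each Ct.
#'
#' @param n_samples Number of samples.
#' @param true_rel_expression Per-sample true relative expression (> 0),
#'   recycled to `n_samples`.
#' @param reference_ct_mean Mean reference-gene Ct (cycles).
#' @param ct_noise_sd Gaussian sd of Ct measurement noise (cycles).
#' @param seed Integer seed.
#' @param target_gene,reference_gene Gene names used in the table.
#' @return A long-format `data.frame` with columns `sample_id`, `gene`, `ct`.
#' @export
generate_ct_table <- function(n_samples, true_rel_expression,
                              reference_ct_mean = 20, ct_noise_sd = 0,
                              seed = 1L, target_gene = "target",
                              reference_gene = "TBP") {
  rel <- rep_len(true_rel_expression, n_samples)
  if (any(!is.finite(rel)) || any(rel <= 0)) {
    stop("true_rel_expression must be positive and finite", call. = FALSE)
  }
  samples <- sprintf("S%02d", seq_len(n_samples))
  noise <- with_seed(seed, matrix(stats::rnorm(2 * n_samples, sd = ct_noise_sd),
                                  ncol = 2))
  ct_ref <- reference_ct_mean + noise[, 1]
  ct_tgt <- ct_ref - log2(rel) + noise[, 2]
  data.frame(sample_id = rep(samples, 2),
             gene = rep(c(target_gene, reference_gene), each = n_samples),
             ct = c(ct_tgt, ct_ref),
             stringsAsFactors = FALSE)
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element returned by a generator.
#' @param path Output path.
#' @export
write_ground_truth_json <- function(truth, path) {
  # named vectors become JSON objects so gene/tissue ids survive the round trip
  truth <- lapply(truth, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
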