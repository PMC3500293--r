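# Presentation artifacts as data: min-max-scaled heatmap matrices, 95%
# density ellipses for scatter panels, and a pipeline orchestrator that
# writes every stage's output plus a reproducibility manifest. Rendering is
# cosmetic and out of scope; the exported files are the surface.

#' Export a heatmap-ready scaled matrix
#'
#' Min-max scales expression to \[0, 1\] either over the whole matrix
#' (`scope = "global"` — all genes on the identical scale, the convention
#' for cross-gene panels) or per gene (`scope = "per_gene"`). A constant
#' scope maps to 0.5 by convention. The returned metadata (observed min/max,
#' transform, pseudocount) suffices to invert the scaling.
#'
#' @param se `SummarizedExperiment` or matrix.
#' @param order Optional `hclust` object (or character vector) giving the
#'   row order; default keeps input order.
#' @param scope `"global"` or `"per_gene"`.
#' @param transform `"linear"` or `"log"` (log2 with half-minimum
#'   pseudocount).
#' @param color_scheme Stored as metadata only (e.g. `"green-black-red"`).
#' @return Object of class `heatmap_export`: list with `values` (scaled
#'   matrix) and `meta`.
#' @export
export_heatmap <- function(se, order = NULL,
                           scope = c("global", "per_gene"),
                           transform = c("linear", "log"),
                           color_scheme = "green-black-red") {
  scope <- match.arg(scope)
  transform <- match.arg(transform)
  m <- exprs_of(se)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty matrix", call. = FALSE)
  if (!is.null(order)) {
    ord <- if (inherits(order, "hclust")) order$labels[order$order] else order
    m <- m[ord, , drop = FALSE]
  }
  pc <- NA_real_
  if (transform == "log") {
    pos <- m[m > 0]
    pc <- if (length(pos) > 0) min(pos) / 2 else .Machine$double.eps
    m <- log2(m + pc)
  }
  scale01 <- function(x) {
    lo <- min(x, na.rm = TRUE)
    hi <- max(x, na.rm = TRUE)
    if (hi == lo) {
      x[] <- 0.5
      attr(x, "range") <- c(lo, hi)
      return(x)
    }
    out <- (x - lo) / (hi - lo)
    attr(out, "range") <- c(lo, hi)
    out
  }
  if (scope == "global") {
    scaled <- scale01(m)
    rng <- matrix(attr(scaled, "range"), nrow = 1,
                  dimnames = list(NULL, c("min", "max")))
    attr(scaled, "range") <- NULL
  } else {
    rows <- lapply(rownames(m), function(g) scale01(m[g, ]))
    scaled <- do.call(rbind, lapply(rows, as.vector))
    dimnames(scaled) <- dimnames(m)
    rng <- do.call(rbind, lapply(rows, attr, "range"))
    dimnames(rng) <- list(rownames(m), c("min", "max"))
  }
  structure(list(values = scaled,
                 meta = list(scope = scope, transform = transform,
                             pseudocount = pc, range = rng,
                             color_scheme = color_scheme,
                             row_order = rownames(scaled))),
            class = "heatmap_export")
}

#' Invert a heatmap export back to the original values
#'
#' @param hx A `heatmap_export`.
#' @return Matrix on the original (pre-scaling, pre-transform) scale.
#' @export
invert_heatmap <- function(hx) {
  v <- hx$values
  rng <- hx$meta$range
  if (hx$meta$scope == "global") {
    lo <- rng[1, "min"]
    hi <- rng[1, "max"]
    m <- if (hi == lo) matrix(lo, nrow(v), ncol(v), dimnames = dimnames(v))
         else v * (hi - lo) + lo
  } else {
    m <- v
    for (g in rownames(v)) {
      lo <- rng[g, "min"]
      hi <- rng[g, "max"]
      m[g, ] <- if (hi == lo) lo else v[g, ] * (hi - lo) + lo
    }
  }
  if (hx$meta$transform == "log") m <- 2^m - hx$meta$pseudocount
  m
}

#' Bivariate normal density ellipse
#'
#' The ellipse `{v : (v - mu)' Sigma^-1 (v - mu) <= q}` with `q` the
#' chi-square(2) quantile at `level`, summarizing a scatter panel. Axis
#' half-lengths come from the eigen-decomposition of the sample covariance.
#'
#' @param x,y Paired values (>= 3 complete pairs).
#' @param level Coverage level in (0, 1); 0.95 by default.
#' @return Object of class `density_ellipse`: `center`, `cov`, `level`,
#'   `q` (chi-square quantile), `axes` (half-lengths), `angle` (radians,
#'   major axis vs x), `degenerate` flag (singular covariance).
#' @export
density_ellipse <- function(x, y, level = 0.95) {
  stopifnot(level > 0, level < 1)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  mu <- c(x = mean(x), y = mean(y))
  S <- stats::cov(cbind(x, y))
  q <- stats::qchisq(level, df = 2)
  ev <- eigen(S, symmetric = TRUE)
  degenerate <- ev$values[2] <= .Machine$double.eps * max(1, ev$values[1])
  axes <- sqrt(pmax(ev$values, 0) * q)
  angle <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  structure(list(center = mu, cov = S, level = level, q = q,
                 axes = axes, angle = angle, n = length(x),
                 degenerate = degenerate),
            class = "density_ellipse")
}

#' Run the full marker-concordance pipeline
#'
#' Orchestrates: optional simulation of the cell-type profiles and the
#' tissue panel (or reading them from TSV), marker-group discovery, outlier
#' screening, the pairwise correlation matrix and dendrogram, gene-set
#' correlations of each anchor against every marker set, pairwise verdicts,
#' heatmap export, and a machine-readable run manifest capturing every
#' seed, threshold and mode. Reruns with the same config are byte-identical.
#'
#' @param config Nested list; recognized entries:
#'   \describe{
#'     \item{profiles_sim}{[cell_type_sim_config()] for the three-condition
#'       stage, or `NULL` to skip discovery.}
#'     \item{profiles_expr,profiles_meta}{TSV paths, alternative to
#'       `profiles_sim`.}
#'     \item{thresholds}{[de_thresholds()] (default thresholds otherwise).}
#'     \item{panel_sim}{[tissue_panel_sim_config()] for the tissue stage, or
#'       `NULL` to skip.}
#'     \item{panel_expr,panel_meta,panel_sets_gmt,panel_anchors}{file-based
#'       alternative to `panel_sim`.}
#'     \item{max_outlier_fraction}{gene-exclusion threshold (default 0.2).}
#'     \item{se_mode}{`"conservative"` (default) or `"independent"`.}
#'     \item{log2_transform}{correlate on log2 scale (default `FALSE`).}
#'   }
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "beigesig",
                   version = as.character(utils::packageVersion("beigesig")),
                   stages = list())
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  thresholds <- if (!is.null(config$thresholds)) config$thresholds else de_thresholds()
  max_frac <- if (!is.null(config$max_outlier_fraction)) config$max_outlier_fraction else 0.2
  se_mode <- if (!is.null(config$se_mode)) config$se_mode else "conservative"
  log2_transform <- isTRUE(config$log2_transform)

  # --- stage 1: three-condition profiles + marker discovery -------------
  profiles <- NULL
  if (!is.null(config$profiles_sim)) {
    profiles <- stage("simulate_profiles",
                      generate_cell_type_profiles(config$profiles_sim))
    write_expression_tsv(profiles$matrix,
                         file.path(out_dir, "profiles_expression.tsv"),
                         file.path(out_dir, "profiles_metadata.tsv"))
    write_ground_truth_json(profiles$truth,
                            file.path(out_dir, "profiles_truth.json"))
    manifest$stages$simulate_profiles <- unclass(config$profiles_sim)
    profiles_se <- profiles$matrix
  } else if (!is.null(config$profiles_expr)) {
    profiles_se <- stage("read_profiles",
                         read_expression_tsv(config$profiles_expr,
                                             config$profiles_meta))
    manifest$stages$read_profiles <- list(expr = config$profiles_expr,
                                          meta = config$profiles_meta)
  } else {
    profiles_se <- NULL
  }
  if (!is.null(profiles_se)) {
    mg <- stage("discover", discover_marker_groups(profiles_se, thresholds))
    utils::write.table(mg$assignments,
                       file.path(out_dir, "marker_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(mg$counts),
                         file.path(out_dir, "group_counts.json"),
                         auto_unbox = TRUE)
    sets <- marker_sets_from_groups(mg)
    write_gmt(sets[lengths(sets) > 0],
              file.path(out_dir, "marker_sets.gmt"))
    manifest$stages$discover <- unclass(thresholds)
    results$marker_groups <- mg
  }

  # --- stage 2: tissue panel concordance --------------------------------
  panel_se <- NULL
  sets <- NULL
  anchors <- NULL
  if (!is.null(config$panel_sim)) {
    panel <- stage("simulate_panel", generate_tissue_panel(config$panel_sim))
    write_expression_tsv(panel$matrix,
                         file.path(out_dir, "panel_expression.tsv"),
                         file.path(out_dir, "panel_metadata.tsv"))
    write_ground_truth_json(panel$truth,
                            file.path(out_dir, "panel_truth.json"))
    write_gmt(config$panel_sim$marker_sets,
              file.path(out_dir, "panel_marker_sets.gmt"))
    panel_se <- panel$matrix
    sets <- config$panel_sim$marker_sets
    anchors <- config$panel_sim$anchor_genes
    manifest$stages$simulate_panel <-
      unclass(config$panel_sim)[setdiff(names(config$panel_sim), "marker_sets")]
    manifest$stages$simulate_panel$marker_sets <- config$panel_sim$marker_sets
  } else if (!is.null(config$panel_expr)) {
    panel_se <- stage("read_panel",
                      read_expression_tsv(config$panel_expr, config$panel_meta))
    sets <- stage("read_sets", read_gmt(config$panel_sets_gmt))
    anchors <- config$panel_anchors
    manifest$stages$read_panel <- list(expr = config$panel_expr,
                                       sets = config$panel_sets_gmt,
                                       anchors = anchors)
  }

  if (!is.null(panel_se)) {
    filt <- stage("outlier_filter",
                  filter_genes_by_outliers(panel_se, max_frac))
    utils::write.table(filt$report,
                       file.path(out_dir, "outlier_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    kept <- rownames(exprs_of(filt$matrix))
    sets_kept <- lapply(sets, intersect, y = kept)
    anchors_kept <- intersect(anchors, kept)
    if (length(anchors_kept) == 0) {
      stop("pipeline stage 'concordance' failed: no anchor gene survived ",
           "outlier screening", call. = FALSE)
    }

    cm <- stage("correlation_matrix",
                correlation_matrix(filt$matrix,
                                   genes = unlist(sets_kept, use.names = FALSE),
                                   log2_transform = log2_transform))
    utils::write.table(
      data.frame(gene_id = rownames(cm$r), cm$r, check.names = FALSE),
      file.path(out_dir, "correlation_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!any(is.na(cm$r))) {
      hc <- stage("cluster", hierarchical_cluster(cm))
      write_dendrogram_newick(hc, file.path(out_dir, "dendrogram.nwk"))
      results$dendrogram <- hc
    }

    gsc <- list()
    verdicts <- list()
    for (anchor in anchors_kept) {
      per_set <- lapply(names(sets_kept), function(s) {
        gene_set_correlation(anchor, sets_kept[[s]], filt$matrix,
                             se_mode = se_mode,
                             log2_transform = log2_transform, set_label = s)
      })
      names(per_set) <- names(sets_kept)
      gsc[[anchor]] <- per_set
      combos <- utils::combn(names(sets_kept), 2, simplify = FALSE)
      verdicts[[anchor]] <- lapply(combos, function(pr) {
        compare_set_correlations(per_set[[pr[1]]], per_set[[pr[2]]])
      })
    }
    jsonlite::write_json(
      lapply(gsc, function(per_set) lapply(per_set, function(g) {
        list(anchor = g$anchor, set = g$set_label, r_bar = g$r_bar,
             z_bar = g$z_bar, se_z = g$se_z, se_mode = g$se_mode,
             n_eff = g$n_eff,
             members = g$members[, c("gene", "r", "n", "flag")])
      })),
      file.path(out_dir, "gene_set_correlations.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      lapply(verdicts, function(vs) lapply(vs, unclass)),
      file.path(out_dir, "verdicts.json"), auto_unbox = TRUE, digits = NA)

    hx <- stage("heatmap", export_heatmap(filt$matrix, scope = "global",
                                          transform = "log"))
    utils::write.table(
      data.frame(gene_id = rownames(hx$values), hx$values, check.names = FALSE),
      file.path(out_dir, "heatmap.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(
      list(scope = hx$meta$scope, transform = hx$meta$transform,
           pseudocount = hx$meta$pseudocount,
           color_scheme = hx$meta$color_scheme,
           range = as.data.frame(hx$meta$range)),
      file.path(out_dir, "heatmap_meta.json"), auto_unbox = TRUE, digits = NA)

    manifest$stages$concordance <- list(max_outlier_fraction = max_frac,
                                        se_mode = se_mode,
                                        log2_transform = log2_transform,
                                        anchors = anchors_kept)
    results$gene_set_correlations <- gsc
    results$verdicts <- verdicts
    results$outliers <- filt$report
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
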