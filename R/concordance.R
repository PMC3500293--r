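# Gene-set concordance: Pearson correlation of an anchor gene with every
# member of a marker set, integrated through Fisher's z into a single
# gene-set correlation coefficient, and a Z-test comparing two competing
# sets. Tukey-whisker outlier screening and average-linkage clustering
# round out the stage.

#' Pearson correlation on complete pairs
#'
#' @param x,y Paired numeric vectors; pairs with a missing value in either
#'   are dropped.
#' @return List with `r`, `n` (complete pairs) and `flag`: `"ok"`,
#'   `"insufficient_n"` (fewer than 3 complete pairs) or `"zero_variance"`
#'   (degenerate input; such correlations are excluded downstream).
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    return(list(r = NA_real_, n = n, flag = "insufficient_n"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = n, flag = "zero_variance"))
  }
  list(r = stats::cor(x, y), n = n, flag = "ok")
}

#' Fisher z-transformation and its inverse
#'
#' `fisher_z()` is the variance-stabilizing transform
#' `z = atanh(r) = 0.5 * ln((1 + r) / (1 - r))`, with sampling variance
#' approximately `1 / (n - 3)`. Correlations at exactly +/-1 (duplicate-like
#' genes) are clamped to `+/-(1 - 1e-6)` with a warning rather than mapped
#' to infinity.
#'
#' @param r Correlation(s) with `|r| <= 1`.
#' @param z Fisher z value(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("|r| > 1 is outside the correlation domain", call. = FALSE)
  }
  hit <- !is.na(r) & abs(r) == 1
  if (any(hit)) {
    warning("|r| = 1 clamped to 1 - 1e-6 before Fisher transform")
    r[hit] <- sign(r[hit]) * (1 - 1e-6)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Gene-set correlation coefficient
#'
#' Correlates the anchor gene with each member of a marker set, transforms
#' each Pearson r to Fisher z, averages with inverse-variance weights
#' `w_i = n_i - 3`, and back-transforms: `r_bar = tanh(sum(w z) / sum(w))`.
#' With a complete panel all weights are equal and the weighted average is
#' the plain mean.
#'
#' Two standard errors for `z_bar` are available. `"conservative"` (default)
#' treats the set as one effective correlated measurement,
#' `SE = 1 / sqrt(n_eff - 3)` with `n_eff` the weight-averaged member n —
#' honest because member genes share the same samples and typically a latent
#' factor. `"independent"` treats members as independent estimates,
#' `SE = 1 / sqrt(sum(w))`, anti-conservative under within-set correlation.
#'
#' @param anchor Anchor gene id (removed from the set if present).
#' @param set Character vector of member gene ids.
#' @param se `SummarizedExperiment` (or matrix) of expression over one
#'   sample panel.
#' @param se_mode `"conservative"` or `"independent"`.
#' @param log2_transform Correlate on `log2(x + pseudocount)` instead of the
#'   linear scale; pseudocount = half the smallest positive value.
#' @return Object of class `gene_set_correlation`: anchor, set label (from
#'   `set_label`), per-member table (r, n, z, weight, flag), `z_bar`,
#'   `r_bar`, `se_z`, `se_mode`, `n_eff`, sample ids.
#' @param set_label Optional name recorded for the set.
#' @export
gene_set_correlation <- function(anchor, set, se,
                                 se_mode = c("conservative", "independent"),
                                 log2_transform = FALSE,
                                 set_label = NULL) {
  se_mode <- match.arg(se_mode)
  m <- exprs_of(se)
  if (!anchor %in% rownames(m)) {
    stop("anchor gene '", anchor, "' not in matrix", call. = FALSE)
  }
  members <- setdiff(intersect(set, rownames(m)), anchor)
  if (length(members) == 0) {
    stop("empty usable gene set for anchor '", anchor, "'", call. = FALSE)
  }
  if (log2_transform) {
    pos <- m[m > 0]
    pc <- if (length(pos) > 0) min(pos) / 2 else .Machine$double.eps
    m <- log2(m + pc)
  }
  av <- m[anchor, ]
  res <- lapply(members, function(g) pearson_r(av, m[g, ]))
  tab <- data.frame(
    gene = members,
    r = vapply(res, `[[`, numeric(1), "r"),
    n = vapply(res, `[[`, numeric(1), "n"),
    flag = vapply(res, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE
  )
  usable <- tab$flag == "ok" & tab$n >= 4  # need positive weight n - 3
  if (!any(usable)) {
    stop("no usable members (all flagged or n < 4) for anchor '", anchor, "'",
         call. = FALSE)
  }
  tab$z <- NA_real_
  tab$z[usable] <- fisher_z(tab$r[usable])
  tab$weight <- ifelse(usable, tab$n - 3, NA_real_)

  w <- tab$weight[usable]
  z <- tab$z[usable]
  z_bar <- sum(w * z) / sum(w)
  n_eff <- sum(w * tab$n[usable]) / sum(w)
  se_z <- switch(se_mode,
                 conservative = 1 / sqrt(n_eff - 3),
                 independent = 1 / sqrt(sum(w)))
  structure(list(anchor = anchor,
                 set_label = if (is.null(set_label)) NA_character_ else set_label,
                 members = tab,
                 n_used = sum(usable),
                 z_bar = z_bar,
                 r_bar = inverse_fisher_z(z_bar),
                 se_z = se_z,
                 se_mode = se_mode,
                 n_eff = n_eff,
                 samples = colnames(m)),
            class = "gene_set_correlation")
}

#' @export
print.gene_set_correlation <- function(x, ...) {
  cat(sprintf(
    "Gene-set correlation: anchor %s vs set %s (%d genes)\n  r_bar = %.4f (z_bar = %.4f, SE = %.4f, %s mode, n_eff = %.1f)\n",
    x$anchor, x$set_label, x$n_used, x$r_bar, x$z_bar, x$se_z, x$se_mode,
    x$n_eff))
  invisible(x)
}

#' Compare two gene-set correlations by Z-test
#'
#' Tests whether the anchor's integrated correlation with set A differs from
#' that with set B: `Z = (z_bar_A - z_bar_B) / sqrt(SE_A^2 + SE_B^2)`,
#' two-sided p from the standard normal. The two integrated coefficients are
#' treated as independent; the shared-sample dependence caveat is recorded in
#' the verdict.
#'
#' @param a,b `gene_set_correlation` objects computed against the same
#'   anchor on the same sample panel.
#' @return Object of class `concordance_verdict`: `Z`, `p`, `winner` (the
#'   set label with higher `r_bar`), both coefficients, SE mode.
#' @export
compare_set_correlations <- function(a, b) {
  stopifnot(inherits(a, "gene_set_correlation"),
            inherits(b, "gene_set_correlation"))
  if (!identical(a$anchor, b$anchor)) {
    stop("both sets must be scored against the same anchor", call. = FALSE)
  }
  if (!identical(a$samples, b$samples)) {
    stop("both sets must be scored on the same sample panel", call. = FALSE)
  }
  if (!identical(a$se_mode, b$se_mode)) {
    stop("SE modes differ between the two sets", call. = FALSE)
  }
  Z <- (a$z_bar - b$z_bar) / sqrt(a$se_z^2 + b$se_z^2)
  p <- 2 * stats::pnorm(-abs(Z))
  winner <- if (a$r_bar >= b$r_bar) a$set_label else b$set_label
  structure(list(anchor = a$anchor,
                 set_a = a$set_label, set_b = b$set_label,
                 r_bar_a = a$r_bar, r_bar_b = b$r_bar,
                 z_bar_a = a$z_bar, z_bar_b = b$z_bar,
                 Z = Z, p = p, winner = winner,
                 se_mode = a$se_mode,
                 note = "sets treated as independent despite shared samples"),
            class = "concordance_verdict")
}

#' @export
print.concordance_verdict <- function(x, ...) {
  cat(sprintf(
    "Concordance verdict for anchor %s:\n  %s r_bar = %.4f vs %s r_bar = %.4f\n  Z = %.3f, two-sided p = %.4g (%s SE) -> winner: %s\n",
    x$anchor, x$set_a, x$r_bar_a, x$set_b, x$r_bar_b, x$Z, x$p, x$se_mode,
    x$winner))
  invisible(x)
}

#' Tukey box-and-whisker outlier detection
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). The whisker edges are the outermost data
#' points within `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`; values strictly beyond the
#' whisker fences are flagged as outliers.
#'
#' @param values Numeric vector (>= 4 finite values for a report; fewer
#'   yields an `insufficient_n` flag and no outlier calls).
#' @return List with `q1`, `q3`, `iqr`, `lower_fence`, `upper_fence`,
#'   `whisker_low`, `whisker_high`, `outliers` (indices into `values`, or
#'   their names), `n`, `flag`.
#' @export
detect_outliers <- function(values) {
  finite <- which(is.finite(values))
  v <- values[finite]
  if (length(v) < 4) {
    return(list(q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                lower_fence = NA_real_, upper_fence = NA_real_,
                whisker_low = NA_real_, whisker_high = NA_real_,
                outliers = integer(0), n = length(v),
                flag = "insufficient_n"))
  }
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  inside <- v >= lo & v <= hi
  out_idx <- finite[!inside]
  if (!is.null(names(values)) && length(out_idx) > 0) {
    out <- names(values)[out_idx]
  } else {
    out <- out_idx
  }
  list(q1 = q[1], q3 = q[2], iqr = iqr,
       lower_fence = lo, upper_fence = hi,
       whisker_low = min(v[inside]), whisker_high = max(v[inside]),
       outliers = out, n = length(v), flag = "ok")
}

#' Screen genes by outlier burden
#'
#' Applies [detect_outliers()] to each gene's values across samples and
#' excludes genes whose flagged-sample fraction exceeds
#' `max_outlier_fraction` — the screening that removed UCP1-like genes with
#' too many extreme samples from the correlation analysis.
#'
#' @param se `SummarizedExperiment` or matrix.
#' @param max_outlier_fraction Exclusion threshold in `[0, 1]` (default 0.2);
#'   a gene is dropped when its outlier fraction is strictly greater.
#' @return List with `matrix` (retained genes, same container type) and
#'   `report` (data.frame: gene, n, n_outliers, outlier_fraction, quartiles,
#'   fences, excluded flag).
#' @export
filter_genes_by_outliers <- function(se, max_outlier_fraction = 0.2) {
  stopifnot(max_outlier_fraction >= 0, max_outlier_fraction <= 1)
  m <- exprs_of(se)
  rep_rows <- lapply(rownames(m), function(g) {
    o <- detect_outliers(m[g, ])
    frac <- if (o$n > 0) length(o$outliers) / o$n else 0
    data.frame(gene = g, n = o$n, n_outliers = length(o$outliers),
               outlier_fraction = frac, q1 = o$q1, q3 = o$q3,
               lower_fence = o$lower_fence, upper_fence = o$upper_fence,
               excluded = frac > max_outlier_fraction,
               flag = o$flag, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  keep <- report$gene[!report$excluded]
  filtered <- if (methods::is(se, "SummarizedExperiment")) {
    se[keep, ]
  } else {
    m[keep, , drop = FALSE]
  }
  list(matrix = filtered, report = report)
}

#' Pairwise Pearson correlation matrix
#'
#' All pairwise correlations among the chosen genes, computed on pairwise
#' complete samples, with the per-pair n retained. Undefined correlations
#' (zero variance, n < 3) propagate as `NA` cells.
#'
#' @param se `SummarizedExperiment` or matrix.
#' @param genes Genes to correlate (default: all rows).
#' @param log2_transform Correlate on log2 with a half-minimum pseudocount.
#' @return Object of class `correlation_matrix`: list with symmetric `r`
#'   and `n` matrices (unit diagonal in `r`).
#' @export
correlation_matrix <- function(se, genes = NULL, log2_transform = FALSE) {
  m <- exprs_of(se)
  if (is.null(genes)) genes <- rownames(m)
  miss <- setdiff(genes, rownames(m))
  if (length(miss) > 0) {
    stop("genes not in matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- m[genes, , drop = FALSE]
  if (ncol(m) < 3) stop("need >= 3 samples", call. = FALSE)
  if (log2_transform) {
    pos <- m[m > 0]
    pc <- if (length(pos) > 0) min(pos) / 2 else .Machine$double.eps
    m <- log2(m + pc)
  }
  k <- length(genes)
  r <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
  n <- matrix(0L, k, k, dimnames = list(genes, genes))
  diag(r) <- 1
  diag(n) <- rowSums(is.finite(m))
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        pr <- pearson_r(m[i, ], m[j, ])
        if (pr$flag == "ok") r[i, j] <- r[j, i] <- pr$r
        n[i, j] <- n[j, i] <- pr$n
      }
    }
  }
  structure(list(r = r, n = n), class = "correlation_matrix")
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Clusters genes (or samples) with UPGMA / average linkage on the distance
#' `d = 1 - r`. Items are ordered lexicographically before clustering so
#' tie-breaking is deterministic.
#'
#' @param cm A `correlation_matrix` (complete, no `NA` off-diagonals) or a
#'   plain symmetric correlation matrix.
#' @return An `hclust` object (heights are average-linkage `1 - r`
#'   distances).
#' @export
hierarchical_cluster <- function(cm) {
  r <- if (inherits(cm, "correlation_matrix")) cm$r else as.matrix(cm)
  if (any(is.na(r))) {
    stop("correlation matrix has missing cells; filter genes first",
         call. = FALSE)
  }
  ord <- order(rownames(r))
  r <- r[ord, ord]
  d <- stats::as.dist(1 - r)
  stats::hclust(d, method = "average")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights, so the written tree
#' preserves the average-linkage distances.
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), path)
  invisible(path)
}
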