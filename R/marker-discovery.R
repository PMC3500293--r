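# Differential-expression filter and four-group enrichment classifier for a
# three-condition (white / beige / brown) experiment.

#' Differential-expression thresholds
#'
#' @param min_fold Minimum linear-scale fold change (> 1); ties at exactly
#'   `min_fold` are included.
#' @param max_p Maximum two-sided p-value (ties included).
#' @param test_variant `"student"` (equal-variance, classic microarray
#'   practice, the default) or `"welch"`.
#' @param p_adjust `"none"` (raw p-values, the default) or `"BH"`
#'   (Benjamini-Hochberg across genes, per contrast).
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(min_fold = 2, max_p = 0.05,
                          test_variant = c("student", "welch"),
                          p_adjust = c("none", "BH")) {
  if (min_fold <= 1) stop("min_fold must be > 1", call. = FALSE)
  if (max_p <= 0 || max_p >= 1) stop("max_p must be in (0, 1)", call. = FALSE)
  structure(list(min_fold = min_fold, max_p = max_p,
                 test_variant = match.arg(test_variant),
                 p_adjust = match.arg(p_adjust)),
            class = "de_thresholds")
}

#' Two-sided unpaired t-test p-value
#'
#' Degenerate inputs follow fixed conventions: zero variance in both groups
#' with equal means gives p = 1 (no evidence of difference), zero variance
#' with unequal means gives p = 0 (infinite t).
#'
#' @param x,y Numeric replicate vectors, each with >= 2 finite values.
#' @param variant `"student"` (pooled variance) or `"welch"`
#'   (Welch-Satterthwaite).
#' @return Two-sided p-value in \[0, 1\].
#' @export
unpaired_t_test <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  d <- mean(x) - mean(y)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- if (se2 > 0) {
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
      NA_real_
    }
  }
  if (se2 == 0) {
    return(if (d == 0) 1 else 0)
  }
  2 * stats::pt(-abs(d / sqrt(se2)), df)
}

#' Linear-scale fold change
#'
#' @param mean_a,mean_b Positive condition means (after epsilon flooring).
#' @return `mean_a / mean_b`.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(!is.finite(c(mean_a, mean_b))) || any(c(mean_a, mean_b) <= 0)) {
    stop("means must be positive and finite (apply flooring first)",
         call. = FALSE)
  }
  mean_a / mean_b
}

#' Classify one gene into an enrichment group
#'
#' Applies the conjunctive enrichment rule: a single-condition label
#' (`WHITE`, `BEIGE_ONLY`, `CLASSICAL_ONLY`) requires that condition's mean
#' to be at least `min_fold` times each other condition's mean with both
#' contrasts significant; `COMMON_BROWN` requires beige and brown each
#' enriched over white with significant contrasts while beige and brown
#' differ by less than `min_fold` in either direction. Anything else is
#' `UNCLASSIFIED`.
#'
#' @param condition_means Named numeric: `white`, `beige`, `brown` (positive).
#' @param pairwise_p Named numeric: `beige_white`, `brown_white`,
#'   `beige_brown` (two-sided p-values).
#' @param thresholds A [de_thresholds()].
#' @return One label among `WHITE`, `BEIGE_ONLY`, `COMMON_BROWN`,
#'   `CLASSICAL_ONLY`, `UNCLASSIFIED`.
#' @export
classify_gene <- function(condition_means, pairwise_p,
                          thresholds = de_thresholds()) {
  mw <- condition_means[["white"]]
  mb <- condition_means[["beige"]]
  mr <- condition_means[["brown"]]
  if (any(c(mw, mb, mr) <= 0)) stop("means must be floored above 0", call. = FALSE)
  p_bw <- pairwise_p[["beige_white"]]
  p_rw <- pairwise_p[["brown_white"]]
  p_br <- pairwise_p[["beige_brown"]]
  mf <- thresholds$min_fold
  mp <- thresholds$max_p
  enr <- function(a, b, p) a >= mf * b && p <= mp

  if (enr(mw, mb, p_bw) && enr(mw, mr, p_rw)) return("WHITE")
  if (enr(mb, mw, p_bw) && enr(mb, mr, p_br)) return("BEIGE_ONLY")
  if (enr(mr, mw, p_rw) && enr(mr, mb, p_br)) return("CLASSICAL_ONLY")
  if (enr(mb, mw, p_bw) && enr(mr, mw, p_rw) &&
      mb < mf * mr && mr < mf * mb) {
    return("COMMON_BROWN")
  }
  "UNCLASSIFIED"
}

#' Discover marker groups from a three-condition expression matrix
#'
#' Floors the matrix at a small epsilon, computes per-condition means, the
#' three pairwise fold changes and unpaired t-test p-values per gene, keeps
#' genes passing the differential-expression filter (any pairwise fold >=
#' `min_fold` in either direction with that contrast's p <= `max_p`), and
#' classifies each kept gene with [classify_gene()].
#'
#' @param se A `SummarizedExperiment` whose colData has a `condition` column
#'   containing exactly the labels `white`, `beige`, `brown`, each with >= 2
#'   replicates.
#' @param thresholds A [de_thresholds()].
#' @param floor_eps Expression floor applied before fold computation;
#'   default half the smallest positive value in the matrix.
#' @return An object of class `marker_groups`: list with `assignments`
#'   (data.frame of gene, de flag, label, condition means, folds, p-values),
#'   `counts` (labelled counts over DE genes), `n_de`, `thresholds`,
#'   `floor_eps`.
#' @export
discover_marker_groups <- function(se, thresholds = de_thresholds(),
                                   floor_eps = NULL) {
  m <- exprs_of(se)
  cond <- SummarizedExperiment::colData(se)$condition
  if (is.null(cond)) stop("colData must have a 'condition' column", call. = FALSE)
  missing_cond <- setdiff(CONDITIONS, unique(cond))
  if (length(missing_cond) > 0) {
    stop("missing condition(s): ", paste(missing_cond, collapse = ", "),
         call. = FALSE)
  }
  reps <- table(factor(cond, levels = CONDITIONS))
  if (any(reps < 2)) {
    stop("each condition needs >= 2 replicates", call. = FALSE)
  }
  if (is.null(floor_eps)) {
    pos <- m[m > 0]
    floor_eps <- if (length(pos) > 0) min(pos) / 2 else .Machine$double.eps
  }
  m <- pmax(m, floor_eps)

  idx <- lapply(CONDITIONS, function(cc) which(cond == cc))
  names(idx) <- CONDITIONS
  means <- vapply(CONDITIONS, function(cc) rowMeans(m[, idx[[cc]], drop = FALSE]),
                  numeric(nrow(m)))
  if (nrow(m) == 1) {
    means <- matrix(means, nrow = 1, dimnames = list(rownames(m), CONDITIONS))
  }

  test_p <- function(a, b) {
    vapply(seq_len(nrow(m)), function(i) {
      unpaired_t_test(m[i, idx[[a]]], m[i, idx[[b]]],
                      variant = thresholds$test_variant)
    }, numeric(1))
  }
  p_bw <- test_p("beige", "white")
  p_rw <- test_p("brown", "white")
  p_br <- test_p("beige", "brown")
  if (thresholds$p_adjust == "BH") {
    p_bw <- stats::p.adjust(p_bw, "BH")
    p_rw <- stats::p.adjust(p_rw, "BH")
    p_br <- stats::p.adjust(p_br, "BH")
  }

  f_bw <- means[, "beige"] / means[, "white"]
  f_rw <- means[, "brown"] / means[, "white"]
  f_br <- means[, "beige"] / means[, "brown"]
  two_sided_fold <- function(f) pmax(f, 1 / f)
  de <- (two_sided_fold(f_bw) >= thresholds$min_fold & p_bw <= thresholds$max_p) |
        (two_sided_fold(f_rw) >= thresholds$min_fold & p_rw <= thresholds$max_p) |
        (two_sided_fold(f_br) >= thresholds$min_fold & p_br <= thresholds$max_p)

  label <- rep("UNCLASSIFIED", nrow(m))
  for (i in which(de)) {
    label[i] <- classify_gene(
      c(white = means[i, "white"], beige = means[i, "beige"],
        brown = means[i, "brown"]),
      c(beige_white = p_bw[i], brown_white = p_rw[i], beige_brown = p_br[i]),
      thresholds
    )
  }

  assignments <- data.frame(
    gene = rownames(m), de = de, label = label,
    mean_white = means[, "white"], mean_beige = means[, "beige"],
    mean_brown = means[, "brown"],
    fold_beige_white = f_bw, fold_brown_white = f_rw, fold_beige_brown = f_br,
    p_beige_white = p_bw, p_brown_white = p_rw, p_beige_brown = p_br,
    row.names = NULL, stringsAsFactors = FALSE
  )
  counts <- table(factor(label[de], levels = MARKER_LABELS))
  structure(list(assignments = assignments,
                 counts = counts,
                 n_de = sum(de),
                 thresholds = thresholds,
                 floor_eps = floor_eps),
            class = "marker_groups")
}

#' @export
print.marker_groups <- function(x, ...) {
  cat("Marker group discovery:", nrow(x$assignments), "genes,",
      x$n_de, "differentially expressed",
      sprintf("(fold >= %g, p <= %g, %s t-test)\n", x$thresholds$min_fold,
              x$thresholds$max_p, x$thresholds$test_variant))
  print(x$counts)
  invisible(x)
}

#' Extract per-label marker gene sets
#'
#' @param mg A `marker_groups` object.
#' @param labels Which labels to export (default: the four enrichment groups).
#' @return Named list of gene-id vectors, suitable for [write_gmt()].
#' @export
marker_sets_from_groups <- function(mg,
                                    labels = setdiff(MARKER_LABELS,
                                                     "UNCLASSIFIED")) {
  a <- mg$assignments[mg$assignments$de, , drop = FALSE]
  sets <- lapply(labels, function(l) a$gene[a$label == l])
  names(sets) <- labels
  sets
}

#' Overlap of a shared marker group with a cell type's total
#'
#' Expresses how large the common (shared brown) group is relative to the
#' total selective genes of one cell type, e.g. common / (common +
#' classical-only).
#'
#' @param count_common Shared gene count (>= 0).
#' @param count_group_total Total gene count for the cell type (> 0,
#'   >= `count_common`).
#' @return List with `percent` (exact), `rounded` (nearest integer) and
#'   `label` (e.g. `"9%"`).
#' @export
overlap_fraction <- function(count_common, count_group_total) {
  if (count_group_total <= 0) stop("total must be > 0", call. = FALSE)
  if (count_common < 0 || count_common > count_group_total) {
    stop("need 0 <= common <= total", call. = FALSE)
  }
  pct <- 100 * count_common / count_group_total
  list(percent = pct, rounded = round(pct),
       label = paste0(round(pct), "%"))
}
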