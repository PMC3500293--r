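# Independent brute-force oracles used to cross-check the implementation on
# small instances. Deliberately written as direct transcriptions of the
# rules, through different code paths than the package.

# Type-7 quantile by direct interpolation between order statistics.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  up <- ceiling(h)
  x[lo] + (h - lo) * (x[up] - x[lo])
}

# Tukey rule: values strictly outside quartile +/- 1.5 IQR.
oracle_outliers <- function(x) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  iqr <- q3 - q1
  which(x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr)
}

# Brute-force UPGMA: returns the cophenetic distance matrix implied by
# average-linkage merging on the original distances.
oracle_upgma_cophenetic <- function(d) {
  items <- rownames(d)
  clusters <- as.list(items)
  coph <- matrix(0, length(items), length(items),
                 dimnames = list(items, items))
  avg_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        h <- avg_dist(clusters[[i]], clusters[[j]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_h
    coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Independent marker-group discovery: stats::t.test per contrast, rules
# transcribed directly from their statement.
oracle_discover <- function(m, cond, min_fold = 2, max_p = 0.05) {
  pos <- m[m > 0]
  eps <- if (length(pos) > 0) min(pos) / 2 else .Machine$double.eps
  m <- pmax(m, eps)
  safe_t <- function(x, y) {
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(x, y, var.equal = TRUE)$p.value
  }
  vapply(rownames(m), function(g) {
    w <- m[g, cond == "white"]
    b <- m[g, cond == "beige"]
    r <- m[g, cond == "brown"]
    mw <- mean(w); mb <- mean(b); mr <- mean(r)
    p_bw <- safe_t(b, w); p_rw <- safe_t(r, w); p_br <- safe_t(b, r)
    de <- (max(mb / mw, mw / mb) >= min_fold && p_bw <= max_p) ||
          (max(mr / mw, mw / mr) >= min_fold && p_rw <= max_p) ||
          (max(mb / mr, mr / mb) >= min_fold && p_br <= max_p)
    if (!de) return("UNCLASSIFIED")
    if (mw >= min_fold * mb && p_bw <= max_p &&
        mw >= min_fold * mr && p_rw <= max_p) return("WHITE")
    if (mb >= min_fold * mw && p_bw <= max_p &&
        mb >= min_fold * mr && p_br <= max_p) return("BEIGE_ONLY")
    if (mr >= min_fold * mw && p_rw <= max_p &&
        mr >= min_fold * mb && p_br <= max_p) return("CLASSICAL_ONLY")
    if (mb >= min_fold * mw && p_bw <= max_p &&
        mr >= min_fold * mw && p_rw <= max_p &&
        mb < min_fold * mr && mr < min_fold * mb) return("COMMON_BROWN")
    "UNCLASSIFIED"
  }, character(1))
}

# A vector with exact Pearson correlation r against `anchor`, built from a
# component orthogonal to it.
vector_with_exact_cor <- function(anchor, r, seed = 1) {
  u <- as.vector(scale(anchor))
  set.seed(seed)
  w <- stats::rnorm(length(anchor))
  w <- stats::residuals(stats::lm(w ~ u))
  w <- w / sqrt(sum(w^2))
  u <- u / sqrt(sum(u^2))
  r * u + sqrt(1 - r^2) * w
}

# Small helper: expression container for ad-hoc matrices.
make_se <- function(m, extra = NULL) {
  meta <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  if (!is.null(extra)) meta <- cbind(meta, extra)
  expression_matrix(m, meta)
}
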