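# Relative quantification of qRT-PCR data by the comparative Ct
# (delta-delta-Ct) method, with an endogenous control gene (TBP role) and
# perfect amplification efficiency (doubling per cycle).

#' Delta-Ct
#'
#' @param ct_target,ct_reference Ct values (cycles). Missing values
#'   propagate as `NA`.
#' @return `ct_target - ct_reference`.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  ct_target - ct_reference
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each target gene and sample computes `2^-(dCt_sample - dCt_calibrator)`
#' where `dCt = Ct_target - Ct_reference`. The calibrator sample therefore
#' gets relative expression exactly 1 for every gene. With no calibrator the
#' output is `2^-dCt` (uncalibrated relative units); downstream correlations
#' are invariant to that choice, which only rescales each gene.
#'
#' @param ct Long-format Ct table: `data.frame` with columns `sample_id`,
#'   `gene`, `ct` (as produced by [generate_ct_table()]). A reference-gene
#'   Ct must be present wherever a target Ct is present.
#' @param reference Reference (endogenous control) gene name, e.g. `"TBP"`.
#' @param calibrator Sample id whose expression is set to 1, or `NULL`.
#' @return A `SummarizedExperiment` of relative expression (targets x
#'   samples). Missing Ct values propagate to `NA` cells, never imputed.
#' @export
relative_expression <- function(ct, reference = "TBP", calibrator = NULL) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(ct)))
  if (!reference %in% ct$gene) {
    stop("reference gene '", reference, "' not in Ct table", call. = FALSE)
  }
  samples <- unique(ct$sample_id)
  targets <- setdiff(unique(ct$gene), reference)
  if (length(targets) == 0) stop("no target genes in Ct table", call. = FALSE)

  ct_of <- function(gene) {
    v <- rep(NA_real_, length(samples))
    names(v) <- samples
    rows <- ct[ct$gene == gene, , drop = FALSE]
    v[rows$sample_id] <- rows$ct
    v
  }
  ref_ct <- ct_of(reference)
  dct <- do.call(rbind, lapply(targets, function(g) delta_ct(ct_of(g), ref_ct)))
  rownames(dct) <- targets

  if (!is.null(calibrator)) {
    if (!calibrator %in% samples || !is.finite(ref_ct[[calibrator]])) {
      stop("calibrator sample '", calibrator,
           "' absent or lacks a reference Ct", call. = FALSE)
    }
    dct_cal <- dct[, calibrator]
    if (any(!is.finite(dct_cal))) {
      stop("calibrator sample lacks target Ct values", call. = FALSE)
    }
    dct <- sweep(dct, 1, dct_cal)
  }
  rel <- 2^(-dct)

  meta <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  # expression_matrix() requires finite values; keep NA propagation by
  # building the container directly when missing cells exist
  if (any(!is.finite(rel))) {
    SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = rel),
      colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id)
    )
  } else {
    expression_matrix(rel, meta)
  }
}
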