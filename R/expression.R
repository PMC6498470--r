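#' Delta-Cq of a target against a reference gene
#'
#' `dCq = Cq[target] - Cq[reference]`. Technical replicates are averaged on
#' the Cq scale before differencing.
#'
#' @param cq_target,cq_reference Numeric Cq vectors (technical replicates).
#' @return A single dCq value in cycles.
#' @examples
#' dcq(c(24.9, 25.0, 25.1), 20) # 5
#' @export
dcq <- function(cq_target, cq_reference) {
  if (!length(cq_reference) || any(!is.finite(cq_reference)))
    stop("missing or non-finite reference-gene Cq")
  if (any(!is.finite(cq_target))) stop("non-finite target Cq")
  mean(cq_target) - mean(cq_reference)
}

#' Fold change by the ddCq method
#'
#' `ddCq = dCq[sample] - dCq[control]`; `fold_change = 2^(-ddCq)` assuming
#' an amplification efficiency of 2 per cycle. The repression fold is the
#' reciprocal, so a ddCq of +1 is a 0.5 fold change and a twofold
#' repression.
#'
#' @param dcq_sample,dcq_control dCq values in cycles.
#' @return List with `ddcq`, `fold_change`, `repression_fold`.
#' @examples
#' ddcq_fold(6, 5)$fold_change # 0.5
#' @export
ddcq_fold <- function(dcq_sample, dcq_control) {
  ddcq <- dcq_sample - dcq_control
  list(ddcq = ddcq, fold_change = 2^(-ddcq), repression_fold = 2^(ddcq))
}

#' Relative expression from a Cq table
#'
#' Full ddCq pipeline: technical replicates averaged per (sample, gene);
#' each sample's dCq computed against the reference gene; ddCq against the
#' mean dCq of the control condition per gene; fold change `2^(-ddCq)`.
#' The per-condition summary uses the geometric mean of fold changes with
#' the SEM on the log2 scale.
#'
#' @param cq data.frame (`sample`, `condition`, `gene`, `replicate`, `cq`).
#' @param reference_gene Reference gene label (e.g. `"GAPDH"`).
#' @param control_condition Condition providing the ddCq baseline.
#' @return List with `per_sample` (sample x gene ExpressionResult rows) and
#'   `per_condition` (geometric-mean summary).
#' @export
relative_expression <- function(cq, reference_gene, control_condition) {
  assert_cols(cq, c("sample", "condition", "gene", "replicate", "cq"), "cq")
  if (!reference_gene %in% cq$gene)
    stop(sprintf("reference gene '%s' absent from Cq table", reference_gene))
  if (!control_condition %in% cq$condition)
    stop(sprintf("control condition '%s' absent", control_condition))
  # mean Cq per (sample, gene) over technical replicates
  agg <- stats::aggregate(cq ~ sample + condition + gene, data = cq,
                          FUN = mean)
  targets <- setdiff(unique(agg$gene), reference_gene)
  rows <- list()
  for (g in targets) {
    sub <- agg[agg$gene == g, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      s <- sub$sample[i]
      ref <- agg$cq[agg$sample == s & agg$gene == reference_gene]
      if (!length(ref))
        stop(sprintf("sample '%s' has no reference-gene Cq", s))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, condition = sub$condition[i], gene = g,
        dcq = sub$cq[i] - ref, stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, rows)
  out <- list()
  for (g in targets) {
    d <- per_sample[per_sample$gene == g, , drop = FALSE]
    base <- mean(d$dcq[d$condition == control_condition])
    d$ddcq <- d$dcq - base
    d$fold_change <- 2^(-d$ddcq)
    d$repression_fold <- 2^(d$ddcq)
    out[[g]] <- d
  }
  per_sample <- do.call(rbind, out)
  rownames(per_sample) <- NULL
  per_condition <- do.call(rbind, lapply(
    split(per_sample, list(per_sample$condition, per_sample$gene),
          drop = TRUE),
    function(d) {
      lg <- log2(d$fold_change)
      data.frame(condition = d$condition[1], gene = d$gene[1],
                 n = nrow(d), fold_change_geomean = 2^mean(lg),
                 log2_sem = stats::sd(lg) / sqrt(nrow(d)),
                 stringsAsFactors = FALSE)
    }))
  rownames(per_condition) <- NULL
  list(per_sample = per_sample, per_condition = per_condition)
}
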