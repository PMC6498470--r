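#' Simulate a qPCR Cq table from true fold changes
#'
#' For each (sample, gene) design row with true expression fold change `f`
#' relative to control, the target Cq is `baseline - log2(f)` plus Gaussian
#' noise; the reference gene's Cq is constant up to the same noise. Each
#' well is measured in technical triplicate. With zero noise the ddCq
#' pipeline recovers the planted fold changes exactly.
#'
#' @param design data.frame (`sample`, `condition`, `gene`,
#'   `fold_change` > 0). Control samples should carry `fold_change = 1`.
#' @param cfg A [sim_config()] (`cq_noise_sd`, `seed`).
#' @param reference_gene Reference gene name (default `"GAPDH"`).
#' @param baseline_cq Target-gene baseline Cq at fold change 1
#'   (default 25).
#' @param reference_cq Reference-gene Cq (default 20).
#' @param n_technical Technical replicates per well (default 3).
#' @return List with `cq` (data.frame `sample`, `condition`, `gene`,
#'   `replicate`, `cq`) and `truth` (the design).
#' @export
simulate_cq <- function(design, cfg, reference_gene = "GAPDH",
                        baseline_cq = 25, reference_cq = 20,
                        n_technical = 3) {
  assert_cols(design, c("sample", "condition", "gene", "fold_change"),
              "design")
  if (any(design$fold_change <= 0)) stop("fold changes must be > 0")
  withr::with_seed(derive_seed(cfg$seed, "cq"), {
    rows <- list()
    for (i in seq_len(nrow(design))) {
      mu <- baseline_cq - log2(design$fold_change[i])
      rows[[length(rows) + 1L]] <- data.frame(
        sample = design$sample[i], condition = design$condition[i],
        gene = design$gene[i], replicate = seq_len(n_technical),
        cq = mu + stats::rnorm(n_technical, 0, cfg$cq_noise_sd),
        stringsAsFactors = FALSE)
    }
    for (s in unique(design$sample)) {
      cond <- design$condition[match(s, design$sample)]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, condition = cond, gene = reference_gene,
        replicate = seq_len(n_technical),
        cq = reference_cq + stats::rnorm(n_technical, 0, cfg$cq_noise_sd),
        stringsAsFactors = FALSE)
    }
    cq <- do.call(rbind, rows)
    rownames(cq) <- NULL
    list(cq = cq, truth = design)
  })
}
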