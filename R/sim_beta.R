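#' Simulate an array-style beta matrix with planted hypermethylation
#'
#' Control samples draw every probe from a Beta distribution centred at the
#' background mean (default 0.07). Treated samples draw the promoter probes
#' of the planted DMR genes from a Beta centred at the planted mean
#' (default 0.48) and all other probes from the background. Both
#' distributions share a concentration ("precision") parameter; replicate
#' draws are independent and values live in `[0, 1]` by construction.
#'
#' @param manifest Probe manifest from [make_annotation()].
#' @param cfg A [sim_config()]; `planted_dmr_genes` selects the planted
#'   promoters.
#' @param timepoint Timepoint label (days) written into the sample sheet.
#' @param planted_genes Optional override of `cfg$planted_dmr_genes`, so
#'   two timepoints can plant different (persistent vs transient) genes.
#' @param seed_stream Tag for the derived random stream (change it to get
#'   an independent draw, e.g. per timepoint).
#' @return List with `betas` (a [beta_matrix()]) and `truth` (list:
#'   `dmr_genes`, `planted_probes`, `per_probe_planted_delta`).
#' @export
simulate_beta_matrix <- function(manifest, cfg, timepoint = 17,
                                 planted_genes = NULL,
                                 seed_stream = paste0("beta", timepoint)) {
  stopifnot(inherits(cfg, "sim_config"))
  planted_genes <- planted_genes %||% cfg$planted_dmr_genes
  if (!all(planted_genes %in% manifest$gene))
    stop("planted_dmr_genes must be a subset of manifest genes")
  if (cfg$beta_precision <= 0) stop("beta_precision must be > 0")

  n_rep <- cfg$n_replicates_per_condition
  samples <- data.frame(
    sample = c(sprintf("control_d%s_r%d", timepoint, seq_len(n_rep)),
               sprintf("treated_d%s_r%d", timepoint, seq_len(n_rep))),
    condition = rep(c("control", "treated"), each = n_rep),
    timepoint_days = timepoint,
    replicate = rep(seq_len(n_rep), 2),
    stringsAsFactors = FALSE)

  planted_probe <- manifest$gene %in% planted_genes &
    manifest$region_group %in% c("TSS1500", "TSS200", "5UTR")
  n_probe <- nrow(manifest)

  b <- withr::with_seed(derive_seed(cfg$seed, seed_stream), {
    mat <- matrix(NA_real_, n_probe, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      mu <- rep(cfg$background_beta_mean, n_probe)
      if (samples$condition[j] == "treated")
        mu[planted_probe] <- cfg$planted_beta_mean
      mat[, j] <- rbeta_mean(n_probe, mu, cfg$beta_precision)
    }
    mat
  })
  rownames(b) <- manifest$probe
  colnames(b) <- samples$sample
  delta <- ifelse(planted_probe,
                  cfg$planted_beta_mean - cfg$background_beta_mean, 0)
  names(delta) <- manifest$probe
  list(betas = beta_matrix(b, samples),
       truth = list(dmr_genes = planted_genes,
                    planted_probes = manifest$probe[planted_probe],
                    per_probe_planted_delta = delta))
}

# Beta draw parameterized by mean and concentration (alpha + beta); the
# infinite-precision limit degenerates to the mean itself
rbeta_mean <- function(n, mean, precision) {
  if (is.infinite(precision)) return(rep(mean, length.out = n))
  stats::rbeta(n, shape1 = mean * precision,
               shape2 = (1 - mean) * precision)
}
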