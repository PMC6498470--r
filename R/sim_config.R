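#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. Defaults encode the effect sizes the assessed experiment operates
#' at: treated promoters averaging 48% methylation against a 7% background,
#' 14 CpG probes per promoter, duplicate arrays per condition, and a 4-fold
#' promoter H3K27ac attenuation at silenced genes.
#'
#' @param seed Master integer seed; every generator derives its own stream
#'   from it (see [derive_seed()]), so modules can be regenerated
#'   independently and reruns are byte-identical.
#' @param n_contigs Number of contigs in the toy genome.
#' @param contig_length Length of each contig in bp (>= 1000).
#' @param gc_fraction Genome GC content in `[0, 1]`.
#' @param n_genes Number of genes to place across the genome.
#' @param probes_per_promoter Array probes per gene promoter (default 14,
#'   the average promoter representation on the EPIC array).
#' @param n_replicates_per_condition Arrays/peak replicates per condition.
#' @param background_beta_mean Mean beta of unmethylated background probes
#'   (default 0.07).
#' @param planted_beta_mean Mean beta of planted hypermethylated probes in
#'   treated samples (default 0.48).
#' @param beta_precision Concentration of the Beta noise distribution
#'   (alpha + beta); larger is tighter. Default 50.
#' @param planted_dmr_genes Character vector of gene ids whose promoter
#'   probes are hypermethylated in treated samples.
#' @param planted_lost_peak_genes Gene ids whose promoter H3K27ac peak is
#'   attenuated in treated samples.
#' @param peak_loss_ratio Control/treated signal ratio at lost-peak genes
#'   (default 4; the strongest loss reported in this regime is ~3.7-fold,
#'   so 4 with jitter spans it).
#' @param peak_jitter_sd Log-normal sd of multiplicative replicate signal
#'   jitter (default 0.1).
#' @param conversion_rate Bisulfite conversion probability of an
#'   unmethylated cytosine (default 0.99).
#' @param clone_count Number of bisulfite clone reads to simulate.
#' @param cq_noise_sd Gaussian sd of simulated Cq values in cycles.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 5)
#' cfg$probes_per_promoter
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 1L,
                       contig_length = 50000L,
                       gc_fraction = 0.45,
                       n_genes = 10L,
                       probes_per_promoter = 14L,
                       n_replicates_per_condition = 2L,
                       background_beta_mean = 0.07,
                       planted_beta_mean = 0.48,
                       beta_precision = 50,
                       planted_dmr_genes = character(),
                       planted_lost_peak_genes = character(),
                       peak_loss_ratio = 4,
                       peak_jitter_sd = 0.1,
                       conversion_rate = 0.99,
                       clone_count = 20L,
                       cq_noise_sd = 0.15) {
  cfg <- list(
    seed = as.integer(seed),
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    gc_fraction = gc_fraction,
    n_genes = as.integer(n_genes),
    probes_per_promoter = as.integer(probes_per_promoter),
    n_replicates_per_condition = as.integer(n_replicates_per_condition),
    background_beta_mean = background_beta_mean,
    planted_beta_mean = planted_beta_mean,
    beta_precision = beta_precision,
    planted_dmr_genes = as.character(planted_dmr_genes),
    planted_lost_peak_genes = as.character(planted_lost_peak_genes),
    peak_loss_ratio = peak_loss_ratio,
    peak_jitter_sd = peak_jitter_sd,
    conversion_rate = conversion_rate,
    clone_count = as.integer(clone_count),
    cq_noise_sd = cq_noise_sd
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fracs <- c("gc_fraction", "background_beta_mean", "planted_beta_mean",
             "conversion_rate")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single fraction in [0, 1]", f))
  }
  counts <- c("n_contigs", "contig_length", "n_genes", "probes_per_promoter",
              "n_replicates_per_condition", "clone_count")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("'%s' must be a positive count", f))
  }
  if (cfg$beta_precision <= 0) stop("'beta_precision' must be > 0")
  if (cfg$peak_loss_ratio <= 0) stop("'peak_loss_ratio' must be > 0")
  if (cfg$peak_jitter_sd < 0) stop("'peak_jitter_sd' must be >= 0")
  if (cfg$cq_noise_sd < 0) stop("'cq_noise_sd' must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d contig(s) x %d bp, %d genes, seed %d",
              x$n_contigs, x$contig_length, x$n_genes, x$seed), "\n")
  cat("  planted DMR genes:      ",
      if (length(x$planted_dmr_genes)) paste(x$planted_dmr_genes, collapse = ", ") else "(none)", "\n")
  cat("  planted lost-peak genes:",
      if (length(x$planted_lost_peak_genes)) paste(x$planted_lost_peak_genes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Derive a stream-specific seed from the master seed
#'
#' Hierarchical seed split: each generator gets its own deterministic stream
#' so regenerating one data type does not perturb the others. Kept below
#' 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed Master integer seed.
#' @param stream Character tag of the consuming generator.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}
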