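#' Simulate replicate H3K27ac peak sets with planted promoter-peak losses
#'
#' Every gene promoter gets a 1-kb peak (summit at the TSS) in the control
#' replicates, plus one 400-bp background peak per gene slot placed away
#' from any promoter window. Treated replicates carry the same peaks except
#' at the planted lost-peak genes, whose promoter signal is attenuated by
#' `cfg$peak_loss_ratio`; when the attenuation exceeds twofold the peak is
#' no longer "called" and is omitted from the treated peak list — mirroring
#' a lost peak — while its residual signal remains measurable in the
#' promoter signal table. Promoter signals scale with a per-sample library
#' size and carry multiplicative log-normal jitter, so library-size
#' normalisation is genuinely exercised downstream.
#'
#' @param annotation Gene annotation from [make_annotation()].
#' @param cfg A [sim_config()]; `planted_lost_peak_genes` selects the
#'   attenuated promoters.
#' @return List with `peaks` (named list of peak data.frames, one per
#'   sample, names like `control_rep1`), `signal` (data.frame `gene`,
#'   `condition`, `replicate`, `signal`, `library_size` — the re-counted
#'   promoter signal for every gene and sample) and `truth` (list:
#'   `lost_peak_genes`, `ratio`).
#' @export
simulate_peaks <- function(annotation, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lost <- cfg$planted_lost_peak_genes
  if (!all(lost %in% annotation$gene))
    stop("planted_lost_peak_genes must be a subset of annotation genes")
  ratio <- cfg$peak_loss_ratio
  n_rep <- cfg$n_replicates_per_condition
  base_promoter <- 100
  base_background <- 50
  omit_called_peak <- ratio > 2  # attenuated below calling threshold

  withr::with_seed(derive_seed(cfg$seed, "peaks"), {
    peaks <- list(); signal <- list()
    for (cond in c("control", "treated")) {
      for (r in seq_len(n_rep)) {
        lib <- stats::runif(1, 0.8e7, 1.2e7)
        rows <- list()
        for (i in seq_len(nrow(annotation))) {
          g <- annotation$gene[i]
          tss0 <- annotation$tss[i] - 1L
          attn <- cond == "treated" && g %in% lost
          sig <- base_promoter * (if (attn) 1 / ratio else 1) *
            (lib / 1e7) * exp(stats::rnorm(1, 0, cfg$peak_jitter_sd))
          bg_sig <- base_background * (lib / 1e7) *
            exp(stats::rnorm(1, 0, cfg$peak_jitter_sd))
          signal[[length(signal) + 1L]] <- data.frame(
            gene = g, condition = cond, replicate = r, signal = sig,
            library_size = lib, stringsAsFactors = FALSE)
          if (!(attn && omit_called_peak))
            rows[[length(rows) + 1L]] <- data.frame(
              contig = annotation$contig[i],
              start = max(0L, tss0 - 500L), end = tss0 + 500L,
              name = sprintf("%s_promoter", g),
              score = round(sig * 10), strand = ".",
              signal = sig, pvalue = -1, qvalue = -1, peak = 500L,
              stringsAsFactors = FALSE)
          # one background peak per gene slot, outside every promoter
          # window: promoter peaks sit within [tss-500, tss+500); the
          # background peak occupies the far side of the 2200-bp slot
          bg_start <- if (annotation$strand[i] == "+") tss0 - 1400L
                      else tss0 + 800L
          rows[[length(rows) + 1L]] <- data.frame(
            contig = annotation$contig[i],
            start = bg_start, end = bg_start + 400L,
            name = sprintf("%s_background", g),
            score = round(bg_sig * 10), strand = ".",
            signal = bg_sig, pvalue = -1, qvalue = -1, peak = 200L,
            stringsAsFactors = FALSE)
        }
        df <- do.call(rbind, rows)
        df <- df[order(df$contig, df$start), , drop = FALSE]
        rownames(df) <- NULL
        peaks[[sprintf("%s_rep%d", cond, r)]] <- df
      }
    }
    list(peaks = peaks, signal = do.call(rbind, signal),
         truth = list(lost_peak_genes = lost, ratio = ratio))
  })
}
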