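#' Simulate bisulfite-converted amplicon clone reads
#'
#' Each clone is the amplicon sequence after in-silico bisulfite
#' conversion: every non-CpG cytosine converts to T with probability
#' `cfg$conversion_rate`; each CpG cytosine is retained (methylated) with
#' its per-CpG methylation probability and otherwise converts. Deterministic
#' per seed. The default assay geometry of interest is a ~229-bp amplicon
#' with 11 CpGs.
#'
#' @param amplicon An [amplicon_reference()] with at least one CpG.
#' @param cfg A [sim_config()] (`clone_count`, `conversion_rate`, `seed`).
#' @param methylation_probs Per-CpG methylation probability, recycled to
#'   the number of CpGs (default 0.5).
#' @return List with `reads` (character vector of clone sequences, named)
#'   and `truth` (list: `clone_methylation_probs`, `conversion_rate`).
#' @export
simulate_bisulfite_clones <- function(amplicon, cfg,
                                      methylation_probs = 0.5) {
  stopifnot(inherits(amplicon, "amplicon_reference"))
  cpg <- amplicon$cpg_positions
  if (!length(cpg)) stop("amplicon must contain at least one CpG")
  probs <- rep(methylation_probs, length.out = length(cpg))
  if (any(probs < 0 | probs > 1))
    stop("methylation probabilities must lie in [0, 1]")
  chars <- strsplit(amplicon$sequence, "")[[1]]
  non_cpg_c <- setdiff(which(chars == "C"), cpg)

  reads <- withr::with_seed(derive_seed(cfg$seed, "bisulfite"), {
    vapply(seq_len(cfg$clone_count), function(k) {
      r <- chars
      conv <- stats::runif(length(non_cpg_c)) < cfg$conversion_rate
      r[non_cpg_c[conv]] <- "T"
      meth <- stats::runif(length(cpg)) < probs
      r[cpg[!meth]] <- "T"
      paste(r, collapse = "")
    }, character(1))
  })
  names(reads) <- sprintf("%s_clone_%03d", amplicon$name,
                          seq_along(reads))
  list(reads = reads,
       truth = list(clone_methylation_probs = stats::setNames(
         probs, paste0("CpG_", seq_along(cpg))),
         conversion_rate = cfg$conversion_rate))
}

#' Write clone reads to FASTA
#' @param reads Named character vector of reads.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path,
                              width = 70L)
  invisible(path)
}
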