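#' Generate a toy genome
#'
#' Draws i.i.d. bases at the requested GC fraction. Deterministic for a
#' fixed seed. The result is a [Biostrings::DNAStringSet] and can be written
#' to FASTA with [write_genome_fasta()].
#'
#' @param cfg A [sim_config()].
#' @return A `DNAStringSet` with contigs named `contig_1`, `contig_2`, ...
#' @examples
#' g <- make_genome(sim_config(seed = 1, contig_length = 1000))
#' Biostrings::width(g)
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$contig_length < 1000)
    stop("contig_length must be >= 1000")
  gc <- cfg$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withr::with_seed(derive_seed(cfg$seed, "genome"), {
    vapply(seq_len(cfg$n_contigs), function(i) {
      paste(sample(names(p), cfg$contig_length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("contig_", seq_len(cfg$n_contigs))
  Biostrings::DNAStringSet(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file path.
#' @return A `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
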