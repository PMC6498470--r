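#' Place genes and promoter probes on a toy genome
#'
#' Assigns each gene a TSS and strand inside a private, non-overlapping
#' slot, then positions `probes_per_promoter` CpG probes over the three
#' promoter region groups (by default 5 in TSS1500, 5 in TSS200, 4 in the
#' 5'UTR, summing to the array's average of 14 probes per promoter). Probe
#' placement is strand-aware: upstream offsets map to coordinates greater
#' than the TSS for minus-strand genes. A CG dinucleotide is written into
#' the genome at every probe position, so the returned (possibly edited)
#' genome must be used downstream.
#'
#' @param genome A `DNAStringSet` from [make_genome()].
#' @param cfg A [sim_config()].
#' @return List with `genome` (edited), `annotation` (data.frame `gene`,
#'   `contig`, `tss` 1-based, `strand`) and `manifest` (data.frame `probe`,
#'   `contig`, `pos` 1-based CpG cytosine, `gene`, `region_group`).
#' @export
make_annotation <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  slot <- 2200L  # per-gene promoter slot: 1600 bp clearance + margin
  margin <- 100L
  per_contig <- (cfg$contig_length - margin) %/% slot
  if (per_contig * length(genome) < cfg$n_genes)
    stop(sprintf(
      "genome too small: %d gene slot(s) available for %d gene(s)",
      per_contig * length(genome), cfg$n_genes))

  offs <- probe_offsets(cfg$probes_per_promoter)
  ann <- list(); man <- list()
  seqs <- as.character(genome)
  gid <- 0L
  for (ci in seq_along(genome)) {
    for (si in seq_len(per_contig)) {
      if (gid >= cfg$n_genes) break
      gid <- gid + 1L
      gene <- sprintf("gene_%02d", gid)
      strand <- if (gid %% 2L == 1L) "+" else "-"
      slot_start <- margin + (si - 1L) * slot  # 0-based slot origin
      # promoter span is [-1500, +500] around the TSS along transcription
      tss <- if (strand == "+") slot_start + 1550L + 1L
             else slot_start + 600L + 1L      # 1-based
      ann[[gid]] <- data.frame(gene = gene, contig = names(genome)[ci],
                               tss = tss, strand = strand,
                               stringsAsFactors = FALSE)
      pos <- if (strand == "+") tss + offs$offset else tss - offs$offset
      man[[gid]] <- data.frame(
        probe = sprintf("%s_p%02d", gene, seq_along(pos)),
        contig = names(genome)[ci], pos = as.integer(pos), gene = gene,
        region_group = offs$group, stringsAsFactors = FALSE)
      # plant a CG dinucleotide at each probe position (C at pos)
      for (p in pos) {
        substr(seqs[ci], p, p) <- "C"
        substr(seqs[ci], p + 1L, p + 1L) <- "G"
      }
    }
  }
  genome_out <- Biostrings::DNAStringSet(seqs)
  names(genome_out) <- names(genome)
  list(genome = genome_out,
       annotation = do.call(rbind, ann),
       manifest = do.call(rbind, man))
}

# deterministic offsets (relative to TSS, along transcription) and region
# groups; n probes split ~evenly as TSS1500/TSS200/5UTR with the remainder
# going to the upstream groups first (14 -> 5/5/4)
probe_offsets <- function(n) {
  base <- n %/% 3L
  rem <- n %% 3L
  n1500 <- base + (rem >= 1L)
  n200 <- base + (rem >= 2L)
  n5utr <- base
  spread <- function(lo, hi, k) {
    if (k == 0L) return(integer(0))
    as.integer(round(seq(lo, hi, length.out = k)))
  }
  data.frame(
    offset = c(spread(-1500L, -300L, n1500),
               spread(-200L, -20L, n200),
               spread(20L, 480L, n5utr)),
    group = c(rep("TSS1500", n1500), rep("TSS200", n200),
              rep("5UTR", n5utr)),
    stringsAsFactors = FALSE)
}

#' Write a gene annotation as 6-column BED
#'
#' The TSS is written as a 1-bp feature with the strand in column 6.
#'
#' @param annotation Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  assert_cols(annotation, c("gene", "contig", "tss", "strand"))
  bed <- data.frame(annotation$contig, annotation$tss - 1L, annotation$tss,
                    annotation$gene, 0L, annotation$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED gene annotation written by [write_annotation_bed()]
#' @param path BED file path.
#' @return Annotation data.frame (`gene`, `contig`, `tss`, `strand`).
#' @export
read_annotation_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(gene = bed[[4]], contig = bed[[1]], tss = bed[[3]],
             strand = bed[[6]], stringsAsFactors = FALSE)
}
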