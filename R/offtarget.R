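#' Guide RNA descriptor
#'
#' A protospacer plus a PAM pattern. SpCas9 guides in this workflow use
#' 19-nt protospacers and the canonical `NGG` PAM; any IUPAC pattern is
#' accepted. The PAM sits immediately 3' of the protospacer on the
#' protospacer-matching strand.
#'
#' @param name Guide identifier.
#' @param protospacer DNA string, 17-23 nt, A/C/G/T only.
#' @param pam_pattern IUPAC string, default `"NGG"`.
#' @return An object of class `guide_rna`.
#' @examples
#' guide_rna("g1", "GGAGGAGGTGGAGGAGGAG")
#' @export
guide_rna <- function(name, protospacer, pam_pattern = "NGG") {
  protospacer <- toupper(protospacer)
  pam_pattern <- toupper(pam_pattern)
  if (!grepl("^[ACGT]+$", protospacer))
    stop("protospacer must contain only A/C/G/T")
  if (nchar(protospacer) < 17 || nchar(protospacer) > 23)
    stop("protospacer must be 17-23 nt")
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (!all(strsplit(pam_pattern, "")[[1]] %in% iupac))
    stop("pam_pattern must contain only IUPAC codes")
  structure(list(name = as.character(name), protospacer = protospacer,
                 pam_pattern = pam_pattern),
            class = "guide_rna")
}

# Allowed genome bases per IUPAC PAM letter. A genome 'N' passes only an 'N'
# PAM position; every other ambiguity code admits its standard base set.
pam_allowed <- function(pam_pattern) {
  letters <- strsplit(pam_pattern, "")[[1]]
  lapply(letters, function(l) {
    set <- strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "")[[1]]
    if (l == "N") set <- c(set, "N")
    set
  })
}

pam_matches <- function(pam_seqs, allowed) {
  if (!length(pam_seqs)) return(logical(0))
  m <- do.call(rbind, strsplit(pam_seqs, ""))
  ok <- rep(TRUE, nrow(m))
  for (j in seq_along(allowed)) ok <- ok & m[, j] %in% allowed[[j]]
  ok
}

#' Enumerate genomic sites matching a guide with bounded mismatches
#'
#' Scans both strands of a genome for windows within a Hamming distance of
#' `max_mismatch` of the protospacer and flanked 3' by a PAM match.
#' Mismatches are counted in the protospacer only, never in the PAM.
#' Ambiguous genome bases (`N`) count as protospacer mismatches and fail all
#' non-`N` PAM positions. Coordinates are reported on the forward strand,
#' 0-based half-open, covering the protospacer footprint (PAM excluded).
#'
#' The scan is backed by [Biostrings::matchPattern()]; correctness is pinned
#' in the test-suite against an independent brute-force sliding-window
#' oracle.
#'
#' @param genome A `DNAStringSet` (or a single DNA string).
#' @param guide A [guide_rna()].
#' @param max_mismatch Maximum protospacer mismatches (default 3).
#' @return A data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `mismatches`, `matched_sequence` (protospacer-strand genomic sequence),
#'   `pam_sequence`, `guide`, sorted by (contig, start, strand).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "TTTGGAGGAGGTGGAGGAGGAGAGGTTT"))
#' find_sites(g, guide_rna("g1", "GGAGGAGGTGGAGGAGGAG"), max_mismatch = 0)
#' @export
find_sites <- function(genome, guide, max_mismatch = 3) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(inherits(guide, "guide_rna"))
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")
  if (length(genome) == 0) stop("genome is empty")
  if (is.null(names(genome)))
    names(genome) <- paste0("contig_", seq_along(genome))

  proto <- Biostrings::DNAString(guide$protospacer)
  proto_rc <- Biostrings::reverseComplement(proto)
  L <- length(proto)
  P <- nchar(guide$pam_pattern)
  allowed <- pam_allowed(guide$pam_pattern)

  res <- list()
  for (ci in seq_along(genome)) {
    contig <- genome[[ci]]
    cname <- names(genome)[ci]
    clen <- length(contig)
    if (clen < L + P) next
    cseq <- as.character(contig)

    # forward strand: protospacer at [s, s+L), PAM at [s+L, s+L+P)
    hits <- Biostrings::matchPattern(proto, contig,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
    s1 <- BiocGenerics::start(hits)            # 1-based
    keep <- s1 + L + P - 1L <= clen
    s1 <- s1[keep]
    if (length(s1)) {
      win <- substring(cseq, s1, s1 + L - 1L)
      pam <- substring(cseq, s1 + L, s1 + L + P - 1L)
      ok <- pam_matches(pam, allowed)
      s1 <- s1[ok]; win <- win[ok]; pam <- pam[ok]
      if (length(s1)) {
        mm <- hamming_vec(win, guide$protospacer)
        res[[length(res) + 1L]] <- data.frame(
          contig = cname, start = s1 - 1L, end = s1 - 1L + L,
          strand = "+", mismatches = mm,
          matched_sequence = win, pam_sequence = pam,
          guide = guide$name, stringsAsFactors = FALSE)
      }
    }

    # minus strand: revcomp(protospacer) on the forward sequence, PAM (as
    # revcomp) immediately 5' of the match
    hits <- Biostrings::matchPattern(proto_rc, contig,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
    s1 <- BiocGenerics::start(hits)
    keep <- s1 - P >= 1L
    s1 <- s1[keep]
    if (length(s1)) {
      win_fwd <- substring(cseq, s1, s1 + L - 1L)
      pam_fwd <- substring(cseq, s1 - P, s1 - 1L)
      win <- revcomp_chr(win_fwd)
      pam <- revcomp_chr(pam_fwd)
      ok <- pam_matches(pam, allowed)
      s1 <- s1[ok]; win <- win[ok]; pam <- pam[ok]
      if (length(s1)) {
        mm <- hamming_vec(win, guide$protospacer)
        res[[length(res) + 1L]] <- data.frame(
          contig = cname, start = s1 - 1L, end = s1 - 1L + L,
          strand = "-", mismatches = mm,
          matched_sequence = win, pam_sequence = pam,
          guide = guide$name, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), mismatches = integer(),
               matched_sequence = character(), pam_sequence = character(),
               guide = character(), stringsAsFactors = FALSE)
  out <- out[out$mismatches <= max_mismatch, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hamming distance of equal-length strings against one reference; any
# non-matching letter (including N) counts as a mismatch.
hamming_vec <- function(strings, ref) {
  if (!length(strings)) return(integer(0))
  refv <- strsplit(ref, "")[[1]]
  m <- do.call(rbind, strsplit(strings, ""))
  as.integer(rowSums(m != matrix(refv, nrow(m), length(refv), byrow = TRUE)))
}

revcomp_chr <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Expand genomic intervals by a symmetric flank
#'
#' Grows each interval by `flank` bp on both sides, clipping at zero and at
#' the contig length when known. The default flank of 146 bp is one
#' nucleosome's worth of DNA, so a 1-bp CpG becomes a 293-bp window.
#'
#' @param intervals data.frame with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param flank Non-negative flank in bp (default 146).
#' @param contig_lengths Optional named vector of contig lengths for
#'   right-clipping.
#' @return The input with `start`/`end` expanded.
#' @export
expand_interval <- function(intervals, flank = 146, contig_lengths = NULL) {
  assert_cols(intervals, c("contig", "start", "end"))
  if (flank < 0) stop("flank must be >= 0")
  intervals$start <- pmax(0L, as.integer(intervals$start - flank))
  intervals$end <- as.integer(intervals$end + flank)
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[intervals$contig]
    hit <- !is.na(lim)
    intervals$end[hit] <- pmin(intervals$end[hit], as.integer(lim[hit]))
  }
  intervals
}

#' All overlapping pairs between two interval sets
#'
#' Half-open semantics: intervals sharing only a boundary do not overlap.
#' Backed by [GenomicRanges::findOverlaps()].
#'
#' @param a,b data.frames with `contig`, `start`, `end` (0-based half-open).
#' @return data.frame with `a_index`, `b_index` (row indices into `a`, `b`)
#'   and the coordinates of both members; zero rows when nothing overlaps.
#' @export
intersect_intervals <- function(a, b) {
  assert_cols(a, c("contig", "start", "end"), "a")
  assert_cols(b, c("contig", "start", "end"), "b")
  empty <- data.frame(a_index = integer(), b_index = integer(),
                      contig = character(),
                      a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  ga <- as_granges0(a)
  gb <- as_granges0(b)
  ov <- GenomicRanges::findOverlaps(ga, gb)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  data.frame(a_index = qi, b_index = si,
             contig = a$contig[qi],
             a_start = a$start[qi], a_end = a$end[qi],
             b_start = b$start[si], b_end = b$end[si],
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$contig,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Write predicted off-target sites as BED6+
#'
#' Columns: contig, start, end, guide name, mismatches, strand, matched
#' sequence, PAM.
#'
#' @param sites Output of [find_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- sites[, c("contig", "start", "end", "guide", "mismatches",
                   "strand", "matched_sequence", "pam_sequence")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
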