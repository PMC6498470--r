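#' Locate CpG sites in a reference sequence
#'
#' @param sequence DNA string (A/C/G/T).
#' @return Integer vector of 1-based positions `i` with
#'   `substr(sequence, i, i + 1) == "CG"`, ascending.
#' @examples
#' locate_cpgs("ACGTCG") # 2, 5
#' @export
locate_cpgs <- function(sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]*$", sequence)) stop("sequence must be A/C/G/T")
  if (nchar(sequence) < 2) return(integer(0))
  chars <- strsplit(sequence, "")[[1]]
  which(chars[-length(chars)] == "C" & chars[-1] == "G")
}

#' Bisulfite amplicon reference
#'
#' An unconverted top-strand reference with its CpG cytosine positions.
#' Emulates an assay geometry of a ~229-bp promoter amplicon carrying 11
#' CpGs immediately upstream of a TSS.
#'
#' @param name Amplicon identifier.
#' @param sequence Unconverted DNA string.
#' @param contig,start Optional genomic anchor (1-based start).
#' @return Object of class `amplicon_reference` with `cpg_positions`
#'   (1-based).
#' @export
amplicon_reference <- function(name, sequence, contig = NA_character_,
                               start = NA_integer_) {
  sequence <- toupper(sequence)
  if (!nchar(sequence)) stop("amplicon sequence must be nonempty")
  if (!grepl("^[ACGT]+$", sequence)) stop("sequence must be A/C/G/T")
  structure(list(name = name, sequence = sequence,
                 cpg_positions = locate_cpgs(sequence),
                 contig = contig, start = start),
            class = "amplicon_reference")
}

#' Call per-CpG methylation states for one clone read
#'
#' The read must be pre-aligned, top-strand oriented and the same length as
#' the reference. At each CpG cytosine, a read `C` is called methylated and
#' a `T` unmethylated; anything else is ambiguous. Conversion efficiency is
#' the fraction of non-CpG reference cytosines read as `T`; a fully
#' unconverted artifact clone therefore scores 0 and is flagged when a
#' floor is set.
#'
#' @param read DNA string, same length as the reference.
#' @param reference An [amplicon_reference()].
#' @param min_conversion Efficiency floor for the `pass_qc` flag
#'   (default 0: no filtering).
#' @return List with `states` (character vector over CpG sites),
#'   `conversion_efficiency`, and `pass_qc`.
#' @export
call_clone <- function(read, reference, min_conversion = 0) {
  stopifnot(inherits(reference, "amplicon_reference"))
  read <- toupper(read)
  if (nchar(read) != nchar(reference$sequence))
    stop("read length must equal reference length")
  ref_chars <- strsplit(reference$sequence, "")[[1]]
  read_chars <- strsplit(read, "")[[1]]
  cpg <- reference$cpg_positions
  states <- vapply(cpg, function(i) {
    switch(read_chars[i], C = "methylated", T = "unmethylated", "ambiguous")
  }, character(1))
  non_cpg_c <- setdiff(which(ref_chars == "C"), cpg)
  eff <- if (length(non_cpg_c))
    mean(read_chars[non_cpg_c] == "T") else NA_real_
  list(states = states, conversion_efficiency = eff,
       pass_qc = is.na(eff) || eff >= min_conversion)
}

#' Build a clone-by-CpG methylation matrix
#'
#' @param reads Character vector (or `DNAStringSet`) of clone reads.
#' @param reference An [amplicon_reference()].
#' @param min_conversion Conversion-efficiency floor; failing clones are
#'   kept in the matrix but flagged.
#' @return Object of class `clone_matrix`: list with `states` (clones x
#'   CpGs character matrix), `conversion_efficiency`, `pass_qc`.
#' @export
clone_matrix <- function(reads, reference, min_conversion = 0) {
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  if (!length(reads)) stop("no reads")
  calls <- lapply(reads, call_clone, reference = reference,
                  min_conversion = min_conversion)
  states <- do.call(rbind, lapply(calls, `[[`, "states"))
  rownames(states) <- names(reads) %||% paste0("clone_", seq_along(reads))
  colnames(states) <- paste0("CpG_", seq_along(reference$cpg_positions))
  structure(list(states = states,
                 conversion_efficiency =
                   vapply(calls, `[[`, numeric(1), "conversion_efficiency"),
                 pass_qc = vapply(calls, `[[`, logical(1), "pass_qc")),
            class = "clone_matrix")
}

#' Aggregate clone calls into per-CpG and overall percentages
#'
#' Per-CpG % methylation is methylated / (methylated + unmethylated) with
#' ambiguous calls excluded; a site with no informative call is flagged
#' `NA`. The overall average is the mean of per-site percentages (primary,
#' matching lollipop-style reporting); the pooled-call fraction is also
#' returned since the two can differ when sites have unequal coverage.
#'
#' @param mat A [clone_matrix()].
#' @param use_qc Drop clones failing the conversion floor (default TRUE).
#' @return List with `per_cpg_pct`, `overall_pct` (mean of sites),
#'   `pooled_pct`, `n_clones_used`, `n_clones_excluded`.
#' @export
aggregate_clones <- function(mat, use_qc = TRUE) {
  stopifnot(inherits(mat, "clone_matrix"))
  keep <- if (use_qc) mat$pass_qc else rep(TRUE, nrow(mat$states))
  st <- mat$states[keep, , drop = FALSE]
  if (!nrow(st)) stop("no clones pass QC")
  meth <- colSums(st == "methylated")
  unmeth <- colSums(st == "unmethylated")
  informative <- meth + unmeth
  per <- ifelse(informative > 0, 100 * meth / informative, NA_real_)
  list(per_cpg_pct = per,
       overall_pct = mean(per, na.rm = TRUE),
       pooled_pct = 100 * sum(meth) / sum(informative),
       n_clones_used = nrow(st),
       n_clones_excluded = sum(!keep))
}

#' Text lollipop rendering of a clone matrix
#'
#' One row per clone, one glyph per CpG: filled circle = methylated, open
#' circle = unmethylated, `?` = ambiguous. Deterministic clone order.
#'
#' @param mat A [clone_matrix()].
#' @return Character vector, one string per clone (invisibly printed with
#'   `cat`-friendly rows).
#' @export
render_lollipop <- function(mat) {
  stopifnot(inherits(mat, "clone_matrix"))
  if (!nrow(mat$states)) stop("empty clone matrix")
  glyph <- c(methylated = "●", unmethylated = "○",
             ambiguous = "?")
  rows <- apply(mat$states, 1, function(r) paste(glyph[r], collapse = ""))
  as.character(rows)
}
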