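#' Read a narrowPeak file
#'
#' BED6+4: chrom, start, end, name, score, strand, signalValue, pValue,
#' qValue, peak (summit offset, -1 when absent). Coordinates are 0-based
#' half-open throughout the package.
#'
#' @param path narrowPeak file.
#' @return data.frame with the ten canonical columns.
#' @export
read_narrowpeak <- function(path) {
  cols <- c("contig", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "peak")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         "numeric", "numeric", "numeric",
                                         "integer"))
  names(df) <- cols
  validate_peaks(df)
  df
}

#' Write a narrowPeak file
#' @param peaks Peak data.frame (see [read_narrowpeak()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peaks(peaks)
  utils::write.table(
    peaks[, c("contig", "start", "end", "name", "score", "strand",
              "signal", "pvalue", "qvalue", "peak")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_peaks <- function(peaks) {
  assert_cols(peaks, c("contig", "start", "end", "signal"), "peaks")
  if (nrow(peaks)) {
    if (any(peaks$start >= peaks$end)) stop("peaks must satisfy start < end")
    if (any(peaks$signal < 0)) stop("peak signal must be >= 0")
  }
  invisible(peaks)
}

#' Top-N peaks by signal
#'
#' The `n` peaks with the highest signalValue; ties broken by score, then
#' by (contig, start) so the selection is deterministic.
#'
#' @param peaks Peak data.frame.
#' @param n Number to keep (default 15000, the robust-peak convention).
#' @return `min(n, nrow(peaks))` peaks.
#' @export
top_n_peaks <- function(peaks, n = 15000) {
  validate_peaks(peaks)
  if (n < 1) stop("n must be >= 1")
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  ord <- order(-peaks$signal, -score, peaks$contig, peaks$start)
  out <- peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# width of overlap between each a-row and best-overlapping b rows
overlap_widths <- function(a, b) {
  ov <- intersect_intervals(a, b)
  if (!nrow(ov)) return(ov)
  ov$width <- pmin(ov$a_end, ov$b_end) - pmax(ov$a_start, ov$b_start)
  ov
}

#' Reproducible peaks by naive overlap
#'
#' Returns the peaks of the first replicate that are supported in every
#' other replicate: a supporting peak must overlap the candidate by at
#' least `min_frac` of the candidate's own length (ENCODE naive-overlap
#' convention; default 50%).
#'
#' @param replicates List of two or more peak data.frames.
#' @param min_frac Minimum overlap fraction of the candidate peak length.
#' @return Subset of `replicates[[1]]`.
#' @export
reproducible_peaks <- function(replicates, min_frac = 0.5) {
  if (!is.list(replicates) || length(replicates) < 2)
    stop("need at least 2 replicates")
  lapply(replicates, validate_peaks)
  cand <- replicates[[1]]
  if (!nrow(cand)) return(cand)
  keep <- rep(TRUE, nrow(cand))
  need <- min_frac * (cand$end - cand$start)
  for (rep_i in replicates[-1]) {
    ov <- overlap_widths(cand, rep_i)
    supported <- rep(FALSE, nrow(cand))
    if (nrow(ov)) {
      ok <- ov$width >= need[ov$a_index]
      supported[unique(ov$a_index[ok])] <- TRUE
    }
    keep <- keep & supported
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peaks found only in the control set
#'
#' Partitions the control peaks by simple >= 1 bp overlap against the
#' treated set: `specific` (no overlap — candidate lost peaks) and
#' `shared`.
#'
#' @param control,treated Peak data.frames.
#' @return List with `specific`, `shared` (both peak data.frames) and
#'   counts `n_control`, `n_specific`, `n_shared`.
#' @export
control_specific_peaks <- function(control, treated) {
  validate_peaks(control); validate_peaks(treated)
  if (!nrow(control) || !nrow(treated))
    stop("both peak sets must be nonempty")
  ov <- intersect_intervals(control, treated)
  hit <- seq_len(nrow(control)) %in% ov$a_index
  specific <- control[!hit, , drop = FALSE]
  shared <- control[hit, , drop = FALSE]
  rownames(specific) <- rownames(shared) <- NULL
  list(specific = specific, shared = shared,
       n_control = nrow(control), n_specific = nrow(specific),
       n_shared = nrow(shared))
}

# peak center: declared summit when present (offset >= 0), else midpoint
# (floor), as 0-based position
peak_center <- function(peaks) {
  center <- peaks$start + (peaks$end - peaks$start) %/% 2L
  if ("peak" %in% names(peaks)) {
    has_summit <- !is.na(peaks$peak) & peaks$peak >= 0
    center[has_summit] <- peaks$start[has_summit] + peaks$peak[has_summit]
  }
  center
}

#' TSS-proximal peaks
#'
#' Pairs each peak with every gene whose TSS lies within `window` bp of the
#' peak center. Distance is signed along the direction of transcription
#' (upstream negative): a peak centered 288 bp upstream of a plus-strand
#' TSS has distance -288. Multiple TSS records per gene are allowed; each
#' (gene, peak) pair keeps the minimal-|distance| record.
#'
#' @param peaks Peak data.frame.
#' @param annotation data.frame (`gene`, `contig`, `tss` 1-based, `strand`).
#' @param window Half-width of the promoter window in bp (default 1000).
#' @return data.frame (`gene`, peak coordinates, `peak_index`,
#'   `tss_distance`).
#' @export
tss_proximal <- function(peaks, annotation, window = 1000) {
  validate_peaks(peaks)
  assert_cols(annotation, c("gene", "contig", "tss", "strand"), "annotation")
  if (window <= 0) stop("window must be > 0")
  empty <- data.frame(gene = character(), contig = character(),
                      start = integer(), end = integer(),
                      signal = numeric(), peak_index = integer(),
                      tss_distance = integer(), stringsAsFactors = FALSE)
  if (!nrow(peaks) || !nrow(annotation)) return(empty)
  center <- peak_center(peaks)
  res <- list()
  for (i in seq_len(nrow(annotation))) {
    tss0 <- annotation$tss[i] - 1L
    sel <- which(peaks$contig == annotation$contig[i] &
                   abs(center - tss0) <= window)
    if (!length(sel)) next
    d <- center[sel] - tss0
    if (annotation$strand[i] == "-") d <- -d
    res[[length(res) + 1L]] <- data.frame(
      gene = annotation$gene[i], contig = peaks$contig[sel],
      start = peaks$start[sel], end = peaks$end[sel],
      signal = peaks$signal[sel], peak_index = sel,
      tss_distance = as.integer(d), stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  # minimal |distance| per (gene, peak)
  out <- out[order(abs(out$tss_distance)), , drop = FALSE]
  out <- out[!duplicated(paste(out$gene, out$peak_index)), , drop = FALSE]
  out <- out[order(out$gene, out$peak_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Library-size-normalised fold change of peak signal
#'
#' Each replicate signal is scaled to counts-per-million of its library,
#' replicate values are averaged within condition, and the fold change is
#' the normalised control mean over the normalised treated mean. A zero
#' treated signal yields an infinite fold change, still classifiable as
#' reduced. This counts-per-million scaling deliberately stands in for a
#' full differential-binding model.
#'
#' @param control_signal,treated_signal Numeric vectors of replicate
#'   signals.
#' @param control_library,treated_library Library sizes (same length as the
#'   corresponding signal vector, or scalars).
#' @return List with `control_signal_norm`, `treated_signal_norm` (averaged
#'   CPM) and `fold_change`.
#' @export
normalized_fold_change <- function(control_signal, treated_signal,
                                   control_library, treated_library) {
  if (any(control_library <= 0) || any(treated_library <= 0))
    stop("library sizes must be > 0")
  cn <- mean(control_signal / control_library * 1e6)
  tn <- mean(treated_signal / treated_library * 1e6)
  fc <- if (tn > 0) cn / tn else Inf
  list(control_signal_norm = cn, treated_signal_norm = tn, fold_change = fc)
}

#' Reduced-promoter report
#'
#' Composition of the promoter peak-loss pipeline: keep the top `n` peaks
#' of each condition, find control-specific peaks, keep those within
#' `window` bp of a TSS, compute the library-size-normalised fold change of
#' promoter signal from the measured signal table, and report genes whose
#' control/treated fold change exceeds `fc_threshold`. Rows are ranked by
#' fold change then by normalised control signal.
#'
#' @param control,treated Merged peak data.frames (one per condition; run
#'   [reproducible_peaks()] upstream if you have replicates).
#' @param annotation Gene annotation (`gene`, `contig`, `tss`, `strand`).
#' @param signal Measured promoter signal table: data.frame (`gene`,
#'   `condition` in `c("control","treated")`, `replicate`, `signal`,
#'   `library_size`) — the re-counted signal at each promoter regardless of
#'   whether a peak was called there.
#' @param n Top-N cut per condition (default 15000).
#' @param window TSS window in bp (default 1000).
#' @param fc_threshold Fold-change cutoff; strictly greater than (default 2).
#' @return data.frame (`gene`, peak coordinates, `tss_distance`,
#'   `control_signal_norm`, `treated_signal_norm`, `fold_change`,
#'   `reduced`), ranked; attribute `n_tss_proximal` records the size of the
#'   control-specific promoter-proximal set before the fold-change filter.
#' @export
reduced_promoter_report <- function(control, treated, annotation, signal,
                                    n = 15000, window = 1000,
                                    fc_threshold = 2) {
  assert_cols(signal, c("gene", "condition", "replicate", "signal",
                        "library_size"), "signal")
  ctrl_top <- top_n_peaks(control, n)
  trt_top <- top_n_peaks(treated, n)
  spec <- control_specific_peaks(ctrl_top, trt_top)$specific
  empty <- data.frame(gene = character(), contig = character(),
                      start = integer(), end = integer(),
                      tss_distance = integer(),
                      control_signal_norm = numeric(),
                      treated_signal_norm = numeric(),
                      fold_change = numeric(), reduced = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(spec)) {
    attr(empty, "n_tss_proximal") <- 0L
    return(empty)
  }
  prox <- tss_proximal(spec, annotation, window)
  if (!nrow(prox)) {
    attr(empty, "n_tss_proximal") <- 0L
    return(empty)
  }
  rows <- lapply(seq_len(nrow(prox)), function(i) {
    g <- prox$gene[i]
    cs <- signal[signal$gene == g & signal$condition == "control", ]
    ts <- signal[signal$gene == g & signal$condition == "treated", ]
    if (!nrow(cs) || !nrow(ts)) return(NULL)
    nf <- normalized_fold_change(cs$signal, ts$signal,
                                 cs$library_size, ts$library_size)
    data.frame(gene = g, contig = prox$contig[i], start = prox$start[i],
               end = prox$end[i], tss_distance = prox$tss_distance[i],
               control_signal_norm = nf$control_signal_norm,
               treated_signal_norm = nf$treated_signal_norm,
               fold_change = nf$fold_change,
               reduced = nf$fold_change > fc_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    attr(empty, "n_tss_proximal") <- nrow(prox)
    return(empty)
  }
  n_prox <- nrow(out)
  out <- out[out$reduced, , drop = FALSE]
  out <- out[order(-out$fold_change, -out$control_signal_norm), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tss_proximal") <- n_prox
  out
}
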