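# Independent brute-force oracles used to pin the fast implementations.
# These deliberately share no code with the package: plain character
# vectors, sliding windows and quadratic loops.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# allowed genome bases per PAM letter for the oracle (N passes N only)
oracle_pam_sets <- function(pam) {
  map <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T", "N"))
  lapply(strsplit(pam, "")[[1]], function(l) map[[l]])
}

# exhaustive sliding-window scan over every position and both strands
oracle_find_sites <- function(genome_chr, protospacer, pam = "NGG",
                              max_mismatch = 3, guide_name = "g") {
  pv <- strsplit(protospacer, "")[[1]]
  L <- length(pv)
  pam_sets <- oracle_pam_sets(pam)
  P <- length(pam_sets)
  rows <- list()
  scan_one <- function(chars, n) {
    hits <- list()
    if (n < L + P) return(hits)
    for (s in 1:(n - L - P + 1)) {
      win <- chars[s:(s + L - 1)]
      mm <- sum(win != pv)
      if (mm > max_mismatch) next
      pamw <- chars[(s + L):(s + L + P - 1)]
      ok <- TRUE
      for (j in 1:P) if (!pamw[j] %in% pam_sets[[j]]) { ok <- FALSE; break }
      if (ok) hits[[length(hits) + 1]] <- list(s = s, mm = mm,
                                               win = paste(win, collapse = ""),
                                               pam = paste(pamw, collapse = ""))
    }
    hits
  }
  for (cname in names(genome_chr)) {
    seq_f <- genome_chr[[cname]]
    n <- nchar(seq_f)
    chars_f <- strsplit(seq_f, "")[[1]]
    for (h in scan_one(chars_f, n)) {
      rows[[length(rows) + 1]] <- data.frame(
        contig = cname, start = h$s - 1L, end = h$s - 1L + L,
        strand = "+", mismatches = h$mm, matched_sequence = h$win,
        pam_sequence = h$pam, guide = guide_name, stringsAsFactors = FALSE)
    }
    chars_r <- strsplit(oracle_revcomp(seq_f), "")[[1]]
    for (h in scan_one(chars_r, n)) {
      # rc position s (1-based, length L) -> forward 0-based [n-s-L+1, n-s+1)
      rows[[length(rows) + 1]] <- data.frame(
        contig = cname, start = n - h$s - L + 1L, end = n - h$s + 1L,
        strand = "-", mismatches = h$mm, matched_sequence = h$win,
        pam_sequence = h$pam, guide = guide_name, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), mismatches = integer(),
               matched_sequence = character(), pam_sequence = character(),
               guide = character(), stringsAsFactors = FALSE)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# quadratic all-pairs interval overlap (half-open)
oracle_overlap_pairs <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$contig[i] == b$contig[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i])
      pairs[[length(pairs) + 1]] <- c(i, j)
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

random_intervals <- function(n, contigs = c("c1", "c2"), max_pos = 5000,
                             max_len = 200) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(contig = sample(contigs, n, replace = TRUE),
             start = start, end = start + sample.int(max_len, n, TRUE),
             stringsAsFactors = FALSE)
}

random_genome_chr <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# mutate k positions of a protospacer (guaranteed base changes)
mutate_proto <- function(proto, k) {
  chars <- strsplit(proto, "")[[1]]
  if (k > 0) {
    idx <- sample(seq_along(chars), k)
    for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# small standard simulation used by several files
small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_contigs = 1, contig_length = 30000, n_genes = 12,
         planted_dmr_genes = c("gene_02", "gene_07"),
         planted_lost_peak_genes = "gene_02"),
    list(...))
  do.call(sim_config, args)
}
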