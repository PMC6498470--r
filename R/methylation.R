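#' Beta value from methylated/unmethylated intensities
#'
#' The array methylation fraction `M / (M + U)`. Probes with zero total
#' intensity are flagged missing (`NA`), never reported as 0.
#'
#' @param M,U Non-negative intensity vectors.
#' @return Numeric vector of beta values in `[0, 1]`, `NA` where
#'   `M + U == 0`.
#' @examples
#' compute_beta(48, 52) # 0.48
#' @export
compute_beta <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  tot <- M + U
  beta <- ifelse(tot > 0, M / tot, NA_real_)
  beta
}

#' Beta-value matrix with sample metadata
#'
#' @param beta Numeric matrix, probes (rows) x samples (columns), values in
#'   `[0, 1]` or `NA` for missing.
#' @param samples data.frame with columns `sample`, `condition`,
#'   `timepoint_days`, `replicate`; `sample` must match `colnames(beta)`.
#' @return Object of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, samples) {
  assert_cols(samples, c("sample", "condition", "timepoint_days", "replicate"))
  beta <- as.matrix(beta)
  if (!identical(colnames(beta), as.character(samples$sample)))
    stop("colnames(beta) must equal samples$sample, in order")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1] (or be NA)")
  structure(list(beta = beta, samples = samples), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%s)\n",
              nrow(x$beta), ncol(x$beta),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' Per-probe differential methylation calls
#'
#' Averages beta values over replicates within each condition and classifies
#' each probe by the mean beta difference `treated - control`:
#' hypermethylated when the difference is at least `threshold`,
#' hypomethylated when at most `-threshold`, otherwise unchanged. Probes
#' missing in any sample of either condition are excluded and tallied in
#' the `qc` attribute; they never contribute a silent zero.
#'
#' @param betas A [beta_matrix()].
#' @param treated,control Condition labels present in the sample sheet.
#' @param threshold Mean-beta-difference cutoff (default 0.2).
#' @return data.frame (`probe`, `mean_beta_treated`, `mean_beta_control`,
#'   `delta_beta`, `direction`) with attribute `qc` listing excluded probes.
#' @export
call_differential_probes <- function(betas, treated, control,
                                     threshold = 0.2) {
  stopifnot(inherits(betas, "beta_matrix"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  conds <- as.character(betas$samples$condition)
  for (lab in c(treated, control))
    if (!lab %in% conds) stop(sprintf("unknown condition label '%s'", lab))
  t_cols <- which(conds == treated)
  c_cols <- which(conds == control)
  b <- betas$beta
  miss <- rowSums(is.na(b[, c(t_cols, c_cols), drop = FALSE])) > 0
  mt <- rowMeans(b[, t_cols, drop = FALSE])
  mc <- rowMeans(b[, c_cols, drop = FALSE])
  delta <- mt - mc
  direction <- ifelse(delta >= threshold, "hyper",
                      ifelse(delta <= -threshold, "hypo", "unchanged"))
  out <- data.frame(probe = rownames(b), mean_beta_treated = mt,
                    mean_beta_control = mc, delta_beta = delta,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[!miss, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- list(n_excluded_missing = sum(miss),
                          excluded_probes = rownames(b)[miss])
  out
}

# expand semicolon-separated gene annotations to one row per (probe, gene)
expand_manifest_genes <- function(manifest) {
  genes <- strsplit(as.character(manifest$gene), ";", fixed = TRUE)
  n <- lengths(genes)
  out <- manifest[rep(seq_len(nrow(manifest)), n), , drop = FALSE]
  out$gene <- unlist(genes)
  rownames(out) <- NULL
  out
}

#' Promoter-level summary of differential probes
#'
#' Counts hypermethylated promoter probes (manifest region groups TSS1500,
#' TSS200, 5UTR) per gene and applies the probe-count promoter rule: a gene
#' is a differentially methylated promoter (DMP) when it carries strictly
#' more than `min_probes` hypermethylated promoter probes (default 3, i.e.
#' at least 4 — a promoter with exactly 3 is not called). Probes annotated
#' to several genes (semicolon-separated) count toward every listed gene.
#'
#' @param calls Output of [call_differential_probes()].
#' @param manifest data.frame (`probe`, `contig`, `pos`, `gene`,
#'   `region_group`).
#' @param min_probes Strict lower bound on hyper probe count (default 3).
#' @param complete If `TRUE`, keep genes with zero hyper probes.
#' @return data.frame (`gene`, `n_hyper_probes`, `n_promoter_probes`,
#'   `mean_beta_treated`, `mean_beta_control`, `is_dmp`), sorted by
#'   decreasing hyper-probe count.
#' @export
summarize_promoters <- function(calls, manifest, min_probes = 3,
                                complete = FALSE) {
  assert_cols(manifest, c("probe", "gene", "region_group"))
  if (!all(calls$probe %in% manifest$probe))
    stop("every called probe must appear in the manifest")
  man <- expand_manifest_genes(manifest)
  man <- man[man$region_group %in% c("TSS1500", "TSS200", "5UTR"), ,
             drop = FALSE]
  m <- merge(man[, c("probe", "gene")], calls, by = "probe")
  if (!nrow(m)) {
    out <- data.frame(gene = character(), n_hyper_probes = integer(),
                      n_promoter_probes = integer(),
                      mean_beta_treated = numeric(),
                      mean_beta_control = numeric(), is_dmp = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  agg <- do.call(rbind, lapply(split(m, m$gene), function(d) {
    data.frame(gene = d$gene[1],
               n_hyper_probes = sum(d$direction == "hyper"),
               n_promoter_probes = nrow(d),
               mean_beta_treated = mean(d$mean_beta_treated),
               mean_beta_control = mean(d$mean_beta_control),
               stringsAsFactors = FALSE)
  }))
  agg$is_dmp <- agg$n_hyper_probes > min_probes
  if (!complete) agg <- agg[agg$n_hyper_probes > 0, , drop = FALSE]
  agg <- agg[order(-agg$n_hyper_probes, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Overlap and concordance of two hypermethylated-probe sets
#'
#' Concordance is the overlap size divided by the smaller set, reported as
#' a percentage: with 1876 shared probes between sets of 2966 and 2018 this
#' is 93% (92.96 before rounding). Undefined (flagged `NA`) when either set
#' is empty.
#'
#' @param probes_a,probes_b Character vectors of probe ids (e.g. hyper
#'   probes at two timepoints).
#' @return List with `overlap` (character vector), `n_a`, `n_b`,
#'   `n_overlap`, and `concordance_pct`.
#' @export
persistence_overlap <- function(probes_a, probes_b) {
  probes_a <- unique(as.character(probes_a))
  probes_b <- unique(as.character(probes_b))
  ov <- intersect(probes_a, probes_b)
  pct <- if (!length(probes_a) || !length(probes_b)) {
    warning("concordance undefined for an empty probe set")
    NA_real_
  } else {
    100 * length(ov) / min(length(probes_a), length(probes_b))
  }
  list(overlap = ov, n_a = length(probes_a), n_b = length(probes_b),
       n_overlap = length(ov), concordance_pct = pct)
}

#' Partition DMP genes of two timepoints
#'
#' @param summaries_a,summaries_b Outputs of [summarize_promoters()]
#'   computed with the same manifest and thresholds.
#' @return List with `a_only`, `shared`, `b_only` gene sets (disjoint).
#' @export
venn_dmps <- function(summaries_a, summaries_b) {
  a <- summaries_a$gene[summaries_a$is_dmp]
  b <- summaries_b$gene[summaries_b$is_dmp]
  list(a_only = setdiff(a, b), shared = intersect(a, b),
       b_only = setdiff(b, a))
}

#' Hypermethylated CpGs near predicted off-target sites
#'
#' Expands each hypermethylated probe's CpG by one nucleosome of flank
#' (default +/-146 bp) and intersects the expanded windows with predicted
#' off-target sites. An empty result is the expected specificity outcome.
#'
#' @param calls Output of [call_differential_probes()]; only rows with
#'   `direction == "hyper"` are used.
#' @param manifest Probe manifest (`probe`, `contig`, `pos` 1-based).
#' @param sites Off-target sites from [find_sites()].
#' @param flank Flank in bp (default 146).
#' @return data.frame of (probe, site) pairs with coordinates; zero rows
#'   when there is no overlap.
#' @export
hyper_cpgs_near_offtargets <- function(calls, manifest, sites, flank = 146) {
  assert_cols(manifest, c("probe", "contig", "pos"))
  hyper <- calls$probe[calls$direction == "hyper"]
  man <- manifest[manifest$probe %in% hyper, , drop = FALSE]
  man <- man[!duplicated(man$probe), , drop = FALSE]
  empty <- data.frame(probe = character(), contig = character(),
                      cpg_pos = integer(), site_start = integer(),
                      site_end = integer(), site_strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (!nrow(man) || !nrow(sites)) return(empty)
  # CpG cytosine at 1-based pos -> 0-based half-open [pos-1, pos)
  cpgs <- data.frame(contig = man$contig, start = man$pos - 1L,
                     end = man$pos, stringsAsFactors = FALSE)
  cpgs <- expand_interval(cpgs, flank = flank)
  pairs <- intersect_intervals(cpgs, sites)
  if (!nrow(pairs)) return(empty)
  data.frame(probe = man$probe[pairs$a_index],
             contig = pairs$contig,
             cpg_pos = man$pos[pairs$a_index],
             site_start = sites$start[pairs$b_index],
             site_end = sites$end[pairs$b_index],
             site_strand = sites$strand[pairs$b_index],
             mismatches = sites$mismatches[pairs$b_index],
             stringsAsFactors = FALSE)
}
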