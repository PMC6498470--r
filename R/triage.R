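#' Run configuration for the integrated pipeline
#'
#' Collects the file paths and the analysis thresholds of one end-to-end
#' run. The threshold defaults are the workflow's canonical values: a mean
#' beta difference of 0.2, more than 3 hyper probes per promoter, a 1-kb
#' TSS window, top-15000 peaks, a twofold peak-reduction cutoff, a 146-bp
#' nucleosome flank, and an NGG PAM with up to three mismatches.
#'
#' @param target_gene The declared on-target gene.
#' @param paths Named list of input paths: `genome_fasta`,
#'   `annotation_bed`, `manifest_tsv`, `beta_a_tsv`, `samples_a_tsv`,
#'   `beta_b_tsv`, `samples_b_tsv`, `control_peaks` (character vector of
#'   narrowPeak files), `treated_peaks`, `signal_tsv`, `guides_tsv`
#'   (columns `name`, `protospacer`).
#' @param outdir Output directory for the report bundle.
#' @param delta_beta,min_probes,tss_window,top_n,fc_threshold,flank,max_mismatch,pam
#'   Analysis thresholds (see above).
#' @param treated_label,control_label Condition labels in the sample
#'   sheets.
#' @return Object of class `run_config`.
#' @export
run_config <- function(target_gene, paths, outdir,
                       delta_beta = 0.2, min_probes = 3,
                       tss_window = 1000, top_n = 15000,
                       fc_threshold = 2, flank = 146,
                       max_mismatch = 3, pam = "NGG",
                       treated_label = "treated",
                       control_label = "control") {
  for (v in c(delta_beta, min_probes, tss_window, top_n, fc_threshold,
              flank, max_mismatch))
    if (!is.numeric(v) || v < 0) stop("thresholds must be non-negative")
  structure(list(target_gene = target_gene, paths = paths, outdir = outdir,
                 delta_beta = delta_beta, min_probes = min_probes,
                 tss_window = tss_window, top_n = top_n,
                 fc_threshold = fc_threshold, flank = flank,
                 max_mismatch = max_mismatch, pam = pam,
                 treated_label = treated_label,
                 control_label = control_label),
            class = "run_config")
}

#' Integrate methylation, peak-loss and off-target evidence per gene
#'
#' One row per gene appearing in any evidence layer. A gene is a
#' `candidate_off_target` when it is a persistent differentially
#' methylated promoter (DMP at both timepoints) AND shows reduced promoter
#' H3K27ac, and is not the declared target; the declared target is always
#' `on_target`. Genes with only (any-timepoint) methylation evidence are
#' `methylation_only`, with only peak evidence `peak_only`, otherwise
#' `background`. Predicted off-target proximity is reported as evidence
#' but does not gate the classification.
#'
#' @param dmps_a,dmps_b Promoter summaries ([summarize_promoters()]) at the
#'   two timepoints.
#' @param reduced_report Output of [reduced_promoter_report()].
#' @param offtarget_pairs Output of [hyper_cpgs_near_offtargets()].
#' @param target_gene Declared on-target gene.
#' @param all_genes Gene universe (annotation); the target must be in it.
#' @param manifest Probe manifest, used to map off-target-proximal probes
#'   to genes.
#' @return data.frame of triage rows, ranked with `on_target` first, then
#'   `candidate_off_target` by hyper-probe count.
#' @export
integrate_evidence <- function(dmps_a, dmps_b, reduced_report,
                               offtarget_pairs, target_gene, all_genes,
                               manifest = NULL) {
  if (!target_gene %in% all_genes)
    stop(sprintf("target gene '%s' absent from annotation", target_gene))
  near_genes <- character(0)
  if (!is.null(manifest) && nrow(offtarget_pairs)) {
    man <- expand_manifest_genes(manifest)
    near_genes <- unique(man$gene[man$probe %in% offtarget_pairs$probe])
  }
  genes <- unique(c(dmps_a$gene, dmps_b$gene, reduced_report$gene,
                    near_genes, target_gene))
  rows <- lapply(genes, function(g) {
    ia <- match(g, dmps_a$gene); ib <- match(g, dmps_b$gene)
    dmp_a <- !is.na(ia) && dmps_a$is_dmp[ia]
    dmp_b <- !is.na(ib) && dmps_b$is_dmp[ib]
    n_hyper <- if (!is.na(ib)) dmps_b$n_hyper_probes[ib]
               else if (!is.na(ia)) dmps_a$n_hyper_probes[ia] else 0L
    ir <- match(g, reduced_report$gene)
    reduced <- !is.na(ir) && isTRUE(reduced_report$reduced[ir])
    fc <- if (!is.na(ir)) reduced_report$fold_change[ir] else NA_real_
    persistent <- dmp_a && dmp_b
    any_dmp <- dmp_a || dmp_b
    cls <- if (g == target_gene) "on_target"
      else if (persistent && reduced) "candidate_off_target"
      else if (any_dmp && !reduced) "methylation_only"
      else if (reduced && !any_dmp) "peak_only"
      else if (any_dmp && reduced) "methylation_only"  # non-persistent DMP
      else "background"
    data.frame(gene = g, n_hyper_probes = n_hyper,
               is_persistent_dmp = persistent,
               has_reduced_h3k27ac = reduced,
               h3k27ac_fold_change = fc,
               near_predicted_offtarget = g %in% near_genes,
               classification = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rank <- c(on_target = 1, candidate_off_target = 2, methylation_only = 3,
            peak_only = 4, background = 5)
  out <- out[order(rank[out$classification], -out$n_hyper_probes,
                   out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Execute the full assessment pipeline from files
#'
#' Reads all inputs named in the [run_config()], runs differential
#' methylation at both timepoints, the DMP Venn partition, the reduced
#' promoter H3K27ac report, the off-target search with nucleosome-flank
#' intersection against persistent hyper CpGs, and the per-gene
#' integration. All intermediate tables, a JSON log of every threshold
#' used, and the final triage table are written under `config$outdir`.
#' Fully deterministic: no randomness is consumed.
#'
#' @param config A [run_config()].
#' @return Invisible list with every intermediate and the final `triage`
#'   table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$paths
  needed <- c(p$genome_fasta, p$annotation_bed, p$manifest_tsv,
              p$beta_a_tsv, p$samples_a_tsv, p$beta_b_tsv, p$samples_b_tsv,
              p$control_peaks, p$treated_peaks, p$signal_tsv, p$guides_tsv)
  missing <- needed[!file.exists(needed)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  manifest <- stage("inputs", read_tsv(p$manifest_tsv))
  annotation <- stage("inputs", read_annotation_bed(p$annotation_bed))

  # -- methylation, two timepoints
  calls_a <- stage("methdiff", {
    b <- read_beta_tsv(p$beta_a_tsv, p$samples_a_tsv)
    call_differential_probes(b, config$treated_label, config$control_label,
                             config$delta_beta)
  })
  calls_b <- stage("methdiff", {
    b <- read_beta_tsv(p$beta_b_tsv, p$samples_b_tsv)
    call_differential_probes(b, config$treated_label, config$control_label,
                             config$delta_beta)
  })
  dmps_a <- stage("methdiff",
                  summarize_promoters(calls_a, manifest, config$min_probes))
  dmps_b <- stage("methdiff",
                  summarize_promoters(calls_b, manifest, config$min_probes))
  venn <- stage("venn", venn_dmps(dmps_a, dmps_b))
  persist <- stage("persistence", persistence_overlap(
    calls_a$probe[calls_a$direction == "hyper"],
    calls_b$probe[calls_b$direction == "hyper"]))

  # -- peaks
  reduced <- stage("peaks", {
    ctrl_reps <- lapply(p$control_peaks, read_narrowpeak)
    trt_reps <- lapply(p$treated_peaks, read_narrowpeak)
    ctrl <- if (length(ctrl_reps) > 1) reproducible_peaks(ctrl_reps)
            else ctrl_reps[[1]]
    trt <- if (length(trt_reps) > 1) reproducible_peaks(trt_reps)
           else trt_reps[[1]]
    signal <- read_tsv(p$signal_tsv)
    reduced_promoter_report(ctrl, trt, annotation, signal,
                            n = config$top_n, window = config$tss_window,
                            fc_threshold = config$fc_threshold)
  })

  # -- off-target prediction and proximity to persistent hyper CpGs
  sites <- stage("offtarget", {
    genome <- read_genome_fasta(p$genome_fasta)
    guides <- read_tsv(p$guides_tsv)
    do.call(rbind, lapply(seq_len(nrow(guides)), function(i) {
      find_sites(genome,
                 guide_rna(guides$name[i], guides$protospacer[i],
                           config$pam),
                 config$max_mismatch)
    }))
  })
  persistent_hyper <- calls_b[calls_b$probe %in% persist$overlap, ,
                              drop = FALSE]
  pairs <- stage("offtarget",
                 hyper_cpgs_near_offtargets(persistent_hyper, manifest,
                                            sites, config$flank))

  triage <- stage("integrate",
                  integrate_evidence(dmps_a, dmps_b, reduced, pairs,
                                     config$target_gene, annotation$gene,
                                     manifest))

  # -- report bundle
  write_tsv(calls_a, out("probe_calls_timepoint_a.tsv"))
  write_tsv(calls_b, out("probe_calls_timepoint_b.tsv"))
  write_tsv(dmps_a, out("promoter_summary_timepoint_a.tsv"))
  write_tsv(dmps_b, out("promoter_summary_timepoint_b.tsv"))
  venn_df <- data.frame(
    gene = c(venn$a_only, venn$shared, venn$b_only),
    set = rep(c("a_only", "shared", "b_only"),
              c(length(venn$a_only), length(venn$shared),
                length(venn$b_only))), stringsAsFactors = FALSE)
  write_tsv(venn_df, out("venn_dmps.tsv"))
  write_tsv(sites, out("offtarget_sites.tsv"))
  write_tsv(pairs, out("hyper_cpg_offtarget_pairs.tsv"))
  write_tsv(reduced, out("reduced_promoters.tsv"))
  write_tsv(triage, out("triage.tsv"))
  jsonlite::write_json(
    list(thresholds = config[c("delta_beta", "min_probes", "tss_window",
                               "top_n", "fc_threshold", "flank",
                               "max_mismatch", "pam")],
         target_gene = config$target_gene,
         concordance_pct = persist$concordance_pct,
         n_hyper_a = persist$n_a, n_hyper_b = persist$n_b,
         n_overlap = persist$n_overlap),
    out("run_log.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(calls_a = calls_a, calls_b = calls_b, dmps_a = dmps_a,
                 dmps_b = dmps_b, venn = venn, persistence = persist,
                 reduced = reduced, sites = sites, pairs = pairs,
                 triage = triage))
}

#' Generate a complete synthetic input bundle on disk
#'
#' Runs every generator and writes all input files a [run_pipeline()] run
#' needs, together with a ground-truth JSON sidecar. Timepoint A plants
#' `cfg$planted_dmr_genes` plus any `transient_genes` (DMP only at A);
#' timepoint B plants `cfg$planted_dmr_genes` only, so those are the
#' persistent DMPs. A guide is planted at the target gene's TSS with a
#' valid PAM.
#'
#' @param cfg A [sim_config()].
#' @param outdir Directory to write into.
#' @param target_gene Declared target (defaults to the first planted DMR
#'   gene).
#' @param transient_genes Genes hypermethylated at timepoint A only.
#' @return A [run_config()] pointing at the generated files.
#' @export
simulate_run <- function(cfg, outdir,
                         target_gene = cfg$planted_dmr_genes[1],
                         transient_genes = character()) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(outdir, x)

  genome0 <- make_genome(cfg)
  ann <- make_annotation(genome0, cfg)
  genome <- ann$genome

  # plant the guide protospacer + AGG PAM just upstream of the target TSS
  planted <- plant_guide_site(genome, ann$annotation, target_gene)
  genome <- planted$genome
  guides <- data.frame(name = "guide_1", protospacer = planted$protospacer,
                       stringsAsFactors = FALSE)

  bm_a <- simulate_beta_matrix(
    ann$manifest, cfg, timepoint = 17,
    planted_genes = unique(c(cfg$planted_dmr_genes, transient_genes)))
  bm_b <- simulate_beta_matrix(ann$manifest, cfg, timepoint = 24,
                               planted_genes = cfg$planted_dmr_genes)
  pk <- simulate_peaks(ann$annotation, cfg)

  write_genome_fasta(genome, f("genome.fa"))
  write_annotation_bed(ann$annotation, f("annotation.bed"))
  write_tsv(ann$manifest, f("manifest.tsv"))
  write_beta_tsv(bm_a$betas, f("beta_d17.tsv"), f("samples_d17.tsv"))
  write_beta_tsv(bm_b$betas, f("beta_d24.tsv"), f("samples_d24.tsv"))
  ctrl_paths <- character(0); trt_paths <- character(0)
  for (nm in names(pk$peaks)) {
    path <- f(paste0(nm, ".narrowPeak"))
    write_narrowpeak(pk$peaks[[nm]], path)
    if (startsWith(nm, "control")) ctrl_paths <- c(ctrl_paths, path)
    else trt_paths <- c(trt_paths, path)
  }
  write_tsv(pk$signal, f("promoter_signal.tsv"))
  write_tsv(guides, f("guides.tsv"))
  jsonlite::write_json(
    list(dmr_genes = cfg$planted_dmr_genes,
         transient_genes = transient_genes,
         lost_peak_genes = cfg$planted_lost_peak_genes,
         peak_loss_ratio = cfg$peak_loss_ratio,
         target_gene = target_gene, seed = cfg$seed),
    f("ground_truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  run_config(target_gene = target_gene,
             paths = list(genome_fasta = f("genome.fa"),
                          annotation_bed = f("annotation.bed"),
                          manifest_tsv = f("manifest.tsv"),
                          beta_a_tsv = f("beta_d17.tsv"),
                          samples_a_tsv = f("samples_d17.tsv"),
                          beta_b_tsv = f("beta_d24.tsv"),
                          samples_b_tsv = f("samples_d24.tsv"),
                          control_peaks = ctrl_paths,
                          treated_peaks = trt_paths,
                          signal_tsv = f("promoter_signal.tsv"),
                          guides_tsv = f("guides.tsv")),
             outdir = f("report"))
}

# write a 19-nt protospacer + AGG at [tss-250, tss-227) of the target gene;
# the location avoids every planted probe CpG at the default 14-probe layout
plant_guide_site <- function(genome, annotation, target_gene) {
  i <- match(target_gene, annotation$gene)
  if (is.na(i)) stop("target gene absent from annotation")
  ci <- match(annotation$contig[i], names(genome))
  seqs <- as.character(genome)
  start <- annotation$tss[i] - 250L   # 1-based
  proto <- withr::with_seed(derive_seed(1L, paste0("guide", target_gene)), {
    paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE), collapse = "")
  })
  site <- paste0(proto, "AGG")
  substr(seqs[ci], start, start + nchar(site) - 1L) <- site
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(genome)
  list(protospacer = proto, genome = g)
}
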