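test_that("make_genome honours length, GC and determinism", {
  cfg <- sim_config(seed = 1, n_contigs = 1, contig_length = 10000,
                    gc_fraction = 0.5, n_genes = 4)
  g <- make_genome(cfg)
  expect_equal(as.integer(Biostrings::width(g)), 10000L)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(make_genome(cfg), f1)
  write_genome_fasta(make_genome(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  g_gc <- make_genome(sim_config(seed = 2, contig_length = 1000,
                                 gc_fraction = 1, n_genes = 1))
  expect_true(grepl("^[GC]+$", as.character(g_gc[[1]])))

  expect_error(make_genome(sim_config(seed = 1, contig_length = 999)),
               "contig_length")
  expect_error(sim_config(contig_length = -5), "positive")
  expect_error(sim_config(gc_fraction = 1.2), "fraction")
})

test_that("make_annotation places strand-aware promoter probes on CpGs", {
  cfg <- small_cfg()
  ann <- make_annotation(make_genome(cfg), cfg)
  # 14 manifest rows per gene, covering all three region groups
  counts <- table(ann$manifest$gene)
  expect_true(all(counts == 14))
  expect_setequal(unique(ann$manifest$region_group),
                  c("TSS1500", "TSS200", "5UTR"))

  # every probe position carries a CG dinucleotide in the edited genome
  seqs <- as.character(ann$genome)
  dinuc <- substring(seqs[ann$manifest$contig], ann$manifest$pos,
                     ann$manifest$pos + 1L)
  expect_true(all(dinuc == "CG"))

  # strand-aware window oracle: upstream groups sit on the TSS side given
  # by the strand; 5'UTR on the opposite side
  m <- merge(ann$manifest, ann$annotation, by = c("gene", "contig"))
  up <- m[m$region_group %in% c("TSS1500", "TSS200"), ]
  expect_true(all(ifelse(up$strand == "+", up$pos < up$tss,
                         up$pos > up$tss)))
  utr <- m[m$region_group == "5UTR", ]
  expect_true(all(ifelse(utr$strand == "+", utr$pos > utr$tss,
                         utr$pos < utr$tss)))
  # minus-strand TSS1500 probes lie at coordinates greater than the TSS
  mi <- m[m$strand == "-" & m$region_group == "TSS1500", ]
  expect_gt(nrow(mi), 0)
  expect_true(all(mi$pos > mi$tss))

  # promoter windows of distinct genes never overlap
  spans <- do.call(rbind, lapply(split(m, m$gene), function(d)
    data.frame(contig = d$contig[1], start = min(d$pos),
               end = max(d$pos) + 1L)))
  ov <- oracle_overlap_pairs(spans, spans)
  expect_true(all(ov[, 1] == ov[, 2]))

  expect_error(
    make_annotation(make_genome(sim_config(seed = 1, contig_length = 3000,
                                           n_genes = 50)),
                    sim_config(seed = 1, contig_length = 3000,
                               n_genes = 50)),
    "too small")
})

test_that("simulate_beta_matrix plants the stated methylation contrast", {
  # enough planted draws for a tight empirical mean
  cfg <- sim_config(seed = 5, n_contigs = 2, contig_length = 45000,
                    n_genes = 40,
                    planted_dmr_genes = sprintf("gene_%02d", 1:20))
  ann <- make_annotation(make_genome(cfg), cfg)
  sim <- simulate_beta_matrix(ann$manifest, cfg)
  b <- sim$betas
  treated <- b$samples$condition == "treated"
  planted <- rownames(b$beta) %in% sim$truth$planted_probes

  expect_true(all(b$beta >= 0 & b$beta <= 1))
  expect_lt(abs(mean(b$beta[planted, treated]) - 0.48), 0.02)
  expect_lt(abs(mean(b$beta[!planted, treated]) - 0.07), 0.02)
  expect_lt(abs(mean(b$beta[, !treated]) - 0.07), 0.02)
  # planted deltas are nonzero exactly for promoter probes of DMR genes
  expect_setequal(names(which(sim$truth$per_probe_planted_delta != 0)),
                  sim$truth$planted_probes)
  expect_equal(unique(sim$truth$per_probe_planted_delta[
    sim$truth$planted_probes]), 0.48 - 0.07)

  # infinite precision degenerates to the exact means
  cfg_inf <- sim_config(seed = 5, n_contigs = 1, contig_length = 10000,
                        n_genes = 3, planted_dmr_genes = "gene_01",
                        beta_precision = Inf)
  ann_i <- make_annotation(make_genome(cfg_inf), cfg_inf)
  sim_i <- simulate_beta_matrix(ann_i$manifest, cfg_inf)
  ti <- sim_i$betas$samples$condition == "treated"
  pl <- rownames(sim_i$betas$beta) %in% sim_i$truth$planted_probes
  expect_true(all(sim_i$betas$beta[pl, ti] == 0.48))
  expect_true(all(sim_i$betas$beta[!pl, ] == 0.07))

  expect_error(sim_config(beta_precision = 0), "beta_precision")
  expect_error(simulate_beta_matrix(ann$manifest, cfg,
                                    planted_genes = "nope"), "subset")
})

test_that("simulate_peaks plants recoverable promoter losses", {
  cfg <- small_cfg(seed = 9)
  ann <- make_annotation(make_genome(cfg), cfg)
  pk <- simulate_peaks(ann$annotation, cfg)
  expect_length(pk$peaks, 4)  # 2 conditions x 2 replicates

  # all intervals within contig bounds
  for (df in pk$peaks) {
    expect_true(all(df$start >= 0))
    expect_true(all(df$end <= cfg$contig_length))
    expect_true(all(df$start < df$end))
  }
  # lost gene's promoter peak present in control, absent in treated
  expect_true(all(vapply(pk$peaks[c("control_rep1", "control_rep2")],
                         function(df) "gene_02_promoter" %in% df$name,
                         logical(1))))
  expect_false(any(vapply(pk$peaks[c("treated_rep1", "treated_rep2")],
                          function(df) "gene_02_promoter" %in% df$name,
                          logical(1))))
  # measured signal ratio at the lost gene ~ planted 4-fold
  s <- pk$signal
  cpm <- s$signal / s$library_size
  r <- mean(cpm[s$gene == "gene_02" & s$condition == "control"]) /
    mean(cpm[s$gene == "gene_02" & s$condition == "treated"])
  expect_lt(abs(log(r / cfg$peak_loss_ratio)), 0.5)

  # ratio 1 -> null planting: treated keeps every promoter peak
  cfg1 <- small_cfg(seed = 9, peak_loss_ratio = 1)
  pk1 <- simulate_peaks(ann$annotation, cfg1)
  expect_true("gene_02_promoter" %in% pk1$peaks$treated_rep1$name)
})

test_that("simulate_bisulfite_clones follows the conversion model", {
  amp <- amplicon_reference("amp", paste0(
    "AT", strrep("CGAAC", 8), "CCATG"))  # CpGs + non-CpG Cs
  cfg <- sim_config(seed = 2, n_genes = 1, clone_count = 5,
                    conversion_rate = 1)
  # prob 1, conversion 1: CpG Cs retained, every other C converted
  sim <- simulate_bisulfite_clones(amp, cfg, methylation_probs = 1)
  for (r in sim$reads) {
    chars <- strsplit(r, "")[[1]]
    expect_true(all(chars[amp$cpg_positions] == "C"))
    ref_chars <- strsplit(amp$sequence, "")[[1]]
    non_cpg_c <- setdiff(which(ref_chars == "C"), amp$cpg_positions)
    expect_true(all(chars[non_cpg_c] == "T"))
  }
  # prob 0: every CpG converted
  sim0 <- simulate_bisulfite_clones(amp, cfg, methylation_probs = 0)
  for (r in sim0$reads)
    expect_true(all(strsplit(r, "")[[1]][amp$cpg_positions] == "T"))

  expect_error(amplicon_reference("x", ""), "nonempty")
  expect_error(simulate_bisulfite_clones(
    amplicon_reference("nocpg", "ATATAT"), cfg), "CpG")

  # deterministic per seed
  expect_identical(simulate_bisulfite_clones(amp, cfg, 0.5)$reads,
                   simulate_bisulfite_clones(amp, cfg, 0.5)$reads)
})

test_that("simulate_cq recovers fold changes in the noiseless limit", {
  design <- data.frame(
    sample = c("ctrl_1", "ctrl_2", "trt_1", "trt_2"),
    condition = rep(c("control", "treated"), each = 2),
    gene = "HER2", fold_change = c(1, 1, 0.5, 0.5),
    stringsAsFactors = FALSE)
  cfg0 <- sim_config(seed = 3, n_genes = 1, cq_noise_sd = 0)
  sim <- simulate_cq(design, cfg0)
  res <- relative_expression(sim$cq, "GAPDH", "control")
  trt <- res$per_sample[res$per_sample$condition == "treated", ]
  expect_equal(trt$fold_change, c(0.5, 0.5))
  expect_equal(trt$repression_fold, c(2, 2))
  ctrl <- res$per_sample[res$per_sample$condition == "control", ]
  expect_equal(mean(ctrl$fold_change), 1)

  # twofold-repression regime recovered within noise
  cfg <- sim_config(seed = 3, n_genes = 1, cq_noise_sd = 0.15)
  res2 <- relative_expression(simulate_cq(design, cfg)$cq, "GAPDH",
                              "control")
  fc <- res2$per_condition$fold_change_geomean[
    res2$per_condition$condition == "treated"]
  expect_lt(abs(log2(fc) - log2(0.5)), 0.5)

  expect_error(simulate_cq(transform(design, fold_change = -1), cfg),
               "> 0")
})

test_that("generators are deterministic under a fixed master seed", {
  cfg <- small_cfg(seed = 42)
  a1 <- make_annotation(make_genome(cfg), cfg)
  a2 <- make_annotation(make_genome(cfg), cfg)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(a1$manifest, a2$manifest)
  expect_identical(simulate_beta_matrix(a1$manifest, cfg)$betas$beta,
                   simulate_beta_matrix(a2$manifest, cfg)$betas$beta)
  expect_identical(simulate_peaks(a1$annotation, cfg)$peaks,
                   simulate_peaks(a2$annotation, cfg)$peaks)
})
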