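make_betas <- function(vals, conditions) {
  # vals: probes x samples matrix
  samples <- data.frame(sample = colnames(vals), condition = conditions,
                        timepoint_days = 17,
                        replicate = stats::ave(seq_along(conditions),
                                               conditions, FUN = seq_along),
                        stringsAsFactors = FALSE)
  beta_matrix(vals, samples)
}

test_that("compute_beta is M/(M+U) with missing flagged, never zero", {
  expect_equal(compute_beta(5, 5), 0.5)
  expect_equal(compute_beta(0, 7), 0)
  expect_equal(compute_beta(7, 0), 1)
  expect_equal(compute_beta(48, 52), 0.48)
  expect_true(is.na(compute_beta(0, 0)))
  expect_equal(compute_beta(c(1, 0), c(1, 0)), c(0.5, NA))
  expect_error(compute_beta(-1, 2), "non-negative")
})

test_that("call_differential_probes applies the 0.2 mean-delta rule", {
  vals <- matrix(c(0.07, 0.07, 0.48, 0.48,   # hyper probe
                   0.50, 0.50, 0.10, 0.10,   # hypo probe
                   0.30, 0.30, 0.40, 0.40,   # unchanged (delta 0.1)
                   0.10, NA,   0.50, 0.50),  # missing -> excluded
                 nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("p", 1:4),
                                 c("c1", "c2", "t1", "t2")))
  b <- make_betas(vals, c("control", "control", "treated", "treated"))
  calls <- call_differential_probes(b, "treated", "control")
  expect_equal(calls$direction, c("hyper", "hypo", "unchanged"))
  expect_equal(calls$delta_beta[1], 0.41)
  expect_equal(attr(calls, "qc")$n_excluded_missing, 1)
  expect_equal(attr(calls, "qc")$excluded_probes, "p4")
  # partition: hyper + hypo + unchanged + excluded = total probes
  expect_equal(nrow(calls) + attr(calls, "qc")$n_excluded_missing,
               nrow(vals))

  # null comparison: identical matrices give no calls either way
  vals0 <- vals[1:3, c(1, 2, 1, 2)]
  colnames(vals0) <- c("c1", "c2", "t1", "t2")
  b0 <- make_betas(vals0, c("control", "control", "treated", "treated"))
  calls0 <- call_differential_probes(b0, "treated", "control")
  expect_true(all(calls0$direction == "unchanged"))

  expect_error(call_differential_probes(b, "nope", "control"),
               "unknown condition")
  expect_error(call_differential_probes(b, "treated", "control",
                                        threshold = 0), "threshold")
})

test_that("planted synthetic deltas are recovered exactly at defaults", {
  cfg <- small_cfg(seed = 21,
                   planted_dmr_genes = sprintf("gene_%02d", c(2, 5, 7, 9)))
  ann <- make_annotation(make_genome(cfg), cfg)
  sim <- simulate_beta_matrix(ann$manifest, cfg)
  calls <- call_differential_probes(sim$betas, "treated", "control")
  hyper <- calls$probe[calls$direction == "hyper"]
  expect_setequal(hyper, sim$truth$planted_probes)  # all 56 and only those
  expect_length(hyper, 4 * 14)
  expect_equal(sum(calls$direction == "hypo"), 0)
  # mean planted delta ~ 0.41
  expect_lt(abs(mean(calls$delta_beta[calls$probe %in% hyper]) - 0.41),
            0.02)
})

test_that("threshold monotonicity and hyper/hypo symmetry hold", {
  cfg <- small_cfg(seed = 33)
  ann <- make_annotation(make_genome(cfg), cfg)
  sim <- simulate_beta_matrix(ann$manifest, cfg)
  b <- sim$betas
  counts <- sapply(c(0.1, 0.2, 0.3, 0.5), function(th) {
    calls <- call_differential_probes(b, "treated", "control", th)
    c(hyper = sum(calls$direction == "hyper"),
      hypo = sum(calls$direction == "hypo"))
  })
  expect_true(all(diff(counts["hyper", ]) <= 0))
  expect_true(all(diff(counts["hypo", ]) <= 0))

  # negating the scale (1 - beta) swaps hyper and hypo exactly
  flipped <- beta_matrix(1 - b$beta, b$samples)
  calls <- call_differential_probes(b, "treated", "control")
  calls_f <- call_differential_probes(flipped, "treated", "control")
  expect_equal(calls$probe[calls$direction == "hyper"],
               calls_f$probe[calls_f$direction == "hypo"])
  expect_equal(calls$probe[calls$direction == "hypo"],
               calls_f$probe[calls_f$direction == "hyper"])
})

test_that("summarize_promoters implements the strict >3-probe rule", {
  # 3 genes: 4 hyper probes, exactly 3, and 12
  manifest <- data.frame(
    probe = sprintf("p%02d", 1:20),
    contig = "c", pos = seq(100, by = 50, length.out = 20),
    gene = c(rep("SHOX2like", 4), rep("edge3", 3), rep("HER2like", 12),
             "other"),
    region_group = c(rep("TSS200", 19), "other"),
    stringsAsFactors = FALSE)
  calls <- data.frame(probe = manifest$probe,
                      mean_beta_treated = 0.5, mean_beta_control = 0.1,
                      delta_beta = 0.4,
                      direction = c(rep("hyper", 19), "hyper"),
                      stringsAsFactors = FALSE)
  s <- summarize_promoters(calls, manifest)
  expect_equal(s$gene[1], "HER2like")        # top-ranked by count
  expect_equal(s$n_hyper_probes[1], 12)
  expect_true(s$is_dmp[s$gene == "HER2like"])
  expect_true(s$is_dmp[s$gene == "SHOX2like"])   # 4 probes -> DMP
  expect_false(s$is_dmp[s$gene == "edge3"])      # exactly 3 -> not a DMP
  expect_false("other" %in% s$gene)  # non-promoter group never counted

  # raising min_probes never increases the DMP count
  n_dmp <- sapply(c(1, 3, 5, 11), function(mp)
    sum(summarize_promoters(calls, manifest, mp)$is_dmp))
  expect_true(all(diff(n_dmp) <= 0))

  # multi-gene probes count toward every listed gene
  manifest2 <- data.frame(probe = paste0("q", 1:5), contig = "c",
                          pos = 1:5 * 100, gene = "A;B",
                          region_group = "TSS1500",
                          stringsAsFactors = FALSE)
  calls2 <- data.frame(probe = manifest2$probe, mean_beta_treated = 0.5,
                       mean_beta_control = 0.1, delta_beta = 0.4,
                       direction = "hyper", stringsAsFactors = FALSE)
  s2 <- summarize_promoters(calls2, manifest2)
  expect_setequal(s2$gene, c("A", "B"))
  expect_true(all(s2$is_dmp))

  expect_error(summarize_promoters(calls2, manifest), "manifest")
})

test_that("persistence_overlap reproduces the printed concordance", {
  # 1876 shared probes between sets of 2966 and 2018 -> 93%
  shared <- sprintf("s%04d", 1:1876)
  a <- c(shared, sprintf("a%04d", 1:(2966 - 1876)))
  b <- c(shared, sprintf("b%04d", 1:(2018 - 1876)))
  ov <- persistence_overlap(a, b)
  expect_equal(ov$n_overlap, 1876)
  expect_equal(round(ov$concordance_pct, 2), 92.96)
  expect_equal(round(ov$concordance_pct), 93)

  expect_equal(persistence_overlap(a, a)$concordance_pct, 100)
  expect_equal(persistence_overlap(a, sprintf("z%d", 1:5))$concordance_pct,
               0)
  # symmetric
  expect_equal(persistence_overlap(b, a)$concordance_pct,
               ov$concordance_pct)
  expect_warning(ovn <- persistence_overlap(a, character(0)), "undefined")
  expect_true(is.na(ovn$concordance_pct))
})

test_that("venn_dmps partitions DMP genes of two timepoints", {
  sa <- data.frame(gene = c("g1", "g2", "g3"), is_dmp = c(TRUE, TRUE, FALSE))
  sb <- data.frame(gene = c("g2", "g4"), is_dmp = c(TRUE, TRUE))
  v <- venn_dmps(sa, sb)
  expect_equal(v$a_only, "g1")
  expect_equal(v$shared, "g2")
  expect_equal(v$b_only, "g4")
  # identical inputs: everything shared; shared subset of each input
  v2 <- venn_dmps(sa, sa)
  expect_equal(v2$shared, c("g1", "g2"))
  expect_length(v2$a_only, 0)
  expect_true(all(v$shared %in% sa$gene[sa$is_dmp]) &&
                all(v$shared %in% sb$gene[sb$is_dmp]))
})

test_that("hyper_cpgs_near_offtargets matches an all-pairs distance check", {
  manifest <- data.frame(probe = paste0("p", 1:6), contig = "c",
                         pos = c(500L, 1000L, 2000L, 3000L, 4000L, 5000L),
                         gene = "g", region_group = "TSS200",
                         stringsAsFactors = FALSE)
  calls <- data.frame(probe = manifest$probe, direction = "hyper",
                      stringsAsFactors = FALSE)
  # site 300 bp from a CpG: beyond the 146 flank -> no pair
  far <- data.frame(contig = "c", start = 799L, end = 818L,
                    strand = "+", mismatches = 1L)
  expect_equal(nrow(hyper_cpgs_near_offtargets(calls, manifest, far)), 0)
  # site 100 bp away -> one pair
  near <- data.frame(contig = "c", start = 1099L, end = 1118L,
                     strand = "-", mismatches = 2L)
  got <- hyper_cpgs_near_offtargets(calls, manifest, near)
  expect_equal(got$probe, "p2")

  withr::with_seed(8, {
    for (rep in 1:5) {
      sites <- random_intervals(40, contigs = "c", max_pos = 6000,
                                max_len = 19)
      sites$strand <- "+"; sites$mismatches <- 0L
      got <- hyper_cpgs_near_offtargets(calls, manifest, sites)
      cpgs <- data.frame(contig = "c",
                         start = pmax(0L, manifest$pos - 1L - 146L),
                         end = manifest$pos + 146L)
      want <- oracle_overlap_pairs(cpgs, sites)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want))
        expect_setequal(paste(got$probe, got$site_start),
                        paste(manifest$probe[want[, 1]],
                              sites$start[want[, 2]]))
    }
  })
})
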