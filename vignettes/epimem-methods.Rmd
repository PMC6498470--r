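---
title: "epimem: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epimem: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`epimem` assesses whether a transiently delivered epigenome-editing
treatment (dCas9 fused to DNA/histone methyltransferases) left a
persistent and locus-specific repressive state. This vignette documents
the statistical procedures, their assumptions, every tunable parameter,
and the design decisions taken where the underlying workflow left choices
open.

## 1. Differential promoter methylation

Methylation arrays report, per CpG probe, a beta value
$\beta = M/(M+U) \in [0,1]$, the fraction of methylated signal intensity.
`compute_beta()` flags probes with $M+U=0$ as missing rather than
reporting 0 — a zero would masquerade as a confident unmethylated call.

`call_differential_probes()` averages betas over replicates within each
condition (unweighted mean; no variance filter is applied because the
procedure is a fixed-threshold filter, not a hypothesis test — no
multiple-testing correction is involved, deliberately) and classifies
each probe by $\Delta\beta = \bar\beta_{treated} - \bar\beta_{control}$:

* hypermethylated if $\Delta\beta \ge$ `threshold` (default **0.2**, the
  smallest change such arrays detect reliably),
* hypomethylated if $\Delta\beta \le -$`threshold`,
* unchanged otherwise.

Probes missing in *any* required sample are excluded and tallied in a QC
attribute, so hyper + hypo + unchanged + excluded always equals the probe
total (a tested invariant).

`summarize_promoters()` restricts to promoter probes (manifest region
groups TSS1500, TSS200 and 5′UTR — 1500 bp upstream, 200 bp upstream and
the 5′ untranslated region) and applies the promoter rule: a gene is a
differentially methylated promoter (DMP) when it has **strictly more
than** `min_probes` (default 3, i.e. ≥ 4) hypermethylated promoter
probes. The strict inequality matters: a promoter with exactly 4 hyper
probes is called, one with exactly 3 is not. Probes annotated to several
genes (semicolon-separated, RefGene-style) count toward every listed
gene; how multi-gene probes should be apportioned is not standardised, so
this inclusive rule is a documented choice.

Persistence across two timepoints uses two views:

* `persistence_overlap()` on hyper-probe sets, with concordance defined
  as $|A \cap B| / \min(|A|, |B|) \times 100$. With the worked-example
  sizes (1876 shared between 2966 and 2018) this gives 92.96 → 93%. The
  min-set denominator is the definition consistent with that printed
  number; the day-24 denominator happens to give the same rounded value
  here, so the choice is flagged and the denominator is the one
  documented behaviour.
* `venn_dmps()` partitions DMP genes of the two timepoints into
  A-only / shared / B-only.

Manifest positions are 1-based (array-manifest convention); all interval
arithmetic inside the package is 0-based half-open, converted at the I/O
boundary.

## 2. Promoter H3K27ac peak loss

Peak records (narrowPeak, BED6+4, 0-based half-open) are consumed, never
produced — peak calling and alignment are upstream. The pipeline is:

1. `top_n_peaks()` — the `n` (default **15 000**) highest-signalValue
   peaks per condition, ties broken by score then coordinate so the
   selection is deterministic.
2. `reproducible_peaks()` — ENCODE-style naive overlap: a replicate-1
   peak is kept if, in every other replicate, some peak overlaps it by at
   least `min_frac` (default **50%**) of its own length. The workflow
   this emulates names the tool but not the fraction; 50% is the ENCODE
   convention and it is configurable.
3. `control_specific_peaks()` — control peaks with zero ≥ 1-bp overlap
   against the treated set (bedtools default semantics; deliberately a
   different criterion from the reproducibility fraction, and both are
   documented). Specific + shared exactly partition the control set.
4. `tss_proximal()` — peaks whose *center* lies within ± `window`
   (default **1000 bp**) of a TSS. Center = declared summit when present,
   else the floor midpoint. Distances are signed along transcription
   (upstream negative), so a peak centered 288 bp upstream of a
   plus-strand TSS reports −288. Genes with several TSS records keep the
   minimal-|distance| pairing.
5. `normalized_fold_change()` — counts-per-million scaling of signal by
   library size, replicate-averaged, then control/treated ratio. A full
   differential-binding model (e.g. DiffBind's) is *not* reimplemented;
   CPM scaling of signalValue stands in, and this substitution is stated
   here and in the docs. Scaling both libraries by a common factor leaves
   every fold change unchanged (tested). Zero treated signal yields an
   infinite fold change that still classifies as reduced.
6. The classifier: fold change **> 2** (strict) ⇒ "reduced".

`reduced_promoter_report()` composes 1–5 and needs a *measured signal
table* (gene × condition × replicate signal + library size) alongside the
peak lists, because a lost peak is, by definition, absent from the
treated peak list while its residual signal is still measurable — exactly
how re-counting under a consensus peak set works in real differential
binding analyses.

## 3. Off-target site enumeration

`find_sites()` returns every position, on both strands, where the genomic
window is within Hamming distance `max_mismatch` (default **3**) of the
protospacer *and* the immediately 3′ window matches the PAM pattern
(default **NGG**; any IUPAC pattern accepted). Conventions:

* PAM immediately 3′ of the protospacer on the protospacer-matching
  strand (SpCas9 convention).
* Mismatches are counted in the protospacer only, never the PAM.
* Ambiguous genome bases (N) count as protospacer mismatches and fail
  every non-N PAM position — the conservative reading.
* Coordinates are forward-strand, 0-based half-open, protospacer
  footprint only (PAM excluded); overlapping sites are all reported.

The scan is backed by `Biostrings::matchPattern()`; the test-suite pins
it against an independent brute-force sliding-window oracle (plain
character comparison, both strands) on random genomes for every mismatch
budget up to 4, plus monotonicity (`k ⊆ k+1`) and
reverse-complement-symmetry properties.

`expand_interval()` grows intervals by a flank of **146 bp** (one
nucleosome) per side — a 1-bp CpG becomes a 293-bp window — and
`hyper_cpgs_near_offtargets()` intersects the expanded CpGs of
hypermethylated probes with predicted sites. An empty intersection is the
expected *specificity* outcome, so the empty result is first-class, not
an error.

## 4. Bisulfite amplicon calling

Reads are assumed pre-aligned and top-strand oriented (alignment is
upstream and out of scope). At each reference CpG cytosine: read C ⇒
methylated, T ⇒ unmethylated, anything else ambiguous. Conversion
efficiency = fraction of non-CpG reference cytosines read as T; a fully
unconverted artifact clone scores 0. The efficiency floor defaults to
**0** (no filtering) because the emulated workflow states none; when set,
failing clones are flagged and excluded from aggregation, with counts
reported.

Whether a published "average % methylation" is a mean of per-site
percentages or a pooled-call fraction is often unstated. `aggregate_clones()`
computes **both**; the per-site mean is primary because it matches
lollipop-style per-CpG reporting. The two coincide when all sites have
equal informative coverage.

## 5. Relative expression (ddCq)

$dCq = Cq_{target} - Cq_{reference}$ with technical replicates averaged
on the Cq scale (not the expression scale); $ddCq$ subtracts the control
condition's mean dCq per gene; fold change $= 2^{-ddCq}$ assuming
amplification efficiency exactly 2 (no efficiency correction — the
emulated workflow applies none). Biological replicates are summarised by
the geometric mean of fold changes with the SEM on the log2 scale — mean
± SEM reporting without a stated scale was interpreted as log-scale,
logged here as the package's choice. A global Cq shift applied to both
genes of a sample cancels; applied to one gene it does not (both
directions are tested).

## 6. The synthetic stated world

The generators emulate the statistical structure of the real assays so
that planted signals are recoverable by the analysis modules at their
default thresholds; they are first-class, tested code. Defaults encode
the effect sizes the assessed experimental regime operates at:

| parameter | default | meaning |
|---|---|---|
| `planted_beta_mean` | 0.48 | treated-promoter methylation (~48%) |
| `background_beta_mean` | 0.07 | background methylation (~7%) |
| `probes_per_promoter` | 14 | array's average promoter representation |
| `beta_precision` | 50 | Beta concentration (α+β) of replicate noise |
| `n_replicates_per_condition` | 2 | arrays / peak replicates |
| `peak_loss_ratio` | 4 | control/treated promoter signal at lost genes |
| `peak_jitter_sd` | 0.1 | log-normal replicate signal jitter |
| `conversion_rate` | 0.99 | bisulfite conversion probability |
| `cq_noise_sd` | 0.15 | Gaussian Cq noise, cycles |

Choices where the emulated workflow states only part of the picture:

* **Beta noise** is a two-parameter Beta distribution parameterized by
  mean and precision: bounded support matches beta values, and only the
  means (48%/7%) are stated. Precision 50 gives a replicate SD of ≈ 0.07
  at the planted mean — a free parameter, chosen once, not inferred and
  not tuned. At `beta_precision = Inf` draws degenerate to the mean
  exactly (a tested limit).
* **Probe layout**: 5 TSS1500 / 5 TSS200 / 4 5′UTR (only the mean of 14
  is stated); deterministic, strand-aware offsets; a CG dinucleotide is
  written into the genome at every probe position, so the *returned*
  genome must be used downstream.
* **Peak jitter** is multiplicative log-normal (SD 0.1) so signals stay
  positive; promoter signals scale with a per-sample library size drawn
  uniformly in [8, 12] million, so CPM normalisation is genuinely
  exercised rather than being a no-op.
* **Lost peaks**: when the attenuation exceeds twofold the treated peak
  is omitted from the treated peak list (it would no longer be called),
  while its residual signal remains in the measured signal table; at
  `peak_loss_ratio = 1` nothing is omitted (null planting). The default
  ratio 4 spans, with jitter, the 3–4-fold regime in which the strongest
  real losses sit.
* **Seeding** is hierarchical: one master seed, split per generator
  through a deterministic hash kept below $2^{31}$, so each data type can
  be regenerated independently and reruns are byte-identical (tested).
* **Guide planting** (`simulate_run()`) writes a random 19-nt
  protospacer + AGG at TSS−250 of the target gene; at the default
  14-probe layout this window collides with no probe CpG. The target's
  own CpGs then fall within one nucleosome of the on-target site — which
  is biologically expected and is why off-target proximity is reported
  as evidence rather than gating the triage classification.

What the generators do **not** emulate — and therefore what a green test
does not establish: probe-type chemistry and array normalisation (noob),
read-level ChIP-seq signal, PCR and strand bias in bisulfite data,
correlated CpG methylation within a promoter, genome-scale LD of
off-target sites, or amplification-efficiency variation in qPCR. Green
planted-truth tests show the *inference logic* is correct at realistic
effect sizes; they say nothing about upstream measurement artifacts.

## 7. Triage integration

One row per gene in any evidence layer:

* `on_target` — the declared target, always.
* `candidate_off_target` — persistent DMP (DMP at **both** timepoints;
  the single-timepoint mode exists but persistence is the default
  criterion) **and** reduced promoter H3K27ac, and not the target.
* `methylation_only` / `peak_only` — one layer only (any-timepoint DMP
  counts as methylation evidence here).
* `background` — in the evidence universe with neither layer (e.g. only
  off-target proximity).

Predicted off-target proximity is carried as evidence but does not gate
the classification — the sequence-prediction layer and the epigenetic
layers are independent witnesses, and requiring their overlap would
silently hide the interesting disagreements; a configuration flag could
tighten this, and every row carries the raw numbers behind each boolean
for auditability. The gene-level (rather than probe-level) integration is
the documented interpretation of the evidence-overlap step.
`n_hyper_probes` in the triage row is taken from the later timepoint when
the gene is present there (the persistence assay), else from the earlier.

Classification is a partition (exactly one label per gene) and tightening
any threshold never adds candidate rows — both are tested invariants.

## 8. Numerical and degenerate-input policy

* All internal interval logic is 0-based half-open; adjacency is never
  overlap. 1-based conventions (manifest positions, TSS) are converted at
  the I/O boundary.
* Ties in `top_n_peaks()` break by score then coordinate; equal-signal
  inputs are therefore reproducible.
* `M + U = 0`, empty hyper-probe sets, zero treated signal and
  zero-informative CpG sites are all flagged (`NA` / warning / `Inf`)
  rather than silently coerced.
* Errors abort with stage-identified messages in `run_pipeline()`; no
  randomness is consumed there, so a rerun on the same inputs is
  byte-identical.

## 9. Known limitations

* CPM scaling of signalValue is a deliberate simplification of
  differential-binding normalisation; absolute fold changes from real
  DiffBind-style pipelines will differ in detail.
* The off-target scanner is a correctness-first implementation (pinned to
  a brute-force oracle); it does not index the genome and is not tuned
  for whole-genome scans, and it scores nothing (no CFD/MIT scores,
  bulges or non-IUPAC PAMs).
* Replicate-to-replicate beta dispersion is a free simulation parameter;
  real array dispersion is probe-dependent.
* The expression layer is standalone (qPCR checks are reported
  separately) and is not folded into the triage classifier.
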