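---
title: "Reconstructing regulatory networks from paired methylation and expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing regulatory networks from paired methylation and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlink)
```

## The model

DNA methylation at distal cis-regulatory elements (enhancers and related
modules) is a usable proxy for their activity: when an enhancer is engaged in
a subset of samples, the CpGs inside it lose methylation in those samples,
and the genes it drives gain expression. `methlink` reconstructs altered
regulatory networks from this anti-correlation in three steps, using only a
probe-level beta-value matrix (values in [0, 1]), a log2 expression matrix
over the same samples, and genomic annotations:

1. **Differentially methylated CpGs (DMCs).** Among *distal* probes (further
   than `tss_distal_cut` = 2 kb from every annotated TSS), a one-sided Welch
   t test compares beta values between two sample groups in a configured
   direction (`hypo`: group 1 loses methylation). p-values are BH-adjusted
   across all tested probes; a DMC requires `padj <= 0.01`, an absolute
   group-mean difference of at least 0.3 beta, and the right sign.
2. **Probe–gene pairing.** Each DMC is tested against its 20 nearest genes
   (10 by TSS on each side). Samples are split into methylated (M) and
   unmethylated (U) groups at the probe and the gene's expression is compared
   with a one-sided Mann–Whitney test ("U expresses more" for hypo runs). The
   raw p-value is then calibrated with a permutation empirical p-value
   (below); a pair is reported at `pe < 0.001`.
3. **Motif enrichment and master regulators (MRs).** Motif instances within
   ±250 bp of a paired probe assign that motif to the probe. Each motif's
   frequency among paired probes is compared against the distal-probe
   background with a one-sided Fisher's exact test (BH across motifs),
   reported as a sample odds ratio with a Woolf 95% CI; a motif is enriched
   when the CI lower bound exceeds 1.1 and at least 10 foreground probes
   carry it. For every enriched motif, the per-sample mean methylation over
   its probes forms a signature; every annotated TF's expression is tested
   against the extremes of that signature and TFs are ranked. Because family
   members share near-identical motifs, the ranking — not the motif label —
   identifies the likely driver; family and sub-family flags from the TF
   annotation make this explicit. MR calls from several two-group analyses
   can be clustered on binary membership (Jaccard dissimilarity,
   average-linkage hierarchical clustering).

Chromatin-state annotation is available as a side analysis: probes are
labelled by the state segment containing them (per cell type), and state
composition of the result set is compared against a seeded random background
drawn from the same distal pool (10x the selected set by default).

## Supervised versus unsupervised comparisons

Two strategies choose the samples being contrasted:

* **Unsupervised**: at every locus, the `extreme_fraction` = 20% of samples
  with the lowest and highest methylation are compared. The subset changes
  from probe to probe, which makes the mode usable when the relevant sample
  subgroup is unknown — at the cost of power, since only 2×20% of samples
  enter each test.
* **Supervised**: the user provides two labels covering all samples
  (case/control, treated/untreated); every test uses all samples of both
  groups. In step 2 the M/U orientation is decided per probe by the group
  means, so the same configuration serves hypo- and hypermethylation runs.

## The permutation null

A raw pairing p-value is not interpretable on its own: a gene whose
expression tracks any sample structure (subtype, purity, global methylation
drift) yields small Mann–Whitney p-values against many probes. The empirical
p-value asks instead: *how extreme is this probe–gene association relative to
the same gene scored against random distal probes?* For each pair,
`n_permutations` = 10,000 (1,000 in the packaged validation runs) random
distal probes are drawn, the gene is scored against the methylation-extreme
M/U groups of each random probe, and

$$P_e = \frac{1 + \#\{\text{null } p \le \text{observed } p\}}{R + 1}.$$

The add-one form keeps $P_e \ge 1/(R+1)$ and counts ties as extreme.

Two design points deserve emphasis:

* **The null always uses extreme-quantile groups at the random probes, in
  both modes.** The random probes carry no meaningful group orientation: had
  the null reused the fixed supervised groups, every random probe would
  reproduce the gene's group-level expression difference (up to a coin-flip
  orientation), the null would contain exact copies of the observed
  statistic, and no pair could ever reach significance. Scoring the gene
  against probe-driven extreme groups preserves exactly what the null must
  capture — the gene's propensity to look associated with an arbitrary
  methylation pattern — while leaving the observed statistic its power
  advantage in supervised mode. This is also why supervised mode is more
  powerful: its observed statistic uses all samples, while the null
  distribution is the same in both modes.
* **Reproducibility without order dependence.** Each pair's null draw is
  seeded by a stable hash of (probe, gene) combined with `rng_seed`, so
  results are identical regardless of evaluation order and across reruns.

Inside the permutation the observed and null statistics are computed with the
same vectorised rank scorer (normal approximation with continuity correction;
ties counted 1/2; no tie term in the variance since expression values are
continuous), keeping the comparison exchangeable. The `raw_pvalue` column
reported to the user comes from the full Mann–Whitney implementation (exact
for small tie-free samples).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `extreme_fraction` | 0.20 | fraction of samples per methylation extreme (unsupervised selection and all permutation nulls) |
| `direction` | hypo | direction of methylation change in group 1; a two-direction study is two runs |
| `dm_pvalue_cut` | 0.01 | BH-adjusted DMC cutoff |
| `dm_min_diff` | 0.3 | minimum beta difference between group means |
| `num_nearest_genes` | 20 | candidate genes per probe (10 per side) |
| `n_permutations` | 10000 | null draws per pair |
| `pe_cut` | 0.001 | empirical p-value cutoff for pairs |
| `motif_window` | 250 bp | half-width of the probe window for motif assignment |
| `or_ci_lower_cut` | 1.1 | motif enrichment requires CI lower bound above this |
| `motif_min_probes` | 10 | minimum foreground probes carrying the motif |
| `mr_top_fraction` | 0.05 | fraction of ranked TFs flagged as MR candidates |
| `tss_distal_cut` | 2000 bp | distal definition (distance to nearest TSS) |
| `min_group_samples` | 5 | minimum usable samples per group at a probe |

Defaults follow the conventions established for this class of analysis;
all are exposed in `analysis_config()`.

## The synthetic cohort generator

`simulate_cohort()` produces a fully specified two-subtype cohort in which
every downstream claim of the package can be checked against known truth:

* a single chromosome with gene TSSs every 50 kb, so every probe has at
  least 10 candidate genes per side and all probes are distal;
* null probes: logit-normal beta values (sd 0.5 on the logit scale) around
  per-probe baselines drawn from U(0.1, 0.9) — the logit-normal keeps the
  [0, 1] support without a separate clipping step;
* planted probes: baselines from U(0.65, 0.9) (a methylated, inactive
  enhancer), shifted down by `beta_shift` (default 0.4) in case samples and
  clipped at 0; the clip rate is reported and stays below 5% at defaults;
* planted target genes: Gaussian log2 expression (sd `noise_sd` = 1) raised
  by `expr_log2fc` (default 2) in case samples; each planted probe sits
  2.5–25 kb from its target's TSS so the target is always a candidate;
* a planted motif instance within the ±250 bp window of every planted probe,
  with a ~5% background rate at other probes, plus 20 decoy motifs at the
  same background rate — strong but not degenerate enrichment;
* a planted TF whose expression is a negative affine transform of the mean
  planted-probe methylation plus noise, annotated to the planted motif
  together with one same-family sibling (30 TFs, 8 families in total).

The generator emulates the *signal structure* of a subtype-restricted
enhancer program. It deliberately does not emulate array probe density, CpG
island structure, copy-number or purity effects, batch effects, or correlated
noise between neighbouring probes. Passing tests therefore demonstrate that
the machinery recovers planted anti-correlation structure at realistic effect
sizes and controls false calls under exchangeable noise — not that any
particular biological dataset will behave as cleanly.

One property of the generator matters when interpreting the packaged
validation numbers: planted probes and planted genes are all driven by the
same case/control label, without extra within-pair coupling. Consequently a
planted probe paired with a *different* planted gene is statistically
indistinguishable from a true pair, and such cross pairs are excluded from
the false-call denominator (they are neither recoverable truth nor honest
nulls). For the same reason the unsupervised mode recovers fewer planted
pairs than one might expect: the other planted probes enter its permutation
null as 2.5% of draws with subtype-aligned extreme groups, flooring the
empirical p-value above `pe_cut`. This mirrors the real-data situation where
co-regulated loci make the unsupervised null conservative.

## Numerical choices

* Coordinates are 0-based half-open everywhere; a CpG probe occupies
  [pos, pos + 1). A motif instance is assigned to a probe when it overlaps
  [pos − w, pos + w + 1). A probe at position `end` of a state segment
  [start, end) is *not* inside it.
* Extreme-group sizes use the ceiling; boundary ties are broken by sample id
  so runs are deterministic.
* The odds ratio is the sample OR (a·d)/(b·c); the Haldane–Anscombe +0.5
  correction is applied to all four cells if and only if some cell is zero;
  the 95% CI is the Woolf log-normal interval on the (corrected) counts.
  Enrichment contrasts use disjoint foreground/background cells (background
  minus foreground in the second row), keeping the table's independence
  assumption.
* BH adjustment passes missing p-values through and adjusts among the tested
  set only.
* Mann–Whitney p-values are exact for tie-free samples with n1 + n2 ≤ 12,
  otherwise a normal approximation with tie and continuity corrections.
  Fully tied inputs return p = 1. Zero-variance Welch comparisons return
  p = 0.5 at equal means and a saturated one-sided p otherwise.
* Probes with fewer than `min_group_samples` usable values in a comparison
  group are skipped and listed separately, never silently dropped.
* Matrices are written with 17 significant digits and re-read with a
  correctly rounding parser, so a written dataset reloads bit-identically.
* Overlapping state segments resolve first-wins (file order) with a warning.
* TF ranking sorts by p-value, then Spearman rho ascending (most
  anti-correlated first), then TF id; rho is reported alongside because the
  signature correlation is what a reader inspects in the ranking plot. The
  p-value is the primary key: it is the quantity the permutation-free MR
  step actually tests, while rho is a descriptive effect size.

## Validation scale

The packaged tests and the acceptance script validate on cohorts of 100
samples, 2,000 distal probes, 300 genes and 50 planted pairs with
`n_permutations` = 1000 — large enough that the add-one floor (1/1001) sits
below `pe_cut` and recovery/false-call rates are stable, small enough that
the full suite runs on a laptop in minutes. Null calibration uses ten
zero-effect cohorts; master-regulator recovery uses twenty seeds.

## Known limitations

* Array-style probe data only: the model assumes sparse, independent CpG
  measurements; sequencing-resolution (WGBS) input is out of scope.
* No covariate adjustment, batch correction or purity model — inputs are
  assumed preprocessed.
* Probe-level calls only; no region (DMR) aggregation.
* The pairing null corrects for a gene's global association propensity but
  cannot separate two co-regulated true targets of the same program (see the
  generator discussion above).
* Supervised analyses with more than two groups are run pairwise; the
  cross-analysis clustering is the tool for synthesising them.
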