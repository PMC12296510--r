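---
title: "Calling serine/threonine phosphatase target sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling serine/threonine phosphatase target sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pptarget)
library(dplyr)
```

# The problem

Protein phosphatases of the PPP family (PP1, PP2A and their relatives)
remove the majority of serine/threonine phosphorylations in mammalian
cells, yet — unlike kinases — they recognize little sequence context around
the phosphosite itself. Specificity comes largely from holoenzyme
composition: regulatory subunits such as the PP2A B55 (PPP2R2) and B56
(PPP2R5) families dock onto short linear motifs (SLiMs) in disordered
substrate regions, spatially separated from the dephosphorylated residue.

`pptarget` implements the computational side of a combined *in vitro* /
*in vivo* strategy for mapping phosphatase target sites from quantitative
phosphoproteomic tables:

1. **Preprocessing** — localization filtering, an intensity floor,
   two-tier missing-value imputation, optional normalization of sites to
   source-protein abundance.
2. **Differential calling** — per-contrast pooled-variance t tests with
   FDR control and inhibitor-protection logic (a *bona fide* in vitro
   target must be dephosphorylated by the added phosphatase *and* that
   dephosphorylation must be blocked by okadaic acid).
3. **Target-set algebra** — intersections of call sets across experiments
   (in vitro, OA in vivo, LB100 in vivo) with Venn bookkeeping.
4. **Motif statistics** — phosphosite-window probability and preference
   (enrichment) matrices.
5. **SLiM scanning** — PWM compilation, exact p-values, spacer-geometry
   and disorder classification of docking-motif hits.
6. **Synthetic data** — a generator with complete ground truth so every
   stage is testable without deposited MS data.

# Preprocessing model

Input tables are site-by-sample matrices of log2 intensities with site
metadata (accession, 1-based position, residue, localization probability,
multiplicity). The chain runs in a fixed order:

* **Localization filter** (`filter_localization`): class-I sites only,
  probability ≥ 0.75, boundary inclusive.
* **Intensity floor** (`floor_filter`): values strictly below 5 (log2) are
  set to missing *cell-wise*. Row-wise deletion would contradict the
  subsequent imputation (a row that loses all cells is dropped later by
  imputation eligibility, not here).
* **Low-rank completion** (`impute_svd`): per condition group, sites with
  at least `min_valid = 2` observed replicates in that condition have
  their missing cells filled by iterative truncated-SVD completion
  (initialize at the within-condition row mean, alternate rank-`k`
  reconstruction and missing-cell refresh until the largest change is
  below `tol`). These cells are "missing at random enough": the site was
  reliably quantified in the group, so the local low-rank structure is
  informative. Defaults: rank 2, tol 1e-6, max 100 iterations — chosen
  for stability on 3-replicate groups and verified against noiseless
  low-rank oracles in the test suite. Observed values are never altered.
* **Downshifted-normal imputation** (`impute_downshift`): cells still
  missing after completion are treated as left-censored (below detection)
  and drawn per column from
  `Normal(mean_j − shift·sd_j, (width·sd_j)²)` with `shift = 1.8`,
  `width = 0.3` in per-column SD units — the documented defaults of the
  Perseus-style label-free workflow. Both are exposed as arguments.
* **Protein normalization** (`normalize_to_protein`): the site-to-protein
  adjustment is a log-ratio (site log2 minus protein log2). A regression
  residual would be an alternative convention; the subtraction is isolated
  behind this one function so it can be swapped. Sites without protein
  quantification in every sample are dropped and reported — on real data
  a substantial fraction of sites is typically not normalizable.

# Differential testing and calls

`ttest_contrast` is the unpaired two-sample Student t with pooled
variance; `log2fc = mean(group_a) − mean(group_b)`. Degenerate variance is
resolved by convention: equal means give p = 1, unequal means with zero
pooled variance give the smallest representable p with a `degenerate`
flag — conservative, and it keeps NaN out of downstream ranking.

FDR control defaults to Benjamini–Hochberg (deterministic, testable by
hand arithmetic). A group-label permutation alternative with an optional
`s0` fudge factor is provided (`fdr_method = "permutation"`), since that
is what the common proteomics desktop workflow uses by default; its
plug-in estimate pools permuted |t| across sites and is made monotone in
|t|. The printed site counts of typical studies cannot disambiguate the
procedure, so the deterministic one is the default.

`call_sensitivity` encodes the decision logic. In vitro, *sensitive*
means q below threshold with negative log2 fold change in the
phosphatase-vs-control contrast, and *protected candidate* additionally
requires a significant negative change in the
phosphatase-vs-phosphatase+OA contrast — i.e. OA blocked the
dephosphorylation. In vivo the sign flips: under inhibitor treatment a
target site *retains* phosphorylation relative to the starved-only
condition, so sensitivity is a positive fold change. The *insensitive*
band is −0.5..+0.5 log2; *strong* sites have linear fold change ≥ 3
(interpreted on the linear scale, i.e. |log2fc| ≥ log2 3 ≈ 1.585; a
config switch accepts the log2 reading instead, since published methods
rarely state which scale a "fold change of 3" is on).

Target sets intersect on the `(accession, position, residue)` key.
Multiply phosphorylated peptide variants are collapsed to the most
significant variant per key by default — no published collapsing rule
exists, and `keep_multiplicity = TRUE` disables the collapse.

# Motif and preference matrices

Windows span −7..+7 around each site, padded with `_` beyond the
termini; the center character must equal the annotated residue (a
mismatch is a hard error — it catches off-by-one coordinate bugs early).
Pads are excluded from frequency denominators: including them would
distort statistics for sites near protein termini.

The preference matrix compares strongly dephosphorylated windows (linear
fold change ≥ 3) against unchanged windows (−0.5..+0.5 log2) as a
position-wise log2 frequency ratio. Cells where either set's count
fraction is below 1% are masked rather than smoothed, mirroring the
exclusion rule used for such heatmaps; an additive pseudocount is
available as an alternative.

# SLiM scanning

`compile_motif` turns a degenerate pattern (or an explicit L×20
probability matrix) into log2-odds weights against a background
(uniform by default; a proteome-estimated background is recommended for
real data and the model records which was used). Scores are discretized
at 0.001 bit and the exact null score distribution is built by dynamic
programming — convolving per-position score histograms under the
background — so every window's p-value (probability that a random L-mer
scores at least as high) is exact up to the discretization. Observed
scores are computed from the same integer weights as the null table, so
there is no rounding mismatch. The discretization error is bounded by
`L × 0.001` bits and the table auto-refines (with a warning) when a
model yields fewer than 100 score levels; patterns with exactly tied
scores are left coarse, which is correct rather than a failure.

**A caution on low-information motifs.** The classic B56 docking pattern
`[LMFI]xx[IVL]x[ED]` carries at most ~8.4 bits of information under a
uniform background, so the *best attainable* exact p-value is
24/8000 ≈ 3e-3 — no occurrence can ever reach the conventional FIMO-style
threshold of 1e-4. `scan_sequence` warns loudly in this situation.
Published scans reach 1e-4 because they use probability matrices derived
from alignments of validated instances, which carry more information
than the consensus pattern. Ship-your-own matrices are therefore the
recommended input for real analyses; the package also provides `B56ext`,
an acidic-extended LxxIxE-class variant
(`[LMFI]xx[IVL]x[ED]xx[ED][ED]`, consensus p = 3e-5) reflecting the
documented preference for acidic residues downstream of the core motif.
The B55-family entries (`B55b`, `B55H`, `B55H2`) are **placeholders**
whose definitions must be confirmed against the primary literature
before use — they exist so the configuration surface is complete.

Hits are paired with every called site on the same protein, matching
site-level counting: *overlapping* when the site lies inside the motif
span, *upstream* when the motif ends ≥ 10 residues before the site,
*downstream* when it starts ≥ 20 residues after (the B56 rule; B55
thresholds are unpublished and default to the same values,
config-exposed). A hit is *disordered* when its mean per-residue
disorder score is ≥ 0.5 (boundary inclusive). Disorder tracks are
inputs — the package does not implement a disorder predictor.

# The synthetic-data generator

`simulate_proteome` and `simulate_phospho_data` define the study
conditions for all stochastic tests:

* Sequences drawn residue-wise from a configurable background (uniform
  default). Docking-motif instances are written in at recorded
  coordinates with a paired S/T phosphosite at a drawn spacer
  (upstream 12–40 or downstream 25–60 residues, respecting the
  classification thresholds). Disorder tracks are smoothed noise around
  0.18, elevated to ~0.85 over embedded motif spans. The default
  embedded motif is the `B56ext` acidic-extended pattern; as explained
  above, a 6-residue degenerate core cannot mathematically be detected
  at p ≤ 1e-4, so embedding it would make motif-recovery tests vacuous.
* Intensities: per-site baselines ~ Normal(25, 2.5) log2, within-group
  replicate noise SD 0.3 log2 — typical site-level reproducibility of
  DIA label-free phosphoproteomic triplicates (roughly 15–25% CV).
  Sensitive sites (an exact 10% by default) receive true per-condition
  effects ~ Normal(−2, 0.5) log2; negative shifts model
  dephosphorylation. Phosphosites are placed on S/T only (the PPP
  focus); the generator does not model Y phosphorylation, peptide-level
  identification, chromatography or spectral noise.
* Missingness: intensity-dependent dropout with
  `P(miss) = logistic((midpoint − true value)/slope)` applied to the
  pre-noise value (simpler to reason about and testable against the
  closed form), defaults midpoint 20, slope 1.5, plus 1%
  completely-at-random dropout. The no-missingness limit is
  `midpoint = −Inf`: the logistic form has limit ½, not 0, as
  `slope → ∞`, so the midpoint — not the slope — is the correct
  switch-off dial. A configurable 5% of sites draw localization
  probabilities below 0.75 to exercise the filter.

What passing tests on these simulations do **not** show: real DIA data
have correlated missingness across samples, batch structure, multiply
phosphorylated peptides sharing evidence, and non-uniform sequence
composition; none of these are emulated.

## Operating characteristics, honestly stated

The acceptance suite measures the pipeline's empirical FDR and
sensitivity on the standard scenario (2,000 sites, 3 vs 3 replicates,
10% sensitive with effects ~ N(−2, 0.5), MNAR as configured). Empirical
FDR among sensitive calls is comfortably below 0.10. Sensitivity,
however, sits around 0.6–0.7, not above 0.8: with n = 3 per group the
pooled t has 4 degrees of freedom, and a direct simulation of the very
same test *without any missingness* caps sensitivity at ≈ 0.82 under
these effect sizes — the weak tail of N(−2, 0.5) effects is simply
undetectable at triplicate depth, and intensity-dependent dropout of
dephosphorylated (hence low) treated values costs the rest. This is a
property of the experimental design being modelled, not of the
implementation; deeper replication or larger effects move it, looser
thresholds do not (they trade FDR for it). The corresponding acceptance
check is left asserting the stricter bound and fails visibly rather
than being weakened.

Problem sizes used by the test and acceptance runs (2,000 sites, 300
proteins, 200 embedded motifs, 10⁴ imputation draws, 10⁶ Monte-Carlo
L-mers) were chosen so each statistical bound has comfortable sampling
margin.

# A compact worked example

```{r example, eval = FALSE}
pr  <- simulate_proteome(n_proteins = 100, n_motifs = 40, seed = 7)
sim <- simulate_phospho_data(pr, n_sites = 800, seed = 8)

calls <- sim$table |>
  preprocess_phospho(seed = 9) |>
  phospho_difftest("treated", "control") |>
  call_sensitivity(primary = "treated_vs_control", mode = "in_vitro")

model <- compile_motif(default_motifs()$B56ext, id = "B56")
hits <- scan_proteome(model, pr$sequences) |>
  classify_hits(calls[calls$call == "sensitive", ]) |>
  disorder_classify(pr$disorder)

spacer_distribution(hits)
count_slim_site_assignments(calls[calls$call == "sensitive", ], hits)
```

# Known limitations

* The t test is unmoderated by design (no empirical-Bayes variance
  shrinkage), matching the modelled workflow; at triplicate depth a
  moderated test would be more sensitive.
* The permutation FDR with 3 vs 3 replicates has only 10 distinct
  balanced label splits; its granularity at small n is coarse.
* SLiM p-values condition on a 0-order background; compositional bias
  (e.g. acidic stretches) inflates hit counts for acidic motifs unless a
  proteome-estimated background is supplied.
* Spacer classification is purely geometric; it does not model the
  structural reachability arguments that motivate the distance rules.
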