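---
title: "Methods: community state typing and diversity analysis of the vaginal microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community state typing and diversity analysis of the vaginal microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmcst)
```

`vmcst` implements the standard analysis chain for 16S rRNA profiles of the
vaginal microbiota — rarefied alpha diversity, Bray–Curtis beta diversity
with ordination and a PERMANOVA group test, gap-statistic cluster-number
estimation, rule-based community state type (CST) assignment, Nugent
scoring, and a morphotype/16S concordance statistic — plus a synthetic
cohort generator that plants known structure so each stage can be validated
end to end. This vignette records the model choices, defaults, and
numerical conventions, and what the synthetic validation does and does not
establish about real data.

## Data model

The central container is a samples × taxa matrix with a `mode` of `counts`
or `relative`. Relative rows must sum to 1 within `1e-6` and are never
renormalized silently: `renormalize()` is an explicit operation, so a table
read from disk is exactly the table analyzed. Taxa are named `Genus` or
`Genus_species`; the genus of a taxon is everything before the first
underscore. Species-call resolution is required only where the CST rules
need it (the four *Lactobacillus* species); everything else may stay at
genus level. Readers accept either orientation; for relative tables the
unit-row-sum signature disambiguates, otherwise samples-in-rows is assumed
with an explicit override, since distributed abundance tables rarely
document their orientation.

## Alpha diversity

Rarefaction subsamples counts **without replacement** (a sequential
hypergeometric chain, equivalent to a multivariate hypergeometric draw), so
a rarefied sample never exceeds its original taxon counts and its total is
exactly the target depth. Samples shallower than a depth are excluded at
that depth and flagged, not dropped from the study.

Shannon diversity is reported in **bits** (`H = −Σ pᵢ log₂ pᵢ`), the
convention of the QIIME-era tooling whose outputs these values are meant to
sit beside; a natural-log switch exists but warns, because values on the
two scales are not comparable. Chao1 uses the **bias-corrected** estimator
`S_obs + F1(F1−1)/(2(F2+1))`, which is defined when no doubletons exist and
reduces to `S_obs` when `F1 ≤ 1`. Singletons are retained throughout.

Defaults: the depth grid is nine evenly spaced depths from 10 to the
largest sample total (overridable; analyses that need a single comparison
depth pin `analysis_depth = 6791`, a depth chosen to retain most samples of
a deeply sequenced cohort while discarding little data); 10 iterations per
(sample, depth), each sub-seeded from the stage seed so the full grid is
reproducible; per-sample values are iteration means, and group curves are
mean ± SEM **across samples** of those per-sample means (SEM across
iterations is also reported per sample, but cross-sample spread is the
quantity group comparisons care about).

Group tests follow the classic applied-biostatistics recipe: Shapiro–Wilk
at α = 0.05 per group decides between Student's t / one-way ANOVA and
Mann–Whitney / Kruskal–Wallis; a group too small (n < 3) or degenerate for
the screen is conservatively routed to the rank test. The chosen test's
name is returned so published p-values can be audited.

## Beta diversity

Bray–Curtis dissimilarity is computed by `vegan::vegdist` on genus-level
relative abundances by default (counts work too; an OTU-level switch is a
matter of passing a different table). PCoA performs Gower double-centering
of `−d²/2` and an eigendecomposition; **negative eigenvalues are reported,
not corrected** (no Cailliez/Lingoes), and the proportion explained is over
the positive-eigenvalue total — matching the ecosystem default a
phyloseq-style workflow uses. Axis signs are fixed deterministically.

PERMANOVA is implemented one-factor from its sum-of-squares definition
(`SS_total = Σ_{i<j} d²ᵢⱼ/N`, within-group analog per group), with
`p = (1 + #{F* ≥ F}) / (1 + n_permutations)` so the observed labeling counts
once and p can never be zero. 999 permutations is the default, consistent
with a smallest attainable p of 0.001. For N ≤ 9 an exhaustive mode
enumerates all relabelings and returns the exact permutation p; the test
suite proves the two engines agree with an independent subset-enumeration
oracle. `vegan::adonis2` is used in the tests only as a cross-check of the
pseudo-F, never as the implementation.

## Community typing

**Gap statistic.** For each k up to `k_max` (default 10), k-means (default
25 restarts) yields the pooled within-cluster dispersion
`W_k = Σ_r D_r/(2n_r)` with `D_r` the full double sum of pairwise squared
distances — so `W_k` equals the total within-cluster sum of squares. `B`
(default 100) reference datasets are drawn uniformly inside the
PCA-aligned bounding box of the data; `gap(k) = E[log W*ₖ] − log Wₖ` and
`se(k) = sd(log W*ₖ)√(1 + 1/B)`. (The `cluster::clusGap` convention halves
`W`; the constant cancels in the gap, and the tests verify agreement up to
that `log 2`.)

The "plateau" of the gap curve is read with the **first-SE-max** rule: find
the first local maximum of the gap curve, then select the smallest k whose
gap is within one standard error of it. The one-line 2001 rule (smallest k
with `gap(k) ≥ gap(k+1) − se(k+1)`) is available as an option but was
rejected as the default on validation: on sharply separated compositional
clusters the gap curve stays flat before jumping at the true k, and the
2001 rule then stops at k = 1 off small fluctuations, failing planted-k
recovery on Dirichlet-mixture cohorts that the first-SE-max rule recovers
cleanly.

**CST assignment is rule-based, not re-clustered.** The most abundant taxon
(ties broken by name) maps *L. crispatus* → I, *L. gasseri* → II,
*L. iners* → III, *L. jensenii* → V, anything else → IV; CST IV samples are
sub-labelled IV-*Streptococcus* / IV-*Gardnerella* / IV-diverse by the top
taxon's genus. This is deterministic, auditable, scale-invariant, and
matches how CST labels are reported in practice; the gap-statistic/k-means
clustering is computed independently as a cross-check rather than forced to
agree. *Lactobacillus* dominance is a separate genus-level call (all
*Lactobacillus* species summed), which is why a cohort can contain more
*Lactobacillus*-dominant samples than CST I–III samples: a diverse sample
whose summed lactobacilli outweigh every single other genus is dominant yet
CST IV.

Hierarchical clustering uses complete linkage by default (average
available), on sample-id-sorted input for deterministic trees, with Newick
export through `ape`. Categorical contrasts use Fisher's exact test for
2×2 tables and chi-square with Yates correction otherwise, falling back to
Fisher whenever an expected cell is below 5 — the conventional criterion,
since the source workflows name both tests without stating one.

## Nugent scoring and concordance

The rubric maps three 0–4 morphotype quantitation scores to points —
*Lactobacillus* morphotypes inversely (4→0 … 0→4), *G. vaginalis* /
*Bacteroides* morphotypes identically (0→0 … 4→4), curved rods compressed
(0→0, 1–2→1, 3–4→2) — summing to the 0–10 score with categories 0–3 / 4–6 /
7–10. The tests check all 125 rubric entries against an independently
generated table.

"Complete agreement" holds when every morphotype class observed under
microscopy (quantitation ≥ 1 by default) is represented among the sample's
top-5 sequenced genera under a genus→morphotype map. The default map is
deliberately conservative: *Lactobacillus* → *Lactobacillus*;
*Gardnerella*, *Bacteroides*, *Prevotella*, *Porphyromonas* →
GV/*Bacteroides*; *Mobiluncus* → *Mobiluncus*; everything else unmapped. In
particular **BVAB1 is left unmapped**, although it is a curved rod that
slide readers commonly score as a *Mobiluncus* morphotype: with the default
map such samples score as disagreements, which is exactly the documented
failure mode of Nugent microscopy in diverse communities. The map is a
plain named vector, so a study with its own slide-reading conventions (or a
reference agreement column to calibrate against) can rebind it — e.g.
`c(default_morphotype_map(), BVAB1 = "Mobiluncus")`. Vacuous agreements
(no morphotypes observed) count as agreement but carry a flag; samples
without morphotype data are excluded from denominators and counted.
Concordance is summarized overall, per group, and per group within two CST
strata: *Lactobacillus*-dominant CSTs (I–III, and V if present) pooled,
versus CST IV.

## The synthetic cohort generator

Each sample draws a planted type from its group's mixture over
{I, II, III, IV-Strep, IV-Gard, IV-diverse}, a composition from that type's
Dirichlet concentration vector over a fixed 25-taxon panel (the four
CST-defining *Lactobacillus* species plus 21 genera spanning the usual
top-genera range), a read depth uniform on [6791, 54288], and multinomial
counts. *Lactobacillus* CST concentrations put weight 40 on the dominant
species against 0.1–1 elsewhere (≥ 40×, i.e. sharply dominant, as real
*Lactobacillus* communities are); CST IV types place a leading taxon
(weight 20 for the *Streptococcus* and *Gardnerella* sub-types) over a broad
anaerobe background, and IV-diverse spreads its mass over
*Prevotella*/*Sneathia*/BVAB1 with no sharp leader. The Dirichlet-
multinomial was chosen over a log-normal for count realism and closed-form
moments.

Morphotype quantitation derives from the true composition through fixed
bands (e.g. *Lactobacillus* fraction ≥ 0.75 → quantitation 4, ≥ 0.40 → 3,
≥ 0.15 → 2, ≥ 0.02 → 1; an anaerobe set feeds the GV score with the same
bands; BVAB1 + *Mobiluncus* feed the curved-rod score with lower
thresholds). With probability `discordance_rate` (default 0.15, a modest
slide-misreading rate) a sample's scores are instead generated from an
independent draw of the cohort's marginal. Everything is reproducible from
one seed; the same seed yields byte-identical cohorts.

`preset_paper_like()` fixes the study conditions the generator emulates:
groups of 19 (NSW) and 48 (FSW); CST mixtures 2/1/8/8 and 5/1/1/41 across
I/II/III/IV respectively, with the IV mass split 20/30/50 over its three
sub-types (the source population reports no sub-type split; the diverse
sub-type is given the largest share as the one described as most common);
menstrual-cycle-stage frequencies per group; ages N(30, 6) clipped to the
adult range.

**What passing the synthetic validation shows — and what it does not.** The
generator plants group mixtures, sharp dominance, depth variation, and a
composition-coupled (band-based) Nugent process. Planted-truth recovery
therefore validates the analysis machinery: CST assignment recovers ≥ 95%
of planted types, empirical mixtures converge to specification, the
FSW-like group shows higher rarefied Shannon diversity, PERMANOVA detects
the planted group difference, and the gap statistic recovers planted k on
well-separated Dirichlet mixtures. It does **not** reproduce properties
that belong to the real data rather than the model. Two are worth naming.
First, the gap statistic on the preset cohort selects about four clusters,
not six: the generator's three CST IV sub-types are deliberately broad and
overlapping, and k-means merges them; a six-cluster readout is a property
of a particular dataset's sub-structure, not of the method. Second, because
the band model ties Nugent scores to composition, low-Nugent samples are
*depleted* of CST IV by construction — the opposite of the decoupling
(diverse communities with low Nugent scores) that makes real sex-worker
cohorts interesting. The generator can emulate that decoupling only by
raising `discordance_rate`; the default keeps scores informative so the
concordance machinery has a planted truth to recover.

## Numerical conventions and degenerate inputs

- All stochastic functions take a `seed` and restore the caller's RNG
  state; the pipeline expands one global seed into fixed per-stage seeds
  (+1 alpha, +2 PERMANOVA, +3 gap), recorded in the manifest.
- Ties in abundance rankings (top taxa, dominant taxon) always break by
  taxon name ascending, so top-n lists are prefixes of top-(n+1) lists.
- Permutation counts of `F* ≥ F` use a `1e-12` relative slack so exact ties
  are counted, matching exhaustive enumeration.
- All-zero samples are rejected by name (Bray–Curtis, renormalization,
  diversity); depth > sample total excludes the sample at that depth rather
  than erroring the run; all-identical points yield `k_hat = 1` with a
  warning; an empty concordance stratum is omitted with a warning rather
  than reported as 0/0.
- JSON summaries always pair percentages with numerator and denominator.

## Problem sizes in the shipped tests

The suite validates at desk scale: 1000-vector oracle sweeps for
Shannon/Chao1 and Bray–Curtis, exhaustive PERMANOVA enumeration up to N = 7,
six-sample linkage oracles, 200 null simulations at 999 permutations for
the PERMANOVA type-I error, 20 planted-k cohorts (n = 60) for gap recovery,
and 20 paper-scale cohorts (67 samples) for the group-level diversity
contrast; the full-pipeline tests run reduced settings (B = 20–50, 99–999
permutations, 2–10 rarefaction iterations), while `scripts/acceptance.R`
runs the complete cohort at full defaults.

## Limitations

- No phylogenetic diversity metrics (UniFrac, Faith's PD) and no NMDS or
  constrained ordination; the implemented set mirrors the motivating
  workflow.
- PERMANOVA is one-factor; confounder adjustment (e.g. cycle stage) is out
  of scope.
- CST V handling is implemented but exercised only synthetically, as
  *L. jensenii*-dominant communities are absent from the motivating cohort.
- The genus→morphotype map ships as a conservative default and is the one
  component that genuinely requires per-study calibration; concordance
  rates are only as meaningful as that map.
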