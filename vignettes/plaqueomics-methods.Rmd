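---
title: "Models and methods behind plaqueomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plaqueomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(plaqueomics)
```

This vignette documents the statistical models, the tunable parameters, the
numerical choices and the known limitations of the package — the reasoning a
maintainer or reviewer needs, in one place. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## The data model

The pipeline operates on an `IntensityMatrix`: log2 protein-group
intensities, proteins in rows and samples in columns (the DIA-NN
`pg_matrix` orientation), with `NA` for non-detection, plus per-sample
metadata (model, age in months, plaque/non-plaque region, pair id). The
pairing invariant — each pair id appears in exactly one plaque and one
non-plaque sample within a model-by-age stratum — is validated on
construction, because every downstream stage relies on it. log2 is the single
internal scale; every fold change is a difference of log2 values.

## What the synthetic generator emulates

`generate_cohort()` encodes the assumed data-generating process:

* per-protein baseline abundances `N(baseline_mean, baseline_sd²)` on the
  log2 scale (defaults 20 and 2, typical of DIA protein-group intensities);
* a capture-level offset shared by the two members of a pair
  (`pair_offset_sd`, default `baseline_sd / 2`), which is what gives the
  paired design its power advantage over a two-sample comparison — the
  within-pair correlation of real captures is not known, so the offset SD is
  an exposed parameter rather than a constant;
* planted differentially abundant proteins (fraction `frac_dap`, default 5%)
  elevated in plaque samples by `effect_size` (default 2 log2 units),
  modulated by temporal class: early/constant (full effect at all ages),
  late (multipliers 0, 0.1, 1 across the three ages) and decline
  (multipliers 1, 0.4, −0.1). The default class fractions (13% late, 5%
  decline) approximate the relative sizes of the three trajectory clusters
  reported in plaque proteomics of 5xFAD mice;
* block-correlated protein groups: members of a block share a per-sample
  latent factor so their pairwise correlation is `block_rho` (default 0.8
  across 5 blocks of 20), the substrate for the network stage;
* an amyloid tracer protein whose plaque enrichment grows strictly with age
  (`effect_size × (1, 1.5, 2)` at 3, 8, 14 months), the positive control for
  capture quality;
* logistic left-censoring: a latent value `x` is observed with probability
  `plogis((x − missing_midpoint) · missing_slope)` (defaults 16 and 1, i.e.
  the detection limit sits two baseline SDs below the mean). This is MNAR by
  construction, which is what makes the minimum-value imputation stage
  meaningfully testable;
* a contaminant fraction (default 2%) carrying keratin/trypsin-style
  identifiers to exercise the contaminant filter.

All randomness flows from one seed through one generator stream per call;
identical configurations reproduce matrices bit for bit.

What the generator deliberately does **not** emulate: peptide-level
structure, retention-time or ion-mobility effects, cross-run normalization
artifacts, non-logistic censoring, or correlated missingness across proteins.
Passing tests therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to every pathology of real DIA data.

## Differential abundance: choices and rationale

**G-test gate.** Detection counts are compared with the likelihood-ratio
test rather than Fisher's exact test because detection is a per-sample
Bernoulli summary and the G statistic is the natural LR form; a degenerate
margin (all detected or all missing in both groups) is defined as
`G = 0, p = 1` rather than an error. The gate is two-sided; whether a
one-sided gate toward plaque-enriched detection was ever intended is not
decidable from the published description, and two-sided is the conservative
reading.

**Equalizing imputation.** The published rule states the goal (equal
detections after imputation with the sample-specific minimum) but not the
mechanism. The package's mechanism is deterministic and minimal: impute only
in the group with fewer detections, filling missing cells in ascending
sample-id order with that sample's observed minimum across all proteins (the
per-sample detection floor, matching left-censoring semantics), stopping at
equality. The better-detected group is never touched, so the detection gap
can only shrink — a property tested on 1,000 random cases.

**Complete-pairs moderated t.** Pairs still missing a member after
imputation are dropped per protein; at least 3 complete pairs are required
to test (not all missing values are filled, to avoid over-interpretation).
The moderation prior (s²₀, d₀) is fitted once per comparison by method of
moments on log s²_g — the classic scaled-F fit: with
`e_g = log s²_g − ψ(d_g/2) + log(d_g/2)`, excess dispersion of `e` over
`ψ'(d_g/2)` determines `d₀` through the inverse trigamma, and `s²₀` through
the mean of `e`. When the observed dispersion is at or below its expectation
the prior df is infinite and all posterior variances collapse to s²₀. Both
hyperparameters can be injected explicitly, which the tests use to check the
two limits (d₀ = 0: classical paired t; d₀ → ∞: posterior variance = s²₀)
and to cross-check the fit against an independent empirical-Bayes
implementation.

**log2FC-z.** Standardization uses mean and sample SD (ddof 1) over all
tested proteins within one comparison; no robust (median/MAD) variant, since
the published thresholds (2.5 mouse, 2.0 human) are stated for plain
z-scores. Each model-by-age stratum is analyzed separately and standardized
within stratum. The Aβ correlation screen defaults to plaque samples only
(all ages pooled), with a switch, because the published sample scope is not
stated.

## Temporal classification

The published clustering was guided by WGCNA output and manual inspection —
not reproducible. The package replaces it with a deterministic rule on
baseline-normalized deltas (Δ_age = mean(age) − mean(3 months), plaque
samples of DAPs only): decline if Δ₁₄ ≤ −τ; late if Δ₁₄ ≥ τ and Δ₈ < τ;
early/constant otherwise, with τ = 0.5 log2 units. Proteins whose Δ₈ and Δ₁₄
have opposite signs are excluded first, unless either magnitude is within
`tol = 0.1` of zero — a tolerance added so that noise-level sign flips near
baseline do not discard proteins (the published exclusion rule carries no
tolerance). DAPs with near-zero change at both ages stay in early/constant.
The rule is validated by planted-truth recovery rather than by comparison to
a manual clustering; the recovery test uses cohorts with a small capture
offset (pair_offset_sd = 0.2) and 25 pairs per age so that the standard
error of Δ is well below τ — at the default offset the per-age plaque means
are noisier and the deterministic rule's accuracy degrades gracefully
(z-noise on Δ of roughly 0.3 log2 units at 20 pairs).

## Co-expression network

**Edge screen.** Proteins with ≥ 50% missingness are dropped; values are
median-centered **per sample**, which removes capture-level offsets (the
published description says only "median-centered"; per-protein centering
would be a no-op for Pearson correlation, so the sample interpretation is the
one that does statistical work). Correlations are pairwise-complete; pairs
with fewer than 3 shared observations are skipped. Significance is a
permutation FDR: each permutation shuffles every protein's sample vector
independently, null |ρ| values are pooled across pairs (a global null chosen
for tractability — the published per-pair scheme is unstated), and
`FDR(t) = mean null count(|ρ| ≥ t) / observed count(|ρ| ≥ t)`. The edge set
is everything at or above the smallest t with FDR(t) ≤ 0.05; per-edge
`q_perm` is the monotone envelope of FDR(t). A known property of such global
thresholds is that, when many strong edges exist, the threshold admits a
tail of noise edges involving otherwise unconnected proteins; the module
size filter downstream absorbs most of the consequences.

**PFN.** Edges are inserted in descending |ρ| (ties broken lexicographically
by id pair, for determinism) and kept iff the graph stays planar, checked
with an exact left-right planarity test (Brandes' formulation of de
Fraysseix–Rosenstiehl) implemented in C++; insertion stops at the maximal
planar count 3(V−2). Every constructed network is property-tested against an
external planarity implementation.

**Modules.** The original multiscale clustering with a "random tetrahedral
network" null is not reproduced — its parameters are unpublished. The
package substitutes a fully specified procedure that preserves the contract
(hierarchical modules on the PFN, significance p < 0.05, size filters):
connected components first, then recursive splitting by weighted-modularity
maximization (Louvain), a split being accepted only if its modularity
exceeds the 95th percentile of modularities obtained on degree-preserving
rewirings of the same subgraph (the observed weight multiset is re-assigned
randomly to rewired edges, since rewiring cannot preserve weight-topology
association). Modules smaller than 10 or larger than half the network are
computed but not reported. Detection is deterministic given the seed;
tie-breaks are lexicographic throughout.

**Hubs.** Within-module connectivity is the sum of |ρ| to other members. A
degree-preserving rewiring null is degenerate here: for forced degree
sequences (a star is the unique simple graph with its degree sequence) every
node would be its own null and no hub could ever be called. The package
instead re-places the module's weighted edges uniformly at random among
member pairs and pools all node slots of this exchangeable null into one
reference distribution; hubs are members beating it at p < 0.05 (BH-adjusted
within module). This null calls the center of a star and nothing in a
regular ring, which is the behavior a connectivity test should have.

**Eigengenes and traits.** Missing values are mean-imputed per protein
*only* for the eigengene computation (correlations elsewhere stay
pairwise-complete); members are standardized, the first right singular
vector gives the per-sample score, the sign is oriented toward the mean
member profile, and the score is scaled to unit variance. Trait association
uses Pearson correlation with the 0/1 plaque indicator, exact t-based
p-values, BH across modules, and the double threshold FDR < 0.05 and
|r| ≥ 0.4.

**DAP enrichment.** The weighted KS enrichment score (weight = |statistic|,
exponent 1) is computed against the |log2FC-z| ranking; the p-value comes
from random member sets of the same size (default 10,000), i.e. a
set-permutation null rather than a sample-permutation null, matching how
ranked-list enrichment is normally run on a single ranking.

## Consensus ranking

Normalized ranks use average ties, `r = rank/M` per study. The joint
order-statistic probability is computed with the alternating recursion
`V_k = Σ (−1)^{i−1} (V_{k−i}/i!) r^i`; in double precision the alternating
sums are benign for N ≤ 20 (the package clamps to (0,1] to absorb round-off
at the boundary), and the implementation is verified against closed forms
for N = 1, 2 and a 10⁶-draw Monte-Carlo oracle for N up to 6. Proteins
absent from a study contribute nothing by default: Q is computed over the
available N, with a minimum-presence filter (default 3 datasets). The
alternative of imputing the worst rank (r = 1) is selectable; the published
treatment of absences shows them but does not define them, and computing
over available datasets avoids penalizing proteins simply for not being
measured. No p-value is attached to Q — it is used ordinally. Ties are
broken by mean normalized rank, then id.

## Overrepresentation

One-sided hypergeometric upper tails (the overrepresentation direction);
fold enrichment `(a/k)/(K/M)`; BH across sets; the double filter FDR < 0.01
and fold > 2. The background defaults to the proteins quantified in the
stratum rather than the whole proteome — the statistically conservative
choice, since enrichment against an inflated background is anti-conservative;
the published background is unstated.

## Problem sizes used in validation

The test suite and acceptance script run, by design, at desk scale: planted
and null differential-abundance cohorts of 2,000 proteins × 120 samples
(20 pairs at each of three ages) over 10 seeds; network cohorts of 100–120
proteins with five 20-member blocks at ρ = 0.8 over 5 seeds; 10⁶-draw
Monte-Carlo checks of the order-statistic recursion; 6-study consensus
fixtures over 20 seeds. These sizes were chosen so that Monte-Carlo error is
small relative to every margin being asserted while the whole suite stays
fast enough to run routinely.

## Known limitations

* The module-detection procedure is a documented substitute for the original
  multiscale clustering; module identities will not match the original
  tool's output, only the contract (planar network, significant hierarchical
  modules, size filters, hub significance, trait statistics).
* The permutation edge screen's global null can admit noise edges when
  strong signal dominates the observed correlation distribution (see above).
* The temporal rule is intentionally simple; trajectories that are genuinely
  non-monotone beyond the direction filter's tolerance are excluded rather
  than modeled. An exploratory hierarchical-clustering mode is not the
  default and carries no recovery guarantee.
* Cross-species identifier harmonization for consensus ranking is assumed
  done upstream.
* The generator's missingness acts independently per cell given intensity;
  structured missingness (whole-sample dropouts, batch-correlated censoring)
  is out of scope.
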