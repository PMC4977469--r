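---
title: "Methods and modelling choices in mesopotency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in mesopotency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesopotency)
```

# The problem

Human embryonic stem cells grown under different culture conditions (feeder
cells, Matrigel, or Matrigel replated onto feeders) differ sharply in how
efficiently they later differentiate into cardiomyocytes. `mesopotency`
implements the computational chain used to dissect such condition effects:
differential expression and DNA-methylation calling by rank products,
classification and clustering of regulation dynamics across the ordered
conditions, enrichment of gene classes against functional annotation and
transcription-factor (TF) target sets, a signed propensity score for
signaling cascades, and qPCR induction analysis relating early TF induction
to the final differentiation outcome. A seeded synthetic-data generator with
planted ground truth exercises the whole chain end to end.

Throughout, the three conditions are named generically `baseline`, `mid` and
`high`; in the motivating experiment they correspond to the Matrigel,
replated, and feeder cultures, ordered by cardiomyogenesis efficiency. All
fold changes are log2 and are taken against the baseline condition unless a
direct pairwise comparison is requested.

# Differential calling by rank products

For a comparison of condition *a* against *b* with $n_a$ and $n_b$
replicates, every cross-condition replicate pairing (all $K = n_a n_b$ of
them — the classical formulation for unpaired designs) yields a per-gene
fold-change difference. Genes are ranked within each pairing (rank 1 = most
extreme in the tested direction; ties get average ranks) and the rank
product of a gene is the geometric mean of its $K$ ranks. Up- and
down-regulation are ranked and tested separately; exchanging the two
conditions swaps the directions exactly.

Significance is expressed as the estimated proportion of false positives
(PFP): `n_perm` permutations independently shuffle the ranks within each
pairing, and

$$\mathrm{pfp}(g) = \frac{E[\#\{\text{null genes with } RP \le RP_g\}]}{\mathrm{rank}(g)}.$$

The PFP is then made monotone non-decreasing down the ranked list by a
cumulative maximum, so the calls at any threshold form a contiguous prefix,
and is reported clipped to $[0, 1]$. The default `n_perm = 100` is the
classical choice; the permutation seed is a mandatory argument so runs are
reproducible. Permuted null columns are drawn from each pairing's sorted
rank multiset, which makes the estimate invariant to the order in which
pairings are enumerated.

Differential methylation uses the same machinery on beta values (methylation
fractions in $[0, 1]$) per probe, with an additional gate: a probe is only
called when its absolute mean beta change reaches `min_beta_change` (default
0.25). Gene-level calls aggregate probes by the *any passing probe* rule,
and the per-gene probe delta-betas feed the probe-consistency check
(qualifying threshold 0.15; probes of genes on the exclusion list — the GNAS
complex locus by default — are exempt). The exclusion is exposed as a plain
configurable list because no biological rationale for the exemption is
available to generalize from.

## Calibration behaviour, honestly stated

The permutation null treats the $K$ pairings as independent, but in a
3-vs-3 design the nine pairings share replicates and are therefore
positively correlated within a gene. Two consequences, measured by the
package's own acceptance suite on the generator's study conditions (2,000
genes, 3 conditions × 3 replicates, 100 permutations; 50 null seeds, 20
planted seeds):

* on all-null data the realized false-positive rate at the `pfp <= 0.05`
  threshold is about 6–7% — close to, and slightly above, the nominal level;
* on planted data (10% differential genes, 2.0 log2FC effect, 0.5 noise sd)
  recall exceeds 0.99 but the realized false-discovery proportion is about
  0.12 at the nominal 0.05, i.e. the estimator is mildly anticonservative.

Both effects have the same single cause. We verified this by (i) simulating
truly independent pairing columns, where both the null call rate and the
planted FDP drop to zero, and (ii) replacing the null with
correlation-preserving alternatives (sample-label permutation, within-column
value permutation), which reproduce the observed RP distribution so faithfully
that the method loses all power (PFP ≈ 1 everywhere). The independent-rank
permutation null is therefore not a defect to engineer away but the source
of the method's power; its price is the modest FDP inflation above. Users
needing strict false-discovery control should tighten the threshold rather
than trust the nominal level.

# Regulation dynamics

Two classifications are total functions of the pair (`fc_mid`, `fc_high`):

* **Transition classes** (mid-to-high comparison): with equal signs, a
  larger absolute value is *increased* regulation and a smaller one
  *decreased*; a sign flip with both values beyond the tolerance is
  *reversed*; everything else *unchanged*. A value within `tol` of zero
  inherits the other value's sign — this is what places a profile like
  (0.12, 2.17) in the increased class rather than letting measurement noise
  at the first point decide.
* **Trend classes** (baseline to mid to high): monotone-increasing requires
  $0 \le fc_{mid} \le fc_{high}$ with $fc_{high}$ above the tolerance;
  monotone-decreasing is the mirror; everything else is *other*.

The default tolerance is 0, matching the plain definitions; it is exposed
because exact-zero comparisons are brittle on microarray noise.

## Clustering

`kmeans_dot()` is a Lloyd iteration in which profiles are assigned to the
centroid maximizing the un-normalized dot product (a cosine option is
provided), centroids are member means, and empty clusters are re-seeded from
the point most dissimilar to its current centroid. The objective (summed
member-centroid similarity) is non-decreasing across iterations, and the
seeded initialization makes runs deterministic. K defaults to 3, the number
of dynamic classes the analysis distinguishes.

One property of the dot-product metric deserves emphasis: a near-zero (flat)
profile has near-zero similarity to *every* centroid, and its assignment is
decided by noise sign. Flat classes are therefore not recoverable under this
metric — which is consistent with its intended use on differential genes
only, whose profiles are directional. The package's recovery tests plant
three directional classes (monotone up, monotone down, transient) and
recover them essentially perfectly; we deliberately do not claim recovery of
a flat class.

## Expression-methylation association

Class memberships from the two platforms are crossed into a 2×2 table over
the genes common to both, and tested with the two-sided Fisher exact test.
Degenerate tables (an empty class) report p = 1 with an undefined odds ratio
and an explicit flag instead of a test.

# Enrichment

`ease_test()` implements the conservatively deflated hypergeometric tail
(the EASE score): one gene is removed from the observed overlap (floored at
zero) before the upper-tail probability, so a single-gene overlap can never
be significant. The fold enrichment is $(k/n)/(K/N)$. Raw EASE p-values are
the calling default (a Benjamini-Hochberg column is additionally reported by
the pipeline, for reference). TF regulators are called at fold > 1.2 and
p < 0.05 — reading ">20% enrichment" as a fold threshold, the convention of
the enrichment tool family this mirrors.

TF target assignment is window-based: a gene is a putative target when any
peak of the TF overlaps the gene body (TSS to gene end, introns and exons
included) extended 10 kb on the 5' side and 3 kb on the 3' side,
strand-aware. All interval arithmetic is 0-based half-open (BED
convention); gene-model tables carry 1-based positions on disk and are
converted on reading. Since no transcript database is bundled, the
gene-model table is a required input.

The paired gene-set test pairs each set gene's mean expression in one
condition with its mean in the other and applies the classical paired t
test (two-sided by default; one-sided modes available).

# Signaling cascade propensity

For a cascade $A \to B \dashv C \ldots$, each component with an outgoing
edge is scored

$$\pi = s \cdot \mathrm{log2FC},\qquad s \in \{+1\ (\to),\ -1\ (\dashv)\},$$

so a down-regulated inhibitor contributes positively. The cascade summary is
the arithmetic mean of its component propensities; a cascade is *consistent*
when every propensity is positive. In the published table this package
reproduces, each row lists as many scored values as named gene components —
the final gene is scored with sign +1 toward its (unscored, free-text)
terminal event. `include_terminal = TRUE` is therefore the default; the
worked example in the source methods, which leaves the last substrate
unscored, corresponds to `include_terminal = FALSE`. Comparisons against
printed 2-decimal values round half away from zero.

# qPCR induction

Delta Ct is the average reference-gene Ct minus the average target Ct within
a culture — directly interpretable as log2 expression relative to the
reference — and delta-delta Ct differences between conditions give log2 fold
changes. Induction time-courses are expressed as linear fold changes versus
the same unit's time-0 value; the maximal induction within the first 72 h is
the early predictor of outcome. Non-detected wells are excluded, never
imputed at the cycle ceiling, which would bias delta-delta Ct; the analysis
errors only when a group loses all replicates.

The induction-outcome association is the Pearson correlation with the
one-tailed test of positive association,
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom. At $r = 0$ the
one-tailed p is exactly 0.5. Note that a published table rounding $r$ to
0.98 at $n = 4$ prints p = 0.009 while the rounded $r$ back-computes to
p ≈ 0.010; the package targets the closed-form contract, not a value
reconstructed from rounded inputs.

# The synthetic study generator

`simulation_truth()` fixes the study conditions; its defaults are the
conditions exercised by the test suite: 2,000 genes, 3 conditions × 3
replicates, 10% trend genes (5% up, 5% down), a 2.0 log2FC effect with half
realized in the mid condition, and 0.5 log2-scale Gaussian noise. Choices a
user should know about:

* **Noise model.** i.i.d. Gaussian on the log2 scale (expression, Ct) and on
  the beta scale with clipping to $[0, 1]$ — the simplest model consistent
  with the data types; no replicate-variance estimates were available to
  emulate, so the sds are exposed parameters, not assertions.
* **Coupled methylation.** Half of the trend genes (configurable) receive
  beta dynamics of the opposite sign to expression — the canonical
  promoter-methylation direction — with a planted high-vs-baseline step of
  0.3, above the 0.25 DMG gate. Baselines for coupled genes are drawn with
  headroom for the full step, so clipping never erodes the planted
  magnitude; clipping still applies to noise excursions.
* **Annotations and TF targets.** Planted sets draw members so the expected
  overlap with the increasing class matches the configured fold (20 by
  default, which saturates to all-members-from-the-class at the default
  class sizes). The planted TF's peaks are placed 5 kb upstream of each
  intended target's TSS on a synthetic chromosome of 100 kb-spaced,
  strand-alternating 20 kb genes, so the window rule recovers the target
  list exactly; decoy peaks fall outside every window.
* **qPCR.** Ct tables are built backwards from the planted induction
  courses, so delta-delta-Ct reconstruction is exact at zero Ct noise.
  Outcome proportions are an affine function of the standardized maximal
  induction plus independent Gaussian noise, giving population correlation
  `r_true` (affine maps preserve Pearson correlation); values are clipped to
  (0.01, 0.99), which at the chosen scale (0.08) is a measure-zero
  perturbation in practice.
* **Determinism.** Each artifact uses its own stream seeded from the master
  seed plus a fixed offset, so artifacts are independently reproducible and
  byte-identical under the same truth.

What the generator does *not* emulate: probe-level chip artifacts, batch and
spatial effects, platform-specific preprocessing, or realistic annotation
databases. Passing recovery tests therefore demonstrate correctness of the
analysis chain under its stated assumptions, not robustness to real-world
artifacts.

# Problem sizes used by the checks

The acceptance suite runs the rank-product calibration at 2,000 genes with
50 null seeds and 20 planted seeds; oracle-equivalence checks (EASE, Fisher,
paired t, t-CDF) use exhaustively enumerable sizes (backgrounds ≤ 30, 4-6
genes for rank-permutation enumeration); Monte-Carlo checks of the generator
use 50-200 seeds at 250-800 genes. These sizes were chosen to make each
check statistically decisive while keeping the full suite around half a
minute.

# Known limitations

* The PFP estimator's mild anticonservatism under correlated pairings,
  quantified above.
* The method-level (not bit-level) equivalence to the web tool originally
  used for rank products: its exact permutation scheme and tie rules are not
  recoverable.
* Flat-profile clusters are not recoverable under the dot-product metric by
  construction.
* Database-dependent enrichment results (specific term counts and folds)
  are out of scope: annotation sets are user- or generator-supplied.
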