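---
title: "Methods: case-control metabolomics screening with metscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control metabolomics screening with metscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscreen)
```

# The analysis problem

Targeted, broad-spectrum serum metabolomics in a small case-control design
(typically a few dozen subjects and a few hundred metabolites grouped into
biochemical pathways) asks four questions in sequence:

1. **Which metabolites distinguish cases from controls?** Individual
   effects are modest (typically ±20% to 2-fold in chronic, non-Mendelian
   disease), so discovery leans on a multivariate projection rather than
   per-metabolite testing alone.
2. **Which pathways carry the signal?** Metabolites are biochemically
   organized; a pathway-level "metabolic impact" summary is more stable and
   more interpretable than a flat hit list.
3. **Can a handful of metabolites serve as a diagnostic classifier**, and
   does its apparent accuracy survive honest resampling validation?
4. **Is the correlation structure of the metabolome itself altered** — are
   metabolite pairs more tightly coupled in cases than in controls?

`metscreen` implements this pipeline end to end, together with a synthetic
cohort generator that plants known truth so that every stage can be tested
for recovery.

# Preprocessing and control-referenced Z-scores

Raw intensities are log-transformed (natural log; a pseudocount of 1 is
applied only when zeros are present) and every sample — case and control
alike — is scaled per metabolite by the control group's mean and sample
standard deviation (n−1):

$$Z_{ij} = \frac{x_{ij} - \bar{x}^{\mathrm{ctrl}}_j}{s^{\mathrm{ctrl}}_j}.$$

Control columns therefore have mean 0 and SD 1 by construction, and a case
Z-score reads directly as "SDs above/below the healthy reference". Logging
before Z-scoring (rather than after) keeps the reference scale
multiplicative, which matches the log-normal behavior of intensity data;
this ordering is a deliberate design choice of the package. Metabolites
missing in more than 20% of samples, or constant in controls, are dropped
with a warning; means and SDs use pairwise-complete values.

One practical consequence worth knowing: for subjects *outside* the
reference group, the sampling error of the estimated control mean and SD
inflates the Z-scale slightly (variance ≈ ×1.15 at 20 controls), so tail
counts such as "metabolites with |Z| ≥ 2" run higher in cases than the
nominal Gaussian 4.6% even under the null. The tests account for this.

# PLS-DA and VIP screening

Discrimination uses partial least squares regression against the centered
0/1 class indicator (PLS1 "discriminant analysis"), fitted by sequential
NIPALS components with X-deflation: each component's weight vector is
$w_a \propto X_{a-1}' y_{a-1}$ (unit norm), scores $t_a = X_{a-1} w_a$ are
mutually orthogonal, and each component explains response sum of squares
$SSY_a = (t_a'y_{a-1})^2 / t_a't_a$. Two components are fitted by default —
enough for the standard 2-D scores plot and stable at n ≪ p — and variable
importance is accumulated over all fitted components with the standard
(Wold) VIP:

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a SSY_a \, w_{ja}^2}{\sum_a SSY_a}},$$

which satisfies $\sum_j \mathrm{VIP}_j^2 = p$ exactly (the mean squared VIP
is 1, so VIP > 1 means "above-average contributor").

A metabolite is called **significant** by the joint rule
*VIP > 1.5 and two-sided Mann-Whitney U p ≤ 0.05*. The U test is exact for
combined samples of at most 20 without ties and a tie-corrected normal
approximation with continuity correction otherwise. Direction (up/down) is
the sign of the mean case Z. Rankings sort by VIP descending with ties
broken by smaller p, then metabolite ID. The joint rule is conservative:
on fully null cohorts it flags about 4% of metabolites (never more than
10% in our test battery).

A note on post-hoc testing: with exactly two groups there are no pairwise
comparisons for a Fisher's-LSD-style post-hoc step to correct, so no such
step exists in this package; FDR control is provided separately
(Benjamini-Hochberg step-up, plus Storey q-values with a spline-smoothed
$\hat\pi_0(\lambda)$ over $\lambda \in \{0.05,\dots,0.95\}$, evaluated at
the largest $\lambda$ and clipped to (0, 1]).

# Pathway metabolic impact

The top k = 30 significant metabolites (by VIP) are assigned to pathways.
For each pathway with $N$ of the $N_{tot}$ measured metabolites:

* expected hits $= (N / N_{tot}) \times k$;
* fold enrichment $=$ observed / expected (expected unrounded);
* **impact** $=$ sum of member VIPs among the selected metabolites;
* impact fraction $=$ impact / total impact over hit pathways.

Report tables round half-up to one decimal (whole percents for fractions);
all intermediates are kept at full precision and rounding happens only at
display. Pathways with zero hits are omitted from the reported table but
available via `all_pathways = TRUE`. k = 30 is the default selection depth
and is configurable.

# Diagnostic panels and validation

Panels of 1-6 metabolites are scored by a seeded probability random forest
(500 trees, single-threaded for determinism). Apparent AUROC uses
*out-of-bag* class probabilities, so it carries no resubstitution optimism;
its 95% CI is bootstrap-percentile over 100 resamples of the score/label
pairs. The 2×2 contingency table is taken at the Youden's J operating
point, with Wilson score intervals on sensitivity and specificity (the
Wilson interval was chosen for its small-n behavior; at 19/20 it gives
0.76–0.99).

Validation has two layers:

* **rdCV** — repeated double cross-validation: 100 stratified random
  splits with 2/3 of each class in training and 1/3 held out, the forest
  refit on every split, reporting the mean held-out AUROC. AUROC (not
  accuracy) is the rdCV statistic throughout, with accuracy available by
  evaluating the contingency table.
* **Permutation p** — class labels permuted B = 1000 times, the statistic
  recomputed per permutation, and $p = (1 + \#\{stat^* \ge stat\})/(B+1)$,
  which can never be 0 and is uniform-valid under the null (verified by a
  200-replicate calibration at B = 200 in the test suite).

Panels are grown greedily: starting from the best single candidate by
rdCV, the candidate maximizing rdCV is added at each step (selection uses
a reduced 25-split rdCV for speed; final evaluations use the full
settings). Greedy forward selection does not explore all subsets — other
panels of equal size may perform equally well.

Sample-size planning for a follow-up study uses the two-sample
normal-approximation formula
$n = 2 (z_{1-\alpha/2} + z_{power})^2 / d^2$ per group, plus one subject
per group per planned predictor as a degrees-of-freedom allowance for
selecting a multi-metabolite classifier in a regression model. The output
names this convention explicitly: published power statements rarely pin
down their multivariable adjustment, so the package reports its own
convention rather than claiming to reproduce any particular printed n.

# Correlation networks and differential coupling

Within each group separately, all $m(m-1)/2$ unordered metabolite pairs
(63,903 for m = 358) get Pearson and Spearman correlations of their
Z-scores, with p-values from the t-approximation
$t = r\sqrt{n-2}/\sqrt{1-r^2}$. **Edge significance uses the Spearman
FDR** (BH within each group over all pairs; Storey q attached), while the
Pearson r is carried for the display threshold: exported networks keep
edges with signed $r \ge 0.85$ by default, with an absolute-value mode
(`mode = "absolute"`) because display conventions differ on whether strong
negative edges are shown.

Differential coupling compares the per-group counts of FDR < 0.05 pairs:
the case/control ratio plus a two-sided Fisher exact test on
{significant, not} × {case, control}. Degenerate cases are defined
explicitly: two empty edge sets give ratio 1; a positive case count over
zero control count gives ratio ∞. Exports are force-layout JSON (nodes
with pathway group, links with weight and sign) and GraphML.

# Diagnostic vs individualized abnormalities

For each subject, every metabolite with |Z| ≥ 2 is an abnormality. It is
**diagnostic** when the metabolite's cohort-level VIP is ≥ 1.5 (the
threshold is inclusive) *and* the subject's Z sign matches the
cohort-level direction; otherwise it is **individualized** — extreme only
in that subject or discordant with the shared signature. The partition is
exhaustive and exclusive over each subject's extreme metabolites. Control
profiles are computed too (useful for calibration) but summarized
separately.

# The synthetic cohort generator

`generate_cohort()` is first-class, tested code — it defines the study
conditions under which the pipeline's recovery properties are established.

**Structure.** 358 metabolites in 46 pathways (eight named pathways of
sizes 31/56/36/18/9/4/7/8 — ceramides, phospholipids, sphingomyelins,
purines, pyrimidines, endocannabinoids, eicosanoids, branched-chain amino
acids — plus 38 null background pathways), 20 cases vs 20 controls.
Log-intensities are multivariate normal from a hierarchical factor model:
a global factor (`rho_between = 0.05`), a per-pathway factor
(`rho_pathway = 0.05`), and a factor per *correlation cluster* of at most
8 metabolites within a pathway (`rho_within = 0.6`), then scaled to
per-metabolite log-normal baselines (log-mean ~ U(6, 12), log-SD ~
U(0.2, 0.6)) and exponentiated. Clusters mimic tightly co-regulated
sub-families (e.g. lipid species sharing a backbone); modeling a 56-member
pathway as a single equicorrelated block instead would hand the whole
pathway a coherent noise factor whose group-mean fluctuation at n = 20/20
(SD ≈ 0.26 Z) overwhelms pathway ranking — a structure we consider both
less realistic and analytically degenerate.

**Planted effects.** Shifts are applied on the log scale in units of the
control log-SD, so planted effects are exactly the Z-shifts downstream
stages should recover: ceramides +0.80, phosphatidylcholine-like members
+0.78 (one phospholipid down at −0.66), sphingomyelins +0.75, purines
−0.70, one pyrimidine up (+0.89) and one down (−0.88), endocannabinoids
−0.84/−0.60, an eicosanoid at −0.84 and a branched-chain amino acid at
+0.64. Affected members are spread evenly across a pathway's clusters.
The *affected fractions* are calibrated to detection: the joint screening
rule detects a |Z| ≈ 0.6-0.9 shift with probability ≈ 0.5-0.65 at 20 vs
20, so shifts are planted on enough members (e.g. 18 of 31 ceramides) that
the expected number of *detected* hits per pathway reproduces the
observed-hit profile 11/5/4/4/2/2/1/1 — published hit counts are
post-detection quantities and planting them directly would systematically
under-recover them.

**Case coupling.** `case_coupling > 1` divides the cases'
metabolite-specific noise SD by that factor and renormalizes marginal
variances to 1 — correlations tighten (0.6 → ≈ 0.77 within clusters at
1.5) while planted Z shifts are untouched, and positive semi-definiteness
is automatic. The default is 1 (no differential coupling); analyses of the
differential-coupling phenomenon use 1.5.

**What it does not emulate.** Missing values, batch and storage-time
effects, heteroscedastic or heavy-tailed measurement noise, medication
confounding, and matched-pair structure. Passing recovery tests therefore
demonstrates that the pipeline's inferences are correct *under the model's
assumptions at study scale* — not that any particular real dataset
satisfies those assumptions.

# Numerical and reproducibility choices

* Sample SD (n−1) everywhere; pairwise-complete handling of missing
  values; metabolites > 20% missing excluded.
* Exact tests where exactness is feasible: Mann-Whitney (combined n ≤ 20,
  untied), Wilcoxon signed-rank in the group-shift test (≤ 20 members,
  untied), Fisher's 2×2 (probability-mass two-sided convention).
* Permutation p-values use (b+1)/(B+1); bootstrap CIs are percentile.
* Display rounding is half-up (base R `round()` is round-half-even and
  would print 2.65 as 2.6); intermediates are full precision.
* One global seed fans out to per-stage seeds by fixed offsets
  (`derive_seed`), so stages can be rerun in isolation and a full pipeline
  run is bit-reproducible; forests run single-threaded with fixed seeds.
* Tie-breaking in rankings: VIP desc → p asc → metabolite ID.

# Problem sizes used by the test battery

Recovery and calibration properties are established at the design scale of
the generator: 20 cases vs 20 controls × 358 metabolites, 20 independent
seeds for direction/pathway recovery and differential coupling, 200
replicates at B = 200 for permutation-p calibration, n = 2000 controls for
correlation-structure convergence, and 40 replicates for planted-shift
recovery on the Z scale. These sizes were chosen to make sampling noise in
the checked proportions small relative to the asserted margins.

# Known limitations

* Greedy panel growth is heuristic; nested panels are not guaranteed
  monotone in rdCV.
* VIP depends on the number of fitted components; the default (2) is a
  convention, and VIPs from deeper models differ.
* The q-value's $\pi_0$ spline estimate is unstable below a few dozen
  p-values; the edge-table builder falls back to $\pi_0 = 1$ (plain BH)
  when fewer than 10 pairs exist.
* With 20 samples per group, pathway impact rankings retain real sampling
  variability: the dominant planted pathway tops the table in ~85% of
  simulated cohorts, not all of them — small-study rankings should be read
  with the same caution.
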