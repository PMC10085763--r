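---
title: "Rapid-cycle recurrent genomic selection: models, simulator and scheme engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid-cycle recurrent genomic selection: models, simulator and scheme engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcgs)
```

## Scope

`rcgs` studies rapid-cycle recurrent genomic selection (RCRGS) in
self-pollinated crops: a training population of inbred lines is phenotyped
once, genomic estimated breeding values (GEBVs) are computed for successive
greenhouse generations of F1 crosses, and the best F1s are intermated cycle
after cycle without any further field phenotyping. The package provides the
four standard prediction models used in this setting, the relationship
structures they need, the cross-validation and gain arithmetic used to
summarize such experiments, and a forward simulator able to run the whole
scheme in silico so that every stage is testable without proprietary data.

## Prediction models

All four models are instances of one linear mixed model,

$$ y = \mu 1 + \sum_k u_k + e, \qquad u_k \sim N(0, \sigma_k^2 K_k), \qquad
   e \sim N(0, \sigma_e^2 I), $$

differing only in the list of covariance structures $K_k$:

* **GBLUP** — one genomic term with $K = MM'/p$, where $M$ holds marker
  dosages centered and standardized by column and $p$ is the marker count.
* **P+GBLUP** — adds a pedigree term with the numerator relationship matrix
  $A$ (twice the coefficient of parentage), computed by the tabular method
  with an explicit treatment of selfing generations.
* **RKHS-KA** — reproducing kernel Hilbert space regression with kernel
  averaging: three Gaussian kernels $K(x_i, x_{i'}) = \exp(-h\,d^2_{ii'})$
  whose bandwidths are $h \in \{1/(5m),\; 1/m,\; 5/m\}$, with $m$ the median
  off-diagonal squared Euclidean distance between lines. Scaling $h$ by
  $1/m$ makes $h\,d^2$ dimension-free; the three bandwidths bracket the
  median-calibrated kernel by a factor of five on either side, so the model
  can weight smoother and sharper covariance decay itself through the three
  variance components.
* **P+RKHS-KA** — pedigree term plus the three kernels; this is the
  configuration a breeding program would use for parental selection, since
  the pedigree emphasizes between-family (additive) variance while the
  kernels also absorb non-additive signal.

Distances for the kernels are computed on the same centered/standardized
marker matrix as $K$, so the genomic matrix and the kernels share one
preprocessing path; selection candidates are standardized with
*training-set* column moments and the bandwidth is frozen at the training
median, which keeps the model identical across selection cycles.

### Gibbs sampler

The engine samples each random term on the eigenbasis of its covariance
matrix: with $K = U\,\mathrm{diag}(d)\,U'$ and $u = Ub$, the prior on $b$ is
independent normal and, because $U$ is orthonormal, the full conditional of
$b$ factorizes into independent normals — no per-iteration matrix solves
are needed. Numerical choices:

* eigenvalues below $10^{-8}$ of the largest are dropped, restricting each
  effect to the numerically non-null eigenspace (near-singular kernels are
  common);
* variances have scaled-inverse-$\chi^2$ priors with `df0 = 5`; the prior
  scale of each genetic term corresponds to an equal share of 50% of the
  phenotypic variance and the error prior to the other 50%. These mirror
  the documented defaults of widely used Bayesian genomic-prediction
  software; the data dominate them at the sample sizes used here;
* the intercept carries a flat prior;
* missing phenotypes are latent variables redrawn each sweep from their
  conditional normal, which is how unphenotyped selection candidates are
  predicted jointly with model fitting;
* default chain: 12,000 iterations, 2,000 burn-in, thinning 5. Tests and
  desk-scale runs use shorter chains (stated below); a fixed-variance mode
  clamps the variance components so the posterior mean can be compared
  against the closed-form BLUP solution.
* any non-finite draw aborts the chain with an iteration-stamped error;
* truncation selection breaks GEBV ties by lexicographic id order so that
  selections are reproducible.

## Heritability, gain and diversity arithmetic

Line-mean heritability is
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_{ge}^2/e + \sigma_e^2/(re))$
with $r$ replications and $e$ environments. Combined cycle means are
averages of per-year means (a balanced-trial convention); realized gain
between first and last cycle is $(\bar y_{C_n} - \bar y_{C_0})/n$ per cycle
and $100(\bar y_{C_n} - \bar y_{C_0})/\bar y_{C_0}$ percent, and per-year
gain spreads $n$ cycles over the elapsed years. Genetic diversity is
tracked with Nei's standard distance
$D = -\ln\!\left(J_{xy}/\sqrt{J_x J_y}\right)$ on per-locus allele
frequencies; an inbred line enters as a one-line population with frequency
dosage/2 (an interpretive convention, common when population distances are
applied to lines), and alternately fixed profiles yield an explicit
infinite distance.

Cross-validated prediction ability is the Pearson correlation of predicted
and observed line values. Within-family ability uses repeated k-fold
partitions inside a family; between-family ability is leave-one-family-out.
By default within-family folds train only on the remainder of that family,
which isolates within-family information; a flag adds all other families to
the training set.

## The simulator

The generator emulates the structure of the motivating experiment rather
than any particular germplasm:

* **Genome** — 21 chromosomes of 1 Morgan; marker allele frequencies drawn
  from Uniform(0.1, 0.9) so the MAF filter has non-trivial action; founders
  fully inbred by default.
* **Meiosis** — Haldane model: Poisson crossover counts per chromosome with
  uniform positions, no interference. Simple and sufficient for testing
  prediction machinery.
* **Advancement** — single-seed descent, or "selected bulks" modeled as a
  random choice among `bulk_k` selfed candidates; the visual selection of
  good spikes is not phenotype-informed, so within-bulk choice is random.
* **Training population** — 16 founders crossed into 14 bi-parental
  families with the published family sizes (total 1,609 lines at study
  scale), F2-derived lines advanced to F4, phenotyped with 2 replicates.
* **Trait** — additive per-marker effects (optional additive×additive
  pairs), intercept 6.71 t/ha and overall genetic SD 0.5 t/ha at the
  defaults. Per-family heritability targets (defaults follow the published
  per-family estimates, 0.01–0.73) are met by solving the line-mean
  heritability identity for the residual variance family by family from
  each family's realized genetic variance.
* **Bulk genotyping** — an F1 entry's marker profile is the mean dosage of
  its sampled sibling plants, as with pooled seedling DNA; bulk dosages are
  real-valued and enter the genomic/kernel structures through the
  training-moment standardization.

What the generator does **not** emulate: the SNP content and LD structure
of real genotyping arrays (all simulated loci are causal and observed),
genotype-by-environment interaction beyond i.i.d. year effects, dominance,
and selection during bulk advancement. Two consequences matter for
interpreting tests. First, because every causal locus is genotyped and
families share founders, information transfers across families more freely
than on real arrays, where marker–QTL phase breaks down between families;
the within- vs between-family ability contrast is therefore assessed with
within-family records added to a shared training set, and the paper-style
contrast under family-only training should not be expected from this
generator at small family sizes. Second, passing directional tests shows
the machinery responds to selection as theory predicts under the stated
architecture — not that field gains of a particular magnitude would be
realized.

## The scheme engine

`run_scheme()` chains the stages: training simulation → marker QC
(intersect → impute → filter order; strict MAF cut at 0.05) → per-family
summary (mean yield, heritability from the replicated trial, within- and
between-family CV ability) → composite family selection by unweighted rank
sum over those four criteria (the experiment lists the criteria but no
weighting; the rule is pluggable) → top lines per family as C0 parents →
crossing plan → recurrent cycles → advancement → simulated two-year,
two-replicate trial.

Decisions where the design was genuinely open:

* **Family-pair choice.** The plan needs a fixed number of family pairs,
  each family appearing in at least three; pairs are chosen by decreasing
  between-family ability (the stated criterion) under a coverage-first
  greedy that guarantees the quota or fails with an explicit error.
* **Cycle families.** An F1 entry's "family" is its cross of origin.
  Within-family crosses in later cycles therefore require sibling entries;
  when the selected set cannot realize the requested number of
  within-crosses, the shortfall moves to between-crosses and is recorded on
  the plan.
* **Parents from entries.** When a selected entry is crossed, one of its
  sibling plants is drawn at random as the genetic parent; entry-level
  GEBVs describe the bulk, individual plants carry Mendelian sampling.
* **Advancement set.** Entries advanced to inbred lines are sampled from a
  GEBV rank band (default ranks 1–36 at desk scale, 1–58 at study scale)
  rather than strictly top-ranked, mirroring the seed-availability
  constraints such experiments report.
* **Training set.** Never updated across cycles; every cycle is predicted
  from the original training population.
* **C0 reference.** The true-breeding-value trajectory uses the full
  training cohort as its C0 point; the simulated field trial uses a sampled
  subset of the C0 parents, as in the motivating experiment.

## Problem sizes

The package's `"study"` configurations reproduce the experiment's counts
(1,609 training lines, ~7,000 markers, 136/88 F1s, top 26/29 selected,
32–35 entries advanced). Examples and tests run the `"desk"` configuration:
14 families × 16 lines, 210 markers on 21 chromosomes, 120 F1 entries per
cycle with 24 selected and 10 advanced, chains of 1,200 iterations (300
burn-in) for cycle fits and 500 (125) for cross-validation folds. These
sizes keep a full scheme run in the tens of seconds while preserving the
study's selection intensity (~20%) and its between:within crossing ratio of
roughly 3:1, which is the feature the diversity-maintenance checks depend
on. Statistical checks on the scheme use seeded replicates at this scale: 20
for the gain-direction property and 40 for the null-drift property, whose
per-replicate drift (sd ≈ 0.11 t/ha) needs the larger sample for a
standard error well inside the 0.05 t/ha tolerance.

## Known limitations

Single trait, single target environment; no dominance or H-matrix
structures; no optimal-contribution selection — truncation only; no
REML path (the Gibbs posterior mean is the point estimate throughout); COP
values from historical pedigree software depend on ancestral-default
conventions that are not reproduced here, so published COP summaries are
not comparison targets. The configuration surface (`scheme_config()`,
`training_pop_config()`, `validate_config()`) exposes every count, rate and
chain setting used above; all randomness flows from explicit seeds.
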