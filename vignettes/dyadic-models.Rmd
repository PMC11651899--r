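---
title: "Methods: dyadic multi-membership models for hybrid-zone communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic multi-membership models for hybrid-zone communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadmm)
```

## Scientific setting

Across a hybrid zone, two closely related host subspecies and their admixed
hybrids live along a spatial gradient. Their intestinal communities — here
decomposed into bacteria, fungi, eukaryotic parasites and plant (diet) DNA —
can differ between hosts for two broad families of reasons: *host filtering*
(host genotype promotes or suppresses taxa: subspecies divergence,
hybridization-induced dysregulation) and *environmental filtering* (hosts
sample different microbial pools across space and time). `dyadmm` quantifies
the two against each other by regressing pairwise community similarity on
pairwise genetic and environmental distances.

## Admixture metrics

Each host's hybrid index is the proportion of one subspecies' diagnostic
alleles among its typed alleles, `HI = n_mmm / n_typed` (14 diploid loci in
the motivating design, but the computation only needs totals). Admixture is
summarized by the expected hybrid heterozygosity `hHe = 2·HI·(1−HI)`: zero
for both pure genotypes, maximal (0.5) at `HI = 0.5`. Its pairwise
derivatives capture two distinct aspects of hybridization: `hhe_dist =
|hHe_i − hHe_j|` (do the two hosts differ in how admixed they are?) and
`hhe_mean = (hHe_i + hHe_j)/2` (how admixed is the pair as a whole?). The
latter is the natural probe for *variance* effects: if hybrids have more
idiosyncratic communities, pairs of hybrids are systematically less similar,
which surfaces as a negative `hhe_mean` coefficient.

`hhe_mean` is implemented as the arithmetic mean rather than the sum. The two
encodings differ only by a factor of 2, and every predictor is min–max scaled
to `[0, 1]` before modelling, so the model inputs — and hence the estimates —
are identical either way.

Hosts with no typed alleles are rejected with an error. Imputation of
incomplete genotypes is deliberately out of scope: it is an upstream,
design-specific step, and silently defaulting a hybrid index would corrupt
every dyad the host takes part in.

## Community assembly

Raw per-amplicon ASV tables pass three filters in a fixed order: samples with
fewer than 100 reads are dropped first; then taxa with prevalence below 1% of
the *retained* samples; then taxa below 0.005% relative abundance. The order
matters because prevalence denominators change with the retained sample set,
and is therefore fixed and documented rather than left to chance. The
relative-abundance rule uses pooled abundance (taxon total over grand total)
by default; a per-sample-mean variant is available via `abundance_rule`
because the convention differs between pipelines. Filtering and total sum
scaling are applied per amplicon, and the normalized amplicons are collated
by sample id afterwards, so each amplicon's compositional closure is
respected.

Component labels (`bacteria`, `fungi`, `parasites`, `diet`, `other`) are a
total function of the taxonomy: fixed phylum lists for bacteria, fungi and
plants, a genus/order list for the parasites, and `other` for everything
unmatched, so downstream code never meets an unlabelled taxon.

## cASV merging

Multi-amplicon designs observe one taxon as several ASVs on different marker
genes. Within each genus, all ASV pairs are tested for Spearman correlation
across samples; edges require a positive coefficient and a
Benjamini–Hochberg-adjusted p below 0.01, with the BH family being that
genus's set of pairwise tests (networks are per genus; a switch for global
correction is not provided because cASVs never span genera anyway).
Correlation p-values are exact for n ≤ 9 samples without ties and use the
t approximation otherwise, which keeps the small shipped fixtures exactly
reproducible. Zero-variance ASVs cannot be tested; they are excluded from
testing with a warning and kept as singleton cASVs.

Clusters come from greedy modularity maximization on the positive-edge
network, weighted by the correlation coefficients. The implementation uses
igraph's agglomerative fast-greedy merge sequence but selects the cut itself,
at the maximum of modularity along the merge path: the library's own cut can
stop short of that maximum on star-like graphs (returning a
negative-modularity partition when the trivial single community has
modularity 0). The test suite compares the resulting partitions against
exhaustive enumeration over all set partitions for networks of up to six
nodes. Member abundances are summed per sample, which conserves per-sample
totals exactly (asserted to 1e−9 over random tables).

## Similarity and the dyad table

Occurrence similarity is `1 −` binary Jaccard distance; abundance similarity
is `1 −` Aitchison distance (Euclidean distance between centered-log-ratio
vectors after adding a pseudocount). Both go through `vegan::vegdist`. Two
numerical choices deserve attention:

* **Pseudocount placement.** A pseudocount of 1 added to relative abundances
  (all ≤ 1) would drown the composition; `similarity_matrices()` therefore
  rescales by 1e6 before adding it (configurable). The scalar
  `aitchison_similarity()` takes its input as given, for count-like vectors.
* **Range.** `1 − Aitchison` is unbounded below; the Gaussian model accepts
  negative responses, and an optional z-standardization of the response
  (`standardize_response`) is provided for users who prefer a unit scale.
  Published intercepts of comparable analyses are sometimes incompatible with
  a raw similarity scale, suggesting an unstated response transformation;
  both scales are supported here and neither is claimed to reproduce any
  specific published coefficient table.

A pair of samples in which *neither* member has any taxon of the component
has an undefined Jaccard ratio (0/0); it is defined as similarity 0, with a
warning, so that sparse components (e.g. parasites) do not crash the
pipeline.

Predictors are min–max scaled per dyad table, i.e. per component model, so
that standardized estimates are comparable within a model. A constant
predictor cannot be scaled and raises an error telling the caller to drop the
term — silently keeping an all-zero column would make its coefficient an
arbitrary draw from the prior.

## The dyadic model and its sampler

The response over all `n(n−1)/2` dyads follows

$$y_{ij} = \alpha + \textstyle\sum_k \beta_k x_k(ij) + u_i + u_j +
\varepsilon_{ij}, \quad u_m \sim N(0, \sigma_u^2), \quad \varepsilon_{ij}
\sim N(0, \sigma^2).$$

The multi-membership random intercepts are the point of the model: dyads
sharing a mouse are dependent, and a fixed-effects-only fit at `σ_u > 0` has
anti-conservative intervals (the test suite asserts this regression —
ordinary-least-squares coverage falls below nominal while the full model
holds it). Both members load with weight 1 by default (`member_weight = 0.5`
gives the mean-of-effects convention; after rescaling of `σ_u` the two are
equivalent).

Priors are weakly informative: `N(0, 5²)` on intercept and coefficients and
half-Student-t(3, 0, 2.5) on both scale parameters. With a Gaussian
likelihood these priors make every full conditional conjugate — the half-t
enters through its inverse-gamma auxiliary representation — so the posterior
is sampled by an **exact blocked Gibbs sampler**. Each sweep draws the whole
`(β, u)` vector in a single joint Gaussian block (the cross-product matrices
are constant, so a sweep costs one Cholesky factorization of a
`(p + M) × (p + M)` matrix), then the two variances. The joint block matters:
updating `β` and `u` separately leaves a random-walk coupling between the
intercept and the mean of `u` that mixes poorly.

Numerical choices: chain-specific overdispersed initial values (ridge
least-squares plus noise for the location of the first sweep's variances);
variance draws floored at 1e−12 because a degenerate response that the member
effects fit exactly would otherwise collapse `σ²` to numerical zero and
overflow the precision matrix; an exactly constant response is rejected with
an explicit error (and skipped with a warning by the component runner). A
near-singular fixed-effect design triggers a warning with the condition
number.

Convergence is assessed with rank-normalized split-$\widehat R$ (bulk and
folded, the larger of the two), computed over independent chains with seeds
derived deterministically from one master seed; fits are bit-reproducible
given that seed. Two thresholds are reported rather than enforced: 1.01
(`reliable` flag per parameter) and 1.05 (summary-level `converged`
attribute plus a warning). Results are flagged, never suppressed.

Default sampler settings are 4 chains × 3000 iterations with 1000 warmup,
matching common practice for this model family; the operating-characteristic
suites run at 4 × 1000 (250 warmup), which the conjugate sampler's mixing
makes ample — observed $\widehat R$ values sit at 1.00–1.01.

## Model variants

* `wild_model_spec()` — spatial, genetic, admixture (`hhe_dist`, `hhe_mean`)
  and temporal terms plus a `gen_dist × hhe_dist` interaction, letting the
  admixture-difference effect vary along the divergence gradient.
* `lab_model_spec()` — the controlled-environment variant: genetic distance,
  admixture difference, and infection-status distance (0 for
  same-status pairs, 1 for mixed pairs); no spatial or temporal terms, no
  interaction. Members are the 22 mice, each contributing two samples
  (before and at the peak of infection).
* `fungi_bacteria_model_spec()` — bacterial similarity as the response with
  the matched fungal similarity (Jaccard with Jaccard, Aitchison with
  Aitchison) as a dyad-level covariate — a property of the pair, not a
  membership term — controlling for the wild model's distance terms. The
  fungal similarity is min–max scaled like every other predictor.

`run_component_models()` recapitulates a spec per component (overall,
bacteria, fungi, parasites, diet) and per response type; components with
fewer than three taxa, or with degenerate constant responses, are skipped
with warnings.

## The synthetic generator

The generator exists for operating-characteristic testing — parameter
recovery, coverage, power — not to mimic any real dataset. It emulates, with
known ground truth:

* an HI cline: hosts placed uniformly on a planar transect, expected HI a
  logistic function of x (`cline_center`, `cline_width` in the transect's
  length units), allele counts binomial around it;
* component-structured communities whose default taxon counts echo a
  realistic wild shape (383 bacteria, 65 fungi, 11 parasites, 45 diet taxa);
* a long-tailed abundance distribution (log-normal baseline, `base_sd = 2.5`)
  — the long tail is what makes occurrence data informative: with an even
  distribution every taxon is present in every sample and Jaccard similarity
  degenerates to a constant;
* host filtering (per-taxon Gaussian loadings on HI, `sd_host`),
  environmental filtering (per-taxon Gaussian fields with exponential
  spatial covariance; `env_range = 20` length units, set so distance decay is
  detectable at 60 mice), and sampling-year effects (`sd_year`);
* hybridization-dependent fungal variance: fungal idiosyncratic noise SD is
  `sd_noise · (1 + γ · 2·hHe)`. The default `γ = 4` was set by a power
  analysis: it is the strength at which the designed effect is detected
  (negative `hhe_mean` CI excluding zero in the fungal occurrence model) in
  essentially all probe replicates at 60 mice, the scale at which the
  package's recovery suites operate; a first guess of 2 gave roughly 40%
  power and would have made the power suite a coin flip;
* an infection perturbation (lab mode): per-taxon shifts applied to
  bacteria, parasites and diet but not fungi, mirroring the designed
  fungal robustness;
* multi-amplicon redundancy: each true taxon emitted as
  `1 + Poisson(amplicon_redundancy)` pseudo-ASVs spread over its component's
  amplicons, sharing the taxon's latent abundance up to a small copy-level
  noise (`pseudo_asv_noise_sd = 0.15`). Realized copy correlations are
  bounded by multinomial sampling noise, so abundant taxa show Spearman
  correlations near 1 while rare taxa decorrelate — exactly the regime real
  multi-marker data present to a co-abundance merger.

What the generator does **not** emulate: sequence-level error, chimeras and
contamination (out of scope — the package starts from count tables),
phylogenetic correlation among taxa, taxon–taxon interaction networks, and
overdispersion beyond the multinomial. Passing tests therefore demonstrate
correct and well-calibrated *inference machinery* under the stated generative
assumptions, not robustness to every property of real amplicon data.

`lab_preset()` reproduces the controlled-environment roster: four parental
inbred strains (3 mice each), intra-subspecies F1 crosses (3 + 2) and
inter-subspecies hybrids (2 + 3) — 22 mice, each sampled before infection and
at its peak (44 samples), with HI 0, 0.5 or 1 by cross and no spatial or
temporal covariates.

## Problem sizes in the test suite

The suites run at the sizes the inference questions demand while staying
desk-sized: recovery and coverage at 60 mice (1,770 dyads, 20 replicates per
setting, 4 × 1000 iterations); the membership-matters regression at 30 mice;
the end-to-end laboratory run at the full 22 × 2 roster with the default
community shape; network/clustering oracles at ≤ 6 nodes (exhaustive
enumeration over all partitions) and 8 samples (exact permutation null,
8! = 40,320 orderings). The whole suite completes in a few minutes on one
CPU.

## Known limitations

* The likelihood is Gaussian with identity link; similarity responses are
  treated as continuous. Jaccard similarities near the boundary of `[0, 1]`
  are not specially handled (no logit link), and `1 − Aitchison` is
  unbounded below by construction.
* Coordinates are planar; no geodesic correction. At hybrid-zone scale
  (tens of km) the error is negligible; continental-scale inputs should be
  projected first.
* cASV merging can, like any co-abundance criterion, merge distinct taxa
  whose abundances covary for biological reasons; the per-genus restriction
  bounds the damage but does not remove it.
* The sampler is exact only for this conjugate model family; switching to a
  non-Gaussian likelihood would require a different kernel.
* Hosts with missing hybrid index, coordinates or year are rejected, not
  imputed.
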