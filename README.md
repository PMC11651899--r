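# dyadmm — dyadic multi-membership models for hybrid-zone microbiome analysis

`dyadmm` asks a question from microbial ecology and speciation genetics: when
two house-mouse subspecies (*Mus musculus domesticus* and *M. m. musculus*)
meet and hybridize across a natural contact zone, how much of the variation in
their intestinal communities — bacteria, fungi, parasites, and plant (diet)
DNA — is explained by **host filtering** (subspecies divergence and
hybridization) versus **environmental filtering** (where and when a mouse was
sampled)? The package provides the full analysis path from host genotypes and
multi-amplicon ASV count tables to fitted Bayesian dyadic regressions, plus a
synthetic hybrid-zone generator with known ground truth so that every stage is
testable without any sequencing data.

It is written for microbial ecologists comparing community similarity between
pairs of hosts, and more generally for anyone fitting distance-based
regressions where observations are pairs and therefore not independent.

## The model

Each mouse carries a hybrid index `HI` (proportion of *Mmm* alleles at 14
diagnostic loci) and an expected hybrid heterozygosity

```
hHe = 2 · HI · (1 − HI)
```

which is 0 for both pure subspecies and maximal (0.5) for balanced hybrids.
For every unordered pair of samples (a *dyad*) the package computes community
similarity — occurrence-based (1 − binary Jaccard distance) and
abundance-based (1 − Aitchison distance, i.e. Euclidean distance between
centered-log-ratio compositions) — and the pairwise predictors: subspecies'
genetic distance `|HI_i − HI_j|`, difference in admixture `|hHe_i − hHe_j|`,
mean admixture `(hHe_i + hHe_j)/2`, spatial (Euclidean) and temporal (years)
distance, all min–max scaled to `[0, 1]` so standardized estimates are
comparable.

Similarity is then modelled over all `n(n−1)/2` dyads with a Gaussian
multi-membership regression,

```
y_ij = α + Σ_k β_k x_k(ij) + u_i + u_j + ε_ij,
u_m ~ N(0, σ_u²),  ε_ij ~ N(0, σ²)
```

where the random intercepts `u` are shared across every dyad a mouse takes
part in — the multi-membership structure that keeps credible intervals honest
when 60 mice generate 1,770 correlated pairs. Because the model is conjugate
under its weakly-informative priors, the posterior is drawn with an exact
blocked Gibbs sampler (single joint (β, u) block per sweep); convergence is
monitored with rank-normalized split-R̂ across independent chains.

Upstream of the model, the package implements the standard multi-amplicon
hygiene: per-amplicon prevalence/abundance/read-depth filtering, total sum
scaling, collation across amplicons, and merging of ASVs that represent the
same taxon on different marker genes into **cASVs** via per-genus Spearman
co-abundance networks (positive, Benjamini–Hochberg-significant edges) and
greedy modularity clustering.

## Worked example

Simulate a 40-mouse transect with the generator's default conditions, run the
community stages, and fit the occurrence model:

```r
library(dyadmm)

cfg    <- sim_config(n_mice = 40, seed = 7)
hosts  <- simulate_hosts(cfg)
sim    <- simulate_communities(hosts, cfg)

per_amp   <- lapply(sim$tables, function(ct) total_sum_scale(filter_asvs(ct)))
community <- merge_amplicons(per_amp)
casv      <- merge_casvs(community)          # 574 ASVs -> 366 cASVs

sims  <- similarity_matrices(casv$table$rel_abund)
dyads <- build_dyads(hosts, sims)            # 780 dyads

fit <- dyad_mm(similarity_jaccard ~ spatial_dist_sc + gen_dist_sc +
                 hhe_dist_sc + hhe_mean_sc + temporal_dist_sc +
                 gen_dist_sc:hhe_dist_sc,
               dyads, chains = 4, iter = 1000, warmup = 250, seed = 1)
summary(fit)
```

```
Bayesian multi-membership dyadic regression
780 dyads over 40 members

               parameter estimate    sd ci_lower ci_upper  rhat significant reliable
             (Intercept)    0.912 0.003    0.905    0.919 1.001        TRUE     TRUE
         spatial_dist_sc   -0.014 0.004   -0.022   -0.006 1.000        TRUE     TRUE
             gen_dist_sc   -0.003 0.002   -0.007    0.002 1.000       FALSE     TRUE
             hhe_dist_sc   -0.003 0.003   -0.008    0.002 1.001       FALSE     TRUE
             hhe_mean_sc   -0.020 0.009   -0.037   -0.002 1.001        TRUE     TRUE
        temporal_dist_sc   -0.001 0.001   -0.003    0.001 1.001       FALSE     TRUE
 gen_dist_sc:hhe_dist_sc   -0.003 0.004   -0.011    0.006 1.000       FALSE     TRUE
                 sigma_u    0.009 0.001    0.007    0.011 1.003          NA     TRUE
                   sigma    0.009 0.000    0.009    0.010 1.002          NA     TRUE
```

Reading the output: dyads of mice trapped further apart share less of their
community (`spatial_dist_sc` negative, CI excluding 0), and pairs with higher
mean admixture are less similar (`hhe_mean_sc` negative) — the generator's
designed hybridization effect on fungal variance showing through in the
overall community. `sigma_u` is the between-mouse scale, `rhat ≤ 1.01` marks
every estimate as reliable. `plot(fit)` draws the forest plot;
`run_component_models()` recapitulates the fit for bacteria, fungi, parasites
and diet separately, and `run_pipeline()` drives the whole path from a config
(YAML or list) with cached stages and a JSON run manifest.

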