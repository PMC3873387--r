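---
title: "Methods: network-based detection of inflammation-to-cancer dysregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based detection of inflammation-to-cancer dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chronic intestinal inflammation (ulcerative colitis, Crohn's disease)
predisposes to colorectal cancer, but the transition is largely invisible to
per-gene differential expression: pivotal regulators often keep their mean
expression while *rewiring* their regulatory relationships. `icnet`
implements a network-level route to such regulators. The pipeline:

1. **Stratify** each disease expression cohort into expression-homogeneous
   sample subsets (K-means on the inflammation + cancer gene space), keeping
   subsets of at least 20 samples.
2. **Infer** a regulatory network per subset: mutual information (MI)
   between every TF and every other gene, a permutation-calibrated
   significance threshold (per-pair p = 0.001 by default), and data
   processing inequality (DPI) pruning at tolerance 0; then restrict to TFs
   plus inflammation/cancer ("IC") genes and take the largest connected
   component.
3. **Cluster** the resulting network collection with a network-level
   topological overlap measure (TOM) and locate mixed inflammation–cancer
   clades — candidate bridge pairs — checking their stability under
   leave-one/two-out reclustering.
4. **Test dysregulation** for a chosen inflammation/cancer network pair:
   for every relationship in the combined neighborhoods of common TFs,
   compare the MI difference between conditions against a pooled permutation
   null, control FDR at 0.05, and intersect significant relationships across
   network pairs into a dysregulated network (largest component).
5. **Select core TFs**: degree at least 8 and inflammation and cancer
   composition ratios each at least 0.1 in the dysregulated network.

A SAM-style differential-expression baseline (`differential_genes`) is
included purely for the contrast in step 5's output: dependence-only
rewiring leaves it empty-handed.

# The MI estimator

The field's reference implementation estimates MI "by the Gaussian kernel
method" after a rank (copula) transform. The exact historical build and
bandwidth are not recoverable, so `estimate_mi` is a fully specified
estimator in the same family, chosen so that it is *consistent and
accurately calibrated on Gaussian dependence*, which is also the regime of
the package's synthetic oracle:

* **Normal scores.** Each vector is replaced by
  `qnorm(rank / (n + 1))`. Estimates depend on ranks only, so they are
  symmetric and exactly invariant under strictly monotone transforms, and
  the estimator's null distribution depends only on `n`.
* **Grid plug-in.** A product-Gaussian kernel density with per-margin
  bandwidth `h = n^(-1/6)` (the two-dimensional Silverman rate; normal
  scores have unit scale) is integrated on a fixed 61-point grid spanning
  [-4.5, 4.5], giving the plug-in MI of the smoothed density.
* **Null centering.** The plug-in value has a positive sampling bias under
  independence. Because the estimator is rank-based this bias is a
  distribution-free function of `n`; it is estimated once per `n` by Monte
  Carlo over random rank pairings (200 draws, an internal fixed seed,
  memoised) and subtracted.
* **Smoothing deconvolution.** Kernel smoothing shrinks a bivariate
  Gaussian's correlation by `1 + h^2`. The centred plug-in value is mapped
  through the Gaussian relation `MI = -log(1 - rho^2)/2`, the shrinkage is
  inverted, and the value is mapped back. For Gaussian dependence of any
  strength the estimate is therefore asymptotically unbiased; for strongly
  non-Gaussian dependence the deconvolution is an approximation (the
  estimate remains a monotone function of the plug-in MI, so thresholding
  and ranking are unaffected).

At `n = 2000` the median estimate is within about 3% of
`-log(1 - rho^2)/2` for correlations 0.3–0.9; at `n = 100` (a typical
subset size) strong dependences are attenuated by 15–20%, which is
immaterial for edge detection because the permutation threshold is
estimated on the same scale. Constant vectors yield MI 0 with a warning.

The estimator sits behind `estimate_mi()` / `calibrate_mi_threshold()`, so a
different estimator (for instance k-nearest-neighbour MI) can be swapped in
without touching the rest of the pipeline.

## Threshold calibration

`calibrate_mi_threshold` draws `n_null` random gene pairs from the dataset,
permutes the sample order of one member of each pair, and returns the
empirical `1 - pvalue` quantile of the resulting null MI values. The
default `n_null = 1e5` keeps roughly 100 draws above the default
`p = 0.001` quantile; `n_null * pvalue < 5` is rejected as unstable.

## DPI pruning

For every fully connected triple, the weakest edge is marked when its MI is
at most `(1 - tolerance)` times the smaller of the other two, and all marked
edges are deleted afterwards (mark-then-delete, evaluated on the original
weights). At the default tolerance 0 this removes the weakest edge of every
triangle, which in a Markov chain X→Y→Z removes exactly the indirect X–Z
edge (the data processing inequality guarantees
`MI(X,Z) <= min(MI(X,Y), MI(Y,Z))` in population). Exact three-way ties
remove the edge with the lexicographically smallest endpoint pair, making
pruning deterministic.

# Network TOM

For one TF present in two networks with neighbor sets `N1`, `N2`, the
overlap is `|N1 ∩ N2| / min(|N1|, |N2|)` (0 when either set is empty). The
original per-TF formula is displayed only as an image in the source
material; this set-overlap generalisation — in the spirit of the
generalised topological overlap measure — is the simplest formula consistent
with the stated ingredients (neighbor counts and common-neighbor count).
One documented consequence: a neighborhood fully contained in the other
scores 1 regardless of the size difference. The formula sits behind
`tf_tom()` so variants can be substituted.

Network TOM is the sum of per-TF overlaps across common TFs; the pairwise
matrix is normalised by its largest off-diagonal entry, so the most similar
network pair has similarity exactly 1. Clustering is agglomerative with
average linkage on `1 - similarity` (the linkage and distance transform are
unstated in the source; average linkage is the standard choice for
similarity-derived distances and is robust to outlier networks). Branch
stability reuses the raw pairwise TOM values, renormalising within each
surviving collection; leave-2-out is capped at 500 sampled pairs by
default. Branch recurrence is exact leaf-set clade matching; single leaves
count as (trivial) clades; a branch whose members were all removed is
not-applicable (NA) rather than 0.

# The dysregulation test

For a pair of networks, candidate relationships are the union of each
common TF's neighborhoods across the two networks. Both MI values of a
candidate are recomputed from the raw expression of each condition —
whether or not the edge survived thresholding/DPI in that network — because
a difference against a structurally forced zero would conflate pruning with
biology (`absent_edge_mi = recompute` semantics). `delta_mi` is
`MI_cancer - MI_inflammation`.

The null distribution is built by **condition-label permutation**: in each
of `n_perm` rounds (default 100) the pooled samples are randomly
reassigned to two pseudo-conditions of the original sizes and every
candidate's MI difference is recomputed; all rounds are pooled into one
empirical null, as the source procedure pools its "random distribution".
Label permutation is the standard differential-coexpression null: it
preserves the pooled data's gene–gene dependence while destroying any
condition difference, so the null carries the MI estimator's sampling
variance at the observed dependence strengths and the empirical p-values
are calibrated under a global null. The alternative reading — permuting
each gene's values independently within each dataset
(`method = "per-gene"`) — is retained for comparison; it destroys all
dependence, produces a null of near-zero MI differences with almost no
spread, and declares essentially every strong relationship significant, so
it is not the default. Since MI values are recomputed from (permuted) data
for every candidate, re-inferring networks on the permuted data would not
change any null delta and is skipped.

Empirical p-values are two-sided with the add-one convention,
`p = (1 + #{|null| >= |observed|}) / (1 + N)`; FDR is Benjamini–Hochberg
(the source does not state its FDR procedure); the default cutoff is
q < 0.05. Relationships significant in *every* supplied network pair are
intersected and the largest connected component is the dysregulated
network. Node bookkeeping reports both counting conventions (per-role
counts where dual-annotated genes increment both categories, and exclusive
counts).

# Core TFs

Per TF in the dysregulated network: degree `k`, adjacent inflammation and
cancer gene counts (a dual-annotated neighbor increments both), and the
composition ratios `r_I = n_I / k`, `r_C = n_C / k`. A TF is **core** when
`k >= 8` and both ratios are at least 0.1 (both thresholds are arguments,
not constants). Categories operationalise "mostly adjacent": cancerogenic
if `r_C > 0.5` and `r_I < 0.1`; inflammatory symmetrically; IC-specific if
both ratios reach 0.1; other otherwise. TF–TF edges count toward `k` but
toward neither ratio unless the neighbor TF is itself IC-annotated.

# The synthetic-data generator

`generate_model` / `simulate_dataset` plant a linear-Gaussian study:

* TFs are i.i.d. standard normal per sample; each planted edge contributes
  `beta * regulator`; targets add `Normal(0, noise_sd)` noise. The defaults
  `beta = 0.9`, `noise_sd = 0.3` give planted edges a population
  correlation `beta / sqrt(beta^2 + noise_sd^2) ≈ 0.95` (MI ≈ 0.83 nats) —
  strong, clean regulation appropriate for validating the machinery.
* A `frac_shared_edges` backbone is regulated identically in every
  condition; remaining targets get condition-private regulators (what makes
  phenotype groups of networks separable); 30% of backbone/private targets
  get a second regulator so inferred networks have a giant connected
  component rather than a forest of TF stars.
* A `frac_dysregulated` fraction of targets flips its coupling between
  `beta` and 0 between the inflammation and cancer conditions (half gains,
  half losses). These edges are concentrated on a few **bridge TFs**
  (~10 targets each, balanced across the inflammation and cancer gene
  sets) and consecutive bridge TFs are chained by dysregulated TF–TF
  edges, so the dysregulated network is connected and the degree-based
  core rule has something to recover — the generator's analogue of a few
  core TFs mediating many dysregulated links.
* Marginal means and variances are identical across conditions by
  construction (every gene is standardised against its own nominal scale
  and mapped to mean 8, sd 2 on the log2-like scale). Condition
  differences therefore live purely in the dependence structure, which is
  exactly the regime where differential expression fails and the network
  route is needed.
* `model_population_mi` returns the exact population MI of any gene pair
  per condition from the planted coefficients, including dependence
  transmitted through TF–TF edges. This is the correct oracle for judging
  discoveries: a significant relationship whose population MI genuinely
  differs between conditions is a true detection even if it is not a
  directly planted edge.

What the generator does *not* emulate: probe-level noise, batch effects,
heavy-tailed or discrete expression, feedback loops, time dynamics.
Passing tests therefore demonstrate that the machinery recovers planted
linear-Gaussian structure at realistic sample sizes, not that any
particular biological cohort will behave as well.

# Numerical and design choices

* **K-means stratification**: `stats::kmeans` with 25 restarts, Euclidean
  distance on the IC-gene log2 values, seeded; k = 4 above 100 samples,
  else k = 2; subsets under 20 samples dropped. No per-gene standardisation
  by default (a `standardize` flag z-scores first). Subset ids are
  size-suffixed (`GSE907_22` style).
* **Candidate edges** are TF–anything (including TF–TF, deduplicated with
  the lexicographically smaller TF first); gene–gene pairs are never
  tested.
* **Units**: nats throughout; only differences and ranks matter downstream.
* **Determinism**: every stochastic entry point takes a seed; dataset seeds
  in `simulate_study` derive from a hash of the dataset id so designs are
  order-invariant; `infer_network` sorts genes internally so results are
  invariant to input row order.
* **Degenerate inputs**: constant genes yield MI 0 (with a warning from
  `estimate_mi`; silently in batch paths); empty IC components and empty
  intersections are errors carrying diagnostic counts.
* **Problem sizes** used by the test-suite and the acceptance script (30
  TFs, 200–350 targets, 60–100 samples per subset, 10–100 permutations,
  10–50 repetitions) were chosen as the smallest sizes at which the
  planted-recovery properties are stable; the statistical conclusions do
  not depend on them.

# Known limitations

* The MI estimator's deconvolution step is exact only for Gaussian
  dependence; strongly non-monotone dependence will be attenuated (though
  still detected while above the calibrated threshold).
* The per-TF TOM formula is a declared stand-in for a formula that the
  source displays only as an image; collections scored with a different
  overlap variant will cluster slightly differently.
* The pooled permutation null follows the source design; per-relationship
  nulls would be more powerful for relationships with atypical variance but
  are not what the procedure specifies.
* Real-cohort edge lists will differ from any historical ARACNe build; the
  package's claims are about the procedure, validated on planted ground
  truth, not about reproducing a specific published edge list.
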