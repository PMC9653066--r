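---
title: "Methods: paired-design microbiome networks, niche metrics and assembly tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-design microbiome networks, niche metrics and assembly tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`netniche` implements the complete post-OTU statistical workflow for a
paired two-group soil microbiome survey: rarefaction and alpha diversity,
gated univariate comparisons, PERMANOVA, a random-forest differential-taxon
screen, Pearson co-occurrence networks with spectral robustness analysis,
Levins/Pianka niche metrics with a permutation generalist test, a
dispersal–niche continuum (DNCI) permutation test, and a Bayesian path
model linking treatment to network change through niche metrics. Because
raw sequence data for such surveys are often not deposited, a synthetic
community generator with known ground truth is a first-class part of the
package: every statistical claim the test suite makes is made against
planted structure or against closed forms.

This vignette records the models, the tunable parameters, the numerical
choices, and what the simulations do and do not establish.

# The synthetic paired community

`generate_paired_counts()` builds log-abundances as

```
log lambda_ts = mu_t + b_{t,p(s)} + (block terms) + (differential shift) + eps_ts
```

with `mu_t ~ N(0, abundance_shape^2)` a heavy-tailed baseline (default
sigma 2, mirroring the dominance structure of real OTU tables),
`b_{t,p} ~ N(0, pair_sd^2)` a pair-level random intercept shared by the
two samples of a pair (the paired-design signal; default 0.5),
`eps ~ N(0, noise_sd^2)` idiosyncratic noise (default 0.2), a shift of
`lfc * log 2` for planted differential taxa in their target group, and a
latent Gaussian factor (scale `factor_sd * loading`, default factor scale
1) shared by the members of each planted correlation block.
Log-abundances are closed to compositions and sampled as one multinomial
draw per sample at Poisson library sizes (`depth_mean`, default 10^4,
matching rarefaction depths around 10,000 sequences).

Two design points deserve emphasis:

* **Block members share their pair-level response.** The Pearson
  correlation of two jointly lognormal variables on the raw (proportion)
  scale is approximately `exp(-(idiosyncratic log-variance))`, *whatever*
  the shared variance. If block members carried independent pair
  intercepts, their raw-scale correlation would be capped near 0.7 and a
  loading-1 block could never clear the conventional `r > 0.8` edge
  threshold. A block is therefore modelled as a coherent module: its
  members share the pair response (scaled by the loading) as well as the
  latent factor.
* **Negative planted edges are not recoverable at `|r| > 0.8`.** The
  raw-scale correlation of lognormals is bounded below by roughly -0.4;
  anti-correlated blocks are supported by the generator (sign -1) but no
  analysis should expect to detect them with a 0.8 threshold. This is a
  property of Pearson-on-proportions, not of the generator.

Blocks may carry a `group` field, in which case the latent factor acts
only on that group's samples and the block's edges exist in one network
only — the mechanism by which the workflow's worked example gives the two
treatment networks different structure. The shared pair intercept then
still leaks a log-scale correlation of about
`pair_sd^2 / (pair_sd^2 + noise_sd^2)` into the other group, so
communities with group-specific blocks should use `pair_sd <= 0.3` to
keep that leak below the edge threshold.

The default design (3 pairs, 2 groups, 10^3 taxa) mirrors the field
survey the package emulates; analyses that need correlation power (any
network stage) use 15 pairs, because 3 samples per group cannot support
Pearson p-values at all (the package refuses fewer than 4 samples).

# Diversity

`rarefy()` subsamples without replacement to a fixed depth and drops
shallower samples. `alpha_diversity()` computes observed richness,
**classic** Chao1 `S + F1^2/(2 F2)` (bias-corrected fallback
`S + F1(F1-1)/2` only when `F2 = 0` — the classic form is what the
hand-checkable `[5,1,1,2] -> 6` example demands; note vegan's
`estimateR()` always uses the bias-corrected variant), ACE with the
conventional rare-abundance cutoff of 10, Shannon entropy in nats (so
Pielou's `J = H / log S` is consistent), inverse Simpson, Fisher's alpha
as the root of `alpha log(1 + N/alpha) = S` (no finite solution when
every individual is its own taxon), Good's coverage `1 - F1/N`, and
Faith's PD. Faith's PD is computed by hand as the total branch length of
the union of root-to-leaf paths over observed taxa — the rooted
convention, including the path to the root — because `picante::pd()`
declines polytomous rooted trees such as stars; picante is retained as a
cross-check oracle on binary trees in the test suite.

# Group inference

`auto_group_test()` encodes the conventional gate: Shapiro–Wilk per group
and Levene (mean-centred) across groups, both at alpha = 0.05; all gates
pass -> Student's t / ANOVA, otherwise Wilcoxon rank-sum /
Kruskal–Wallis. Groups of fewer than three values cannot be
normality-tested and fall through to the rank branch. One consequence of
the paired design worth knowing: the pair intercept induces positive
dependence between the two groups, which makes *unpaired* tests
conservative — the generator's calibration test therefore switches the
pairing off (`pair_sd = 0`) to isolate sampling noise.

`permanova()` implements Anderson's pseudo-F from among/within sums of
squared distances with free label permutation,
`p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, and exhaustive enumeration
of all label arrangements for two groups whenever that is cheaper than
sampling (20 arrangements for the 3-vs-3 design — which is why the field
design's PERMANOVA p-values are multiples of 0.05). A pair-restricted
permutation scheme (within-pair label swaps) is exposed as an option.
`vegan::adonis2()` agrees with the pseudo-F and R² to 1e-10 and serves as
the independent oracle in tests, never as the implementation.

The random-forest screen ranks taxa by mean decrease in Gini impurity
(stratified bootstrap, 10^4 trees by default — Gini ranks at n = 30 are
noisy under small forests) and attaches per-taxon Kruskal–Wallis
p-values; the discriminating set is read off at `kw_p < 0.05`. A
compositional caveat surfaced during verification: a planted fold-change
on an *abundant* taxon redistributes so much relative abundance that
other taxa acquire real mirrored signal; the planted-recovery study
therefore uses 100 taxa so the planted taxon's share stays modest.

# Networks

`filter_otus()` applies the two standard inclusion rules (present in at
least 2 samples; total relative abundance at least 0.1%, read as the
taxon's share of the grand total, with a mean-per-sample option).
`build_network()` computes Pearson correlations of relative abundances,
two-sided p-values via the t transform, Benjamini–Hochberg adjustment
over all pairs, and keeps edges with `|r| > 0.8` and adjusted
`p < 0.001`. The absolute-value criterion (rather than signed `r > 0.8`)
is deliberate: co-occurrence figures in this literature show negative
links. Pearson on proportions is compositionally biased; the workflow
reproduces the field-standard construction and the simulations quantify
the consequences (coincidental-leverage false edges appear at very heavy
tails, which is why the planted-recovery study runs at
`abundance_shape = 1`).

Properties: clusters are connected components; modularity is Newman's Q
of the greedy agglomerative partition; degree centralization is
Freeman's `sum(dmax - d_i) / ((N-1)(N-2))`; "central eigen" is the
maximum entry of the unit-normalized principal adjacency eigenvector;
vulnerability is the largest relative drop in global efficiency (mean
inverse shortest-path length over ordered pairs, 0 for disconnected
pairs) over single-node deletions; natural connectivity is
`ln((1/N) sum exp(lambda_i))` over adjacency eigenvalues, computed with
the largest eigenvalue factored out for stability and verified against a
brute-force eigendecomposition to 1e-9.

Stability and robustness follow the removal protocol: uniformly random
deletion of a fraction of nodes (or edges), average degree and natural
connectivity on the remainder, replicate distributions for KS and
Kruskal–Wallis comparisons (the study's headline comparison removes 50%
of nodes), and decline curves over a removal grid with an OLS slope
attached. Bootstrap node-attribute distributions resample the intact
graph's per-node attribute vectors (degree, harmonic closeness, local
clustering, eigenvector centrality) with replacement — attributes are
*not* recomputed per resample, which is what makes 10^5 draws feasible;
tests scale the default to 10^4.

High/low-degree classes use quantiles of the positive degrees (defaults
0.75/0.25) since the field literature reports the classes without
defining cutoffs; the partition records cross-network shared/specific
sets, per-shared-node degree pairs, high-to-low / low-to-high
transitions, and class abundance totals. `delta_degree()` is the absolute
degree difference of shared nodes (a signed option exists).

# Niche metrics and assembly

Resource states are individual samples. Levins breadth is
`B = 1 / sum_j P_ij^2` (unstandardized by default, with `B_A` as an
option); Pianka overlap is the cosine of two taxa's usage profiles. The
generalist/specialist test compares observed breadth with its
distribution over random tables drawn with both margins fixed
(Patefield's algorithm, `r2dtable`; the exchangeable construction makes
the type-I calibration testable exactly). Count-level swap algorithms
were rejected because they fail on dense tables without checkerboard
submatrices. On strongly overdispersed tables — including the synthetic
communities — most taxa are patchier than the fixed-margins null and are
classified specialists; that is a property of the null, not a bug, and
matches the small generalist percentages such surveys report.

The DNCI reconstruction binarizes the table, drops species present
everywhere or nowhere, and compares the observed ranked SIMPER profile
(per-taxon contributions to between-group dissimilarity, sorted,
normalized) with profiles of permuted matrices under three nulls:
row-wise shuffles preserving species occurrence totals
("dispersal-controlled"), column-wise shuffles preserving sample richness
("niche-controlled"), and curveball permutations preserving both. The
goodness-of-fit statistic is
`E = sum_ranks (log10 obs - log10 perm)^2` over common positive ranks;
the selected regime is the single-constraint null with the lower mean E,
with the both-margins E reported alongside. This is a reconstruction of
the published dispersal–niche continuum index restricted to regime
selection; the effect-size and confidence-interval machinery of the full
method is out of scope.

The assembly scenarios encode the two regimes the test must separate:
niche mode gives every species the same occupancy (60% of sites) but
heterogeneous group specificity — the signal is *where* a species occurs;
dispersal mode gives heterogeneous Beta prevalence independent of group —
the signal is *how many* sites it occupies. Prototyping showed this
asymmetry is essential: with homogeneous preferences the ranked-profile E
statistic cannot separate the regimes, because the occupancy-fixed null
reproduces any occupancy-driven profile shape. Note the neutral paired
generator is itself prevalence-driven, so applying the DNCI to it
correctly selects the dispersal regime; the niche-restriction finding of
field surveys is reproduced by the niche scenario, not by the neutral
community.

SIMPER uses the mean over between-group sample pairs of
`|x_i - y_i| / sum_t (x_t + y_t)` on relative abundances. Two boundary
conventions: when total between-group dissimilarity is zero the
normalized profile is uniform; and because proportions are closed, a
taxon with identical *counts* across groups generally still contributes
(closure moves its proportions) — contribution-free taxa are those with
identical relative abundances.

# The path model

`fit_path_model()` estimates `M = a0 + a T + e1`,
`Y = b0 + b M + c T + e2` by conjugate Gibbs sampling
(Normal(0, 10^2) coefficient priors, Inverse-Gamma(0.001, 0.001)
variances; 4 chains x 5,000 iterations with 1,000 burn-in by default).
Variables are standardized by default so the coefficients are comparable
path estimates; the coverage simulations run unstandardized so the
planted coefficients are on the model scale. A pathway is accepted iff
its central 95% credible interval excludes zero; the indirect effect is
the posterior of `a*b`. Convergence is monitored with split R-hat and a
run above 1.1 is flagged with a warning. Observations are per-taxon
records (group, niche metric, degree), two per shared taxon — the
observational unit is a modelling choice the field reports ambiguously,
and it is documented here rather than hidden.

# Pipeline and reproducibility

`run_pipeline()` sequences the stages (filter, rarefy, diversity + gated
tests, PERMANOVA on Bray–Curtis and Jaccard, Venn, RF screen, function
comparisons, per-group networks with the full property/stability suite,
niche metrics, DNCI on the unfiltered table — the occurrence nulls need
the absences — regressions, path models), writes machine-readable
TSV/JSON plus a run log, and aborts on a stage failure with the stage
name and a `FAILED` marker. A single master seed deterministically spawns
per-stage substreams; two runs with the same configuration are
byte-identical, which the test suite checks by hashing every output file.

# Problem sizes and what the tests show

The simulation studies run at desk scale, chosen once: calibration
batteries use 500 null replicates per test family; edge recovery uses 50
replicates of a 53-taxon / 30-sample community with four loading-1
blocks; the RF screen uses 100 replicates at 100 taxa; DNCI direction
uses 20 scenarios per regime; path coverage uses 100 datasets of n = 200
with 2 chains x 1,500 iterations. Passing these establishes internal
correctness (closed forms, calibration, recovery of planted structure
under the generator's assumptions). It does not establish that Pearson
networks on real compositional data recover true ecological
interactions, that the DNCI reading transfers to communities whose
assembly mixes regimes, or that the path model's per-taxon observational
unit matches any particular field study's choice — those are scientific
caveats that survive any amount of green testing.

# Known limitations

* Pearson-on-proportions inherits compositional bias; SparCC-style
  compositional correlation is deliberately out of scope.
* Negative edges are theoretically unreachable at `|r| > 0.8` for
  lognormal abundances (see above).
* The DNCI implementation selects a regime by mean-E comparison only and
  is labelled a reconstruction of the cited method.
* Exhaustive PERMANOVA enumeration covers the two-group case;
  multi-group designs always use sampled permutations.
* The fixed-margins generalist null treats counts as freely
  redistributable individuals; overdispersed tables are mostly classified
  non-neutral.
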