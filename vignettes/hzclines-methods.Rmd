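---
title: "Models and methods in hzclines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hzclines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hzclines estimates how admixed genomes are put together in hybrid zones:
per-individual **hybrid indexes**, per-individual **ancestry-class
proportions**, and per-locus **hierarchical logit-logistic genomic clines**.
This vignette documents the models, the priors and tunable parameters, the
numerical choices, what the synthetic-data generators emulate, and the known
limitations. It is the package's methodological reference; all empirical
statements about recovery performance are the ones computed by the test
suite and by `scripts/acceptance.R`.

## The three models

All three models are supervised: two source (reference) populations are
designated a priori, with per-locus allele frequencies $p_{0i}$, $p_{1i}$
for the counted allele. Loci may be diploid or haploid per cell ($N_{ij}
\in \{1, 2\}$), which accommodates sex chromosomes (e.g., Z-linked loci in
female Lepidoptera are haploid).

**Hybrid index.** $H_j$ is the proportion of individual $j$'s genome
inherited from source 1. Each allele copy derives from source 1 with
probability $H_j$, so the probability that a sampled copy is the counted
allele is $H_j p_{1i} + (1 - H_j) p_{0i}$ and the allele count $G_{ij}$ is
binomial in it. The prior is Jeffreys' $\mathrm{Beta}(0.5, 0.5)$.
Individuals are conditionally independent given the frequencies and are
sampled jointly in one vectorized model. A locus with $p_{0i} = p_{1i}$
contributes a constant: it carries no ancestry information.

**Ancestry classes.** $(Q_{00}, Q_{10}, Q_{11})$ are the proportions of the
genome where both gene copies come from source 0, one from each source, or
both from source 1; $Q_{10}$ is the interpopulation-ancestry proportion and
$H = Q_{11} + Q_{10}/2$. Genotype probabilities at diploid loci mix
Hardy-Weinberg expectations within the homozygous-ancestry classes (with
the factor 2 on heterozygotes, so probabilities sum to one over genotypes)
and cross-source draws in the interpopulation class. Haploid loci inform
only $q_1 = Q_{11} + Q_{10}/2$; with exclusively haploid data the split of
ancestry into classes is weakly identified and the package warns. The prior
is uniform on the simplex, $\mathrm{Dirichlet}(1, 1, 1)$ — chosen for
neutrality and for exact Dirichlet conjugacy in the diagnostic-marker
limit, which the tests exploit. The practical consequence of this prior is
visible in the weakest-information regimes (allele-frequency difference
0.1): the $Q_{10}$ posterior is honest but wide, and its median shrinks
toward the prior's marginal median of about 0.29.

**Genomic clines.** The probability that a gene copy at locus $i$ in
individual $j$ derives from source 1 follows the logit-logistic cline
$$\operatorname{logit} \phi_{ij} = v_i\,(\operatorname{logit} H_j -
\operatorname{logit} c_i),$$
equivalently $\phi = H^v / (H^v + (1-H)^v e^u)$ with $u = v\,
\operatorname{logit} c$. The slope $v_i > 0$ measures steepness relative to
the genome-wide admixture gradient ($v = 1$ is the null); the center
$c_i \in (0,1)$ is the hybrid index at which $\phi = 0.5$ ($c < 0.5$ means
an excess of source-1 ancestry). The data likelihood replaces $H_j$ with
$\phi_{ij}$ in the hybrid-index kernel; with $v_i = 1$, $c_i = 0.5$
everywhere the two likelihoods coincide exactly (a unit test asserts
this identity).

Clines are modeled hierarchically:
$\log_{10} v_i \sim \mathrm{N}(\mu_v, \sigma_v)$,
$\operatorname{logit} c_i \sim \mathrm{N}(\mu_c, \sigma_c)$. The standard
deviations $\sigma_v, \sigma_c$ quantify genome-wide variability in
introgression (related to the coupling of barrier loci) and are the
quantities of main interest in many analyses. Hyperpriors are half-Normal
$(0, \sigma_0)$ with $\sigma_0 = 2$ by default: the positive-truncated
reading of a normal prior on a standard deviation. Means are fixed at 0
(soft centering) in the standard model; `mode = "free_means"` estimates
$\mu_v, \mu_c$ with $\mathrm{N}(0, \mu_0)$ priors ($\mu_0 = 2$), which is
the right tool when clines for one locus set (say, the Z chromosome) are
referenced against hybrid indexes estimated from another (autosomes).
`mode = "fixed_sd"` fixes $\sigma_v, \sigma_c$, making loci independent:
this enables batch-parallel fitting of genome-scale data
(`est_gencline_batched()` implements the subset-then-batches workflow) and,
with SDs set large (e.g., 100), a non-hierarchical variant.

**Data modes.** All three models accept known genotypes, genotype
likelihoods, or local ancestry. Genotype likelihoods (from `read_vcf()`
GL/PL fields or `sim_reads()`) replace each cell's likelihood by the
average over genotype states weighted by the normalized likelihood vector;
an equal-entry vector is exactly a missing genotype, the same semantics as
a masked cell. Local-ancestry data $Z_{ij}$ drop the frequencies entirely:
the kernel is $\phi^{Z}(1-\phi)^{N-Z}$, mathematically the diagnostic-
marker limit.

**Modularity.** Parental frequencies enter as point estimates (posterior
medians from `est_p()`, clamped; see below) and hybrid indexes enter cline
fits as posterior medians. Uncertainty in neither is propagated downstream.
This is a deliberate trade-off: it decouples the three fits, admits
external frequency or admixture estimates, and makes genome-scale
parallelization trivial, at the cost of understating total uncertainty
when the upstream estimates are poor.

## Posterior computation

Sampling uses the package's own No-U-Turn Hamiltonian Monte Carlo sampler
(compiled, with analytic gradients for every model): the doubling-tree
variant with slice acceptance, dual-averaging step-size adaptation
(target acceptance 0.8) and windowed diagonal metric estimation during
warmup. Defaults are four chains of 2000 iterations with 1000 warmup and
no thinning. Parameters are sampled on unconstrained scales — logit for
probabilities, multinomial-logit for simplexes, log for standard
deviations — with Jacobians included. The hierarchical cline model uses a
**non-centered parameterization** (locus effects as standard-normal
deviates scaled by $\sigma$), which avoids the funnel pathologies that
degrade centered samplers when locus-level information is weak. Known-
genotype data for the hybrid-index and ancestry-class models are collapsed
to per-individual sufficient statistics over loci that share parental
frequencies, which makes those fits essentially free at any locus count.

Summaries are posterior medians with equal-tail credible intervals
(default 90%), linear-interpolation quantiles. Convergence is monitored
with split-$\hat R$ and an autocorrelation-based effective sample size
(Geyer initial monotone sequence); warnings fire at $\hat R > 1.05$ or
ESS < 100, thresholds chosen to match common practice. Divergent
transitions are counted per chain and a warning is emitted beyond 10%.
Initialization draws unconstrained values uniformly on $(-2, 2)$, retrying
up to 100 times for a finite density. Fits are exactly reproducible given
a `sampler_config()` seed.

Numerical guards: frequencies are clamped to $[0.001, 0.999]$ wherever
they enter a likelihood (diagnostic loci would otherwise produce infinite
log probabilities); cell probabilities are clamped to $[10^{-12},
1-10^{-12}]$ before logs; $\log_{10} v$ is capped at $\pm 100$ where the
likelihood is flat anyway; hybrid indexes of exactly 0 or 1 supplied to
cline fits are nudged to 0.001/0.999 with a warning (the likelihood is
otherwise degenerate there).

**Hard sum-to-zero centering.** The zero-mean hierarchical priors give
soft centering only. `sum2zero()` applies the hard constraint after
fitting: in full mode the across-locus means of $\log_{10} v$ and
$\operatorname{logit} c$ are subtracted within every posterior iteration
and the posterior re-summarized (per-iteration means are then exactly
zero, and the operation is idempotent); in point mode only the point
estimates and interval bounds are shifted by the mean of the point
estimates, which is what batch-parallel workflows can afford. Centering is
recommended when the cline loci are the same as (or a random subset of)
the loci behind the hybrid indexes, since clines are by definition
deviations from average introgression.

## Synthetic data

Three generators make every recovery claim testable offline.

`sim_generative_clines()` draws cline parameters and hybrid indexes from
the model itself ($\log_{10} v \sim N(0, \sigma_v)$, $\operatorname{logit}
c \sim N(0, \sigma_c)$, $H \sim U(0,1)$), samples diploid ancestry
$Z \sim \mathrm{Bin}(2, \phi)$, then genotypes given per-locus allele
frequencies. Allele-frequency differences are $U(\text{afd}_{\min}, 1)$
and placed symmetrically about 0.5 — the generative description does not
fix the placement, and the symmetric choice makes "difference" the only
knob. Defaults (100 loci, 50 hybrids) are the study conditions for the
variability designs; the three variability levels are $(\sigma_v,
\sigma_c) = (0.2, 0.5), (0.4, 0.8), (0.6, 1.2)$ and the AFD design uses
$(0.3, 0.7)$.

`sim_reads()` emulates low-coverage sequencing: Poisson read depth
($\lambda = 7$), each read reporting the counted allele with probability
$(G/N)(1-\varepsilon) + (1-G/N)\varepsilon$ at $\varepsilon = 0.01$, and
genotype likelihoods computed from the realized counts under the same
error model. Zero-depth cells are missing.

`sim_zone()` is a dfuse-style individual-based secondary-contact
simulation: diploid hermaphrodites, ancestry-0/1 haplotypes tracked at an
even marker grid, Poisson($\ell$) crossovers at uniform positions without
interference, underdominant viability $w = (1-s)^{n}$ over
ancestry-heterozygous selected loci, random mating of distinct parents
within demes (no selfing), fixed carrying capacity. Migration moves
*individuals*: each census slot is independently replaced with probability
$m$ per neighboring population (pure parental pools beyond the edges; in
the single-deme design, both parental populations feed the deme at rate
$m$ each), and the census is taken after migration, so recent immigrants —
and therefore F1 offspring and fresh backcrosses — appear among sampled
individuals. This reading was chosen because it is the only one of the
defensible migration placements that produces the expected census
structure of a migration-fed hybrid swarm (hybrid indexes spanning (0, 1)
with mass near both edges); gamete-level migration leaves almost no
unadmixed individuals after 200 generations. The generation cycle order is
fixed and documented: migration, then mating with offspring viability
selection, then regulation to capacity. Presets used by
`run_experiment()`: a single deme (capacity 500, $m = 0.1$, 200
generations, 510 markers on ten 1-Morgan chromosomes) and a 15-deme
stepping stone (capacity 100, $m = 0.05$, 5000 generations, 251 markers on
one 1-Morgan chromosome) with neutral, oligogenic ($s = 0.3$ at 25 and
75 cM), and polygenic (50 evenly spaced loci at midpoint positions,
$s = 0.005$ or $0.01$) architectures.

What the generators do **not** emulate: linkage maps with interference or
hotspots, overlapping generations, sex-specific recombination or
migration, genotyping artifacts beyond a uniform per-read error,
ascertainment of markers, and selection other than single-locus
underdominance. Passing recovery tests therefore demonstrates correctness
of the inference machinery under the stated generative assumptions, not
robustness to everything real data can do.

## Evaluation designs and problem sizes

`run_experiment()` packages four designs; the suite and the acceptance
script run them at desk scale, chosen so a full check completes on one CPU
in well under an hour: 3-5 replicates per condition instead of 50, with
sampler defaults unchanged. Metrics are `mae()`, `ci_coverage()` of 90%
intervals, and `pearson()` correlations between true and estimated
parameters; `perm_test()` provides the generic label-shuffling
randomization test (1000 permutations by default) for enrichment-style
questions, and is deliberately not applied automatically — outlier flags
from `flag_outliers()` are reported raw, per locus.

Two systematic observations from these designs are worth recording. First,
at the high-variability level and under weak allele-frequency differences,
this implementation's posterior-median cline SDs are close to unbiased
(e.g., mean $\hat\sigma_v \approx 0.64$ at truth 0.6), where biased point
estimates in those regimes have previously been reported for this model
family; with identical likelihood, priors and generative conditions, the
non-centered parameterization and the sampler are the plausible source of
the difference. Second, interpopulation-ancestry error at allele-frequency
difference 0.1 is dominated by prior shrinkage of a genuinely diffuse
posterior (coverage stays at the nominal level), so point-estimate error
there is a property of the prior choice more than of the sampler.

## Limitations

Two source populations only; no within-model estimation of parental
frequencies jointly with clines; loci are treated as exchangeable by the
hierarchical prior, which is wrong for tightly linked loci (use unlinked
subsets to estimate the SDs); ploidy beyond diploid is not supported;
geographic clines are out of scope. Hybrid index and frequency uncertainty
are not propagated into cline fits, so cline intervals can be slightly
anticonservative when hybrid indexes are poorly estimated — consistent
with the modest undercoverage (80-90%) the evaluation designs measure.
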