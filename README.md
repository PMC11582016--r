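# hzclines

Hierarchical Bayesian analysis of hybrid zones: hybrid indexes,
ancestry-class proportions, and logit-logistic genomic clines.

When two lineages meet and interbreed, the composition of admixed genomes
carries information about reproductive isolation. `hzclines` quantifies it
at two levels. Per individual, the **hybrid index** $H_j$ (proportion of
the genome from source population 1) and the **ancestry-class proportions**
$(Q_{00}, Q_{10}, Q_{11})$ — with $Q_{10}$ the interpopulation-ancestry
proportion and $H = Q_{11} + Q_{10}/2$ — summarize genome composition.
Per locus, the **logit-logistic genomic cline**

$$\operatorname{logit}\,\phi_{ij} = v_i\,\bigl(\operatorname{logit} H_j - \operatorname{logit} c_i\bigr)$$

gives the probability $\phi_{ij}$ that a gene copy derives from source 1
as a function of the genome-wide admixture gradient: slopes $v_i > 1$
mark loci introgressing more steeply than the genome average, centers
$c_i \ne 0.5$ mark directional excess. Clines are fit hierarchically —
$\log_{10} v_i \sim N(\mu_v, \sigma_v)$, $\operatorname{logit} c_i \sim N(\mu_c, \sigma_c)$ — so the standard deviations $\sigma_v, \sigma_c$
measure genome-wide variability in introgression, a quantity tied to the
coupling of barrier loci.

The package is aimed at population geneticists analyzing SNP data from
hybrid zones. It accepts known genotypes, genotype likelihoods (VCF GL/PL;
low-coverage sequencing), or local-ancestry calls, handles mixed
haploid/diploid loci (sex chromosomes), and samples posteriors with a
built-in No-U-Turn HMC sampler with compiled gradients. Individual-based
hybrid-zone simulators (secondary contact with underdominant selection), a
generative cline simulator, and a read simulator make every method check
reproducible without external data.

## Worked example

Simulate 50 hybrids at 100 loci from the generative cline model (moderate
cline variability, allele-frequency differences at least 0.5), estimate
hybrid indexes, then fit the hierarchical cline model:

```r
library(hzclines)

sim <- sim_generative_clines(n_loci = 100, n_ind = 50, sigma_v = 0.4,
                             sigma_c = 0.8, afd_min = 0.5, seed = 42)

hi <- est_hi(sim$genotypes, sim$freqs, config = sampler_config(seed = 42))
tidy(hi)
#> # A tibble: 50 x 6
#>   individual      H     lo    hi   ess  rhat
#>   <chr>       <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1 ind_1      0.0675 0.0185 0.131 2424. 1.00
#> 2 ind_2      0.529  0.451  0.607 2872. 1.000
#> 3 ind_3      0.685  0.608  0.761 2589. 1.00
#> 4 ind_4      0.490  0.410  0.565 2647. 1.00
#> # i 46 more rows

mae(sim$truth$H, hi_point(hi))
#> [1] 0.052

cl <- est_gencline(sim$genotypes, sim$freqs, hi, mode = "hierarchical",
                   config = sampler_config(seed = 43))
cl
#> <genomic cline fit (hierarchical): 100 loci; sigma_v = 0.384, sigma_c = 0.659>
```

Each row of `tidy(hi)` is an individual's posterior median hybrid index
with its 90% equal-tail credible interval and sampler diagnostics; the
mean absolute error against the simulated truth is 0.05. The cline fit
recovers the genome-wide variability parameters (posterior medians 0.38
and 0.66 against simulated values 0.4 and 0.8 for this single data set —
centers are harder than slopes at these allele-frequency differences).
Loci deviating credibly from genome-average introgression:

```r
flags <- flag_outliers(cl)
table(flags$v_flag)
autoplot(cl)        # cline curves, outliers highlighted
```

`est_Q()` estimates ancestry classes (`autoplot()` draws the triangle
plot), `sum2zero()` applies the hard sum-to-zero recentering to fitted
clines, and `est_gencline_batched()` scales cline fitting to large locus
sets by fixing the hierarchy SDs estimated on a subset. A thin
command-line front end with the same operations ships in
`inst/cli/hzclines`.

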