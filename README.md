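# famscan

Gene-family somatic mutation burden and survival combination analysis.

## The problem

Individual genes of a large, partially redundant family — the motivating
case is the 43 human collagen genes in stomach adenocarcinoma — are often
mutated too rarely for per-gene driver statistics, yet the family as a
group may carry real signal: a mutation in *any* of several members can
have the same consequence for the tumor and the patient. famscan provides
the three analyses such a family needs, plus a synthetic cohort generator
that makes their calibration and power measurable:

1. **Size-aware burden.** Are family genes mutated above background once
   gene length is accounted for? Genes are ranked by mutation events per
   coding base and the family's rank ECDF is compared to the uniform CDF
   with a sup-norm (Kolmogorov-Smirnov-type) statistic,

   D = max_i | i/m − r_(i)/n |,

   where r_(1) < … < r_(m) are the family's rank positions among n genes.
   Significance comes from random gene sets of the same size drawn from
   coding-length-decile-matched bins, with the add-one permutation
   estimator p = (1 + #{D_null ≥ D}) / (B + 1).

2. **Combination survival scan.** Among expressed family genes (mean
   RSEM > 200), every subset of size 2–3 mutated in ≥ 5% of samples is
   tested for mutated-vs-wildtype survival separation by the log-rank
   statistic. Each subset-size stratum gets an empirical null of random
   gene sets matched on total observed mutation count (accumulated to
   within ±5 of the target), scored by the identical procedure; q-values
   are the empirical-null plug-in F0(p_i) = (1 + #{p_bg ≤ p_i}) / (B + 1)
   entered into a Benjamini-Hochberg ratio F0(p_i)·m / rank(p_i) with the
   step-up sweep. Size-3 subsets containing an already-significant pair
   are excluded. Per-gene inclusion frequencies summarize which family
   members drive the signal.

3. **Survival core and association tests.** Kaplan-Meier, two-group
   log-rank, and Newton-Raphson Cox partial-likelihood fitting
   (Efron/Breslow ties) implemented from first principles with
   oracle-tested contracts (score test at β = 0 equals the log-rank
   chi-square; estimates match `survival::coxph` to ~1e-7). Fisher exact /
   chi-square clinicopathological association screens, and Kruskal-Wallis
   comparison of somatic versus germline protein-position distributions
   with exact enumeration at small n.

The synthetic generator emulates a TCGA-style stomach cohort: MSS/MSIH
mutation-burden classes (2 vs 20 mutations/Mb by default),
length-proportional mutation placement, missense/truncation labels,
exponential survival under proportional hazards with planted effect gene
sets, independent censoring, and RSEM-like expression — with the planted
truth returned for recovery testing.

## Worked example

Simulate a 400-sample cohort with a planted protective pair (hazard ratio
0.4 for carriers of a mutation in either gene), then recover it:

```r
library(famscan)

cfg <- sim_config(n_samples = 400, frac_msih = 0.25, n_genes = 500,
                  n_family_genes = 6, gene_length_range = c(3000, 4000),
                  mut_rate_mss = 8, mut_rate_msih = 42,
                  expression_range = c(300, 2000), censoring_rate = 0.004,
                  effect_sets = list(list(genes = c(1, 2),
                                          log_hr = log(0.4))),
                  seed = 7001)
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic cohort: 400 samples (112 MSIH), 500 genes (6 family), 12205 mutations

scan <- combo_scan(cohort$maf, cohort$clinical, cohort$expression,
                   cohort$genes,
                   config = combo_config(n_background = 2000, seed = 1))
scan
#> Combination scan: 26 candidates over 6 eligible genes, 400 samples
#>   3 combination(s) significant at q <= 0.05
#>        genes n_mutated prevalence    logrank_p direction     q_value
#>  G0262,G0293        42     0.1050 4.951501e-06 longer_OS 0.007496252
#>  G0262,G0486        34     0.0850 8.563159e-03 longer_OS 0.034982509
#>  G0262,G0490        43     0.1075 9.798837e-03 longer_OS 0.034982509
```

The top combination, `G0262,G0293`, *is* the planted pair
(`cohort$truth$effect_sets[[1]]$genes`): mutated in 10.5% of samples,
log-rank p = 5.0e-06, associated with longer overall survival at
q = 0.0075. The other two significant pairs each share one planted gene —
their carriers partially overlap the true carriers — which is why the
inclusion-frequency table ranks the planted genes first:

```r
head(scan$inclusion, 3)
#>    gene direction n_combinations
#> 1 G0262 longer_OS              3
#> 2 G0293 longer_OS              1
#> 3 G0486 longer_OS              1
```

A Cox fit on the true carrier indicator recovers the planted hazard ratio
(0.4) with its Wald confidence interval:

```r
carrier <- cohort$truth$samples$hazard_multiplier < 1
cox_fit(data.frame(time = cohort$clinical$os_months,
                   event = cohort$clinical$os_event),
        matrix(as.numeric(carrier), ncol = 1,
               dimnames = list(NULL, "carrier")))
#> Cox proportional hazards fit (n = 400, events = 320, converged)
#>            coef     HR    se lower95 upper95 p
#> carrier -0.8751 0.4168 0.197  0.2833  0.6133 0
```

The methods vignette
(`vignettes/gene-family-mutation-survival.Rmd`) documents the model, every
tunable threshold, the open design choices, and known limitations.

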