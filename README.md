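# mastphylo

Phylogenetic comparative analysis of mast seeding — the synchronous, highly
variable interannual seed production of perennial plants — and its link to
plant functional traits, above all adult plant height.

`mastphylo` is for comparative ecologists who have (a) annual seed- or
fruit-crop records per species and (b) a dated phylogeny, and who want to
ask whether masting intensity co-varies with height, life form, pollination
vector or major seed-plant lineage once shared ancestry is accounted for.

## What it computes

**Masting intensity.** The consecutive disparity index of a seed-crop
series p_1..p_n,

    D = 1/(n-1) * sum_{i=1}^{n-1} | ln((p_{i+1} + k) / (p_i + k)) |,

with pseudo-count k = 1 by default, captures both interannual variability
and lag-1 autocorrelation; D = 0 iff the series is constant.

**Phylogenetic signal.** For continuous traits, Pagel's λ (the multiplier
of the off-diagonal phylogenetic covariance, 0 = no signal, 1 = Brownian
motion) is estimated by maximum likelihood with the mean and rate profiled
out, and tested both by a boundary-corrected likelihood-ratio test and by a
tip-shuffling randomization test. For binary traits, the Fritz–Purvis D
statistic standardizes the observed sum of sister-clade differences between
a prevalence-preserving permutation null (D ≈ 1, random structure) and a
Brownian-threshold null (D ≈ 0, clumped structure), reporting Pr and Pb,
the permutation probabilities of each regime.

**Trait–masting models.** A Gaussian phylogenetic generalized linear mixed
model y = Xβ + u + e with u ~ N(0, σ²_p C) and e ~ N(0, σ²_e I), fitted by
ML with GLS-profiled coefficients and a 1-D search over the phylogenetic
variance proportion; Wald z tests per coefficient; AIC. Pairwise
correlations corrected for phylogeny via independent contrasts (GLS variant
behind a flag), Welch t tests between trait groups, and likelihood-based
partial R² (R²_lik = 1 − exp(−2ΔlnL/n)) partitioning response variance
among each predictor and the phylogeny itself.

**Synthetic data.** Pure-birth trees, λ-structured continuous traits,
threshold-model or shuffled binary traits, AR(1) log-normal seed-crop
series, and full datasets with recorded ground truth, so every stage is
verifiable end to end.

## Worked example

```r
library(mastphylo)

consecutive_disparity(c(0, 10, 0, 10))
#> Consecutive disparity index
#>   D = 2.3979  (n = 4 years, k = 1)

ds    <- simulate_full_dataset(sim_config(n_species = 80, seed = 42))
paths <- write_dataset(ds, "demo")
rep   <- run_all(list(tree = paths[["tree"]], traits = paths[["traits"]],
                      n_sim = 500L, n_perm = 499L, seed = 42L))
print(rep)
```

Output (abridged):

```
Phylogenetic signal (continuous, Pagel's lambda):
  trait    lambda    logLik p_perm        p_lrt n_perm seed
 height 0.8318013 -20.12804  0.002 2.692476e-12    499   43
      D 0.6527439 -83.70250  0.002 6.042696e-11    499   44

Phylogenetic signal (binary, Fritz-Purvis D):
         trait     D_stat          Pr          Pb
     life_form  0.8004892 0.095808383 0.001996008
   pollination -0.1507593 0.001996008 0.738522954
 spermatophyte -0.5330882 0.001996008 0.970059880

Multivariate phylogenetic mixed model:
          term    estimate        se          z            p
   (Intercept) -0.05677279 0.2851318 -0.1991107 8.421761e-01
        height  0.16883813 0.2126843  0.7938440 4.272862e-01
     life_form -0.26559325 0.1374234 -1.9326639 5.327761e-02
   pollination  0.82494590 0.1814583  4.5461998 5.462318e-06
 spermatophyte -0.12951092 0.2240852 -0.5779540 5.632952e-01
  logLik = -73.780  AIC = 161.6  n = 80
```

Reading it: the simulated height trait carries strong phylogenetic signal
(λ = 0.83, randomization p = 0.002, the smallest value 499 permutations can
report); the threshold-simulated binary traits score D well below 1 with Pr
small and Pb large (consistent with Brownian clumping) while the shuffled
life form scores D = 0.80 with Pb = 0.002 (random structure); and the mixed
model recovers the large simulated pollination effect (z = 4.55) at this
sample size while the weaker height effect (true β = 0.288, n = 80) is not
individually significant. The partial-R² table (printed below the model)
ranks pollination and phylogeny as the dominant variance components for
this draw.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/mastphylo simulate --seed 1 --out-dir data/
Rscript inst/scripts/mastphylo run --config analysis.yaml
Rscript inst/scripts/mastphylo disparity --series crops.csv --out d.tsv
```

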