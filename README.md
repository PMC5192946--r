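# coaldemog

Coalescent simulation and approximate Bayesian inference of island
population demography from phased multilocus haplotype data.

`coaldemog` is aimed at phylogeographers analyzing a handful of sequenced
nuclear loci (hundreds of bp each) from multiple populations — the classic
multilocus Sanger design — who want to go beyond descriptive diversity
tables and ask *which demographic history produced these data*. It
implements the full chain:

1. **Summary statistics** per locus and per population: segregating sites
   *S*, haplotype count *h*, nucleotide diversity π (Nei), Watterson's
   θ_W = S/(a_n·L), Tajima's *D*, Fay and Wu's *H* (unnormalized,
   outgroup-polarized), the four-gamete minimum recombination count *R*_M
   (Hudson–Kaplan interval reduction), the largest non-recombining block,
   and between-population *D*_xy.
2. **Coalescent simulation** (infinite sites, no intralocus recombination,
   ms conventions: time in 4N₀ generations, θ = 4Nμ per locus) under five
   demographic models: standard neutral (SNM), exponential growth (EXP),
   instantaneous size reduction (BOT, with severity = θ₀/θ_A), growth
   after reduction (BOT_EXP), and a two-population
   isolation-with-migration model (IM2: θ₁, θ₂, θ_A, t_split, m₁₂, m₂₁).
3. **Rejection ABC**: model choice among the four single-population models
   and parameter estimation with posterior modes and 95% highest posterior
   density (HPD) intervals, posterior predictive checks, and the IM2 fit
   with the population migration rate identity 2NM = 0.5·θ·m and time
   conversions t = Tμ ⇒ T = t/μ.
4. **Neutrality tests**: coalescent simulation p-values for Tajima's *D*
   (two-tailed) and Fay and Wu's *H* (one-tailed low) under the fixed-S
   convention, and the multilocus HKA test (one- and two-species
   variants) with the 1987 moment equations and variance formulas.
5. **Synthetic data**: a generator that emits study-shaped datasets
   (FASTA per locus + population map + truth JSON) with known demographic
   truth, so the entire pipeline is testable end to end.

The coalescent core is written in C++ (Rcpp); everything else is base R.
The ABC fits are returned as classed S3 objects with `print`, `summary`,
`coef` and `plot` methods.

## Worked example

Generate a synthetic three-population study in which `pop01` underwent a
recent severe bottleneck (backwards in time its θ jumps 20-fold at
t_b = 0.05), then compute diversity tables and run ABC model choice:

```r
library(coaldemog)
set.seed(2025)

cfg <- default_island_config(theta_site = 0.004)
cfg$populations <- cfg$populations[c("pop01", "pop02", "pop06")]
cfg$populations$pop01$model    <- "BOT"
cfg$populations$pop01$t_b      <- 0.05
cfg$populations$pop01$severity <- 0.05

st   <- generate_island_study(cfg, "demo_study", seed = 2025)
res  <- run_stats(st$fasta, st$map, "demo_out")
print(res$population, digits = 3)
#>   population  island  n L_total      pi theta_w tajima_d
#> 1      pop01 island1 16    3340 0.06980 0.06235    0.524
#> 2      pop02 island1 16    3340 0.00395 0.00433   -0.375
#> 3      pop06 island5 16    3340 0.00390 0.00433   -0.419

fits <- run_model_choice(st$fasta, st$map, "demo_out",
                         populations = "pop01",
                         n_sims = 4000, tolerance = 0.01, seed = 99)
summary(fits$pop01)
#> model posteriors:
#>     SNM     EXP     BOT BOT_EXP
#>   0.138   0.006   0.700   0.156
#>
#>  BOT parameter posteriors (mode, 95% HPD):
#>            mode     lo      hi
#> theta0   2.2532 0.5292 17.5923
#> t_b      0.1748 0.0678  0.4874
#> severity 0.0702 0.0206  0.5790
```

The per-population table shows the bottleneck signature: `pop01` carries
an order of magnitude more diversity (its deep ancestral coalescences)
and a positive Tajima's *D*, while the constant-size populations sit at
the simulated θ ≈ 0.004 with *D* near zero. The ABC fit ranks the
instantaneous-size-reduction model first (posterior 0.70) and its
severity mode 0.07 is close to the generating value 0.05; the wide theta0
HPD reflects how little an S/π/D/h summary of eight short loci constrains
the present-day size of a recently bottlenecked population.

`run_neutrality()` adds simulation p-values for *D* and *H* and the HKA
test; `run_im()` fits the IM2 model to a population pair and converts the
split time to years given a mutation rate. A thin command-line wrapper
around these functions is installed at `inst/scripts/coaldemog-cli.R`.

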