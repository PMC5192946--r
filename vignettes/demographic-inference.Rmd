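---
title: "Methods: coalescent models, summary statistics and ABC inference in coaldemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent models, summary statistics and ABC inference in coaldemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coaldemog)
```

This vignette is the package's account of its science: the models and
statistics it implements, the conventions and numerical choices behind
them, what the synthetic-data generator does and does not emulate, and the
known limitations of the inference.

## Data model and filtering conventions

The substrate of every statistic is the `site_matrix`: haplotypes by
strictly segregating biallelic sites, with 0 for the reference (major or
ancestral) allele and 1 for the alternate (derived, when polarized). It is
produced from a phased per-locus alignment by `extract_site_matrix()`
under **complete deletion**: any alignment column carrying a gap or `N` in
an ingroup sequence is removed entirely and does not count toward the
analyzed length `L`. This mirrors the default missing-data treatment of
the standard desktop tools that produce per-population diversity tables,
and it makes `L` the correct denominator for all per-site quantities. The
alternative (pairwise deletion) would make per-site statistics depend on
which pair of haplotypes is compared and is deliberately not offered.

Two further rules:

* **Multiallelic ingroup columns** (three or more alleles) are excluded
  from the matrix — the infinite-sites statistics assume biallelic sites —
  but retained in `L` and counted separately (`n_multiallelic`).
* **Unpolarized coding** uses the major allele as 0; an exact 50/50 tie is
  broken by the allele of the first haplotype row, which makes the coding
  deterministic for a fixed input file. All statistics except Fay and Wu's
  *H* are invariant to this choice.

With an outgroup, a column is polarized only when every outgroup sequence
agrees, carries no gap/`N`, and matches one ingroup allele. A column that
fails this stays in the matrix under major-allele coding and is flagged:
it still contributes to *S*, π, θ_W and *D*, but is excluded from *H*,
which needs derived-allele frequencies. Mononucleotide-repeat masking is
treated as upstream data preparation: the reader accepts a BED-like column
mask but implements no repeat detector.

## Summary statistics

Per locus, `locus_summary()` reports *S*, the haplotype count *h*,
π (mean pairwise differences, total and per site), θ_W = S/(a_n·L) with
a_n = Σ_{i<n} 1/i, Tajima's *D* with the 1989 variance constants, Fay and
Wu's *H*, the minimum recombination count *R*_M, and the largest
non-recombining block.

Conventions worth making explicit:

* ***D* is undefined at S = 0** and reported as `NA`, never as 0; pooled
  and ABC summaries substitute 0 *and* carry a separate count of
  monomorphic loci, so the information is not silently lost (dropping such
  loci would bias ABC toward high-θ parameter draws).
* ***H* is unnormalized** (θ_π − θ_H per locus, with
  θ_H = Σ 2·S_i·i²/(n(n−1)) over derived-allele counts i), the convention
  in which per-locus values of order ±1–2 are reported in multilocus
  studies.
* ***R*_M** applies the four-gamete test to all column pairs and reduces
  the incompatible intervals by the Hudson–Kaplan greedy right-endpoint
  scan, which yields the maximum number of pairwise-disjoint incompatible
  intervals. The test suite checks it against an exhaustive dynamic
  program on random matrices.
* **Block boundaries.** The largest non-recombining block is a length in
  bp, but no published convention fixes where a block starts and ends
  between segregating sites. Here a block spanning columns j..k runs from
  the midpoint between columns j−1 and j to the midpoint between k and
  k+1, clamped to the alignment bounds; a locus with no four-gamete
  violation therefore returns its full alignment length. The inclusive
  column-span alternative would systematically shorten blocks by the
  flanking invariant stretches, which contradicts the full-length
  behaviour expected when *R*_M = 0.
* **Pooling "over all loci"** (per-population tables) concatenates
  analyzed sites: pooled π = Σk̄_l / ΣL_l, pooled θ_W = ΣS_l/(a_n·ΣL_l),
  and pooled *D* from the pooled totals. This reproduces the per-site
  definitions exactly and matches common tool behaviour; an unweighted
  mean of per-locus statistics is the documented alternative, and users
  comparing against published per-population tables should check which
  convention those used. When the per-locus sample size varies within a
  population, the population's minimum n supplies the harmonic constants;
  this is exact in the usual case of constant n.

## The coalescent simulator

Time is measured in units of 4N₀ generations and θ = 4Nμ is per locus (ms
conventions), so k lineages in a deme of relative size ρ coalesce at total
rate k(k−1)/ρ and mutations fall as a Poisson process with mean
θ × total branch length. Under the standard neutral model this gives
E[TMRCA] = 0.5 for n = 2 and E[S] = θ·a_n, the identities the acceptance
checks verify by simulation.

The five models:

* **SNM** — constant relative size 1.
* **EXP** — growth toward the present: backwards, ρ(t) = e^(−g·t).
  Waiting times use the closed-form inverse of the cumulative hazard, so
  no time discretization is involved.
* **BOT** — backwards, ρ jumps from 1 to 1/severity at t_b, with
  severity = θ₀/θ_A; severity < 1 is a forward-in-time size reduction.
  The severity is defined relative to θ₀ (not to the size reached at t_b
  under growth), which keeps the parameter interpretable across models.
* **BOT_EXP** — e^(−g·t) until t_b, then the constant ancestral size.
* **IM2** — two demes of sizes θ₁ (the reference: θ₀ = θ₁), θ₂, with
  per-lineage backwards migration rates m₁₂, m₂₁ (scaled as 4N₀M), merging
  into an ancestor of size θ_A at t_split. Exact event-driven (Gillespie)
  simulation; at t_split all lineages transfer to the ancestral deme.

Model identities — EXP(g = 0) ≡ SNM, BOT(severity = 1) ≡ SNM, IM2 with
t_split = 0 ≡ panmixia at θ_A — are tested distributionally.

There is **no intralocus recombination**: the multilocus analyses this
package supports treat loci as non-recombining blocks, with recombination
handled during data preparation (the largest-non-recombining-block
statistic exists precisely to choose those blocks). This is a documented
limitation, not an approximation switch.

Numerical details: mutation positions are uniform in (0,1); the rare exact
ties produced by the RNG's finite resolution are redrawn so the
infinite-sites invariant (strictly increasing positions) holds. All
randomness flows through R's RNG, so a single `set.seed()` makes every
simulation — including the C++ core — bit-for-bit reproducible.

## Rejection ABC

`abc_model_choice()` compares SNM, EXP, BOT and BOT_EXP for one
population; `fit_im2()` fits the two-population IM model. The summary
space is the msABC-style multilocus reduction: means and variances across
loci of S, π (per-locus totals), θ_W (per-locus totals), Tajima's *D* and
*h*, plus the monomorphic-locus count; the IM2 space uses per-deme means
plus the mean and variance of per-locus D_xy. Summaries are standardized
by their median absolute deviation pooled across models (robust to the
heavy-tailed summaries that high-θ draws produce), distances are
Euclidean, and the accepted set is the tolerance fraction of nearest rows
pooled across models. Model posteriors are the per-model shares of that
accepted set — simple rejection, not regression-adjusted. The
local-linear adjustment is a known improvement and a natural extension
hook, but it changes the accepted draws themselves; keeping plain
rejection keeps the model-choice and parameter posteriors mutually
consistent and easy to reason about.

Point estimates are **posterior modes** (Gaussian kernel, Silverman
bandwidth, 512-point grid spanning the sample range; density ties resolve
to the lower value) with **95% HPD intervals** defined as the shortest
window containing ⌈0.95n⌉ sorted draws — checked against a brute-force
window scan. The mode may sit at an HPD edge; the interval is defined by
sample containment, not by bracketing the mode. **Posterior predictive
checks** resample accepted parameter vectors, re-simulate the observed
design, and report each observed summary's quantile in its predictive
distribution.

Defaults: tolerance 0.5% of 10⁵ simulations per model is the recommended
production setting; the test suite and the examples here use 10⁴ (or
fewer) per model with proportionally looser tolerances, sizes at which the
recovery and coverage properties below already hold. Priors are
config-driven; the defaults (θ₀ log-uniform on (0.5, 20) per locus, g
uniform on (0, 50), t_b uniform on (0.05, 0.5), severity log-uniform on
(0.02, 1), IM2 t_split uniform on (0.01, 2), migration uniform on (0, 2))
were chosen once to bracket the parameter scales a few-hundred-bp,
θ/site ≈ 0.002–0.006 multilocus design can actually constrain.

For IM2, the derived population migration rates use the identity
2NM = 0.5·θ·m, and in place of likelihood-ratio tests of nested
zero-migration models (an MCMC machinery this package deliberately does
not reimplement) the fit reports the **posterior mass below a migration
threshold** — a methodological substitution that is stated in the fit's
output, not hidden. Mutation-scaled times t = Tμ convert to years as
T = t/μ and to coalescent units as t/θ_ref.

## Neutrality tests

The simulation p-values for *D* and *H* condition on the observed number
of segregating sites (**fixed-S**): each null replicate draws a
standard-neutral genealogy and places exactly S mutations multinomially by
branch length. This matches the convention of the common tool chain;
conditioning on θ instead (mutation count Poisson, monomorphic replicates
discarded) is available by flag. The fixed-S null ignores the mild
correlation between S and genealogy length, which makes the test very
slightly anticonservative; the acceptance suite verifies the empirical
size at α = 0.05 stays within [0.03, 0.07]. *D* is two-tailed
(2·min(P(≤obs), P(≥obs)), capped at 1); *H* is one-tailed toward low
values, its classic direction. Both use the add-one correction
(1+count)/(n_reps+1), and *H* defaults to 10,000 simulations.

The **HKA test** solves the 1987 moment equations — per-locus totals plus
the polymorphism column sums — for the per-locus θ_i, the divergence time
T (in 2N generations) and, in the two-species variant, the size ratio f.
Substituting θ_i = total_i/(a_A + f·a_B + T + (1+f)/2) reduces the system
to two equations in (T, f); these are solved by a bounded quasi-Newton on
log-parameters (convergence tolerance 1e−10, residual check, second
start), and when sample sizes are equal across loci the solution has a
closed form that the test suite uses as an independent oracle. The
goodness-of-fit statistic uses the 1987 variance formulas including the θ²
terms; degrees of freedom are L−1 (one species: L+1 parameters, 2L cells)
or 2L−2 (two species: L+2 parameters, 3L cells). The two-species variant
is the default: with 8 loci it gives df = 14, the convention under which a
X² of 15.043 corresponds to p ≈ 0.375. Null calibration is checked by
simulating polymorphism from coalescent genealogies and divergence from
the implied Poisson-exponential mixture.

## The synthetic-data generator

`generate_island_study()` emulates the *shape* of a multilocus island
phylogeography study: 8 loci of 339–470 bp, 18 populations on 8 islands
with 14–16 phased haplotypes each, θ/site ≈ 0.004, one outgroup sequence
per locus at 10× the within-species diversity (so polarization is
unambiguous in expectation; a flag allows outgroup mutations to hit
segregating columns and create mispolarization). Site matrices are
threaded onto a random reference with one substitution per segregating
column; derived bases are uniform over the three alternatives —
transition/transversion bias is not modeled because infinite-sites
statistics are blind to base identity.

What it does **not** emulate, and what passing tests therefore do not
show: populations are simulated independently (no shared ancestry or
migration between them except through the explicit IM2 model), there is
no intralocus recombination, no sequencing or phasing error, and no
indels. Tests passing on these data validate the statistical machinery,
not robustness to those real-data features.

`generate_model_panel()` produces balanced labeled datasets for
model-recovery benchmarking, drawing from well-separated regimes (growth
g in (5, 50); bottleneck severity in (0.02, 0.1)) — the regime in which
"recovery" is a meaningful target; near the model-identity boundaries
(g → 0, severity → 1) the models are genuinely indistinguishable and only
honesty (no spurious certainty) is asserted.

## Problem sizes and verification

The test suite verifies, at sizes chosen to keep the default run quick:
coalescent moments at 20,000 replicates (3 standard errors), model
identities at 10,000 replicates (two-sample tests at α = 0.01), *R*_M and
HPD against brute force on hundreds of random instances, estimator
calibration over 200 replicates of the full 18-population design,
neutrality-test size over 2,000 datasets at 1,000 null replicates each,
ABC bottleneck recovery (≥80% of 50 datasets, 10⁴ simulations/model,
tolerance 1%) and HPD coverage (≥85/100 fits; the IM2 coverage runs at a
reduced 4-locus, n = 8+8 scale), and HKA calibration over 1,000 null
replicates. Reference tables are reused across replicate observed
datasets, which is statistically legitimate (the table does not depend on
the observed data) and is what makes these studies cheap.

## Known limitations

* Rejection ABC with modest simulation counts under-covers slightly; the
  coverage targets above (≥85% for nominal 95%) acknowledge this rather
  than hide it. Regression adjustment would tighten posteriors and is
  intentionally out of scope.
* The IM model is pairwise only; a joint fit of more than two populations
  (an MCMC genealogy sampler's job) is not attempted.
* *H* requires outgroup polarization; columns lost to outgroup
  disagreement reduce its information content silently (the count is
  logged on the statistic).
* Pooled per-population *D* uses the concatenation convention; published
  tables computed as per-locus averages will differ, especially with few
  polymorphic loci.
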