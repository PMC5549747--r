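# scalescape

Monte Carlo exploration of nucleobase/amino-acid affinity-scale space.

## The problem

An mRNA coding sequence and the protein it encodes are tied together,
codon by residue, through the genetic code. One way to quantify a
physicochemical echo of that tie is to compare, along each cognate pair,
two windowed sequence profiles:

- the **nucleobase-density profile** of the mRNA — the sliding-window
  fraction of a target base (URA, CYT, ADE, GUA, or the purine class PUR)
  over 63-nucleotide (21-codon) windows of the coding sequence, and
- the **affinity profile** of the protein — the sliding 21-residue mean of
  per-residue weights taken from a 20-element amino-acid scale
  *w* = (w_A, …, w_Y).

Their agreement for one pair is the Pearson correlation R of the two
profiles (both have length L − 20 for an L-residue protein and are in
exact register), and for a whole proteome the fitness is the unweighted
average ⟨R⟩ over all cognate pairs. Because affinity scales follow the
binding-free-energy convention (low weight = strong affinity), *matching*
profiles give **negative** ⟨R⟩.

`scalescape` asks: out of the combinatorially vast space of possible
20-element scales, which ones make cognate mRNA and protein profiles
complementary, how unique are they, and how is that space shaped? It
answers with:

- a zero-temperature, downhill Metropolis Monte Carlo search over scale
  space. Each attempted move perturbs 1–4 randomly chosen weights by
  offsets drawn uniformly from \[−a, +a\], with the amplitude *a* annealed
  linearly from 0.1 to 0.01 over the run; a move is accepted iff it
  strictly lowers ⟨R⟩. Searches start from the uniform (all-equal) scale,
  whose fitness is 0 by the zero-variance convention;
- the **codon-content reference scale**: per amino acid, the usage-weighted
  mean fraction of the target base in its codons — the scale the genetic
  code itself implies, negated ("affinity" orientation) so that matching is
  negative. Converged searches recover it to scale correlations ≈ 0.997+;
- **landscape analysis**: ensembles of suboptimal scales selected at a
  fitness level (±0.01) from many independent runs, hierarchically
  clustered with the distance 1 − R between scales; cluster counts per
  distance cutoff trace a funnel — many dissimilar scales at intermediate
  ⟨R⟩, essentially one basin at the optimum;
- **randomization significance**: the fraction of 10⁶ i.i.d. uniform
  null scales whose correlation with a reference scale is at least as
  extreme as observed, two-tailed conversion (2p if p < 0.5, else 1 − p),
  and Fisher combination −2Σln pᵢ ~ χ²(2k);
- a **seeded synthetic-proteome generator** (random codon sequences from a
  configurable codon-usage table, translated by the standard genetic code)
  so the whole pipeline is testable end to end without any download.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures, so results drop straight into dplyr/ggplot2
workflows. A thin CLI (`exec/scalescape`) exposes the main operations
(`simulate`, `validate`, `evaluate`, `codon-scale`, `optimize`,
`landscape`, `compare`, `combine`, `profiles`) for shell use.

## Worked example

```r
library(scalescape)

# a synthetic proteome: 200 cognate pairs, lognormal protein lengths
# (mean 300), every synonymous codon equally likely
proteome <- generate_proteome(200, "lognormal:300,0.4",
                              codon_usage = "uniform", seed = 42)

# the genetic-code reference scale for purines, affinity-oriented
codon_scale <- codon_content_scale(uniform_codon_usage(), "PUR")

# how well do cognate profiles match under it?
proteome_mean_R(proteome, codon_scale, target = "PUR")
#> # <R> = -0.89 over 200 pair(s), target PUR

# five independent Monte Carlo searches from the uniform scale
cache    <- profile_cache(proteome, targets = "PUR")
campaign <- run_campaign(cache, n_runs = 5, base_seed = 7,
                         config = mc_config(n_steps = 1500, target = "PUR"))
glance(campaign)
#> # A tibble: 1 × 6
#>   n_runs best_R mean_final_R sd_final_R target n_pairs
#>    <int>  <dbl>        <dbl>      <dbl> <chr>    <int>
#> 1      5 -0.891       -0.891  0.0000367 PUR        200

scale_correlation(campaign$mean_scale, codon_scale)
#> [1] 0.9990842
```

Reading the numbers: the codon-content scale already matches the mRNA
purine-density profiles at ⟨R⟩ = −0.89 on this proteome; five independent
searches, started blind from a flat scale, all land within 4·10⁻⁵ of the
same minimum (a funnel-shaped landscape) and their mean scale correlates
with the genetic-code reference at R = 0.999 — the search rediscovers the
code's purine content purely from profile matching.

`autoplot(campaign)`, `plot_profile_pair()`, and
`plot_landscape(landscape_table(...))` visualize trajectories, cognate
profile pairs, and cluster-count landscapes.

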