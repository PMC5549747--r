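---
title: "Exploring nucleobase/amino-acid affinity-scale space"
author: "scalescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring nucleobase/amino-acid affinity-scale space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalescape)
```

## The model

A cognate pair is a coding sequence and the protein it encodes, linked
residue-to-codon by the standard genetic code. For a protein of length
$L$, the package builds two aligned profiles:

* **mRNA nucleobase density** $m_i$: the fraction of a target base (URA,
  CYT, ADE, GUA, or the purine class PUR = ADE + GUA) among the 63
  nucleotides of codons $i \dots i{+}20$, stop codon excluded;
* **protein affinity profile** $p_i(w)$: the mean of the scale weights
  $w_{a}$ over residues $i \dots i{+}20$, where $w \in \mathbb{R}^{20}$
  assigns one weight per amino acid.

Both vectors have length $L - 20$ and are compared with the Pearson
correlation $R$; the proteome-level fitness is the unweighted mean
$\langle R \rangle$ over pairs. Lower weights mean stronger affinity
(binding free-energy convention), so complementary profiles give
*negative* $\langle R \rangle$, and the search **minimizes** it.

Pyrimidine density is identically $1 - $ purine density, so a PYR profile
(`pyr_density_profile()`) flips the sign of every correlation and PYR is
never a separate search target.

### Profile alignment

Smoothing uses a 63-nucleotide window on the mRNA and a 21-residue window
on the protein. These two windows produce profiles of different raw
lengths; the package aligns them by evaluating the mRNA window *per
codon* — 63 nt = 21 codons centered on codon $i$ — which puts both
profiles on the same $L-20$ grid in exact register. Since
$63 = 3 \times 21$ this is the natural correspondence, and profile
matching is known to be insensitive to the window size. Only full
("valid") windows are used: shrunken edge windows would inject
high-variance edge artifacts into short proteins. Window sizes are
parameters (`window`, default 21) rather than constants.

### Fast evaluation

Optimization needs $\langle R \rangle$ for thousands of candidate scales
on a fixed dataset. `protein_window_matrix()` factorizes weighting from
smoothing: row $i$ holds the amino-acid frequencies of window $i$, so
$p(w) = Ww$. `profile_cache()` stores, per pair, the centered
cross-products $a = W^\top(m - \bar m)$, the centered Gram matrix
$S = W_c^\top W_c$, and $\sum (m - \bar m)^2$, reducing each pair's $R(w)$
to

$$ R(w) = \frac{a^\top w}{\sqrt{\left(\sum (m-\bar m)^2\right)\, w^\top S w}} $$

— two matrix–vector products per proteome per candidate scale. Tests
verify the cached path against naive per-window recomputation to 1e-10.

## The search

`run_mc()` is a zero-temperature, downhill Metropolis Monte Carlo with a
simulated-annealing proposal amplitude:

* **start**: the uniform scale (all weights equal). Its protein profiles
  are constant, so Pearson $R$ is undefined; the package adopts the
  convention $R = 0$ ("no matching") for any zero-variance profile, which
  gives the start a well-defined fitness of 0.
* **proposal**: $k \sim \mathrm{Unif}\{1,2,3,4\}$ distinct weights, each
  shifted by an independent offset $\sim \mathrm{Unif}[-a, a]$. A
  `shared_offset` flag applies one common offset instead, for the reading
  of the scheme in which a single offset perturbs all chosen entries; the
  independent-offset default mixes better and converges to the same
  optimum.
* **annealing**: $a$ ramps linearly from `amp_start = 0.1` (first move) to
  `amp_end = 0.01` (last move).
* **acceptance**: strictly downhill, `new_R < old_R`; ties are rejected.
* **length**: `n_steps = 1500` by default — at least three times the
  typical number of moves needed to reach a stable minimum (a few
  hundred).

`moves_to_threshold()` counts *attempted* moves (the move index) by
default; an `"accepted"` counting mode is provided because either reading
of "number of MC moves" is defensible.

Absolute weight values are meaningless: windowing and Pearson correlation
are invariant under positive affine maps $w \mapsto \alpha w + \beta$
(tested to 1e-12 for generic maps). Every reported scale is therefore
canonicalized by `rescale_unit()` — minimum to 0, maximum to 1 — so that
genuinely different scales can be distinguished from rescaled copies. The
all-equal scale has no such map and is returned as all 0.5 with a
`degenerate` attribute.

## The genetic-code reference scale

`codon_content_scale()` computes, per amino acid, the usage-weighted mean
fraction of the target base across its codons, with the usage taken from
the analyzed dataset itself (`codon_usage_from()`) — organism-specific
usage is exactly what differentiates organisms' optimal scales. The
`orientation` parameter makes the sign convention explicit: `"content"`
is the plain base fraction, `"affinity"` (default) is its negation before
unit rescaling, so that the scale *matches* (negative
$\langle R \rangle$) under the binding convention. Negating before or
after usage weighting is equivalent; the package negates the aggregated
content. Under uniform usage the purine content puts Lys/Glu
(AAA/AAG, GAA/GAG) at raw content 1 and Phe (TTT/TTC) at 0, so the
affinity orientation pins Phe at weight 1 and Glu/Lys at 0 — the extreme
residues that converged searches reproduce.

## Landscape of suboptimal scales

The search only visits levels it passes through, so scale ensembles "at"
a level $\ell$ are assembled per independent run as the accepted state
whose $\langle R \rangle$ is closest to $\ell$, admitted when within
$\pm 0.01$. Fast early descent means low-$|\ell|$ levels are represented
in only a fraction of runs; `landscape_table()` skips a level entirely
when fewer than `n_required` runs contribute (default 1000, the
full-campaign convention; tests use smaller ensembles and lower
`n_required` accordingly).

Ensembles are clustered agglomeratively on the distance $1 - R$ between
scales. The linkage is a free choice nowhere pinned down by the funnel
narrative; the package defaults to *average* linkage and exposes single
and complete, recording the choice in the output's `linkage` attribute,
because cluster *counts* (unlike the qualitative funnel shape) do depend
on it. `n_clusters()` cuts the dendrogram so that within-cluster merges
are at heights $\le$ cutoff. Counts are non-increasing in the cutoff at
any level, and collapse to ~1 at the converged level while staying large
(tens at 100 runs, hundreds at 1000) at intermediate levels — the funnel.

## Significance

`randomization_p()` draws `n_random` (default $10^6$) null scales with 20
i.i.d. $\mathrm{Unif}[0,1]$ weights — matching the unit-rescaling
convention — and reports the fraction whose correlation with the
reference scale is at least as extreme as observed. The tail needs care:
a literal "more negative" test would declare strong *positive*
correlations non-significant, yet positive correlations are exactly what
comparisons of matching scales produce. The default direction
`"toward-observed"` therefore tests the tail of the observed sign, with
`"negative"`/`"positive"` available to fix the tail explicitly. The
estimate has Monte-Carlo resolution $1/n_{\mathrm{random}}$; an exact 0
is reported as computed and must be floored at $1/n_{\mathrm{random}}$
before Fisher combination (`fisher_combine()` refuses $p = 0$).

`two_tailed()` implements the conversion $2p$ if $p < 0.5$, else $1 - p$.
Note this map is intentionally discontinuous at $p = 0.5$ (values just
below 0.5 give ~1, the point itself gives 0.5): it is the stated
conversion rule, not a smooth transform. `fisher_combine()` refers
$-2\sum \ln p_i$ to the upper tail of $\chi^2_{2k}$.

## Synthetic proteomes

`generate_proteome()` emulates a whole proteome as the *null* the search
machinery should be tested against: protein lengths from a configurable
distribution (default lognormal with mean 300 residues, sdlog 0.4 —
typical of bacterial proteomes; a 22-residue floor guarantees 2-point
profiles), residues i.i.d. from configurable amino-acid frequencies
(uniform by default; `ecoli_aa_frequencies()` is a labeled organism-like
preset), codons drawn per residue from a codon-usage table, and a random
stop codon appended. Every generated pair passes validation with
translation checking on, and generation is bit-reproducible under its
seed.

Residues are deliberately i.i.d.: with no positional autocorrelation, any
profile complementarity in the output is driven purely by the genetic
code and codon usage. That makes parameter recovery a clean end-to-end
test — searches on generated data must rediscover the generating
codon-content scale (measured correlations ≈ 0.9997 at 1000 pairs) — but
it also bounds what passing tests show about real data: real coding
sequences have compositional autocorrelation, GC gradients, and biased
gene content that the generator does not emulate, so agreement with
published whole-proteome numbers is checked separately and only when the
original datasets are supplied by the user.

## Numerical choices

* **Zero-variance convention**: any profile or scale whose relative
  variance is $\le 10^{-12}$ (sd/rms $\le 10^{-6}$) counts as constant
  and yields $R = 0$. The threshold is deliberately far above the
  $\sim 10^{-17}$ cancellation noise of the cached quadratic form (so a
  constant scale cannot leak noise-valued correlations) and far below any
  genuine windowed-profile variance (the smallest nonzero mRNA-profile
  step is $1/63$).
* **Ties** in the downhill acceptance are rejected, keeping accepted
  fitness strictly decreasing.
* **Degenerate inputs**: empty proteomes, duplicate ids, non-canonical
  characters, and missing amino acids in scale files are hard errors, not
  silent fixes; sub-window proteins are rejected at profile level and
  proteins shorter than 22 residues at proteome construction (22 is the
  shortest protein with a 2-point profile, hence a defined Pearson R).
* **Seeds** are explicit and required throughout the API (`run_mc()`,
  `generate_proteome()`, `randomization_p()`, `sample_random_scales()`);
  campaigns derive run $i$'s seed as `base_seed + i - 1` and record a
  manifest (package version, config, dataset checksum). The CLI defaults
  to a logged time-derived seed for interactive use.

## Problem sizes used by the tests and the acceptance script

The shipped checks run on synthetic proteomes of 1000 pairs at mean
length 300 (the realistic configuration; 100 independent searches for
landscape and recovery statistics, 10 for funnel checks) and a 60-pair
proteome for cheap unit-level ensembles; randomization-test calibration
uses 500 replicates at $10^4$ null scales, and the null-SD check
$10^5$ scales. These sizes make every stochastic assertion stable across
seeds while keeping a full run in the minutes range on one CPU.

## Known limitations

* Nucleotide-resolution profiles and alternative inter-profile alignments
  are not implemented; the codon-resolution register is the package's
  single convention.
* Cluster counts depend on linkage and on near-duplicate scales in an
  ensemble; only the qualitative funnel shape is linkage-robust.
* The analysis is purely sequence-based: no mRNA or protein structure,
  no binding measurements. A search that recovers physically meaningful
  scales from sequence alone is evidence about the fitness landscape of
  *profile matching*, not direct evidence of binding.
* The randomization null (i.i.d. uniform weights) is one natural choice;
  scales with correlated weights would define a different null family.
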