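---
title: "Spatial point pattern analysis of blastoderm transcriptional states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial point pattern analysis of blastoderm transcriptional states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastospp)
```

## The question

In the syncytial blastoderm, nuclei divide every ~10 minutes, and mitosis
aborts transcription; yet target genes of the anterior morphogen resume
active transcription within seconds of exiting mitosis — far faster than
the tens of minutes that concentration sensing is estimated to require. One
resolution is that a nucleus inherits its transcriptional state from its
parent instead of re-deciding it each cycle. Inheritance leaves a spatial
fingerprint: because daughter nuclei stay near their parent's position, the
nuclei sharing an ancestral decision form loose spatial clusters at
interphase 14.

`blastospp` analyses this fingerprint. Each nucleus of the monolayer is a
point in a bounded 100 x 100 um field with a transcriptional type: the
number of gene copies (0, 1 or 2; counts above 2 clamp to 2) caught
actively transcribing in a fixed snapshot, read out as nascent-transcript
"intron dots". The package asks two things: do like-typed nuclei cluster
beyond what random labelling of the same positions produces, and is mitotic
inheritance across cycles 11-14 sufficient to generate the clustering?

## First-order statistics

Overall density is `d = N/A` exactly; local density around nucleus *i* is
`d_i = n_i / (pi R^2)` with `R = 8` um, a little over the ~6 um nuclear
diameter, counting neighbours of a chosen type within `R` and excluding
the nucleus itself (its own reported local densities sit slightly above
the overall density, which self-inclusion would inflate further; exclusion
is the convention here). The regularity index (RI) is the mean
nearest-neighbour distance divided by its sample (n-1) standard deviation.
For points placed completely at random in the plane the index tends to
`sqrt(pi / (4 - pi)) ~ 1.913`; regular spacing gives larger values, and
the blastoderm monolayer, with its tight uniform packing, sits an order of
magnitude above the random value.

Nearest-neighbour distances default to the minimum-image torus metric of
the field rectangle. This was a deliberate estimator choice: on a bounded
window the uncorrected NND of edge nuclei is inflated, which biases the
CSR regularity index down to ~1.85 at the study's field size (240 nuclei
in 100 x 100 um), while the torus metric restores the asymptotic value
and matches the regime reported for matched random simulations
(1.97 +/- 0.11). It is also the same edge compensation used everywhere
else in the package. `nnd(..., periodic = FALSE)` gives the uncorrected
variant.

## Second-order statistics

The univariate Ripley function for type *i*,

    K_i(r) = (1 / (d_i N_i)) * sum_i #{other type-i nuclei within r},

counts, around each type-*i* nucleus, the type-*i* nuclei within radius
*r*, normalised by the type's density so that complete spatial randomness
(CSR) gives `K(r) = pi r^2` at every density. The bivariate version uses
type-*i* references and counts type-*j* neighbours, normalised by `d_j`;
if the two types are placed independently, `K_ij(r) = pi r^2` regardless
of each type's own pattern. Both are reported on annuli of width 2 um up
to 100 um, evaluated at bin upper edges, as cumulative circle counts (K is
a cumulative statistic; the annuli are its increments). The H-transform
`H(r) = sqrt(K(r)/pi) - r` turns the CSR parabola into the zero line:
positive H means clustering at that scale, negative H repulsion, and
`H >= -r` always.

Edge effects are compensated exclusively by the 3x3 periodic tiling:
the field is surrounded by 8 translated copies, references run over the
centre tile only, and neighbours are counted across all nine tiles. Up to
half the field size this equals the torus metric exactly (a property the
test suite asserts against an independent brute-force implementation); up
to the full field size an image of a nucleus can be counted in addition to
the nucleus itself, which is the intended behaviour of the tiling
construction — profiles at `r` approaching 100 um therefore need not
converge to zero and are interpreted with that in mind. No isotropic or
border-discard correction is offered.

One subtlety worth recording: under random labelling of a hard-core
monolayer, the bivariate `K_ij` does **not** equal `pi r^2` below the
nuclear spacing — labels cannot create cross-type pairs at distances the
positions do not contain. It instead tracks the mold's combined K (zero
inside the hard core), converging to `pi r^2` beyond the first
coordination shell. The independence benchmark in its clean form holds on
CSR positions.

## Synthetic molds

A "mold" is a fixed set of nuclear positions that receives labels by
permutation or simulation. The generator emulates the study conditions:
100 x 100 um, 0.024 nuclei/um^2 (240 nuclei), minimum spacing near the
6 um nuclear diameter.

The default process is a disordered hard-core packing: uniform random
seeds are relaxed on the torus — every pair closer than `min_spacing` is
pushed apart symmetrically until no overlap remains (to a 0.1% tolerance;
at 75% of the hexagonal bound the last fraction of overlap shrinks
geometrically and exact resolution would never terminate) — followed by a
0.5 um uniform jitter representing residual positional disorder. The
result has exactly 240 nuclei, minimum NND around 5-6 um, RI around
16-20, and, crucially, pair correlations that decay after the first
coordination shell, as in a real monolayer. A jittered triangular lattice
is available as `process = "lattice"`; it was rejected as the default
because its crystalline long-range order imprints persistent oscillations
on every type-specific H-profile at all radii, fragmenting mid-range
clustering signals that are contiguous on disordered molds. What the
synthetic mold does *not* emulate: the density anomaly of the embryo's
terminal regions, nuclear movements during cellularization, and
measurement noise of centre detection — conclusions about those features
cannot be drawn from tests passing on these molds.

Random labelling uses exact-count apportionment (largest-remainder
rounding of the proportions, then a random permutation over positions),
because the permutation null must hold per-field type counts fixed, not
merely in expectation.

## Monte Carlo significance

The null model fixes positions and permutes labels. 199 permutations per
field set, with the statistic averaged across fields, give a pointwise
95% band as the 5th-smallest and 5th-largest null value per bin (5/200
per tail, ~2.5% each side). No multiplicity correction is applied across
radius bins — ranges of consecutive significant bins are reported and
read as descriptions, not family-wise claims. Radius ranges where two
sets of per-field profiles differ are found by a two-sample KS test at
each bin with `p < 0.05`, reported as maximal contiguous runs; per-bin
testing (rather than pooling) was chosen because results are stated as
r-ranges. With small per-side counts the exact KS test is discrete and
flags at somewhat below the nominal rate (~3% at alpha = 5%).

Voronoi immediate neighbours are nuclei whose cells share an edge of
positive length; contact through a single degenerate vertex (four
co-circular points, as in exact lattices) does not count. The
tessellation is computed on the periodic tiling so every centre-tile cell
is bounded, with neighbours wrapped to centre-tile identities; on very
small fields a cell can meet the same neighbour along two distinct edges
and is then counted with multiplicity. Neighbour-type proportions around
a focal type are compared both against the label-permutation envelope and
against the normal-approximation binomial interval
`P +/- 1.96 sqrt(P(1-P)/N)` with the global type proportions as `P` and
the pooled neighbour count as `N`.

## The lineage model

Cycle-14 nuclei are assigned to nested clones of 8, 4 and 2 — the
descendants of single nuclei at cycles 11, 12 and 13 — without modelling
earlier positions: a random unassigned nucleus is grouped with its 7
nearest unassigned neighbours, repeatedly; leftovers (`N mod 8`) form one
undersized clone, excluded from width statistics by default. Each 8-clone
splits uniformly at random into two 4-clones, each 4-clone into two
2-clones. Greedy aggregation keeps most clones compact, but clones formed
late from scattered remnants are stringier; on the default mold the
median within-clone diameter is below 4 nearest-neighbour distances while
the upper tail is not, and the anteroposterior clone width averages
~3.5% of a 590 um egg length, matching the 3.4 +/- 0.5% EL regime of
comparable lineage simulations (read as mean +/- SD of per-simulation
means; per-clone spread is several times larger).

Transcribing probabilities per gene copy are 90%, 90%, 50%, 50% at cycles
11-14. With inheritance, each cycle-11 ancestor draws
`Binomial(2, 0.9)` active copies; daughters adopt the parental state, and
wherever the schedule steps down each active copy is independently
retained with probability `p_next / p_prev` at the matching clone level
(entering cycle 13 at the defaults: retention 5/9, i.e. switch-off 4/9,
drawn once per 2-clone). This makes the cycle-14 marginal exactly
`Binomial(2, 0.5)` — identical to the no-inheritance scenario, so the two
scenarios differ only in spatial arrangement, never in type fractions.
Schedules may not increase between cycles (no switch-on mechanism is
modelled) and must hold cycle 14 at the cycle-13 value. Snapshot
fractions are `(1-p)^2, 2p(1-p), p^2`: (1%, 18%, 81%) at p = 0.9,
(25%, 50%, 25%) at p = 0.5.

The replicated experiment (99 fresh clone assignments and state draws on
one fixed mold, per scenario) yields per-replicate H-profiles for each
type and for the Type-0/Type-2 bivariate pair. With inheritance, the mean
Type-0 and Type-2 profiles rise above zero over one contiguous range
starting just above the nuclear diameter (roughly 8-44 um on the default
mold) and the bivariate profile is negative there (mutual repulsion);
without inheritance all profiles stay inside the 199-permutation CSR
envelope. The qualitative contrast is robust to lowering the early
transcribing probability to 60% and moving the late one between 40% and
60%.

## Numerical conventions and degenerate inputs

* Distance-to-edge comparisons are inclusive (`d <= r`), with the
  subtraction ordered `(x_ref - x_target) - offset` so that a nucleus's
  own periodic images land at exactly the field size.
* Cropping is half-open, `[min, max)` on both axes, so adjacent windows
  partition a field without double counting.
* The regularity index refuses inputs whose NND spread is zero to within
  relative 1e-9 (perfect lattices).
* Ties in envelope order statistics resolve by sort order; exact ties
  give identical bounds.
* Problem sizes in the test-suite simulations (replicate counts of
  15-99, fields of 100-2000 points) were chosen as the smallest that
  separate the tested effects from Monte Carlo noise by a comfortable
  margin; the headline experiment runs the full 99 replicates against
  199-permutation envelopes.

## Worked contrast

```{r contrast, eval = FALSE}
mold <- generate_mold(seed = 1)
on  <- run_experiment(mold, inheritance = TRUE,  n_replicates = 99, seed = 2)
off <- run_experiment(mold, inheritance = FALSE, n_replicates = 99, seed = 3)
on$positive_ranges$H2   # contiguous clustering range of Type-2 nuclei
off$positive_ranges$H2  # nothing comparable without inheritance
```

## Known limitations

* The acceptance benchmarks are analytic and simulation targets; the
  study's experimental numbers (embryo RI values, experimental H-profiles
  and their significant ranges) depend on microscopy data that is not
  distributed, and nothing here reproduces them.
* Only the 3x3 tiling correction is implemented; inhomogeneous K, the
  pair-correlation function and alternative edge corrections are out of
  scope, as is anything upstream of a point table (image processing, dot
  detection, embryo flattening).
* Strict inheritance is an idealisation: every nucleus keeps its clone's
  state, so simulated clustering is tighter than a real embryo's, and the
  Type-0 vs Type-1 distance distributions around Type-2 nuclei separate
  only weakly under it.
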