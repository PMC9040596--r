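---
title: "Models and methods behind soilcosm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind soilcosm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcosm)
```

soilcosm studies a specific question about species-rich soil bacterial
communities: when replicate microcosms inoculated from the same community
diverge in composition, how much of that divergence is explained purely by
the finite size of the inoculum? A soil community holds hundreds of taxa
spanning five or more orders of magnitude in relative abundance. Any
laboratory inoculum is a sample of a few hundred thousand cells from that
distribution, so taxa rarer than about 1 in 20,000 are present in 0–10
copies — or absent — by chance alone. If some of those rare taxa are fast
opportunistic growers, their presence or absence at time zero propagates
into percent-scale differences in the grown community, with no biological
interaction required. The package provides the generative model for this
hypothesis, the serial-transfer machinery of the culturing regime, and the
measurement pipeline (amplicon identifier counting, flow-cytometry
anchoring, community metrics) needed to express simulated and measured
communities in the same terms.

## The growth model

Growth is deterministic; sampling is stochastic. A batch is the
shared-substrate Monod competition system

$$\frac{dN_i}{dt} = \mu_i \frac{S}{K_s + S} N_i, \qquad
  \frac{dS}{dt} = -\frac{c_\mathrm{cell}}{Y} \sum_i \frac{dN_i}{dt},$$

with one carbon pool $S$ common to all taxa, no interaction terms, no
death and no lag. This is deliberately the *minimal* model in which an
inoculum-sampling effect can express itself: any compositional divergence
between replicates is attributable to the multinomial inoculum draw and
the multinomial sequencing subsample, because everything in between is an
ODE. Two consequences of the model are used as internal checks throughout
the test suite:

* **Stoichiometric closure.** Every batch runs to substrate depletion, so
  the final *total* community size is
  $N_\mathrm{tot}(\infty) = N_\mathrm{tot}(0) + Y S_0 / c_\mathrm{cell}$,
  independent of $\mu_i$ and $K_s$. Kinetics decide *who* gets the carbon,
  stoichiometry decides *how much* biomass there is.
* **Mass balance.** $(\sum_i N_i^\mathrm{final} - \sum_i N_i^0)\,
  c_\mathrm{cell}/Y$ must equal the carbon consumed, and the integrator is
  required to respect this to 0.1% relative error.

Integration uses `deSolve::lsodar` with a root function that terminates
the run when $S$ falls below $10^{-6} S_0$, with a hard cap of $10^4$
hours. The suite cross-checks the adaptive integrator against a deliberately
naive fixed-step forward-Euler implementation (step $10^{-3}$ h) on small
systems, requiring agreement within $10^{-3}$ relative.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `c_cell` | 2e-13 | g C cell⁻¹ | 200 fg of carbon to build one cell, a standard soil-bacterium quota |
| `Y` | 0.2 | g C (g C)⁻¹ | one fifth of consumed substrate carbon becomes biomass carbon |
| `S0` | 2e-4 | g C batch⁻¹ | sized so a 2×10⁵-cell inoculum grows to ≈2×10⁸ cells, the scale a soil-extract-fed microcosm supports |
| `K_s` | 0.05·S0 | g C | not identifiable from final states (see stoichiometric closure); a small value keeps growth near-exponential until shortly before depletion |
| `mu` range | 0.01–0.4 | h⁻¹ | slow-to-moderate rates typical of soil taxa on complex substrate |
| focal rates | 0.55–0.8 | h⁻¹ | fast opportunists; assigned to rare taxa by `pick_focal_taxa()` |

The same 200 fg / 20% numbers power `carbon_budget()`: a silt with 1.5 mg
total organic carbon per gram supports $1.5\times10^{-3} \cdot 0.2 /
2\times10^{-13} = 1.5\times10^9$ cells g⁻¹, i.e. order $10^9$ — which is
why a microcosm inoculated at $10^6$ cells g⁻¹ has room for roughly eight
doublings in its first week.

### The abundance-to-rate map

Non-focal taxa receive $\mu_i$ linearly in $\log_{10}$ relative abundance,
with the most abundant taxon at `mu_max` and the rarest at `mu_min`. The
direction of this map — abundant means fast — is a modelling choice, not a
measured relationship: the scenario under study is one where the community
is dominated by taxa that grow well under the culturing condition, and the
interesting exceptions (rare but fast) are added explicitly as focal taxa.
The map's direction and both endpoints are arguments, so the opposite
convention is one call away. Degenerate pools (single taxon, or all
abundances equal) collapse the map to `mu_max` by convention.

The focal set defaults to five taxa with rates 0.55, 0.25, 0.8, 0.6 and
0.35 h⁻¹, chosen among taxa whose expected draw in a 2×10⁵-cell inoculum
is between 0 and 10 cells. Both the number of focal taxa and their rates
are configurable — analyses varying the focal-set size (e.g. six taxa
spanning 0.25–0.8 h⁻¹) fit the same machinery.

## The transfer engine

`run_cycles()` renders the weekly culturing regime in silico: batch growth
to substrate depletion, a sequencing-depth multinomial subsample for the
record, then a 1:10 transfer into fresh matrix. Dilution is **binomial
thinning** of each taxon's integer cell count with retention probability
$1/\mathrm{factor}$ — each cell independently makes the transfer or not —
because the repeated bottleneck is itself the phenomenon of interest;
deterministic division by 10 would silently delete it. Unconsumed
substrate is carried over (divided by the dilution factor) and added to
the next cycle's fresh pool. A community that reaches zero total cells at
a transfer truncates the trajectory with an explicit extinction flag.

The serial-cycle engine extends the single-batch generative model to the
full experimental regime; its per-cycle behaviour is pinned by a
closed-form test (a single taxon settles at
$N_{prev}/10 + Y S_0/c_\mathrm{cell}$ per cycle) and a selection test
(the faster of two taxa takes over across cycles).

## Amplicon quantification

Strains in defined communities are counted by exact forward-strand
substring search of each strain's unique identifier (a 60- or 90-nt
stretch of its 16S rRNA gene variable region) in the read pool. Choices
the data do not dictate, made explicit here:

* counting is **per read**, not per occurrence;
* a read matching two or more identifiers is **ambiguous** and excluded
  from all counts (the exclusion count is reported and logged);
* matching is forward-strand only by default, with a `revcomp` flag for
  unoriented reads;
* no mismatches are tolerated — the counting operation is exact by
  definition, and the read generator is correspondingly error-free by
  default.

Raw counts are divided by each strain's 16S rRNA operon copy number
(counts of gene copies → counts of cells) and renormalized. Multiplying
the corrected relative abundances by an independently measured total
community size (flow cytometry) yields absolute per-strain densities.
Note the subtlety the round-trip tests encode: a strain's share of
*reads* is proportional to cells × copies, so recovering cell proportions
requires the correction, and the tests generate reads accordingly.

## Flow-cytometry counting

Events are gated with strict inequalities, FSC-H > 50 and FITC-H > 350
(instrument units, SYBR Green I staining), thresholds calibrated on
buffer controls. Background from uninoculated material is subtracted on
**gated counts** at matched acquisition volume and dilution — not on
derived densities — and the subtraction is clipped at zero with a warning
rather than returning a negative density. Density is
$(\mathrm{gated} - \mathrm{blank}) / (V_{\mu L} \cdot 10^{-3})\cdot
\mathrm{dilution}$ cells mL⁻¹ at the default 20 µL acquisition volume.

## Community metrics

* `normalize_depth()` rescales each sample to a common total (default
  5×10⁴ reads) with **continuous** values; rounding before thresholding
  would create floor artifacts at the detection limit.
* `richness()` counts taxa at or above `detect_min = 1` in the normalized
  row — i.e. presence at sequencing depth.
* `shannon()` is $-\sum p_i \ln p_i$ in natural-log units (nats); the
  convention is stated because the literature mixes bases.
* `bray_curtis()` implements $\sum|x_i-y_i| / \sum(x_i+y_i)$ directly; the
  full pairwise matrix (`bc_distance_matrix()`) delegates to
  `vegan::vegdist`, and the two routes are cross-checked in the tests.
* `centroid_distances()` measures replicate variability as each sample's
  Bray-Curtis distance to its group's arithmetic-mean composition. This
  is a simple dispersion measure on purpose; ordination-based dispersion
  (PCoA-space `betadisper`) and permutation tests are intentionally left
  to external statistical environments, for which distance matrices are
  exported as TSV.

## Synthetic data

The generators produce inputs with the statistical structure the analysis
assumes, plus machine-readable truth for round-trip testing:

* `make_rank_abundance()`: lognormal abundances (default 314 taxa,
  `sdlog = 2`), normalized and sorted. The lognormal is a choice of
  convenient shape with the right qualitative property — a handful of
  dominants and a long rare tail (over half the taxa below 10⁻³) — not a
  fit to any measured soil distribution.
* `make_reads()`: each read embeds exactly one strain's identifier in
  random background, rejection-sampled so background never recreates a
  catalog identifier; strains drawn multinomially from given proportions.
* `make_fcm_events()`: bivariate-normal cell and background clouds; with
  default means the clouds sit on opposite sides of the gate and the
  expected misclassification (recorded in the truth attribute, from the
  normal CDF) is below 10⁻⁶ per event.

What passing tests on these fixtures do **not** show: real amplicon data
contain sequencing errors, chimeras and unclassifiable reads; real soil
rank-abundance curves are not lognormal in detail; real FCM scatter is
not Gaussian and stained-cell populations can overlap the colloid
background. The fixtures validate the arithmetic of the pipeline, not the
robustness of exact-match counting to error-prone reads.

## Numerical and design notes

* All randomness flows through explicit integer seeds; every multi-step
  routine derives child seeds deterministically from one root, so a run
  is reproducible from its metadata JSON alone.
* Integration tolerances: `rtol = 1e-8`, substrate `atol = 1e-18` (g C —
  far below one cell's worth of carbon), termination at
  $S < 10^{-6} S_0$; monotonicity of trajectories is additionally
  enforced by construction (`pmax` against the inoculum) to keep the
  no-death invariant exact against integrator wiggle.
* The long-batch regime is represented by a single batch to depletion.
  The slow multi-month community decline seen in long incubations
  involves death and carbon turnover, which the model intentionally
  excludes; simulating it would require a death/recycling term the
  available observations cannot constrain.
* Test and example problem sizes (tens of taxa, 10³–10⁵-cell inocula)
  are scaled down from the full 314-taxon, 2×10⁵-cell configuration; the
  full configuration itself runs in well under a second per replicate
  and is exercised by the acceptance checks.

## Worked example

```{r example, eval = FALSE}
pool <- make_rank_abundance(314, sdlog = 2, seed = 2024) |>
  assign_growth_rates(mu_min = 0.01, mu_max = 0.4) |>
  pick_focal_taxa(rates = c(0.55, 0.25, 0.8, 0.6, 0.35))

ens <- run_replicate_ensemble(pool, growth_params(), n_replicates = 5,
                              n_cells = 2e5, depth = 2e5, seeds = 2024)
glance(ens)
autoplot(ens)

m <- normalize_depth(community_matrix(ens), 1)
centroid_distances(m)
```

Replicates reach identical total sizes (stoichiometry) but differ in
composition wherever a focal taxon's inoculum draw differed — the
quantitative signature of inoculum-bottleneck stochasticity that the
package exists to expose.
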