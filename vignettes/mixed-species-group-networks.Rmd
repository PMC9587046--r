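---
title: "Mixed-species group networks along stress gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-species group networks along stress gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msgnet)
```

# The scientific question

Savanna herbivores routinely aggregate across species lines. Under the
stress gradient hypothesis, such positive interspecific associations should
become more frequent where environmental stress is higher — near predators,
or where forage conditions are poor for a given species. `msgnet` implements
an analysis chain for testing this with transect sighting data:

1. **Group formation** — sightings within 50 m of one another on the same
   survey occasion form a group; a group with two or more distinct species
   is a mixed-species group (MSG).
2. **Scenario classification** — each group is placed inside or outside a
   predator (lion) home range, into an NDVI productivity tertile, and into
   a core or edge human-activity zone.
3. **MSG occurrence regression** — logistic regression of mixed (1) versus
   single-species (0) status on the scenario covariates, reported as odds
   ratios with Wald 95% intervals.
4. **Association networks** — per scenario, a weighted species network with
   Dice-index edges, compared across scenarios through three node measures.
5. **Dyadic null models** — fixed-margin matrix randomisation tests for
   individual species pairs, with a habitat-stratified variant that asks
   whether an association survives conditioning on habitat use.
6. **Assortative mixing** — permutation regression of association strength
   on similarity in lion-prey susceptibility and in diet.

A synthetic data generator with planted, known structure stands in for
field data, so every stage has a parameter-recovery test.

# Models and statistics

## Dice's index and node measures

For species $i$ and $j$ observed in $N_i$ and $N_j$ groups and together in
$N_{ij}$ groups, the edge weight is Dice's index

$$w_{ij} = \frac{2N_{ij}}{N_i + N_j} \in [0, 1],$$

the ratio of observed to potential co-occurrences. Per node we compute:

* **strength** $s_i = \sum_j w_{ij}$ — total association weight;
* **Y-measure (disparity)** $Y_i = \sum_j (w_{ij}/s_i)^2$ — near $1/k_i$
  (degree $k_i$) when associations are evenly spread, near 1 when one
  partner dominates;
* **weighted clustering coefficient** — how strongly a node's neighbours
  are themselves connected. The methodological literature offers several
  weighted variants; the default closes each triangle with the arithmetic
  mean of the two adjacent edge weights and normalises by $s_i(k_i - 1)$
  (Barrat-style). A geometric-mean variant is available
  (`node_measures(..., wcc_variant = "geometric")`); every report carries
  the variant used, and all comparison logic is variant-agnostic.

Isolated nodes get `NA` for $Y$ and clustering rather than an arbitrary
zero; degree-1 nodes get `NA` clustering.

## Scenario comparisons

Two scenarios are compared by first downsampling the larger to the
smaller's size (equal observation effort), partitioning each side into
$k = 3$ disjoint random replicates, computing node measures per replicate
network on a common node set, and averaging over the six focal species.
That yields 3 aggregated values per measure per side, compared by a
two-tailed Welch $t$-test on natural logarithms. The log transform is used
because margin-matched random networks (see below) produce aggregated
measures whose distribution is close to log-normal — this is exactly what
`check_lognormality()` verifies, using the package's own fixed-margin
sampler as its definition of "random networks with the same
characteristics" (the report records this choice). Replicates are disjoint
thirds rather than repeated halves: disjointness makes the three values
independent given the data, which the $t$-test assumes. The tiny per-side
sample ($n = 3$) is inherited from the design; the test has low power and
the package reports it honestly rather than inflating replication.

## Fixed-margin randomisation

Dyadic association tests condition on every species' occurrence count and
every group's size: the null is the uniform distribution over binary
group-by-species matrices with the observed row and column sums. The
sampler walks this space with checkerboard swaps — pick two rows and two
columns; flip the $2\times2$ submatrix if it is $\bigl(\begin{smallmatrix}
1&0\\0&1\end{smallmatrix}\bigr)$ or its mirror — which conserves margins by
construction. In stratified mode both rows must share a habitat class, which
additionally conserves each species' per-habitat occurrence counts: a pair
significant unstratified but not stratified associates only through shared
habitat preference.

Implementation choices:

* "Steps" are swap *attempts*; the realised acceptance rate is attached to
  every result so users can judge mixing. The default plan (burn-in $10^5$,
  thinning $10^3$, $10^4$ samples) totals about $10^7$ attempts.
* The chain statistic (pairwise co-occurrence counts) is maintained
  incrementally in compiled code — a successful swap only touches pairs
  involving the two flipped columns — so long chains are cheap.
* Upper-tail Monte-Carlo p-values use the add-one estimator
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n + 1)$: the observed matrix
  counts as one sample, p-values are never exactly zero, and the test is
  one-sided because the question is whether species co-occur *more* often
  than chance allows. The estimator choice is recorded in the output
  metadata.
* Only pairs co-occurring more than twice are tested; rarer pairs yield
  skip records, not errors.
* A burn-in/thinning chain is the default; a serial backward–forward
  construction (`randomisation_plan(serial = TRUE)`) is available. The
  swap chain is reversible, so the backward run is implemented as a
  forward run of a random length. Both constructions are validated against
  the same exact oracle.

Correctness is anchored by exact enumeration, not by the chain flavour:
`enumerate_null()` performs a depth-first enumeration of all matrices with
the observed margins (per stratum, since the constraints decouple across
strata) on guard-sized instances, and the test suite requires chain
p-values to agree with exact p-values within $\pm 0.02$ at $10^5$ samples,
for both nulls. An independent sequential sampler from the community
ecology literature (vegan's curveball) is used as a second, external
cross-check of the enumeration itself.

## MSG occurrence regression

`fit_msg_model()` fits a maximum-likelihood logit (IRLS, tolerance
$10^{-8}$) with fixed reference levels — habitat *bushland*, NDVI *medium*,
home range *outside*, zone *edge* — so every contrast reads as "stressed
versus reference". Wald intervals (symmetric on the log scale) rather than
profile intervals are reported, matching how odds ratios with 95% CIs are
conventionally printed for this kind of community analysis. Species-level
models restrict the data to groups containing the focal species and drop
the zone term by default, mirroring the community-level null result for
human activity; the term can be restored by listing it explicitly. No
multiple-testing correction is applied across terms or species — raw
p-values at $\alpha = 0.05$ are the reporting convention here, and the
package does not silently second-guess it. Complete separation and
zero-variance predictors abort with the offending term named.
Collinearity among covariates is screened with Cramér's V
(`cramers_v()`, Pearson $\chi^2$ without continuity correction).

## Spatial classification

* **Home range**: minimum convex polygon with isopleth peeling — remove the
  $\lceil (1-q) n \rceil$ points farthest from the arithmetic mean centre
  (the usual MCP convention in home-range software; ties broken by input
  order), then take the convex hull. The product $(1-q)n$ is rounded at
  nine decimals before the ceiling, because the binary representation of,
  say, $0.15 \times 20$ lies a hair above 3 and would otherwise peel an
  extra point.
* **Point-in-polygon**: convex half-plane test with the polygon's
  orientation determined once from its signed area; boundary points count
  as inside (documented convention, tolerance $10^{-9}$).
* **NDVI tertiles**: boundaries at the 33rd and 67th percentiles of the
  group-level values, computed as exact tertile probabilities (1/3, 2/3)
  with type-7 interpolation, because the three classes are defined to be
  equal-sized; values exactly at a boundary fall to the lower class.
  Binning happens at the group level — the unit of every downstream
  analysis. Degenerate (constant) NDVI raises an error instead of
  producing empty classes.
* **Zone**: core if the group centroid lies more than 2 km (the livestock
  grazing buffer) from the boundary polyline, else edge.
* **Group formation**: single-linkage chaining at 50 m within a survey
  day, matching the field practice of scanning outward from a sighting; a
  complete-linkage (`rule = "clique"`) switch is provided. Group habitat
  is the modal member habitat with ties resolved by the canonical habitat
  order (grassland, open bushland, bushland, riverine); the group location
  is the unweighted centroid.

## Assortative mixing

Association strengths $w_{ij} \in [0,1]$ are regressed on two pair
similarities: $-|J_i - J_j|$ for Jacobs'-index prey susceptibility and
$-|m_i - m_j|$ for dietary monocot proportion (higher = more similar, both
enter one joint model). Because the response is a continuous proportion,
the model is a fractional logit — the Bernoulli-form quasi-likelihood whose
point estimates coincide with binomial-logit estimates. The variance model
is immaterial because inference never uses it: significance comes from
node-label permutation (shuffle the species-to-attribute assignment,
recompute covariates, refit, $10^4$ times), with the one-tailed rule that
an observed coefficient is significant when it sits among the largest 5% of
the permutation distribution. Zero-weight pairs stay in the regression —
never co-occurring is information, not missingness. Coefficients depend on
attribute differences only, so they are invariant to shifting all Jacobs'
indices by a constant (a property the test suite checks).

# The synthetic generator

`simulate_groups()` emulates the structure of the field data without any
download: ~951 group events whose exploded sighting table has ~1254 rows of
15 species, species-specific habitat preferences, planted pairwise
affinities, and scenario-dependent mixing propensities.

The assembly model is deliberately a **one-round independent-joining
model**, not a spatial point process: for each group event a location,
habitat, NDVI value, home-range membership and zone are drawn; a seed
species is drawn proportional to abundance times habitat preference; every
other species $j$ carries a joiner probability
$\operatorname{logit}^{-1}(\alpha_j + \text{habitat term} + a_{sj})$ with
$a$ the symmetric planted affinity matrix. This reproduces exactly the
statistical objects the downstream tests consume — margins plus pairwise
affinities — with controllable effect sizes.

Whether a group is mixed at all is decided at the **group level**: the
baseline probability of at least one joiner is computed from the joiner
model, and the scenario terms (`beta_lhr`, NDVI and habitat betas) shift
its log-odds. Mixed groups then draw their joiner set conditioned on being
non-empty. This design choice is what makes the planted scenario effects
identifiable: the downstream logistic regression of MSG status is then
correctly specified, and a planted `beta_lhr = log 2` is recovered as a
group-level odds ratio of 2. Had the scenario terms instead been added to
every per-joiner logit, the induced group-level odds ratio would exceed
the planted value by roughly 15% at realistic group sizes (the "at least
one joiner" event compounds per-joiner boosts), and recovery tests would
chase a biased target. With all scenario terms zero the two formulations
coincide and the joiner vector is exactly independent Bernoulli — the
property the independence tests exploit.

Defaults are the study conditions:

* 951 groups; baseline $\alpha_0 = -5.0$, calibrated once so the default
  pool yields a mean group size near 1.32 (≈1254 sightings from 951
  groups, ~31% MSGs);
* abundances proportional to the bundled per-species sighting counts
  (15 species present in all scenarios);
* scenario effects at the odds ratios the community-level analysis
  estimates: LHR $\log 1.69$, small NDVI $\log 1.82$, large NDVI
  $\log 1.64$, open bushland $\log 1.49$;
* planted affinities for the classic grazer dyads (zebra–wildebeest 2.5,
  the two gazelles 3.0) plus two weaker browser pairs;
* a fixed landscape: a 13.5 km square (~182 km²), a convex predator home
  range covering about half of it, an NDVI field summing three 2-D
  Gaussian productivity bumps (no raster dependency, still realistic
  tertile geography), and smooth habitat propensity surfaces that give
  spatially autocorrelated habitat draws;
* group centroids at least 110 m apart, so that 50-m chaining on the
  exploded sightings (members jittered within 24 m of the centroid)
  recovers the planted grouping exactly;
* predator points: a fixed 90% share (rounded up) falls inside the home
  range polygon, guaranteeing the ≥85% containment the home-range
  estimate assumes.

What the generator does **not** emulate — and hence what passing recovery
tests do *not* establish about field data: temporal autocorrelation and
repeat encounters of the same animals across days; animal movement and
home-range dynamics; imperfect or distance-dependent detection;
observation effort gradients; NDVI measurement error. The generator treats
every group record as independent, which is also how the analysis treats
the field records (the survey design separates repeat observations by at
least 24 h, and the package takes that at face value).

# Numerical conventions and degenerate inputs

* Species identifiers are case-insensitive slugs; attribute joins fail
  loudly on mismatch rather than silently dropping records.
* All randomness is routed through explicit integer seeds (R's own RNG
  stream, including inside the compiled chain), so identical seeds give
  byte-identical outputs across platforms.
* Frozen matrices (margins admit a single configuration) produce a warning
  and p-values of 1, not an error; all-equal Welch inputs short-circuit to
  $t = 0, p = 1$; aggregated measure values $\le 0$ make the log-scale
  Welch test fail loudly with the replicate named.
* Matrix rows that lose all species under a restricted node set are
  dropped (every occurrence-matrix row keeps sum ≥ 1).
* Network display filtering (edges shown only with weight ≥ 0.05 and at
  least 2 co-occurrences in `export_dot()`) never feeds back into any
  analysis.

# Problem sizes used by the test suite

The suite exercises the study scale where the study scale is the point
(951 groups for margin conservation and grouping recovery; $10^5$ null
samples for chain-versus-enumeration agreement) and smaller, repeated
designs where the target is a rate: 500 replicates of 400 groups for the
type-I error of the dyadic test, 100 replicates each for affinity
detection, habitat-artefact dissection, and odds-ratio CI coverage at
$n = 1000$, and 500 small-network replicates for permutation validity of
the assortment test. These sizes give the binomial checks standard errors
comfortably inside the asserted bands while the whole suite stays quick to
run.

# Known limitations

* The scenario comparison inherits its $n = 3$ aggregated values per side;
  significance statements from `compare_networks()` are coarse by design.
* The dyadic test is conditional on margins; for generator data the
  unconditional law is not exactly the conditional-uniform null (the seed
  species mechanism induces weak dependence), though the realised test
  size is nominal in the suite's experiments.
* The fractional-logit assortment coefficients are comparable across
  networks only up to the (unmodelled) variance structure; only their sign
  and permutation significance are interpreted.
* `filter_common_species()` requires a non-empty intersection; synthetic
  communities with very rare species can drop below the nominal 15 common
  species in some scenarios, and the node set then shrinks accordingly.

# A worked example

```{r example, eval = FALSE}
library(msgnet)

sim <- simulate_groups(sim_config(seed = 1))
groups <- sim$groups

# H1-H4: community-level odds ratios
fit_msg_model(groups)

# scenario networks on the common node set
sc <- scenario_groups(groups)
common <- filter_common_species(sc)
net_in <- dice_network(sc$inside_lhr, species = common, scenario = "inside_lhr")
node_measures(net_in)

# H5: inside versus outside the predator home range
focal <- c("giraffe", "zebra", "wildebeest", "grants_gazelle",
           "impala", "thomsons_gazelle")
compare_networks(sc$inside_lhr, sc$outside_lhr, focal_species = focal,
                 species = common, seed = 1)

# H6: dyadic randomisation tests, both nulls
dyad_test(sc$inside_lhr,
          plan = randomisation_plan(n_samples = 2000, burn_in = 5e4,
                                    thin = 500, seed = 3))

# H7: assortative mixing against the bundled attribute table
fit_assortment(net_in, species_reference(), n_perms = 1e4, seed = 4)
```
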