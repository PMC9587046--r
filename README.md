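# msgnet

Association-network analysis of **mixed-species groups (MSGs)** of savanna
mammals along environmental stress gradients — for behavioural and community
ecologists working with transect sighting data.

The stress gradient hypothesis predicts that positive interspecific
interactions intensify with environmental stress. `msgnet` tests this from
three angles with a reproducible, fully tested pipeline:

* **Does stress raise MSG frequency?** Logistic regression of mixed (1)
  versus single-species (0) group status on predation risk (inside/outside
  a lion home range), primary productivity (NDVI tertiles), habitat
  structure, and human activity (core/edge zone), reported as odds ratios
  with Wald 95% CIs; Cramér's V collinearity screen.
* **Does stress restructure association networks?** Per-scenario weighted
  species networks with Dice's index edges,
  `w_ij = 2 N_ij / (N_i + N_j)`, compared through node strength, the
  Y-measure (disparity `Y_i = Σ_j (w_ij/s_i)²`) and a weighted clustering
  coefficient, via Welch t-tests on log-transformed measures aggregated
  over three disjoint replicate subnetworks.
* **Which dyads associate beyond chance?** Fixed-margin matrix
  randomisation: checkerboard swaps walk the space of binary group×species
  matrices with the observed row and column sums (uniform null), with a
  habitat-stratified variant that additionally conserves per-habitat
  species totals — separating true affinity from shared habitat
  preference. Exact enumeration on small matrices anchors the sampler.
* **What drives group composition?** Node-label permutation regression of
  association strength on similarity in lion-prey susceptibility (Jacobs'
  index) and diet (monocot proportion).

A synthetic sighting generator with planted structure (habitat preferences,
pairwise affinities, scenario effects) plus spatial utilities (85% minimum
convex polygon home range, NDVI tertiles, 2-km core/edge zoning, 50-m group
chaining) complete the pipeline; every stage has parameter-recovery tests.

## A worked example

```r
library(msgnet)

sim <- simulate_groups(sim_config(seed = 1))   # study-scale synthetic data
groups <- sim$groups                           # 951 groups, 1286 sightings

fit_msg_model(groups)
#>                   term odds_ratio ci_low ci_high  p_value   n
#> 1     habitatgrassland      2.347  1.625   3.390 5.44e-06 951
#> 2 habitatopen_bushland      2.149  1.491   3.097 4.08e-05 951
#> 3      habitatriverine      0.331  0.113   0.968 4.35e-02 951
#> 4            ndvismall      1.422  1.000   2.022 5.00e-02 951
#> 5            ndvilarge      1.278  0.872   1.873 2.09e-01 951
#> 6            lhrinside      1.487  0.974   2.271 6.62e-02 951
#> 7             zonecore      0.867  0.556   1.352 5.29e-01 951
```

Groups in open terrain are about twice as likely to be mixed as groups in
closed bushland (the reference level), and the fitted lion-home-range odds
ratio (1.49 here) estimates the generator's planted predation-risk effect
(log 1.69 ≈ OR 1.69; a single draw scatters around it). The zone term is
null, as planted.

```r
sc <- scenario_groups(groups)
common <- filter_common_species(sc)            # node set shared by all 5 scenarios
net_in <- dice_network(sc$inside_lhr, species = common, scenario = "inside_lhr")
net_in
#> Dice association network [inside_lhr]: 15 species, 460 groups, 31 non-zero edges

dyad_test(sc$inside_lhr,
          plan = randomisation_plan(n_samples = 2000, burn_in = 5e4,
                                    thin = 500, seed = 3))[1:3, ]
#>        species_1        species_2   dice n_cooccur p_unstratified p_stratified tested
#> 1     wildebeest            zebra 0.4800        84         0.0005       0.0005   TRUE
#> 2 grants_gazelle thomsons_gazelle 0.3673        18         0.0005       0.0005   TRUE
#> 4 grants_gazelle          warthog 0.0923         3         0.0325       0.0285   TRUE
```

The two planted grazer dyads (zebra–wildebeest, Grant's–Thomson's gazelle)
come out maximally significant under both nulls: their co-occurrence counts
are never reached by any of the 2000 margin-preserving randomisations
(add-one p = 1/2001 ≈ 0.0005), whether or not per-habitat occurrences are
held fixed. A pair significant only in `p_unstratified` would be one whose
association is explained by shared habitat preference.

```r
fit_assortment(net_in, species_reference(), n_perms = 1e4, seed = 4)
#> Assortative mixing [inside_lhr] (105 pairs, 10000 node-label permutations):
#>   prey-susceptibility similarity: coef = 1.031, p = 0.0979
#>   diet similarity:                coef = 1.827, p = 0.0980
```

Positive coefficients mean similar species associate more strongly; the
permutation p-values ask whether the observed coefficient sits among the
largest 5% under random attribute shuffling.

See the methods vignette
(`vignettes/mixed-species-group-networks.Rmd`) for the models, the
generator's design, numerical conventions, and known limitations.

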