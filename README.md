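# nichepair

Trait-based tests of environmental filtering versus competition in
coexisting species pairs, with ancestral-state reconstruction under
Brownian-motion (BM) and Ornstein–Uhlenbeck (OU) models.

## The scientific problem

When two closely related species coexist in an extreme habitat — the
motivating system is pairs of *Niphargus* amphipods in the sulfidic caves of
Movile (Romania) and Frasassi (Italy) — two opposing eco-evolutionary
processes can shape their functional morphology:

* **environmental filtering**: the harsh environment admits only species
  with suitable trait values, so coexisting species are *more similar* than
  a random draw from the regional species pool;
* **competition / character displacement**: limiting similarity forces
  coexisting species to be *more different* than a random draw.

`nichepair` operationalizes this comparison for two trait sets: **body
size** (species mean adult body length, mm; a proxy for the trophic niche)
and the 4-dimensional shape of the **ventral channel** (ventro-distal
lengths of coxal plates II and III, widths of the bases of pereopods V and
VII), the groove that channels oxygenated water over the gills. It then
asks whether the present-day pattern already existed in the pair's
ancestors, by reconstructing trait values at the most recent common
ancestor of each focal species and its sister lineage and re-running the
same test on the reconstructed pair.

## The statistics at its core

**Allometric standardization.** Each channel measurement *y* is regressed
on body length *L* across species (`y = a + bL + ε`) and expressed as the
standardized residual `ε̂ / σ̂`, with `σ̂² = RSS/(n−2)`. Body size is
analyzed in raw mm.

**Virtual-species null model.** Real regional pools here are small (4 and 7
species), so the null distribution is simulated: 100 virtual species are
drawn with each trait independently uniform between the pool's observed
minimum and maximum; 1000 random pairs of distinct virtual species give a
null distribution of Euclidean distances. The observed pair distance *d*
gets two one-sided add-one empirical p-values,

```
p_similarity = (#{d_null ≤ d} + 1) / (n + 1)
p_difference = (#{d_null ≥ d} + 1) / (n + 1)
```

and is classified **competition** (`p_difference ≤ α`), **filtering**
(`p_similarity ≤ α`) or **random** (α = 0.05 by default).

**Trait evolution and ancestors.** On a rooted, branch-length phylogeny,
each trait is fitted by maximum likelihood under BM
(`cov(i,j) = σ² s_ij`, where `s_ij` is the shared root-to-MRCA path length)
and under a root-conditioned OU process

```
cov(i,j) = σ²/(2α) · exp(−α(t_i + t_j − 2 s_ij)) · (1 − exp(−2α s_ij)),
```

whose α → 0 limit is exactly BM, so the two fits are AIC-comparable
(k = 2 vs 3). The ancestral state at a node is the conditional expectation
of the joint Gaussian given all tip values; its SE is the conditional SD,
and the analysis is repeated for the `mean`, `lower = mean − SE` and
`upper = mean + SE` reconstructions. Divergence factors are
`extant distance / ancestral distance` per reconstruction variant.

## Worked example

Generate a fully synthetic scenario (7-species regional pool, a focal pair
planted at the 99th percentile of the null distance distribution, a
20-tip pure-birth tree) and run the complete pipeline:

```r
library(nichepair)

dir <- tempfile()
sc  <- make_scenario(scenario_spec("competition", effect_percentile = 99,
                                   seed = 42), dir = dir)
cfg <- analysis_config(traits = sc$paths[["traits"]],
                       tree   = sc$paths[["tree"]],
                       pools  = list(synthetic = sc$paths[["pool"]]),
                       pairs  = sc$paths[["pairs"]],
                       seed = 7, model = "BM")
run_analysis(cfg)
```

```
Eco-evolutionary pair analysis report
(distances: mm for body_size, standardized units for channel)

 pair_id    region trait_set             row distance     p_label     process normalized factor
   focal synthetic body_size          extant   4.6816   p = 0.012 competition    0.90303     NA
   focal synthetic body_size ancestral-lower   0.1436  p = 0.0559      random    0.02769 32.609
   focal synthetic body_size  ancestral-mean   1.5259   p = 0.481      random    0.29433  3.068
   focal synthetic body_size ancestral-upper   2.9082   p = 0.161      random    0.56097  1.610
   focal synthetic   channel          extant   3.4975 p = 0.00799 competition    0.67439     NA
   focal synthetic   channel ancestral-lower   0.9993  p = 0.0579      random    0.19268  3.500
   focal synthetic   channel  ancestral-mean   0.7862   p = 0.034   filtering    0.15160  4.449
   focal synthetic   channel ancestral-upper   1.0655  p = 0.0679      random    0.20545  3.283
```

Reading the table: the planted extant pair is correctly called
*competition* for both trait sets (its distance exceeds the 95th percentile
of the null), while its reconstructed ancestors are closer together —
`factor > 1` means the pair diverged since the ancestral node, here by a
factor ≈ 3–4.4 for the channel. `normalized` rescales each distance by the
pool's theoretical extremes (0 = identical species, 1 = the bounding-box
diagonal of the pool's trait ranges).

The published distance summaries for the two real cave systems ship with
the package, and the divergence-factor arithmetic can be reproduced from
them directly:

```r
subset(published_divergence_factors(), trait_set == "channel" & region == "movile")
#>   region trait_set variant ancestral_distance factor
#>   movile   channel   lower             0.9876 2.8520
#>   movile   channel    mean             0.5494 5.1267
#>   movile   channel   upper             0.4197 6.7110
```

The Movile pair's ventral channel diverged by a factor of 2.85–6.71
relative to its reconstructed ancestors; the Frasassi pair's body size by
11.8–21.0.

A thin command-line wrapper is included
(`inst/exec/nichepair`, subcommands `simulate`, `run`, `test-pair`,
`ancestors`).

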