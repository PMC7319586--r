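# coopfit

Quantitative analysis of transcription-factor autoregulation at promoters
carrying multiple operator sites, built around the regulatory logic of
bacterial toxin–antitoxin (TA) systems. Type IV antitoxins of the AbiEi /
Rv2827c family double as transcriptional repressors: they bind tandem 23-bp
inverted-repeat (IR) operators upstream of their own operon and shut it
down. When one promoter carries several operators with widely differing
affinities, the repressor fills them sequentially — tightest first — and the
composite binding curve shows *apparent negative cooperativity* (Hill
coefficient below 1) even when the sites are thermodynamically independent.
`coopfit` provides the model, the gel-shift (EMSA) analysis pipeline, the
sequence scanner and the reporter-assay arithmetic needed to work with such
systems, plus seeded synthetic-data generators that stand in for gels and
plate reads.

## The model

A promoter with sites `i = 1..n` (dissociation constants `K_i`, µM) at free
repressor concentration `c` occupies configuration `S` with probability
proportional to

```
w(S) = ∏_{i∈S} (c / K_i) × ∏_{i<j∈S} ω_ij
```

with pairwise coupling factors `ω_ij` (1 = independent, >1 cooperative).
Marginalising over the number of bound sites gives the predicted EMSA band
species `k = 0..n`; with `ω = 1` this is the Poisson-binomial distribution of
per-site occupancies `p_i = c/(c + K_i)`. Fractional saturation is
`Y = E[k]/n`, and the apparent Hill coefficient is the slope of
`log₁₀(Y/(1−Y))` versus `log₁₀ c` at half saturation, from which the
dissociation constant is extracted as `K_d = 10^(x-intercept)`.

Key entry points, by module:

| Area | Functions |
| --- | --- |
| Occupancy model | `promoter_model()`, `configuration_distribution()`, `band_distribution()`, `fractional_saturation()`, `apparent_hill_coefficient()` |
| EMSA / Hill pipeline | `band_table()`, `band_table_to_saturation()`, `hill_transform()`, `hill_fit()`, `classify_cooperativity()`, `analyze_emsa()` |
| Kd fitting | `fit_single_site()`, `fit_multisite()` |
| Operator scanning | `find_inverted_repeats()`, `to_promoter_coordinates()`, `consensus_matrix()`, `score_arm_against_consensus()` |
| Reporter assays | `miller_units()`, `normalize_activity()`, `repression_ratio()` |
| Synthetic data | `simulate_emsa()`, `mutate_probe()`, `plant_inverted_repeats()`, `simulate_reporter()` |
| Workflow | `run_pipeline()`, `run_demo()`, CLI at `inst/cli/coopfit.R` |

## Worked example

A synthetic single-site EMSA titration (generated with `simulate_emsa()` at
Kd = 0.121 µM, 5% multiplicative band noise, triplicates) ships with the
package:

```r
library(coopfit)

path <- system.file("extdata", "synthetic_single_site_emsa.csv",
                    package = "coopfit")
tab <- read_band_table(path)
res <- analyze_emsa(tab)
res$result
#> Hill fit: n_H = 0.9993, Kd = 0.1188 uM (non-cooperative; 6 points, R2 = 0.9998)
```

The Hill slope is 1 within noise (a single site cannot be cooperative) and
the fitted Kd lands within 2% of the generating 0.121 µM. The equilibrium
model built from the four measured per-repeat affinities of the Rv2827c
promoter (IR1 0.0205, IR4 0.121, IR2 0.862, IR3 11.0 µM) shows the
affinity-ladder effect directly:

```r
m <- rv2827c_promoter_model()
apparent_hill_coefficient(m)
#> [1] 0.4788
classify_cooperativity(apparent_hill_coefficient(m))
#> [1] "negative"
```

`run_demo(out_dir, seed)` regenerates a complete synthetic study — full
four-band titration, per-site polyC mutant probes, promoter scan, reporter
repression — and is byte-reproducible for a fixed seed.

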