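# lddexpand

Spatially explicit simulation and approximate Bayesian computation (ABC)
for range expansions with long-distance dispersal (LDD), aimed at the
population-genetic question of how humans settled the Old World: did
migrants only step between neighbouring demes, did long-distance dispersal
knit distant populations together, and did the last glacial maximum force
a range contraction (RC) into southern refugia that left a genetic trace?
The package is for population geneticists who want a tested, desk-scale
implementation of the full pipeline — forward lattice demography, backward
structured coalescent, microsatellite summary statistics, and ABC model
choice and parameter estimation — on schematic landscapes and synthetic
data.

## The model

The world is a lattice of square demes (side 150 km). Forward in time,
from `2·Ne_ANC` genes in an East-African origin deme `T_STARTEXP`
generations ago, each generation applies

* logistic regulation `N' = N + rN(1 − N/K)` per deme (densities in gene
  copies, carrying capacity `K` in diploids),
* emigration of a pool `2·N·m` gene copies, of which a binomial
  `B(pool, LDD_PROP)` share disperses long-distance — distance
  `~ Gamma(α, α/µ̄)` rounded and truncated to 2–6 demes, direction uniform
  — and the rest splits equally over the four lattice neighbours,
* deposition of immigrants, with a per-generation record of densities and
  of immigrant counts by source (the forward→backward contract).

Eurasia opens through a Levant corridor at `T_OOA`; under RC, 30
contraction events (4 generations apart, 120 generations in total,
starting 1,000 generations ago) strip the habitable area down to four
refugia for 160 generations. LDD regimes `any`, `empty_only` (`*ep`) and
`occupied_only` (`*op`) restrict which targets accept long-distance
migrants; a Neolithic variant replaces `K` by `KNeo` from 320 generations
ago. Backward in time, sampled genes trace through the record
(`P(source s | deme d) = immigrants(s→d)/N(d)`), coalesce within demes at
rate `1/N`, and mutate under the strict stepwise model. Each dataset is
summarised by 39 named statistics — group-averaged allele counts,
unbiased heterozygosity `H`, modified Garza–Williamson `NGW`, R_ST within
and between the regional groups AFR/ENA/CAS/EAS, and two
heterozygosity-vs-least-cost-distance slopes — which feed rejection ABC,
multinomial-logistic model choice, and Box-Cox/PLS parameter estimation
with local-linear adjustment.

## Worked example

```r
library(lddexpand)
land <- fixture_landscape("schematic-old-world-mini")
sc   <- scenario_from_name("LDDRC")
params <- c(T_STARTEXP = 4000, T_OOA = 2000, Ne_ANC = 12000, K = 1000,
            r = 0.56, m = 0.155, LDD_PROP = 0.038, mu_bar = 4.78,
            alpha = 1.25, STR_MUTRATE = 1.7e-4, KNeo = 0)
rec <- run_forward(land, sc, params, seed = 1)
rec
#> <demography_record> 12x24 demes, 4000 generations (LDDRC)
#>   occupied at present: 170 demes; LDD arrival events: 3863221

design <- sampling_design(land, n_loci = 20)
ds <- simulate_dataset(rec, design, params[["STR_MUTRATE"]], seed = 2)
ss <- summarize_dataset(ds, land, design)
signif(ss[c("H_AFR", "H_EAS", "FST_AFR-EAS", "FST_ENA-EAS", "slope")], 3)
#>       H_AFR       H_EAS FST_AFR-EAS FST_ENA-EAS       slope
#>    7.95e-01    7.87e-01    2.42e-02    1.28e-02   -4.04e-06
```

Read: under LDD with contraction, heterozygosity stays high outside
Africa (0.787 in East Asia vs 0.795 in Africa), between-group R_ST is
small (~0.01–0.02), and population heterozygosity still declines with
least-cost distance from the origin (negative slope per km) — the serial
founder effect softened, but not erased, by long-distance gene flow.
Without LDD the same pipeline gives visibly lower non-African `H`, higher
between-group R_ST and a steeper slope.

Derived quantities from the published posterior means (25-year
generations, 150-km demes, 3:1 census:effective):

```r
round(derived_identities(), 3)
#>   ldd_mean_distance_km census_density_per_km2  ldd_migrants_pct_of_K
#>                717.000                  0.138                  0.772
```

i.e. LDD migrants travelled ~717 km on average, hunter-gatherer census
density ~0.14 individuals/km², and ~0.8% of a deme's effective size left
as long-distance migrants each generation.

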