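---
title: "Spatial range expansions with long-distance dispersal: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial range expansions with long-distance dispersal: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lddexpand)
```

`lddexpand` implements a spatially explicit simulation-plus-ABC analysis of
a range expansion out of a single origin — the classic serial-founder model
of the human settlement of the Old World — extended with long-distance
dispersal (LDD), a glacial range contraction (RC) into refugia, and a
Neolithic carrying-capacity increase. This vignette lays out the model, the
parameters, the numerical choices and the limitations; the README shows the
worked example.

## The two-pass simulation design

**Forward pass.** The world is a lattice of square demes (150 km side by
default; 250 km as an alternative). Each generation, every deme is
logistically regulated,

$$N_{t+1} = N_t + r N_t (1 - N_t/K),$$

with densities in gene copies (a deme at carrying capacity `K` diploids
holds `2K` genes). Regulation is followed by migration: a pool of
`round(2*N*m)` gene copies leaves each occupied deme. A binomial
`B(pool, LDD_PROP)` share of the pool disperses long-distance; the rest is
split equally over the four lattice neighbours (genes aimed at sea or
barrier demes are lost — emigration pressure does not depend on coastline
shape). Each LDD migrant travels a distance drawn from
`Gamma(shape = alpha, rate = alpha/mu_bar)`, rounded to the nearest integer
and constrained to 2–6 demes (LDD is non-adjacent by definition; the cap
avoids unrealistic jumps), in a direction uniform on the circle. Under the
`empty_only` regime an LDD gene is discarded unless the target deme is
empty (every accepted event is a founding event); under `occupied_only`
unless it is occupied. Discarded genes die rather than returning home; the
discard counts are recorded so the regimes differ only through target
validity.

The forward pass records, for every generation, the deme densities and the
immigrant ledger — adjacent arrivals by source direction and LDD arrivals
by source deme. That record is the contract with the backward pass.

**Backward pass.** Sampled genes are traced backward through the record: a
lineage in deme *d* at generation *g* was, one generation earlier, in
source *s* with probability `immigrants(s -> d, g) / N_g(d)` (residual mass
stays put). Lineages co-resident in a deme of haploid size *N* coalesce
pairwise with probability `1/N`, at most one merger per deme per
generation — an approximation that is accurate while co-resident lineage
counts stay far below deme sizes, as they do at the scales used here. At
the start of the expansion all remaining lineages join a single ancestral
Wright–Fisher deme of `2*Ne_ANC` genes. Each locus gets an independent
genealogy; microsatellite genotypes arise by dropping `Poisson(rate x
branch length)` strict stepwise mutations (±1 repeat, equal probability)
from a root repeat count of 30 — an arbitrary anchor, since every statistic
used is translation-invariant.

## Scenarios and parameters

Nine named scenarios combine three switches: LDD regime (`none`, `any`,
`empty_only`, `occupied_only`), range contraction (on/off) and Neolithic
growth (`noLDDnoRC`, `noLDDRC`, `LDDnoRC`, `LDDRC`, `LDDnoRCep`,
`LDDnoRCop`, `LDDRCep`, `LDDRCop`, `noLDDRCNeo`).

Fixed scenario constants: contraction onset 1,000 generations BP, 30
contraction events 4 generations apart (120 generations total), each
stripping the northernmost remaining non-refuge rows; a 160-generation
refugia-only phase; release and free recolonisation afterwards; Neolithic
switch at 320 generations BP; 25-year generations. The literature fixes the
totals (30 events, "two or four generations apart", 120 generations) but
not the alternation; 30 gaps from {2, 4} can only sum to 120 if all equal
4, which is what we use.

Priors (one editable file, `inst/extdata/priors.yaml`): `T_STARTEXP ~
U[3200, 6000]` gen, `STR_MUTRATE ~ U[5e-5, 3e-4]` and `KNeo ~ U[2500,
7500]` are fixed by the study design; `T_OOA ~ U[1200, 3000]` gen follows
the stated spread time out of sub-Saharan Africa; the remaining bounds
(`Ne_ANC ~ U[5000, 20000]`, `K ~ U[50, 2000]`, `r ~ U[0.2, 1]`,
`m ~ U[0.05, 0.3]`, `LDD_PROP ~ U[0, 0.05]`, `mu_bar ~ U[2, 6]`,
`alpha ~ U[0.5, 2]`) are reconstructed as the smallest round intervals
containing the published 95% posterior intervals and are labelled
"reconstructed" in the file.

## The landscape and its fixtures

Landscapes are ASCII-grid configurations (`.` sea, `L` land, `B` barrier,
`C` corridor, `R` refuge) with an origin deme, a sampling design (deme,
diploid count, regional group: AFR, ENA, CAS, EAS) and optional short
sea-crossing edges. Least-cost distances run over 4-neighbour land paths
(sea and barriers impassable) with edges of one deme side; `levant_only`
routing uses land only, `levant_horn_gibraltar` additionally opens the
configured Horn-of-Africa and Gibraltar crossings.

The real GIS-derived world (9,047 demes) is out of scope; the package ships
schematic stand-ins with the same topology — an Africa–Eurasia pair joined
by a Levant corridor that opens at `T_OOA`, a Sahara band, Arabian desert
and Himalaya barriers, and four refuge blocks (sub-Saharan Africa, a narrow
North-African strip, a southern-Europe continuum, India + South-East
Asia):

* `schematic-old-world-small` (30 x 60, 927 land demes, 22 sampled demes
  shaped like the empirical panel: >= 15 diploids except two samples of
  10);
* `schematic-old-world-mini` (12 x 24, 170 land demes, 12 sampled demes, 3
  per group) — the desk-scale world for simulation studies;
* `strip-16` and `island-pair` for closed-form checks.

## Summary statistics

Thirty-nine named statistics per dataset: for each regional group, the
group means of per-population locus-means and locus-SDs of the allele
count `K`, unbiased expected heterozygosity `H = n/(n-1) (1 - sum p_i^2)`
and the modified Garza–Williamson `NGW = K/(range + 1)` (24 values); the SD
over loci of each statistic on the pooled sample (3); mean pairwise
R_ST within each group (4) and between each group pair (6); and the OLS
slope of population heterozygosity on least-cost distance from the origin
under each routing (`slope`, `slope_levant`). R_ST is the AMOVA variance
decomposition of squared repeat differences, numerators and denominators
summed over loci before dividing. The exact composition of the published
39-statistic list is not printed anywhere we can reach; this reconstruction
matches the stated building blocks and the count, and the layer is
name-driven so a corrected list can be dropped in.

## ABC machinery

* **Rejection**: statistics standardised by reference-table column
  means/SDs (the conventional choice; the source display standardisation
  uses bootstrap SDs, but is silent for distances), Euclidean distance,
  exactly `ceiling(tolerance * n)` rows retained, ties by row order.
* **Model choice**: weighted multinomial logistic regression
  (Epanechnikov kernel weights on the retained distances) of the model
  label on the standardised summaries, evaluated at the observed vector;
  quasi-separated fits fall back to a ridge-penalised fit and are flagged.
  Observation-side uncertainty comes from 1,000 bootstrap panels of 50
  loci resampled without replacement from the 87-locus panel; medians and
  95% intervals are order statistics over the replicates.
* **Parameter estimation**: per-column Box-Cox (shift to positivity by
  `-min + eps`; profile-ML lambda on [-2, 2]), PLS regression of
  parameters on transformed summaries (12 components by default, with an
  RMSE-vs-components curve emitted from a 4:1 held-out split), rejection
  in component space, weighted local-linear adjustment of the retained
  parameter values, truncation to the prior support (fraction reported).
  Posterior mode by Gaussian KDE argmax on a 512-point grid; 95% HPDI as
  the shortest interval over the sorted adjusted sample.
* **Power studies**: pseudo-observed datasets (PODS) are reference
  simulations scored with themselves left out of the table; a PODS is
  assigned to the model whose posterior probability exceeds the threshold
  (0.50 or 0.85), else unassigned.
* **Goodness of fit**: 2D highest-density-region p-values (Gaussian
  product-kernel density over the bootstrap cloud; p = fraction of cloud
  points with density below the queried point) and posterior-predictive
  PCA with 50/75/95% envelopes over the first four components.

## Numerical choices

* **Discrete-logistic overflow**: the raw recurrence sends a deme far above
  `K` (the ancestral deme holds `2*Ne_ANC >> 2K` genes) to a negative
  density. A deme above capacity therefore declines toward `K` and never
  below it; demes at or below `K` follow the raw recurrence unchanged
  (fixed point at `K`, overshoot bounded by `K(1 + r/4)` for `r <= 1`).
* **LDD kernel sampling**: the forward core samples the truncated-rounded
  kernel from its exact probability mass (numerical gamma integrals),
  identical in law to round-and-resample rejection sampling but O(1) per
  migrant; both samplers are chi-squared-tested against the numeric pmf.
* **Backward-move edge cases**: recorded pre-growth densities in (0, 1)
  are legal (the deme emigrated after growth); only N <= 0 under a lineage
  is a record-corruption error. Immigrant probabilities are walked
  cumulatively, residual mass stays put.
* **Determinism**: one seed fully determines a reference table; each
  simulation draws its own sub-seed from the master stream and is recorded
  in the table, so any row can be regenerated in isolation.
* **Failed replicates** (whole-metapopulation extinction, or a sampled
  deme smaller than its sample at present) are logged, counted and
  replaced by fresh prior draws.

## Problem sizes

The source analysis runs 100,000 simulations per model on a 9,047-deme
world and 87 empirical loci. This package's studies are scaled to a
desk: the shipped tests and the acceptance script build reference tables
of 100 simulations per model with 12 loci per dataset on the mini world
(a forward+backward simulation there costs ~0.5 s without LDD and ~1-2 s
with it), run power studies with 20 PODS per model at rejection tolerance
0.5 (the conventional 2-10% tolerance would retain only 8-40 of 400 rows,
far too few for a 39-covariate logistic fit; the Epanechnikov weights
provide the localisation), and use the 30 x 60 world with single
replicates for the signatures that need a long distance axis
(heterozygosity-distance slopes, the AFR -> EAS heterozygosity gradient).
Parameter-recovery coverage uses a 400-simulation single-model table and
40 PODS. At these sizes the qualitative structure of the published results
(noLDD vs LDD separation, block-diagonal dominance of the confusion
matrix, negative diversity-distance slopes, LDD raising non-African
diversity and lowering between-group differentiation) is reproducible; the
printed percentages are not, being grid- and prior-dependent.

## What the synthetic data do and do not emulate

Pseudo-observed panels reproduce the shape of the filtered empirical panel
— 22 populations in 4 regional groups (>= 15 diploids, two samples of 10),
87 unlinked microsatellites, < 5% missing data injected completely at
random — and are generated by the same code path as reference-table
simulations, so they are exchangeable with them by construction. They do
not emulate: real sampling coordinates (schematic placements preserve the
group structure), ascertainment of trinucleotide loci, mutation-model
violations (indels, compound repeats), archaic admixture, or any
environmental heterogeneity in `K` and `m`. Passing tests therefore
demonstrate the machinery's internal correctness and the direction of the
model's mechanistic signatures, not the empirical posteriors.

## Known limitations

* One coalescence per deme per generation (documented approximation).
* The schematic worlds compress geography; absolute distances, and with
  them slope magnitudes, are smaller than in the real world.
* The 39-statistic list is a reconstruction (see above).
* `empty_only` regimes discard almost every LDD gene once the world is
  full; their reference tables carry correspondingly weaker LDD signal at
  small simulation counts.
* Posterior probabilities from the weighted logistic regression carry
  sampling noise of order `sqrt(4 * 39 / n_retained)` at the observed
  point; at desk-scale retained sets this dominates fine calibration
  claims.
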