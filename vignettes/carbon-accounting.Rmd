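---
title: "Methods: carbon accounting in an Andean forest-grassland mosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon accounting in an Andean forest-grassland mosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punacarbon)
```

## The problem

Above the crop line in the tropical Andes (roughly 4200–4900 m), zonal
vegetation is a mosaic of *Polylepis* forest and tussock grassland. On
slopes accessible to people and livestock, fire, grazing and firewood
harvesting have pushed the mosaic almost entirely to grassland; cliff-bound
ledges inaccessible to both preserve a close analogue of the pristine
state. `punacarbon` implements the accounting needed to compare the two:
stand structure and aboveground tree carbon from inventories, soil organic
carbon (SOC) and root carbon from volumetric soil profiles, community
composition statistics, and a landscape-scale counterfactual that asks what
the carbon stock would be if all zonal land still carried the inaccessible
forest–grassland proportion.

## Soil accounting

Profiles are sampled in fixed depth increments (0–5, 5–10, 10–20, 20–30,
30–40, >40 cm) down to continuous rock. Per layer $i$, with oven-dry
fine-earth mass $W_{fe,i}$ (g), rock mass $W_{r,i}$ (g) and sample volume
$V_i$ (cm³):

$$\rho_{w,i} = \frac{W_{fe,i}+W_{r,i}}{V_i}, \qquad
  M_{w,i} = \rho_{w,i}\,h_i, \qquad
  M_{fe} = \sum_i \frac{M_{w,i}\,W_{fe,i}}{W_{fe,i}+W_{r,i}},$$

where $h_i$ is the layer height in mm, so that g cm⁻³ × mm yields kg m⁻²
with a numeric factor of one. The package implements both the
rock-percentage form of $M_{fe}$ and its algebraic simplification above and
verifies their agreement to 1e-9 relative as a property test; the
simplified form is the default because it also handles an all-rock layer
(zero fine earth) gracefully. Fine-earth bulk density divides $W_{fe}$ by
the non-rock volume at an assumed rock density of 2.65 g cm⁻³. Element
stocks multiply layer concentrations by layer fine-earth masses; root
stocks scale the washed-subsample root:soil mass ratio by the same layer
masses (live and dead roots pooled). Because both bulk-density conventions
appear in soil literature, the per-profile table reports the
thickness-weighted mean of $\rho_w$ *and* $\rho_{fe}$.

Design choices where the method leaves room:

* **Root carbon fraction** is not fixed by the field protocol; the default
  0.5 matches the aboveground assumption and is configurable.
* **Profile base saturation** is the fine-earth-mass-weighted mean over
  layers, consistent with how stocks are mass-weighted.
* **Rock volume fraction** is $(W_r/2.65)/V$ per layer,
  thickness-weighted for the profile.

## Soil classification

These young, single-A-horizon soils over continuous rock fall into four
groups, assigned in rule order: (1) profiles ≤ 25 cm deep or with ≥ 80
vol-% rock are Leptosols, qualified *Mollic* when the mollic-horizon
criteria hold (≥ 0.6% organic carbon, Munsell value and chroma ≤ 3
throughout, base saturation ≥ 50%, ≥ 10 cm over rock); (2) deeper profiles
with base saturation ≥ 50% are Phaeozems; (3) the remaining, more acidic
profiles are Umbrisols. The mollic criterion of a 0.6% carbon excess over
parent material cannot be evaluated without parent-material analyses and is
treated as satisfied — for these organic-rich A-horizons over bare rock it
is not the binding constraint.

## Tree carbon

The allometry is *Polylepis*-specific: dbh (130 cm) is mapped to bole
diameter at 50 cm by $d_{50} = 1.1613\,dbh + 0.4628$, then dry biomass per
tree is $-16.51 + 40.26\log_{10}(\mathrm{height}) +
9.30\log_{10}(d_{50})$, interpreted as kg per tree (a configurable scale
would only rescale stocks linearly). Carbon is 50% of biomass. Trees below
the calibration range can yield negative predictions; these are floored at
zero and counted in a warning. Stems qualify for inventory above 10 cm
circumference (dbh > 10/π cm); the CSV reader applies this filter and
reports exclusions. Standing deadwood is excluded from carbon stocks by
default (its decay state is unknown) but reported separately, and the
biomass equation is applied per tree and summed, not to stand aggregates.

## Landscape scenario

The mapped landscape splits into zonal-inaccessible, zonal-accessible and
azonal fractions; each accessibility class's zonal area divides between
forest and grassland by its forest-cover fraction. Per-plot stocks are
summarised per habitat type × pool as min, quartiles, mean and max, and
the scenario is recomputed at each statistic to propagate uncertainty
without resampling. The potential scenario applies the inaccessible
forest-cover fraction and (by default) inaccessible per-m² stocks to all
zonal land — a deliberately static assumption; a `potential_source`
switch allows accessible stocks for sensitivity. Azonal area (rock,
moraine, bogs, landslides) carries zero stock in both scenarios, a known
understatement that cancels to first order in the comparison. The mapped
area itself is always a user input.

## Community metrics

IndVal follows the specificity × fidelity definition: $A_{ij}$ is species
$i$'s mean cover in group $j$ over the sum of its group mean covers
(cover-based abundances; a presence-based variant would change $A$ only),
$B_{ij}$ the occurrence fraction in group $j$, and the statistic
$100\,A_{ij}B_{ij}$ maximised over groups. Significance comes from random
reassignment of plot labels with the add-one rule
$p = (1+k)/(n_{perm}+1)$ (default 999 permutations, seedable), avoiding
zero p-values; tiny designs can instead enumerate all label arrangements
exactly. Presence means cover > 0, with no trace-cover rounding.

Trait syndromes standardise the 32 binary/ordinal trait columns, extract
principal components (constant columns dropped with a warning), fix each
component's sign so its largest-magnitude loading is positive (PCA signs
are otherwise arbitrary), and average species scores over the species
present in each plot — unweighted by default, matching a
"mean over species per plot" convention; cover-weighting is available.

Mixed-model habitat contrasts are out of scope; tests instead assert the
direction of group-mean differences on synthetic data.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is exercised. Defaults mirror the study design — 24
forest plots (10 × 10 m) per accessibility class, 10 soil profiles per
habitat type, 118 community plots (2 × 2 m) per habitat type, a
1.1% / 56.9% / 42.0% zonal-inaccessible / zonal-accessible / azonal split,
and forest-cover fractions 70% / 7.5%. Field-data shapes that motivated the
distributional choices: dbh and covers are lognormal (positive,
right-skewed), soil depth truncated normal on 15–90 cm (median near
55 cm), deadwood and species occurrence Bernoulli, traits
binomial draws from two archetype probability profiles
(grazing/burning-adapted versus not).

Effect directions are built in: inaccessible forest is denser (Poisson
stem mean 70 vs 45) with larger trees (median dbh 40 vs 30 cm) and far
more standing deadwood (rate 0.30 vs 0.05); grassland soils get a lower
base saturation (mean 34% vs 66%, putting most forest soils in the
Phaeozem and most grassland soils in the Umbrisol branch) and a ~10%
higher surface carbon concentration, so grassland holds modestly more SOC
per m²; root densities favour forest; undescribed species are frequent and
dominant on inaccessible plots while introduced species and widespread
generalists concentrate on accessible plots. Stock magnitudes were chosen
once as field-plausible for these systems (forest tree carbon near
10 kg C m⁻², SOC near 10–12 kg C m⁻², root biomass averaging near
2 kg m⁻²); within-habitat variances are free parameters of the
configuration, since the generator emulates between-habitat structure, not
any particular site's variance components.

What the generator does *not* emulate — spatial autocorrelation, site-level
random effects, measurement error in cover estimation, climate variation —
bounds what passing tests show: they demonstrate the accounting and the
direction-recovery of configured effects, not inference on real field data.

Ground truth (per-profile stocks recomputed inline by direct summation,
and the class implied by the generating fields) is stored beside the
tables, so recovery tests compare the package's accounting against an
independent arithmetic path. One top-level seed drives everything;
per-table sub-seeds are derived deterministically, and identical seeds
give byte-identical outputs.

## Numerical choices and degenerate inputs

* Quantiles use the R default (type 7); summaries report the mean alongside
  the five-number summary.
* Permutation exceedance uses a 1e-12 absolute slack so floating-point ties
  count as exceedances.
* Zero-ECEC layers give `NA` base saturation with a warning; an all-rock
  layer contributes zero fine-earth mass and is reported; an empty plot
  yields zero densities and `NA` means; a profile missing diagnostic fields
  classifies as "undetermined" with a reason attribute.
* Classification is a total function on valid profiles: rule order makes
  the groups mutually exclusive and exhaustive.

## Problem sizes used in the tests

The test-suite runs the equation oracles on 10⁴ random inputs, the
classification recovery on 1000 generated profiles, the IndVal null
calibration on 500 simulated species at 199 permutations (12 plots), the
exact-enumeration check on a 6-plot toy, and the scenario sign-pattern
recovery on three seeds with 60 soil profiles per habitat type — sizes at
which the configured effects dominate sampling noise while the suite stays
quick on a laptop.

## Known limitations

* Aboveground herbaceous biomass and soil inorganic carbon are not
  accounted (both minor in these acidic, grass-dominated systems).
* The potential scenario is static: it transplants present-day
  inaccessible stocks, ignoring successional dynamics.
* The allometry is calibrated for *Polylepis* within 3–12 m; other growth
  forms need their own equations.
* IndVal p-values are marginal per species; no multiple-testing correction
  is applied (report-level control is the caller's choice).
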