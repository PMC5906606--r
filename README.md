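# leptodiet

Metabarcoding diet analysis and prey-field bioenergetics for European eel
larvae (leptocephali).

## The problem

What do young eel larvae eat in the oligotrophic Sargasso Sea? Their guts
look empty under a microscope, so diet must be read from DNA: 18S rRNA
amplicons from gut contents are clustered into OTUs, assigned a taxonomy
against a curated plankton reference, and compared with the composition of
marine-snow aggregates sampled alongside the larvae. The striking result in
this study system is an inversion — gut reads dominated by gelatinous
Hydrozoa (phylum Cnidaria, ~76% of reads, of which 98% Hydrozoa), snow
reads dominated by Crustacea (~52%) — which argues against marine snow as
the main food source and for selective feeding on siphonophores. A
bioenergetic closure then asks whether observed siphonophore densities can
actually sustain a larva.

`leptodiet` implements that entire quantitative chain as an R package for
researchers working on larval-fish trophic ecology and metabarcoding
pipelines:

* **synthetic data** — a reference database evolved along a 33-leaf
  plankton taxonomy; Dirichlet-multinomial gut/snow communities;
  host-contaminated amplicon reads with a blocking-primer retention model;
  larval length cohorts; depth-stratified Hydrozoa fields;
* **OTU processing** — end-gap-free pairwise alignment, greedy 99% centroid
  clustering, the study's filters (singletons, <9 reads, host OTUs,
  fish OTUs within 2% of the host, 1,000-read sample minimum, 10,000-read
  cap), and 97% closed-reference clustering;
* **taxonomy** — best-hit assignment under a coverage >= 0.98 /
  identity >= 0.95 / perfect-run >= 100 nt conjunction, with
  lowest-common-ancestor resolution of ties;
* **community statistics** — median-of-ratios size factors (strict and
  zero-robust "poscounts"), log-transform PCA, a multivariate
  negative-binomial likelihood-ratio test with label-permutation p-values,
  Holm adjustment, threshold-prevalence summaries;
* **plankton biomass** — length-to-carbon power laws, depth-stratified
  integration to mg C m^-2, larval-occurrence regression;
* **bioenergetics** — the encounter model `V = (pi R^2 / 2) u T`,
  encounters `V D`, carbon intake `V C_v`, energy supply through the 15%
  carbon-to-dry-weight ceiling and the 2.0–5.0 kJ g^-1 energy-density
  interval, against the allometric demand `72.64 W^0.55` J day^-1.

## Worked example: can siphonophores feed a leptocephalus?

```r
library(leptodiet)
print(run_budget())
```

```
searched volume: 1.247 m3 day-1 (hemisphere)
encounters: 4.99 prey day-1 (reported as 5)
metabolic demand: 8.4 J day-1
size_based (0.4 mg C m-3): 0.499 mg C day-1, supply 6.7-16.6 J day-1, ratio 0.79-1.97
weight_based (2.0 mg C m-3): 2.494 mg C day-1, supply 33.3-83.1 J day-1, ratio 3.94-9.84
```

Reading this: a 15 mm larva cruising at one body length per second for a
12 h feeding day, reacting to prey within 35 mm inside a hemisphere above
its head, searches about 1.25 m^3 and so encounters about 5 siphonophores
at the observed maximum density of 4 ind m^-3. Converting the swept
volumetric prey carbon into energy brackets the supply at 6.7–16.6 J/day
(size-based carbon) or 33–83 J/day (measured carbon), against a minimum
demand of 8.4 J/day — a supply-to-demand ratio straddling 1 in the
conservative branch and well above it in the other. Siphonophores alone
are energetically sufficient.

The community side runs the same way at study scale (a few minutes):

```r
cfg <- default_config(seed = 20140330)
cfg$stats$n_perm <- 199
report <- run_pipeline(cfg)
print(report)
#> leptodiet pipeline report
#>   reads: 1099451 total (39451 host) across 106 samples
#>   OTUs: 70268 formed, 32 kept after filters
#>   gut Cnidaria: 77.3% of reads; snow Crustacea: 43.7%
#>   gut vs snow NB test: LR = 925.0, p = 0.005
#>   Hydrozoa biomass: mean 13.2 mg C m-2 over 13 stations
#>   occurrence regression: R2 = 0.04, p = 0.50, n = 13
#>   energy budget: 5 encounters day-1, demand 8.4 J day-1
```

(Here the permutation count was 199, so p = 0.005 is the smallest
attainable value; cohort compositions scatter around their calibrated
means — 76% gut Cnidaria, 52% snow Crustacea — with the sampling noise a
75/31-sample survey really has.)

Station biomass from a simulated Hydrozoa field:

```r
b <- integrate_station(draw_hydrozoa_field(n_stations = 13, seed = 1))
head(b, 3)
#>   station biomass_mgC_m2
#> 1    st01       8.239251
#> 2    st02      27.226618
#> 3    st03      26.512914
mean(b$biomass_mgC_m2)  # 16.1 mg C m-2
```

A thin command-line front end covering
`simulate | cluster | assign | stats | biomass | energy | run` ships as
`inst/cli/leptodiet.R`.

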