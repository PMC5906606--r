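---
title: "Models and methods behind leptodiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leptodiet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leptodiet)
```

`leptodiet` re-creates, as tested code, the quantitative chain of a
DNA-metabarcoding diet study of European eel larvae (leptocephali) in the
Sargasso Sea: amplicon reads from larval guts and from marine-snow
aggregates are clustered into OTUs, filtered, assigned a taxonomy against a
curated plankton reference, and compared statistically; depth-stratified
Hydrozoa records are converted to areal carbon biomass; and a bioenergetic
model asks whether calycophoran siphonophores alone could cover the larvae's
energy demand. Because the original sequencing data live in public archives
and are not required here, the package ships a synthetic-data generator that
reproduces the *statistical structure* of the study system, so that every
downstream method can be exercised against a known truth.

This vignette explains each model, its assumptions, the defaults and why
they were chosen, and what passing tests do and do not demonstrate.

## The synthetic study system

**Reference database.** `study_reference_db()` evolves one ~300 nt marker
sequence per taxon down a fixed 33-leaf taxonomy (seven ranks,
kingdom–species) that mirrors the taxonomic groups of the study: four
Hydrozoa (three siphonophores, one trachymedusa), two Anthozoa, four
Crustacea, the host *Anguilla anguilla* plus three non-anguillid fishes, and
the minor gut/snow groups (fungi, radiolarians, seagrasses, chaetognaths,
stramenopiles, dinoflagellates, molluscs, ciliates, tunicates, an
entoproct). Each lineage node substitutes a fixed fraction of its parent's
positions — 25% at kingdom down to 0.8% at species — so sequence identity
decays monotonically with taxonomic distance: congeneric species sit near
98.4% identity (distinct OTUs at the 99% threshold, merged at 97%), while
cross-phylum identity saturates near 60%. Non-anguillid fishes differ from
the host by far more than the 2% host-exclusion radius, as they must for
real prey to survive that filter.

**Communities.** Gut and snow communities are Dirichlet-multinomial: each
sample draws group fractions from a Dirichlet centred at the profile means
and splits its reads multinomially over groups, then uniformly over the
leaves within a group. The gut profile mean is Cnidaria 76% of reads (98%
Hydrozoa / 2% Anthozoa), Crustacea 7%, and nine minor groups; the snow
profile mean is Crustacea 52%, Cnidaria 21% (88/12), and eight minor
groups. Three siphonophore leaves among four Hydrozoa leaves give
siphonophores 75% of Hydrozoa reads, matching the study's "at least 75%".

Two concentrations govern realism versus estimability:

* gut concentration **1.4** — solved so the *expected minimum and maximum*
  Hydrozoa fraction across a 75-gut cohort land at roughly 4% and 99%, the
  reported per-gut span;
* snow concentration **1.5** — chosen so between-aggregate spread is strong
  (about one aggregate in eight nearly Crustacea-free, half above 50%
  Crustacea), approaching the reported pattern while keeping the 31-sample
  cohort mean interpretable.

A consequence worth stating plainly: with spreads this wide, the mean
composition of a single 31-sample snow cohort has a standard deviation of
roughly 7 percentage points (about 3 for the 75-gut cohort). Cohort-level
summaries at the study's sample sizes are therefore noisy *by construction*,
exactly as in the real survey; calibration checks in the test suite use
1,000-sample cohorts where the generator mean is pinned to well under one
point, and use the study-sized cohorts to verify that the measurement
pipeline transmits each cohort's known sampled truth to within 1.5 points.

**Reads.** Each counted read copies its leaf sequence with independent
per-base substitution errors (default 0.005, the scale of a filtered
amplicon run); indels are off by default so that ungapped and gapped
comparisons agree exactly, and can be enabled. Host contamination models
the blocking primer as a retention probability: with pre-blocking host
template fraction `h` and blocking efficiency `beta`, host reads are added
so their expected share of the emitted reads is `h (1 - beta)`. The study
reports no quantitative blocking efficiency, so the default (`h = 0.5`,
`beta = 0.9`, i.e. ~5% host reads in gut samples) is a free, explicit
parameter, not a calibrated one.

**Larvae and Hydrozoa fields.** Lengths come from a truncated normal on
[9.2, 24.7] mm whose parent parameters are moment-matched so the *truncated*
distribution has mean 15.2 and SD 2.6 — the reported statistics are sample
moments of truncated data, so matching the parent directly would bias the
mean upward by ~0.07 mm. Wet mass uses isometric scaling `W = c L^3`
anchored at 15 mm = 0.02 g. Hydrozoa fields draw station-integrated biomass
from a gamma distribution (mean 16 mg C m^-2, CV 0.6 = 9.6/16), split it
over three depth strata (0–50, 50–100, 100–200 m; epipelagic-weighted
0.45/0.30/0.25) and two taxon groups (Hydromedusae 0.55 / Siphonophorae
0.45), draw lengths lognormally around 4 and 5 mm, and back-solve the
volumetric abundance, so integration reproduces the target exactly at
CV = 0. The default length-to-carbon regression `a L^b` uses `b = 3` and
`a = 0.8` µg C mm^-3, calibrated from the study system's own pairing of
4 ind m^-3 of 5 mm siphonophores with 0.4 mg C m^-3 (100 µg C per
individual); for real data, published taxon-specific coefficients must be
substituted.

## OTU processing

`pairwise_identity()` is a full dynamic-programming global alignment with
free terminal gaps (match +1, mismatch −1, gap −2 — BLASTN-like defaults,
configurable). Identity is matches over aligned columns; coverage is the
aligned fraction of the shorter sequence (BLAST query-coverage convention);
arguments are put in canonical order first so the function is exactly
symmetric despite tie-breaking among co-optimal alignments. For *decisions*
— greedy clustering and nearest-reference assignment — identity is instead
normalized by the shorter sequence's full extent, because under free end
gaps two unrelated sequences often share a short perfect overlap that would
otherwise masquerade as 100% identity.

`greedy_cluster()` dereplicates reads, orders unique sequences by
decreasing abundance (ties lexicographic) and assigns each to the first
centroid within the threshold, else founds a new OTU — the classic greedy
centroid scheme, deterministic and order-invariant by construction. For
equal-length, substitution-only reads the membership test reduces exactly to
a mismatch count, which is accelerated by a blocked exact-substring
prefilter (with at most *k* mismatches at least 16−*k* of 16 fixed blocks
are intact); reads with indels should use `method = "align"`.

The filters implement the study's stated rules in text order: singletons,
OTUs under 9 total reads, OTUs whose centroid equals the host sequence, and
fish-lineage OTUs within 2% of the host (fish status from an explicit class
map or by nearest-reference lookup; the filter runs before taxonomy
assignment, as in the study's workflow). Samples under 1,000 reads are
dropped and samples over 10,000 reads subsampled without replacement.
Chimera formation and detection are out of scope; the generator produces
none.

## Taxonomy assignment

`score_hits()` ranks every reference by (identity, coverage, reference id)
— a total order. `assign_taxonomy()` applies the three acceptance criteria
as a conjunction: coverage ≥ 0.98, identity ≥ 0.95, and a perfect-identity
run ≥ 100 nt. Ties among passing top hits — identical (identity, coverage)
after rounding to four decimals, an explicit tie definition floating-point
scores need — resolve to the lowest common ancestor of the tied lineages.
When no hit passes, a nearest-neighbour fallback stands in for the study's
tree-placement step: if the best hit still covers the query adequately
(coverage ≥ 0.98) and its identity is at least 0.80, its lineage is assigned
truncated to family. Only the identity and perfect-run criteria are
relaxed; a poorly covered hit remains unassigned no matter how similar. The
perfect-run criterion is applied here, and not during clustering, since it
belongs to the hit-acceptance rules.

`aggregate_by_rank()` pools read counts per group at a requested rank,
with assignments shallower than that rank collected into an explicit
"unassigned" group, and normalizes rows to 1 for compositions.

## Community statistics

Counts are normalized by median-of-ratios size factors. The classic
estimator (reference features positive in every sample; medians taken on
the log scale, matching DESeq2's interpolation for even reference counts)
is the default and *fails loudly* when no all-positive feature exists.
That failure is not hypothetical: under the study design's overdispersion
virtually every OTU is absent from some sample, so the pipeline uses the
`"poscounts"` variant (geometric means over positive counts, zeros counted
in the denominator, factors rescaled to geometric mean 1) — the standard
recourse for zero-rich metabarcoding tables.

PCA operates on `log(count / s_j + 1)`; the transform is a package choice,
made explicit because the original analysis does not state one. Scores,
loadings and variance fractions come from a singular value decomposition of
the column-centred matrix.

The gut-versus-snow test is a multivariate negative-binomial
likelihood-ratio test: per OTU, intercept-only versus two-group NB
regressions with log link, offset `log s_j`, and per-OTU dispersion
estimated once by method-of-moments on normalized counts (floored at 1e-8,
the Poisson limit); the global statistic is the sum of per-OTU LR
statistics. Significance comes from permuting group labels:
`p = (1 + #{perm >= obs}) / (1 + B)`. Because the dispersion estimate
ignores the labels, the statistic is permutation-invariant in distribution
and the test is exact under exchangeability — the test suite confirms a
type-I error inside [0.03, 0.07] at the nominal 0.05 over 500 null
replicates, and this exactness is why label permutation was preferred to a
residual bootstrap, which the original analysis does not specify. Per-OTU
p-values from the same permutations are Holm-adjusted (stepdown, running
maximum, capped at 1).

## Biomass and bioenergetics

Depth integration is the textbook sum of abundance x per-individual carbon
x stratum thickness over non-overlapping strata covering 0–200 m; it is
linear in abundance and additive under stratum splitting, and both
properties are tested. The larval-occurrence regression is ordinary least
squares with the slope F-test.

The foraging model chains closed forms. A cruising larva searching a
hemisphere above its head sweeps the half-disc cross-section `pi R^2 / 2`
along its track, so the searched volume is `V = (pi R^2 / 2) u T`; the
initial static hemisphere `(2/3) pi R^3` is below 0.01% of a day's sweep
and is neglected. With R = 35 mm, u = 1 body length s^-1 for the 15 mm
reference larva (the energy-demand anchor; the cohort mean 15.2 mm is
settable) and T = 12 h, `V = 1.247 m^3` — of the same magnitude as, though
not numerically forced to, the ">1.3 m^3" a coarser rounding chain yields.
Encounters are `V D` (about 5 siphonophores per day at D = 4 ind m^-3);
ingested carbon is `V C_v` for both volumetric carbon variants, which are
carried as separate branches and never averaged; supply divides carbon by
the 15% carbon-to-dry-weight ceiling (a conservative choice — a lower true
fraction would only raise supply) and multiplies by the 2.0–5.0 kJ g^-1
energy-density interval; demand is the allometric minimum
`72.64 W^0.55 = 8.4 J day^-1` at 0.02 g. The resulting sufficiency
intervals are [0.787, 1.968] (size-based carbon) and [3.936, 9.840]
(weight-based): the first straddles, the second clearly exceeds, the
demand — the model's qualitative conclusion that siphonophores at observed
densities can cover the larval energy budget. Reports round encounters to
integers and energies to one decimal; stored values are unrounded.

## Workflow, determinism and problem sizes

`run_pipeline()` chains all stages with stage seeds derived from one master
seed; identical configurations give byte-identical artifacts, and
`validate_config()` returns violations as data rather than throwing. The
package-level analyses are desk-scale by design: the default pipeline
simulates the full study layout (75 gut + 31 snow samples x 10,000 reads,
about 1.1 million reads) in a few minutes on one core; the test suite uses
1,000-sample cohorts for calibration checks, 500 null replicates for test
size, 100 replicates for power, and 200 stations for biomass calibration —
sizes at which the Monte-Carlo error of each check is several times smaller
than its tolerance.

## What the tests show — and what they cannot

Passing tests demonstrate that the implemented machinery is correct (against
brute-force oracles and closed forms), calibrated (the generator reproduces
the compositional landmarks it was built to encode), and faithful in
transmission (the clustering-assignment pipeline recovers a known simulated
truth with sub-point bias). They cannot validate the biological claims on
real data: the generator has no chimeras, no PCR amplification bias, no
gene-copy-number variation between taxa, no quality-score structure, and
its taxonomy is a 33-leaf idealization; read tallies, OTU richness and
station-level figures of the original survey depend on the archived
sequencing data and are out of reach of simulation. The bioenergetic model
is a feasibility argument, not a dynamic energy budget: it ignores capture
success, handling time, turbulence and vertical-migration coupling.
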