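---
title: "Methods: diversity, runs of homozygosity and LD-based N_E in hybrid wolfdog breeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, runs of homozygosity and LD-based N_E in hybrid wolfdog breeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wolfdogpop` characterizes SNP-array panels from hybrid dog breeds —
populations founded within the last century by crossing a domestic breed
with wolves, then managed as closed stud books with occasional wild
infusions. Czechoslovakian-Wolfdog-like and Saarloos-Wolfdog-like histories
are the motivating systems. The package covers four analysis stages (panel
harmonization, diversity statistics, runs of homozygosity, LD-based
effective population size) plus a forward simulator that generates data with
known ground truth so every stage can be verified by parameter recovery
rather than against unavailable proprietary genotypes.

## Data model

All stages exchange a `snp_dataset`: a samples-by-SNPs matrix of dosages
(0/1/2 copies of the counted allele, `NA` for missing calls), a physical map
sorted by chromosome and 1-based base-pair position, and a sample-to-
population table. The counted allele (`allele_b`) is the minor allele
observed at load time unless an explicit allele-reference table fixes the
orientation; every statistic below is invariant under relabeling except the
sign of frequency differences, and the test suite asserts that invariance.
Non-autosomal SNPs are excluded on load; SNPs sharing a position keep the
lexicographically first id.

## Panel harmonization

Merging array panels typed on different chips requires reconciling strand
and allele order. For SNPs shared by id, a panel is brought onto the
reference panel's convention by strand-flipping reverse-complement allele
pairs and recoding dosages (`2 - x`) where the pair is listed in the
opposite order. A/T and C/G SNPs are indistinguishable from their own
strand flip, so they are removed from both panels rather than guessed;
irreconcilable allele pairs are removed and counted separately. Merging
intersects SNP sets, unions samples (duplicate ids are an error), and a
missingness filter then drops SNPs with missing calls in more than
`max_missing_samples` samples (default 6, a count rather than a rate,
matching the merged-panel convention for panels of ~100 samples). The
filter is applied after the final merge; applying it per-panel would remove
different SNPs from each source and shrink the intersection.

## Diversity statistics

Observed heterozygosity per SNP is the fraction of non-missing genotypes
that are heterozygous; expected heterozygosity is the plug-in `2p(1-p)`.
Neither uses a small-sample correction: the plug-in form is the common
array-panel convention and keeps values comparable across unequal sample
sizes. The consequence worth remembering is that plug-in `H_E`
underestimates the population quantity by a factor `1 - 1/(2n)`, so a
panmictic sample of 12 shows an apparent heterozygote *excess* of roughly
4%; genuine deficits (inbreeding, Wahlund effect) must exceed that to be
visible. Reported `H_O`/`H_E` are means over all panel SNPs with at least
one call in the population, *including* SNPs monomorphic within it —
restricting to polymorphic SNPs would inflate the means and break
cross-population comparability.

Pairwise differentiation uses the Weir–Cockerham (1984) two-population
estimator combined across loci as a ratio of averages (sum of per-locus
numerators over sum of per-locus denominators), excluding SNPs monomorphic
across both samples. The source study computed F_ST with an R package
whose estimator identity is undocumented, so exact numeric agreement with
its tables is not claimed; a Hudson-type estimator is available behind
`estimator = "hudson"` for sensitivity. Negative raw estimates (expected
when true differentiation is ~0) are clamped to zero in the reported
matrix, with raw values kept in a side channel.

## Runs of homozygosity

Detection is the sliding-window procedure standard for canine arrays: a
window of 50 consecutive SNPs is "homozygous" if it contains at most 1
heterozygous and at most 1 missing call; each SNP's support is the fraction
of overlapping windows (the actual count near chromosome edges, avoiding
edge suppression) that are homozygous; SNPs with support ≥ 0.05 are in-run;
maximal in-run stretches are split at inter-SNP gaps above 1 Mb and
emitted when they contain ≥ 20 SNPs and span ≥ 1 kb. Only the window size
(50) and the minimum SNPs per run (20) are scientifically anchored
settings; the other four knobs are the documented defaults of the
prevailing implementation, exposed in `roh_params()` and echoed in run
logs. Segment coordinates are SNP-bounded (first to last in-run SNP), so
results are reproducible from the map alone. The detector is verified
against an exhaustive window-enumeration oracle on hundreds of random
chromosomes.

Run lengths are summarized in the five canonical classes 0–2, 2–4, 4–8,
8–16 and >16 Mbp. The class bounds are half-open `[lo, hi)` — a run of
exactly 2.0 Mbp counts as 2–4 — a convention the source tables leave
ambiguous, fixed here and tested. Long runs signal recent inbreeding: an
IBD segment surviving `g` generations of recombination has expected length
`100/(2g)` cM, so >16 Mbp runs (at 1 cM/Mb) date to roughly the last three
generations. `F_ROH` is total run length over the SNP-covered genome
length (per-chromosome span of the map), the assumption-free genomic
inbreeding coefficient.

## LD-based effective population size

The expectation `E(r²) = 1/(1 + 4 N_E c) + 1/n` (Sved's relation plus the
finite-sample inflation `1/n`) links mean squared genotypic correlation at
genetic distance `c` to effective size. `r²` is the squared Pearson
correlation of dosage vectors — composite LD, appropriate for unphased
array data; no phasing is attempted. Physical distance converts to Morgans
at a constant 1e-8 M/bp (100 Mb = 1 Morgan). Distance `c` probes
`t = 1/(2c)` generations ago; trajectories cover `t = 1..30`, i.e. 90
years at the 3-year dog generation interval, which spans the entire
history of both wolfdog breeds. Bin edges sit at midpoints of adjacent
`1/(2t)` centers in `1/c` space, so the bins tile `(0, 0.5]` Morgans
without overlap.

Choices the source leaves open, fixed here and configurable in
`ne_params()`: the `t = 1/(2c)` mapping itself; MAF floor 0.05 for SNPs
entering pairs; `n` = number of genotyped individuals in the `1/n` term
(a `1/(2n)` chromosome-count variant sits behind a flag, off by default);
all qualifying pairs are computed exactly via per-chromosome correlation
matrices rather than subsampled. Bins whose mean r² does not exceed the
`1/n` sampling floor cannot be inverted and are flagged invalid rather
than dropped or smoothed. Estimates are dated
`sampling_year - 3t` (default sampling year 2021); heterogeneity in actual
collection years is not modeled.

Parameter recovery defines the accuracy claim: on constant-size
Wright–Fisher simulations (N = 100, 100 generations of drift — several
times the 30-generation lookback, enough for LD at all probed distances to
reach drift-recombination equilibrium — 50 sampled diploids, 10
chromosomes × 2,000 SNPs), the median recovered N_E over `t ∈ [5, 30]`
falls within a factor of 1.5 of truth for every tested seed, with a mild
(~10–20%) upward bias typical of composite-LD estimators. Recent-time
bins (`t < 5`, few large-`c` pairs per bin) are noisier.

## The synthetic study system

`simulate_wolfdog_scenario()` generates the default verification dataset:

* **Ancestral pool** — allele frequencies from Beta(0.8, 0.8) truncated to
  [0.05, 0.95], emulating a common-variant array spectrum (ascertainment
  is symmetric; dog-vs-wolf discovery bias is acknowledged but not
  modeled); founders at linkage equilibrium.
* **Parental pools** — a dog pool (N = 100) and wolf pool (N = 200) drift
  50 generations from the shared pool under Wright–Fisher mating with
  recombination (Poisson crossovers at 1 cM/Mb, no interference, no new
  mutation — decades are mutation-negligible, the worked product
  `mu x gen x N_E ~ 0.004` quantifies why). The dog pool spends its final
  15 generations as three closed lineages, mimicking separated stud-book
  lines; sampling the pooled lineages produces the Wahlund heterozygote
  deficit (~F(1-1/k) ≈ 13% of H) that a real multi-line breed sample
  shows. The closure depth matters: a shallower closure (~5% deficit)
  is canceled by the 1/(2n) plug-in bias at n = 12 and the pooled sample
  then shows no net deficit.
* **CSW-like breed** — founded by 4 dogs + 1 wolf, wolf infusions at
  generations 2, 4, 6 and 9 (the recorded 1960/1968/1974/1983 cadence at
  3 years per generation from a mid-1950s founding), 22 generations of 60
  offspring, moderate sire concentration (Dirichlet weight 2).
* **SAW-like breed** — a single dog × wolf founder pair, early infusions
  only (generations 3, 5, 7, 9), 29 generations of 40, heavy sire reuse
  (weight 0.25): the longer, more bottlenecked history.
* **Sampling** — 46/20/12/20 individuals (CSW-like/SAW-like/GSH-like/
  WLF-like), 1% planted missingness.

Ground truth recorded per breed: the full pedigree; per-individual
pedigree inbreeding from the tabular kinship method (verified against
Wright's path-counting formula); per-generation realized N_E over distinct
breeders, both as `4 N_m N_f / (N_m + N_f)` and with a per-sex
Crow–Denniston adjustment for offspring-number variance; and mean
heterozygosity per generation. Dams are drawn uniformly; sires by
Dirichlet-weighted popularity, recovering uniform multinomial usage in the
large-weight limit.

What passing tests on this generator do **not** show: real array data
carry ascertainment asymmetry between dogs and wolves, LD from admixture
rather than drift alone, genotyping error, and uneven marker density —
none of which are emulated. The simulator establishes that the estimators
recover what they claim from data satisfying their assumptions, not that
those assumptions hold in any particular real panel.

## Numerical and degenerate-input conventions

Monomorphic SNPs have undefined correlation and are excluded from r²
pairs; all-missing SNPs yield undefined frequencies and are flagged, not
imputed. Chromosomes with fewer SNPs than one window yield no ROH calls.
F_ST ties (minor-allele identity) break deterministically to the
alphabetically later allele. Pipeline runs are reproducible
byte-for-byte from the seed recorded in the run manifest; every stochastic
step derives from that one seed.

## Problem sizes used in the shipped verification suite

Module-level tests run on toy fixtures (≤ 15 samples × ≤ 1,000 SNPs) where
brute-force oracles are exact and instant. Simulation-recovery checks use
the default 20,000-SNP genome: 10 seeds for the constant-size N_E
recovery and 20 scenario replicates for the breed-contrast directions;
drift-expectation and infusion-heterosis properties run on reduced maps
(2 chromosomes × a few hundred SNPs) with replicate counts chosen so the
tested expectation dominates Monte-Carlo noise.

## Known limitations

Harmonization matches SNPs by id only (positional matching across builds
would need lift-over chain files, out of scope). `H_E`/F_ST carry no
ascertainment-bias correction. The N_E trajectory inherits every caveat of
the Sved relation: equilibrium assumption, composite LD, constant
recombination rate, and admixture LD contaminating drift LD at recent
horizons in hybrid populations — in the wolfdog setting the post-infusion
bins should be read qualitatively (peaks mark outcrossing events), not as
census estimates.
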