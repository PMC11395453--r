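---
title: "Models and methods behind ovipop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ovipop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

ovipop implements the analysis battery commonly applied to medium-density
SNP-array data from livestock populations — quality control, genetic
diversity, runs of homozygosity (ROH), genomic inbreeding, three
complementary selection-signature scans, a mixed-model GWAS for repeated
records, and candidate-gene annotation — together with a simulator that
generates panels with known ground truth. This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and what
the simulation-based validation does and does not establish about real data.

## The synthetic-data generator

`simulate_panel()` runs a forward Wright–Fisher simulation. Founder
haplotypes are drawn site-independently with allele frequencies from
Beta(0.5, 0.5), giving the U-shaped frequency spectrum typical of drifted
populations; random mating then proceeds for `n_generations` with Poisson
recombination (`recombination_rate_cM_per_Mb`, default 1 cM/Mb, the usual
mammalian sex-averaged figure) and symmetric per-site mutation (default
1e-6 per gamete). Mating is dioecious: an offspring's two parents are always
distinct individuals, as in a sheep flock; without this, occasional selfed
offspring (F = 0.5) dominate any autozygosity analysis. Burn-in runs at
`founder_size` and the final generation expands to `n_individuals`. The seed
fully determines the panel.

The forward model is deliberately minimal: no demography (bottlenecks,
migration), no sex chromosomes (the X is just another diploid chromosome,
appropriate for an all-female design), no gene conversion or mutation-rate
heterogeneity. Drift and linkage are real, so LD decays with distance and
related individuals share IBD segments — the features the downstream
detectors consume. Array ascertainment (the preferential inclusion of
intermediate-frequency SNPs on genotyping chips) is *not* modelled; per-bp
quantities such as windowed π are therefore not comparable to sequence-based
values, on simulated or real arrays alike.

Three planting operations create ground truth:

* `plant_autozygosity()` copies one haplotype over the other across a
  region — exact homozygosity with known bounds.
* `plant_sweep()` raises the minor allele at the focal marker to a target
  frequency by copying a single donor haplotype onto every final carrier.
  Each copy extends outward over an exponential window on either side of
  the core (mean `1/escape_rate`; default 1 Mb per side), an analogue of
  recombinational escape during a sweep. This homogenizes the swept class —
  extended haplotype homozygosity and a locally distorted frequency
  spectrum — while keeping the focal position and final frequency exact.
  It is a construction, not a selection simulation: the temporal dynamics
  and the diversity of partially swept haplotypes are absent, so detector
  power on these fixtures bounds, but does not equal, power on real sweeps.
* `plant_qtl()` redraws one marker's genotypes at a chosen allele
  frequency, deliberately free of LD with its neighbours, so GWAS hits can
  be attributed unambiguously.

`simulate_phenotypes()` generates repeated litter-size records as
y = mean + parity + year + season + dosage·effect + a + pe + e, with the
additive values drawn jointly with covariance `var_additive`·GRM — the same
VanRaden GRM the estimation stage uses, so simulation and inference share
one relationship matrix by construction. Defaults describe a prolific
meat-sheep flock: mean litter size 2.36, unit latent variance split
0.1/0.1/0.8 (heritability 0.10, repeatability 0.20), three records per ewe
at parities 1–3. Litter size is generated as Gaussian on the latent scale,
not as a count; the repeatability model treats it the same way, but users
applying the package to real counts should note the scale mismatch at the
extremes.

## Quality control and input formats

`qc_filter()` removes SNPs failing, in order: call rate < 0.95, minor
allele frequency < 0.05, Hardy–Weinberg exact-test p < 1e-6. The exact test
is the standard two-sided enumeration over heterozygote counts with no
mid-p adjustment. Each SNP is charged to the first criterion it fails, so
the removal report reads like a sequential filtering log. Missing genotypes
are then filled with the per-SNP major-allele homozygote — a deliberate,
transparent single-marker rule rather than haplotype imputation. Under the
0.95 call-rate floor the fill can move an allele frequency by at most the
missing rate (≤ 5%); haplotype statistics (EHH, iHS) require panels that
are phased by construction (the simulator, or phased VCF input), and refuse
unphased data rather than phase it.

PLINK ped/map and binary bed/bim/fam (SNP-major) and VCF (GT field, `|`
preserved as phase) are supported in both directions. Coordinates are
1-based inclusive everywhere inside the package; the only 0-based,
half-open conversions happen at BED file boundaries.

## ROH detection

The minimum run length in SNPs is the false-positive-controlled count
l = ⌊ln(α/(n_s·n_i)) / ln(1 − het)⌋ with α = 0.05; the same l is both the
sliding-window size and the minimum SNPs per emitted run (the two are
coupled in sliding-window detectors). Flooring is the default and a ceiling
is available. A window is eligible when it has at most one heterozygous and
one missing call; a SNP is in-run when at least 5% of the windows covering
it are eligible. Maximal stretches of in-run SNPs are then segmented
greedily from the left so that every emitted run itself satisfies the
het/missing allowances and the 1 Mb maximum gap — without this the lenient
window threshold can chain two distant heterozygous sites into one run that
violates the allowance. Runs are finally filtered by minimum length (1 Mb),
minimum SNP count (l), and density (≥ 1 SNP per 500 kb). Segment bounds are
the first and last SNP positions, so a planted region's detected length is
underestimated by at most one marker spacing per side, and boundary SNPs
just outside a homozygous block can be pulled in (at most one heterozygous
SNP, by the allowance). A brute-force re-implementation with explicit loops
ships in the test helpers and the detector is required to match it
segment-for-segment on random small panels.

## Inbreeding coefficients

F_ROH divides an individual's summed ROH length (total, or within the
1–5 / 5–10 / 10–20 / >20 Mb classes, half-open at the upper bounds) by the
mapped genome length, defined as the per-chromosome span between first and
last markers. F_HOM uses the PLINK `--het` formula with the small-sample
2n/(2n−1) correction; F_GRM is the VanRaden GRM diagonal minus one; F_UNI
averages the per-site uniting-gametes correlation. All three use sample
allele frequencies from the analysed panel and exclude monomorphic sites
(whose contributions are degenerate or undefined). Correlations among the
eight coefficients are plain Pearson with t-distribution p-values and
significance stars at 0.01 / 0.001.

## Selection signatures

**ROH islands.** Per-SNP incidence is the fraction of individuals whose
segments cover the marker; SNPs at or above the top-1% empirical quantile
(ties included) are merged into islands when within 1 Mb of each other.

**CLR.** The composite likelihood ratio compares, at each grid point (one
per 50 kb from the chromosome start), a sweep model of the folded site
frequency spectrum against the genome-wide background. The sweep model is a
star-like escape approximation: at distance d a lineage escapes the sweep
with probability p_e = 1 − exp(−αd); the escapees are a binomial draw from
the pre-sweep frequency and the non-escapees coalesce into one lineage.
Integrating over the empirical background spectrum this collapses to the
closed form

P(D = j | p_e, p) = (1 − p)·Binom(j; n, p_e·p) + p·Binom(n − j; n, p_e·(1 − p)),

which makes the scan a table lookup (escape probabilities discretized into
200 log-spaced bins; mixture frequencies into ≤ 40 classes). Only
segregating sites enter, probabilities are conditioned on segregation and
folded, and the background model is the p_e → 1 limit of the same family —
so the null is nested, distant sites contribute nothing, and CLR =
2(max_α logL_sweep − logL_bg) is clamped at zero. The intensity grid is 12
log-spaced values spanning sweep widths from roughly 10 kb to 100 Mb. The
top 1% of grid points (ties included) are flagged and merged into candidate
regions.

**iHS.** EHH for a core allele is the probability that two random carrier
haplotypes are identical from the core to a marker, computed by
partition refinement; it is 1 at the core and non-increasing outward. iHH
integrates EHH over physical distance by the trapezoid rule until EHH
drops below 0.05 (chromosome ends truncate the integral; such cores are
kept, a known conservative bias shared with standard implementations).
iHS = ln(iHH_ancestral/iHH_derived) is standardized to mean 0, s.d. 1
within derived-allele-frequency bins of width 0.025 (bins with fewer than
two scores are dropped), and mapped to p_iHS = −log10(1 − 2|Φ(iHS) − 0.5|),
computed as −log10 of the two-sided normal tail for numerical stability.
Ancestral alleles are unknown on arrays; the major allele stands in by
default (an `ancestral` argument overrides), and the frequency-bin
standardization absorbs most mispolarization. The windowed test scores
500 kb windows advancing 400 kb (100 kb overlap) by the mean p_iHS of their
SNPs and flags the top 1%.

**Consensus.** The genomic footprint covered by at least two of the three
candidate-region sets (islands, CLR regions, iHS windows) is reported, with
the supporting methods listed per interval.

## The repeatability-model GWAS

The null model y = Wα + Xβ + Zμ + e has fixed parity/year/season effects,
an additive polygenic effect with GRM covariance, a permanent-environment
effect per ewe, and an i.i.d. residual. The restricted likelihood is
profiled on σ²e and maximized over the two variance ratios by
coordinate-wise golden-section search, declared converged when the
restricted log-likelihood moves by less than 1e-6 between sweeps (at most
200 sweeps); ratios live on [0, 50] and the zero boundary is checked
explicitly, so all components are non-negative by construction. The algebra
runs at individual level via the Woodbury identity in the eigenbasis of the
GRM, with a fully diagonal fast path when every ewe has the same record
count. Single records per ewe make σ²pe unidentifiable and raise an error.

Per-SNP tests hold the variance components at their null estimates and add
the SNP dosage to the fixed part (the standard two-stage, EMMAX-style
approximation); effects and standard errors come from generalized least
squares with the record-level covariance, significance from a 1-df Wald
chi-square. λ_gc is the median association chi-square over 0.4549364.
Benjamini–Hochberg at q = 0.005 supplies the significance flags and the
implied −log10 p threshold. In parameter-recovery simulations the
non-negativity constraints leave a small positive finite-sample bias
(order 0.005 on a unit-variance trait) in the individual-level components;
the validation suite therefore checks Monte-Carlo means within three
standard errors.

## Annotation

Consensus regions are used as-is; significant SNPs are expanded by ±250 kb
(clipped at position 1). A gene is reported when its interval shares at
least one bp with the query, regardless of strand — flanking distance, not
transcriptional direction, is what the ±250 kb convention means. GFF3 input
keeps `gene` features; BED is converted to 1-based inclusive internally.
Functional enrichment is out of scope: it depends on live external
databases, and the gene lists are this package's terminal output.

## Validation design and problem sizes

The test suite validates by recovery on simulated panels with planted
truth, at sizes chosen to keep the full suite comfortably reproducible on a
laptop: ROH detection is checked segment-for-segment against brute force on
100 random ≤ 50-SNP panels; F_ROH recovery plants 1/5/10% autozygosity on
8000-SNP panels bred as single-generation crosses of 500 outbred founders,
so the planted segments are the only autozygosity present; CLR localization
uses 20 paired sweep/neutral panels of 2000 SNPs × 200 individuals on a
50 Mb chromosome (25 kb marker spacing, comparable per-window SNP counts to
a 50K ovine array); GWAS calibration and power use 500 ewes × 3 records
with 20 genotype permutations, 20 QTL replicates, and 60 variance-recovery
replicates on panels bred from 40 founders over 80 generations — a deep
pedigree whose relationship spread is what separates the additive from the
permanent-environment component.

Passing these tests shows the implementations are internally correct and
that the detectors recover planted truth under drift-plus-linkage panels.
It does not certify performance on real arrays, where ascertainment,
genotyping error, map errors, and true demography all matter; parameter
defaults (QC thresholds, ROH allowances, scan window sizes) follow standard
array practice and should be revisited for other marker densities.

## Known limitations

* Major-allele filling is not imputation; at the 5% missingness ceiling its
  effect is bounded but real, and haplotype statistics require pre-phased
  input.
* The CLR sweep model is a star-like approximation (no intra-sweep
  genealogy) on the folded spectrum; it trades some power for robustness to
  unknown ancestral states.
* iHS near chromosome ends is conservative (truncated integrals).
* The simulator's sweeps and QTLs are constructions with exact truth, not
  population-genetic processes; power estimates on them are optimistic for
  weak or old selection.
* Windowed π on array SNPs is not an estimate of sequence diversity.
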