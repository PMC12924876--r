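---
title: "Methods: sliding-window runs of homozygosity, heterozygosity-rich regions, and island calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window runs of homozygosity, heterozygosity-rich regions, and island calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runscan)
```

## Scope and model

`runscan` implements the genomic-characterization workflow used for dense
SNP-array studies of livestock populations: quality control of PLINK text
genotypes, per-breed diversity indices, identity-by-state (IBS) population
structure, sliding-window detection of runs of homozygosity (ROH) and
heterozygosity-rich regions (HRR), per-individual and per-breed run
statistics, and the calling of ROH/HRR "islands" — genomic intervals where
runs recur across many individuals of a breed, a standard screen for
selection signatures.

A ROH is an uninterrupted stretch of homozygous genotypes in one
individual, reflecting autozygosity; its genome fraction
`F_ROH = S / L_genome` (total ROH length over SNP-covered autosomal
length) is a genomic inbreeding coefficient. An HRR is the heterozygous
analog, of interest for balancing selection and hypervariable regions; its
genome fraction is written `D_HRR`. Both are detected with the same
sliding-window machinery, differing only in which genotype counts as
"opposite" and in the window/length thresholds.

## Sliding-window run detection

For one individual on one chromosome of `m` mapped SNPs, a window of `w`
consecutive SNPs slides one SNP at a time (windows are index ranges
`[i, i+w-1]`, so there are `m - w + 1` of them and none when `m < w`). A
window passes when it holds at most `max_opposite_in_window` opposite
genotypes (heterozygotes in HOM mode, homozygotes in HET mode) and at most
`max_missing_in_window` missing calls. Each SNP is then scored by the
fraction of windows *fully containing it* that pass; the SNP is classified
in-run when this proportion strictly exceeds `prop_threshold`. Maximal
stretches of in-run SNPs become candidate runs, which are split at
inter-SNP gaps above `max_gap_bp` and then kept only if they hold at least
`min_snps` SNPs, span at least `min_length_bp` (span = last SNP bp − first
SNP bp) and reach the density `n_snps >= span * min_density_snp_per_bp`.

Defaults, chosen for high-density (600K-class) ovine arrays:

| parameter | ROH (HOM) | HRR (HET) | unit |
|---|---|---|---|
| `window_snps` | 50 | 15 | SNPs |
| `max_opposite_in_window` | 0 | 0 | genotypes |
| `max_missing_in_window` | 0 | 0 | genotypes |
| `prop_threshold` | 0.05 | 0.05 | fraction of windows |
| `min_snps` | 50 | 15 | SNPs |
| `min_length_bp` | 1,000,000 | 100,000 | bp |
| `max_gap_bp` | 1,000,000 | 1,000,000 | bp |
| `min_density_snp_per_bp` | 1/100,000 | 1/100,000 | SNPs per bp |

Numerical choices worth stating explicitly:

* **Edge windows.** A SNP's proportion denominator counts only windows
  fully contained in the chromosome (`c_j = min(j, m-w+1) - max(1, j-w+1)
  + 1`); no phantom windows are imagined beyond the ends. One consequence,
  verified in the unit tests, is that a long homozygous stretch flanked by
  heterozygous background is trimmed by exactly the SNPs whose passing
  containing-window count falls at or below `prop_threshold * c_j` — with
  the HOM defaults, two SNPs at each end of an interior stretch.
* **Strictness.** The proportion comparison is strict (`> 0.05`), and the
  same threshold is applied in HET mode for symmetry, where a single
  passing 15-SNP window is already enough to flag its members
  (`1/15 > 0.05`).
* **Gap before size.** Gap splitting precedes the count/length/density
  filters: a gap invalidates contiguity first, then the surviving pieces
  are judged.
* **Chromosomes shorter than the window** yield no windows and hence no
  runs.
* **Length convention.** Run and island lengths are `end_bp - start_bp`
  on 1-based inclusive SNP-anchored intervals, matching how published
  island tables in this field print their lengths. The BED export converts
  to 0-based half-open coordinates.

`detect_runs()` computes window and per-SNP counts with cumulative sums;
`oracle_detect_runs()` re-derives the same result by explicit enumeration
of every window and every SNP's containing windows. The two are required
to agree exactly, and the test suite drives both over randomized planted
datasets (the acceptance suite uses 50 datasets of 5 individuals and
200–2,000 SNPs in both modes).

## Run statistics

Per individual and mode: run count `N`, mean length `L` (Mb), total length
`S` (Mb) and `F = S / L_genome`. The genome length defaults to the
SNP-covered length (sum over chromosomes of last-minus-first SNP bp),
with a configuration override for studies that standardize on a constant
(e.g. 2.4 Gb for the ovine autosomes). Per breed, means and sample
standard deviations (n − 1) are taken over individuals; individuals with
zero runs are included with `N = 0` by default, which keeps
`N_mean * n_individuals = total_runs` an exact identity. Published tables
sometimes average only run-carrying individuals — the two conventions
differ detectably, so `breed_summary(zero_runs = "exclude")` provides the
alternative. Runs are also tallied into five right-open length classes
([1,2), [2,4), [4,8), [8,16), [16,∞) Mb for ROH; (0,150), [150,200),
[200,300), [300,400), [400,∞) kb for HRR); right-open edges make the
classes a partition, so the class counts conserve the total.

## Island calling

For each breed, every SNP gets an occurrence fraction: the share of the
breed's genotyped individuals whose runs cover it. The calling threshold
is the top-0.1% occurrence value under the nearest-rank rule
(`k = ceiling(0.001 * n_snps)`, threshold = k-th largest, ties admitted —
the rank rule is exact and deterministic where interpolating quantile
estimators are not). The threshold is computed over all SNPs of the map
(a flag restricts it to SNPs with non-zero occurrence). Qualifying SNPs
must also clear a strict absolute floor — occurrence > 0.20 for ROH
islands, > 0.30 for HRR islands — and islands are maximal stretches of
map-consecutive qualifying SNPs with at least `min_island_snps = 2`
members ("adjacent SNPs" implies plurality; no published minimum exists,
so the value is configurable). Genes from a user-supplied interval table
are assigned by ≥ 1 bp overlap of closed intervals. Shared regions across
breeds report every maximal set of breeds whose islands intersect within a
connected component of overlapping islands; subsets of a reported larger
set are suppressed, which is what makes "one region shared by three
breeds" a single row rather than four.

## Diversity indices and structure

Observed heterozygosity `H_O` is the mean per-SNP heterozygote fraction;
expected heterozygosity `H_E` uses the small-sample-corrected estimator
`2p(1-p) * 2n/(2n-1)`. The per-individual inbreeding coefficient is the
method-of-moments `F = (O_hom - E_hom)/(L - E_hom)`, and the breed's
`F_IS` is the mean ± s.d. over individuals — the per-individual route is
chosen because published breed values carry standard deviations, which
implies individual values exist. Frequencies default to within-breed
(indices are reported per breed); a pooled option exists because sources
rarely state which was used. IBS between two individuals is the mean of
`(2 - |g_i - g_j|)/2` over pairwise-complete SNPs and `1 - IBS` is the
stored distance; LD pruning (greedy, physical 50 kb window, 10-variant
step, r² > 0.5 removes the lower-MAF member, tie broken toward the later
position) precedes the structure analyses only — runs and islands use the
full QC'd set. The printed "50 kb window, 10-variant step" mixes physical
and count units; the physical reading is implemented as stated, and a
SNP-count window (`ld_prune_params(window_snps = )`) is available since
the PLINK idiom uses marker counts. r² is the squared Pearson correlation
of 0/1/2 codes over pairwise-complete individuals (composite LD — no
phasing, standard for unphased array data). Classical (Torgerson) MDS
double-centers `-D²/2` and eigendecomposes; negative and numerically-zero
eigenvalues are truncated to zero (with a warning for genuinely
non-Euclidean input), and each coordinate column's largest-magnitude entry
is made positive so results are deterministic.

Quality control runs in a fixed order — autosomes only, SNP call rate
(strict `> 0.95`), individual call rate (strict `> 0.90`), then MAF
(inclusive `>= 0.01`) on the surviving individuals — mirroring common
PLINK practice of computing MAF after sample removal; the order is fixed
so attrition reports are deterministic. Genotypes are coded 0/1/2/NA with
allele 1 = first allele seen in the file. Only het/hom/missing states
matter downstream, so 0/2 polarity is meaningless; one documented
consequence is that a written-and-reread dataset preserves codes exactly
only when each SNP's first non-missing call is 0 or 1 (always true of
datasets that came from disk), since the first-seen rule otherwise flips
the polarity of the 0/2 codes.

## The synthetic generator

`simulate_dataset()` emulates the study design the package targets: a few
breed groups of tens to ~150 individuals, 2–26 autosomes with ~4 kb mean
marker spacing (exponential inter-SNP gaps, rounded up to ≥ 1 bp), per-SNP
allele frequencies uniform on 0.05–0.95, Hardy-Weinberg background
genotypes, optional Bernoulli missingness, and planted tracts: homozygous
tracts draw one allele per SNP at its frequency and double it, so carriers
are homozygous but not allele-identical; heterozygous tracts set carriers
heterozygous. Carriers are sampled without replacement to match the
requested fraction. Missingness is excluded inside planted tracts by
default so that the zero-missing window rule cannot fragment planted
runs; a flag restores uniform missingness for robustness checks.

The background has **no linkage disequilibrium** (independent SNPs) and no
demography, mutation or pedigree structure. That is deliberate: an
LD-free HWE background makes the null analytically tractable (with
frequencies in 0.2–0.8 the chance of a spurious 50-SNP homozygous window
is below 1e-9 per window, so zero background ROH calls is the expected
outcome, and `F_IS` is centered at zero), and planted tracts exercise the
entire run/island path with known truth. The corollary is what passing
tests do *not* show: recovery fidelity on real data with LD, autozygosity
from genuine inbreeding, array-specific genotyping error, or ascertainment
bias is not measured here. `evaluate_recovery()` reports per-carrier
bp Jaccard between planted and detected intervals, aggregate bp
precision/recall, and whether an island was called inside the tract.

Validation problem sizes were chosen once: tract recovery uses one breed
of 50 individuals on a 3,000-SNP chromosome (~12 Mb) with a 400-SNP
(~1.6 Mb) homozygous tract or a 100-SNP (~0.4 Mb) heterozygous tract at
carrier fraction 0.5; at these sizes detection recovers carriers with
mean Jaccard above 0.95 and the called island falls inside the tract.

## Pipeline and reproducibility

`run_pipeline()` executes ingest/simulate → QC → diversity → LD prune →
IBS/MDS → ROH → HRR → summaries → islands → annotation from one validated
configuration (R list or YAML), writes every table as TSV/JSON under the
output directory with a manifest (configuration echo, dataset
fingerprint, package version), and is byte-deterministic given the seed.
Degenerate inputs fail with the stage name: missing input files at
ingest, an empty post-QC dataset at qc, breeds of fewer than two
individuals at diversity.

## Known limitations

* Sliding-window edge behavior in the first/last `w - 1` SNPs follows the
  fully-contained-window definition above; other implementations leave
  their edge handling implicit, so bit-for-bit agreement with them is not
  claimed — the package's own brute-force oracle is the reference.
* Island fixation percentages are means over member SNPs of run
  occurrence, so they depend on the detection parameters upstream.
* The IBS matrix is computed densely; for cohorts far beyond a few
  thousand individuals a blocked implementation would be preferable.
* ADMIXTURE-style ancestry estimation, tree building/plotting, variant
  consequence prediction and live annotation-database queries are out of
  scope; the package exports the distance matrices, coordinates and
  interval tables those tools consume.
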