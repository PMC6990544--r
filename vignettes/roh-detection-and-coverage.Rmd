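---
title: "Scanning-window ROH detection and coverage-aware inbreeding estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning-window ROH detection and coverage-aware inbreeding estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohcov)
```

## The problem

A run of homozygosity (ROH) is a long uninterrupted stretch of homozygous
genotypes, taken as evidence that the two chromosome copies descend from a
recent common ancestor. The genomic inbreeding coefficient

$$F_{ROH} = \frac{L_{ROH}}{L_{aut}}$$

divides an individual's total ROH length by the autosomal genome length.
On medium-density arrays (≈ one SNP per 50 kb) ROH are usually called with
a scanning-window detector whose nine settings interact in non-obvious
ways; several common choices leave substantial parts of the genome where
no ROH can be detected *at all*, silently deflating $F_{ROH}$. This
package implements the detector, and — its central point — makes the
detectability loss measurable and correctable.

## The detector

Detection runs per individual and chromosome in three steps.

**1. Window hit rates.** A window of `window_snp` consecutive SNPs slides
one SNP at a time; only windows lying fully on the chromosome count. A
window is *homozygous* when it contains at most `window_het` heterozygous
and at most `window_missing` missing calls. Each SNP's hit rate is the
fraction of windows containing it that are homozygous. Two conventions
the algorithm needs but the usual description leaves open are fixed here:
near chromosome ends the denominator is the number of windows actually
containing the SNP (fewer than `window_snp`), and a chromosome shorter
than the window has zero windows, hence all-zero hit rates.

**2. Thresholding.** SNPs whose hit rate is at least `window_threshold`
form maximal candidate runs. The comparison is `>=`: with a window of 100
and threshold 0.05, a SNP appearing in exactly five homozygous windows
qualifies. Runs are trimmed so both ends are homozygous, non-missing
calls — a segment bounded by a heterozygous or missing call is not
defensible.

**3. Splitting and filtering.** Each candidate run is (i) split at every
adjacent-SNP interval wider than `max_gap_kb`; (ii) while a piece
contains more heterozygous calls than `max_het`, split at the first
(leftmost) heterozygous SNP, excising it — the offending call belongs to
neither flank; (iii) re-trimmed to homozygous ends; (iv) kept only if its
mean spacing `length_kb / n_snp` does not exceed `max_density`, its
length reaches `min_kb` and its SNP count reaches `min_snp`. Segments may
end up shorter than the scanning window; no lower bound of `window_snp`
is imposed. Missing calls inside a final segment are tolerated without
limit (only `window_missing` constrains them).

Where the three-step description is ambiguous, the package fixes a
deterministic rule and documents it: gap splitting precedes heterozygote
splitting (observable only in rare composite cases); the leftmost-het
excision rule above (any deterministic choice preserves the qualitative
behaviour; this one guarantees the left piece is het-free and terminates);
and segment length is the inclusive bp span `(end - start + 1)/1000` kb.
Chromosome length uses the same inclusive convention, which makes the
coverage identities below exact rather than off by one bp per chromosome.

## Genome coverage and the two estimators

A parameterization's *genome coverage* is measured by construction: build
an individual whose every call is homozygous on the population's own map
(`homozygous_individual()`), run the detector on it with exactly the
settings under evaluation, and sum the detected lengths. That total is
the maximal detectable ROH length $L_{cov}$; coverage is
$100 \cdot L_{cov} / L_{aut}$. Two estimators follow:

$$F_{ROH,aut} = L_{ROH}/L_{aut} \qquad F_{ROH,cov} = L_{ROH}/L_{cov}$$

$F_{ROH,cov}$ corrects the bias of incomplete coverage; because detected
segments are disjoint sub-intervals of each chromosome's span,
$L_{cov} \le L_{aut}$ and hence $F_{ROH,cov} \ge F_{ROH,aut}$ exactly,
for every individual and every setting. Coverage of the all-homozygous
individual is invariant to `window_threshold` (its hit rates are 1
everywhere windows exist) and monotone non-decreasing in `max_gap_kb` and
`max_density`; the test suite asserts all three properties on constructed
maps.

## Parameters that matter, and defaults

| setting            | meaning (units)                        | constructor default | evaluation baseline |
|--------------------|----------------------------------------|---------------------|---------------------|
| `window_snp`       | scanning window size (SNPs)            | 50                  | 20                  |
| `window_het`       | max het calls per window               | 1                   | 0                   |
| `window_missing`   | max missing calls per window           | 5                   | 1                   |
| `window_threshold` | hit-rate threshold                     | 0.05                | 0.05                |
| `min_snp`          | min SNPs per ROH                       | 100                 | from `lencz_min_snp()` |
| `min_kb`           | min ROH length (kb)                    | 1000                | 1000                |
| `max_density`      | max mean spacing (kb/SNP)              | 50                  | 200                 |
| `max_gap_kb`       | max adjacent-SNP interval (kb)         | 1000                | 2000                |
| `max_het`          | max het calls per final ROH            | unlimited           | 0                   |

`roh_params()` defaults mirror PLINK's, because users arrive with those
habits; `baseline_params()` is the permissive one-factor-at-a-time
evaluation baseline (small window, large gap, high density ceiling). The
density default deserves emphasis: 50 kb/SNP is roughly the *average*
spacing of a medium-density array, so on such data half the candidate
segments sit near the threshold — `cmd_detect()` warns whenever
`max_density` was left defaulted, and always writes the coverage report.

Two derived settings have closed forms. The minimum SNP count uses the
Lencz/Purfield rule
$L = \ln(\alpha/(n_s n_i)) / \ln(1 - het)$
with $n_s$ SNPs per individual, $n_i$ individuals, tolerated expected
false-positive count $\alpha$ (0.05), and mean heterozygosity $het$; the
real-valued $L$ is rounded *up* (a minimal count must be an integer and
the ceiling is the conservative closure; floor of 1). The window
threshold for excluding $N_{out}$ chance-homozygous outer SNPs per side is
$t = floor((N_{out}+1)/L,\,3)$, floored to three decimals
(`window_threshold(100, 4)` = 0.05); flooring to zero is an error rather
than a silent always-pass threshold.

## Pruning

MAF filtering (`maf_filter()`) removes SNPs with minor allele frequency
strictly below the threshold, computed over non-missing calls with an
integer numerator (`min(count_A, count_B) / 2n`) so boundary values like
0.20 compare exactly. LD pruning (`indep_pairwise()`) is greedy and
windowed: within each window of 50 consecutive kept SNPs (step 5), one
member of every pair with dosage $r^2$ above the threshold is removed,
and passes repeat until no window contains a violating pair. The victim
rule — remove the smaller-MAF member, ties remove the later SNP — is a
deterministic choice approximating PLINK 1.9; $r^2$ is the squared
Pearson correlation of 0/1/2 dosages over pairwise-complete individuals
(composite LD; the data are unphased). Undefined $r^2$ (monomorphic or
near-empty SNPs) never triggers removal. Note the package's sweeps exist
to *measure* what pruning does to ROH detection — the usual finding being
that both MAF and LD pruning can erase real homozygous regions — not to
recommend it.

## The synthetic-data generator

`synth_generate()` emulates the data regime the detector is meant for:
per-chromosome maps at a stated mean spacing (uniform, or
gamma-distributed with shape 4 for realistic irregularity and occasional
wide gaps), per-SNP allele frequencies drawn uniformly from a MAF range,
Hardy–Weinberg background genotypes drawn independently per SNP, planted
homozygous segments specified in SNP indices (so their bp truth is exact
on any spacing model), and independent missingness. Supplying
`background_het` instead fixes the constant allele frequency solving
$2f(1-f) = het$. Two simplifications are deliberate and matter for
interpretation: there is no background LD (each test isolates its own
assumption; `ld_block_map()` adds block LD when a test needs it, with
copy probability $r2^{1/4}$ so the expected pairwise dosage $r^2$ within
a block equals the target), and no pedigree or coalescent structure —
planted segments are exogenous, not inherited. Passing tests therefore
demonstrate algorithmic correctness and calibration on idealized array
data, not robustness to haplotype structure, genotyping error beyond
missingness, or array ascertainment bias.

Default study conditions used by the recovery tests: 20 individuals,
3 chromosomes × 1000 SNPs at 50 kb, background heterozygosity 0.32,
missingness 1%, planted segments of 40–80 SNPs (2–4 Mb), `min_snp` from
the Lencz rule. At these sizes the full suite (including ~240
brute-force oracle comparisons) runs in well under a minute; the sizes
are chosen so every regime of the detector (edge windows, gap splits,
het excision, density rejection) actually occurs.

## Numerical choices and degenerate inputs

- Hit-rate comparison uses a $10^{-9}$ guard below the threshold; rates
  are ratios of small integers, so the guard can only absorb float noise,
  never admit a genuinely smaller rate.
- `window_threshold()` computes `floor((n_out + 1) * 1000 / window_size)`
  on an integer numerator for the same reason.
- All-missing SNPs have undefined MAF and undefined $r^2$; they are
  removed by `maf_filter()` at any positive threshold and never counted
  as LD violations.
- Single-SNP chromosomes contribute one bp of length and are warned
  about; chromosomes shorter than the window contribute zero coverage.
- A/B allele labels are assigned per SNP by first observation in the
  `.ped` file. The labels are arbitrary and invisible to every statistic;
  the only observable consequence is that re-reading a written file can
  swap 0 and 2 at SNPs whose first non-missing call was HOM-B.

## Known limitations

Exact bit-compatibility with any particular PLINK build is not promised —
PLINK's handling of windows at chromosome ends has undocumented corner
cases; correctness here is defined by the three-step description above
and verified against an independent brute-force enumeration. Sex
chromosomes, binary `.bed` input, VCF, consensus ROH across individuals
and model-based HBD inference are out of scope.
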