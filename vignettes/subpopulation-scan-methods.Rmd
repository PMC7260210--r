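---
title: "Methods: characterizing and scanning two subpopulations of one breed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing and scanning two subpopulations of one breed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpopscan)
```

This vignette is the package's own account of its statistical machinery:
the models and rules each stage implements, the parameters that matter and
their defaults, what the synthetic-data generator does and does not
emulate, and the choices we made where the methodology was genuinely open.

## The setting

Two subpopulations of a single breed — think of a beef breed raised both in
its source country and abroad — are genotyped on SNP arrays, imputed and
phased upstream, and reduced to a shared marker panel. Two kinds of
questions follow. *Global*: how much overall diversity, relatedness,
inbreeding and LD does each gene pool carry, and how well do linkage phases
transfer between them (the decisive quantity for pooling them in genomic
prediction)? *Local*: which genomic regions show the footprint of
selection, either shared (both subpopulations autozygous at the same place)
or divergent (allele frequencies or LD structure pulled apart)?

## Quality control

The analysis panel is produced by four filters, in a fixed order that the
QC log records: sample call rate ≥ 0.90, SNP call rate ≥ 0.90 (recomputed
after sample removal), a Hardy–Weinberg screen, and restriction to SNPs
polymorphic in the pooled sample (for two separate input panels,
`keep_shared_polymorphic()` additionally intersects the maps and
reconciles swapped ref/alt coding; mismatched allele pairs are dropped —
strand flips are deliberately not guessed).

The HWE test is the 1-df chi-square goodness-of-fit test at the sample
allele frequency, applied **within each subpopulation** with a SNP removed
if it fails in either (threshold `p < 1e-5`). Two open choices sit here.
Chi-square vs exact test: at a few hundred samples per group and a 1e-5
threshold the two agree except at very rare genotype classes, and the
chi-square is the array-era convention; we use it. Pooled vs per-group
application: testing within groups avoids flagging SNPs whose pooled
genotype counts deviate merely because the groups differ in frequency (a
Wahlund effect, which is signal for this package, not artifact); both
scopes are exposed via `scope =`.

## Relationships and inbreeding

`compute_grm()` implements the VanRaden method-1 matrix with a **fixed**
base allele frequency `p0` (default 0.5) for every SNP:
`G = ZZ'/(2 m p0 (1-p0))`, `Z = dosage - 2 p0`. Fixing `p0 = 0.5` rather
than using observed frequencies makes the scale independent of the sample
composition — important when the point is to compare two groups — and
yields an exact algebraic identity, `F_GRM = G_ii - 1 = 1 - 2 het_i`,
which the test suite verifies to 1e-12 on every panel. PCA of `G` is a
full dense eigendecomposition (sample counts here are hundreds, not tens
of thousands); coordinates are eigenvectors scaled by the square root of
their eigenvalues, and small negative eigenvalues are floored at zero for
variance proportions only.

## Runs of homozygosity

Two detectors are provided because the field uses both and their agreement
is itself a check:

* `detect_roh_sliding()` is the PLINK-style two-stage algorithm: windows
  of 30 SNPs pass when they hold at most 1 heterozygote and 0 missing
  calls; a SNP is "in run" when at least 5% of the windows spanning it
  pass; maximal in-run stretches become candidate segments.
* `detect_roh_consecutive()` extends runs SNP by SNP, closing a run just
  before a heterozygote that would exceed the budget and restarting just
  after it, so every reported sub-run again holds at most one heterozygote.

Both then apply identical screens: split at adjacent gaps > 1 Mb, keep
segments ≥ 1 Mb with mean spacing ≤ 120 kb (a mean-density rule in PLINK's
sense, not a per-gap rule — the per-gap rule is the 1 Mb split). The 5%
hit-rate threshold is not printed in most papers but is the PLINK default
that gives the scanning window its meaning. The missing-call allowance
defaults to 0 because the package expects imputed or synthetic (complete)
panels; it is configurable.

Marker density matters here: with the density screen at 120 kb per SNP, a
map much sparser than ~1 SNP / 100 kb cannot support ROH detection, so the
ROH-oriented experiments in the tests use ~50 kb spacing (usual array
density) while the LD/F_ST experiments use ~100 kb.

`f_roh()` divides summed segment length by the map-covered genome (sum
over chromosomes of last-minus-first SNP position). Island calling takes
the per-SNP autozygosity score (fraction of a subpopulation's samples
whose ROH set covers the SNP, boundaries inclusive), thresholds it at the
genome-wide 99.9th percentile (linear-interpolation percentile of the
score distribution), and requires **at least two map-adjacent SNPs
strictly above** the threshold. Strict exceedance makes the degenerate
constant-track case well-defined (no islands). Because autozygosity scores
are discrete (k/n), ties at the threshold are common and the strict rule
also prevents entire plateaus from being called on a tie.

`generations_to_ancestor()` applies the expectation that an autozygous
segment of length `L` cM coalesces ~`100/(2L)` generations back, with the
1 cM/Mb bovine convention; the integer part is reported.

## Linkage disequilibrium and persistence of phase

All LD is computed on phased haplotype columns: `r` is the correlation of
the two alternate-allele indicator vectors, identical to
`D/sqrt(p_i q_i p_j q_j)`. Pairs involving a SNP monomorphic within the
analyzed group are **excluded as undefined, never zeroed** — zeros would
drag decay curves toward 0 in exactly the low-MAF bins where the bias
matters most. Decay uses half-open distance bins (10 kb steps to 100 kb,
then 100–200, 200–500, 500–1000 kb). Adjacent-SNP summaries filter SNPs by
within-group MAF (strictly greater, in *both* groups, for positive
thresholds; a threshold of 0 means no filter) and report distance classes
as disjoint bands (0,100], (100,300], (300,500] kb — the class counts
published for this design are consistent with bands, not cumulative
classes, and `cumulative = TRUE` provides the other reading. The standard
error of mean r² treats pairs as independent (`sd/sqrt(pairs)`).

Persistence of phase correlates the two subpopulations' *signed* r across
all pairs within 100 kb distance bins up to 5 Mb. Because both groups
share one map and allele coding, the sign of r is comparable; a common
allele swap flips both signs and leaves the correlation invariant (tested).
High values mean marker–QTL phases transfer between the groups, the
premise for a joint reference population.

## varLD

For each 15-SNP sliding window, each subpopulation contributes a symmetric
`r²` matrix with unit diagonal; the raw score is the sum of absolute
differences between the two matrices' descending eigenvalues. Window size
is fixed in SNPs, not bp, because the statistic needs homologous matrices.
SNPs monomorphic within one group keep their row/column with off-diagonal
zeros so dimensions stay homologous. Since both matrices have trace 15,
eigenvalues sum to 15 on both sides (tested to 1e-9) and the score is a
pure shape contrast; it is symmetric in its arguments and invariant under
a common SNP permutation. Raw scores are standardized genome-wide (mean 0,
sd 1) — a monotone transform that changes nothing about percentile calls
but matches conventional reporting. Regions are ≥ 2 consecutive windows
strictly above the 99.9th percentile.

The matrices use `r²`, not signed r: the tool this statistic comes from is
described in terms of pairwise `r²` matrices, and we follow that.

## F_ST and the heterozygosity-binned outlier rule

`wc_fst_components()` implements the Weir–Cockerham (1984) two-population
estimator with its three variance components (among populations `a`, among
individuals within populations `b`, within individuals `c`) and
`theta = a/(a+b+c)`; negative estimates are retained (clamping would bias
percentile ranks). Windows combine SNPs as the low-bias ratio of averages
`sum(a)/sum(a+b+c)`; window heterozygosity is the mean expected total
heterozygosity `2 pbar (1-pbar)` — the binning variable.

Outlier calling groups windows into 20 equal-count heterozygosity bins
(quantile bins stabilize the extreme percentile better than equal-width
bins), computes the 99.9th percentile of window theta inside each bin, and
then **smooths the per-bin thresholds with a centered 3-bin moving
average** before flagging windows strictly above their bin's threshold.
The smoothing is essential, not cosmetic: a linearly interpolated 99.9th
percentile of a bin with fewer than ~1,000 windows lies between the bin's
top two order statistics, so at most one window per bin could ever exceed
it and the ≥ 2-consecutive-windows rule would be unsatisfiable — the
empirical threshold would chase any real signal out of reach. Smoothing
lets a bin dominated by one strong peak be judged against the tail of
comparable-heterozygosity windows instead of against the peak itself,
which is how the established F_ST–heterozygosity outlier tooling behaves.
`smooth = FALSE` restores the literal per-bin threshold. Bins smaller than
`min_bin_size = 50` windows are merged with a neighbor; 50 reflects the
smallest bin at which a per-bin tail quantile is still meaningful at this
package's intended scan sizes (a few thousand windows).

## Consensus signatures

Candidate regions from the four sources (ROH islands per subpopulation,
F_ST, varLD) are overlap-merged with a ≥ 1 bp criterion, reporting the
union span — when two tests see the same event their boundary estimates
differ, and the union matches how such tables are reported. A cluster
qualifies as a signature only with ≥ 2 *distinct* sources; two regions
from the same test never qualify. Classification: only the two
subpopulations' ROH islands → `shared_selection` (the same region
autozygous in both gene pools); any F_ST or varLD support →
`divergent_selection`. A cluster holding both subpopulations' ROH islands
*and* a differentiation test is classified divergent, since direct
evidence of between-group differentiation outweighs the shared-autozygosity
reading.

## The synthetic-data generator

`simulate_two_pops()` is a forward Wright–Fisher simulator on haplotypes,
chosen over coalescent machinery because planting selection and sib-mating
is then trivial and runtimes at a few thousand SNPs are seconds. The
generative chain: ancestral frequencies from Beta(0.8, 0.8) truncated to
[0.05, 0.95]; founder haplotypes as mosaics of a 6-template pool
(Li–Stephens-style copying with a 4e-6/bp switch rate — this is what gives
the founders realistic distance-decaying LD); 10 ancestral Wright–Fisher
generations; a split into two populations of effective size 100 each; 20
further generations per population with recombination at 1 cM/Mb
(exponential crossover spacing), matching the convention used for ROH age.

The defaults were calibrated once against the published profile of the
system this package targets and then frozen: on the emitted panels the
post-QC mean MAF is ~0.26–0.27 (Beta(0.4, 0.4) was tried first and landed
visibly low once the template pool and drift act on it), adjacent r²
exceeds 0.2 below ~50 kb and falls to ~0.1 beyond 100 kb, and global
F_ST at 20 post-split generations is ~0.07–0.09 — the published value for
this kind of across-country pair is 0.072. Five chromosomes of 60 Mb with
600 SNPs each keep every scan a few seconds at 200 samples per population.

**Selection** is planted as a deterministic per-generation frequency shift
`s` at a chosen locus in one population, realized by whole-haplotype
replacement: carriers of the disfavoured allele are replaced by copies of
favoured-allele haplotypes. The frequency trajectory is the deterministic
`clamp(p0 + g*s)` the parameterization promises, but — unlike flipping
single alleles — linkage with flanking SNPs is preserved, so the locus
drags a hitchhiking footprint exactly as real selection would, which is
the physical signal the F_ST and varLD scans detect. The planting site
snaps to the nearest SNP where the target population still segregates a
low-frequency allele (MAF 0.05–0.30 at the split): a shift cannot act on a
monomorphic site, and driving a rare allele up emulates the hard-sweep
scenario that produces both a frequency and an LD footprint. The sign of
`s` defaults to "away" (toward the extreme farther from the split
frequency, maximizing divergence); "up"/"down" are available.

**Autozygosity** comes from two controls: a fraction of samples produced
by full-sib matings (long ROH from genuine recent inbreeding) and
`plant_roh_cohort()`, which copies one haplotype interval onto its
homolog, creating IBD segments whose exact coordinates are recorded as
ground truth for recall measurements.

What the generator does **not** emulate: genotyping error and missingness
(panels are emitted complete; the QC filters are exercised by injecting
missingness in tests), mutation, a realistic cattle recombination map
(uniform 1 cM/Mb instead), gene flow after the split (the real system has
ongoing semen exchange, which lowers differentiation), and chromosome-count
realism (5 autosomes, not 29). Passing the parameter-recovery suite
therefore shows the statistics behave correctly under drift, selection and
inbreeding — not that they are robust to array artifacts or demographic
complications.

## What the scans can and cannot recover at this scale

The package's own acceptance experiments (200 samples per population,
3,000 SNPs, 20 replicates) recover a planted hard sweep (`s = 0.05`, 20
generations) through the F_ST outlier scan in ~85–90% of replicates, and
planted 5 Mb IBD segments through both ROH detectors with recall above
0.95; F_ROH from the two detectors correlates above 0.95, and F_GRM
correlates with F_ROH above 0.8 once real autozygosity is present.

The varLD scan is different, and it is worth being explicit. With ~2,900
windows, the strict 99.9th percentile admits only the top two or three
windows genome-wide, and twenty generations of independent drift at
effective size 100 generate LD contrasts whose extreme tail is comparable
to a completed sweep's eigenvalue footprint (a swept region ends up nearly
monomorphic — locally *low*-information). The implementation itself is
sound: totally homogenizing a few Mb of one population produces the
genome's top scores at exactly that region and the region is called. But
under the realistic drift background the planted sweep wins the genome-wide
tail only occasionally (~15% of replicates), so at this scan size varLD
should be read as a corroborating test — which is precisely how the
consensus rule uses it — rather than a stand-alone detector. Power returns
with more windows (the published scans used ~31,000, giving the threshold
ten times more room) or a lower percentile.

## Numerical conventions

Coordinates are 1-based inclusive bp everywhere inside the package; BED
output converts to 0-based half-open at a single point (`write_regions()`),
with a 1-based TSV companion. Percentiles are type-7 (linear
interpolation) quantiles; thresholds are always strict (`>`). Windows
advance one SNP and never span chromosomes; a chromosome shorter than the
ROH scanning window is scanned with a window equal to its SNP count, while
a chromosome shorter than an LD window is skipped with a warning.
Undefined statistics (monomorphic SNPs, empty bins) propagate as `NA` or
are excluded, never silently zeroed. All randomness flows from explicit
seeds; `run_pipeline()` records parameters, seed and output hashes in a
JSON manifest, and a rerun with the same inputs and seed is bit-identical.

## Problem sizes used in the test suite

Module tests run on miniature panels (2 chromosomes × 150 SNPs, 50 samples
per group) chosen so each statistical property is still identifiable;
parameter-recovery experiments use the generator defaults (5 × 600 SNPs,
200 per group) with 10–20 replicates, and the ROH experiments use 50 kb
marker spacing as discussed above. These sizes are the package's own
testing choices: they keep a full run of the suite in the minutes range
while leaving every assertion statistically meaningful.
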