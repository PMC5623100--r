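---
title: "Models and methods: crossover detection, interference and segregation distortion from single-gamete genotypes"
author: "sgrec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgrec)
```

# Scope

`sgrec` analyses meiotic recombination from sparse haploid genotype calls
of single gametes (flow-sorted pollen nuclei genotyped by shallow
single-cell sequencing) or double haploid (DH) lines of a biparental
cross. The pipeline starts from per-SNP parental-origin calls (VCF) and a
marker table; everything upstream — read trimming, alignment, variant
calling, SNP ascertainment — is out of scope and assumed done by standard
tools. Five analysis stages follow:

1. **Binned consensus genotyping** — aggregate sparse SNP calls into
   1-Mbp bins coded 2 (parent-1 allele), 0 (parent-2 allele) or missing.
2. **Crossover detection** — find parental-origin transitions along each
   gamete after masking error-prone bins.
3. **Recombination landscape** — sliding-window cM/Mbp along each
   chromosome.
4. **Crossover interference** — fit a stationary gamma renewal model to
   inter-crossover distances by simulation.
5. **Segregation distortion** — chi-square scan of window allele
   frequencies against the Mendelian 1:1 ratio and delineation of
   distorted regions (SDRs).

A meiosis-and-observation simulator with complete ground truth backs
every stage, so all statistical behaviour documented here is verified by
the test suite rather than asserted.

# The meiosis model

Crossovers on the four-chromatid bundle are modelled as a **stationary
gamma renewal process** on the genetic map. Inter-event distances (in
Morgans) are i.i.d. Gamma(shape $\nu$, rate $2\nu$), giving the bundle an
intensity of 2 events/Morgan. A single gamete samples one chromatid: each
bundle event is retained independently with probability 1/2 (no
chromatid interference), so a chromosome of genetic length $G$ Morgans
carries on average $G$ crossovers per gamete — the defining property of
the Morgan.

The shape $\nu$ measures interference: $\nu = 1$ reduces the process to
homogeneous Poisson placement (no interference), $\nu > 1$ makes spacings
more regular than Poisson (positive interference), $\nu < 1$ more
clustered (negative interference).

**Stationarity.** A renewal process started with a gap from the origin
drawn from the inter-event law is not count-stationary. The first event
is therefore drawn from the equilibrium forward-recurrence distribution,
whose CDF has the closed form

$$F_e(x) = 2x\,\bigl(1 - F_\nu(x)\bigr) + F_{\nu+1}(x),$$

with $F_a$ the CDF of Gamma($a$, $2\nu$). This is inverted numerically
once per $\nu$ on a 4096-point grid (cached), making batch simulation
cheap. The test suite checks the two consequences that matter: event
counts have equal means in the two halves of the interval for
$\nu \in \{0.5, 1, 5\}$, and at $\nu = 1$ uncensored inter-event gaps
pass a KS test against Exponential(rate 2). Note that gaps *observed
inside a finite interval* are right-censored — long gaps straddling the
boundary are lost — so the exponential check must use gaps far from the
interval end; naive within-window gaps have a visibly reduced variance
and that is not a bug.

**Obligate crossover.** `obligate_co` is off by default: an appreciable
fraction of real chromatids shows no detectable crossover, and with
$G = 1.4$ the model reproduces a zero-event class of roughly 15–20%
without forcing one event per bivalent.

# The synthetic genome and observation model

`default_genome_map()` builds a barley-like genome: 7 chromosomes of
558–767 Mbp, one segregating SNP per 100 kb, and three 10-Mbp
marker-free gaps per chromosome emulating regions monomorphic between
the parents. Each chromosome gets a genetic length of 1.4 Morgans
(140 cM, i.e. ~1.4 crossovers per gamete and chromosome, totalling ~10
per gamete over 7 chromosomes) and, by default, a **distal-elevated
genetic map**: a piecewise-linear physical-to-genetic function placing
90% of the genetic length in the two distal 15% segments of the
chromosome. This mimics the recombination landscape of large-genome
cereals, where the (peri-)centromeric majority of the physical map is
nearly recombination-free. A uniform map is available
(`map_type = "uniform"`) and is used wherever a test needs a neutral
coordinate system.

The observation model works at the genotype-call level (no reads): each
marker is seen in a sample with probability `detect_prob` (default 0.1 —
the analogue of ~0.1x single-cell coverage, where most SNPs go
unobserved) and an observed call is flipped with probability
`error_rate` (default 0.01, a realistic post-filter error for shallow
single-cell genotyping). What the generator does **not** emulate:
read-level artefacts (chimeric amplification, mapping bias), gene
conversion / non-crossover events, correlated dropout along amplicons,
and contamination. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to
every pathology of real single-cell libraries.

**Transmission bias** (for DH-like populations) is specified per locus as
the marginal transmission probability $p$ of the parent-1 allele and
implemented by rejection sampling of whole gametes: a gamete carrying
the disfavoured allele is rejected with probability $|2p-1|/\max(p,1-p)$,
which makes the accepted-gamete marginal exactly $p$ at the locus.
Linked markers inherit a distortion that decays with recombination
distance — the mechanism that turns a selected locus into a
segregation-distortion *region*. With several loci the per-locus
acceptance probabilities multiply; marginals at individual loci are then
exact only for unlinked loci, which is how the defaults place them.

# Binned consensus genotypes

Bins are 0-based half-open intervals of `bin_size` (default 1 Mbp); a
marker at 1-based position $p$ belongs to bin $\lfloor (p-1)/10^6
\rfloor$. Per sample and bin, the consensus is the majority parent if at
least `min_support` (default 1) calls are present and the majority
fraction reaches `purity` (default 0.8); exact ties are never called.
The defaults keep single-call bins — at 0.1x-like sparsity most
informative bins hold one or two calls, and discarding them would
discard most of the data — while the purity rule censors conflicting
multi-call bins instead of guessing. Both knobs are config-exposed, and
raising `purity` can only censor, never call (a monotonicity the tests
enforce).

VCF genotypes are read with `vcfR`. Haploid GTs (`0`, `1`, `.`) are the
native dialect; homozygous diploid GTs are collapsed to the haploid
call; heterozygous GTs are impossible in a haploid nucleus, flag error
or contamination, and are counted and treated as missing, as are called
alleles matching neither parent. Bins whose missing fraction across
samples strictly exceeds 50% are removed before any window statistics.

# Crossover detection and curation

Detection scans the informative (non-missing) bins of each sample and
chromosome in order and emits one event per adjacent informative pair
with different codes — the classic graphical-genotype transition
`0 0 0 2 2 2`. Missing bins are bridged, never used as boundaries; event
boundaries are the inner edges of the two flanking informative bins and
the event position is the interval midpoint (unbiased under symmetric
missingness). An exhaustive test checks equivalence with a brute-force
sign-change oracle on all $3^8$ genotype vectors of length 8.

**Marker curation.** Bins where many samples show the
`0 → 2 → 0` / `2 → 0 → 2` singleton-flip motif (flanks agreeing,
centre disagreeing, missing bins bridged) are genotyping-error
signatures: a real double crossover this tight is possible in one
gamete, not recurrently across gametes. Bins with a flip rate above
`max_flip_rate` (default 0.1) are masked in all samples; rates are
recomputed until no bin exceeds the threshold, which makes the operation
idempotent. The threshold quantifies a criterion that is usually applied
by eye; the per-bin report lets users audit what was removed.

**A note on error-driven event inflation.** With one call per bin, a
single flipped call makes a spurious singleton bin, and a singleton
produces *two* spurious events. Such errors are not recurrent per bin,
so bin-level curation cannot remove them: at the default sparsity and
1% error a 40-gamete run roughly quadruples its raw event count.
`detect_events(mask_singletons = TRUE)` masks per-sample singleton flips
before scanning, suppressing these pairs at the price of hiding any real
double crossover confined to a single bin (undetectable at bin
resolution anyway). The option is off by default so that the default
scan remains the pure transition search; sensitive downstream analyses
(interference on noisy data) should switch it on or lower the error
rate/raise `min_support`.

# Recombination landscape

For windows of `window` bp (default 5 Mbp) advanced by `step` (default
1 Mbp — the step is not standardised anywhere, so it is exposed), the
window's genetic distance is $\text{cM} = 100 \cdot \text{count}/N$ with
$N$ the number of gametes, and the rate is cM divided by the window span
in Mbp. Events are assigned by midpoint; the final window is truncated
at the chromosome end and uses its true span as denominator. With
`step = window` the windows partition the chromosome and total genetic
length is conserved exactly: $\sum_w \text{cM}_w = 100\,E/N$ for $E$
total events — an identity the acceptance tests verify to numerical
precision.

# Interference estimation

Samples with at least two events on a chromosome yield inter-crossover
distances (adjacent midpoint differences). The estimator compares the
observed distance distribution with distances simulated from the gamma
renewal model across a grid of candidate $\nu$ (default 0.5–12 by 0.25)
and returns the grid argmin of a Cramér–von Mises discrepancy between
the two samples (KS available as an option; CvM integrates over the
whole distribution instead of a single worst point). Ties break toward
smaller $\nu$, i.e. toward the weaker-interference interpretation.

Three design choices matter and are deliberate:

* **Conditioning on counts, not rates.** Simulated chromatids are
  conditioned to reproduce the observed per-chromosome event-count
  distribution (among $\geq 2$-event chromatids). This isolates spacing
  (interference) from intensity (genetic length), so a wrong guess about
  map length cannot masquerade as interference.
* **Intensity from all gametes.** The interval length used in the
  simulation is estimated from the mean event count per chromatid over
  *all* samples, which for a stationary renewal chromatid equals the
  genetic length in Morgans whatever $\nu$ is. Inverting a
  truncated-count mean under a Poisson assumption instead is badly
  biased under interference and was measurably so; the truncated
  inversion survives only as a fallback when the full count distribution
  is unavailable.
* **Chromosome-normalised coordinates.** Distances are compared as
  fractions of the chromosome ($d/L$) so that chromosomes of different
  physical lengths pool coherently; whether the original analyses pooled
  physical or genetic distances is not documented anywhere, so both
  coordinate systems are supported through the genome map (a uniform
  map makes them proportional).

The same derived RNG stream is replayed at every grid point (common
random numbers), so the discrepancy profile is smooth in $\nu$ and
bit-for-bit reproducible given the seed. Parameter recovery is part of
the acceptance suite: across $\nu \in \{1, 3, 5\}$, the median estimate
over 20 replicate datasets of 400 gametes falls within ±15% of truth,
and within ±40% at the 40-gamete scale of a single-plant pollen
experiment.

`class_split_fit()` fits the near (<100 Mbp) and far (>400 Mbp) distance
classes separately — the split used to argue for coexisting
interference-sensitive (class I) and insensitive (class II) crossover
pathways; the distance filter is applied to observed and simulated
distances alike. Groups below 10 distances are refused loudly, never
fitted silently. The minimum event requirement is $\geq 2$ (two events
already yield a distance); the phrase "more than two" that sometimes
accompanies this analysis conflicts with distances being computable from
exactly two, so the threshold is a `min_events` argument with default 2.

# Segregation distortion

Allele frequencies are scanned in 10-Mbp windows stepped by 1 Mbp. The
chi-square test against 1:1 uses $X^2 = (a-b)^2/(a+b)$ (one degree of
freedom, no continuity correction). The **counting unit** is one
consensus call per sample per window by default: the gamete is the
independent replication unit, and a 300-window null simulation confirms
a type-I error within sampling error of $\alpha$. Pooling all bin calls
in the window (`unit = "bin"`) mirrors a window-average of bin
frequencies but treats ~10 near-perfectly correlated bins of one sample
as independent observations; measured on the same null it rejects ~36%
of windows at $\alpha = 0.05$. It is retained for comparison, not for
inference.

Significant windows (uncorrected $P < 0.05$ by default, mirroring common
practice in this analysis; `BH` and `bonferroni` adjustments are
options) are merged into maximal same-direction runs to give SDRs
annotated with size, percent of chromosome, direction and minimum P.
Genome-wide summaries use the union of significant base pairs, so
overlapping windows are never double-counted. Because adjacent windows
share 90% of their span and linkage correlates even non-overlapping
windows, the number of *regions* is the interpretable unit under the
uncorrected default; the planted-locus acceptance test uses the
Bonferroni option to demand exactly one region.

# Numerical and degenerate-input conventions

* Zero-length genetic intervals simulate to zero events; `nu <= 0` is a
  parameter error everywhere.
* Exact consensus ties are missing regardless of `purity`.
* Empty populations write a header-only VCF that the reader accepts.
* Event boundaries are 1-based inclusive base pairs; adjacent
  informative bins give an interval of width 1 bp.
* All-missing or constant genotype vectors yield zero events; windows
  with no calls carry `NA` statistics and are excluded from testable
  window counts.
* `estimate_nu` refuses fewer than 10 distances and degenerate grids.

# Problem sizes

The test and acceptance runs use sizes chosen to make every stochastic
assertion decisive at desk scale: 10,000 replicates for renewal-process
moments, 6561 vectors for the detection oracle, 20 replicate datasets of
400 (and 40) gametes for interference recovery, a 300-chromosome /
500-gamete null for scan calibration, and 10 replicate 40-vs-89-gamete
population pairs for the pollen-vs-DH contrast. The full-genome
demonstration in the README uses 40 gametes at `detect_prob = 0.3`.

# Known limitations

* Double crossovers within one bin are invisible by construction;
  event positions are only megabase-accurate, so interference fits on
  *detected* (rather than true) events inherit that blur.
* The consensus has no imputation and no HMM smoothing; this is a
  deliberate match to the direct-consensus-plus-curation approach, not
  a statement that an HMM would not help at higher noise.
* The two-pathway interpretation is supported only through the distance
  class split; no joint mixture likelihood is fitted.
* Uncorrected window tests control per-window error, not genome-wide
  error; SDR genome percentages at small sample sizes are noisy and
  should be compared between populations run at the same scale.
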