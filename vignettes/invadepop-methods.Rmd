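---
title: "Methods and design of the invadepop pipeline"
author: "invadepop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the invadepop pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`invadepop` implements the population-genomic analyses used to
characterise a recently introduced insect population from individual
whole-genome resequencing: cohort quality control, genetic sex
assignment from sequencing coverage, detection of putative chromosomal
inversions from long-range linkage disequilibrium (LD), relatedness and
population structure, windowed diversity statistics that tolerate
missing data, and haplotype- and differentiation-based selection scans
whose outlier windows are intersected across tests.  The pipeline
starts at a genotyped multi-sample VCF; read mapping, variant calling
and phasing are upstream.

Because realistic inputs at study scale (hundreds of resequenced
individuals, a 146-Mb genome) are not practical for routine testing,
the package ships a synthetic-cohort generator that emulates the
statistical structure every stage relies on, with full ground truth.
All tests and the acceptance script run on these fixtures.

# The synthetic cohort generator

## Population model

Ancestral allele frequencies are drawn per site from a symmetric
Beta($\theta$, $\theta$) with $\theta = 0.8$ by default; population
frequencies follow the Balding–Nichols distribution
$p_k \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$,
so the drift parameter $F$ sets the expected differentiation (the
multi-locus Weir–Cockerham $F_{ST}$ recovered from such panels is close
to $F$).  Haplotypes are assembled by block-wise copying from a
population founder pool (30 founder haplotypes, geometric block lengths
with mean 20 SNPs by default), which creates local LD — needed for
extended-haplotype statistics — while keeping realized frequencies
unbiased (realized-on-intended regression slope 1 within 5% over
$10^4$ SNPs).

Two consequences of the copying process matter for interpretation:

* **Extra drift.** Resampling a finite founder pool adds differentiation
  of order $1/(2 n_\mathrm{founders})$ on top of $F$ (about +0.017 at
  the default pool of 30).  Fixtures whose purpose is parameter
  recovery for $F_{ST}$ therefore use a pool of 200 founders, which
  makes the draws effectively site-wise Balding–Nichols; fixtures that
  need LD keep the small pool.
* **Non-equilibrium SFS.** The generator is not a coalescent simulator;
  its site-frequency spectrum is Beta-shaped, not $1/x$, and founder
  reuse amplifies rare variants.  Windowed Tajima's $D$ on neutral
  panels is therefore centred around $+1$, not 0.  Sweeps still depress
  $D$ by more than a unit relative to the panel background, which is
  the relative signal outlier scans use (the tests assert this relative
  depression, not absolute negativity).

## Genome layout and the X

The default fixture genome is scaled down (a 4-Mb autosome and a 1-Mb
X) but preserves the X:autosome proportion of a drosophilid genome
(roughly one fifth).  That proportion matters: males sequenced at mean
depth $d$ have X depth $d/2$, and with $d = 16$ about 31% of male X
genotypes fall below the 7-read genotype filter.  If the X were an
outsized fraction of the genome, every male would exceed the 10%
missingness cutoff and be removed — an artefact of layout, not of the
filters.  Males are simulated with a single X haplotype throughout; no
Y and no pseudoautosomal region are modelled.

## Inversions

An injected inversion assigns each target individual an arrangement
genotype $\sim \mathrm{Binomial}(2, q)$ (one draw for the male X) and
replaces carrier haplotypes in the region with draws from a small,
internally recombination-free arrangement pool.  Divergent sites — the
fraction `arrangement_divergence`, default 0.15 — are placed where the
standard arrangement is (near-)fixed and flipped to the rare allele,
the way new mutations accumulate on a non-recombining background.
This detail is load-bearing: if divergent sites were flipped at random
segregating sites, the arrangement allele would also be common among
standard haplotypes and pairwise dosage $r^2$ between arrangement
markers would saturate far below the 0.75 call threshold.  The default
divergence is higher than the 2–5% a fresh inversion might show because
the fixture's SNP density (1 per kb) is several-fold sparser than the
study-scale data; what detection needs is the per-window *count* of
arrangement-tagging SNPs, and the default reproduces a realistic count
at fixture density.

## Sweeps

A hard sweep copies one template haplotype into a carrier set of
exactly $\lfloor q \cdot n_{hap} \rceil$ haplotypes (uniformly chosen)
over `core ± span/2`, fixes the derived allele at the core in
carriers, and removes it entirely from non-target (native)
populations.  The carrier count is exact rather than Bernoulli: the
configured frequency is the study condition, and letting it drift
binomially couples the core's haplotype signal to sampling noise in a
way no downstream property can distinguish from low power.  Each carrier then receives
independent residual mutations (per-site rate 0.01 by default).  The
residual rate is the generator's stand-in for the recombination that,
in real sweeps, erodes hitchhiker linkage: with a rate near zero every
span SNP is a perfect proxy for the core, the core is not
distinguishable from its own hitchhikers, and the frequency bins used
to standardize iHS are flooded by SNPs of identical extremeness.

## Pedigrees

Offspring receive one recombinant haplotype per parent (Poisson
crossovers, uniform positions; a son's X comes only from his mother,
a daughter receives the father's single X).  The default map density
(`xover_rate = 1e-5` per bp, about 50 crossovers per 5-Mb fixture
chromosome) is deliberately denser than a physical-scale drosophilid
map: realized kinship disperses as $1/\sqrt{L}$ in the number of
independently segregating segments, and a 21-Mb fixture genome with a
literal fly map would have so few segments that first-cousin kinship
would straddle its classification bin.  The default reproduces on the
fixture genome roughly the dispersion a full-size genome provides.
Drosophilid male achiasmy is not modelled.

## Depth and missingness

Per-genotype read depth is Poisson with the configured mean (male X
halved); genotypes at DP 0 are missing, and independent Bernoulli
missingness (default 0.2%) is layered on.  Fixtures are written as
VCFv4.2 with `GT:DP`, haploid male X calls as single alleles, truth
intervals as 0-based half-open BED.

# Quality control

Filters follow a fixed order — genotype-level depth, then site-level,
then individual-level — with per-stage counts logged:

* genotype calls with DP $\le 6$ or DP $> 100$ set missing;
* sites with mean depth $< 10$ or $> 50$ removed (exact boundary
  values retained, matching the quoted inequalities), sites within
  20 bp of an indel-affected base removed (inclusive of the 20th bp),
  and sites inside the repeat mask removed;
* individuals with mean coverage $< 7\times$ or missingness $> 10\%$
  removed (exactly 10% is retained).

Coordinates are 1-based inclusive in VCF I/O and reports and 0-based
half-open internally and in BED, converted only at the boundary.

Sex is assigned from the ratio of mean X depth to mean autosomal depth:
above 0.8 female, below 0.8 male.  A ratio exactly at 0.8 is assigned
male with a warning — the conservative choice for X-chromosome analyses
that are restricted to females, since a mis-assigned male contributes a
haploid X.  Discordance with the recorded sex is flagged and the
coverage-based call wins.

Polarization designates the ancestral allele per site as the major
allele among the reference (native-range) population's non-missing
allele copies.  An exact 50/50 tie keeps the reference allele and flags
the site; flagged and unpolarized sites are excluded from iHS.

# Inversion detection from long-range LD

For each SNP segregating with complete genotypes in the focal
population, one partner SNP is sampled uniformly within ±5% of each
target distance (100, 200, 300, 400, 500 kb; either direction), and
composite LD is computed as the squared Pearson correlation of
genotype dosages (male X dosages enter as 0/1).  Non-overlapping
100-kb windows are flagged when any SNP located in them — focal or
partner, since the evidence is symmetric — participates in a pair with
$r^2 > 0.75$.  Maximal runs of at least 10 consecutive flagged windows
become called regions.  Windows with no eligible SNPs break runs:
bridging across SNP deserts would let two short spurious runs merge.

Two eligibility details matter.  Segregation is judged on allele
counts, not on distinct dosage values: on the X a site fixed for one
allele still "varies" in dosage (females 2, males 1), and treating it
as polymorphic would hand every such site pair $r^2 = 1$ through sex
alone.  And with few samples the $r^2$ tail of rare-variant pairs is
heavy, which is why the run rule (not single flagged windows) defines
calls.

The one-partner-per-distance-per-focal-SNP choice (all five distances)
is configurable; both it and the ±5% band interpretation are exposed
as arguments.

# Relatedness, inbreeding, structure

KING-robust kinship is computed per pair over pairwise-complete
autosomal genotypes:
$\phi = (N_{AaAa} - 2N_{opp}) / (N_{Aa}^{(i)} + N_{Aa}^{(j)})$, with
opposite-homozygote counts and heterozygote counts restricted to the
shared non-missing sites.  A sample paired with itself gives exactly
0.5; parent–offspring pairs have zero opposite homozygotes before
depth noise.  Degrees use the standard powers-of-two bins
(0.354/0.177/0.0884/0.0442), which partition $(0.0442, \infty)$ without
gaps.

The per-individual inbreeding coefficient is the method-of-moments
$F = (O_{hom} - E_{hom})/(L - E_{hom})$ with
$E_{hom} = \sum_s \left(1 - 2p_s(1-p_s)\frac{n_s}{n_s-1}\right)$ from
sample allele counts, the vcftools `--het` convention.

LD pruning removes SNPs below the minor-allele-count floor (3 for the
PCA track), then greedily scans left to right, dropping the later SNP
of any within-window pair with $r^2$ above 0.2.  One deterministic
pruner serves both the PCA and count-preparation roles.  PCA operates
on dosages centred at $2\hat p$ and scaled by
$\sqrt{2\hat p(1-\hat p)}$ with missing entries zero-filled after
standardization (per-SNP mean imputation), eigendecomposing the
individual covariance matrix.

$F_{ST}$ uses the Weir–Cockerham (1984) variance components $a$, $b$,
$c$ per SNP, with the multi-SNP estimate the ratio of summed
components; the MAC filter defaults to $>3$ for $F_{ST}$ and $\ge 3$
for pruning, matching the two quoted rules.  X-chromosome runs are
restricted to assigned females.  The temporal-differentiation
regression is ordinary least squares of pairwise $F_{ST}$ on days
between collections, with explicit exclusions and
df $= n_\mathrm{pairs} - 2$; exclusions are caller-supplied input, not
guessed.

# Windowed diversity

Within 5-kb non-overlapping windows, $\pi$ is the ratio of summed
per-site mismatch pair counts $n_{alt} \cdot n_{ref}$ to summed pair
counts $\binom{k}{2}$ over variant *and callable invariant* sites
($k$ = non-missing allele copies), and $D_{xy}$ is the corresponding
cross-population ratio with denominator $k_A k_B$.  The
invariant-site denominator defaults to "every non-variant window
position is callable at full copy number", which is exact for the
synthetic fixtures; real data require an all-sites VCF or a
callability mask, and the `callable_sites` argument accepts one.

Tajima's $D$ is computed from hard genotypes (not genotype
likelihoods): $S$ segregating sites, $\theta_W = S/a_1$, $\theta_\pi$
summed per-site heterozygosity, and the 1989 constants evaluated at
the window-median non-missing copy number.  With hard genotypes the
folded/unfolded distinction changes neither $S$ nor $\theta_\pi$, so
the standard formula applies.  Windows with $S = 0$ are reported
missing rather than zero.

Relative depth divides each individual's window mean DP by their
chromosome mean DP and averages within population, so the genome-wide
mean ratio is 1 by construction and copy-number anomalies stand out.

# Selection scans

**EHH / iHS.**  EHH at a site $x$ is the probability that two randomly
chosen carrier haplotypes of the core allele are identical over
$[\mathrm{core}, x]$, computed per flank by incremental haplotype
grouping (Rcpp kernel).  A haplotype is dropped from the carrier set
when it reaches a missing allele, with the denominator tracking the
evaluable carriers — the behaviour needed for panels phased from VCFs
with missing genotypes.  Each male contributes exactly one X
haplotype.  iHH integrates EHH against physical distance (no genetic
map exists for this system), truncated before the first SNP below the
0.05 EHH cutoff; iHS$_{raw}$ = $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$
for SNPs with derived-frequency MAF $\ge 0.05$, and standardization
subtracts the mean and divides by the SD within 0.05-wide
derived-frequency bins (bins under 10 SNPs merge into their nearest
neighbour).  Bin means and SDs are exactly 0 and 1 afterwards by
construction.  Truncation cutoff, MAF floor and bin width follow the
conventional defaults of haplotype-scan software and are exposed as
arguments.

**Differentiation score.**  The among-population dispersion score
$\sum_k (p_k - \bar p)^2 / (\bar p(1-\bar p)/\tilde n + \varepsilon)$
(unweighted mean $\bar p$, harmonic-mean copy number $\tilde n$) plays
the role a structure-aware differentiation statistic plays in outlier
scans.  It is monotone in frequency dispersion and is *not* a
posterior quantity from a hierarchical covariance model; any
externally computed per-SNP differentiation track can be substituted
in the intersection step.

**POD threshold.**  Significance is calibrated with pseudo-observed
data: a Beta ancestral-frequency distribution is moment-matched to the
observed mean frequencies after subtracting the drift and binomial
sampling components of their variance; the drift parameter is
estimated by a multi-locus allele-count (haploid) Weir–Cockerham
estimator; 10,000 SNPs are simulated under that null with the observed
sample sizes; and the threshold is the 99.9% quantile of their scores.
On data drawn from the fitted family the null exceedance is within
binomial error of 0.1%.  On cohorts from the copying-process
generator the exceedance runs about twofold high (the copying noise is
not Beta-binomial), a known limitation documented here rather than
absorbed into the fit.

**Intersection.**  Per track, the genome-wide top 1% of non-missing
SNPs are marked, ties at the boundary included; 1-kb windows at 500-bp
steps (grid anchored at position 1, windows reported 1-based
inclusive) are flagged per track when they contain a marked SNP, and
windows flagged in every track form the intersection.  Marking is
genome-wide, not per chromosome.

# Orchestration

`run_pipeline()` executes the fixed stage graph — simulate (or read a
VCF), QC, sex assignment and polarization, LD scan (whose called
regions mask the structure-stage analyses), structure, diversity,
selection scan — under one output directory, with per-stage seeds
derived from the global seed by a stable hash so stage-level reruns
reproduce.  A JSON manifest with per-stage file checksums and record
counts is written even on failure, recording the failing stage.
`--resume` semantics are file-level: a completed run with an identical
configuration hash is returned as-is.  There is no shell entry point:
the numbered scripts under `analysis/` are the driver layer, each a
thin narrative over the package functions.

# Problem sizes

Tests and the acceptance script use fixture-scale problems chosen so
every property is measurable with comfortable margins: cohorts of
50–80 diploids; genomes of 3–21 Mb at 1–2.5 SNPs per kb; 3-Mb
inversions at frequency 0.3 scanned in 10-Mb chromosomes; 500-kb
sweeps at derived frequency 0.6 scanned in 7-Mb chromosomes (the span
must be a minor fraction of the genome or sweep hitchhikers dominate
the iHS standardization bins — the same reason the statistic is
standardized genome-wide on real data); kinship panels of four 5-Mb
autosomes; POD calibration at 10,000 observed and 10,000 simulated
SNPs.  The full test suite runs in a few minutes on one CPU.

# Known limitations

* The generator emulates drift, LD, inversions, sweeps and pedigrees
  statistically; it is not a coalescent and its absolute Tajima's $D$
  baseline is positive (see above).  Passing tests demonstrate the
  estimators and detection rules, not demographic realism.
* Genotype likelihoods are not modelled anywhere; all statistics use
  hard genotypes.
* The differentiation score stands in for a hierarchical
  covariance-aware statistic; its POD calibration is exact only under
  its own null family.
* Inversion calls are regions of elevated long-range LD, not
  breakpoints; per-individual arrangement genotyping is outside scope.
* The LD-scan false-positive behaviour at very small sample sizes
  (under ~25 diploids) is dominated by rare-variant $r^2$ noise; the
  run rule protects chromosomes much longer than 1 Mb, and fixture
  X chromosomes are kept small relative to that scale.
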