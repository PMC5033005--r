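---
title: "Methods: read-frequency analysis of allopolyploid genome composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-frequency analysis of allopolyploid genome composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodose)
```

## Scope and rationale

`allodose` analyses the genome composition of a young allopolyploid
system — a diploid parent (G), a tetraploid parent (L), their sterile
triploid hybrid (GLL), and a fertile hexaploid (GGLLLL) formed by
whole-genome doubling of the triploid — from targeted capture
sequencing. The decisive design choice is that **every analysis runs on
per-sample allele read depths, never on called genotypes**. In
polyploids, a genotype call collapses dosage information (GGL and GLL
are both "heterozygous"), whereas the read frequency of an allele
estimates its copy fraction directly: 1/3 for one copy in three, 1/6
for one copy in six. All downstream rules are thresholds on this
frequency.

Upstream processing (alignment, deduplication, base/mapping-quality
filtering, variant calling) is out of scope; the package starts from a
multi-sample VCF with `AD` fields and a sample panel declaring each
individual's role in the cross.

## Genotype states and heterozygosity

For a cell with reference-allele frequency $q$:

* heterozygous if $0.1 \le q \le 0.9$;
* homozygous-reference if $q > 0.9$; homozygous-alternate if $q < 0.1$.

The band bounds are **inclusive**. The natural dosage frequencies of a
hexaploid single copy ($1/6 \approx 0.167$) and a boundary read ratio
such as $5/50 = 0.1$ must not be split off the band by floating-point
noise; whether the original rule was applied inclusively cannot be
determined from its wording, so the bounds are configuration-exposed
(`lo`, `hi`) with inclusive defaults.

Sites are filtered in a fixed order so per-rule attrition is
reproducible: depth (≥ 50× in every individual) → no missing AD cells →
at most one alternate allele → (for SNP analyses only) polymorphic in
the panel. The biallelic rule deliberately keeps monomorphic sites:
per-individual heterozygosity is a per-base statistic over *all*
genotyped sites, while the SNP analyses additionally apply the
polymorphic rule, after which retained sites have exactly two observed
alleles.

## Diagnostic sites and subgenome dosage

A site is *diagnostic* when every diploid-parent sample shows one
allele at $q > 0.9$ and every tetraploid-parent sample shows the other.
A frequency threshold is used instead of "zero alternative reads"
because a handful of error reads should not disqualify a fixed site;
0.9 is the complement of the heterozygote band. At diagnostic sites the
hybrid dosage $f_A$ is the fraction of reads carrying the
diploid-parent allele **among reads carrying either diagnostic
allele** — dosage is defined as a two-allele ratio, so third-allele
error reads are excluded from the denominator.

Expected $f_A$ is 1/3 for GLL and GGLLLL. Capture (hybridization) bias
is diagnosed by splitting sites into two classes: parent-A allele
matches the reference genome the probes were designed from, or the
parent-B allele does. Under biased capture the reference-matching
allele is over-recovered, so the two class means straddle 1/3 in
opposite directions; under no bias they agree. Dosage summaries are
emitted both as pooled (site × individual) moments and as per-site
cross-individual means averaged over sites, because either pooling
convention may be wanted and they differ under unequal depth; per-probe
means and 0.1-wide left-closed histogram bins are also produced.

Hybrid cells homozygous at a diagnostic site ($f_A < 0.1$ or
$f_A > 0.9$) are reported as missing-parental-allele events, tallied
per individual, probe, linkage group, and per taxon as "homozygous in
at least one individual". The package deliberately does not assign a
mechanism (deletion vs gene conversion vs unsampled parental
variation); read counts cannot distinguish them.

## Gain, loss, and the window scan

Between the triploid and the hexaploid, three rules apply, globally and
for geographically paired individuals:

* **unique alleles**: frequency $> 0.167$ in some hybrid, $< 0.1$ in
  every parental sample (both strict, following the quantifiers of the
  source rules: "all" on the fixed side, "any" on the carrier side);
* **gains**: fixed ($q > 0.9$) in all scoped triploids, other allele at
  $\ge 0.167$ in some scoped hexaploid;
* **losses**: heterozygous in all scoped triploids
  ($0.167 < q < 0.833$), homozygous in some scoped hexaploid
  ($q < 0.1$ or $q > 0.9$ — the conservative band).

Each report carries its own denominator (sites passing filters and
meeting the triploid-side condition), since "potentially informative
loci" differs per comparison.

The window scan slides a 10-SNP window (step 1) along each linkage
group over *informative* sites — sites heterozygous in the scanned
triploid, the only places where loss or conversion in its doubled
derivative is observable. The statistic is the signed mean of
$f_{6x} - f_{3x}$ for the reference allele (a signed difference matches
a zero-reference baseline; absolute values are emitted alongside).
Conversion of one of six copies shifts the mean by 1/6. Run detection
(`detect_runs`) formalizes the by-eye identification of such regions:
maximal runs of ≥ 5 consecutive windows with $|\bar\Delta| \ge 0.1$, no
gap merging. Both thresholds are parameters; they are plumbing around
the scan, not part of the scientific claim.

## Relationships

Genotype states are encoded as alternate-allele prevalence
$s \in \{0, 0.5, 1\}$ and treated as per-individual allele frequencies
$(1-s, s)$. Nei's (1972) standard distance, neighbor joining, locus
bootstrap, and PCA are implemented from first principles because the
encoding-to-distance path is part of the method being provided, and the
tool chains used in published analyses do not document their exact
variant on presence/absence data. Choices made where the design was
open:

* **Nei variant**: the standard distance
  $D = -\ln(J_{xy}/\sqrt{J_x J_y})$ with sums over loci typed in both
  individuals (pairwise deletion). Identical individuals get $D = 0$
  regardless of heterozygosity, which is the property the tree analysis
  relies on.
* **NJ ties and negative branches**: ties in the Q-criterion are broken
  lexicographically by leaf label (determinism); negative branch
  lengths are clamped to zero with the excess moved to the sibling so
  path lengths are preserved. On additive matrices the algorithm is
  exact (tested against a path-length oracle).
* **Bootstrap unit**: the SNP column, resampled with replacement;
  support is the fraction of replicates containing each internal-edge
  bipartition, computed from canonical bipartition keys rather than
  tree shapes.
* **PCA**: column centering only, no variance scaling (the codes share
  a scale); missing cells are imputed to the locus mean, i.e. zero
  after centering; computed by SVD.

## The synthetic study design

The simulator generates the conditions the analyses are designed for,
with defaults fixed to the study system's observed regimes:

| parameter | default | meaning |
|---|---|---|
| `het_parentA` | 0.019 | per-individual heterozygous fraction, diploid parent |
| `het_parentB` | 0.047 | fixed 2:2 homeolog heterozygosity, tetraploid parent |
| `d_fixed` | 0.0095 | fraction of sites reciprocally fixed between taxa |
| `depth_mean` | 83/88/105/100 | per-role Poisson mean depth (×) |
| `bias` | 1 | capture odds multiplier for reference-matching reads |
| `error` | 0.001 | per-read allele flip probability |

Site classes are drawn independently per site: reciprocally fixed
(`d_fixed`), diploid-polymorphic (pool $2\,h_A$, each diploid
heterozygous with probability 1/2 — low-frequency variants segregating
mostly as heterozygotes, so hom-alt diploids do not occur), tetraploid
fixed-heterozygous ($h_B$), otherwise monomorphic. Triploids receive
one reduced diploid gamete (uniform at heterozygous sites) and one
disomic tetraploid gamete (2:2 heterozygosity transmits as 1:1);
hexaploids are exact doublings of a designated triploid. Under this
design the expected triploid heterozygosity is
$d_\mathrm{fixed} + h_B + h_A/2$; the default `d_fixed` is the value
that makes this 0.066, the observed triploid regime, given the two
parental regimes. This calibration is fixed once, as part of the study
design, and the simulator's truth tables expose the realized fraction
for every draw.

Injected events model post-polyploidization change:
`single_copy_conversion` (one copy switched to a target allele, the
1/6-shift signature), `full_allele_loss` (all copies of one allele
converted — loss and conversion are indistinguishable at read level,
and this keeps copy number equal to ploidy), `single_copy_loss` (a true
deletion; the only event after which copy counts sum below ploidy), and
`novel_allele_gain` (one copy switched to an allele absent from the
parents; at an already biallelic site this is refused rather than
making the site triallelic). Read counts are Poisson-total,
binomial-split with odds `copy_count × bias^[allele = ref]`, then
error-flipped. Each generator stage seeds its RNG stream from
`seed + {0,1,2}`, so every stage and the emitted VCF are bit-identical
under a fixed configuration.

What the simulator does **not** emulate: linkage disequilibrium and
recombination (sites are independent), within-taxon population
structure beyond the diploid's private polymorphism (tetraploid
individuals are identical in truth), probe-level depth heterogeneity
(depth is i.i.d. Poisson per cell), indels, and mapping artifacts.
Passing recovery tests therefore demonstrates the estimators are
correct under the declared sampling model, not that real capture data
are free of the biases the model omits — which is exactly why the
capture-bias decomposition is part of the pipeline rather than of the
simulator's defaults.

## Numerical and degenerate-input choices

* Missing AD cells carry zero depth and a flag; they fail the depth
  filter rather than being dropped at parse time, so attrition is
  auditable.
* Cells with zero depth have undefined frequency (`NA`) and state
  `missing`; samples with zero genotyped sites get `NaN` heterozygosity
  rather than an error.
* An empty site set filters to an empty result with a complete report.
* A fully deleted site (repeated copy losses) yields zero reads.
* Distances are undefined (error) for sample pairs sharing no typed
  loci; an all-constant presence matrix yields zero PCA components.
* Window scans on linkage groups with fewer informative sites than the
  window emit no rows and record the group as skipped.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
panels: heterozygosity recovery uses 20,000 sites at 80–100× (the mean
estimate's Monte-Carlo SD is then ~0.001–0.002, tight enough to
separate the three regimes); dosage recovery uses ~1,000 diagnostic
sites at 100×; the window-scan signature uses a 30-site conversion
region at 150× (plateau SE ≈ 0.01); the demo pipeline uses ~4,800
sites and a 100-replicate bootstrap. These sizes make every claim
testable in seconds while keeping Monte-Carlo bands well below the
effect sizes being recovered.

## Known limitations

* Dosage genotypes (GGL vs GLL at a single site) are not called;
  dosage is estimated as a frequency, following the read-ratio design.
* Heterozygosity here is defined by the read-frequency rule at ≥ 50×;
  studies computing it from polyploid-mode genotype calls will differ
  slightly in the denominator.
* The Nei-distance prevalence encoding approximates, but cannot be
  proven identical to, the unpublished variants in common tool chains;
  the variant is documented and swappable.
* Bootstrap supports on clades containing truth-identical individuals
  are near-arbitrary among those individuals (any resolution of a
  zero-distance tie is topologically equivalent).
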