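---
title: "Genotype calling and diversity analysis for polyploid SNP arrays: models and methods"
author: "polyarray authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype calling and diversity analysis for polyploid SNP arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyarray)
```

## The problem

Genotyping arrays score a biallelic SNP from the intensities of two allele
probes, A and B. In an allohexaploid such as bread wheat (genomes A, B and
D), a probe rarely interrogates just one locus: homoeologous copies on the
sister subgenomes contribute signal, compressing and shifting the genotype
clusters; and structural variation means some accessions simply lack the
probe target, producing a fourth, low-intensity "null allele" cluster
(an off-target variant, OTV). `polyarray` implements the full analysis
chain for such arrays — signal transformation, penalized mixture-model
calling with OTV detection, probeset quality classification, diversity and
presence/absence analysis, mapping-population preparation, and the
resequencing-side SNP discovery and array design filters — together with a
synthetic-data module that generates every input with known truth.

## Signal space

Raw channel intensities `a` and `b` are mapped to

* contrast `= log2((100a + 100) / (100b + 100))`, and
* size `= [log2(100a + 100) + log2(100b + 100)] / 2`.

The offset keeps both finite at zero intensity. AA genotypes sit at
positive contrast, BB at negative, AB near zero; the size axis carries the
overall hybridization strength, which is what collapses for null-allele
carriers. The transform is invertible on `size >= log2(100) + |contrast|/2`,
and the generator samples in (contrast, size) space and inverts, so the
forward transform reproduces the sampled coordinates to machine precision
(the round-trip is asserted in the tests).

## The calling model

Each probeset is fit independently with an expectation–maximization (EM)
mixture of up to three diagonal-covariance Gaussian components in
(contrast, size), labelled BB ≤ AB ≤ AA by contrast order.

**Inbred penalty.** Inbred material carries almost no true heterozygotes,
so the AB component's prior mixing weight is divided by `2^penalty` and
the weights renormalized (penalty 4 is mild, 16 strong). The weights are
held at these penalized prior values during EM rather than re-estimated:
a multiplicative penalty has no maximum-likelihood fixed point (freely
re-estimated weights simply absorb it), and with fixed weights each EM
iteration provably does not decrease the data log-likelihood — an
invariant the test suite checks. The variance floor (`1e-8`) acts as a box
constraint and preserves the guarantee.

**Initialization.** Points are split into contiguous contrast-quantile
groups (ties broken by sample order), then refined by deterministic 1-D
Lloyd iterations on contrast. The refinement matters on skewed probesets:
with a 92/8 split of samples between two clusters, plain quantile thirds
place no centre near the minority cluster and EM can converge to a
component straddling both clouds.

**Structure cleanup.** After convergence a component is pruned when it
holds less than half an expected sample of posterior mass (a mixing
fraction below `1/(2n)`) or fewer than two hard-assigned members — a
single point is not a cluster, and every downstream metric (HomFLD in
particular) requires at least two. Two components are merged only when a
refit merged model loses less than `2 log n` log-likelihood, the BIC
credit for the four parameters freed: duplicate components splitting one
Gaussian cloud merge, while a component holding a genuinely distinct
cluster survives because removing it costs far more likelihood. Distance
thresholds were tried first and proved unstable — an asymmetric "flank
slice" of a big cluster looks exactly like a small distinct cluster in
mean/SD terms, and a variance-inflated straddling component can swallow a
tight distinct one.

**Labelling with fewer than three components.** A two-cluster probeset is
ambiguous: clusters at contrast 0 and +1.1 could be AB/AA (a locus with no
minor homozygote) or a compressed BB/AA pair (the polyploid signature).
The label assignment maximizes a penalized score: the log penalized prior
weight of each candidate label plus a Gaussian position anchor (BB, AB, AA
expected near contrast −1, 0, +1, scale 0.35). Because the same
`2^-penalty` factor enters the score, a mild penalty reads a near-zero
cluster as AB while a strong penalty re-reads it as a compressed
homozygote. This is precisely the mechanism behind two-step recalling:
probesets classified `NMH` or `Other` at penalty 4 are refit at penalty
16, and compressed-minor-homozygote probesets flip from NMH to PHR.

**Calls.** Each sample receives the maximum-posterior component label with
the posterior as confidence; below the confidence threshold (default 0.95)
the call is `NN`. Missing signals are excluded from fitting and always
call `NN`.

**Penalty monotonicity.** Raising the penalty never increases the number
of AB calls on resolvable geometry (cluster separation ≥ 6 SD; tested
across penalties 0–16) and between the two operating penalties 4 and 16 on
overlapping geometry. From the exact zero-penalty limit on heavily
overlapping clusters the unpenalized mixture MLE is structurally
ambiguous — the het component legitimately straddles the homozygote
clouds — so strict monotonicity from 0 is not claimed there.

## Off-target variant (null allele) detection

A null-allele cluster lies well below the genotype clusters in size. Two
detection routes run after each fit:

1. *Component rule*: among substantive components (≥ 2 members), the
   lowest-size component is declared a null cloud when its centre sits at
   least `2 × otv_size_gap` pooled size-SDs below the remaining components
   and it carries a minority of the mass.
2. *Robust fallback*: points below `median − otv_size_gap × MAD` of the
   size distribution form a candidate set; it is accepted when it has at
   least 3 members whose median lies `2 × otv_size_gap` scaled MADs below
   the median of the remaining ("clean") points, judged by the clean
   points' own MAD. The fallback catches null clouds that EM absorbed
   into a variance-inflated genotype component, and the doubled-gap
   confirmation keeps ordinary distribution tails from triggering it.

On detection the genotype mixture is refit on the non-null points, an OTV
component is added from the members' moments, and members are re-called
`OO`. The default gap is 2.0 pooled SDs. If every point lies in one low
cloud there is no gap to define and no split is made.

## Probeset QC and classification

Per-probeset metrics are computed from the calls and the called points'
empirical cluster statistics, so they can be re-derived from raw calls +
points (the tests re-derive them independently to 1e-9):

* **call rate** `1 − n_NN/n`; **het rate** `n_AB / called`;
* **HomRO**, the contrast position of the homozygous cluster closest to
  zero (`min(c_AA, −c_BB)` when both are present) — positive when the
  homozygous clusters flank zero as in a diploid, negative under
  homoeologous compression;
* **HomFLD**, the homozygote cluster separation over the
  membership-weighted pooled within-cluster contrast SD (undefined with
  fewer than 2 members in either cluster; undefined metrics fail every
  threshold comparison).

The six-way category cascade: call rate < 0.97 ⇒ `CRBT`; a null-allele
component ⇒ `OTV`; one called genotype ⇒ `MHR`; both homozygotes with at
least 2 minor-homozygote calls and HomFLD ≥ 3.6 ⇒ `PHR`; a missing or
too-thin minor homozygote ⇒ `NMH`; otherwise `Other`. `PHR` and `OTV` are
the *converted* categories, and a converted probeset is *diploidized*
when HomRO > 0.3 and HomFLD > 10. The call-rate threshold (0.97) and the
minor-homozygote minimum (2) are array-analysis conventions, configurable
because they are conventions rather than measurements; the HomFLD
thresholds 3.6 and 10 and the HomRO threshold 0.3 are the working values
of this analysis chain. CRBT is evaluated before OTV — an
unscorable probeset should not be promoted to a converted category by a
stray low-size cloud.

## Diversity

Per-locus variability is PIC `= 1 − Σ p_i²` over the allele frequencies
(two alleles per homozygote, one each per het; `NN` excluded, and `OO`
excluded too since a null allele is neither A nor B). Pairwise
dissimilarity is simple matching — mismatches over pairwise-complete
loci — with `OO` treated by default as a fourth state that can match or
mismatch (options: drop it, or force it to mismatch). Trees: Ward's
minimum-variance dendrogram (`hclust` `ward.D2`, i.e. the Lance–Williams
update on squared dissimilarities) and Saitou–Nei neighbor joining
(`ape::nj`), with negative NJ branch lengths clamped to zero and the
deficit moved to the sibling so path lengths are preserved. On an
additive matrix the NJ tree is exact, which the tests verify against the
unique realization of the tree metric up to 8 taxa.

For presence/absence analysis, loci categorized OTV with no missing call
anywhere are recoded `OO → 0` (target absent), any called genotype `→ 1`,
giving a binary matrix suitable for PAV phylogenies.

## Mapping preparation

Mapping-population markers pass five rules, all violations recorded:
category PHR; diploidized; both parents called, homozygous and opposite;
progeny missingness ≤ 15%; and a 1-degree-of-freedom chi-square of the
two parental homozygote counts against 1:1 with p > 0.01 (residual
heterozygotes and missing calls are excluded from the test — the
conventional marker-distortion test, without continuity correction).
Under a simulated null (10,000 markers, 430 individuals) the filter's
type-I rate is 1% within three binomial standard errors.

Cosegregation bins group markers whose genotype vectors agree at every
individual where both are called (and that share at least one such
individual). Missing-tolerant equality is not transitive, so bins are the
single-linkage transitive closure of that relation, and bins whose
members are not pairwise compatible are flagged. The bin representative
is the member with fewest missing calls, ties by identifier. Map
summaries report, per chromosome and overall: marker count, map length
(max − min), unique genetic positions (distinct cM values), non-redundant
markers (singleton bins), and mean bin length = length / unique
positions. Map-to-map concordance is the Spearman rank correlation of
shared-marker positions per chromosome.

## SNP discovery and array design

Variant records (VCF 4.2 with INFO `DP`/`MQ` and per-line `GT`) pass a
depth ≥ 5 and RMS mapping quality ≥ 30 filter (boundaries inclusive).
Loci are classified by the observed genotype set across lines: class 1
(only AA and BB), class 2 (AA, AB and BB), class 3 (one homozygote plus
AB), class 4 (all AB); only classes 1–2 are usable for array design. The
class-3 definition is stated one-sidedly (AA + AB) in the source
taxonomy; it is applied symmetrically by allele relabelling, with a
strict mode available. Transitions are `{A,G}`/`{C,T}` pairs; the Ts/Tv
ratio is undefined only when there are no transversions. A SNP is private
to a line when that line is the only non-reference carrier among
informative lines (records with fewer than two informative lines are
excluded from denominators).

Array candidates must be carried by at least two lines, polymorphic
within the European pool, single-hit in the genome, and of usable class.
Per-arm quotas are proportional to physical arm size with D-genome arms
double-weighted (compensating the D genome's depressed polymorphism),
integerized by largest remainder so the total is exact; arms are filled
in order of descending carrier count, then position, then identifier.

## The synthetic-data module

The generator produces every input the pipeline consumes, with truth:

* **Array experiments** (default 96 samples × 1000 probesets): a class
  mix mirroring the observed spectrum of a hexaploid wheat array —
  45% diploidized geometry (tight AA/AB/BB clusters at contrast ±1.2/0),
  14% homoeologous-offset (both homozygous centres on one side, the
  nearest at contrast 0.1, giving the low-HomRO signature), 17%
  monomorphic, 9% null-allele-bearing (carrier frequency 0.3, null cloud
  3 size-units below), 15% low-quality (overlapping clusters plus excess
  missingness). Residual heterozygosity defaults to 1.5% as observed for
  inbred panels. Signal-level missingness defaults to 0.5%: the ~1%
  missing-call rate of a good run combines absent signals with
  low-confidence calls, and at 96 samples a raw 1% missing-at-random rate
  alone would drop ~7% of perfect probesets below the 0.97 call-rate
  threshold, which does not match the category spectrum being emulated.
  Sampled (contrast, size) coordinates are clamped to the invertible
  region of the transform (channel intensities cannot be negative);
  this touches only the extreme tail of the null cloud.
* **Diversity panels**: Balding–Nichols structure — group allele
  frequencies are Beta draws around a uniform ancestral frequency with
  variance `fst·p(1−p)`; fully inbred genotypes; missing completely at
  random.
* **RIL populations** (default F6 by single-seed descent, 430
  individuals): parents are fixed opposite homozygotes; along each
  chromosome the inherited allele follows a Markov chain whose
  adjacent-marker switch probability is the inverse Kosambi (or Haldane)
  function of the cM gap; residual heterozygosity is a second Markov mask
  with stationary rate `(1/2)^(generation−1)` whose re-draw probability,
  `2(g−1)r`, also vanishes at zero distance — so fully linked markers
  give identical columns while per-locus heterozygosity matches the SSD
  expectation of 3.125% at F6. Because genotypes are correlated along
  chromosomes, the calibration tests use cluster-robust standard errors
  across individuals rather than naive binomial ones. Distortion loci
  resample the transmitted allele with the configured bias (which
  decouples that marker from its neighbours — adequate for testing the
  distortion filter, not for fine-mapping studies of distorted regions).
* **Variant records**: per-line genotype patterns realizing a requested
  class 1–4 mix, ref/alt pairs drawn to a target transition fraction,
  depth and mapping quality from user distributions, fraction labels and
  multi-hit flags for the design filters. The locus-class definitions
  are parameterised over the number of lines, since the source taxonomy
  speaks of "ten lines" where eight were sequenced.

Seeding: one master seed; each generator derives a child seed by a fixed
offset, so runs are bitwise reproducible and independent stages do not
share streams.

**What passing on synthetic data does and does not show.** The generator
reproduces the geometry and the marginal statistics the methods rely on
(cluster positions and spreads, size collapse for null alleles, class
proportions, recombination and residual-het rates, Ts/Tv composition).
It does not emulate plate/batch effects, probe-sequence-specific
intensity bias, linkage disequilibrium beyond group structure,
non-random missingness, or segregation distortion arising from linked
selection. Recovery rates measured here (category recovery ≥ 90–95%,
calling accuracy ≥ 99% at ≥ 6 SD separation) are therefore statements
about the algorithms under the stated model, not field performance
guarantees.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the array pipeline at 96
samples × 1000 probesets (category recovery), 150 probesets of pure
diploidized geometry (accuracy), a 5 × 19 panel at 2000 loci (PIC), a
430-individual RIL population over 5 chromosomes × 200 markers, a
10,000-marker distortion null, and 20,000 variant records. These sizes
give sub-percent Monte-Carlo noise on every reported rate while keeping a
full run in the low tens of seconds; published table counts are used as
inputs where the corresponding real datasets (whole-genome resequencing,
the physical array, the mapping population) are not reproducible at desk
scale.

## Known limitations

* The caller is a stand-in for the array vendor's proprietary pipeline:
  it honours the documented behaviours (penalized het prior, two-step
  recalling, OTV splitting, HomRO/HomFLD-based QC) but does not reproduce
  its numerical output.
* Two-cluster label assignment is genuinely ambiguous for clusters near
  contrast 0.1–0.3; the penalized score resolves it the way the inbred
  penalty dictates, and compressed homoeologous probesets with a thin
  minor cluster may classify NMH at the mild penalty until the second
  pass re-reads them.
* Cosegregation binning is quadratic in markers (vectorized as indicator
  cross-products); beyond ~50k markers it should be applied per
  chromosome.
* Map construction itself (linkage grouping, ordering) is out of scope;
  summaries operate on supplied maps.
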