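---
title: "Modeling UV-induced mitotic recombination and LOH in a diploid genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling UV-induced mitotic recombination and LOH in a diploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvloh)
```

## The system being modeled

A diploid budding-yeast-like genome heterozygous at ~13,000 SNPs is
irradiated with UV in G1. Pyrimidine dimers are processed by nucleotide
excision repair; a small fraction of lesions become recombinogenic breaks.
Two break classes matter for loss of heterozygosity (LOH):

* **SCB** — a single-chromatid break, arising in S/G2 when replication runs
  over an unrepaired lesion or excision gap. One of the two sister
  chromatids is broken; repair off the homolog produces a 3:1 conversion
  tract (three chromatids carry one parent's allele).
* **DSCB** — a double-sister-chromatid break, arising when a G1 double-strand
  break (typically from two closely-opposed dimers on opposite strands) is
  replicated. Both sisters are broken at the same position; independent
  repair of the two sisters produces 4:0 tracts, hybrid 3:1/4:0 tracts, and
  frequent crossover association.

Repair pathways are sampled per broken chromatid: SDSA (non-crossover
conversion), double-Holliday-junction repair resolved with or without a
crossover, and break-induced replication (BIR), which copies the donor
homolog from the break to the telomere. A crossover exchanges everything
distal to the tract between the recombinant chromatids; whether that
produces reciprocal terminal LOH in the daughter cells depends on which
chromatids co-segregate — the two patterns are equiprobable, so only half
of crossovers are detectable as LOH. Conversions and BIR are always
detectable. This factor-of-two asymmetry drives the detection correction in
`detection_corrected_counts()`.

A terminal copy-number colour marker on one chromosome (0/1/2 copies give
red/pink/white colonies) defines a ~120 kb selected interval: a crossover
between the centromere and the marker that segregates reciprocally yields a
red/white sectored colony, and the two sectors are the two daughter
genomes. The caller and classifier operate on exactly this sector pair.

## What the simulator emulates — and what it does not

`make_default_genome()` builds a 16-chromosome, ~12.7 Mb diploid with
~13,000 SNPs at ~0.9 kb mean spacing, 20 kb SNP-free subtelomeric ends
(arrays cannot assay repetitive chromosome ends), an rDNA-like cluster
covering ~10% of the genome on one large chromosome (SNP-free, as tandem
repeats are array-invisible), and dispersed LTR/tRNA/ncRNA-like annotation
classes for enrichment analyses.

The generator's defaults are the study conditions:

| parameter | default | why |
|---|---|---|
| `dimers_per_jm2` | 500 /J/m2 | ~7500 dimers per diploid genome at 15 J/m2 |
| `closely_opposed_max_sep` | 75 bp | definition of a closely-opposed pair |
| `scb_rate_per_dimer` | 0.00255 | with `interhomolog_prob`, ~4 interhomolog SCB events/cell at 15 J/m2 |
| `dscb_from_opposed` | 0.048 | ~4 DSCB events/cell at 15 J/m2: about half of events are mechanistically DSCBs, so that the *observed* DSCB share among classified conversions (which loses DSCBs whose second sister tract covers <2 SNPs) lands near 44% |
| `interhomolog_prob` | 0.21 | S/G2 SCBs repaired off the sister are invisible to LOH and are pruned at generation; G1-origin DSCBs have no intact sister and always use the homolog |
| `pathway_probs` | sdsa .37, dsbr_co .315, dsbr_nco .26, bir .055 | after the 1/2 crossover detection loss, observed events split ~79% conversions, ~16% crossovers, ~5.5% BIR |
| `tract_median_kb` / `tract_median_co_kb` | 3.9 / 7.15 | see tract calibration below |
| `noise_sd` | 0.1 | array-like ratio noise |

Together these give about eight interhomolog events per cell at 15 J/m2 and
a red/white sectored-colony frequency of order 1%, dominated by SCBs at
1 J/m2 (SCB counts scale linearly with dose, closely-opposed pairs — hence
DSCBs — quadratically).

Deliberate simplifications: dimer placement is sequence-independent (no
dipyrimidine weighting; AA/TT composition effects are handled analytically
in `dinucleotide_freq()`/`dinucleotide_compare()` instead); the rDNA is one
interval, not repeat units; no checkpoint signaling, fork geometry, or
transcription-coupled repair; damage persisting into the second division is
off by default (`second_division_prob = 0`) because nearly all events in
the modeled system arise before the first division; the three G1 mechanisms
that convert closely-opposed dimers into a DSB are collapsed into a single
DSCB channel, since their LOH outcomes are indistinguishable. Passing tests
therefore demonstrate internal consistency of the method under these
conditions, not fidelity to every feature of real arrays (probe-specific
bias, spatial artifacts, GC effects are not modeled).

## Tract lengths and their calibration

Conversion tracts are gamma-distributed (shape 2), parameterized by their
median; the scale is set so the median is exact. Crossover-associated
tracts draw from a longer-median distribution. For a DSCB, with probability
`dscb_equal_tract_prob` (0.4) the two sisters share identical tract bounds
(a pure 4:0 tract); otherwise the second sister's tract is nested inside
the first's, producing hybrid 3:1/4:0 patterns while keeping the
event-level tract on the calibrated distribution — independent per-sister
draws would systematically inflate the union span.

Tract lengths are *measured* as the mean of the minimal span (first to last
LOH SNP) and maximal span (flanking heterozygous SNPs), which is unbiased
at the marker resolution. But tracts covering fewer than `min_run = 2`
SNPs are undetectable, and this selection raises the median of *observed*
tracts by roughly 1 kb at ~0.9 kb spacing. The draw medians (3.9 kb
non-crossover, 7.15 kb crossover-associated) are therefore set below the
target observed medians (~4.9 and ~7.6 kb, overall ~5.6 kb), so that what
the full array → call → classify → measure pipeline reports matches the
observed-scale medians. This distinction — calibrating the latent
distribution against the observable statistic — is the package's own
design choice and is worth keeping in mind when changing either the SNP
density or `min_run`.

## Calling and segmentation choices

`call_states()` uses fixed ratio bands: homozygous for the retained allele
at ≥1.4 with the lost allele at ≤0.6, heterozygous with both channels in
[0.7, 1.3], `NOCALL` otherwise. The bands are calibrated on the simulator
(at `noise_sd = 0.15`, >99% of called SNPs are correct, and errors land in
`NOCALL` rather than the wrong state); no published numeric cutoffs exist
for this assay, so the defaults are exposed as arguments.

`segment_states()` requires `min_run = 2` SNPs to call an LOH segment —
single-SNP discordances are treated as noise, which matches the ~1 kb
resolution claim of the array. `NOCALL` SNPs never break a run, and every
transition carries an inner bound (last SNP of the left segment) and outer
bound (first SNP of the right segment), the min/max localisation the
markers allow. There is deliberately no HMM or smoothing: behaviour is
auditable SNP by SNP, and the classifier's cluster logic supplies the
robustness that smoothing would otherwise provide.

## Classifier decision rules

Events are classified per *independent cluster*: LOH separated by more than
15 kb of shared heterozygosity is assumed to derive from independent
initiating lesions. Within a cluster, each SNP is coded jointly across the
two sectors (reciprocal homozygosity = crossover point; one-sector
homozygosity = 3:1; same-direction homozygosity in both = 4:0) and the
rules are, in order: whole-chromosome LOH in one sector → chromosome loss;
reciprocal terminal LOH → crossover (with conversion if 3:1/4:0 points are
present); terminal LOH in exactly one sector → BIR; interstitial LOH →
3:1, 4:0 or hybrid conversion; anything else → complex. Two sectors' tracts
count as "identical" (4:0) when their bounds agree to within one SNP per
boundary, since exact coincidence is unobservable at array resolution. Any
4:0 segment implies a DSCB; a pure 3:1 tract implies an SCB; patterns
without a tract leave the mechanism undetermined. The recipient homolog is
the one whose alleles were overwritten — the homolog that received the
break — so the donor is simply the direction of the new homozygosity.

A crossover whose conversion tract lies on the unexpected sector, and a
DSCB with one BIR sister, are both reported as `complex` rather than being
decomposed into multi-break reconstructions; the ground-truth labels of the
simulator make the same choice, so cohort statistics stay comparable.

## Statistics layer

* Median confidence intervals use the binomial order-statistic construction
  (ranks n/2 ± z√n/2), the standard tabulated small-sample method.
* Distribution comparisons use the two-sided Mann-Whitney U test — exact
  for small tie-free samples, normal approximation with tie correction
  otherwise; the test suite holds it against a complete-enumeration oracle
  for n1+n2 ≤ 12.
* Control normalization subtracts untreated counts scaled by the ratio of
  colonies examined; per-kb frequencies multiply by the detection factor
  (2 for crossovers) before dividing by interval length. Rounding happens
  only at reporting.
* Regional expectation tests report both the exact binomial p and a 1-df
  chi-square p (continuity correction available via `correct = TRUE`; note
  that for the rDNA cold-spot example, 0 observed versus 6 expected of 60,
  the uncorrected chi-square gives p ≈ 0.01 and the corrected one ≈ 0.02).
* Element enrichment is a permutation test: same-length tracts are placed
  uniformly on the SNP-covered genome (SNP-free regions are excluded
  because observed tracts can only be seen where markers exist), with
  two-sided add-one empirical p-values and Benjamini-Hochberg adjustment
  across element classes.
* The chromosome XII assay (`predict_phenotypes()`, `classify_rdna_colony()`,
  `tabulate_rdna()`) resolves marker zygosity, not only growth phenotype:
  5-FOA papillation separates URA3/URA3 crossover sectors from ura3/URA3
  BIR sectors, and the BIR class that produces no growth sectoring at all
  is imputed as equal to its counterpart on the other homolog, never
  altering crossover counts.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive internally; BED output is 0-based
half-open. All randomness flows from explicit seeds; experiments derive
per-colony child seeds from the root seed, so any colony can be
regenerated alone. Negative normalized counts clamp to zero with a
warning; empty cohorts give zero tables; a median CI needs n ≥ 8; empty
annotation classes are skipped with a warning; the closely-opposed
expectation is 0 for fewer than two dimers.

Problem sizes used by the test suite and the acceptance script — a few
hundred simulated colonies for tract medians and classifier recovery, 10^4
segregations for the crossover sectoring probability, 100 paired seeds for
the dose sweep — were chosen so each statistic's Monte-Carlo error is well
inside the tolerance being checked.

## Known limitations

The closely-opposed-pair expectation under uniform placement is ~44–88
depending on ploidy and windowing assumptions, and does not reduce to the
~35 sometimes quoted from dosimetry-based calculations under any single
assumption set; the function exposes its assumptions as parameters and is
validated against a Monte-Carlo oracle rather than that figure. Real
genome sequence is not shipped, so genome-wide AA/TT values and a real
event map cannot be reproduced here; the composition machinery is instead
verified against closed forms on synthetic sequence, and applying it to
real data only requires passing the sequences of tracts and background
regions to `dinucleotide_compare()`. Chromosome-loss calling checks the
LOH geometry but does not independently verify copy number; with real
array data a colour/copy-number cross-check is advisable.
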