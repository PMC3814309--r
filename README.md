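# uvloh

Genome-wide analysis of UV-induced mitotic recombination in a
SNP-heterozygous diploid, as read out by loss of heterozygosity (LOH) in
sectored colonies.

UV lesions (pyrimidine dimers) become recombinogenic chromosome breaks: a
single-chromatid break (SCB, one broken sister chromatid, S/G2 origin) or a
double-sister-chromatid break (DSCB, both sisters broken at one position,
from a G1 double-strand break at closely-opposed dimers). Repair off the
homolog — by synthesis-dependent strand annealing, double-Holliday-junction
resolution (± crossover), or break-induced replication (BIR) — converts
heterozygous SNPs to homozygosity. On ~13,000-SNP arrays, a colony's two
sectors (the two daughter cells of the irradiated cell) show diagnostic
joint patterns: a 3:1 conversion tract (one sector interstitially
homozygous) marks an SCB, a 4:0 or hybrid 3:1/4:0 tract (both sectors
homozygous in the same direction) marks a DSCB, reciprocal terminal LOH
marks a crossover (detectable in only half of segregations), and
one-sector terminal LOH marks BIR.

The package provides, as a connected pipeline:

* **`recomb simulator`** — a forward simulator from dose to colony:
  Poisson dimer placement (~500/diploid genome per J/m², so ~7500 at
  15 J/m²), closely-opposed-pair detection (≤75 bp, opposite strands),
  SCB/DSCB generation, pathway sampling, gamma-distributed median-calibrated
  conversion tracts with directional/patchy mismatch repair, chromatid
  segregation, colony colour from a terminal copy-number marker
  (0/1/2 copies → red/pink/white), and array-like hybridization ratios
  (`sim_config()`, `simulate_colony()`, `simulate_experiment()`).
* **LOH caller** — per-SNP zygosity from allele-specific ratios and
  segmentation into LOH blocks with minimal/maximal transition bounds
  (`call_states()`, `segment_states()`).
* **Event classifier** — pairs the two sectors, groups LOH into independent
  clusters (>15 kb of shared heterozygosity ⇒ independent events), and
  assigns kind / conversion pattern / SCB–DSCB mechanism / recipient
  homolog (`classify_events()`, `summarize_cohort()`).
* **Statistics** — tract lengths with rank-based median CIs, Mann-Whitney
  comparisons, detection-corrected rates (crossovers ×2), control
  normalization, regional expectation tests, chromosome-size regression,
  permutation element enrichment with Benjamini-Hochberg adjustment, and
  AA/TT dinucleotide composition (`tract_lengths()`, `median_with_ci()`,
  `normalized_induced()`, `region_expectation_test()`,
  `element_enrichment()`, ...).
* **Chromosome XII rDNA assay** — the three-marker (HYG / intra-rDNA TRP1 /
  distal URA3, with 5-FOA papillation) logic for crossovers, BIR and
  intrachromosomal events around the rDNA cluster (`predict_phenotypes()`,
  `classify_rdna_colony()`, `tabulate_rdna()`).

## Worked example

Simulate one irradiated G1 cell at 15 J/m², hybridize both sectors, and
classify:

```r
library(uvloh)
genome <- make_default_genome(seed = 1)   # 16 chromosomes, ~13,000 SNPs
cfg    <- sim_config(dose = 15)
colony <- simulate_colony(cfg, genome, seed = 42)
colony
#> colony_truth: unsectored colony (pink/pink), 4 interhomolog event(s)
#>   chrom    pos mechanism           kind pattern
#> 1 chr12 862751       SCB             CO    none
#> 2 chr03 108298       SCB NCO_conversion     3:1
#> 3 chr08 141179      DSCB             CO     3:1
#> 4 chr03  43107      DSCB NCO_conversion     4:0

events <- classify_colony(simulate_array(colony$daughters$a, config = cfg),
                          simulate_array(colony$daughters$b, config = cfg))
events[, c("chrom", "kind", "pattern", "mechanism", "recipient",
           "tract_min", "tract_max")]
#>   chrom           kind pattern mechanism recipient tract_min tract_max
#> 1 chr03 NCO_conversion     4:0      DSCB        P2      1295      4265
#> 2 chr08            BIR    none      <NA> ambiguous        NA        NA
```

This cell suffered four interhomolog events, but the arrays see two — which
is the point of the model. The chr12 crossover co-segregated its recombinant
chromatids into the same daughter (the undetectable half of crossovers), the
chr03 SCB tract covered too few SNPs to call, and the chr03 DSCB shows the
textbook 4:0 tract: both sectors homozygous for the P1 homolog over the same
tract (minimal length 1.3 kb between the outermost LOH SNPs, maximal 4.3 kb
between the flanking heterozygous SNPs), so the recipient of the break was
the P2 homolog. The chr08
DSCB-crossover presents as one-sector terminal LOH under this segregation,
which an array reader can only label BIR.

The chromosome XII assay reproduces a full normalized count table from
observed sector phenotypes, imputing the phenotypically silent BIR class:

```r
tabulate_rdna(observed  = c(49, 9, 2, 77, 16, 9, 15, 8, NA, 116),
              untreated = c(1, 0, 0, 5, 2, 1, 0, 1, NA, 6),
              n_treated = 3902, n_untreated = 5197)
#> rdna_table: 3902 treated / 5197 untreated colonies
#>           category observed untreated normalized
#> 1    RCO CEN12-HYG       49         1         48
#> ...
#> 10             ICR      116         6        111
#> crossovers/kb: CEN12-HYG 8.2e-05, HYG-URA3 3.9e-05
```

The per-kb crossover frequency inside the 1170 kb rDNA-containing interval
is 2–4× lower than in the flanking 300 kb interval — the rDNA cold spot —
after multiplying by the detection factor 2 (only half of crossovers
produce sectors) and subtracting the spontaneous background scaled by the
ratio of colonies examined.

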