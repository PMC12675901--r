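# degronseq

Spike-in calibrated analysis of nascent RNA-seq time courses after acute
transcription-factor depletion (auxin-inducible degron style designs), for
computational biologists working on transcriptional regulation in stem
cells and similar systems.

When a master regulator is destroyed within hours, most of the
transcriptome goes down together. Library-size normalization silently
re-centres such data and erases the effect; exogenous spike-in RNA added
in constant amounts per sample anchors the scale instead. `degronseq`
implements the full desk-side pipeline around that idea:

* **Quantification** — interval counting of aligned-read intervals over
  genes, enhancers, called eRNAs and spike-ins (`countReads()`), held in a
  `SummarizedExperiment` subclass with spike-in flags and condition labels.
* **Normalization** — median-of-ratios size factors computed from
  spike-ins only, `s_j = median_f k_fj / (∏_j k_fj)^{1/n}`, rescaled to
  geometric mean 1 (`calcSizeFactors()`). Spike-in factors are invariant
  to arbitrary fold changes on biological features.
* **Differential expression** — negative-binomial Wald test
  (`Var = μ + αμ²`, method-of-moments dispersion, pseudocount 0.5,
  delta-method SE), BH adjustment, and threshold calling at the two
  conventions used in this field: genes at fold change > 2 with adjusted
  p < 0.05, enhancers/eRNAs at fold change > 1.5 with raw p < 0.05
  (`waldTest()`, `callFeatures()`).
* **eRNA calling** — per-strand segmentation of coverage (depth ≥ 2
  bridged across ≤ 250 bp gaps, minimum 200 bp), exclusion of units
  overlapping protein-coding genes on either strand or structural ncRNAs,
  designation by TSS-in-enhancer, nearest-TSS target assignment within
  100 kb (`callTranscriptUnits()`, `designateErnas()`, `assignTargets()`).
* **Integration** — ChIP-seq occupancy of super-enhancers (SE) and
  typical enhancers (TE), four-way classification of down-regulated genes
  by the enhancer classes targeting them, bound-vs-unbound rank-sum
  comparisons, and the direct-target intersections
  (`integrateReport()`).
* **Simulation** — a deterministic generator of the whole miniature study
  (annotation, catalogs, peaks, counts with planted global shutdown,
  coverage with planted eRNA units) plus a structural reference fixture
  (`simulateAnnotation()`, `simulateCounts()`, `simulateCoverage()`,
  `referenceFixture()`).

Inputs are plain text in standard formats — BED, GTF, bedGraph — parsed
into `GRanges` with strict validation (`readBed()`, `readGtfGenes()`,
`readBedGraph()` and matching writers).

## Worked example

The reference fixture encodes a complete integration run structurally, so
the example is exact and instantaneous:

```r
library(degronseq)

fx  <- referenceFixture()
rep <- integrateReport(fx$geneDE, fx$enhDE, fx$genes, fx$enhancers,
                       fx$peaks, fx$seMap, fx$teMap)
rep
#> IntegrationReport
#>   SE: 231 total, 169 bound, 104 down-called
#>   TE: 8563 total, 4577 bound, 295 down-called
#>   down genes: 604  up genes: 22  bound-down genes: 288
#>   gene classes: SE_and_TE=20 Only_SE=22 Only_TE=311 Not_assigned=251
#> DirectTargetReport
#>   list1 (bound, down genes):            288
#>   list2 (targets of bound-down SEs):    84
#>   list3 (targets of bound-down TEs):    201
#>   overlap 1&2: 26   overlap 1&3: 86   union: 111

head(percentTable(rep), 6)
#>            label numerator denominator percent
#> 1       SE bound       169         231    73.2
#> 2       TE bound      4577        8563    53.5
#> 3        SE down       104         231    45.0
#> 4        TE down       295        8563     3.4
#> 5  down SE bound        84         104    80.8
#> 6  down TE bound       201         295    68.1
```

Reading the output: 169 of 231 super-enhancers (73.2 %) overlap a peak of
the depleted factor; of the 104 super-enhancers transcriptionally
down-regulated at the acute timepoint, 84 (80.8 %) are factor-bound. Of
604 down-regulated genes, 288 are factor-bound (list 1); intersecting
list 1 with the targets of bound, down-regulated SEs and TEs gives 26 and
86 genes respectively, one gene shared — a union of 111 putative direct
targets.

The statistical side runs on the simulator:

```r
cfg <- simulationConfig(seed = 1)          # 60% of genes truly down 4-fold
ann <- simulateAnnotation(cfg)
sim <- simulateCounts(cfg, ann)
res <- waldTest(sim$se, "0h", "4h")        # spike-in factors by default
nullG <- setdiff(ann$genes$gene_id, sim$truth$downGenes)
median(res[nullG, "log2fc"])
#> [1] -0.01173329
```

Under all-features normalization the same null genes come out shifted by
about +1.4 log2 units — the artifact the spike-ins exist to prevent.

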