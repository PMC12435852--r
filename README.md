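# gczone

Spatial analysis of germinal-center (GC) zonation for single-cell resolved
spatial transcriptomics. The GC is functionally split into a dark zone (DZ),
where B cells proliferate and hypermutate, and a light zone (LZ), where they
are selected through contact with T cells. Most T-cell subsets are excluded
from the DZ, and aggressive "DZ-like" lymphomas echo this immune-cold
phenotype. `gczone` provides the computational toolkit to quantify this
organisation in one pre-cropped GC: per-cell DZ/LZ signature scoring and
classification, graph-based region segmentation with boundary extraction,
distance-binned T-cell enrichment profiling with a Monte-Carlo slope
envelope, and a nearest-neighbor immune-exclusion test. A synthetic tissue
generator with analytic ground truth backs every stage, so the whole
pipeline is testable without external data.

## The method

Given a cells × genes count matrix with micrometre coordinates:

1. **QC and normalization.** Cells with ≥ 3,000 detected genes or ≤ 400
   total counts are removed. Counts are scaled to the median library size,
   `log1p`-transformed and z-scaled per gene.
2. **Scoring and classification.** DZ and LZ signature scores are the mean
   z-scaled expression over the signature genes (an expression-matched
   control-bin method is available). The combined score
   `s = score_DZ − score_LZ` classifies each cell: `s > 0.3` → DZ,
   `s < −0.3` → LZ, otherwise intermediate.
3. **Region formation.** A spatial graph connects cells within a neighbor
   radius (default 30 µm). Synchronous sweeps relabel intermediate cells by
   the majority phenotype of their neighbors, and flip DZ/LZ cells whose
   originally-opposite neighbor fraction exceeds a dissimilarity threshold
   (default 0.5), until a fixpoint. Each region must retain ≥ 70% of its
   namesake phenotype (measured against the original calls) before a
   boundary is extracted from the midpoints of DZ–LZ cross edges.
4. **Enrichment gradient.** Signed boundary distance (negative = DZ) is
   binned in 10-µm steps over −100…100 µm; the per-bin subtype fraction is
   regressed on the bin centers by OLS. The observed slope is compared with
   a null distribution from Monte-Carlo relabellings (subtype assigned to a
   uniformly random subset of observed positions, count fixed; default
   10,000 draws). Slopes above the 97.5th null percentile are called
   *increasing* (toward the LZ), below the 2.5th *decreasing*, otherwise
   *random*.
5. **Exclusion test.** Nearest-neighbor distances between two cell
   populations are compared with randomized controls (label permutation over
   pooled positions) by a two-sided Wilcoxon rank-sum test.

The packaged 169-gene DZ / 201-gene LZ lists are a synthetic stand-in with a
core of canonical zone markers (see `?gc_signatures`); any GMT or
two-column TSV signature can be supplied instead.

## Worked example

```r
library(gczone)

sim <- generate_gc(synthetic_config(
  n_cells = 2000, signature_effect = 1.5, label_noise = 0.1,
  subtypes = list(subtype_spec("Tfh", 150, gradient_beta = 0.03),
                  subtype_spec("DN", 150, gradient_type = "uniform")),
  seed = 42))

report <- run_gc_pipeline(sim$cells, dz_sig = sim$signatures$DZ,
                          lz_sig = sim$signatures$LZ, n_sim = 1000, seed = 7)
report
#> <gczone_report> 2000/2000 cells after QC; DZ purity 0.886, LZ purity 0.903 (minimum 0.70): pass
#>   DN: slope -3.18e-05, trend random
#>   Tfh: slope 0.00134, trend increasing
```

The simulated GC carries a Tfh-like subtype with a logistic enrichment
gradient toward the LZ and a spatially uniform double-negative (DN)
control. The pipeline recovers exactly that: both regions pass the 70%
purity gate, the Tfh fraction rises by ≈ 0.0013 per µm across the boundary
and is called `increasing` against the Monte-Carlo envelope, while the DN
slope is indistinguishable from randomness. The exclusion statistic on the
same tissue:

```r
tfh <- subset(report$annotation, subtype == "Tfh")
dzb <- subset(report$annotation, region == "DZ_region" & subtype == "none")
excl <- nn_exclusion_test(cbind(tfh$x, tfh$y), cbind(dzb$x, dzb$y),
                          n_rand = 100, seed = 1)
#> Tfh vs DZ cells: median NN 102.0 um (null 3.3), p = 2.15e-98, excluded
```

Tfh cells sit a median 102 µm from the nearest DZ cell, against 3.3 µm
under the randomized control — strong spatial exclusion from the DZ.

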