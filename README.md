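# tagdge

Differential gene expression from **tag-based digital transcript abundance
(DTA/DGE) profiling** — the NlaIII/MmeI library design in which every mRNA
contributes a single 21-bp 3' tag (a CATG anchor plus 17 variable bases) and
tag counts are a digital readout of transcript abundance. The package is
aimed at analysts working with SAGE/DGE-style libraries against a de novo
assembled reference transcriptome (unigene set), typically in non-model
organisms: it covers virtual-tag indexing, tag cleaning, mismatch-tolerant
unambiguous mapping, TPM normalization, exact-test significance calls with
FDR control, tag-to-unigene rollup, and the companion qRT-PCR and
phenotype (fruit-abscission) quantifications such studies report. A
synthetic-data generator emulates the whole study design so every stage is
testable without external downloads.

## The statistic at the core

For an entity with `x` copies among the `N1` clean tags of library 1, the
Audic–Claverie exact conditional test asks how surprising `y` copies among
`N2` clean tags of library 2 would be under equal relative abundance:

    p(y | x) = (N2/N1)^y * (x+y)! / ( x! * y! * (1 + N2/N1)^(x+y+1) )

equivalently the negative-binomial law `NB(x+1, N1/(N1+N2))`. `tagdge`
evaluates it in log-space via log-gamma, forms inclusive two-sided tail
p-values, adjusts them with Benjamini–Hochberg, and calls an entity
significant when `q ≤ 0.001` and `|log2(TPM2/TPM1)| ≥ 1` (fold-change ≥ 2),
all thresholds inclusive. TPM is *transcripts per million clean tags*:
`count / total_clean * 1e6`.

## Worked example

Simulate a small two-condition study (1,000 unigenes, 200,000 tags per
library, 10% of unigenes planted at a four-fold change) and run the full
pipeline:

```r
library(tagdge)

cfg <- sim_config(n_unigenes = 1000, depth_per_library = 200000,
                  frac_de = 0.1, log2fc_magnitude = 2,
                  error_rate = 0.01, frac_n_tags = 0.02, seed = 42)
ref    <- generate_reference(cfg)
truth  <- assign_abundances(ref, cfg)
tags_a <- simulate_library(ref, truth, "a", cfg)   # control library
tags_b <- simulate_library(ref, truth, "b", cfg)   # treatment library

bundle <- run_pipeline(pipeline_config(reference = ref, tags_a = tags_a,
                                       tags_b = tags_b, out_dir = "run1"))
```

The run logs the attrition of every stage and ends with the unigene calls:

```
indexing 1000 unigenes (both strand)
cleaned library_a: 200,000 raw -> 182,258 clean (7,437 distinct); removed length=0 N=4,000 low-complexity=124 copy<2=13,618
cleaned library_b: 200,000 raw -> 182,730 clean (7,135 distinct); removed length=0 N=4,000 low-complexity=92 copy<2=13,178
mapped library_a: 7,419 distinct unambiguous (182,222 copies) into 990 unigenes
mapped library_b: 7,110 distinct unambiguous (182,679 copies) into 981 unigenes
significant unigenes: 66 (39 up, 27 down) of 992 tested
```

Reading the numbers: of 200,000 raw tags per library, the N-containing,
low-complexity and singleton tags are removed (the singletons are mostly
one-off sequencing errors); nearly all remaining distinct tags map
unambiguously back to the reference; and at `FDR ≤ 0.001` with
`|log2 ratio| ≥ 1`, 66 unigenes are called (planted effects at low
abundance stay undetected by design — two libraries of this depth cannot
resolve them). The per-unigene table shows counts, TPM, ratio and q-value:

```r
head(subset(bundle$unigene_result$records, significant))
#>          id   x   y      tpm1       tpm2 log2_ratio      q_value direction
#> 4  UN000004  57  12  312.7435   65.67066  -2.251659 3.388152e-07      down
#> 40 UN000040  64 216  351.1506 1182.07191   1.751156 6.443698e-19        up
#> 44 UN000044 274  57 1503.3634  311.93564  -2.268873 6.270829e-34      down
```

`run1/` now holds every stage as a TSV (clean report, mapping reports,
count/TPM matrix, tag- and unigene-level DE tables, fold-change
distribution, category summary) plus `summary.json`, whose numbers are all
recomputable from the tables. `delta_delta_ct()` and `cfar()` handle the
qRT-PCR and abscission sides of such a study; see the methods vignette
(`vignettes/tag-dge-methods.Rmd`) for the model, parameter and convention
details, and `inst/cli/tagdge-pipeline.R` for a shell entry point.

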