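---
title: "Methods: tag-based digital gene expression analysis with tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based digital gene expression analysis with tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The measurement model

Digital transcript abundance (DTA) profiling of the NlaIII/MmeI type reads
out gene expression as tag counts. NlaIII cuts cDNA at every CATG; the
3'-most fragment is captured on beads, and MmeI, anchored at the adaptor
junction, cuts 17 bp downstream of the CATG. Each transcript therefore
contributes one 21-mer tag -- the CATG anchor plus 17 variable bases -- and
the number of times a tag is sequenced is a digital estimate of its
transcript's abundance. `tagdge` implements the complete analysis path for a
two-library comparison (a treatment against a control), from virtual-tag
indexing of a reference transcriptome to significance calls per unigene,
plus the two companion quantifications such studies use for validation:
delta-delta-Ct qRT-PCR and cumulative fruit abscission rates.

## Virtual-tag index

`build_tag_index()` enumerates, for every unigene, each CATG occurrence
followed by at least 17 bases (`find_virtual_tags()`), recording the 21-mer,
its 0-based position, and its strand. Two design choices were genuinely
open:

* **All CATG sites are indexed, not only the canonical 3'-most one.**
  Assembled unigenes can be fragmentary and real libraries contain tags from
  internal sites after incomplete digestion; indexing every site maximizes
  mappability. The canonical site keeps an `is_canonical` flag because the
  simulator emits only canonical tags (the faithful model of the bead
  capture step).
* **Both strands are indexed by default** (`strand_mode = "both"`). De novo
  unigenes assembled from randomly primed, non-stranded libraries have
  unknown orientation, and a reverse-complement hit still identifies the
  unigene. Note that CATG is its own reverse complement, so every site
  yields a tag on each strand; a minus-strand locus stores the sense-strand
  start of the 21-mer interval it occupies. `strand_mode = "sense"` is
  available when orientation is trusted.

A tag whose loci span more than one unigene is flagged *ambiguous*; the flag
is a pure function of the reference and is recomputable from the loci.

## Cleaning

`clean_tags()` applies the standard filters in order, counting the copies
each one removes so that attrition always reconciles with the raw input:

1. wrong length (adaptor remnants, empty tags);
2. tags containing `N` or any other unknown letter;
3. low-complexity tags;
4. tags with copy number below 2 (singletons, which are dominated by
   sequencing error).

The low-complexity rule had to be defined here: a tag is rejected when its
17-bp variable region contains at most 2 distinct nucleotides
(`max_var_nt`, configurable). This removes homopolymer and
dinucleotide-repeat artifacts while leaving real tags untouched -- a random
17-mer has a vanishing probability of using only two letters. The
copy-number filter is applied last, per library, after the sequence filters.

## Mapping

`map_tags()` assigns each distinct clean tag to a unigene with at most one
mismatch (`max_mismatch` in {0, 1}):

* an exact index hit takes precedence; only tags without one are looked up
  through their 63 one-substitution variants (mirroring best-hit semantics
  of short-read aligners -- there are no base qualities to break ties with);
* the candidate set is the union of unigenes over all hit loci: one
  candidate assigns the tag, several make it *ambiguous*, none leaves it
  *unmapped*;
* ambiguous and unmapped tags contribute to no unigene's count.

Lowering `max_mismatch` from 1 to 0 can only shrink the set of assigned
tags, which the test suite checks as a property.

## Normalization

`aggregate_counts()` computes per-unigene raw counts (the summed copies of
assigned tags) and TPM, *transcripts per million clean tags*:
`count / total_clean * 1e6`. The denominator is the library's total clean
tags, not the unambiguously mapped subset, following the definition of the
unit literally; both totals are carried in the objects, so the alternative
is one division away. The identity
`sum(TPM) == 1e6 * unambiguous_total / total_clean` holds to floating
precision on every run.

## The Audic-Claverie test

Conditional on `x` copies among `N1` tags in library 1, the number of copies
`Y` in library 2 under equal relative abundance has

```
p(y | x) = (N2/N1)^y * (x+y)! / ( x! * y! * (1 + N2/N1)^(x+y+1) )
```

which is the negative-binomial mass `NB(x + 1, N1/(N1 + N2))`.
`ac_probability()` evaluates it in log-space via `lgamma`. Tails
(`ac_pvalue()`) are inclusive of the observed count: the lower tail is the
exact finite sum over `0..y` (via log-sum-exp), and the upper tail is summed
upward adaptively -- past the mode, terms decay at least geometrically with
ratio `N2/(N1+N2)`, so summation stops when the next term can no longer
move the total at machine precision. The two-sided p-value doubles the
smaller tail and caps at 1, because both directions of regulation are of
interest; a one-sided mode (the smaller tail) is retained as an option.

Two numerical facts are worth recording:

* The exact exchange identity `P(Y <= y | x; N1, N2) =
  1 - P(X <= x | y; N2, N1)` holds for the inclusive tails, which implies
  the doubled-min two-sided p-value is only *nearly* symmetric under
  exchanging the libraries: the two directions can differ by up to twice
  the observed point's probability mass. The tests assert the exact
  identity and this bound; exact two-sided symmetry is impossible with
  inclusive tails.
* For equal counts in equal libraries each inclusive tail is exactly 1/2,
  so the two-sided p-value is 1 (to within a few ulps of the log-gamma
  evaluation).

FDR control is Benjamini-Hochberg step-up (`bh_fdr()`, delegating to
`stats::p.adjust`), computed over all tested entities at the chosen level.
The calling rule (`call_de()`) is `q <= alpha` **and**
`|log2 ratio| >= lfc_min`, both inclusive, with defaults `alpha = 0.001`
and `lfc_min = 1` (fold-change of at least 2).

### Zero counts and ratios

Log2 ratios in the test records floor TPM at a pseudo-value
(`pseudo_tpm = 0.001` by default) so every record is finite and rankable.
The *fold-change distribution* (`fold_change_distribution()`) uses a
different floor on purpose: an entity unobserved in one library is known
only to be *below one copy* there, so it is floored at that library's
one-copy TPM (`1e6/N`). Under the tiny reporting pseudo-value every
library-specific tag would count as an effectively infinite fold change and
the distribution would describe the floor, not the data; with the one-copy
floor the "within five-fold" fraction measures ratios the libraries can
actually resolve. Band edges are inclusive on the inner side: an entity at
exactly five-fold is *within* five-fold.

### Testing level and rollup

The primary test runs at the distinct-tag level and rolls up to unigenes
(`rollup_to_unigenes()`): a unigene is significant iff at least one of its
tags is, its ratio / p / q are recomputed from aggregated counts, and its
direction follows the aggregate ratio; unigenes whose significant tags
disagree in direction carry a `conflict` flag. A direct unigene-level mode
(testing aggregated counts) is available through
`pipeline_config(level = "unigene")` -- with single-tag unigenes the two
coincide.

## The synthetic-data generator

`sim_config()` fixes the emulated study design; the defaults are the
conditions the pipeline targets rather than knobs to revisit:

| parameter | default | rationale |
|---|---|---|
| `n_unigenes` | 57,050 | size of a typical de novo fruit transcriptome |
| `length_range` | 200-1,000 bp | assembled unigene lengths, mean about 600 bp |
| `depth_per_library` | 3.5M / 3.6M | high-quality tags per library (A = control, B = treatment) |
| `lnorm_sigma` | 1.5 | log-normal abundance law; long-tailed copy-number spectrum |
| `frac_de`, `log2fc_magnitude` | 0.1, 2 | planted four-fold effects, split evenly up/down |
| `error_rate` | 0.01 | per-base substitution, the Q20 regime |
| `frac_n_tags` | 0.02 | junk tags carrying `N` (the raw-to-clean attrition rate is not documented for such libraries, so this is a free parameter) |
| `qpcr_sd` | 0.15 cycles | technical Ct noise |

Each simulated transcript emits only its canonical tag (one tag per
transcript, as the bead chemistry dictates); errors are independent
substitutions (MmeI tags have fixed length, so no indels); per-condition
abundances are normalized after planting effects, so `true_log2fc` records
the planted effect before the (tiny, composition-driven) renormalization
shift. One master seed drives deterministic per-stage child streams, so the
reference, each library, the Ct table and the fruit counts are each
independently reproducible.

What the generator does **not** emulate -- and hence what green tests do not
certify on real data: PCR duplication bias, adapter read-through, quality
score structure, partial NlaIII digestion, CATG-site loss by polymorphism,
and any mis-assembly of the reference. The abscission generator's default
per-interval drop probabilities (`abscission_drop_probs()`) are calibrated
so the expected day-7 cumulative abscission is about 88.5% (shaded) and
62.2% (control), the magnitude of shade-induced fruitlet drop the pipeline
is meant to reproduce; counts follow a binomial survival process per shoot
(10 shoots on each of 3 trees, 20 fruit per shoot).

## Validation arithmetic

`delta_delta_ct()` averages technical replicates first, forms
`dCt = Ct_target - Ct_reference` per biological replicate, and subtracts the
calibrator sample's mean dCt (the control at day 1 by default). The
sample-level relative expression `2^-ddCt` is computed from the difference
of sample-level means, so the calibrator's own value is *exactly* 1 -- also
in floating point -- while standard errors come from per-replicate values.
Perfect doubling per cycle is assumed (no amplification-efficiency
correction). `cfar()` computes, per tree, the percentage of day-0 fruit
dropped by each day; `cfar_summary()` adds the group mean and the standard
error over trees (biological replicates). `two_sample_ttest()` is Student's
t by default (Welch behind a flag) with a stated convention for degenerate
variance: identical constant groups give `t = 0, p = 1` with a warning.

## Problem sizes used by the checks

The statistical property checks simulate studies of 5,000 unigenes at one
million tags per library -- large enough that a four-fold effect on a
well-expressed unigene (expected count of at least 50) is essentially always
detectable, and small enough to keep the whole suite inside a coffee break.
At those sizes the suite verifies: empirical size of the test at most 0.06
at nominal 0.05 (the exact conditional test is discrete, hence
conservative); at most 0.2% of unigenes called on a null study at the
default thresholds; sensitivity of at least 0.9 with false discovery
proportion at most 0.05 on the planted four-fold mixture; and more than 99%
of distinct entities within five-fold on a null pair. The exact statistic
itself is checked against an integer-ratio product oracle on the full grid
`x, y <= 30`, `N2/N1 in {1/2, 1, 2}` to 1e-9 on the log scale, and tag
extraction and one-mismatch mapping are checked against brute-force offset
and Hamming-distance scans.

## Known limitations

* The test compares exactly two libraries without biological replication --
  the p-value measures sampling noise of the tag counts, not between-tree
  variability. This is inherent to the design it models.
* One-mismatch mapping treats all substitutions equally; there is no
  quality-weighted rescue.
* Ambiguous tags are discarded rather than fractionally assigned, so
  closely homologous unigenes lose signal.
* The fold-change distribution depends on the zero-count floor convention
  (documented above); numbers produced under different conventions are not
  comparable.
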