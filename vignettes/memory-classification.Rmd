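---
title: "Classifying transcriptional memory under repeated dehydration stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcriptional memory under repeated dehydration stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmem)
```

## The model

The experimental design behind this package samples plants in three states:
a watered control (W), immediately after a first dehydration stress (S1),
and immediately after a third stress (S3), each stress separated by a full
watered recovery. Transcriptional *memory* is defined operationally, not
mechanistically: a memory gene is one that responds significantly in S1
versus W **and** whose S3 level differs significantly from its S1 level. A
gene that responds in S1 but repeats the same level in S3 is a non-memory
gene; a gene silent in S1 that responds only in S3 is a late-response gene.
Two tri-state calls therefore suffice to place every gene in a nine-class
partition, written `[s1/s3]` with `+`, `-`, `=` for up, down and no change.

Two points about this definition deserve emphasis:

* `=` means *failure to reach significance*, not demonstrated equality. No
  equivalence test is performed; a gene labelled `[+/=]` may have a real but
  sub-threshold S3 shift. Users should read "no change" as "no detected
  change".
* Late-response genes are computed and reported but excluded from memory
  statistics and from the memory fraction's denominator, because memory is
  defined within the fraction responding to the *first* stress.

## Significance criteria

A call is `up` or `down` only when all three criteria hold:

1. **q ≤ 0.05** — Benjamini–Hochberg FDR-adjusted p-value
   (`benjamini_hochberg()`, a validated wrapper over `stats::p.adjust`).
2. **|log₂ fold change| ≥ 1** — a two-fold change; infinite fold changes
   (a zero denominator printed as `inf`/`-inf` by cuffdiff) count as
   passing, since their sign still carries the call.
3. **Expression floor** — the FPKM of at least one of the two contrasted
   samples must be *strictly larger* than the 25th percentile of that
   sample's per-gene FPKM distribution. This suppresses calls made entirely
   inside the noise floor of lowly expressed genes.

All three thresholds are configurable through `significance_criteria()`;
the defaults above are the package's reference settings. Both inequalities
are inclusive: a gene at exactly q = 0.05 and |log₂FC| = 1 is significant.
The percentile uses the linear-interpolation definition
(`stats::quantile`, type 7) so that the floor of `0:4` at the 25th
percentile is exactly 1; the definition is fixed and recorded here because
percentile conventions differ across software. The floor is evaluated per
sample over all genes of that sample, and against the two contrasted
samples only — the most literal reading of "at least one sample out of the
two"; both choices are deliberate defaults rather than derivable facts, and
the floor reference set can be changed by passing pre-computed `floors`.

Rows of external differential tables whose status is not `OK` (`NOTEST`,
`LOWDATA`, `FAIL`, ...) carry no valid test and are always `nochange`.

## The stand-in differential test

External cuffdiff tables are consumed as-is; their statistics are never
recomputed. When only replicate FPKM tables are available (notably for
synthetic data), `simple_de_test()` produces the per-contrast tables. Fold
changes are `log2((mean_b + ε)/(mean_a + ε))` over replicate means, with a
pseudocount ε = 10⁻³ FPKM guarding zeros (ε applies only to this stand-in
test, never to external tables). P-values default to a **limma moderated
t** on `log2(FPKM + ε)`: with two replicates per condition a per-gene
variance estimate has essentially one degree of freedom, and an unmoderated
per-gene test (the `method = "welch"` alternative, retained for
comparison) has practically no power after FDR adjustment at this depth —
in our fixed-seed experiments at CV 0.2 and |log₂FC| = 2 over 5,000 genes
it recovers none of the planted responders, while the moderated test
recovers ~99%. Variance shrinkage across genes is the standard remedy in
this field, so the moderated test is the default. The method used is
recorded in the output's `de_method` attribute. When the data are exactly
noise-free the linear model degenerates (all residual variances are zero);
the implementation detects this and falls back to an exact comparison of
means (p = 0 for any difference, 1 otherwise), which keeps noise-free
simulations well-defined.

## Annotation transfer

Query proteomes with sparse native annotation borrow function from a
well-annotated reference. Per query:

1. hits from a BLASTP run (tabular outfmt 6, pre-filtered at e ≤ 10⁻³) are
   sorted by ascending e-value, then descending alignment length, then
   descending percent identity, then subject id (a total, deterministic
   order);
2. the **e-value window** keeps every hit within a multiplicative factor
   10¹⁰ of the best e-value, bound inclusive — a best hit at 10⁻⁶³ admits
   hits up to 10⁻⁵³. When the best e-value is exactly 0 the multiplicative
   rule degenerates; the window is then `{e = 0}` plus hits at or below an
   absolute guard of 10⁻¹⁷⁰, preserving the closest-homology intent without
   admitting everything (both knobs are arguments of `evalue_window()`);
3. a functional description is synthesized as the top-3 **longest common
   substrings** of the window members' reference descriptions, and the
   native description is used whenever it is informative (empty,
   "hypothetical protein" and "putative protein" count as absent);
4. GO terms are *always* aggregated from the window: per domain (cellular
   component, molecular function, biological process), term occurrences are
   counted over unique (subject gene, term) pairs — isoforms such as
   `AT1G01010.1`/`.2` are collapsed to their gene before lookup — and the
   top 10 terms by count (lexical tie-break) are reported.

The LCS extraction is greedy: strings are lower-cased and
whitespace-collapsed, the longest substring common to **all** descriptions
(ties: earliest occurrence in the first description) is extracted, its
occurrence masked in every string, and the search repeated up to k = 3
times, so results never overlap within a description. Results are trimmed
to word boundaries and must keep at least 4 characters (`min_len`).
Requiring commonality across *all* members is the strict reading; it can
return nothing for heterogeneous windows, which is then flagged rather than
papered over. The implementation is verified against a brute-force
all-substrings oracle on hundreds of random string triples in the test
suite.

## Functional category matrices

`build_matrix()` crosses the six response classes with an editable table of
category predicates (GO ids and/or case-insensitive term substrings;
multi-pattern predicates are unions). Genes matching several categories are
counted in each, so columns deliberately do not sum to the class totals.
Percentages are `round_half_up(100·count/total)` with the class total as
denominator — except transcription-factor sub-families (NAC, AP2/ERF,
bHLH, ...), which use the class's TF count, mirroring how such tables are
conventionally reported. Round-half-away-from-zero is used because it
matches the way printed tables in this literature round; one published
cell (17/162 printed as 11% where the rule gives 10%) cannot be reproduced
by any consistent rounding rule and is not forced. Heatmap intensities are
a linear ramp from 0 at 0% to 1 at 60%, saturating above — low-frequency
categories stay distinguishable while a handful of dominant cells do not
compress the scale. The shipped `default_categories()` approximates the
usual row set (membranes, hormone responses, TF families); the published
GO-to-category mapping is not public, so exact row membership parity is
out of scope and the table is meant to be edited.

## Cross-species conservation

Memory conservation is judged per maize memory gene over *all* its mapped
homologs (any-homolog semantics), with verdict precedence
`memory_same_type` > `memory_different_type` > `homolog_non_memory` >
`homolog_no_response` > `no_homolog`. Gene families are commonly
one-to-many; a single family member retaining the same memory class is
taken as evidence of conservation. Because tallies over unique homolog
genes and over (maize gene, homolog) pairs differ for one-to-many maps,
`conservation_tables()` reports both conventions. Reference-species class labels
are consumed as an input table, never recomputed: they come from the
reference species' own repeated-stress analysis. Homologs in late-response
or non-responsive classes count as "no S1 response" in the partition,
since neither responds to the first stress.

## The synthetic-data generator

`sim_config()` fixes the study conditions the test suite runs under:

| parameter | default | rationale |
|---|---|---|
| class proportions | observed partition / 39,635 | response ≈ 5% of genes, memory ≈ 40% of responders |
| baseline FPKM | lognormal(meanlog 3, sdlog 1.5) | right-skewed, median ≈ 20 FPKM, realistic dynamic range |
| effect size | \|log₂FC\| = 2 per responding step | comfortably above the 2-fold threshold |
| replicate noise | mean-one lognormal, CV 0.2 | typical bulk RNA-seq biological replicates |
| replicates | 2 per condition | the study design |
| conservation fraction | 0.25 | ≈ 206/816 conserved-memory genes |
| homolog outcome split | 0.5 / 0.25 / 0.25 | ≈ the 1,066/662/556 three-way homolog partition |

Planted responders have their baseline resampled above the 30th baseline
quantile *scaled by the deepest planted down-step* (2^effect): a `[-/-]`
gene ends 16-fold below baseline, and without the scaled margin the
expression floor would censor it by design — which is a property of the
criteria, not a recovery failure, and is therefore excluded from recovery
benchmarks by construction. The generator emulates FPKM-level data directly
(log-normal multiplicative noise), not read counts: the significance
criteria operate on FPKM, and no read-level process (library size, gene
length, mapping bias, count discreteness) is modelled. Passing tests
therefore demonstrate the correctness of the classification machinery under
the stated noise model, not the behaviour of upstream quantification on
real libraries. Annotation draws are independent Bernoulli per category
with per-class enrichment multipliers; real GO annotation is far more
correlated. Homolog maps are one-to-many with independent outcomes;
conserved pairs are planted explicitly and non-conserved memory outcomes
exclude the query's own class, so the planted conservation fraction is
exact. All generators take the mandatory seed and are bit-reproducible.

## Numerical choices and edge cases

* `inf`/`-inf` fold changes map to signed `Inf` sentinels, never `NaN`.
* BH input must be finite and in [0, 1]; q-values are returned in input
  order and are permutation-equivariant.
* Zero-variance replicate data short-circuit the DE test (see above);
  a zero-variance first replicate is an error in the QC regression.
* Empty hit lists yield empty windows; empty windows yield empty, flagged
  annotations.
* An all-`[=/=]` classification leaves the memory fraction `NA` with an
  explicit `undefined_fractions` flag rather than dividing by zero.
* Class symbols serialize exactly as `[+/+]` etc. in every output, so
  downstream greps match the printed notation.
* Percentages of empty classes render as `-` in written matrices.

## Problem sizes in the test suite

The suite exercises recovery at 2,000 noise-free and 5,000 noisy genes,
the LCS oracle on 500 random triples (length ≤ 40), BH against a hand
step-up oracle on 20 vectors, and the conservation estimate on a
55,000-gene run yielding >1,000 memory genes (binomial 99% CI ≈ ±3.7
percentage points at n = 1,000). The acceptance script runs the full
pipeline at the transcriptome scale of 39,635 genes. These sizes were
chosen so each check has clear statistical resolution while the whole
suite stays interactive.

## Known limitations

* The cuffdiff dispersion model is not reimplemented; external tables are
  authoritative for their own statistics, and the stand-in test is labelled
  as such in output metadata.
* Only the three-condition, two-contrast design is supported (no S2
  contrast, no multi-factor designs).
* GO terms are used as flat labels; no propagation to ancestor terms.
* Orthology is consumed, not inferred: no reciprocal-best-hit or synteny
  logic.
* Category predicates are substring/GO-id heuristics; they approximate but
  cannot exactly reproduce manually curated category tables.
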