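---
title: "Sex-exclusive variant discovery in small matched exome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-exclusive variant discovery in small matched exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexvar)
```

## The problem

Metabolic dysfunction-associated steatohepatitis (MASH) progresses
differently in women and men, and cohort studies of archived liver tissue
are necessarily small: a typical design has a handful of age-matched
patients per sex, each contributing a MASH-vs-normal paired whole-exome
call set. At that scale, allele-frequency association models have no
power. What such a design *can* detect is the extreme presence pattern:
a variant called in **every** patient of one sex and in **none** of the
other — a *sex-exclusive* (perfect-split) variant. sexvar implements that
discovery procedure as a reusable, tested pipeline: per-patient VCF
ingestion, a cohort presence matrix, an exact test for the split pattern,
region-class and per-gene accounting, and the immunoblot densitometry
normalization used for protein-level follow-up of candidate genes.

## The exact test

Condition on the carrier margin: of the $N = n_F + n_M$ patients, $n$
carry the variant. Under the null hypothesis that carrier status is
independent of sex, the number $k$ of female carriers is hypergeometric,

$$P(k) = \frac{\binom{n_F}{k}\binom{n_M}{n-k}}{\binom{N}{n}},$$

and the two-sided Fisher p-value is the sum of $P(k')$ over all tables at
most as probable as the observed one (the classic "small p-values"
convention, with a relative tolerance of one part in $10^7$ when
comparing table probabilities, as in standard implementations). The
kernel is computed in log-space with `lchoose`, so no factorial
overflows occur at any cohort size.

For an equal design the perfect split is the most extreme table in
either orientation, so the smallest attainable p-value is

$$p_{\min}(n, n) = \frac{2}{\binom{2n}{n}},$$

which for the reference 4-vs-4 design is $2/70 = 0.0286$. This number is
worth internalizing: it is not a conventional $0.05$-style threshold but
the *design's floor*. `min_achievable_p()` exposes it, and
`filter_sex_specific()` uses it as the default `alpha`.

Three consequences shape the defaults:

* **The filter uses `p <= alpha`, not `p < alpha`.** The perfect-split
  table attains the floor exactly; a strict inequality would reject
  every variant the design is built to find.
* **`p = 1` is never significant.** In a 1-vs-1 cohort the floor itself
  is 1; flagging splits there would be noise promotion. The pipeline
  warns when a design's floor is 1.
* **`require_perfect_split` defaults to `TRUE`.** The discovery rule is
  the split pattern; setting it to `FALSE` generalizes the tool to
  near-exclusive patterns ranked by p (e.g. 3-of-4 vs 0-of-4,
  $p = 8/56 = 0.143$), which an equal 4v4 design can never call
  significant at its floor but larger cohorts can.

No multiple-testing correction is applied by default — the procedure is a
screen whose candidates are expected to be validated orthogonally (PCR,
Sanger sequencing, immunoblot); an exome-wide Bonferroni column is
emitted for reference but never used for filtering.

## Presence semantics

A variant's identity is the full `(chrom, pos, ref, alt)` tuple.
Multiallelic records keep their comma-joined ALT string (`"T,CTT"`) as
one key: published variant tables print them joined, and splitting would
change the unit of analysis out from under the golden counts. A patient
*carries* a variant when the genotype holds at least one alternate allele
and FILTER is `PASS` or `.` (relaxable via `keep_filtered`). Explicit
no-calls (`./.`) count as absent for the test — the conservative choice
for a presence screen — but are tracked as missing cells and surfaced in
an `n_missing` column so users can impose a completeness requirement.
Chromosome labels are normalized to the `chr`-prefixed hg19 dialect with
a warning; the reference build itself is metadata, no sequence is loaded.

## Region accounting and the vocabulary bridge

Variant-type accounting follows the ANNOVAR-style region vocabulary
(`exonic`, `intronic`, `UTR3`, `ncRNA_exonic`, ...), while published
per-variant annotation tables often carry Sequence-Ontology terms
(`intron_variant`, `missense_variant`, ...). `category_to_region()`
ships a fixed bridge: coding consequences map to `exonic`, the 5'-UTR
premature-start-codon gain to `UTR5`, combined splice-region/intron
terms to `splicing`, and region-class terms map to themselves. SNV
versus InDel is decided purely by allele lengths: an SNV requires REF
and every ALT allele to have length 1.

Percentages are recomputed from counts and printed in table style
(integers; one decimal below 1%; bare `0` when even the decimal rounds
away). Full precision is kept in the numeric columns. One consequence of
recomputing rather than echoing: on the bundled exome-wide count grid,
exonic SNVs are $35{,}000/134{,}961 = 25.9\%$, which prints as 26 — the
reference study's own summary prints 27% for this cell, a figure not
reproducible from its printed counts. The package reports the
arithmetic.

## The bundled reference tables

`load_printed_tables()` returns machine-readable encodings of the
published female- and male-exclusive variant tables from the reference
eight-patient MASH cohort study, checksum-verified, with indel and
multiallelic rows (`AGCGCTG→A`, `C→T,CTT`) preserved verbatim. Two
transcription notes, preserved rather than adjudicated:

* The female table contains **64** distinct `(chrom, pos, ref, alt)`
  rows although the study's running text counts 63. Every per-gene
  multiplicity stated in that text (SLC17A2 = 6, RGSL1 = 3, ALPK2 = 2,
  ...) matches the 64-row table, so no row can be identified as
  spurious and the table is shipped as printed. Pipeline counts on the
  fixture cohort therefore report 64, not 63.
* The rsID rs1865760 appears on two different positions, and a handful
  of `Gene_Full_Name` strings disagree with their gene symbols; both
  are printed artifacts of the source and are passed through untouched.

`build_fixture_cohort()` turns the tables into a live cohort — four
female patients each carrying the full female table, four males the male
table, plus a configurable shared background — which the pipeline must
reconstruct row for row. This is the package's golden test.

## The synthetic cohort simulator

`simulate_cohort()` generates what the statistic actually consumes:
presence patterns. Background variants are present in each patient
independently with `carrier_prob` (rows landing in zero patients are
resampled, since such variants would never be called at all); planted
variants follow the exclusivity contract exactly. Positions are drawn
without replacement within chromosomes; region classes follow
`region_dist` and the SNV/InDel mix follows `indel_frac`.

Defaults encode the reference study's conditions: `n_f = n_m = 4`
patients, `carrier_prob = 0.5` (a maximally unstructured background,
and the hardest case for false perfect splits: each background variant
splits perfectly with probability $2 \cdot 0.5^8 \approx 0.78\%$),
63 + 54 planted variants matching the published set sizes, the published
exome-wide SNV region proportions, and `indel_frac = 13925/148881`. The
default background of $10^4$ variants is the scale at which the
false-split calibration checks run; the full exome scale
($\sim 1.5 \times 10^5$) is available by setting `n_background`.

Reproducibility: one integer seed drives everything; per-patient
background draws use deterministically derived substreams so changing
the cohort size does not reshuffle unrelated draws, and `write_cohort()`
emits byte-stable VCFs (no timestamps).

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and population allele
frequencies (background presence is independent across patients and
variants), coverage- or callability-driven missingness (real no-calls
cluster in hard regions), shared germline structure between matched
samples, and annotation realism (one synthetic gene per variant).
The parameter-recovery results certify the *procedure*, not the
biological interpretability of any particular hit.

Calibration facts the test suite verifies: with a sex-blind background at
`carrier_prob = 0.5`, the number of false perfect splits among $B$
background variants is Binomial$(B, 2 \cdot 0.5^8/(1 - 0.5^8))$ — about
78 per $10^4$ — and observed counts must sit within $3\sigma$ of that
expectation across 20 seeds; planted variants must be recovered with
recall and orientation precision 1. The simulated region-class mix is
checked against `region_dist` by a $\chi^2$ goodness-of-fit test at
$n = 10^5$, $\alpha = 0.01$. These problem sizes (20 cohorts of $10^4$;
one draw of $10^5$) were chosen as the smallest scales at which the
binomial and multinomial checks have meaningful resolution.

## Densitometry normalization

For each immunoblot lane the target band intensity is divided by the
loading-control (GAPDH) intensity; each ratio is then divided by the mean
ratio of the same sex's normal group, so the normal group's mean fold is
1 *identically* (the implementation computes the normal group's mean as
a self-quotient, exact in IEEE arithmetic, not as a mean of rounded
folds). Group comparisons use the equal-variance Student's t-test on
folds (Welch behind a flag). Because folds are ratios scaled by one
group-level constant, the t statistic on folds equals the t statistic on
raw ratios — the choice affects only the reported scale, and the package
standardizes on folds. Degenerate inputs are handled explicitly:
non-positive intensities are validation errors, groups with fewer than
two replicates get no p-value, and zero within-group variance (identical
replicate ratios) reports `NA` rather than an infinite statistic.

## Numerical and design choices

* Exact kernel in log-space (`lchoose`); two-sided sum with the
  $1 + 10^{-7}$ relative tolerance; p-values depend only on the carrier
  counts, so each distinct table is computed once per cohort.
* Sorting is total and deterministic: chromosomes in karyotype order
  (chr1..chr22, chrX, chrY), then position, REF, ALT — ties cannot
  occur because the key is the identity.
* The test suite validates the analytic test against two independent
  routes: `stats::fisher.test` on random tables and brute-force
  enumeration of all carrier placements for every design up to 6-vs-6
  (agreement to $10^{-12}$).
* All file outputs are timestamp-free, so re-running an analysis on
  identical inputs is byte-identical — the property that makes result
  diffs meaningful under version control.

## Limitations

The method is a presence/absence screen: it cannot rank effect sizes,
model dosage, or distinguish germline from somatic origin; its floor
p-value is fixed by cohort size, so a 4-vs-4 design can only ever say
"as extreme as possible for this design". Variants on sex chromosomes
pass through untouched — an X-linked hit in a sex comparison warrants
extra scrutiny that is left to the analyst. And the exclusivity
criterion is brittle by construction: one missed call in the carrying
sex demotes a true signal to `partial`, which is why missing cells are
tracked and reported.
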