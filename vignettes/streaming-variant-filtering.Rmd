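---
title: "Streaming annotation-based variant filtering with vcfsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming annotation-based variant filtering with vcfsift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfsift)
```

## The problem

Annotation-based filtering is the step of a sequencing analysis where an
annotated VCF — typically carrying upstream annotator output such as read
depth, population allele frequency and functional class in its INFO column —
is reduced to the handful of variants compatible with the case under study.
Two practical constraints shape the design here. First, annotated cohort
VCFs easily reach tens of gigabytes, so the tool must not load the file into
memory: vcfsift processes records in a single disk-streaming pass with a
bounded buffer, and memory use is independent of file size. Second, clinical
filter sets are reused across cases, so filters live in a plain-text
*filter-order file* that can be versioned and shared; reproducibility of a
run reduces to the pair (input VCF, filter file).

## The filtering model

A filter chain is an **ordered conjunction**: every directive must hold for
a record to pass, and directives are evaluated in file order with
short-circuit at the first failure. Order therefore never changes *which*
records pass — conjunction is commutative — but it does change the
per-directive failure attribution, which is reported as a funnel (how many
records each directive removed, among those that survived the earlier ones).
Putting cheap, high-yield filters first makes both the funnel and the run
more informative and faster.

Directives target annotations through three scopes: `INFO` keys, per-sample
`FORMAT` keys, and `SITE` for the fixed QUAL and FILTER columns, which are
deliberately served through the same evaluation path rather than
special-cased, so one grammar covers quality, depth and frequency filters
alike. The grammar is documented in `?filter_grammar`.

Three semantic choices deserve explanation:

* **Any-allele numerics.** Comma-separated numeric annotations (per-alternate
  allele frequencies, say) pass when *any* token satisfies the comparison.
  A multi-allelic record with one rare and one common allele is a live
  candidate for the rare allele, so existential semantics keeps it.
* **All-samples FORMAT selector.** `FORMAT DP * >= 10` requires every sample
  to satisfy the bound — the natural reading of "depth at least 10 in all
  samples". A single sample is selected by name.
* **Missing values keep by default.** A directive on an absent annotation
  (no key, `.`, or no numeric tokens) passes unless `missing=drop` is given.
  In rarity-driven filtering an absent population frequency usually *is* the
  signal — the variant is too rare to be catalogued — and silently dropping
  such records is the costlier error. `missing=drop` is available per
  directive for strict gating.

String filters are unanchored, case-sensitive Perl-compatible regular
expressions searched over the raw annotation text (`match`/`nomatch`), which
handles annotator composites such as `exonic;splicing` without exact-match
gymnastics; numeric equality is compared within an absolute tolerance of
1e-9 because annotations are decimal text round-tripped through parsing.

## Header validation before streaming

Before any record is read the chain is checked against the VCF header:
undeclared INFO/FORMAT keys, unknown sample names, and numeric filters on
`Type=Flag` keys are reported as findings. Strict mode (the default) aborts
on any finding *before any output file is opened* — a typo in a key name
should produce an error, not an empty pass file after an hour of streaming —
and a failed run never leaves partial outputs. Permissive mode instead drops
the offending directives with a warning, for headers that under-declare
keys the records actually carry.

## Genotype filters and de novo isolation

Genotypes are normalized phase-insensitively (`0/1`, `0|1` and `1|0` are the
same call) and classified per site from GT alone: `homref`, `het` (any two
distinct alleles with at least one alternate, so `1/2` is heterozygous),
`homalt`, `missing`, or `other` for the remainder such as triploid
three-allele calls. No read-evidence heuristics are consulted — the filters
operate on the genotype the caller wrote.

`ZYG include|exclude <class> <sample|*>` filters on those classes, and a
`GT` directive constrains several samples at once:

```
GT child=het mother=homref father=homref
```

is the de novo construct for a trio. Missing genotypes are conservative in
both constructs: they never satisfy an include target and never trigger an
exclude target, so an uncalled parent can never convert an inherited variant
into a "de novo" call.

## Outputs

Passing and failing records are routed to separate VCFs whose lines are the
input lines verbatim (the header is copied unchanged), so outputs are
byte-faithful and re-filterable; a `drop_failed` option discards failures
instead, which also skips the slowest part of a run — writing records that
are about to be ignored. Passed variants can be flattened to a TSV whose
columns are the fixed VCF columns, every header-declared INFO key in
declaration order (a deterministic layout across runs), and one GT column
per sample; flags render as `TRUE`/`.`. Because a cohort VCF with hundreds
of samples makes a useless spreadsheet, TSV export is disabled with a
cautionary warning when the sample count strictly exceeds 50 (configurable;
a force flag overrides but keeps the caution).

When a BED file of target intervals is supplied, passed variants whose
footprint — the 0-based half-open range `[pos-1, pos-1+nchar(REF))`,
REF-length only, no symbolic END parsing — overlaps an interval are written
to a second TSV with the matched interval's name. The report imposes no
zygosity constraint: it gathers all passed variants per region so compound-
heterozygous candidates can be reviewed by the analyst. Chromosome matching
tolerates a `chr` prefix mismatch between VCF and BED, a mixed convention
common enough that silent zero-overlap output would be a worse failure mode.
Tie-breaks are deterministic (smallest interval start, then end).

## The synthetic-data generators

`generate_synthetic_vcf()` emulates an annotated small-variant VCF: per-site
read depth `DP` uniform on 1..100, population allele frequency `AF` drawn
per alternate allele from a fixed rarity ladder (0.0005–0.5) and missing for
20% of sites, functional class `Func` over exonic/intronic/splicing/UTR5
including the composite `exonic;splicing`, a `DB` membership flag, and
`GT:DP` sample columns, with occasional multi-allelic sites, multi-base REF
alleles, missing QUAL and non-PASS FILTER values. `generate_trio_vcf()`
plants a chosen number of child-het/parents-homref sites in a background of
Mendelian-consistent configurations that *never* form that pattern, so the
planted list is the exact truth set by construction. Identical arguments
give byte-identical files.

What the generators do **not** emulate: linkage, realistic allele-frequency
spectra, sequencing errors, annotator quirks (multiple transcripts, URL-encoded
strings), or structural/symbolic alleles. Passing tests therefore demonstrate
the correctness of parsing, evaluation and routing logic under the VCF
grammar, not robustness to every real-world annotator dialect.

Verification is dual-route throughout: a brute-force oracle
(`oracle_filter()`) re-reads the file with its own minimal parsing and its
own comparison, regex and zygosity call sites, evaluating every directive
with no short-circuit, and the engine must agree with it exactly on
randomized files and randomized chains drawn from the grammar. The BED
report is checked the same way against an all-pairs overlap scan
(`oracle_bed_overlaps()`).

## Numerical and procedural choices

* gzip input is detected from the magic bytes, never the extension; bgzip
  files read fine as gzip (no index support, none needed for one pass).
* Input accepts `\n` and `\r\n`; output is always `\n`, UTF-8.
* Duplicate INFO keys within a record keep the last value with a warning —
  real annotator output contains duplicates and rejecting records is worse.
* Records on contigs absent from the header are processed normally; contig
  and FILTER meta lines are preserved verbatim but not modeled.
* The engine is single-pass and sequential by contract; no parallelism, no
  re-sorting of outputs.
* Test and verification problem sizes — VCFs of tens to a few hundred
  records, about a hundred randomized engine-versus-oracle trials, a
  500-record trio with 12 planted de novo sites — were chosen so the full
  dual-route comparison (the oracle is quadratic-ish and deliberately naive)
  completes in about a minute while exercising every directive class,
  missing-value path and boundary case; the properties checked are
  size-independent.

## Limitations

BCF binary input, tabix random access, soft-filtering (writing FILTER tags
rather than routing records), boolean OR/grouping between directives, and
gene-aware compound-het pairing are out of scope. The filter chain is a pure
conjunction; analyses needing disjunction run two chains and combine the
outputs.
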