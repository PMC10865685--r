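# vcfsift

Streaming annotation-based filtering of VCF files.

After variant calling and annotation, the step that turns a multi-gigabyte
annotated VCF into a reviewable candidate list is filtering on the
annotations themselves: read depth, call quality, population allele
frequency, functional class, genotype configuration. vcfsift does this for
researchers and clinicians who want that step to be **reproducible** (the
filter set is a plain-text file that can be versioned and reused across
cases) and **scalable** (records are processed in a single disk-streaming
pass over plain or gzip-compressed input, so memory use is independent of
file size — no loading the VCF into RAM).

## The filtering model

A run is defined by a *filter-order file*: one directive per line, applied
to every record in order as an ordered conjunction with short-circuit at the
first failing directive. A record passes only if it satisfies every
directive; failure counts per directive give a funnel view of the chain.

```
# keep deep, rare, exonic candidates
INFO DP >= 20
INFO AF <= 0.01
INFO Func match exonic|splicing missing=drop
SITE QUAL > 30
FORMAT DP * >= 10
ZYG exclude homref S1
GT child=het mother=homref father=homref
```

Numeric directives (`< <= > >= == !=`) use any-allele semantics over
comma-separated values and an absolute tolerance of 1e-9 for equality;
string directives are unanchored case-sensitive regular expressions
(`match`/`nomatch`); `missing=keep` (default) or `missing=drop` decides
records lacking the annotation; `*` means every sample must satisfy the
directive; the `GT` line is the de novo construct for trios. The chain is
validated against the VCF header **before** any record is read — undeclared
keys, unknown samples and numeric filters on flags abort a strict run before
any output file is created. See `?filter_grammar` for the full syntax.

Outputs: pass/fail VCFs with input lines reproduced verbatim, an optional
TSV of passed variants (disabled with a caution when the input has more than
50 samples, overridable), and an optional TSV of passed variants overlapping
a BED file of target intervals — e.g. to gather candidate compound
heterozygotes per gene region.

## Worked example

```r
library(vcfsift)

# a seeded synthetic annotated VCF (DP, AF, Func, DB; one sample)
fx <- generate_synthetic_vcf("demo.vcf", n_records = 200, n_samples = 1, seed = 42)

writeLines(c("INFO DP >= 20",
             "INFO AF <= 0.01",
             "INFO Func match exonic|splicing missing=drop"), "filters.txt")

filter_vcf("demo.vcf", "filters.txt",
           out_pass = "pass.vcf", out_fail = "fail.vcf",
           tsv = "pass.tsv", quiet = FALSE)
```

which prints:

```
Filtering run: 200 records, 58 passed
  [0] INFO DP >= 20                                      failed 36
  [1] INFO AF <= 0.01                                    failed 54
  [2] INFO Func match exonic|splicing missing=drop       failed 52
```

200 input records; 36 failed the depth filter, 54 of the survivors failed
the rarity filter, 52 of the remainder were not exonic/splicing (records
with *no* AF annotation were kept by the default missing policy — absent
population frequency suggests a rare variant — while `missing=drop` on the
functional-class filter discarded unannotated records). The 58 passing
records are written verbatim to `pass.vcf` and flattened to `pass.tsv`:

```
CHROM  POS  ID        REF  ALT  QUAL   FILTER  DP  AF     Func    DB    GT_S1
1      28   .         C    G    .      .       45  0.005  exonic  .     0/0
1      30   rs855156  C    T    484.2  q10     70  .      exonic  TRUE  0/0
```

The same run from the shell, via the installed `exec/vcfsift` script:

```sh
vcfsift --vcf demo.vcf --filters filters.txt \
        --out-pass pass.vcf --out-fail fail.vcf --tsv pass.tsv
vcfsift fixtures --type trio --out trio.vcf --n 500 --denovo 12 --seed 7
```

Exit codes: 0 success, 1 usage error, 2 validation failure (strict mode),
3 I/O or parse error.

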