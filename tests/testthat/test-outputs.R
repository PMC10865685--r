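test_that("read_bed parses BED3/BED4, skips headers and rejects bad intervals", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("track name=demo", "browser position chr1",
               "# comment", "",
               "chr1\t99\t200\tGENE1",
               "chr1\t10\t50\tGENE2",
               "2\t5\t15"), path)
  bed <- read_bed(path)
  expect_s3_class(bed, "bed_intervals")
  expect_setequal(names(bed), c("chr1", "2"))
  # sorted by start then end within chromosome
  expect_identical(bed$chr1$start, c(10L, 99L))
  expect_identical(bed$chr1$name, c("GENE2", "GENE1"))
  expect_true(is.na(bed[["2"]]$name))

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t200\t100", bad)
  expect_error(read_bed(bad), "line 1.*start")
  writeLines(c("chr1\t1\t2", "chr1\t5"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("variant footprints use half-open arithmetic over the REF length", {
  bed <- read_bed(write_tmp_vcf(c("chr1\t99\t100", "chr1\t101\t102",
                                  "chr1\t100\t200")))
  # SNV at pos 100: footprint [99,100)
  snv <- mini_record(chrom = "chr1", pos = 100, ref = "A", samples = NULL)
  hit <- variant_overlaps(snv, read_bed(write_tmp_vcf("chr1\t99\t100")))
  expect_identical(hit$start, 99L)
  expect_null(variant_overlaps(snv, read_bed(write_tmp_vcf("chr1\t100\t200"))))
  # deletion pos 100 ref ATG: footprint [99,102) reaches [101,102)
  del <- mini_record(chrom = "chr1", pos = 100, ref = "ATG", samples = NULL)
  expect_identical(variant_overlaps(del, read_bed(write_tmp_vcf("chr1\t101\t102")))$start, 101L)
  # tie-break: smallest start, then smallest end
  multi <- read_bed(write_tmp_vcf(c("chr1\t95\t105", "chr1\t90\t101", "chr1\t90\t99")))
  expect_identical(variant_overlaps(snv, multi)$start, 90L)
  expect_identical(variant_overlaps(snv, multi)$end, 101L)
})

test_that("chr prefix mismatches between VCF and BED are tolerated", {
  bed <- read_bed(write_tmp_vcf("chr1\t0\t1000"))
  rec <- mini_record(chrom = "1", pos = 50, samples = NULL)
  expect_identical(variant_overlaps(rec, bed)$chrom, "chr1")
  bed2 <- read_bed(write_tmp_vcf("1\t0\t1000"))
  rec2 <- mini_record(chrom = "chr1", pos = 50, samples = NULL)
  expect_identical(variant_overlaps(rec2, bed2)$chrom, "1")
})

test_that("interval lookups agree with the brute-force all-pairs oracle", {
  set.seed(31)
  for (trial in 1:15) {
    fx <- generate_synthetic_vcf(tempfile(fileext = ".vcf"),
                                 n_records = sample(20:120, 1),
                                 n_samples = 1L, seed = 4000L + trial)
    bd <- generate_bed(tempfile(fileext = ".bed"),
                       n_intervals = sample(3:25, 1), seed = 8000L + trial)
    intervals <- read_bed(bd$path)
    rd <- open_vcf(fx$path)
    hits <- integer(0)
    i <- 0L
    repeat {
      r <- rd$next_record()
      if (is.null(r)) break
      i <- i + 1L
      if (!is.null(variant_overlaps(r, intervals))) hits <- c(hits, i)
    }
    rd$close()
    expect_identical(hits, oracle_bed_overlaps(fx$path, bd$path))
  }
})

test_that("TSV rows follow the declared column plan", {
  hdr <- parse_vcf_header_from_lines(mini_vcf_lines("S1"))
  plan <- tsv_column_plan(hdr)
  expect_identical(plan, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                           "FILTER", "DP", "AF", "Func", "DB", "GT_S1"))

  rec <- mini_record(info = "DP=30;DB", alt = "G,T", fmt = "GT:DP",
                     sample_cols = "0/1:9")
  row <- record_to_tsv_row(rec, hdr, plan)
  expect_length(row, length(plan))
  expect_identical(row[plan == "DP"], "30")
  expect_identical(row[plan == "AF"], ".")        # undeclared in record
  expect_identical(row[plan == "DB"], "TRUE")     # flag rendering
  expect_identical(row[plan == "ALT"], "G,T")
  expect_identical(row[plan == "GT_S1"], "0/1")

  # sites-only VCF: no GT columns
  hdr0 <- parse_vcf_header_from_lines(mini_vcf_lines(NULL))
  expect_false(any(startsWith(tsv_column_plan(hdr0), "GT_")))

  # embedded separators sanitized
  rec2 <- mini_record(info = "Func=a\tb")
  row2 <- record_to_tsv_row(rec2, hdr, plan)
  expect_false(any(grepl("\t", row2)))
})

test_that("the sample guard fires strictly above the threshold", {
  hdr_n <- function(n) parse_vcf_header_from_lines(mini_vcf_lines(paste0("S", seq_len(n))))
  g50 <- apply_sample_guard(hdr_n(50), tsv_enabled = TRUE, threshold = 50)
  expect_true(g50$tsv_enabled)
  expect_null(g50$warning)
  g51 <- apply_sample_guard(hdr_n(51), tsv_enabled = TRUE, threshold = 50)
  expect_false(g51$tsv_enabled)
  expect_match(g51$warning, "over 50")
  # force keeps TSV but still records the caution
  gf <- apply_sample_guard(hdr_n(60), tsv_enabled = TRUE, threshold = 50,
                           force_tsv = TRUE)
  expect_true(gf$tsv_enabled)
  expect_match(gf$warning, "forced")
  # guard irrelevant when TSV not requested
  expect_null(apply_sample_guard(hdr_n(60), tsv_enabled = FALSE)$warning)
})

test_that("pass + fail outputs partition the input record lines", {
  fx <- generate_synthetic_vcf(tempfile(fileext = ".vcf"), n_records = 100L,
                               n_samples = 2L, seed = 21L)
  chain <- parse_filter_chain(c("INFO DP >= 50", "ZYG exclude homref S1"))
  op <- tempfile(fileext = ".vcf")
  of <- tempfile(fileext = ".vcf")
  filter_vcf(fx$path, chain, out_pass = op, out_fail = of)
  input_recs <- grep("^#", readLines(fx$path), invert = TRUE, value = TRUE)
  pass_recs <- grep("^#", readLines(op), invert = TRUE, value = TRUE)
  fail_recs <- grep("^#", readLines(of), invert = TRUE, value = TRUE)
  expect_identical(sort(c(pass_recs, fail_recs)), sort(input_recs))
  expect_length(intersect(pass_recs, fail_recs), 0L)
})

test_that("filter_vcf writes TSV and BED-overlap TSV consistent with the pass set", {
  fx <- generate_synthetic_vcf(tempfile(fileext = ".vcf"), n_records = 120L,
                               n_samples = 1L, seed = 33L)
  bd <- generate_bed(tempfile(fileext = ".bed"), n_intervals = 12L, seed = 34L)
  chain <- parse_filter_chain("INFO DP >= 30")
  op <- tempfile(fileext = ".vcf")
  tsv <- tempfile(fileext = ".tsv")
  btsv <- tempfile(fileext = ".tsv")
  filter_vcf(fx$path, chain, out_pass = op, tsv = tsv, bed = bd$path,
             bed_tsv = btsv)
  pass_n <- length(grep("^#", readLines(op), invert = TRUE))
  tsv_lines <- readLines(tsv)
  expect_identical(length(tsv_lines) - 1L, pass_n)
  # rectangular, tab-separated
  widths <- lengths(strsplit(tsv_lines, "\t", fixed = TRUE))
  expect_identical(unique(widths), widths[1])
  # BED rows are a subset of TSV rows (modulo the interval-name column)
  bed_lines <- readLines(btsv)[-1]
  if (length(bed_lines)) {
    trimmed <- sub("\t[^\t]*$", "", bed_lines)
    expect_true(all(trimmed %in% tsv_lines[-1]))
  }
  # and exactly the overlapping subset
  intervals <- read_bed(bd$path)
  rd <- open_vcf(op)
  n_overlap <- 0L
  repeat {
    r <- rd$next_record()
    if (is.null(r)) break
    if (!is.null(variant_overlaps(r, intervals))) n_overlap <- n_overlap + 1L
  }
  rd$close()
  expect_identical(length(bed_lines), n_overlap)
})

test_that("strict validation aborts before any output exists; permissive drops directives", {
  fx <- generate_synthetic_vcf(tempfile(fileext = ".vcf"), n_records = 20L,
                               n_samples = 1L, seed = 2L)
  chain <- parse_filter_chain(c("INFO DP >= 20", "INFO gnomAD_AF <= 0.01"))
  op <- tempfile(fileext = ".vcf")
  expect_error(filter_vcf(fx$path, chain, out_pass = op),
               class = "vcfsift_validation_error")
  expect_false(file.exists(op))

  s <- suppressWarnings(filter_vcf(fx$path, chain, out_pass = op, strict = FALSE))
  expect_true(file.exists(op))
  expect_identical(names(s$failed_by_directive), "0")  # reindexed survivor
  expect_match(s$warnings, "dropped directive", all = FALSE)
})

test_that("gzip_out writes gzip pass output equivalent to the plain run", {
  fx <- generate_synthetic_vcf(tempfile(fileext = ".vcf"), n_records = 40L,
                               n_samples = 1L, seed = 44L)
  chain <- parse_filter_chain("INFO DP >= 40")
  plain <- tempfile(fileext = ".vcf")
  gz <- tempfile(fileext = ".vcf.gz")
  filter_vcf(fx$path, chain, out_pass = plain)
  filter_vcf(fx$path, chain, out_pass = gz, gzip_out = TRUE)
  con <- file(gz, "rb")
  magic <- readBin(con, "raw", 2)
  close(con)
  expect_identical(magic, as.raw(c(0x1f, 0x8b)))
  expect_identical(readLines(gzfile(gz)), readLines(plain))
})
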