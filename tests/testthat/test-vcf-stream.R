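test_that("line source yields plain and gzip-compressed files identically", {
  lines <- c(mini_vcf_lines(), mini_record_line(), mini_record_line(pos = 200))
  plain <- write_tmp_vcf(lines)
  gz <- write_tmp_vcf(lines, gzip = TRUE)

  read_all <- function(path) {
    src <- open_variant_stream(path)
    on.exit(src$close())
    out <- character(0)
    repeat {
      l <- src$read()
      if (is.null(l)) break
      out <- c(out, l)
    }
    out
  }
  expect_identical(read_all(plain), lines)
  expect_identical(read_all(gz), lines)

  empty <- write_tmp_vcf(character(0))
  src <- open_variant_stream(empty)
  expect_null(src$read())
  src$close()

  expect_error(open_variant_stream(tempfile()), "no such file")
})

test_that("corrupt gzip stream reports a decompression error naming the path", {
  path <- tempfile(fileext = ".vcf.gz")
  con <- file(path, "wb")
  writeBin(c(as.raw(0x1f), as.raw(0x8b), as.raw(sample(0:255, 64, replace = TRUE))), con)
  close(con)
  src <- open_variant_stream(path)
  on.exit(src$close())
  expect_error(while (!is.null(src$read())) NULL, "decompression error.*vcf.gz")
})

test_that("CRLF line endings are accepted and normalized", {
  path <- tempfile(fileext = ".vcf")
  con <- file(path, "wb")
  writeLines(c(mini_vcf_lines(NULL), mini_record_line()), con, sep = "\r\n")
  close(con)
  rd <- open_vcf(path)
  on.exit(rd$close())
  rec <- rd$next_record()
  expect_identical(rec$pos, 100L)
  expect_false(endsWith(rec$raw_line, "\r"))
})

test_that("parse_header extracts INFO/FORMAT definitions and sample names", {
  hdr <- parse_vcf_header_from_lines(mini_vcf_lines(c("S1")))
  expect_s3_class(hdr, "vcf_header")
  expect_setequal(names(hdr$info_defs), c("DP", "AF", "Func", "DB"))
  expect_identical(hdr$info_defs$DP$type, "Integer")
  expect_identical(hdr$info_defs$AF$type, "Float")
  expect_identical(hdr$info_defs$DB$type, "Flag")
  # Description with embedded comma parsed whole
  expect_identical(hdr$info_defs$AF$description, "Allele frequency, per alt")
  expect_setequal(names(hdr$format_defs), c("GT", "DP"))
  expect_identical(hdr$sample_names, "S1")

  sites_only <- parse_vcf_header_from_lines(mini_vcf_lines(NULL))
  expect_identical(sites_only$sample_names, character(0))

  # record before the column line
  expect_error(
    parse_vcf_header_from_lines(c("##fileformat=VCFv4.2", mini_record_line())),
    "malformed header")
  # missing column line entirely
  expect_error(parse_vcf_header_from_lines("##fileformat=VCFv4.2"),
               "no '#CHROM'")
  # duplicate INFO definition
  dup <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  expect_error(parse_vcf_header_from_lines(dup), "duplicate INFO.*DP")
})

test_that("parse_record maps fixed columns, INFO and sample fields", {
  rec <- mini_record(info = "DP=30;DB")
  expect_identical(rec$pos, 100L)
  expect_identical(rec$qual, 50)
  expect_identical(rec$info$DP, "30")
  expect_true(isTRUE(rec$info$DB))

  rec <- mini_record(qual = ".", alt = "G,T", fmt = "GT:DP", sample_cols = "0/1:12")
  expect_true(is.na(rec$qual))
  expect_identical(rec$alts, c("G", "T"))
  expect_identical(unname(rec$sample_values$S1[["GT"]]), "0/1")
  expect_identical(unname(rec$sample_values$S1[["DP"]]), "12")

  # trailing absent FORMAT subfields are missing
  rec <- mini_record(fmt = "GT:DP", sample_cols = "0/1")
  expect_true(is.na(rec$sample_values$S1[["DP"]]))

  hdr <- parse_vcf_header_from_lines(mini_vcf_lines("S1"))
  expect_error(parse_record("1\tX\t.\tA\tG\t.\t.\tDP=1", hdr, line_number = 9L),
               "line 9.*POS")
  expect_error(parse_record("1\t100\t.\tA", hdr), "fewer than 8")
})

test_that("parse_info splits entries, flags, missing and duplicates", {
  m <- parse_info("DP=30;AF=0.01,0.5;DB")
  expect_identical(names(m), c("DP", "AF", "DB"))
  expect_identical(m$AF, "0.01,0.5")
  expect_true(isTRUE(m$DB))
  expect_length(parse_info("."), 0L)
  expect_warning(m2 <- parse_info("DP=1;DP=2"), "duplicate INFO key")
  expect_identical(m2$DP, "2")
})

test_that("get_annotation serves SITE, INFO and FORMAT scopes uniformly", {
  rec <- mini_record(info = "AF=0.01,0.5;DB", qual = ".",
                     fmt = "GT:DP", sample_cols = "0/1:7")
  hdr <- parse_vcf_header_from_lines(mini_vcf_lines("S1"))

  av <- get_annotation(rec, "INFO", "AF", hdr)
  expect_equal(av$numeric_values, c(0.01, 0.5))
  expect_true(get_annotation(rec, "INFO", "gnomAD_AF", hdr)$is_missing)
  expect_true(get_annotation(rec, "SITE", "QUAL", hdr)$is_missing)
  expect_identical(get_annotation(rec, "SITE", "FILTER", hdr)$raw, "PASS")
  expect_identical(get_annotation(rec, "INFO", "DB", hdr)$raw, "TRUE")
  expect_equal(get_annotation(rec, "FORMAT", "DP", hdr, "S1")$numeric_values, 7)
  expect_error(get_annotation(rec, "FORMAT", "DP", hdr, "nope"), "unknown sample")
})

test_that("header + verbatim record lines round-trip the file byte for byte", {
  fx <- generate_synthetic_vcf(tempfile(fileext = ".vcf"), n_records = 50L,
                               n_samples = 2L, seed = 11L)
  input <- readLines(fx$path)
  rd <- open_vcf(fx$path)
  out <- c(rd$header$meta_lines, rd$header$column_line)
  repeat {
    r <- rd$next_record()
    if (is.null(r)) break
    out <- c(out, r$raw_line)
  }
  rd$close()
  expect_identical(out, input)
})

test_that("parsing a file and its gzip copy yields identical records", {
  fx <- generate_synthetic_vcf(tempfile(fileext = ".vcf"), n_records = 40L,
                               n_samples = 1L, seed = 12L)
  gz <- write_tmp_vcf(readLines(fx$path), gzip = TRUE)
  collect <- function(path) {
    rd <- open_vcf(path)
    on.exit(rd$close())
    recs <- list()
    repeat {
      r <- rd$next_record()
      if (is.null(r)) break
      recs[[length(recs) + 1L]] <- r
    }
    list(header = rd$header, recs = recs)
  }
  a <- collect(fx$path)
  b <- collect(gz)
  expect_identical(a$header, b$header)
  expect_identical(a$recs, b$recs)
})

test_that("the reader is streaming: early records arrive before later reads", {
  # source counts how many lines have been pulled; the first record must be
  # parseable before the whole (large) body has been consumed
  n_total <- 5000L
  hdr_lines <- mini_vcf_lines(NULL)
  st <- new.env()
  st$i <- 0L
  path <- write_tmp_vcf(c(hdr_lines,
                          vapply(seq_len(n_total), function(i) {
                            mini_record_line(pos = i)
                          }, character(1))))
  src <- open_variant_stream(path, chunk_size = 16L)
  on.exit(src$close())
  hdr <- parse_header(src)
  first <- src$read()
  expect_match(first, "^1\t1\t")
  expect_lt(src$line_number(), length(hdr_lines) + 100L)
})
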