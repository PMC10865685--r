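# Shared fixtures built in code: a small hand-written VCF exercising INFO
# flags, multi-allelic AF, FORMAT columns and missing markers.

mini_vcf_lines <- function(samples = c("S1")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency, per alt\">",
    "##INFO=<ID=Func,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
}

mini_record_line <- function(chrom = "1", pos = 100, id = ".", ref = "A",
                             alt = "G", qual = "50", filter = "PASS",
                             info = "DP=30", fmt = NULL, sample_cols = NULL) {
  paste(c(chrom, pos, id, ref, alt, qual, filter, info, fmt, sample_cols),
        collapse = "\t")
}

write_tmp_vcf <- function(lines, gzip = FALSE) {
  path <- tempfile(fileext = if (gzip) ".vcf.gz" else ".vcf")
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  path
}

# parse a single record line against the mini header
mini_record <- function(..., samples = c("S1")) {
  hdr <- parse_vcf_header_from_lines(mini_vcf_lines(samples))
  parse_record(mini_record_line(...), hdr)
}

parse_vcf_header_from_lines <- function(lines) {
  path <- write_tmp_vcf(lines)
  src <- open_variant_stream(path)
  on.exit(src$close())
  parse_header(src)
}

# run the streaming engine over a file, returning 1-based pass indices and
# the run summary (shared by oracle-equivalence and invariance tests)
engine_pass_set <- function(path, chain) {
  rd <- open_vcf(path)
  on.exit(rd$close())
  st <- new.env()
  st$i <- 0L
  st$pass <- integer(0)
  nr <- function() {
    r <- rd$next_record()
    if (!is.null(r)) st$i <- st$i + 1L
    r
  }
  summary <- run_stream(nr, chain, rd$header,
                        pass_sink = function(rec) st$pass <- c(st$pass, st$i))
  list(pass = st$pass, summary = summary)
}
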