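#' Filter a VCF file through a filter-order chain
#'
#' The end-to-end run: parse the header, parse the filter-order file,
#' validate the chain against the header, apply the multi-sample TSV guard,
#' then stream every record once through the chain, routing passing records
#' to the pass output and failing records to the optional fail output.
#' Output VCFs reproduce the input header and record lines verbatim. When a
#' TSV path is given, passing records are also flattened to a spreadsheet-
#' friendly table; when a BED file is given, the subset of passed records
#' overlapping any interval is written to a second TSV (with the matched
#' interval's name) to support compound-heterozygous candidate review.
#'
#' In strict mode (the default) any validation finding aborts the run before
#' any output file is opened, so a failed run never leaves partial outputs.
#' In permissive mode offending directives are dropped with a warning.
#'
#' @param vcf Path to the input VCF (plain or gzip-compressed).
#' @param filters Path to a filter-order file, or a `filter_chain`.
#' @param out_pass Path for the pass VCF (required).
#' @param out_fail Optional path for the fail VCF.
#' @param drop_failed Discard failing records instead of writing them.
#' @param tsv Optional path for the passed-variants TSV.
#' @param bed Optional path to a BED file of target intervals.
#' @param bed_tsv Path for the BED-overlap TSV (required when `bed` is given
#'   and defaults to `<tsv>` with a `.bed.tsv` suffix when `tsv` is set).
#' @param sample_guard Sample-count threshold for the TSV guard (default 50;
#'   the guard fires strictly above it).
#' @param force_tsv Keep TSV output enabled even when the guard fires.
#' @param strict Abort on validation findings (default) instead of dropping
#'   offending directives.
#' @param gzip_out gzip-compress the pass/fail VCF outputs.
#' @param summary_tsv Optional path for the per-directive summary TSV.
#' @param quiet Suppress the printed funnel summary.
#' @return A `run_summary`, invisibly. Validation failures in strict mode
#'   signal a condition of class `vcfsift_validation_error`; I/O and parse
#'   failures signal regular errors.
#' @examples
#' \donttest{
#' fx <- generate_synthetic_vcf(tempfile(fileext = ".vcf"), n_records = 100,
#'                              n_samples = 1, seed = 1)
#' ff <- tempfile(fileext = ".txt")
#' writeLines(c("INFO DP >= 20", "INFO AF <= 0.01"), ff)
#' filter_vcf(fx$path, ff, out_pass = tempfile(fileext = ".vcf"))
#' }
#' @export
filter_vcf <- function(vcf, filters, out_pass, out_fail = NULL,
                       drop_failed = FALSE, tsv = NULL, bed = NULL,
                       bed_tsv = NULL, sample_guard = 50L, force_tsv = FALSE,
                       strict = TRUE, gzip_out = FALSE, summary_tsv = NULL,
                       quiet = TRUE) {
  reader <- open_vcf(vcf)
  on.exit(reader$close(), add = TRUE)
  header <- reader$header

  chain <- if (inherits(filters, "filter_chain")) filters else parse_filter_file(filters)
  findings <- validate_chain(chain, header)
  guard_warnings <- character(0)
  if (nrow(findings) > 0L) {
    if (strict) {
      stop(validation_error(findings))
    }
    keep <- !vapply(chain$directives, function(d) d$index %in% findings$directive_index,
                    logical(1))
    for (m in findings$message) {
      warning("dropping directive: ", m, call. = FALSE)
      guard_warnings <- c(guard_warnings, paste0("dropped directive: ", m))
    }
    chain$directives <- chain$directives[keep]
    for (i in seq_along(chain$directives)) chain$directives[[i]]$index <- i - 1L
  }

  tsv_requested <- !is.null(tsv)
  guard <- apply_sample_guard(header, tsv_requested, sample_guard, force_tsv)
  if (!is.null(guard$warning)) {
    warning(guard$warning, call. = FALSE)
    guard_warnings <- c(guard_warnings, guard$warning)
  }
  tsv_enabled <- guard$tsv_enabled

  intervals <- if (!is.null(bed)) read_bed(bed) else NULL
  if (!is.null(intervals) && is.null(bed_tsv)) {
    if (!is.null(tsv)) bed_tsv <- sub("(\\.tsv)?$", ".bed.tsv", tsv)
    else stop("bed_tsv path required when a BED file is given", call. = FALSE)
  }

  # sinks are opened only after validation succeeds: no partial outputs
  pass <- open_line_sink(out_pass, gzip = gzip_out)
  on.exit(pass$close(), add = TRUE)
  fail <- NULL
  if (!is.null(out_fail) && !drop_failed) {
    fail <- open_line_sink(out_fail, gzip = gzip_out)
    on.exit(fail$close(), add = TRUE)
  }
  header_lines <- c(header$meta_lines, header$column_line)
  for (l in header_lines) pass$write(l)
  if (!is.null(fail)) for (l in header_lines) fail$write(l)

  plan <- tsv_column_plan(header)
  tsv_sink <- NULL
  bed_sink <- NULL
  if (tsv_enabled && !is.null(tsv)) {
    tsv_sink <- open_line_sink(tsv)
    on.exit(tsv_sink$close(), add = TRUE)
    tsv_sink$write(paste(plan, collapse = "\t"))
  }
  if (!is.null(intervals)) {
    bed_sink <- open_line_sink(bed_tsv)
    on.exit(bed_sink$close(), add = TRUE)
    bed_sink$write(paste(c(plan, "INTERVAL_NAME"), collapse = "\t"))
  }

  pass_sink <- function(rec) {
    pass$write(rec$raw_line)
    if (!is.null(tsv_sink) || !is.null(bed_sink)) {
      row <- record_to_tsv_row(rec, header, plan)
      if (!is.null(tsv_sink)) tsv_sink$write(paste(row, collapse = "\t"))
      if (!is.null(bed_sink)) {
        hit <- variant_overlaps(rec, intervals)
        if (!is.null(hit)) {
          nm <- if (is.na(hit$name)) "." else hit$name
          bed_sink$write(paste(c(row, nm), collapse = "\t"))
        }
      }
    }
  }
  fail_sink <- if (!is.null(fail)) function(rec) fail$write(rec$raw_line)

  summary <- run_stream(reader$next_record, chain, header, pass_sink,
                        fail_sink, drop_failed = drop_failed)
  summary$warnings <- c(guard_warnings, summary$warnings)
  if (!is.null(summary_tsv)) write_summary_tsv(summary, summary_tsv)
  if (!quiet) print(summary)
  invisible(summary)
}

validation_error <- function(findings) {
  msg <- paste0("filter chain failed header validation (",
                nrow(findings), " finding(s)):\n",
                paste0("  [", findings$directive_index, "] ", findings$message,
                       collapse = "\n"))
  structure(
    class = c("vcfsift_validation_error", "error", "condition"),
    list(message = msg, call = NULL, findings = findings)
  )
}
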