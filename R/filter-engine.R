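# Numeric equality on annotation text is compared within an absolute
# tolerance: annotations are decimal text and exact float equality is brittle.
NUMERIC_EQ_TOL <- 1e-9

#' Evaluate a numeric comparison against an annotation value
#'
#' Comma-separated annotation values (e.g. per-alternate-allele frequencies)
#' use any-allele semantics: the directive passes when ANY numeric token
#' satisfies the comparison, so a record with one rare and one common allele
#' survives a rarity filter. Missing values (absent key, `.`, or no numeric
#' tokens) are decided by the missing policy alone.
#'
#' @param value An annotation value from [get_annotation()] / [annotation_value()].
#' @param op One of `<`, `<=`, `>`, `>=`, `==`, `!=`.
#' @param threshold Finite numeric threshold.
#' @param missing_policy `"keep"` (missing passes) or `"drop"` (missing fails).
#' @return `TRUE` if the directive passes.
#' @export
eval_numeric <- function(value, op, threshold, missing_policy = "keep") {
  vals <- value$numeric_values
  if (value$is_missing || length(vals) == 0L) {
    return(missing_policy == "keep")
  }
  hit <- switch(op,
    "<"  = vals < threshold,
    "<=" = vals <= threshold,
    ">"  = vals > threshold,
    ">=" = vals >= threshold,
    "==" = abs(vals - threshold) <= NUMERIC_EQ_TOL,
    "!=" = abs(vals - threshold) > NUMERIC_EQ_TOL,
    stop("unknown numeric operator '", op, "'", call. = FALSE))
  any(hit)
}

#' Evaluate a regular-expression filter against an annotation value
#'
#' The pattern is searched unanchored and case-sensitively over the raw
#' annotation text (PCRE), so `exonic` matches annotator composites like
#' `"exonic;splicing"`; anchor with `^`/`$` when exact matching is wanted.
#'
#' @param value An annotation value.
#' @param pattern A regular expression (validated at parse time).
#' @param mode `"match"` (pass on hit) or `"nomatch"` (pass on miss).
#' @param missing_policy `"keep"` or `"drop"`, applied when the value is missing.
#' @return `TRUE` if the directive passes.
#' @export
eval_string <- function(value, pattern, mode = "match", missing_policy = "keep") {
  if (value$is_missing) {
    return(missing_policy == "keep")
  }
  m <- grepl(pattern, value$raw, perl = TRUE)
  if (mode == "match") m else !m
}

#' Evaluate one filter directive on one record
#'
#' Dispatches on directive kind: numeric and string directives resolve their
#' annotation through [get_annotation()] (a FORMAT directive with the `*`
#' selector requires every sample to satisfy it); zygosity and genotype
#' directives delegate to [eval_zygosity_filter()] and
#' [match_genotype_spec()]. A sample selector unknown at run time (possible
#' only in permissive mode) is treated as a missing value with a warning.
#'
#' @param record A `vcf_record`.
#' @param directive A `filter_directive`.
#' @param header The governing `vcf_header`.
#' @param warn Callback receiving warning messages (default [warning()]).
#' @return `TRUE` if the record passes this directive.
#' @export
eval_directive <- function(record, directive, header, warn = warning) {
  kind <- directive$kind
  if (kind == "ZYGOSITY") {
    return(eval_zygosity_filter(record, directive$zyg_mode, directive$zyg_class,
                                directive$sample_selector, header, warn))
  }
  if (kind == "GENOTYPE") {
    return(match_genotype_spec(record, directive$gt_spec, warn))
  }
  eval_one <- function(value) {
    if (kind == "NUMERIC") {
      eval_numeric(value, directive$op, directive$operand, directive$missing_policy)
    } else {
      eval_string(value, directive$pattern, directive$op, directive$missing_policy)
    }
  }
  if (directive$scope == "FORMAT") {
    samples <- if (identical(directive$sample_selector, "*")) {
      header$sample_names
    } else {
      directive$sample_selector
    }
    for (s in samples) {
      value <- if (s %in% header$sample_names) {
        get_annotation(record, "FORMAT", directive$key, header, s)
      } else {
        warn(paste0("unknown sample '", s, "' at run time; treated as missing"))
        annotation_value(NA_character_)
      }
      if (!eval_one(value)) return(FALSE)   # all-samples semantics
    }
    return(TRUE)
  }
  eval_one(get_annotation(record, directive$scope, directive$key, header))
}

#' Evaluate a whole chain on one record
#'
#' Directives are applied in chain order with short-circuit at the first
#' failure, which defines the per-directive failure attribution reported in
#' the run summary.
#'
#' @param record A `vcf_record`.
#' @param chain A validated `filter_chain`.
#' @param header The governing `vcf_header`.
#' @param warn Warning callback.
#' @return A list with `passed` (logical) and `failed_at` (0-based index of
#'   the first failing directive, or `NA` when the record passes).
#' @export
filter_outcome <- function(record, chain, header, warn = warning) {
  for (d in chain$directives) {
    if (!eval_directive(record, d, header, warn)) {
      return(list(passed = FALSE, failed_at = d$index))
    }
  }
  list(passed = TRUE, failed_at = NA_integer_)
}

#' Stream records through a filter chain
#'
#' The single-pass core: each record is pulled from the source, evaluated
#' once, and immediately routed to the pass sink or (unless `drop_failed`)
#' the fail sink, so at no point is more than one record resident regardless
#' of input size. Failure counts are attributed to the first failing
#' directive, giving a funnel view of the chain.
#'
#' @param next_record Function returning the next `vcf_record`, or `NULL` at
#'   end of input (e.g. the `next_record` element of [open_vcf()]).
#' @param chain A validated `filter_chain`.
#' @param header The governing `vcf_header`.
#' @param pass_sink Function consuming each passing record.
#' @param fail_sink Optional function consuming each failing record.
#' @param drop_failed When `TRUE`, failing records are discarded without
#'   touching `fail_sink`.
#' @return An object of class `run_summary`: `total_records`,
#'   `passed_records`, `failed_by_directive` (named integer vector keyed by
#'   0-based directive index), `directive_text` and `warnings`. On
#'   completion `passed_records + sum(failed_by_directive) == total_records`.
#' @export
run_stream <- function(next_record, chain, header, pass_sink,
                       fail_sink = NULL, drop_failed = FALSE) {
  nd <- length(chain$directives)
  failed_by <- integer(nd)
  names(failed_by) <- if (nd) vapply(chain$directives, function(d) as.character(d$index), character(1))
  total <- 0L
  passed <- 0L
  warnings_seen <- character(0)
  warn <- function(msg) {
    msg <- paste(msg, collapse = " ")
    if (!(msg %in% warnings_seen)) warnings_seen <<- c(warnings_seen, msg)
  }
  repeat {
    rec <- next_record()
    if (is.null(rec)) break
    total <- total + 1L
    outcome <- filter_outcome(rec, chain, header, warn)
    if (outcome$passed) {
      passed <- passed + 1L
      pass_sink(rec)
    } else {
      slot <- outcome$failed_at + 1L
      failed_by[[slot]] <- failed_by[[slot]] + 1L
      if (!drop_failed && !is.null(fail_sink)) fail_sink(rec)
    }
  }
  structure(
    list(total_records = total,
         passed_records = passed,
         failed_by_directive = failed_by,
         directive_text = vapply(chain$directives, serialize_directive, character(1)),
         warnings = warnings_seen),
    class = "run_summary"
  )
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Filtering run:", x$total_records, "records,",
      x$passed_records, "passed\n")
  if (length(x$failed_by_directive)) {
    for (i in seq_along(x$failed_by_directive)) {
      cat(sprintf("  [%s] %-50s failed %d\n",
                  names(x$failed_by_directive)[[i]],
                  x$directive_text[[i]],
                  x$failed_by_directive[[i]]))
    }
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write a run summary as a small TSV
#'
#' One row per directive: 0-based index, directive text, failed count; a
#' final row reports the pass total.
#'
#' @param summary A `run_summary`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  lines <- c("directive_index\tdirective\tfailed")
  for (i in seq_along(summary$failed_by_directive)) {
    lines <- c(lines, paste(names(summary$failed_by_directive)[[i]],
                            summary$directive_text[[i]],
                            summary$failed_by_directive[[i]], sep = "\t"))
  }
  lines <- c(lines, paste("total_passed", ".", summary$passed_records, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
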