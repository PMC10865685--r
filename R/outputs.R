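#' Read a BED file of target intervals
#'
#' BED3/BED4 with 0-based half-open coordinates; `track`, `browser`, `#` and
#' blank lines are skipped. Column 4, when present, is stored as the interval
#' name. Intervals are grouped by chromosome and sorted by start then end so
#' overlap queries are deterministic.
#'
#' @param path Path to a BED file.
#' @return An object of class `bed_intervals`: a named list (one element per
#'   chromosome) of data frames with columns `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read BED file '", path, "': no such file", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  chrom <- character(0); start <- integer(0); end <- integer(0); name <- character(0)
  for (ln in seq_along(lines)) {
    line <- sub("\r$", "", lines[[ln]])
    if (line == "" || startsWith(line, "#") ||
        startsWith(line, "track") || startsWith(line, "browser")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed BED line ", ln, ": fewer than 3 columns", call. = FALSE)
    }
    s <- suppressWarnings(as.integer(fields[[2L]]))
    e <- suppressWarnings(as.integer(fields[[3L]]))
    if (is.na(s) || is.na(e)) {
      stop("malformed BED line ", ln, ": non-integer coordinates", call. = FALSE)
    }
    if (s >= e) {
      stop("malformed BED line ", ln, ": start ", s, " >= end ", e, call. = FALSE)
    }
    chrom <- c(chrom, fields[[1L]])
    start <- c(start, s)
    end <- c(end, e)
    name <- c(name, if (length(fields) >= 4L) fields[[4L]] else NA_character_)
  }
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   stringsAsFactors = FALSE)
  out <- lapply(split(df, df$chrom), function(g) {
    g <- g[order(g$start, g$end), c("start", "end", "name")]
    rownames(g) <- NULL
    g
  })
  structure(out, class = "bed_intervals")
}

# Interval chromosome names a record chromosome can match: its own name plus
# the "chr"-prefix-toggled form, since a BED may mix both conventions.
resolve_bed_chroms <- function(chrom, intervals) {
  alt <- if (startsWith(chrom, "chr")) substr(chrom, 4L, nchar(chrom)) else paste0("chr", chrom)
  intersect(c(chrom, alt), names(intervals))
}

#' Find the BED interval overlapped by a variant
#'
#' The variant footprint is the 0-based half-open range
#' `[pos - 1, pos - 1 + nchar(ref))`, i.e. the reference bases the variant
#' spans; symbolic END tags are not consulted. Chromosome matching tolerates a
#' `chr` prefix mismatch between VCF and BED. When several intervals overlap,
#' the one with the smallest start (then smallest end) is returned.
#'
#' @param record A `vcf_record`.
#' @param intervals A `bed_intervals` object.
#' @return A list with `chrom`, `start`, `end`, `name` for the matched
#'   interval, or `NULL` when the footprint overlaps no interval.
#' @export
variant_overlaps <- function(record, intervals) {
  chroms <- resolve_bed_chroms(record$chrom, intervals)
  if (length(chroms) == 0L) return(NULL)
  fp_start <- record$pos - 1L
  fp_end <- fp_start + nchar(record$ref)
  best <- NULL
  for (chrom in chroms) {
    g <- intervals[[chrom]]
    hits <- which(g$start < fp_end & g$end > fp_start)
    if (length(hits) == 0L) next
    h <- hits[[1L]]  # within a group, sorted (start, end): first is smallest
    cand <- list(chrom = chrom, start = g$start[[h]], end = g$end[[h]],
                 name = g$name[[h]])
    if (is.null(best) || cand$start < best$start ||
        (cand$start == best$start && cand$end < best$end)) {
      best <- cand
    }
  }
  best
}

#' Build the TSV column plan for a run
#'
#' Fixed columns CHROM, POS, ID, REF, ALT, QUAL, FILTER, then every header
#' INFO key in declaration order (making the layout deterministic across
#' runs), then one GT column per sample.
#'
#' @param header A `vcf_header`.
#' @return Character vector of column names.
#' @export
tsv_column_plan <- function(header) {
  c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
    names(header$info_defs),
    if (length(header$sample_names)) paste0("GT_", header$sample_names))
}

#' Project a record onto the TSV column plan
#'
#' Missing values render as `.`; INFO flags render `TRUE` when present and
#' `.` otherwise; ALT alleles are joined by `,`; embedded tabs and newlines
#' are replaced by spaces so every row stays rectangular.
#'
#' @param record A `vcf_record`.
#' @param header The governing `vcf_header`.
#' @param plan Column plan from [tsv_column_plan()].
#' @return Character vector of cells, one per plan column.
#' @export
record_to_tsv_row <- function(record, header, plan = tsv_column_plan(header)) {
  cell <- function(x) {
    if (is.null(x) || length(x) == 0L || is.na(x) || x == "") return(".")
    gsub("[\t\r\n]", " ", as.character(x))
  }
  cells <- c(cell(record$chrom),
             cell(record$pos),
             cell(record$id),
             cell(record$ref),
             cell(paste(record$alts, collapse = ",")),
             if (is.na(record$qual)) "." else cell(format(record$qual, scientific = FALSE, trim = TRUE)),
             cell(record$filter))
  for (key in names(header$info_defs)) {
    v <- record$info[[key]]
    cells <- c(cells,
               if (is.null(v)) "."
               else if (isTRUE(v)) "TRUE"
               else cell(v))
  }
  for (s in header$sample_names) {
    vals <- record$sample_values[[s]]
    gt <- if (is.null(vals)) NA_character_ else vals[["GT"]]
    cells <- c(cells, cell(gt))
  }
  stopifnot(length(cells) == length(plan))
  cells
}

#' Apply the multi-sample TSV guard
#'
#' TSV export of a cohort VCF with hundreds of samples produces unwieldy
#' spreadsheets, so when the sample count strictly exceeds the guard
#' threshold (default 50) TSV outputs are disabled with a cautionary warning.
#' A force flag keeps TSV enabled but still records the warning.
#'
#' @param header A `vcf_header`.
#' @param tsv_enabled Whether TSV output was requested.
#' @param threshold Sample-count threshold; the guard fires strictly above it.
#' @param force_tsv When `TRUE`, TSV stays enabled despite the guard.
#' @return A list with `tsv_enabled` (effective setting) and `warning`
#'   (message text, or `NULL` when the guard did not fire).
#' @export
apply_sample_guard <- function(header, tsv_enabled, threshold = 50L,
                               force_tsv = FALSE) {
  stopifnot(threshold >= 1L)
  n <- length(header$sample_names)
  if (tsv_enabled && n > threshold) {
    msg <- paste0("input VCF contains ", n, " samples (over ", threshold,
                  "); TSV output ",
                  if (force_tsv) "forced on despite the sample guard"
                  else "disabled by the sample guard")
    return(list(tsv_enabled = force_tsv, warning = msg))
  }
  list(tsv_enabled = tsv_enabled, warning = NULL)
}

# Line sink over a (possibly gzip) connection; always "\n" line endings.
open_line_sink <- function(path, gzip = FALSE) {
  con <- if (gzip) gzfile(path, open = "wb") else file(path, open = "wb")
  list(
    write = function(line) writeLines(line, con, sep = "\n", useBytes = TRUE),
    close = function() close(con)
  )
}
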