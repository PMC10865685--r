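#' Open a VCF file as a lazy line source
#'
#' Opens a plain-text or gzip-compressed file and returns a closure-based
#' line source that yields lines one at a time in file order. Compression is
#' detected from the gzip magic bytes (`0x1f 0x8b`), never from the file
#' extension, so bgzip output and misnamed files are handled transparently.
#' Only a small fixed-size chunk of the file is buffered at any time, which is
#' what makes single-pass filtering of arbitrarily large files possible.
#'
#' @param path Path to a VCF file, plain or gzip-compressed.
#' @param chunk_size Number of lines buffered per read from the connection.
#' @return A list with elements `read` (function returning the next line, or
#'   `NULL` at end of file), `close` (function releasing the connection),
#'   `line_number` (function returning the number of lines yielded so far) and
#'   `path`.
#' @examples
#' f <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), f)
#' src <- open_variant_stream(f)
#' src$read()
#' src$close()
#' @export
open_variant_stream <- function(path, chunk_size = 1024L) {
  if (!file.exists(path) || dir.exists(path)) {
    stop("cannot read '", path, "': no such file", call. = FALSE)
  }
  gz <- is_gzip_file(path)
  con <- if (gz) {
    gzfile(path, open = "rt", encoding = "UTF-8")
  } else {
    file(path, open = "rt", encoding = "UTF-8")
  }
  buf <- character(0)
  pos <- 0L
  eof <- FALSE
  nline <- 0L
  closed <- FALSE

  fill <- function() {
    report <- function(c) {
      if (gz) {
        stop("decompression error reading '", path, "': ",
             conditionMessage(c), call. = FALSE)
      }
      stop("error reading '", path, "': ", conditionMessage(c),
           call. = FALSE)
    }
    # a corrupt gzip stream surfaces as a warning before the read fails, so
    # both conditions are promoted to the same named error
    lines <- tryCatch(
      readLines(con, n = chunk_size, warn = FALSE),
      error = report, warning = report
    )
    if (length(lines) == 0L) {
      eof <<- TRUE
    } else {
      buf <<- lines
      pos <<- 0L
    }
  }

  read_line <- function() {
    if (pos >= length(buf)) {
      if (eof) return(NULL)
      fill()
      if (eof) return(NULL)
    }
    pos <<- pos + 1L
    nline <<- nline + 1L
    # accept CRLF input; all internal handling is "\n"
    line <- buf[[pos]]
    if (endsWith(line, "\r")) line <- substr(line, 1L, nchar(line) - 1L)
    line
  }

  close_fn <- function() {
    if (!closed) {
      closed <<- TRUE
      close(con)
    }
    invisible(NULL)
  }

  list(read = read_line, close = close_fn,
       line_number = function() nline, path = path)
}

# gzip magic bytes 0x1f 0x8b at offset 0
is_gzip_file <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readBin(con, what = "raw", n = 2L)
  length(magic) == 2L && magic[[1L]] == as.raw(0x1f) && magic[[2L]] == as.raw(0x8b)
}

#' Parse the header section of a VCF line source
#'
#' Consumes `##` meta lines and the `#CHROM` column line from a line source,
#' extracting INFO and FORMAT definitions (ID, Number, Type, Description) and
#' sample names. Meta lines are retained verbatim so output files can
#' reproduce the input header byte for byte. After return the source is
#' positioned at the first record line.
#'
#' @param src A line source from [open_variant_stream()].
#' @return An object of class `vcf_header`: a list with `meta_lines`,
#'   `info_defs`, `format_defs`, `sample_names` and `column_line`. Each entry
#'   of `info_defs`/`format_defs` is a list with `number`, `type` and
#'   `description`.
#' @export
parse_header <- function(src) {
  meta_lines <- character(0)
  info_defs <- list()
  format_defs <- list()
  column_line <- NULL
  repeat {
    line <- src$read()
    if (is.null(line)) {
      stop("malformed header: no '#CHROM' column line found", call. = FALSE)
    }
    if (startsWith(line, "##")) {
      meta_lines <- c(meta_lines, line)
      if (startsWith(line, "##INFO=<")) {
        def <- parse_structured_meta(line)
        if (!is.null(def)) {
          if (def$id %in% names(info_defs)) {
            stop("duplicate INFO definition for key '", def$id, "'",
                 call. = FALSE)
          }
          info_defs[[def$id]] <- def[c("number", "type", "description")]
        }
      } else if (startsWith(line, "##FORMAT=<")) {
        def <- parse_structured_meta(line)
        if (!is.null(def)) {
          if (def$id %in% names(format_defs)) {
            stop("duplicate FORMAT definition for key '", def$id, "'",
                 call. = FALSE)
          }
          format_defs[[def$id]] <- def[c("number", "type", "description")]
        }
      }
    } else if (startsWith(line, "#CHROM")) {
      column_line <- line
      break
    } else {
      stop("malformed header: record or unexpected line before '#CHROM': ",
           substr(line, 1L, 60L), call. = FALSE)
    }
  }
  cols <- strsplit(column_line, "\t", fixed = TRUE)[[1L]]
  sample_names <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  structure(
    list(meta_lines = meta_lines,
         info_defs = info_defs,
         format_defs = format_defs,
         sample_names = sample_names,
         column_line = column_line),
    class = "vcf_header"
  )
}

#' @export
print.vcf_header <- function(x, ...) {
  cat("VCF header:", length(x$meta_lines), "meta lines,",
      length(x$info_defs), "INFO keys,",
      length(x$format_defs), "FORMAT keys,",
      length(x$sample_names), "samples\n")
  if (length(x$sample_names)) {
    cat("  samples:", paste(utils::head(x$sample_names, 8L), collapse = ", "),
        if (length(x$sample_names) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

# Pull ID / Number / Type / Description out of an ##INFO=<...> or
# ##FORMAT=<...> line. Description may contain commas inside its quotes, so
# the simple fields are matched individually rather than split on ",".
parse_structured_meta <- function(line) {
  inner <- sub("^##(INFO|FORMAT)=<", "", line)
  inner <- sub(">\\s*$", "", inner)
  grab <- function(field) {
    m <- regmatches(inner, regexec(paste0("(^|,)", field, "=([^,>\"]+)"), inner))[[1L]]
    if (length(m) >= 3L) m[[3L]] else NA_character_
  }
  id <- grab("ID")
  if (is.na(id)) return(NULL)
  desc <- regmatches(inner, regexec("Description=\"([^\"]*)\"", inner))[[1L]]
  list(id = id,
       number = grab("Number"),
       type = grab("Type"),
       description = if (length(desc) >= 2L) desc[[2L]] else NA_character_)
}

#' Parse one VCF record line
#'
#' Maps the fixed columns, splits ALT on commas, parses INFO via
#' [parse_info()], and splits each sample column positionally against the
#' FORMAT keys. The verbatim source line is retained so pass/fail output
#' files reproduce input lines byte for byte. Trailing FORMAT subfields
#' absent from a sample column are treated as missing, as the VCF standard
#' allows.
#'
#' @param line One tab-separated record line.
#' @param header The governing [parse_header()] result.
#' @param line_number Optional source line number used in error messages.
#' @return An object of class `vcf_record`.
#' @export
parse_record <- function(line, header, line_number = NA_integer_) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  where <- if (is.na(line_number)) "" else paste0(" at line ", line_number)
  if (length(fields) < 8L) {
    stop("malformed record", where, ": fewer than 8 columns", call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(fields[[2L]]))
  if (is.na(pos)) {
    stop("malformed record", where, ": POS '", fields[[2L]],
         "' is not an integer", call. = FALSE)
  }
  qual <- if (fields[[6L]] == ".") NA_real_ else suppressWarnings(as.numeric(fields[[6L]]))
  n_samples <- length(header$sample_names)
  format_keys <- character(0)
  sample_values <- list()
  if (length(fields) >= 10L) {
    if (length(fields) - 9L != n_samples) {
      stop("malformed record", where, ": ", length(fields) - 9L,
           " sample columns for ", n_samples, " declared samples",
           call. = FALSE)
    }
    format_keys <- strsplit(fields[[9L]], ":", fixed = TRUE)[[1L]]
    for (i in seq_len(n_samples)) {
      vals <- strsplit(fields[[9L + i]], ":", fixed = TRUE)[[1L]]
      if (length(vals) < length(format_keys)) {
        vals <- c(vals, rep(NA_character_, length(format_keys) - length(vals)))
      } else if (length(vals) > length(format_keys)) {
        vals <- vals[seq_along(format_keys)]
      }
      names(vals) <- format_keys
      sample_values[[header$sample_names[[i]]]] <- vals
    }
  }
  structure(
    list(chrom = fields[[1L]],
         pos = pos,
         id = fields[[3L]],
         ref = fields[[4L]],
         alts = strsplit(fields[[5L]], ",", fixed = TRUE)[[1L]],
         qual = qual,
         filter = fields[[7L]],
         info = parse_info(fields[[8L]]),
         format_keys = format_keys,
         sample_values = sample_values,
         raw_line = line),
    class = "vcf_record"
  )
}

#' Parse a VCF INFO column into an ordered key/value map
#'
#' Entries are split on `;`; `key=value` pairs map to their raw value text,
#' bare keys become flags (stored as `TRUE`), and `.` yields an empty map.
#' Insertion order is preserved. A duplicated key within one record keeps the
#' last value with a warning: real annotator output contains duplicates and
#' rejecting the record outright would be worse than tolerating them.
#'
#' @param info_text The 8th VCF column.
#' @return A named list; flag keys hold `TRUE`, others their raw value text.
#' @export
parse_info <- function(info_text) {
  if (is.na(info_text) || info_text == "." || info_text == "") {
    return(structure(list(), names = character(0)))
  }
  parts <- strsplit(info_text, ";", fixed = TRUE)[[1L]]
  out <- list()
  for (part in parts) {
    if (part == "") next
    eq <- regexpr("=", part, fixed = TRUE)
    if (eq > 0L) {
      key <- substr(part, 1L, eq - 1L)
      val <- substr(part, eq + 1L, nchar(part))
    } else {
      key <- part
      val <- TRUE
    }
    if (key %in% names(out)) {
      warning("duplicate INFO key '", key, "' in record; keeping last value",
              call. = FALSE)
    }
    out[[key]] <- val
  }
  out
}

#' Wrap a raw annotation string as an annotation value
#'
#' @param raw Raw value text, or `NA` when the annotation is absent.
#' @return A list with `raw`, `numeric_values` (finite numbers parsed from
#'   comma-separated tokens, non-numeric tokens skipped) and `is_missing`
#'   (`TRUE` when raw is absent, `"."` or empty).
#' @export
annotation_value <- function(raw) {
  if (length(raw) != 1L || is.na(raw) || identical(raw, ".") || identical(raw, "")) {
    return(list(raw = NA_character_, numeric_values = numeric(0), is_missing = TRUE))
  }
  raw <- as.character(raw)
  toks <- strsplit(raw, ",", fixed = TRUE)[[1L]]
  nums <- suppressWarnings(as.numeric(toks))
  nums <- nums[is.finite(nums)]
  list(raw = raw, numeric_values = nums, is_missing = FALSE)
}

#' Resolve an annotation from a record by scope and key
#'
#' One uniform access path for everything a filter can target: `SITE` serves
#' the fixed QUAL and FILTER columns, `INFO` the INFO map, and `FORMAT` a
#' named sample's subfield. A present INFO flag is exposed with raw text
#' `"TRUE"` (matching its TSV rendering); it carries no numeric tokens.
#'
#' @param record A `vcf_record`.
#' @param scope One of `"SITE"`, `"INFO"`, `"FORMAT"`.
#' @param key Annotation key; for `SITE` one of `QUAL`, `FILTER`.
#' @param header The governing `vcf_header` (needed to validate sample names).
#' @param sample Sample name, required for `FORMAT` scope.
#' @return An annotation value as produced by [annotation_value()].
#' @export
get_annotation <- function(record, scope, key, header = NULL, sample = NULL) {
  if (scope == "SITE") {
    if (key == "QUAL") {
      raw <- if (is.na(record$qual)) NA_character_ else {
        # preserve the numeric value exactly; raw text is only used for display
        format(record$qual, scientific = FALSE, trim = TRUE)
      }
      av <- annotation_value(raw)
      if (!av$is_missing) av$numeric_values <- record$qual
      return(av)
    }
    if (key == "FILTER") return(annotation_value(record$filter))
    stop("SITE scope serves keys QUAL and FILTER, not '", key, "'",
         call. = FALSE)
  }
  if (scope == "INFO") {
    v <- record$info[[key]]
    if (is.null(v)) return(annotation_value(NA_character_))
    if (isTRUE(v)) {
      return(list(raw = "TRUE", numeric_values = numeric(0), is_missing = FALSE))
    }
    return(annotation_value(v))
  }
  if (scope == "FORMAT") {
    if (is.null(sample)) stop("FORMAT scope requires a sample name", call. = FALSE)
    if (!is.null(header) && !(sample %in% header$sample_names)) {
      stop("unknown sample '", sample, "'", call. = FALSE)
    }
    vals <- record$sample_values[[sample]]
    if (is.null(vals) || !(key %in% names(vals))) {
      return(annotation_value(NA_character_))
    }
    return(annotation_value(vals[[key]]))
  }
  stop("unknown annotation scope '", scope, "'", call. = FALSE)
}

#' Open a VCF file for streaming record access
#'
#' Convenience wrapper combining [open_variant_stream()] and [parse_header()]
#' into a record-level iterator. Blank lines are skipped.
#'
#' @param path Path to a plain or gzip-compressed VCF file.
#' @return A list with `header` (a `vcf_header`), `next_record` (function
#'   returning the next `vcf_record` or `NULL` at end of file), `close`, and
#'   `path`.
#' @export
open_vcf <- function(path) {
  src <- open_variant_stream(path)
  header <- parse_header(src)
  next_record <- function() {
    repeat {
      line <- src$read()
      if (is.null(line)) return(NULL)
      if (line == "") next
      return(parse_record(line, header, line_number = src$line_number()))
    }
  }
  list(header = header, next_record = next_record, close = src$close,
       path = path)
}

#' @export
print.vcf_record <- function(x, ...) {
  cat(sprintf("VCF record %s:%d %s>%s", x$chrom, x$pos, x$ref,
              paste(x$alts, collapse = ",")), "\n")
  invisible(x)
}
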