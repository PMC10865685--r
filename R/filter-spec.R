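#' @name filter_grammar
#' @title The filter-order file grammar
#' @description
#' A filter-order file holds one directive per line; blank lines and lines
#' starting with `#` are ignored. Directives form an ordered conjunction (the
#' "filtering order"): a record must pass every directive, and directives are
#' evaluated in file order with short-circuit at the first failure. The
#' grammar, with whitespace-separated tokens:
#'
#' \preformatted{
#' SITE QUAL <op> <number> [missing=keep|drop]
#' SITE FILTER match|nomatch <regex> [missing=keep|drop]
#' INFO <key> <op> <number> [missing=keep|drop]
#' INFO <key> match|nomatch <regex> [missing=keep|drop]
#' FORMAT <key> <sample|*> <op> <number> [missing=keep|drop]
#' ZYG include|exclude het|homalt|homref <sample|*>
#' GT <sample>=<class>[,<class>...] [<sample>=<classes> ...]
#' }
#'
#' with `<op>` one of `<`, `<=`, `>`, `>=`, `==`, `!=` and genotype classes
#' from `homref`, `het`, `homalt`, `missing`. The `*` sample selector means
#' every sample must satisfy the directive. `missing=keep` (the default)
#' passes records lacking the annotation — in rarity-driven filtering an
#' absent population frequency usually marks a rare variant that must not be
#' discarded silently; `missing=drop` fails them. String patterns are
#' unanchored, case-sensitive Perl-compatible regular expressions matched
#' against the raw annotation text. A `GT` line with several
#' `sample=classes` assignments requires all of them to hold; the de novo
#' construct for a trio is `GT child=het mother=homref father=homref`.
NULL

NUMERIC_OPS <- c("<", "<=", ">", ">=", "==", "!=")
ZYG_CLASSES <- c("homref", "het", "homalt")
GT_CLASSES <- c("homref", "het", "homalt", "missing")

#' Parse filter-order text into a filter chain
#'
#' @param text Character vector of filter-order lines (or a single string
#'   with embedded newlines).
#' @return An object of class `filter_chain`: list with `directives` (ordered
#'   list of `filter_directive`) and `source_text`.
#' @seealso [filter_grammar] for the directive syntax,
#'   [parse_filter_file()] to read from a file.
#' @export
parse_filter_chain <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  directives <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (line == "" || startsWith(line, "#")) next
    d <- parse_directive_line(line, ln)
    d$index <- length(directives)        # 0-based chain position
    directives[[length(directives) + 1L]] <- d
  }
  structure(
    list(directives = directives, source_text = paste(lines, collapse = "\n")),
    class = "filter_chain"
  )
}

#' Read and parse a filter-order file
#'
#' @param path Path to a plain-text filter-order file.
#' @return A `filter_chain`; see [parse_filter_chain()].
#' @export
parse_filter_file <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read filter file '", path, "': no such file", call. = FALSE)
  }
  parse_filter_chain(readLines(path, warn = FALSE))
}

syntax_error <- function(ln, ...) {
  stop("filter syntax error at line ", ln, ": ", ..., call. = FALSE)
}

parse_directive_line <- function(line, ln) {
  toks <- strsplit(line, "\\s+")[[1L]]
  scope <- toks[[1L]]

  # optional trailing missing= option (numeric/string directives only)
  missing_policy <- "keep"
  last <- toks[[length(toks)]]
  if (grepl("^missing=", last)) {
    val <- sub("^missing=", "", last)
    if (!(val %in% c("keep", "drop"))) {
      syntax_error(ln, "missing policy must be keep or drop, got '", val, "'")
    }
    missing_policy <- val
    toks <- toks[-length(toks)]
  }

  d <- list(index = NA_integer_, scope = scope, kind = NA_character_,
            key = NA_character_, sample_selector = NULL,
            op = NA_character_, operand = NA_real_, operand_text = NA_character_,
            pattern = NA_character_, zyg_mode = NA_character_,
            zyg_class = NA_character_, gt_spec = NULL,
            missing_policy = missing_policy, text = line)

  if (scope == "SITE") {
    if (length(toks) != 4L) syntax_error(ln, "SITE directive needs 4 tokens")
    key <- toks[[2L]]
    if (key == "QUAL") {
      d <- fill_numeric(d, ln, op = toks[[3L]], operand = toks[[4L]])
      d$key <- "QUAL"
    } else if (key == "FILTER") {
      d <- fill_string(d, ln, mode = toks[[3L]], pattern = toks[[4L]])
      d$key <- "FILTER"
    } else {
      syntax_error(ln, "SITE scope supports QUAL and FILTER, got '", key, "'")
    }
  } else if (scope == "INFO") {
    if (length(toks) != 4L) syntax_error(ln, "INFO directive needs 4 tokens")
    d$key <- toks[[2L]]
    if (toks[[3L]] %in% c("match", "nomatch")) {
      d <- fill_string(d, ln, mode = toks[[3L]], pattern = toks[[4L]])
    } else {
      d <- fill_numeric(d, ln, op = toks[[3L]], operand = toks[[4L]])
    }
  } else if (scope == "FORMAT") {
    if (length(toks) != 5L) syntax_error(ln, "FORMAT directive needs 5 tokens")
    d$key <- toks[[2L]]
    d$sample_selector <- toks[[3L]]
    d <- fill_numeric(d, ln, op = toks[[4L]], operand = toks[[5L]])
  } else if (scope == "ZYG") {
    if (length(toks) != 4L) syntax_error(ln, "ZYG directive needs 4 tokens")
    if (!(toks[[2L]] %in% c("include", "exclude"))) {
      syntax_error(ln, "ZYG mode must be include or exclude, got '", toks[[2L]], "'")
    }
    if (!(toks[[3L]] %in% ZYG_CLASSES)) {
      syntax_error(ln, "ZYG class must be one of ",
                   paste(ZYG_CLASSES, collapse = "/"), ", got '", toks[[3L]], "'")
    }
    d$kind <- "ZYGOSITY"
    d$zyg_mode <- toks[[2L]]
    d$zyg_class <- toks[[3L]]
    d$sample_selector <- toks[[4L]]
  } else if (scope == "GT") {
    if (length(toks) < 2L) syntax_error(ln, "GT directive needs at least one sample=classes assignment")
    spec <- list()
    for (tok in toks[-1L]) {
      eq <- regexpr("=", tok, fixed = TRUE)
      if (eq <= 1L) syntax_error(ln, "bad GT assignment '", tok, "'")
      sample <- substr(tok, 1L, eq - 1L)
      classes <- strsplit(substr(tok, eq + 1L, nchar(tok)), ",", fixed = TRUE)[[1L]]
      bad <- setdiff(classes, GT_CLASSES)
      if (length(bad) || length(classes) == 0L) {
        syntax_error(ln, "bad genotype class '",
                     if (length(bad)) bad[[1L]] else "", "' in '", tok, "'")
      }
      if (sample %in% names(spec)) syntax_error(ln, "sample '", sample, "' assigned twice")
      spec[[sample]] <- classes
    }
    d$kind <- "GENOTYPE"
    d$gt_spec <- spec
  } else {
    syntax_error(ln, "unknown scope token '", scope, "'")
  }
  structure(d, class = "filter_directive")
}

fill_numeric <- function(d, ln, op, operand) {
  if (!(op %in% NUMERIC_OPS)) {
    syntax_error(ln, "unknown operator '", op, "'")
  }
  val <- suppressWarnings(as.numeric(operand))
  if (is.na(val) || !is.finite(val)) {
    syntax_error(ln, "operand '", operand, "' is not a finite number")
  }
  d$kind <- "NUMERIC"
  d$op <- op
  d$operand <- val
  d$operand_text <- operand
  d
}

fill_string <- function(d, ln, mode, pattern) {
  ok <- tryCatch({ grepl(pattern, "", perl = TRUE); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) {
    stop("filter pattern error at line ", ln, ": '", pattern,
         "' is not a valid regular expression", call. = FALSE)
  }
  d$kind <- "STRING"
  d$op <- mode
  d$pattern <- pattern
  d
}

#' Serialize a filter chain back to filter-order lines
#'
#' Reconstructs one grammar line per directive from the parsed fields (not
#' from the stored source text), so `parse_filter_chain(serialize_filter_chain(x))`
#' reproduces the chain.
#'
#' @param chain A `filter_chain`.
#' @return Character vector of directive lines.
#' @export
serialize_filter_chain <- function(chain) {
  vapply(chain$directives, serialize_directive, character(1))
}

serialize_directive <- function(d) {
  miss <- if (identical(d$missing_policy, "drop")) " missing=drop" else ""
  switch(d$kind,
    NUMERIC = {
      if (d$scope == "FORMAT") {
        paste0("FORMAT ", d$key, " ", d$sample_selector, " ", d$op, " ",
               d$operand_text, miss)
      } else {
        paste0(d$scope, " ", d$key, " ", d$op, " ", d$operand_text, miss)
      }
    },
    STRING = paste0(d$scope, " ", d$key, " ", d$op, " ", d$pattern, miss),
    ZYGOSITY = paste0("ZYG ", d$zyg_mode, " ", d$zyg_class, " ", d$sample_selector),
    GENOTYPE = paste0("GT ", paste(vapply(names(d$gt_spec), function(s) {
      paste0(s, "=", paste(d$gt_spec[[s]], collapse = ","))
    }, character(1)), collapse = " ")),
    stop("unknown directive kind '", d$kind, "'")
  )
}

#' Validate a filter chain against a VCF header
#'
#' Cross-checks every directive against the header before any record is read:
#' INFO/FORMAT keys must be declared, sample selectors must name declared
#' samples, and numeric directives must not target keys declared `Type=Flag`.
#' Findings are returned as data — the caller decides whether to abort
#' (strict mode) or drop the offending directives (permissive mode). An empty
#' finding table means the chain is runnable. The function never mutates its
#' arguments.
#'
#' @param chain A `filter_chain`.
#' @param header A `vcf_header`.
#' @return A data frame with columns `directive_index` (0-based), `type`
#'   (`unknown-key`, `unknown-sample` or `type-mismatch`) and `message`;
#'   zero rows when the chain is runnable.
#' @export
validate_chain <- function(chain, header) {
  idx <- integer(0); type <- character(0); msg <- character(0)
  add <- function(i, t, m) {
    idx <<- c(idx, i); type <<- c(type, t); msg <<- c(msg, m)
  }
  check_sample <- function(i, sel) {
    if (!is.null(sel) && !identical(sel, "*") && !(sel %in% header$sample_names)) {
      add(i, "unknown-sample",
          paste0("sample '", sel, "' not among header samples"))
    }
  }
  for (d in chain$directives) {
    if (d$scope == "INFO") {
      def <- header$info_defs[[d$key]]
      if (is.null(def)) {
        add(d$index, "unknown-key",
            paste0("INFO key '", d$key, "' not declared in header"))
      } else if (d$kind == "NUMERIC" && identical(def$type, "Flag")) {
        add(d$index, "type-mismatch",
            paste0("numeric filter on INFO key '", d$key, "' declared Type=Flag"))
      }
    } else if (d$scope == "FORMAT") {
      def <- header$format_defs[[d$key]]
      if (is.null(def)) {
        add(d$index, "unknown-key",
            paste0("FORMAT key '", d$key, "' not declared in header"))
      } else if (d$kind == "NUMERIC" && identical(def$type, "Flag")) {
        add(d$index, "type-mismatch",
            paste0("numeric filter on FORMAT key '", d$key, "' declared Type=Flag"))
      }
      check_sample(d$index, d$sample_selector)
    } else if (d$kind == "ZYGOSITY") {
      check_sample(d$index, d$sample_selector)
    } else if (d$kind == "GENOTYPE") {
      for (s in names(d$gt_spec)) check_sample(d$index, s)
    }
  }
  data.frame(directive_index = idx, type = type, message = msg,
             stringsAsFactors = FALSE)
}

#' @export
print.filter_chain <- function(x, ...) {
  cat("Filter chain with", length(x$directives), "directive(s):\n")
  for (d in x$directives) {
    cat(sprintf("  [%d] %s\n", d$index, serialize_directive(d)))
  }
  invisible(x)
}

#' @export
print.filter_directive <- function(x, ...) {
  cat(serialize_directive(x), "\n")
  invisible(x)
}
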