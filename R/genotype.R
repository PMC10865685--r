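#' Normalize a GT genotype string
#'
#' Splits on `/` or `|`, encodes missing alleles (`.`) as `-1`, and sorts
#' allele indices ascending, so `"0/1"` and `"1|0"` normalize identically.
#' Normalization is deliberately phase-insensitive: zygosity filters and
#' genotype specifications must not depend on phasing or allele order.
#'
#' @param gt_text A GT subfield, e.g. `"0/1"`, `"1|0"`, `"./."`, `"2"`.
#' @return An object of class `genotype`: list with `allele_indices` (sorted
#'   integers, `-1` for missing), `phased` and `raw`.
#' @export
normalize_gt <- function(gt_text) {
  if (length(gt_text) != 1L || is.na(gt_text) || gt_text == "") {
    stop("malformed genotype: empty GT value", call. = FALSE)
  }
  phased <- grepl("|", gt_text, fixed = TRUE)
  toks <- strsplit(gt_text, "[/|]")[[1L]]
  if (length(toks) == 0L) {
    stop("malformed genotype '", gt_text, "'", call. = FALSE)
  }
  bad <- toks != "." & !grepl("^[0-9]+$", toks)
  if (any(bad) || any(toks == "")) {
    stop("malformed genotype '", gt_text, "': allele token '",
         toks[bad | toks == ""][[1L]], "'", call. = FALSE)
  }
  idx <- ifelse(toks == ".", -1L, suppressWarnings(as.integer(toks)))
  structure(
    list(allele_indices = sort(as.integer(idx)), phased = phased, raw = gt_text),
    class = "genotype"
  )
}

#' Classify the zygosity of a normalized genotype
#'
#' The classification is total over syntactically valid GT strings: any
#' missing allele makes the call `missing`; all-reference is `homref`; all
#' copies of one alternate allele is `homalt`; exactly two distinct alleles
#' with at least one alternate is `het` (so multi-allelic calls like `1/2`
#' count as heterozygous); anything else — e.g. a triploid call with three
#' distinct alleles — is `other`.
#'
#' @param gt A `genotype` from [normalize_gt()], or a GT string.
#' @return One of `"homref"`, `"het"`, `"homalt"`, `"missing"`, `"other"`.
#' @export
classify_zygosity <- function(gt) {
  if (is.character(gt)) gt <- normalize_gt(gt)
  idx <- gt$allele_indices
  if (any(idx < 0L)) return("missing")
  if (all(idx == 0L)) return("homref")
  u <- unique(idx)
  if (length(u) == 1L) return("homalt")    # all equal, > 0 at this point
  if (length(u) == 2L) return("het")
  "other"
}

# Zygosity class of one sample's GT in a record; absent or unparseable GT
# values are conservatively classed "missing".
sample_zygosity <- function(record, sample) {
  vals <- record$sample_values[[sample]]
  gt <- if (is.null(vals)) NA_character_ else vals[["GT"]]
  if (is.null(gt) || is.na(gt) || gt == "" || gt == ".") return("missing")
  tryCatch(classify_zygosity(gt), error = function(e) "missing")
}

#' Apply a zygosity include/exclude filter to a record
#'
#' `include` passes a record only when every selected sample has the target
#' zygosity; `exclude` passes only when no selected sample has it. Samples
#' with a missing genotype never satisfy an include target and never trigger
#' an exclude target, so uncalled samples cannot smuggle variants through
#' either way.
#'
#' @param record A `vcf_record`.
#' @param mode `"include"` or `"exclude"`.
#' @param target Target class: `"homref"`, `"het"` or `"homalt"`.
#' @param sample_selector A sample name or `"*"` for all samples.
#' @param header The governing `vcf_header`.
#' @param warn Callback invoked with a message when GT is absent from the
#'   record's FORMAT keys (the directive then passes, i.e. missing-keep).
#' @return `TRUE` if the record passes the directive.
#' @export
eval_zygosity_filter <- function(record, mode, target, sample_selector,
                                 header, warn = warning) {
  if (!("GT" %in% record$format_keys)) {
    warn("GT absent from FORMAT; zygosity filter not applied to record")
    return(TRUE)
  }
  samples <- if (identical(sample_selector, "*")) header$sample_names else sample_selector
  classes <- vapply(samples, function(s) sample_zygosity(record, s), character(1))
  if (mode == "include") {
    all(classes == target)
  } else {
    !any(classes == target)
  }
}

#' Match a record against a per-sample genotype specification
#'
#' A genotype specification maps sample names to sets of allowed zygosity
#' classes; a record matches when every named sample's class is in its
#' allowed set. The canonical de novo specification for a trio is
#' child = het, mother = homref, father = homref: a heterozygous call in the
#' child absent from both parents.
#'
#' @param record A `vcf_record`.
#' @param spec Named list: sample name to character vector of allowed classes
#'   (subset of `homref`, `het`, `homalt`, `missing`).
#' @param warn Callback used when GT is absent from the record's FORMAT keys
#'   (the directive then passes).
#' @return `TRUE` if the record matches the specification.
#' @examples
#' # de novo specification for a trio
#' spec <- list(child = "het", mother = "homref", father = "homref")
#' @export
match_genotype_spec <- function(record, spec, warn = warning) {
  if (!("GT" %in% record$format_keys)) {
    warn("GT absent from FORMAT; genotype specification not applied to record")
    return(TRUE)
  }
  for (sample in names(spec)) {
    if (!(sample_zygosity(record, sample) %in% spec[[sample]])) return(FALSE)
  }
  TRUE
}

#' @export
print.genotype <- function(x, ...) {
  cat("genotype", x$raw, "-> [", paste(x$allele_indices, collapse = ","), "]",
      if (x$phased) "(phased)" else "", "\n")
  invisible(x)
}
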