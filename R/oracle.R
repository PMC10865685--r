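# Independent brute-force verification oracles. These deliberately share no
# code with the streaming engine: they load the whole file, re-parse records
# with their own minimal splitting, and evaluate every directive without
# short-circuiting, using separate comparison, regex (regexpr rather than
# grepl) and zygosity call sites. Agreement between engine and oracle is
# therefore evidence, not tautology.

#' Brute-force filtering oracle
#'
#' Loads an entire (small) VCF into memory and naively evaluates every
#' directive of the chain on every record, independently of the streaming
#' engine's parsing and evaluation paths.
#'
#' @param path Path to a plain or gzip-compressed VCF small enough to load.
#' @param chain A `filter_chain`.
#' @return Integer vector of passing record indices (1-based, in file order).
#' @export
oracle_filter <- function(path, chain) {
  con <- gzfile(path, open = "rt")    # reads plain text transparently too
  lines <- readLines(con, warn = FALSE)
  close(con)
  lines <- sub("\r$", "", lines)
  col_i <- which(startsWith(lines, "#CHROM"))[1L]
  cols <- strsplit(lines[[col_i]], "\t", fixed = TRUE)[[1L]]
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  records <- lines[seq_along(lines) > col_i & lines != ""]
  passing <- integer(0)
  for (i in seq_along(records)) {
    f <- strsplit(records[[i]], "\t", fixed = TRUE)[[1L]]
    ok <- TRUE
    for (d in chain$directives) {
      if (!oracle_eval(d, f, samples)) { ok <- FALSE }   # no short-circuit
    }
    if (ok) passing <- c(passing, i)
  }
  passing
}

# raw text of the annotation a directive targets, or NA when absent
oracle_raw_value <- function(d, f, samples, sample) {
  if (d$scope == "SITE") {
    v <- if (d$key == "QUAL") f[[6L]] else f[[7L]]
    return(v)
  }
  if (d$scope == "INFO") {
    if (f[[8L]] == ".") return(NA_character_)
    kv <- strsplit(f[[8L]], ";", fixed = TRUE)[[1L]]
    out <- NA_character_
    for (item in kv) {
      pieces <- strsplit(item, "=", fixed = TRUE)[[1L]]
      if (pieces[[1L]] == d$key) {
        out <- if (length(pieces) >= 2L) {
          paste(pieces[-1L], collapse = "=")
        } else "TRUE"                   # flag; later duplicates overwrite
      }
    }
    return(out)
  }
  # FORMAT scope
  if (length(f) < 10L) return(NA_character_)
  keys <- strsplit(f[[9L]], ":", fixed = TRUE)[[1L]]
  k <- match(d$key, keys)
  s <- match(sample, samples)
  if (is.na(k) || is.na(s)) return(NA_character_)
  vals <- strsplit(f[[9L + s]], ":", fixed = TRUE)[[1L]]
  if (k > length(vals)) return(NA_character_)
  vals[[k]]
}

oracle_gt_class <- function(f, samples, sample) {
  if (length(f) < 10L) return("missing")
  keys <- strsplit(f[[9L]], ":", fixed = TRUE)[[1L]]
  k <- match("GT", keys)
  s <- match(sample, samples)
  if (is.na(k) || is.na(s)) return("missing")
  vals <- strsplit(f[[9L + s]], ":", fixed = TRUE)[[1L]]
  if (k > length(vals)) return("missing")
  gt <- vals[[k]]
  if (is.na(gt) || gt == "" || gt == ".") return("missing")
  alleles <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)[[1L]]
  if (any(alleles == ".")) return("missing")
  a <- suppressWarnings(as.integer(alleles))
  if (any(is.na(a))) return("missing")
  if (max(a) == 0L) return("homref")
  u <- unique(a)
  if (length(u) == 1L) return("homalt")
  if (length(u) == 2L) return("het")
  "other"
}

oracle_numeric_ok <- function(raw, op, threshold, keep_missing) {
  if (is.na(raw) || raw == "." || raw == "") return(keep_missing)
  vals <- suppressWarnings(as.numeric(strsplit(raw, ",", fixed = TRUE)[[1L]]))
  vals <- vals[!is.na(vals) & is.finite(vals)]
  if (length(vals) == 0L) return(keep_missing)
  sat <- FALSE
  for (v in vals) {
    hit <- if (op == "<") v < threshold
      else if (op == "<=") v <= threshold
      else if (op == ">") v > threshold
      else if (op == ">=") v >= threshold
      else if (op == "==") abs(v - threshold) <= 1e-9
      else abs(v - threshold) > 1e-9
    if (hit) sat <- TRUE
  }
  sat
}

oracle_string_ok <- function(raw, pattern, mode, keep_missing) {
  if (is.na(raw) || raw == "." || raw == "") return(keep_missing)
  hit <- regexpr(pattern, raw, perl = TRUE) > 0L
  if (mode == "match") hit else !hit
}

oracle_eval <- function(d, f, samples) {
  keep_missing <- identical(d$missing_policy, "keep")
  if (d$kind == "ZYGOSITY") {
    keys <- if (length(f) >= 10L) strsplit(f[[9L]], ":", fixed = TRUE)[[1L]] else character(0)
    if (!("GT" %in% keys)) return(TRUE)
    who <- if (identical(d$sample_selector, "*")) samples else d$sample_selector
    classes <- vapply(who, function(s) oracle_gt_class(f, samples, s), character(1))
    return(if (d$zyg_mode == "include") all(classes == d$zyg_class)
           else !any(classes == d$zyg_class))
  }
  if (d$kind == "GENOTYPE") {
    keys <- if (length(f) >= 10L) strsplit(f[[9L]], ":", fixed = TRUE)[[1L]] else character(0)
    if (!("GT" %in% keys)) return(TRUE)
    for (s in names(d$gt_spec)) {
      if (!(oracle_gt_class(f, samples, s) %in% d$gt_spec[[s]])) return(FALSE)
    }
    return(TRUE)
  }
  who <- if (d$scope == "FORMAT") {
    if (identical(d$sample_selector, "*")) samples else d$sample_selector
  } else NA_character_
  for (s in who) {
    raw <- oracle_raw_value(d, f, samples, s)
    ok <- if (d$kind == "NUMERIC") {
      oracle_numeric_ok(raw, d$op, d$operand, keep_missing)
    } else {
      oracle_string_ok(raw, d$pattern, d$op, keep_missing)
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Brute-force BED overlap oracle
#'
#' All-pairs overlap check between every record of a VCF and every interval
#' of a BED file, independent of the grouped-and-sorted interval structure
#' used by [variant_overlaps()]. A record overlaps when its footprint
#' `[pos - 1, pos - 1 + nchar(ref))` intersects an interval on the same
#' chromosome (tolerating a `chr` prefix mismatch).
#'
#' @param vcf_path Path to a small VCF.
#' @param bed_path Path to a BED file.
#' @return Integer vector of record indices (1-based) overlapping at least
#'   one interval.
#' @export
oracle_bed_overlaps <- function(vcf_path, bed_path) {
  con <- gzfile(vcf_path, open = "rt")
  lines <- readLines(con, warn = FALSE)
  close(con)
  col_i <- which(startsWith(lines, "#CHROM"))[1L]
  records <- lines[seq_along(lines) > col_i & lines != ""]
  bed <- readLines(bed_path, warn = FALSE)
  bed <- bed[bed != "" & !startsWith(bed, "#") &
             !startsWith(bed, "track") & !startsWith(bed, "browser")]
  strip <- function(x) sub("^chr", "", x)
  hits <- integer(0)
  for (i in seq_along(records)) {
    f <- strsplit(records[[i]], "\t", fixed = TRUE)[[1L]]
    fp_start <- as.integer(f[[2L]]) - 1L
    fp_end <- fp_start + nchar(f[[4L]])
    for (b in bed) {
      g <- strsplit(b, "\t", fixed = TRUE)[[1L]]
      if (strip(g[[1L]]) != strip(f[[1L]])) next
      if (as.integer(g[[2L]]) < fp_end && as.integer(g[[3L]]) > fp_start) {
        hits <- c(hits, i)
        break
      }
    }
  }
  hits
}
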