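# Seeded synthetic-data generators. These stand in for annotated study VCFs:
# ANNOVAR-style INFO keys (coverage depth DP, population allele frequency AF,
# functional class Func, dbSNP flag DB) plus GT:DP FORMAT columns. Identical
# arguments always produce byte-identical files.

synthetic_header_lines <- function(sample_names) {
  c("##fileformat=VCFv4.2",
    "##source=vcfsift-synthetic",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=Func,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(sample_names)) c("FORMAT", sample_names)),
          collapse = "\t"))
}

AF_LEVELS <- c(0.0005, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5)
FUNC_LEVELS <- c("exonic", "intronic", "splicing", "UTR5", "exonic;splicing")
BASES <- c("A", "C", "G", "T")

# run the generator body under a private, restorable RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic annotated VCF
#'
#' Emits a well-formed single- or multi-sample VCF whose header declares the
#' default annotation schema: `DP` (integer, uniform on 1..100), `AF`
#' (per-alternate allele frequency drawn from a fixed rarity ladder, missing
#' at `missing_rate`), `Func` (functional class including the composite
#' `exonic;splicing` that exercises regex filters) and the `DB` flag, plus
#' `GT:DP` sample columns. A ground-truth table records every emitted value
#' so filter predicates can be evaluated independently of the VCF parser.
#'
#' @param path Output path for the VCF.
#' @param n_records Number of records (0 gives a header-only VCF).
#' @param n_samples Number of sample columns (0 gives a sites-only VCF).
#' @param seed Integer seed; identical arguments give byte-identical files.
#' @param missing_rate Fraction of AF annotations emitted as missing.
#' @param gzip Write gzip-compressed output.
#' @return A list with `path` and `truth` (data frame, one row per record,
#'   raw annotation strings with `"."` for missing).
#' @export
generate_synthetic_vcf <- function(path, n_records = 200L, n_samples = 1L,
                                   seed = 1L, missing_rate = 0.2,
                                   gzip = FALSE) {
  samples <- if (n_samples > 0L) paste0("S", seq_len(n_samples)) else character(0)
  with_seed(seed, {
    lines <- synthetic_header_lines(samples)
    truth <- vector("list", n_records)
    if (n_records > 0L) {
      chrom <- sort(sample(c("1", "2", "X"), n_records, replace = TRUE))
      pos <- integer(n_records)
      last <- c("1" = 0L, "2" = 0L, "X" = 0L)
      for (i in seq_len(n_records)) {
        last[[chrom[[i]]]] <- last[[chrom[[i]]]] + sample(1:500, 1L)
        pos[[i]] <- last[[chrom[[i]]]]
      }
      for (i in seq_len(n_records)) {
        ref <- if (runif(1) < 0.1) {
          paste(sample(BASES, sample(2:4, 1L), replace = TRUE), collapse = "")
        } else sample(BASES, 1L)
        n_alt <- if (runif(1) < 0.15) 2L else 1L
        alt <- paste(sample(setdiff(BASES, substr(ref, 1L, 1L)), n_alt),
                     collapse = ",")
        id <- if (runif(1) < 0.3) paste0("rs", sample(1e6, 1L)) else "."
        qual <- if (runif(1) < 0.05) "." else as.character(round(runif(1, 0, 1000), 1))
        filt <- sample(c("PASS", "q10", "."), 1L, prob = c(0.7, 0.2, 0.1))
        dp <- if (runif(1) < 0.05) "." else as.character(sample(1:100, 1L))
        af <- if (runif(1) < missing_rate) "." else {
          paste(sample(AF_LEVELS, n_alt, replace = TRUE), collapse = ",")
        }
        func <- if (runif(1) < 0.1) "." else {
          sample(FUNC_LEVELS, 1L, prob = c(0.35, 0.3, 0.1, 0.1, 0.15))
        }
        db <- runif(1) < 0.3
        info <- character(0)
        if (dp != ".") info <- c(info, paste0("DP=", dp))
        if (af != ".") info <- c(info, paste0("AF=", af))
        if (func != ".") info <- c(info, paste0("Func=", func))
        if (db) info <- c(info, "DB")
        info_text <- if (length(info)) paste(info, collapse = ";") else "."
        row <- list(record = i, chrom = chrom[[i]], pos = pos[[i]], id = id,
                    ref = ref, alt = alt, qual = qual, filter = filt,
                    DP = dp, AF = af, Func = func, DB = db)
        cols <- c(chrom[[i]], pos[[i]], id, ref, alt, qual, filt, info_text)
        if (n_samples > 0L) {
          gts <- sample(c("0/0", "0/1", "1/1", "./.", "0|1", "1|0"),
                        n_samples, replace = TRUE,
                        prob = c(0.35, 0.25, 0.15, 0.05, 0.1, 0.1))
          sdp <- ifelse(runif(n_samples) < 0.05, ".",
                        as.character(sample(1:100, n_samples, replace = TRUE)))
          cols <- c(cols, "GT:DP", paste(gts, sdp, sep = ":"))
          for (k in seq_len(n_samples)) {
            row[[paste0("GT_", samples[[k]])]] <- gts[[k]]
            row[[paste0("DP_", samples[[k]])]] <- sdp[[k]]
          }
        }
        truth[[i]] <- row
        lines <- c(lines, paste(cols, collapse = "\t"))
      }
    }
    con <- if (gzip) gzfile(path, open = "wb") else file(path, open = "wb")
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
    truth_df <- if (n_records > 0L) {
      do.call(rbind, lapply(truth, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    } else NULL
    list(path = path, truth = truth_df, sample_names = samples)
  })
}

#' Generate a synthetic trio VCF with planted de novo variants
#'
#' Samples are named `child`, `mother`, `father`. Background sites carry
#' Mendelian-consistent genotype configurations that never form the
#' child-het / parents-homref pattern, so the planted sites are the only
#' de novo candidates by construction; `denovo_count` sites carry child 0/1
#' (sometimes phased as 1|0) with both parents 0/0. The annotation schema
#' matches [generate_synthetic_vcf()].
#'
#' @param path Output path.
#' @param n_records Total number of records.
#' @param denovo_count Number of planted de novo sites.
#' @param seed Integer seed.
#' @param gzip Write gzip-compressed output.
#' @return A list with `path`, `denovo_sites` (data frame with `record`,
#'   `chrom`, `pos`) and `sample_names`.
#' @export
generate_trio_vcf <- function(path, n_records = 500L, denovo_count = 12L,
                              seed = 7L, gzip = FALSE) {
  stopifnot(denovo_count <= n_records)
  samples <- c("child", "mother", "father")
  # Mendelian-consistent (child, mother, father) configurations with no
  # child-het/parents-homref pattern; "./." rows exercise missing handling.
  background <- list(
    c("0/0", "0/0", "0/0"),
    c("0/1", "0/1", "0/0"),
    c("0/1", "0/0", "0/1"),
    c("0/0", "0/1", "0/1"),
    c("0/1", "0/1", "0/1"),
    c("1/1", "0/1", "0/1"),
    c("1/1", "1/1", "1/1"),
    c("0/0", "0/1", "0/0"),
    c("0/0", "0/0", "0/1"),
    c("./.", "0/1", "0/0"),
    c("0/1", "./.", "0/0"),
    c("1/1", "1/1", "0/1")
  )
  phase_variant <- function(gt) {
    if (gt == "0/1" && runif(1) < 0.3) sample(c("0|1", "1|0"), 1L) else gt
  }
  with_seed(seed, {
    lines <- synthetic_header_lines(samples)
    denovo_idx <- sort(sample(seq_len(n_records), denovo_count))
    chrom <- sort(sample(c("1", "2", "X"), n_records, replace = TRUE))
    pos <- integer(n_records)
    last <- c("1" = 0L, "2" = 0L, "X" = 0L)
    for (i in seq_len(n_records)) {
      last[[chrom[[i]]]] <- last[[chrom[[i]]]] + sample(1:500, 1L)
      pos[[i]] <- last[[chrom[[i]]]]
    }
    for (i in seq_len(n_records)) {
      ref <- sample(BASES, 1L)
      alt <- sample(setdiff(BASES, ref), 1L)
      gts <- if (i %in% denovo_idx) {
        c(phase_variant("0/1"), "0/0", "0/0")
      } else {
        vapply(background[[sample(length(background), 1L)]], phase_variant,
               character(1), USE.NAMES = FALSE)
      }
      dp <- sample(1:100, 1L)
      af <- if (runif(1) < 0.2) NULL else sample(AF_LEVELS, 1L)
      func <- sample(FUNC_LEVELS, 1L)
      info <- paste(c(paste0("DP=", dp),
                      if (!is.null(af)) paste0("AF=", af),
                      paste0("Func=", func)), collapse = ";")
      sdp <- as.character(sample(1:100, 3L, replace = TRUE))
      cols <- c(chrom[[i]], pos[[i]], ".", ref, alt,
                as.character(round(runif(1, 0, 1000), 1)), "PASS", info,
                "GT:DP", paste(gts, sdp, sep = ":"))
      lines <- c(lines, paste(cols, collapse = "\t"))
    }
    con <- if (gzip) gzfile(path, open = "wb") else file(path, open = "wb")
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
    list(path = path,
         denovo_sites = data.frame(record = denovo_idx,
                                   chrom = chrom[denovo_idx],
                                   pos = pos[denovo_idx],
                                   stringsAsFactors = FALSE),
         sample_names = samples)
  })
}

#' Generate a random BED file of target intervals
#'
#' Intervals are drawn on the chromosomes used by the VCF generators, with a
#' mix of bare (`1`) and `chr`-prefixed (`chr1`) names to exercise the
#' prefix-tolerant overlap matching, and optional interval names.
#'
#' @param path Output path.
#' @param n_intervals Number of intervals.
#' @param seed Integer seed.
#' @param max_pos Upper bound for interval coordinates.
#' @return A list with `path` and `intervals` (data frame `chrom`, `start`,
#'   `end`, `name`).
#' @export
generate_bed <- function(path, n_intervals = 20L, seed = 1L, max_pos = 30000L) {
  with_seed(seed, {
    chroms <- sample(c("1", "chr1", "2", "chr2", "X"), n_intervals, replace = TRUE)
    start <- sample(0:(max_pos - 2L), n_intervals, replace = TRUE)
    len <- sample(1:2000, n_intervals, replace = TRUE)
    end <- pmin(start + len, max_pos)
    named <- runif(1) < 0.5
    name <- if (named) paste0("GENE", seq_len(n_intervals)) else rep(NA_character_, n_intervals)
    df <- data.frame(chrom = chroms, start = start, end = end, name = name,
                     stringsAsFactors = FALSE)
    body <- if (named) {
      paste(df$chrom, df$start, df$end, df$name, sep = "\t")
    } else {
      paste(df$chrom, df$start, df$end, sep = "\t")
    }
    lines <- c("track name=targets", body)
    writeLines(lines, path, useBytes = TRUE)
    list(path = path, intervals = df)
  })
}

#' Draw a random filter chain from the grammar
#'
#' Used by property tests: samples 1 or more directives over the synthetic
#' annotation schema (INFO DP/AF/Func, SITE QUAL/FILTER, FORMAT DP, ZYG, GT),
#' all targeting keys the synthetic header declares so strict validation
#' passes. Draws from the current RNG state; seed externally for
#' reproducibility.
#'
#' @param sample_names Sample names of the target VCF (used for FORMAT/ZYG/GT
#'   directives; with zero samples only site/INFO directives are drawn).
#' @param n_directives Number of directives.
#' @return A `filter_chain`.
#' @export
random_filter_chain <- function(sample_names, n_directives = sample(1:10, 1L)) {
  pick_sample <- function() {
    if (length(sample_names) == 0L) return(NULL)
    if (runif(1) < 0.4) "*" else sample(sample_names, 1L)
  }
  pats <- c("exonic", "^exonic", "splicing|UTR5", "intronic$", "exonic;splicing", "UTR")
  make_one <- function() {
    kinds <- c("dp", "af", "func", "qual", "filter")
    if (length(sample_names) > 0L) kinds <- c(kinds, "fmt_dp", "zyg", "gt")
    kind <- sample(kinds, 1L, prob = c(rep(3, 5), rep(1, length(kinds) - 5L)))
    miss <- if (runif(1) < 0.3) " missing=drop" else ""
    op <- sample(NUMERIC_OPS, 1L)
    switch(kind,
      dp = paste0("INFO DP ", op, " ", sample(1:100, 1L), miss),
      af = paste0("INFO AF ", op, " ", sample(AF_LEVELS, 1L), miss),
      func = paste0("INFO Func ", sample(c("match", "nomatch"), 1L), " ",
                    sample(pats, 1L), miss),
      qual = paste0("SITE QUAL ", op, " ", sample(0:1000, 1L), miss),
      filter = paste0("SITE FILTER ", sample(c("match", "nomatch"), 1L), " ",
                      sample(c("PASS", "^PASS$", "q10"), 1L)),
      fmt_dp = paste0("FORMAT DP ", pick_sample(), " ", op, " ",
                      sample(1:100, 1L), miss),
      zyg = paste0("ZYG ", sample(c("include", "exclude"), 1L), " ",
                   sample(ZYG_CLASSES, 1L), " ", pick_sample()),
      gt = {
        who <- sample(sample_names, sample(seq_along(sample_names), 1L))
        paste0("GT ", paste(vapply(who, function(s) {
          paste0(s, "=", paste(sample(GT_CLASSES, sample(1:2, 1L)), collapse = ","))
        }, character(1)), collapse = " "))
      })
  }
  parse_filter_chain(vapply(seq_len(n_directives), function(i) make_one(),
                            character(1)))
}
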