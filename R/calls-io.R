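# Variant-call tables and coverage summaries.
#
# The on-disk dialect is a flat tab-separated table with one row per
# variant call and a fixed column order; a VCF 4.2 rendering with
# reserved INFO keys is provided for interoperability. All
# filter-relevant evidence travels with the call: per-strand mutant and
# reference read counts, the count of mutant reads with base quality
# >25, the mean mapping quality of supporting reads, the "supported only
# by the first/last 15 bp of reads" flag, the adjacent-repeat count REP
# for indels, and the two caller-support read counts used by the indel
# filters.

.VARIANT_COLUMNS <- c(
  "sample_id", "position", "ref", "alt", "kind",
  "mutant_reads", "total_depth", "vaf",
  "fwd_mut", "rev_mut", "fwd_ref", "rev_ref",
  "bq25_count", "mean_mq", "read_end_only", "rep_count",
  "pindel_reads", "bwa_reads"
)

#' Assemble a variant-call table
#'
#' Builds and validates the canonical in-memory variant table used by
#' every pipeline stage. `vaf` is recomputed from `mutant_reads /
#' total_depth`; a stored value disagreeing beyond 1e-6 is an error, not
#' a warning.
#'
#' @param df Data frame with (a subset of) the dialect columns; missing
#'   evidence columns are filled with permissive defaults.
#' @return Validated data frame with class `variant_table`.
#' @export
variant_table <- function(df) {
  required <- c("sample_id", "position", "ref", "alt",
                "mutant_reads", "total_depth")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    .stopf("variant table lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  if (is.null(df$kind)) {
    df$kind <- ifelse(nchar(df$ref) == nchar(df$alt), "substitution",
                      ifelse(nchar(df$ref) < nchar(df$alt),
                             "insertion", "deletion"))
  }
  fill <- list(fwd_mut = NA_integer_, rev_mut = NA_integer_,
               fwd_ref = NA_integer_, rev_ref = NA_integer_,
               bq25_count = NA_integer_, mean_mq = NA_real_,
               read_end_only = FALSE, rep_count = 0L,
               pindel_reads = NA_integer_, bwa_reads = NA_integer_)
  for (col in names(fill)) if (is.null(df[[col]])) df[[col]] <- rep(fill[[col]], n)

  df$position <- as.integer(df$position)
  int_cols <- c("mutant_reads", "total_depth", "fwd_mut", "rev_mut",
                "fwd_ref", "rev_ref", "bq25_count", "rep_count",
                "pindel_reads", "bwa_reads")
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  df$mean_mq <- as.numeric(df$mean_mq)
  df$read_end_only <- as.logical(df$read_end_only)

  bad <- which(df$mutant_reads > df$total_depth | df$mutant_reads < 0)
  if (length(bad)) {
    .stopf("row %d: mutant_reads (%d) exceeds total_depth (%d)",
           bad[1L], df$mutant_reads[bad[1L]], df$total_depth[bad[1L]])
  }
  vaf <- ifelse(df$total_depth > 0, df$mutant_reads / df$total_depth, 0)
  if (!is.null(df$vaf)) {
    off <- which(abs(df$vaf - vaf) > 1e-6)
    if (length(off)) {
      .stopf("row %d: stored VAF %.6f inconsistent with %d/%d",
             off[1L], df$vaf[off[1L]], df$mutant_reads[off[1L]],
             df$total_depth[off[1L]])
    }
  }
  df$vaf <- vaf
  strands <- !is.na(df$fwd_mut) & !is.na(df$rev_mut)
  bad <- which(strands & (df$fwd_mut + df$rev_mut != df$mutant_reads))
  if (length(bad)) {
    .stopf("row %d: strand counts %d+%d do not sum to mutant_reads %d",
           bad[1L], df$fwd_mut[bad[1L]], df$rev_mut[bad[1L]],
           df$mutant_reads[bad[1L]])
  }
  df <- df[, .VARIANT_COLUMNS]
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read a variant-call table
#'
#' Accepts either the tab-separated dialect written by
#' [write_variant_table()] or the VCF 4.2 rendering (detected from the
#' `##fileformat=VCF` header). Gzip-compressed files are transparent.
#'
#' @param path File path.
#' @return A [variant_table()].
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) .stopf("variant table not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "##fileformat=VCF")) {
    return(.read_variant_vcf(path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         ref = "character",
                                         alt = "character"))
  tryCatch(variant_table(df), error = function(e) {
    .stopf("while reading %s: %s", path, conditionMessage(e))
  })
}

#' Write a variant-call table
#'
#' Lossless, deterministic tab-separated serialisation (stable column
#' order, fixed NA encoding); [read_variant_table()] round-trips it
#' exactly.
#'
#' @param calls A [variant_table()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(.write_variant_vcf(calls, path))
  df <- as.data.frame(calls)[, .VARIANT_COLUMNS, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# reserved INFO keys of the VCF rendering
.VCF_INFO_KEYS <- c(
  KIND = "kind", MR = "mutant_reads", DP = "total_depth",
  FM = "fwd_mut", RM = "rev_mut", FR = "fwd_ref", RR = "rev_ref",
  BQ25 = "bq25_count", MMQ = "mean_mq", RDEND = "read_end_only",
  REP = "rep_count", PR = "pindel_reads", BR = "bwa_reads"
)

.write_variant_vcf <- function(calls, path) {
  df <- as.data.frame(calls)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mtclade",
    '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Sample identifier">',
    '##INFO=<ID=KIND,Number=1,Type=String,Description="substitution, insertion or deletion">',
    '##INFO=<ID=MR,Number=1,Type=Integer,Description="Mutant read count">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##INFO=<ID=FM,Number=1,Type=Integer,Description="Forward-strand mutant reads">',
    '##INFO=<ID=RM,Number=1,Type=Integer,Description="Reverse-strand mutant reads">',
    '##INFO=<ID=FR,Number=1,Type=Integer,Description="Forward-strand reference reads">',
    '##INFO=<ID=RR,Number=1,Type=Integer,Description="Reverse-strand reference reads">',
    '##INFO=<ID=BQ25,Number=1,Type=Integer,Description="Mutant reads with base quality >25">',
    '##INFO=<ID=MMQ,Number=1,Type=Float,Description="Mean mapping quality of supporting reads">',
    '##INFO=<ID=RDEND,Number=0,Type=Flag,Description="Supported only by first/last 15 bp of reads">',
    '##INFO=<ID=REP,Number=1,Type=Integer,Description="Adjacent repeats of the indel unit">',
    '##INFO=<ID=PR,Number=1,Type=Integer,Description="Pindel-supporting reads">',
    '##INFO=<ID=BR,Number=1,Type=Integer,Description="BWA-supporting reads">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(df)) {
    fmt_num <- function(x) {
      out <- vapply(x, function(v) {
        if (is.na(v)) "." else format(v, scientific = FALSE, trim = TRUE)
      }, character(1L))
      out
    }
    info <- paste0("SAMPLE=", df$sample_id)
    for (key in names(.VCF_INFO_KEYS)) {
      col <- .VCF_INFO_KEYS[[key]]
      if (key == "RDEND") {
        info <- paste0(info, ifelse(df[[col]], ";RDEND", ""))
      } else {
        info <- paste0(info, ";", key, "=", fmt_num(df[[col]]))
      }
    }
    writeLines(paste("MT", df$position, ".", df$ref, df$alt, ".", "PASS",
                     info, sep = "\t"), con)
  }
  invisible(path)
}

.read_variant_vcf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(variant_table(data.frame(sample_id = character(),
                                    position = integer(), ref = character(),
                                    alt = character(),
                                    mutant_reads = integer(),
                                    total_depth = integer())))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_bad <- which(lengths(fields) != 8L)
  if (length(n_bad)) .stopf("malformed VCF row at data line %d", n_bad[1L])
  rec <- do.call(rbind, lapply(fields, function(f) f))
  info <- strsplit(rec[, 8L], ";", fixed = TRUE)
  get_key <- function(kv, key) {
    hit <- kv[startsWith(kv, paste0(key, "="))]
    if (!length(hit)) return(NA_character_)
    sub(paste0(key, "="), "", hit[1L], fixed = TRUE)
  }
  num <- function(key) {
    v <- vapply(info, get_key, character(1L), key = key)
    suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  }
  df <- data.frame(
    sample_id = vapply(info, get_key, character(1L), key = "SAMPLE"),
    position = as.integer(rec[, 2L]),
    ref = rec[, 4L], alt = rec[, 5L],
    kind = vapply(info, get_key, character(1L), key = "KIND"),
    mutant_reads = num("MR"), total_depth = num("DP"),
    fwd_mut = num("FM"), rev_mut = num("RM"),
    fwd_ref = num("FR"), rev_ref = num("RR"),
    bq25_count = num("BQ25"), mean_mq = num("MMQ"),
    read_end_only = vapply(info, function(kv) "RDEND" %in% kv, logical(1L)),
    rep_count = num("REP"), pindel_reads = num("PR"), bwa_reads = num("BR"),
    stringsAsFactors = FALSE
  )
  variant_table(df)
}

#' Assemble coverage summaries
#'
#' One row per sample: mean mtDNA coverage, mean nuclear coverage and
#' ploidy, with the two QC flags the pipeline consumes: hosts with mean
#' coverage below 20X are "low coverage" (stricter contamination checks
#' apply), and samples above 300X mtDNA coverage are flagged for
#' exclusion from copy-number and indel analysis.
#'
#' @param df Data frame with columns `sample_id`, `mt_cov`, `nucl_cov`
#'   and optionally `ploidy` (default 2).
#' @param low_cov_threshold,high_cov_threshold Flag thresholds in X.
#' @return Data frame with class `coverage_summary`.
#' @export
coverage_summary <- function(df, low_cov_threshold = 20,
                             high_cov_threshold = 300) {
  stopifnot(all(c("sample_id", "mt_cov", "nucl_cov") %in% names(df)))
  if (is.null(df$ploidy)) df$ploidy <- 2
  if (any(df$mt_cov < 0) || any(df$nucl_cov < 0)) {
    .stopf("coverage values must be non-negative")
  }
  if (any(df$ploidy < 1)) .stopf("ploidy must be >= 1")
  df$low_coverage <- df$mt_cov < low_cov_threshold
  df$high_coverage <- df$mt_cov > high_cov_threshold
  df <- df[, c("sample_id", "mt_cov", "nucl_cov", "ploidy",
               "low_coverage", "high_coverage")]
  rownames(df) <- NULL
  class(df) <- c("coverage_summary", "data.frame")
  df
}

#' Read / write coverage summaries
#'
#' @param path File path (tab-separated).
#' @rdname coverage_io
#' @export
read_coverage_summary <- function(path) {
  if (!file.exists(path)) .stopf("coverage summary not found: %s", path)
  coverage_summary(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @param cov A [coverage_summary()].
#' @rdname coverage_io
#' @export
write_coverage_summary <- function(cov, path) {
  utils::write.table(as.data.frame(cov)[, c("sample_id", "mt_cov",
                                            "nucl_cov", "ploidy")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
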