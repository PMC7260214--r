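# Count table schema: cpg_id, chrom, pos (1-based), condition, replicate,
# day, coverage, meth_count. Tab-separated, header required, NA as empty field.
.COUNT_COLS <- c("cpg_id", "chrom", "pos", "condition", "replicate", "day",
                 "coverage", "meth_count")

.validate_counts <- function(counts, where = "count table") {
  stopifnot(is.data.frame(counts))
  missing_cols <- setdiff(.COUNT_COLS, names(counts))
  if (length(missing_cols)) {
    stop(sprintf("%s lacks required columns: %s", where,
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.na(counts$meth_count) & !is.na(counts$coverage) &
                 counts$meth_count > counts$coverage)
  if (length(bad)) {
    stop(sprintf("%s: meth_count > coverage at rows %s", where,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  key <- paste(counts$cpg_id, counts$condition, counts$replicate, counts$day,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("%s: duplicate (cpg_id, condition, replicate, day) at rows %s",
                 where, paste(utils::head(dup, 5), collapse = ", ")))
  }
  as.data.frame(counts)
}

#' Read a methylation count table
#'
#' Tab-separated with header columns `cpg_id`, `chrom`, `pos` (1-based),
#' `condition`, `replicate`, `day`, `coverage`, `meth_count`. Missing calls are
#' empty fields. Leading `#` comment lines are skipped. Schema violations
#' (missing columns, `meth_count > coverage`, duplicate keys) are hard errors
#' reported with row numbers.
#'
#' @param path TSV file.
#' @return data.frame in the schema above.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  first <- readLines(path, n = 100L)
  skip <- match(FALSE, startsWith(first, "#")) - 1L
  if (is.na(skip)) stop(sprintf("%s: no header line found", path))
  header <- strsplit(first[skip + 1L], "\t", fixed = TRUE)[[1]]
  if (!all(.COUNT_COLS %in% header)) {
    stop(sprintf("%s: header must contain: %s", path,
                 paste(.COUNT_COLS, collapse = ", ")))
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = skip,
                          na.strings = "", colClasses = list(
                            character = c("cpg_id", "chrom", "condition")
                          ))
  df <- as.data.frame(dt)
  .validate_counts(df, where = path)
}

#' Write a methylation count table
#'
#' Lossless counterpart of [read_counts()]; NA values are written as empty
#' fields.
#'
#' @param counts Count table.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- .validate_counts(counts)
  data.table::fwrite(counts, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Write rate estimates to TSV
#'
#' @param estimates [fit_rates()] output (or any data.frame).
#' @param path Output TSV; a `#` comment header records package version.
#' @return `path`, invisibly.
#' @export
write_rates <- function(estimates, path) {
  writeLines(sprintf("# methkinetics %s rate estimates",
                     as.character(utils::packageVersion("methkinetics"))),
             path)
  suppressWarnings(utils::write.table(estimates, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' Read rate estimates written by [write_rates()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_rates <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, na.strings = ""))
}

#' Write a bedGraph track of a rate field
#'
#' CpGs carry 1-based positions; bedGraph is 0-based half-open, so a CpG at
#' `pos` is emitted as the interval `[pos - 1, pos)`.
#'
#' @param estimates [fit_rates()] or [tet_comparison()] output with `chrom`,
#'   `pos` and the requested field.
#' @param field Column to export (e.g. `"k_me"`, `"k_de"`, `"steady_state"`,
#'   `"tet_activity"`).
#' @param path Output file.
#' @param include_unidentifiable Keep CpGs flagged unidentifiable (default
#'   `FALSE`; rows lacking an `identifiable` column are kept).
#' @return `path`, invisibly.
#' @export
write_rates_bedgraph <- function(estimates, field, path,
                                 include_unidentifiable = FALSE) {
  stopifnot(is.data.frame(estimates))
  if (!field %in% names(estimates)) {
    stop(sprintf("unknown field '%s'", field))
  }
  if (!all(c("chrom", "pos") %in% names(estimates))) {
    stop("estimates must carry chrom and pos")
  }
  df <- estimates
  if (!include_unidentifiable && "identifiable" %in% names(df)) {
    df <- df[df$identifiable %in% TRUE, , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# methkinetics %s",
                     as.character(utils::packageVersion("methkinetics"))), con)
  writeLines(sprintf("track type=bedGraph name=%s", field), con)
  if (nrow(df)) {
    writeLines(sprintf("%s\t%d\t%d\t%.6g", df$chrom, as.integer(df$pos) - 1L,
                       as.integer(df$pos), df[[field]]), con)
  }
  invisible(path)
}

#' Read a BED interval file
#'
#' BED3/BED4 (0-based, half-open); intervals are sorted per chromosome.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` and optional `name`.
#' @export
read_intervals <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3L) stop(sprintf("%s: BED needs >= 3 columns", path))
  df <- as.data.frame(dt)[, seq_len(min(4L, ncol(dt))), drop = FALSE]
  names(df) <- c("chrom", "start", "end", "name")[seq_len(ncol(df))]
  if (any(df$start >= df$end)) stop("BED intervals must satisfy start < end")
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Summarize a rate field over genomic intervals
#'
#' Overlaps CpG estimates (1-based point positions) with BED-style intervals
#' (0-based half-open) and computes a per-interval statistic.
#'
#' @param estimates data.frame with `chrom`, `pos` and the rate field.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `name`, e.g. from [read_intervals()].
#' @param field Column of `estimates` to summarize. Default `"k_me"`.
#' @param statistic `"mean"`, `"median"` or `"count"`.
#' @return data.frame with one row per interval: the interval columns, `n_cpgs`
#'   and `value` (NA where no CpG overlaps and the statistic is not `"count"`).
#' @export
aggregate_over_intervals <- function(estimates, intervals, field = "k_me",
                                     statistic = c("mean", "median", "count")) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("chrom", "pos") %in% names(estimates)),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (statistic != "count" && !field %in% names(estimates)) {
    stop(sprintf("unknown field '%s'", field))
  }
  cpg_gr <- GenomicRanges::GRanges(
    estimates$chrom,
    IRanges::IRanges(start = as.integer(estimates$pos), width = 1L)
  )
  # BED half-open [start, end) -> 1-based closed [start + 1, end]
  iv_gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = as.integer(intervals$start) + 1L,
                     end = as.integer(intervals$end))
  )
  hits <- GenomicRanges::findOverlaps(cpg_gr, iv_gr)
  out <- intervals
  out$n_cpgs <- 0L
  tab <- table(S4Vectors::subjectHits(hits))
  out$n_cpgs[as.integer(names(tab))] <- as.integer(tab)
  if (statistic == "count") {
    out$value <- out$n_cpgs
    return(out)
  }
  out$value <- NA_real_
  if (length(hits)) {
    vals <- split(estimates[[field]][S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits))
    fn <- if (statistic == "mean") mean else stats::median
    out$value[as.integer(names(vals))] <-
      vapply(vals, fn, numeric(1), USE.NAMES = FALSE)
  }
  out
}
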