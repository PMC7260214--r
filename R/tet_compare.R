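#' Mock-baseline normalization of a Cre time course
#'
#' Removes transduction-protocol drift from Cre-treated measurements using the
#' paired mock-treated samples. CpGs are binned by their mock day-0 methylation
#' level in 10% increments; within each bin the mock levels are averaged per
#' timepoint and divided by the bin's day-0 average, giving per-bin correction
#' factors `f_bin(t)`. Each Cre-level is then divided by its bin's factor
#' (default direction) and re-expressed as counts at the original coverage.
#'
#' @param cre,mock Count tables (schema of [read_counts()]) over the same CpGs
#'   and timepoints.
#' @param bins Number of equal-width day-0 level bins. Default 10
#'   (`[0, 0.1), ..., [0.9, 1]`).
#' @param direction `"divide"` (default; cancels mock drift) or `"multiply"`.
#' @return The corrected Cre count table (`meth_count` recomputed as
#'   `round(corrected_level * coverage)` and clipped to `[0, coverage]`). The
#'   per-bin factors are attached as attribute `"factors"`.
#' @export
mock_normalize <- function(cre, mock, bins = 10L,
                           direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  cre <- .validate_counts(cre)
  mock <- .validate_counts(mock)
  days <- sort(unique(cre$day))
  if (!all(days %in% unique(mock$day))) {
    stop("mock table is missing timepoints present in the Cre table")
  }
  mock$level <- mock$meth_count / mock$coverage

  # bin assignment from the mock day-0 mean level per CpG
  d0 <- mock[mock$day == 0 & !is.na(mock$level), , drop = FALSE]
  d0_mean <- tapply(d0$level, d0$cpg_id, mean)
  edges <- seq(0, 1, length.out = bins + 1L)
  bin_of <- function(x) pmin(findInterval(x, edges, rightmost.closed = TRUE),
                             bins)
  cpg_bin <- stats::setNames(bin_of(as.numeric(d0_mean)), names(d0_mean))

  mock$bin <- cpg_bin[as.character(mock$cpg_id)]
  ok <- !is.na(mock$bin) & !is.na(mock$level)
  f <- matrix(1, nrow = bins, ncol = length(days),
              dimnames = list(NULL, as.character(days)))
  means <- tapply(mock$level[ok],
                  list(mock$bin[ok], factor(mock$day[ok], levels = days)),
                  mean)
  for (b in seq_len(bins)) {
    br <- as.character(b)
    if (!br %in% rownames(means) || is.na(means[br, "0"]) ||
        means[br, "0"] == 0) {
      if (any(cpg_bin == b, na.rm = TRUE)) {
        warning(sprintf("empty or degenerate mock bin %d: factor set to 1", b))
      }
      next
    }
    f[b, ] <- ifelse(is.na(means[br, ]), 1, means[br, ] / means[br, "0"])
  }

  out <- cre
  lvl <- out$meth_count / out$coverage
  b <- cpg_bin[as.character(out$cpg_id)]
  fac <- f[cbind(b, match(out$day, days))]
  fac[is.na(fac)] <- 1
  lvl <- switch(direction, divide = lvl / fac, multiply = lvl * fac)
  lvl <- pmin(pmax(lvl, 0), 1)
  out$meth_count <- as.integer(pmin(round(lvl * out$coverage), out$coverage))
  attr(out, "factors") <- f
  out
}

#' Predict the wild-type demethylation rate from steady states
#'
#' With a shared de novo rate `k_me` between the two genetic backgrounds, the
#' steady-state relation `M_eq = k_me / (k_me + k_de)` gives
#' `k_me = k_de_ttko * m_ttko / (1 - m_ttko)` and hence
#' `k_de_wt = k_de_ttko * (m_ttko * (1 - m_wt)) / ((1 - m_ttko) * m_wt)`:
#' the wild-type demethylation rate predicted purely from the shift in
#' steady-state methylation, without a wild-type time course.
#'
#' @param m_wt,m_ttko Steady-state methylation fractions in the two
#'   backgrounds, each strictly inside (0, 1). Values exactly 0 or 1 are an
#'   error unless `clip = TRUE`, in which case they are moved 1e-6 inward and
#'   flagged via attribute `"clipped"`.
#' @param k_de_ttko Demethylation rate inferred in the TET triple-knockout.
#' @param clip Clip degenerate steady states instead of erroring.
#' @return Predicted wild-type demethylation rate(s).
#' @examples
#' predict_kde_wt(m_wt = 0.5, m_ttko = 0.8, k_de_ttko = 0.1) # 0.4
#' @export
predict_kde_wt <- function(m_wt, m_ttko, k_de_ttko, clip = FALSE) {
  stopifnot(length(m_wt) == length(m_ttko),
            all(k_de_ttko > 0, na.rm = TRUE))
  degen <- m_wt <= 0 | m_wt >= 1 | m_ttko <= 0 | m_ttko >= 1
  if (any(degen, na.rm = TRUE)) {
    if (!clip) {
      stop("steady states at 0 or 1 give undefined predictions; see `clip`")
    }
    m_wt <- pmin(pmax(m_wt, 1e-6), 1 - 1e-6)
    m_ttko <- pmin(pmax(m_ttko, 1e-6), 1 - 1e-6)
  }
  out <- k_de_ttko * (m_ttko * (1 - m_wt)) / ((1 - m_ttko) * m_wt)
  if (any(degen, na.rm = TRUE)) attr(out, "clipped") <- which(degen)
  out
}

#' TET activity as a log2 rate fold change
#'
#' @param k_de_wt,k_de_ttko Demethylation rates (per day, > 0).
#' @return `log2(k_de_wt) - log2(k_de_ttko)`; 0 means no TET contribution,
#'   log2(3) ~ 1.585 a three-fold faster demethylation in wild type.
#' @examples
#' tet_activity_log2(0.3, 0.1) # log2(3)
#' @export
tet_activity_log2 <- function(k_de_wt, k_de_ttko) {
  if (any(k_de_wt <= 0 | k_de_ttko <= 0, na.rm = TRUE)) {
    stop("rates must be positive for a log2 fold change")
  }
  log2(k_de_wt) - log2(k_de_ttko)
}

#' Agreement between time-course and steady-state demethylation rates
#'
#' Pearson correlation of log10 rates between wild-type demethylation rates
#' inferred from the full time course and those predicted from steady states
#' alone ([predict_kde_wt()]), restricted to pairs where both are available.
#'
#' @param k_de_timecourse,k_de_predicted Paired positive rate vectors.
#' @return List with `r` (Pearson correlation of log10 rates), `n` (pairs
#'   used) and `data` (the paired log10 rates).
#' @export
validate_prediction <- function(k_de_timecourse, k_de_predicted) {
  stopifnot(length(k_de_timecourse) == length(k_de_predicted))
  ok <- is.finite(k_de_timecourse) & is.finite(k_de_predicted) &
    k_de_timecourse > 0 & k_de_predicted > 0
  if (sum(ok) < 3L) stop("need at least 3 valid pairs")
  x <- log10(k_de_timecourse[ok])
  y <- log10(k_de_predicted[ok])
  list(r = stats::cor(x, y), n = sum(ok),
       data = data.frame(log10_timecourse = x, log10_predicted = y))
}

#' Per-CpG TET comparison table
#'
#' Assembles the steady-state comparison for paired WT/TTKO estimates:
#' predicted wild-type demethylation rate and TET activity per CpG.
#'
#' @param m_wt,m_ttko Day-0 (steady-state) methylation fractions.
#' @param k_de_ttko TTKO demethylation rates (time-course inferred).
#' @param cpg_id,chrom,pos Optional CpG annotations carried through.
#' @param clip Passed to [predict_kde_wt()].
#' @return data.frame with `m_wt`, `m_ttko`, `k_de_ttko`, `k_de_wt_hat`,
#'   `tet_activity` (plus annotations when given).
#' @export
tet_comparison <- function(m_wt, m_ttko, k_de_ttko,
                           cpg_id = NULL, chrom = NULL, pos = NULL,
                           clip = TRUE) {
  k_hat <- predict_kde_wt(m_wt, m_ttko, k_de_ttko, clip = clip)
  out <- data.frame(
    m_wt = m_wt, m_ttko = m_ttko, k_de_ttko = k_de_ttko,
    k_de_wt_hat = as.numeric(k_hat),
    tet_activity = tet_activity_log2(as.numeric(k_hat), k_de_ttko)
  )
  if (!is.null(cpg_id)) out <- cbind(cpg_id = cpg_id, out)
  if (!is.null(chrom)) out$chrom <- chrom
  if (!is.null(pos)) out$pos <- pos
  out
}
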