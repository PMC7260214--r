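#' Multiplicative rate grid
#'
#' Builds the brute-force parameter grid: `grid_steps` values per axis starting
#' at `grid_max` and descending by factor `grid_step_factor`
#' (`v_i = grid_max / factor^i`), crossed over the two axes. At the defaults
#' (max 2, factor 1.1, 80 steps) this spans about three orders of magnitude and
#' yields 6400 (k_de, k_me) combinations.
#'
#' @param config A [model_config()].
#' @return A list of class `"param_grid"` with elements `values` (descending),
#'   `combos` (data.frame with columns `k_de`, `k_me`; `k_de` varies fastest),
#'   `k` (values per axis), `step_factor` and `grid_max`.
#' @examples
#' g <- build_grid(model_config())
#' nrow(g$combos) # 6400
#' @export
build_grid <- function(config = model_config()) {
  stopifnot(inherits(config, "meth_config"))
  k <- config$grid_steps
  values <- config$grid_max / config$grid_step_factor^(0:(k - 1L))
  combos <- data.frame(
    k_de = rep(values, times = k),
    k_me = rep(values, each = k)
  )
  structure(
    list(values = values, combos = combos, k = k,
         step_factor = config$grid_step_factor, grid_max = config$grid_max),
    class = "param_grid"
  )
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf("rate grid: %d values/axis in [%.4g, %g] (factor %g), %d combos\n",
              x$k, min(x$values), x$grid_max, x$step_factor, nrow(x$combos)))
  invisible(x)
}

#' Coverage / missingness filtering of count tables
#'
#' Applies the assay-specific quality rules before inference.
#'
#' For `assay = "amplicon"`: any call with coverage below `min_coverage`
#' (default 100) is set to NA; a replicate series is dropped when its day-0
#' call is NA/absent or when it has more than one NA across the time course.
#' With `joint = TRUE` the whole CpG (within a condition) is dropped as soon as
#' any of its replicate series fails.
#'
#' For `assay = "sureselect"`: a CpG (within a condition) is dropped unless
#' coverage reaches `min_coverage` (default 50) at every timepoint in every
#' replicate.
#'
#' @param counts Count table (see [read_counts()] for the schema).
#' @param assay `"amplicon"` or `"sureselect"`.
#' @param timepoints Expected days; defaults to the days present in `counts`.
#'   Missing rows count as NA calls.
#' @param min_coverage Override of the assay default threshold.
#' @param joint Amplicon only: drop whole CpGs instead of single replicate
#'   series (default `FALSE`).
#' @return Filtered count table; attrition counts are attached as attribute
#'   `"attrition"` and reported via `message()`.
#' @export
filter_counts <- function(counts, assay = c("amplicon", "sureselect"),
                          timepoints = NULL, min_coverage = NULL,
                          joint = FALSE) {
  assay <- match.arg(assay)
  counts <- .validate_counts(counts)
  if (is.null(timepoints)) timepoints <- sort(unique(counts$day))
  if (!0 %in% timepoints) stop("timepoints must include day 0")
  n_cpg_in <- length(unique(counts$cpg_id))
  n_series_in <- nrow(unique(counts[, c("cpg_id", "condition", "replicate")]))

  if (assay == "amplicon") {
    if (is.null(min_coverage)) min_coverage <- 100L
    low <- !is.na(counts$coverage) & counts$coverage < min_coverage
    counts$coverage[low] <- NA_integer_
    counts$meth_count[low] <- NA_integer_
    key <- paste(counts$cpg_id, counts$condition, counts$replicate, sep = "\r")
    ok <- vapply(split(counts, key), function(sub) {
      n_na <- sum(is.na(sub$coverage)) + sum(!timepoints %in% sub$day)
      day0 <- sub$coverage[sub$day == 0]
      day0_ok <- length(day0) == 1L && !is.na(day0)
      day0_ok && n_na <= 1L
    }, logical(1))
    if (joint) {
      cpg_cond <- paste(counts$cpg_id, counts$condition, sep = "\r")
      bad <- unique(cpg_cond[!ok[key]])
      keep <- !(cpg_cond %in% bad)
    } else {
      keep <- ok[key]
    }
    out <- counts[keep, , drop = FALSE]
  } else {
    if (is.null(min_coverage)) min_coverage <- 50L
    key <- paste(counts$cpg_id, counts$condition, sep = "\r")
    ok <- vapply(split(counts, key), function(sub) {
      complete <- nrow(sub) ==
        length(timepoints) * length(unique(sub$replicate))
      complete && !anyNA(sub$coverage) && all(sub$coverage >= min_coverage)
    }, logical(1))
    out <- counts[ok[key], , drop = FALSE]
  }
  rownames(out) <- NULL

  attrition <- c(
    cpgs_in = n_cpg_in,
    cpgs_out = length(unique(out$cpg_id)),
    series_in = n_series_in,
    series_out = if (nrow(out)) {
      nrow(unique(out[, c("cpg_id", "condition", "replicate")]))
    } else 0L
  )
  message(sprintf(
    "filter_counts[%s, min %sx]: CpGs %d -> %d; replicate series %d -> %d",
    assay, min_coverage, attrition[["cpgs_in"]], attrition[["cpgs_out"]],
    attrition[["series_in"]], attrition[["series_out"]]
  ))
  attr(out, "attrition") <- attrition
  out
}

#' Posterior over the rate grid for one replicate time course
#'
#' Computes `p(data | k_de, k_me)` for every grid combination by multiplying
#' the per-timepoint (beta-)binomial probabilities of the observed counts given
#' the expected trace of that combination, then renormalizes to a posterior
#' under a uniform prior.
#'
#' @param series A data.frame with columns `day`, `coverage`, `meth_count` for
#'   one CpG and one replicate. NA coverage/count rows are skipped; at least
#'   two informative timepoints are required.
#' @param bank Trace bank from [build_trace_bank()] (rows aligned with
#'   `grid$combos`).
#' @param error An [error_model()].
#' @return A list of class `"posterior_grid"`: `joint` (vector over combos,
#'   sums to 1), `marginal_de`, `marginal_me` (each over `grid$values`), `mle`
#'   (list with `k_de`, `k_me`, `index`), and `grid`.
#' @export
fit_replicate <- function(series, bank, error = error_model()) {
  stopifnot(is.data.frame(series),
            all(c("day", "coverage", "meth_count") %in% names(series)),
            inherits(error, "error_model"))
  grid <- attr(bank, "grid")
  times <- attr(bank, "times")
  if (is.null(grid) || is.null(times)) {
    stop("`bank` must be built by build_trace_bank()")
  }
  series <- series[!is.na(series$coverage) & !is.na(series$meth_count), ,
                   drop = FALSE]
  idx_t <- match(series$day, times)
  if (anyNA(idx_t)) stop("series contains days absent from the trace bank")
  if (nrow(series) < 2L) {
    stop("unfittable series: fewer than 2 informative timepoints")
  }
  ll <- .bb_loglik_grid(as.integer(series$meth_count),
                        as.integer(series$coverage),
                        bank[, idx_t, drop = FALSE],
                        if (error$kind == "binomial") -1 else error$gamma)
  ll_max <- max(ll)
  w <- exp(ll - ll_max)
  joint <- w / sum(w)

  top <- which(ll == ll_max)
  if (length(top) > 1L) {
    tot <- grid$combos$k_de[top] + grid$combos$k_me[top]
    top <- top[which.min(tot)]
    message("fit_replicate: posterior tie broken toward lower total turnover")
  }
  k <- grid$k
  jm <- matrix(joint, k, k) # rows: k_de index, cols: k_me index
  structure(
    list(
      joint = joint,
      marginal_de = rowSums(jm),
      marginal_me = colSums(jm),
      mle = list(k_de = grid$combos$k_de[top], k_me = grid$combos$k_me[top],
                 index = top),
      grid = grid,
      loglik_max = ll_max
    ),
    class = "posterior_grid"
  )
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf("grid posterior: MLE k_de = %.4g, k_me = %.4g (combo %d of %d)\n",
              x$mle$k_de, x$mle$k_me, x$mle$index, length(x$joint)))
  invisible(x)
}

#' Central credible interval on a grid marginal
#'
#' Trims mass `(1 - level) / 2` from each tail of the ordered marginal: grid
#' points are removed from either end while the cumulative removed mass stays
#' within the tail allowance, and the remaining contiguous range is the
#' interval.
#'
#' @param marginal Marginal probabilities over the grid values (sums to 1).
#' @param values Grid rate values the marginal is indexed by (descending);
#'   needed to express the width in log10 rate units.
#' @param level Credible mass, in (0, 1). Default 0.95.
#' @return List with `lo`, `hi` (index range into `values`), `width_log10`
#'   (`|log10(values[lo] / values[hi])|`) and `level`.
#' @export
credible_interval <- function(marginal, values, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  stopifnot(length(marginal) == length(values),
            abs(sum(marginal) - 1) < 1e-6)
  k <- length(marginal)
  tail_mass <- (1 - level) / 2
  csum_lo <- cumsum(marginal)
  csum_hi <- rev(cumsum(rev(marginal)))
  # largest prefix / suffix whose mass stays within the tail allowance
  n_lo <- sum(csum_lo <= tail_mass + 1e-12)
  n_hi <- sum(csum_hi <= tail_mass + 1e-12)
  lo <- min(n_lo + 1L, k)
  hi <- max(k - n_hi, lo)
  list(lo = lo, hi = hi,
       width_log10 = abs(log10(values[lo]) - log10(values[hi])),
       level = level)
}

#' Border-mass identifiability rule
#'
#' A fit is identifiable when both marginal posteriors place less than
#' `threshold` probability on the extreme grid value at each end of the
#' parameter space; substantial border mass indicates the optimum lies outside
#' the grid.
#'
#' @param posterior A [fit_replicate()] posterior.
#' @param threshold Border-mass cutoff (0.08 for data fits, 0.05 for the
#'   landscape).
#' @return Logical flag; the maximum border mass is attached as attribute
#'   `"border_mass"`.
#' @export
is_identifiable <- function(posterior, threshold = 0.08) {
  stopifnot(inherits(posterior, "posterior_grid"),
            threshold > 0, threshold < 1)
  k <- length(posterior$marginal_de)
  borders <- c(posterior$marginal_de[c(1L, k)], posterior$marginal_me[c(1L, k)])
  out <- all(borders < threshold)
  attr(out, "border_mass") <- max(borders)
  out
}

#' Combine per-replicate estimates
#'
#' Rates are combined as per-axis medians of the replicate MLEs; credible
#' interval widths as the standard error `sqrt(sum(ci_i^2)) / r` (the printed
#' 3-replicate form generalized to `r`); the identifiability flag is the AND
#' over replicates.
#'
#' @param estimates data.frame with one row per replicate and columns `k_de`,
#'   `k_me`, `ci_de`, `ci_me`, `identifiable`.
#' @return A list of class `"rate_estimate"` with `k_de_hat`, `k_me_hat`,
#'   `ci_de`, `ci_me`, `identifiable`, `n_replicates`.
#' @export
combine_replicates <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("k_de", "k_me", "ci_de", "ci_me", "identifiable") %in%
                  names(estimates)))
  r <- nrow(estimates)
  if (r < 1L) stop("combine_replicates requires at least one replicate")
  structure(
    list(
      k_de_hat = stats::median(estimates$k_de),
      k_me_hat = stats::median(estimates$k_me),
      ci_de = sqrt(sum(estimates$ci_de^2)) / r,
      ci_me = sqrt(sum(estimates$ci_me^2)) / r,
      identifiable = all(estimates$identifiable),
      n_replicates = r
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "rate estimate (%d replicates): k_de = %.4g (ci %.3g), k_me = %.4g (ci %.3g), %s\n",
    x$n_replicates, x$k_de_hat, x$ci_de, x$k_me_hat, x$ci_me,
    if (x$identifiable) "identifiable" else "NOT identifiable"
  ))
  invisible(x)
}

#' Fit methylation/demethylation rates for every CpG in a count table
#'
#' Runs the full brute-force Bayesian pipeline: builds (or reuses) the grid and
#' trace bank, fits each replicate of each CpG/condition separately, extracts
#' MLE rates and 95% marginal credible intervals, applies the border
#' identifiability rule per replicate, and combines replicates.
#'
#' @param counts Count table (schema of [read_counts()]); apply
#'   [filter_counts()] beforehand.
#' @param config A [model_config()].
#' @param error An [error_model()].
#' @param bank Optional precomputed [build_trace_bank()] result.
#' @param border_threshold Identifiability cutoff; defaults to
#'   `config$border_threshold_fit`.
#' @return data.frame with one row per (CpG, condition): `cpg_id`, `chrom`,
#'   `pos`, `condition`, `k_me`, `k_de`, `ci_me_log10`, `ci_de_log10`,
#'   `steady_state`, `identifiable`, `n_replicates`.
#' @export
fit_rates <- function(counts, config = model_config(),
                      error = error_model(), bank = NULL,
                      border_threshold = config$border_threshold_fit) {
  counts <- .validate_counts(counts)
  if (is.null(bank)) {
    bank <- build_trace_bank(build_grid(config), config)
  }
  grid <- attr(bank, "grid")
  key <- paste(counts$cpg_id, counts$condition, sep = "\r")
  groups <- split(seq_len(nrow(counts)), key)

  rows <- lapply(groups, function(idx) {
    sub <- counts[idx, , drop = FALSE]
    per_rep <- lapply(split(sub, sub$replicate), function(ser) {
      fit <- tryCatch(fit_replicate(ser, bank, error), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      ci_de <- credible_interval(fit$marginal_de, grid$values, config$ci_level)
      ci_me <- credible_interval(fit$marginal_me, grid$values, config$ci_level)
      data.frame(
        k_de = fit$mle$k_de, k_me = fit$mle$k_me,
        ci_de = ci_de$width_log10, ci_me = ci_me$width_log10,
        identifiable = as.logical(is_identifiable(fit, border_threshold))
      )
    })
    per_rep <- do.call(rbind, per_rep)
    if (is.null(per_rep) || nrow(per_rep) == 0L) return(NULL)
    est <- combine_replicates(per_rep)
    data.frame(
      cpg_id = sub$cpg_id[1L], chrom = sub$chrom[1L], pos = sub$pos[1L],
      condition = sub$condition[1L],
      k_me = est$k_me_hat, k_de = est$k_de_hat,
      ci_me_log10 = est$ci_me, ci_de_log10 = est$ci_de,
      steady_state = steady_state(est$k_me_hat, est$k_de_hat),
      identifiable = est$identifiable,
      n_replicates = est$n_replicates,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
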