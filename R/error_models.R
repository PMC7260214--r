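#' Observation (error) model specification
#'
#' Links an expected methylation fraction `p` and a read coverage `n` to the
#' distribution of the methylated-read count `c`. The binomial model is
#' appropriate for moderate coverage (capture bisulfite, >= 50x); the
#' reparameterized beta-binomial adds an over-dispersion parameter `gamma`
#' capturing the replicate-to-replicate biological noise that dominates at
#' amplicon depth (~4000x).
#'
#' @param kind `"betabinomial"` or `"binomial"`.
#' @param gamma Over-dispersion in `[0, 1)`; `gamma = 0` reduces the
#'   beta-binomial to the binomial. Default 0.0055 (amplicon fit).
#' @return A list of class `"error_model"`.
#' @examples
#' error_model("binomial")
#' error_model("betabinomial", gamma = 0.0055)
#' @export
error_model <- function(kind = c("betabinomial", "binomial"), gamma = 0.0055) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma < 1)
  if (kind == "binomial") gamma <- 0
  structure(list(kind = kind, gamma = gamma), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("error model: %s%s\n", x$kind,
              if (x$kind == "betabinomial") sprintf(" (gamma = %g)", x$gamma)
              else ""))
  invisible(x)
}

.clip_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Binomial log-likelihood of methylated-read counts
#'
#' @param c Methylated read count(s), `0 <= c <= n`.
#' @param n Read coverage(s).
#' @param p Expected methylation fraction(s) in `[0, 1]`.
#' @return Log of the binomial pmf; `-Inf` where `p` is degenerate and
#'   incompatible with `c`.
#' @examples
#' loglik_binomial(1, 2, 0.5) # log(0.5)
#' @export
loglik_binomial <- function(c, n, p) {
  stopifnot(all(c >= 0), all(c <= n), all(p >= 0), all(p <= 1))
  stats::dbinom(c, n, p, log = TRUE)
}

#' Beta-binomial log-likelihood of methylated-read counts
#'
#' Uses the mean/dispersion reparameterization `alpha = p * (1/gamma - 1)`,
#' `beta = (1 - p) * (1/gamma - 1)`, under which the count variance is
#' `n * p * (1 - p) * (1 + (n - 1) * gamma)`.
#'
#' @inheritParams loglik_binomial
#' @param gamma Over-dispersion in `[0, 1)`; `gamma = 0` falls back to the
#'   binomial model. Degenerate `p` in `{0, 1}` gives a point mass at `c = 0`
#'   or `c = n`.
#' @return Log pmf values.
#' @examples
#' loglik_betabinomial(50, 100, 0.5, gamma = 0.0055)
#' @export
loglik_betabinomial <- function(c, n, p, gamma) {
  stopifnot(gamma >= 0, gamma < 1, all(c >= 0), all(c <= n),
            all(p >= 0), all(p <= 1))
  if (gamma == 0) {
    return(loglik_binomial(c, n, p))
  }
  len <- max(length(c), length(n), length(p))
  out <- numeric(len)
  c <- rep_len(c, len); n <- rep_len(n, len); p <- rep_len(p, len)
  deg0 <- p == 0
  deg1 <- p == 1
  out[deg0] <- ifelse(c[deg0] == 0, 0, -Inf)
  out[deg1] <- ifelse(c[deg1] == n[deg1], 0, -Inf)
  i <- !(deg0 | deg1)
  if (any(i)) {
    s <- 1 / gamma - 1
    a <- .clip_p(p[i]) * s
    b <- (1 - .clip_p(p[i])) * s
    out[i] <- lchoose(n[i], c[i]) + lbeta(c[i] + a, n[i] - c[i] + b) -
      lbeta(a, b)
  }
  out
}

#' Predicted standard deviation of the methylation fraction
#'
#' Standard deviation of `c/n` under the (beta-)binomial model:
#' `sqrt(p * (1 - p) * (1 + (n - 1) * gamma) / n)`. `gamma = 0` gives the
#' plain binomial error; at high coverage the floor `sqrt(p * (1 - p) * gamma)`
#' from biological over-dispersion dominates.
#'
#' @param n Read coverage(s), >= 1.
#' @param p Expected methylation fraction(s).
#' @param gamma Over-dispersion (default 0).
#' @return Standard deviation(s) of the observed methylation fraction.
#' @examples
#' predicted_sd(4000, 0.5, gamma = 0.0055)
#' @export
predicted_sd <- function(n, p, gamma = 0) {
  stopifnot(all(n >= 1), all(p >= 0), all(p <= 1), gamma >= 0, gamma < 1)
  sqrt(p * (1 - p) * (1 + (n - 1) * gamma) / n)
}

#' Sample beta-binomial counts
#'
#' Two-stage construction: per observation a success probability is drawn from
#' `Beta(p * s, (1 - p) * s)` with `s = 1/gamma - 1`, then the count from a
#' binomial. With `gamma = 0` the sampler is exactly `rbinom`.
#'
#' @param nobs Number of observations.
#' @param size Coverage(s).
#' @param p Expected fraction(s).
#' @param gamma Over-dispersion.
#' @return Integer vector of counts.
#' @export
rbetabinom <- function(nobs, size, p, gamma = 0) {
  stopifnot(gamma >= 0, gamma < 1)
  if (gamma == 0) {
    return(stats::rbinom(nobs, size, p))
  }
  s <- 1 / gamma - 1
  pc <- .clip_p(rep_len(p, nobs))
  pr <- stats::rbeta(nobs, pc * s, (1 - pc) * s)
  stats::rbinom(nobs, size, pr)
}

#' Default over-dispersion sweep grid
#'
#' `gamma = 0` plus 100 logarithmically spaced values from 1e-5 to 0.1.
#' @return Numeric vector of candidate `gamma` values.
#' @export
gamma_sweep_default <- function() {
  c(0, 10^seq(log10(1e-5), log10(0.1), length.out = 100))
}

#' Fit the beta-binomial over-dispersion from day-0 replicates
#'
#' Estimates `gamma` by a parameter sweep: replicate day-0 measurements are
#' stratified by coverage and by mean methylation level, the pooled empirical
#' standard deviation of the methylation fraction is computed per stratum, and
#' the `gamma` minimizing the sum of squared errors between empirical and
#' [predicted_sd()] values is returned.
#'
#' @param day0 A data.frame with columns `cpg_id`, `replicate`, `coverage`,
#'   `meth_count` (rows restricted to day 0; a `day` column, if present, is
#'   filtered to `day == 0`).
#' @param sweep Candidate `gamma` values ([gamma_sweep_default()]); `NULL`
#'   disables the sweep and returns the amplicon default 0.0055.
#' @param coverage_bins,level_bins Number of quantile strata per dimension
#'   (default 10 each).
#' @return The fitted `gamma` (length-1 numeric) with the sweep SSE table in
#'   attribute `"sweep"` and the strata in attribute `"strata"`.
#' @export
fit_gamma <- function(day0, sweep = gamma_sweep_default(),
                      coverage_bins = 10L, level_bins = 10L) {
  if (is.null(sweep)) {
    return(0.0055)
  }
  stopifnot(is.data.frame(day0),
            all(c("cpg_id", "replicate", "coverage", "meth_count") %in%
                  names(day0)))
  if ("day" %in% names(day0)) day0 <- day0[day0$day == 0, , drop = FALSE]
  day0 <- day0[!is.na(day0$coverage) & day0$coverage > 0, , drop = FALSE]
  day0$level <- day0$meth_count / day0$coverage

  per_cpg <- stats::aggregate(
    cbind(level, coverage) ~ cpg_id, data = day0,
    FUN = mean
  )
  reps <- stats::aggregate(level ~ cpg_id, data = day0, FUN = length)
  vars <- stats::aggregate(level ~ cpg_id, data = day0, FUN = stats::var)
  per_cpg$n_rep <- reps$level[match(per_cpg$cpg_id, reps$cpg_id)]
  per_cpg$var <- vars$level[match(per_cpg$cpg_id, vars$cpg_id)]
  per_cpg <- per_cpg[per_cpg$n_rep >= 2L, , drop = FALSE]
  if (nrow(per_cpg) == 0L) {
    stop("fit_gamma requires at least 2 replicates at day 0")
  }

  qcut <- function(x, k) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1)))
    if (length(br) < 2L) return(factor(rep(1L, length(x))))
    cut(x, breaks = br, include.lowest = TRUE)
  }
  strata <- interaction(qcut(per_cpg$coverage, coverage_bins),
                        qcut(per_cpg$level, level_bins), drop = TRUE)
  grp <- split(per_cpg, strata)
  empty <- vapply(grp, nrow, 1L) == 0L
  if (any(empty)) {
    warning(sprintf("%d empty strata skipped", sum(empty)))
    grp <- grp[!empty]
  }
  stats_tab <- do.call(rbind, lapply(grp, function(g) {
    data.frame(n_bar = mean(g$coverage), p_bar = mean(g$level),
               sd_emp = sqrt(mean(g$var)), n_cpgs = nrow(g))
  }))

  sse <- vapply(sweep, function(g) {
    sum((stats_tab$sd_emp -
           predicted_sd(stats_tab$n_bar, stats_tab$p_bar, g))^2)
  }, numeric(1))
  gamma_hat <- sweep[which.min(sse)]
  attr(gamma_hat, "sweep") <- data.frame(gamma = sweep, sse = sse)
  attr(gamma_hat, "strata") <- stats_tab
  gamma_hat
}
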