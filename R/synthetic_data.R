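#' Specification of a synthetic study cohort
#'
#' Describes a fully synthetic bisulfite time-course dataset with the
#' statistical structure the inference pipeline assumes: per-CpG true rate
#' pairs, dampened decay traces with residual-allele mixing and conversion
#' error, and (beta-)binomial count sampling at configurable coverage.
#'
#' @param n_cpgs Number of CpGs.
#' @param rate_sampling `"loguniform"` (both rates log-uniform over the grid
#'   range), `"two-arm"` (a mixture placing steady states above 70% and below
#'   50%, mimicking the bimodal methylome), or `"fixed"` (use `k_me` / `k_de`).
#' @param k_me,k_de Fixed rate vectors (recycled to `n_cpgs`) for
#'   `rate_sampling = "fixed"`.
#' @param rate_range Rate range for the random regimes; defaults to the default
#'   grid span `c(2 / 1.1^79, 2)`.
#' @param coverage_mean Mean read coverage. Default 4000 (amplicon-like); use
#'   ~80 for capture-like data.
#' @param coverage_dispersion Negative-binomial `size`; `Inf` gives fixed
#'   coverage. Default 10.
#' @param replicates Biological replicates per condition. Default 3.
#' @param conditions Subset of `c("cre", "mock")`. `"cre"` follows the dampened
#'   decay; `"mock"` stays at the (conversion-corrected) steady state.
#' @param tet_multiplier Ratio `k_de_wt / k_de_ttko` used by
#'   [simulate_paired_conditions()]; scalar or per-CpG vector.
#' @param mock_drift Optional multiplicative drift per timepoint (applied to
#'   expected levels of ALL conditions, emulating a transduction-protocol
#'   artifact; length must match the configured timepoints).
#' @param seed Integer seed; fully determines the generated data.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_cpgs,
                        rate_sampling = c("loguniform", "two-arm", "fixed"),
                        k_me = NULL, k_de = NULL,
                        rate_range = c(2 / 1.1^79, 2),
                        coverage_mean = 4000,
                        coverage_dispersion = 10,
                        replicates = 3L,
                        conditions = "cre",
                        tet_multiplier = 3,
                        mock_drift = NULL,
                        seed = 1L) {
  rate_sampling <- match.arg(rate_sampling)
  stopifnot(n_cpgs >= 1, coverage_mean >= 1, replicates >= 1,
            all(conditions %in% c("cre", "mock")),
            rate_range[1] > 0, rate_range[2] > rate_range[1])
  if (rate_sampling == "fixed" && (is.null(k_me) || is.null(k_de))) {
    stop("fixed rate sampling requires k_me and k_de")
  }
  structure(
    list(n_cpgs = as.integer(n_cpgs), rate_sampling = rate_sampling,
         k_me = k_me, k_de = k_de, rate_range = rate_range,
         coverage_mean = coverage_mean,
         coverage_dispersion = coverage_dispersion,
         replicates = as.integer(replicates), conditions = conditions,
         tet_multiplier = tet_multiplier, mock_drift = mock_drift,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Draw true rate pairs for a synthetic cohort
#'
#' Draws are made CpG by CpG from a single RNG stream seeded with `spec$seed`,
#' so enlarging `n_cpgs` preserves the prefix of generated CpGs.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with columns `cpg_id`, `k_me`, `k_de`, `m_eq`.
#' @export
sample_true_rates <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_cpgs
  lo <- log(spec$rate_range[1]); hi <- log(spec$rate_range[2])
  k_me <- k_de <- numeric(n)
  for (i in seq_len(n)) {
    if (spec$rate_sampling == "loguniform") {
      k_me[i] <- exp(stats::runif(1, lo, hi))
      k_de[i] <- exp(stats::runif(1, lo, hi))
    } else if (spec$rate_sampling == "two-arm") {
      upper <- stats::runif(1) < 0.5
      m_eq <- if (upper) stats::runif(1, 0.70, 0.97) else
        stats::runif(1, 0.03, 0.50)
      k_tot <- exp(stats::runif(1, log(max(spec$rate_range[1] * 4, 1e-3)),
                                log(spec$rate_range[2] / 2)))
      k_me[i] <- min(max(m_eq * k_tot, spec$rate_range[1]),
                     spec$rate_range[2])
      k_de[i] <- min(max((1 - m_eq) * k_tot, spec$rate_range[1]),
                     spec$rate_range[2])
    } else {
      k_me[i] <- rep_len(spec$k_me, n)[i]
      k_de[i] <- rep_len(spec$k_de, n)[i]
    }
  }
  data.frame(
    cpg_id = sprintf("cpg_%05d", seq_len(n)),
    k_me = k_me, k_de = k_de,
    m_eq = k_me / (k_me + k_de)
  )
}

.draw_coverage <- function(n, mean, dispersion) {
  if (!is.finite(dispersion)) {
    return(rep(as.integer(round(mean)), n))
  }
  pmax(stats::rnbinom(n, mu = mean, size = dispersion), 1L)
}

#' Simulate a count table from true rates
#'
#' For every CpG, condition, replicate and timepoint: the expected methylation
#' fraction comes from the forward model ([expected_trace()] for `"cre"`; the
#' conversion-corrected steady state, constant in time, for `"mock"`), an
#' optional per-timepoint drift is applied, coverage is drawn from the coverage
#' model, and the methylated count is sampled from the error model. Sampling is
#' CpG-major from one stream seeded with `spec$seed + 1`, so the generated
#' prefix is stable under changes of `n_cpgs`.
#'
#' @param true_rates Output of [sample_true_rates()] (columns `cpg_id`, `k_me`,
#'   `k_de`; extra columns ignored).
#' @param spec A [cohort_spec()].
#' @param config A [model_config()].
#' @param error An [error_model()] giving the count sampling law.
#' @return Count table in the [read_counts()] schema with one row per
#'   CpG x condition x replicate x timepoint, plus a `true_level` column.
#' @export
simulate_counts <- function(true_rates, spec, config = model_config(),
                            error = error_model()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "meth_config"),
            inherits(error, "error_model"),
            all(c("cpg_id", "k_me", "k_de") %in% names(true_rates)))
  times <- config$timepoints
  drift <- spec$mock_drift
  if (!is.null(drift) && length(drift) != length(times)) {
    stop("mock_drift must have one factor per configured timepoint")
  }
  n <- nrow(true_rates)
  nt <- length(times)

  # expected levels per CpG x time, per condition
  lv_cre <- lv_mock <- NULL
  if ("cre" %in% spec$conditions) {
    m0 <- true_rates$k_me / (true_rates$k_me + true_rates$k_de)
    sol <- .solve_damped_ode(true_rates$k_me, true_rates$k_de, config$k_E,
                             m0, times,
                             rtol = config$ode_rel_tol,
                             atol = config$ode_abs_tol)
    lv <- t(pmin(pmax(sol, 0), 1))
    lv <- (1 - config$excision_residual) * lv + config$excision_residual * m0
    lv_cre <- (1 - 2 * config$conversion_error) * lv + config$conversion_error
  }
  if ("mock" %in% spec$conditions) {
    m0 <- true_rates$k_me / (true_rates$k_me + true_rates$k_de)
    lv_mock <- matrix((1 - 2 * config$conversion_error) * m0 +
                        config$conversion_error, n, nt)
  }
  apply_drift <- function(m) {
    if (is.null(drift)) return(m)
    pmin(pmax(sweep(m, 2, drift, `*`), 0), 1)
  }
  lv_cre <- if (!is.null(lv_cre)) apply_drift(lv_cre)
  lv_mock <- if (!is.null(lv_mock)) apply_drift(lv_mock)

  set.seed(spec$seed + 1L)
  rows_per_cpg <- length(spec$conditions) * spec$replicates * nt
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cond <- rep(spec$conditions, each = spec$replicates * nt)
    repl <- rep(rep(seq_len(spec$replicates), each = nt),
                times = length(spec$conditions))
    day <- rep(times, times = length(spec$conditions) * spec$replicates)
    p <- unlist(lapply(spec$conditions, function(cd) {
      m <- if (cd == "cre") lv_cre else lv_mock
      rep(m[i, ], times = spec$replicates)
    }), use.names = FALSE)
    cov <- .draw_coverage(rows_per_cpg, spec$coverage_mean,
                          spec$coverage_dispersion)
    cnt <- rbetabinom(rows_per_cpg, cov, p, error$gamma)
    out[[i]] <- data.frame(
      cpg_id = true_rates$cpg_id[i],
      chrom = "chrS1",
      pos = 1000L + 100L * i,
      condition = cond, replicate = repl, day = day,
      coverage = cov, meth_count = cnt, true_level = p,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate paired wild-type / TTKO cohorts
#'
#' Draws a shared de novo rate `k_me` and a TTKO demethylation rate per CpG,
#' sets `k_de_wt = tet_multiplier * k_de_ttko`, and simulates both decay time
#' courses (each starting at its own steady state). The truth table carries all
#' generating values for recovery tests.
#'
#' @param spec A [cohort_spec()]; `tet_multiplier` must be positive.
#' @param config A [model_config()].
#' @param error An [error_model()].
#' @return List with `wt` and `ttko` count tables (condition columns set to
#'   `"wt"` / `"ttko"`) and `truth` (per-CpG `k_me`, `k_de_ttko`, `k_de_wt`,
#'   `m_ttko`, `m_wt`, `tet_multiplier`).
#' @export
simulate_paired_conditions <- function(spec, config = model_config(),
                                       error = error_model()) {
  stopifnot(inherits(spec, "cohort_spec"))
  mult <- rep_len(spec$tet_multiplier, spec$n_cpgs)
  if (any(mult <= 0)) stop("tet_multiplier must be positive")
  rates <- sample_true_rates(spec)
  truth <- data.frame(
    cpg_id = rates$cpg_id,
    k_me = rates$k_me,
    k_de_ttko = rates$k_de,
    k_de_wt = rates$k_de * mult,
    tet_multiplier = mult
  )
  truth$m_ttko <- truth$k_me / (truth$k_me + truth$k_de_ttko)
  truth$m_wt <- truth$k_me / (truth$k_me + truth$k_de_wt)

  spec_one <- spec
  spec_one$conditions <- "cre"
  ttko <- simulate_counts(
    data.frame(cpg_id = truth$cpg_id, k_me = truth$k_me,
               k_de = truth$k_de_ttko),
    spec_one, config, error
  )
  ttko$condition <- "ttko"
  spec_wt <- spec_one
  spec_wt$seed <- spec$seed + 104729L # distinct stream for the WT draws
  wt <- simulate_counts(
    data.frame(cpg_id = truth$cpg_id, k_me = truth$k_me,
               k_de = truth$k_de_wt),
    spec_wt, config, error
  )
  wt$condition <- "wt"
  list(wt = wt, ttko = ttko, truth = truth)
}
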