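#' Global model configuration
#'
#' Bundles the forward-model constants shared by trace simulation, inference
#' and the identifiability landscape.
#'
#' @param excision_residual Fraction of functional alleles escaping Cre
#'   excision; this fraction of the day-0 methylation level is mixed back into
#'   every simulated timepoint. Default 0.08 (genotyping estimate of residual
#'   alleles).
#' @param conversion_error Per-direction bisulfite conversion / sequencing
#'   error epsilon; levels are transformed as `y = (1 - 2*eps) * x + eps`.
#'   Default 0.0025 (99.75% conversion efficiency).
#' @param timepoints Days sampled in the time course. Must be strictly
#'   increasing and start at 0. Default `c(0, 4, 8, 10, 13, 17, 29)`.
#' @param k_E Exponential dampening rate (per day) applied to the de novo
#'   methylation rate after induced DNMT3 deletion. Default 0.5, roughly half
#'   the theoretical maximum loss rate `log(2)/(16/24)` for a 16-h doubling
#'   time.
#' @param grid_max Largest rate value (per day) on each grid axis. Default 2.
#' @param grid_steps Number of rate values per axis. Default 80.
#' @param grid_step_factor Multiplicative spacing between consecutive grid
#'   values. Default 1.1 (10% steps), so the default grid spans about three
#'   orders of magnitude.
#' @param ci_level Credible mass for marginal credible intervals. Default 0.95.
#' @param border_threshold_fit Maximum marginal posterior mass allowed at any
#'   grid border for a data fit to be called identifiable. Default 0.08.
#' @param border_threshold_landscape Border-mass cutoff used when computing the
#'   identifiability landscape. Default 0.05.
#' @param ode_rel_tol,ode_abs_tol Relative/absolute tolerances of the adaptive
#'   ODE integrator. Default 1e-8.
#'
#' @return A list of class `"meth_config"`.
#' @examples
#' cfg <- model_config()
#' cfg$timepoints
#' @export
model_config <- function(excision_residual = 0.08,
                         conversion_error = 0.0025,
                         timepoints = c(0, 4, 8, 10, 13, 17, 29),
                         k_E = 0.5,
                         grid_max = 2,
                         grid_steps = 80L,
                         grid_step_factor = 1.1,
                         ci_level = 0.95,
                         border_threshold_fit = 0.08,
                         border_threshold_landscape = 0.05,
                         ode_rel_tol = 1e-8,
                         ode_abs_tol = 1e-8) {
  stopifnot(
    is.numeric(excision_residual), length(excision_residual) == 1L,
    excision_residual >= 0, excision_residual < 1,
    is.numeric(conversion_error), length(conversion_error) == 1L,
    conversion_error >= 0, conversion_error < 0.5,
    is.numeric(timepoints), length(timepoints) >= 2L,
    is.numeric(k_E), length(k_E) == 1L, k_E >= 0,
    is.numeric(grid_max), grid_max > 0,
    grid_steps >= 2L,
    grid_step_factor > 1,
    ci_level > 0, ci_level < 1,
    border_threshold_fit > 0, border_threshold_fit < 1,
    border_threshold_landscape > 0, border_threshold_landscape < 1,
    ode_rel_tol > 0, ode_abs_tol > 0
  )
  if (timepoints[1L] != 0 || is.unsorted(timepoints, strictly = TRUE)) {
    stop("`timepoints` must be strictly increasing and start at day 0")
  }
  structure(
    list(
      excision_residual = excision_residual,
      conversion_error = conversion_error,
      timepoints = as.numeric(timepoints),
      k_E = k_E,
      grid_max = grid_max,
      grid_steps = as.integer(grid_steps),
      grid_step_factor = grid_step_factor,
      ci_level = ci_level,
      border_threshold_fit = border_threshold_fit,
      border_threshold_landscape = border_threshold_landscape,
      ode_rel_tol = ode_rel_tol,
      ode_abs_tol = ode_abs_tol
    ),
    class = "meth_config"
  )
}

#' @export
print.meth_config <- function(x, ...) {
  cat("methylation turnover model configuration\n")
  cat(sprintf("  timepoints (days): %s\n", paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  k_E = %g/day; excision residual = %g; conversion error = %g\n",
              x$k_E, x$excision_residual, x$conversion_error))
  cat(sprintf("  grid: %d values/axis, max %g, step factor %g\n",
              x$grid_steps, x$grid_max, x$grid_step_factor))
  cat(sprintf("  CI level %g; border thresholds: fit %g, landscape %g\n",
              x$ci_level, x$border_threshold_fit, x$border_threshold_landscape))
  invisible(x)
}

#' Kinetic parameters of a single CpG
#'
#' @param k_me De novo methylation rate (per day, >= 0).
#' @param k_de Demethylation rate (per day, >= 0). `k_me + k_de` must be
#'   positive so the steady state is defined.
#' @param k_E Dampening rate of DNMT3 loss (per day, >= 0). Default 0.5.
#'
#' @return A list of class `"rate_params"` carrying `k_me`, `k_de`, `k_E` and
#'   the steady-state methylation `m_eq = k_me / (k_me + k_de)`.
#' @examples
#' rate_params(0.5, 0.5)$m_eq
#' @export
rate_params <- function(k_me, k_de, k_E = 0.5) {
  stopifnot(
    is.numeric(k_me), length(k_me) == 1L, is.finite(k_me), k_me >= 0,
    is.numeric(k_de), length(k_de) == 1L, is.finite(k_de), k_de >= 0,
    is.numeric(k_E), length(k_E) == 1L, is.finite(k_E), k_E >= 0
  )
  if (k_me + k_de <= 0) {
    stop("degenerate rates: k_me + k_de must be > 0")
  }
  structure(
    list(k_me = k_me, k_de = k_de, k_E = k_E, m_eq = k_me / (k_me + k_de)),
    class = "rate_params"
  )
}

#' Steady-state methylation level
#'
#' Equilibrium of the two-rate model, `M_eq = k_me / (k_me + k_de)`: the level
#' at which methylation gain and loss balance. Vectorized over both rates.
#'
#' @param k_me De novo methylation rate(s), or a [rate_params()] object.
#' @param k_de Demethylation rate(s); ignored when `k_me` is a `rate_params`.
#'
#' @return Numeric vector of steady-state methylation fractions in `[0, 1]`.
#' @examples
#' steady_state(0.5, 0.5) # equal rates -> 50% methylation
#' steady_state(0.3, 0.1) # 0.75
#' @export
steady_state <- function(k_me, k_de = NULL) {
  if (inherits(k_me, "rate_params")) {
    return(k_me$m_eq)
  }
  stopifnot(is.numeric(k_me), is.numeric(k_de))
  if (any(k_me < 0) || any(k_de < 0)) stop("rates must be non-negative")
  tot <- k_me + k_de
  if (any(tot <= 0)) stop("degenerate rates: k_me + k_de must be > 0")
  k_me / tot
}
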