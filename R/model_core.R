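#' Construct a methylation trace
#'
#' @param times Days (numeric, non-negative).
#' @param levels Expected methylation fractions, same length as `times`, each
#'   in `[0, 1]`.
#' @return A list of class `"meth_trace"`.
#' @export
meth_trace <- function(times, levels) {
  stopifnot(is.numeric(times), is.numeric(levels),
            length(times) == length(levels))
  if (any(levels < -1e-9 | levels > 1 + 1e-9, na.rm = TRUE)) {
    stop("trace levels must lie in [0, 1]")
  }
  structure(list(times = as.numeric(times), levels = pmin(pmax(levels, 0), 1)),
            class = "meth_trace")
}

#' @export
print.meth_trace <- function(x, ...) {
  cat("methylation trace:\n")
  print(data.frame(day = x$times, level = signif(x$levels, 6)))
  invisible(x)
}

.trace_levels <- function(x) if (inherits(x, "meth_trace")) x$levels else x

.trace_like <- function(template, levels) {
  if (inherits(template, "meth_trace")) {
    meth_trace(template$times, levels)
  } else {
    levels
  }
}

#' Numerically solve the dampened two-rate methylation ODE
#'
#' Integrates `dm/dt = k_me * exp(-k_E * t) * (1 - m) - k_de * m` from day 0.
#' The exponential factor models the gradual loss of DNMT3 after induced
#' deletion; with `k_E = 0` the model reduces to the constant-rate two-state
#' system with closed-form solution [closed_form_trace()].
#'
#' @param params A [rate_params()] object.
#' @param times Days at which the solution is requested (non-negative; any
#'   order).
#' @param m0 Initial methylation fraction at day 0. Defaults to the undampened
#'   steady state `k_me / (k_me + k_de)`, i.e. the system is assumed to be at
#'   equilibrium when deletion is induced.
#' @param rtol,atol Solver tolerances.
#'
#' @return A [meth_trace()].
#' @examples
#' solve_trace(rate_params(0.2, 0.1), times = c(0, 4, 8))
#' @export
solve_trace <- function(params, times, m0 = NULL,
                        rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "rate_params"))
  if (is.null(m0)) m0 <- params$m_eq
  stopifnot(is.numeric(m0), length(m0) == 1L, m0 >= 0, m0 <= 1)
  lv <- .solve_damped_ode(params$k_me, params$k_de, params$k_E, m0, times,
                          rtol = rtol, atol = atol)
  meth_trace(times, as.numeric(lv))
}

#' Closed-form trace of the undampened two-rate model
#'
#' With constant rates (no DNMT3 dampening) the model has the exact solution
#' `m(t) = M_eq + (m0 - M_eq) * exp(-(k_me + k_de) * t)` with
#' `M_eq = k_me / (k_me + k_de)`. Used as the analytic oracle for the numeric
#' solver and to simulate mock (no-deletion) conditions.
#'
#' @param k_me,k_de Constant rates (per day, >= 0).
#' @param m0 Initial methylation fraction.
#' @param times Days.
#' @return A [meth_trace()]. When `k_me + k_de == 0` the trace is constant at
#'   `m0`.
#' @export
closed_form_trace <- function(k_me, k_de, m0, times) {
  stopifnot(k_me >= 0, k_de >= 0, m0 >= 0, m0 <= 1, all(times >= 0))
  tot <- k_me + k_de
  if (tot == 0) {
    return(meth_trace(times, rep(m0, length(times))))
  }
  m_eq <- k_me / tot
  meth_trace(times, m_eq + (m0 - m_eq) * exp(-tot * times))
}

#' Mix back the residual unexcised signal
#'
#' Cre excision of the Dnmt3 alleles is incomplete; a residual fraction of
#' cells keeps the day-0 dynamics. The observable trace is modelled as a
#' mixture: `y -> (1 - residual) * y + residual * day0_level`.
#'
#' @param trace A [meth_trace()] or numeric vector of levels.
#' @param day0_level Methylation level of the unexcised population (fraction).
#' @param residual Residual allele fraction in `[0, 1)`. Default 0.08.
#' @return Same type as `trace`.
#' @export
apply_excision_mix <- function(trace, day0_level, residual = 0.08) {
  stopifnot(residual >= 0, residual < 1)
  if (!is.numeric(day0_level) || any(day0_level < 0) || any(day0_level > 1)) {
    stop("day0_level must be a methylation fraction in [0, 1]")
  }
  y <- .trace_levels(trace)
  .trace_like(trace, (1 - residual) * y + residual * day0_level)
}

#' Inject bisulfite conversion and sequencing error
#'
#' Applies `y = (1 - 2 * epsilon) * x + epsilon`, i.e. a symmetric
#' per-direction miscall rate `epsilon`; 0.0025 corresponds to 99.75%
#' conversion efficiency.
#'
#' @param trace A [meth_trace()] or numeric vector of levels.
#' @param epsilon Per-direction error in `[0, 0.5)`.
#' @return Same type as `trace`, with all levels in `[epsilon, 1 - epsilon]`.
#' @export
apply_conversion_error <- function(trace, epsilon = 0.0025) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  x <- .trace_levels(trace)
  .trace_like(trace, (1 - 2 * epsilon) * x + epsilon)
}

#' Expected observable methylation trace
#'
#' Composes the forward model: numeric ODE solution (starting from the
#' undampened steady state), clamping to `[0, 1]` against solver round-off,
#' residual-allele mixing with the uncorrected day-0 steady state, then
#' conversion-error injection.
#'
#' @param params A [rate_params()] object (its `k_E` is used for dampening).
#' @param config A [model_config()].
#' @param times Days; defaults to `config$timepoints`.
#' @return A [meth_trace()] with values in
#'   `[conversion_error, 1 - conversion_error]`.
#' @examples
#' expected_trace(rate_params(0.5, 0.5), model_config())
#' @export
expected_trace <- function(params, config = model_config(),
                           times = config$timepoints) {
  stopifnot(inherits(params, "rate_params"), inherits(config, "meth_config"))
  tr <- solve_trace(params, times,
                    rtol = config$ode_rel_tol, atol = config$ode_abs_tol)
  lv <- pmin(pmax(tr$levels, 0), 1)
  lv <- apply_excision_mix(lv, day0_level = params$m_eq,
                           residual = config$excision_residual)
  lv <- apply_conversion_error(lv, epsilon = config$conversion_error)
  meth_trace(times, lv)
}

#' Bank of expected traces over the whole parameter grid
#'
#' Solves the dampened ODE for every (k_de, k_me) grid combination in a single
#' vectorized integration and applies the excision-mix and conversion-error
#' corrections row-wise. Row `i` corresponds to `grid$combos[i, ]`.
#'
#' @param grid A [build_grid()] parameter grid.
#' @param config A [model_config()]; supplies `k_E`, corrections, timepoints
#'   and solver tolerances.
#' @param times Days; defaults to `config$timepoints`.
#' @return A numeric matrix (`nrow(grid$combos)` x `length(times)`) with
#'   attributes `times`, `grid` and `config`.
#' @examples
#' g <- build_grid(model_config(grid_steps = 10))
#' dim(build_trace_bank(g, model_config(grid_steps = 10)))
#' @export
build_trace_bank <- function(grid, config = model_config(),
                             times = config$timepoints) {
  stopifnot(inherits(grid, "param_grid"), inherits(config, "meth_config"))
  k_me <- grid$combos$k_me
  k_de <- grid$combos$k_de
  m0 <- k_me / (k_me + k_de)
  sol <- .solve_damped_ode(k_me, k_de, config$k_E, m0, times,
                           rtol = config$ode_rel_tol, atol = config$ode_abs_tol)
  lv <- t(sol) # combos x times
  lv <- pmin(pmax(lv, 0), 1)
  lv <- (1 - config$excision_residual) * lv + config$excision_residual * m0
  lv <- (1 - 2 * config$conversion_error) * lv + config$conversion_error
  attr(lv, "times") <- as.numeric(times)
  attr(lv, "grid") <- grid
  attr(lv, "config") <- config
  lv
}
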