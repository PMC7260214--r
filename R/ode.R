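# Adaptive Dormand-Prince RK45 integrator for a vector-valued state.
# The state here is the methylation level of one CpG (scalar) or of all grid
# combinations at once (length grid_steps^2); the right-hand side is smooth,
# so a 5(4) pair with standard PI-free step control is ample at tol 1e-8.

.DP_A <- list(
  c2 = 1 / 5,
  c3 = 3 / 10, c4 = 4 / 5, c5 = 8 / 9, c6 = 1, c7 = 1,
  a21 = 1 / 5,
  a31 = 3 / 40, a32 = 9 / 40,
  a41 = 44 / 45, a42 = -56 / 15, a43 = 32 / 9,
  a51 = 19372 / 6561, a52 = -25360 / 2187, a53 = 64448 / 6561, a54 = -212 / 729,
  a61 = 9017 / 3168, a62 = -355 / 33, a63 = 46732 / 5247, a64 = 49 / 176,
  a65 = -5103 / 18656,
  b1 = 35 / 384, b3 = 500 / 1113, b4 = 125 / 192, b5 = -2187 / 6784,
  b6 = 11 / 84,
  # 4th-order embedded weights
  e1 = 5179 / 57600, e3 = 7571 / 16695, e4 = 393 / 640, e5 = -92097 / 339200,
  e6 = 187 / 2100, e7 = 1 / 40
)

# deriv(t, y) -> dy/dt. Returns a matrix length(times) x length(y0) of the
# solution at `times` (ascending, times[1] is the initial time).
.ode_rk45 <- function(deriv, y0, times, rtol = 1e-8, atol = 1e-8,
                      max_steps = 1e6L) {
  stopifnot(!is.unsorted(times), length(times) >= 1L)
  A <- .DP_A
  n_out <- length(times)
  out <- matrix(NA_real_, n_out, length(y0))
  out[1L, ] <- y0
  if (n_out == 1L) return(out)

  t <- times[1L]
  y <- y0
  k1 <- deriv(t, y)
  h <- min(diff(range(times)) / 100, 0.1)
  steps <- 0L
  for (i_out in 2L:n_out) {
    t_target <- times[i_out]
    while (t < t_target) {
      if (steps >= max_steps) {
        stop(sprintf("ODE solver failed to converge: %d steps at t = %g (h = %g)",
                     steps, t, h))
      }
      h_try <- min(h, t_target - t)
      k2 <- deriv(t + A$c2 * h_try, y + h_try * A$a21 * k1)
      k3 <- deriv(t + A$c3 * h_try, y + h_try * (A$a31 * k1 + A$a32 * k2))
      k4 <- deriv(t + A$c4 * h_try,
                  y + h_try * (A$a41 * k1 + A$a42 * k2 + A$a43 * k3))
      k5 <- deriv(t + A$c5 * h_try,
                  y + h_try * (A$a51 * k1 + A$a52 * k2 + A$a53 * k3 + A$a54 * k4))
      k6 <- deriv(t + h_try,
                  y + h_try * (A$a61 * k1 + A$a62 * k2 + A$a63 * k3 +
                                 A$a64 * k4 + A$a65 * k5))
      y5 <- y + h_try * (A$b1 * k1 + A$b3 * k3 + A$b4 * k4 + A$b5 * k5 +
                           A$b6 * k6)
      k7 <- deriv(t + h_try, y5) # FSAL
      y4 <- y + h_try * (A$e1 * k1 + A$e3 * k3 + A$e4 * k4 + A$e5 * k5 +
                           A$e6 * k6 + A$e7 * k7)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- max(abs(y5 - y4) / sc)
      steps <- steps + 1L
      if (err <= 1 || h_try <= 1e-12) {
        t <- t + h_try
        y <- y5
        k1 <- k7
      }
      fac <- if (err > 0) 0.9 * err^(-0.2) else 5
      h <- h_try * min(5, max(0.2, fac))
      if (h < 1e-12) h <- 1e-12
    }
    out[i_out, ] <- y
  }
  out
}

# Solve dm/dt = k_me * exp(-k_E t) * (1 - m) - k_de * m for vectors of rates,
# starting at t = 0. Returns length(times) x length(k_me) matrix. `times` may
# be in any order; negative times are rejected.
.solve_damped_ode <- function(k_me, k_de, k_E, m0, times,
                              rtol = 1e-8, atol = 1e-8) {
  if (any(times < 0)) stop("times must be non-negative")
  if (any(k_me < 0) || any(k_de < 0) || k_E < 0) {
    stop("rates must be non-negative")
  }
  tu <- sort(unique(c(0, times)))
  deriv <- function(t, y) k_me * exp(-k_E * t) * (1 - y) - k_de * y
  sol <- .ode_rk45(deriv, m0, tu, rtol = rtol, atol = atol)
  sol[match(times, tu), , drop = FALSE]
}
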