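test_that("steady_state follows k_me / (k_me + k_de)", {
  expect_identical(steady_state(0.5, 0.5), 0.5)
  expect_identical(steady_state(0, 1), 0)
  expect_equal(steady_state(0.3, 0.1), 0.75)
  expect_equal(steady_state(rate_params(0.3, 0.1)), 0.75)
  expect_error(steady_state(0, 0), "degenerate")
  expect_error(rate_params(0, 0), "degenerate")
})

test_that("closed-form trace matches its defining formula", {
  expect_equal(closed_form_trace(0, 1, 1, 1)$levels, exp(-1))
  # m0 at equilibrium -> constant
  expect_equal(closed_form_trace(0.4, 0.6, 0.4, c(0, 5, 50))$levels,
               rep(0.4, 3))
  # long-time limit -> M_eq
  expect_equal(closed_form_trace(0.3, 0.1, 0.1, 1000)$levels, 0.75)
  # degenerate zero rates -> constant trace
  expect_equal(closed_form_trace(0, 0, 0.7, c(0, 3))$levels, c(0.7, 0.7))
})

test_that("numeric solver agrees with analytic limits", {
  # k_me = 0: pure exponential decay
  tr <- solve_trace(rate_params(0, 0.5, k_E = 0.5), times = 2, m0 = 0.8)
  expect_equal(tr$levels, 0.8 * exp(-1), tolerance = 1e-7)

  # t = 0 returns m0 exactly
  expect_identical(solve_trace(rate_params(0.3, 0.2), times = 0,
                               m0 = 0.61)$levels, 0.61)

  # k_E = 0 reduces to the closed form (sample of rate pairs)
  times <- default_config()$timepoints
  for (rates in list(c(0.01, 1.5), c(0.5, 0.5), c(2, 0.002), c(0.1, 0.1))) {
    tr <- solve_trace(rate_params(rates[1], rates[2], k_E = 0), times,
                      m0 = 0.9)
    cf <- closed_form_trace(rates[1], rates[2], 0.9, times)
    expect_lt(max(abs(tr$levels - cf$levels)), 1e-6)
  }

  expect_error(solve_trace(rate_params(0.1, 0.1), times = -1), "non-negative")
})

test_that("dampened solution matches the integrating-factor quadrature oracle", {
  times <- c(0, 4, 8, 10, 13, 17, 29)
  cases <- list(c(0.5, 0.5), c(1.8, 0.01), c(0.03, 0.9), c(0.2, 0.05))
  for (rates in cases) {
    p <- rate_params(rates[1], rates[2], k_E = 0.5)
    tr <- solve_trace(p, times)
    oracle <- quad_trace_oracle(rates[1], rates[2], 0.5, p$m_eq, times)
    expect_lt(max(abs(tr$levels - oracle)), 1e-6)
  }
})

test_that("excision mixing is the stated affine blend", {
  expect_equal(apply_excision_mix(0, day0_level = 1, residual = 0.08), 0.08)
  expect_equal(apply_excision_mix(0.5, day0_level = 0.9, residual = 0.08),
               0.532)
  # fixed point: mixing a level with itself changes nothing
  expect_equal(apply_excision_mix(0.37, day0_level = 0.37, residual = 0.3),
               0.37)
  expect_error(apply_excision_mix(0.5, day0_level = 1.2), "fraction")
  # trace input preserved
  tr <- apply_excision_mix(meth_trace(c(0, 4), c(0, 0.5)), 1, 0.08)
  expect_s3_class(tr, "meth_trace")
  expect_equal(tr$levels, c(0.08, 0.54))
})

test_that("conversion error is y = (1 - 2 eps) x + eps", {
  expect_equal(apply_conversion_error(0, 0.0025), 0.0025)
  expect_equal(apply_conversion_error(1, 0.0025), 0.9975)
  expect_equal(apply_conversion_error(0.5, 0.17), 0.5)
  expect_error(apply_conversion_error(0.5, 0.6), "epsilon")
})

test_that("expected_trace composes solver, mixing and conversion", {
  cfg <- default_config()
  # 0.5 is a fixed point of both corrections and the day-0 value for equal rates
  et <- expected_trace(rate_params(1, 1), cfg)
  expect_equal(et$levels[1], 0.5)
  # dampened k_me -> 0, so the long-run level is mix + conversion of 0
  et_inf <- expected_trace(rate_params(0.5, 0.5), cfg, times = c(0, 1000))
  expect_equal(et_inf$levels[2],
               0.995 * (0.08 * 0.5) + 0.0025, tolerance = 1e-5)
  # pointwise in t: invariant under permutation of requested timepoints
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  et_perm <- expected_trace(rate_params(0.4, 0.2), cfg,
                            times = cfg$timepoints[perm])
  et_sorted <- expected_trace(rate_params(0.4, 0.2), cfg)
  expect_equal(et_perm$levels, et_sorted$levels[perm], tolerance = 1e-9)
})

test_that("expected traces are monotone non-increasing on the grid", {
  cfg <- default_config()
  set.seed(1)
  g <- default_grid()
  for (i in sample(nrow(g$combos), 25)) {
    et <- expected_trace(rate_params(g$combos$k_me[i], g$combos$k_de[i],
                                     cfg$k_E), cfg)
    expect_true(all(diff(et$levels) <= 1e-9))
  }
})

test_that("trace bank covers the grid with bounded corrected levels", {
  bank <- default_bank()
  expect_equal(dim(bank), c(6400L, 7L))
  expect_true(all(bank >= 0.0025 - 1e-12 & bank <= 0.9975 + 1e-12))
  # rows with k_me = k_de start at exactly 0.5
  g <- default_grid()
  eq <- which(g$combos$k_me == g$combos$k_de)
  expect_equal(unname(bank[eq, 1]), rep(0.5, length(eq)))
  # increasing k_de at fixed k_me lowers every post-day-0 level
  k <- g$k
  fixed_me <- 30L # k_me column index
  rows <- (fixed_me - 1L) * k + seq_len(k) # ascending k_de index = descending rate
  sub <- bank[rev(rows), , drop = FALSE]   # rows now by increasing k_de
  for (t in 2:7) expect_true(all(diff(sub[, t]) < 0))
})
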