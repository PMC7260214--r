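test_that("default grid spans 80 x 80 with exact 10% steps", {
  g <- default_grid()
  expect_length(g$values, 80L)
  expect_equal(nrow(g$combos), 6400L)
  expect_equal(g$values[1], 2)
  expect_equal(min(g$values), 2 / 1.1^79, tolerance = 1e-12)
  expect_equal(unique(round(g$values[-80] / g$values[-1], 12)), 1.1)
  # ~3 orders of magnitude below the maximum
  expect_equal(log10(g$values[1] / g$values[80]), 79 * log10(1.1))
  expect_error(build_grid(model_config(grid_step_factor = 0.9)))
})

test_that("amplicon filtering applies the 100x / NA rules", {
  days <- c(0, 4, 8, 10, 13, 17, 29)
  ok <- make_counts(cpg_id = "keep", coverage = 200L, meth_count = 50L)
  low8 <- make_counts(cpg_id = "na_day8", coverage = 200L, meth_count = 50L)
  low8$coverage[low8$day == 8] <- 99L
  low0 <- make_counts(cpg_id = "bad_day0", coverage = 200L, meth_count = 50L)
  low0$coverage[low0$day == 0] <- 99L
  two_na <- make_counts(cpg_id = "two_na", coverage = 200L, meth_count = 50L)
  two_na$coverage[two_na$day %in% c(8, 13)] <- 99L
  tab <- rbind(ok, low8, low0, two_na)

  suppressMessages(out <- filter_counts(tab, "amplicon", timepoints = days))
  expect_setequal(unique(out$cpg_id), c("keep", "na_day8"))
  # the low-coverage day-8 call survives as NA
  expect_true(is.na(out$coverage[out$cpg_id == "na_day8" & out$day == 8]))
  expect_equal(attr(out, "attrition")[["cpgs_in"]], 4L)

  # joint mode drops a CpG when any replicate series fails
  r1 <- make_counts(cpg_id = "cg", replicate = 1L)
  r2 <- make_counts(cpg_id = "cg", replicate = 2L)
  r2$coverage[r2$day == 0] <- 10L
  r2$meth_count[r2$day == 0] <- 5L
  suppressMessages(out_pr <- filter_counts(rbind(r1, r2), "amplicon",
                                           timepoints = days))
  expect_equal(unique(out_pr$replicate), 1L)
  suppressMessages(out_j <- filter_counts(rbind(r1, r2), "amplicon",
                                          timepoints = days, joint = TRUE))
  expect_equal(nrow(out_j), 0L)
})

test_that("sureselect filtering enforces 50x everywhere", {
  days <- c(0, 4, 8, 10, 13, 17, 29)
  ok <- make_counts(cpg_id = "keep", replicate = 1:3, coverage = 60L,
                    meth_count = 20L)
  bad <- make_counts(cpg_id = "drop", replicate = 1:3, coverage = 60L,
                     meth_count = 20L)
  bad$coverage[bad$day == 13 & bad$replicate == 2L] <- 49L
  suppressMessages(out <- filter_counts(rbind(ok, bad), "sureselect",
                                        timepoints = days))
  expect_setequal(unique(out$cpg_id), "keep")
  expect_error(suppressMessages(filter_counts(ok, "capture")))
})

test_that("fit_replicate recovers the generating grid combo from pseudo-counts", {
  cfg <- default_config()
  g <- default_grid()
  bank <- default_bank()
  em <- error_model("betabinomial", 0.0055)
  i <- which(g$combos$k_de == g$values[20] & g$combos$k_me == g$values[15])
  counts <- pseudo_counts_from_trace(meth_trace(cfg$timepoints, bank[i, ]),
                                     n = 3997)
  fit <- fit_replicate(counts, bank, em)
  expect_equal(fit$mle$index, i)
  expect_equal(sum(fit$joint), 1, tolerance = 1e-9)
  expect_equal(sum(fit$marginal_de), 1, tolerance = 1e-9)
  expect_equal(sum(fit$marginal_me), 1, tolerance = 1e-9)

  # invariance to timepoint order of the records
  perm <- c(4, 1, 6, 3, 7, 2, 5)
  fit_perm <- fit_replicate(counts[perm, ], bank, em)
  expect_equal(fit_perm$joint, fit$joint, tolerance = 1e-12)
  expect_identical(fit_perm$mle$index, fit$mle$index)

  # NA timepoints are skipped; too few informative points error
  counts_na <- counts
  counts_na$coverage[2:3] <- NA
  counts_na$meth_count[2:3] <- NA
  expect_silent(fit_na <- fit_replicate(counts_na, bank, em))
  all_na <- counts
  all_na$coverage[-1] <- NA
  expect_error(fit_replicate(all_na, bank, em), "unfittable")
})

test_that("flat mid-level data with slow kinetics yield wide marginals", {
  cfg <- default_config()
  g <- default_grid()
  bank <- default_bank()
  slow <- which.min(abs(g$combos$k_de - 0.003) + abs(g$combos$k_me - 0.003))
  counts <- pseudo_counts_from_trace(meth_trace(cfg$timepoints, bank[slow, ]),
                                     n = 3997)
  fit <- fit_replicate(counts, bank, error_model("betabinomial", 0.0055))
  ci <- credible_interval(fit$marginal_de, g$values, 0.95)
  fast <- which.min(abs(g$combos$k_de - 0.3) + abs(g$combos$k_me - 0.3))
  counts_f <- pseudo_counts_from_trace(meth_trace(cfg$timepoints, bank[fast, ]),
                                       n = 3997)
  fit_f <- fit_replicate(counts_f, bank, error_model("betabinomial", 0.0055))
  ci_f <- credible_interval(fit_f$marginal_de, g$values, 0.95)
  expect_gt(ci$width_log10, ci_f$width_log10)
})

test_that("credible intervals trim equal tails on the grid", {
  v <- default_grid()$values
  point <- c(rep(0, 39), 1, rep(0, 40))
  ci <- credible_interval(point, v, 0.95)
  expect_equal(ci$lo, 40L)
  expect_equal(ci$hi, 40L)
  expect_identical(ci$width_log10, 0)

  unif <- rep(1 / 80, 80)
  ci_u <- credible_interval(unif, v, 0.95)
  expect_equal(ci_u$hi - ci_u$lo + 1L, 76L)

  # central interval contains the marginal mode for unimodal mass
  m <- dnorm(seq_along(v), mean = 25, sd = 6)
  m <- m / sum(m)
  ci_m <- credible_interval(m, v, 0.95)
  expect_true(ci_m$lo <= 25 && 25 <= ci_m$hi)
  expect_error(credible_interval(unif, v, level = 1.2), "level")
})

test_that("border mass rule flags unidentifiable fits", {
  g <- default_grid()
  k <- g$k
  mk_post <- function(marg_de, marg_me) {
    joint <- as.vector(outer(marg_de, marg_me))
    structure(list(joint = joint, marginal_de = marg_de, marginal_me = marg_me,
                   mle = list(), grid = g),
              class = "posterior_grid")
  }
  interior <- c(rep(0, 40), 1, rep(0, k - 41))
  expect_true(is_identifiable(mk_post(interior, interior), 0.08))
  border_me <- c(rep(0, k - 1), 0.1)
  border_me <- border_me + (1 - sum(border_me)) * interior
  expect_false(is_identifiable(mk_post(interior, border_me), 0.08))
  expect_false(is_identifiable(mk_post(interior, border_me), 0.05))
  expect_equal(attr(is_identifiable(mk_post(interior, border_me), 0.08),
                    "border_mass"), 0.1)
})

test_that("replicate combination uses medians and the stated ci formula", {
  est <- data.frame(k_de = c(0.1, 0.2, 0.4), k_me = c(0.3, 0.3, 0.3),
                    ci_de = c(0.2, 0.2, 0.2), ci_me = c(0.1, 0.2, 0.2),
                    identifiable = c(TRUE, TRUE, TRUE))
  comb <- combine_replicates(est)
  expect_equal(comb$k_de_hat, 0.2)
  expect_equal(comb$ci_de, 0.2 / sqrt(3))
  expect_equal(comb$ci_me, sqrt(0.01 + 0.04 + 0.04) / 3)
  expect_true(comb$identifiable)
  est$identifiable[2] <- FALSE
  expect_false(combine_replicates(est)$identifiable)
  expect_error(combine_replicates(est[0, ]), "at least one")
})

test_that("binomial MLE converges to the nearest grid point at large n", {
  cfg <- default_config()
  g <- default_grid()
  bank <- default_bank()
  em <- error_model("binomial")
  for (i in c(1500L, 2750L, 4000L)) {
    counts <- pseudo_counts_from_trace(meth_trace(cfg$timepoints, bank[i, ]),
                                       n = 2e5)
    fit <- fit_replicate(counts, bank, em)
    expect_equal(fit$mle$index, i)
  }
})

test_that("fit_rates assembles the per-CpG estimate table", {
  cfg <- default_config()
  g <- default_grid()
  bank <- default_bank()
  set.seed(3)
  spec <- cohort_spec(4, "fixed", k_me = c(0.3, 0.1, 0.6, 0.05),
                      k_de = c(0.2, 0.3, 0.1, 0.4),
                      coverage_mean = 3000, coverage_dispersion = Inf,
                      replicates = 3, seed = 3)
  counts <- simulate_counts(sample_true_rates(spec), spec, cfg,
                            error_model("betabinomial", 0.0055))
  est <- fit_rates(counts, cfg, error_model("betabinomial", 0.0055),
                   bank = bank)
  expect_equal(nrow(est), 4L)
  expect_named(est, c("cpg_id", "chrom", "pos", "condition", "k_me", "k_de",
                      "ci_me_log10", "ci_de_log10", "steady_state",
                      "identifiable", "n_replicates"))
  expect_equal(est$n_replicates, rep(3L, 4))
  expect_equal(est$steady_state, est$k_me / (est$k_me + est$k_de))
  # rates land within two grid steps of the truth for these central combos
  expect_lt(max(abs(log10(est$k_de / c(0.2, 0.3, 0.1, 0.4)))),
            2.5 * log10(1.1))
})
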