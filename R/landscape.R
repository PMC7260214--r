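#' Noise-free pseudo-counts from an expected trace
#'
#' Converts expected methylation fractions to the count data an idealized
#' (noise-free) experiment at fixed coverage would report:
#' `c_t = round(n * p_t)`, rounded half-to-even by default.
#'
#' @param trace A [meth_trace()] or numeric vector of expected fractions.
#' @param n Read coverage (>= 1).
#' @param rounding `"half-even"` (base `round`) or `"truncate"`.
#' @return data.frame with columns `day`, `coverage`, `meth_count`.
#' @examples
#' pseudo_counts_from_trace(meth_trace(c(0, 4), c(0.9975, 0.5)), n = 1000)
#' @export
pseudo_counts_from_trace <- function(trace, n,
                                     rounding = c("half-even", "truncate")) {
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  p <- .trace_levels(trace)
  days <- if (inherits(trace, "meth_trace")) trace$times else seq_along(p) - 1
  cnt <- switch(rounding,
                "half-even" = round(n * p),
                "truncate" = trunc(n * p))
  data.frame(day = days, coverage = as.integer(n), meth_count = as.integer(cnt))
}

#' Identifiability landscape of the assay design
#'
#' For every (k_de, k_me) grid combination: simulate its expected trace,
#' convert it to noise-free pseudo-counts at coverage `n`, run the full grid
#' inference against those counts, and record the 95% marginal credible
#' interval widths and the border mass. Replicates are identical pseudo-data,
#' so the combined interval is the single-fit width scaled by
#' `sqrt(replicates) / replicates` (the standard-error combination), and the
#' border rule uses the landscape cutoff (default 0.05).
#'
#' The result maps where the design can recover rates: a central
#' high-confidence basin; an unidentifiable corner of unmethylated CpGs (high
#' k_de, low k_me); widened intervals for low-rate 50%-methylated CpGs; and,
#' for highly methylated CpGs, precise k_de but imprecise k_me.
#'
#' @param config A [model_config()].
#' @param error An [error_model()] (amplicon beta-binomial by default, since
#'   the reference coverage is the amplicon median).
#' @param n Pseudo-count coverage; default 3997 (median amplicon coverage).
#' @param replicates Number of (identical) pseudo-replicates; default 3.
#' @param grid,bank Optional precomputed grid / trace bank.
#' @param rounding Pseudo-count rounding rule, see
#'   [pseudo_counts_from_trace()].
#' @return data.frame of class `"meth_landscape"` with one row per combination:
#'   `k_de`, `k_me`, `steady_state`, `ci_de`, `ci_me` (combined log10 widths),
#'   `border_mass`, `identifiable`.
#' @export
compute_landscape <- function(config = model_config(),
                              error = error_model("betabinomial", 0.0055),
                              n = 3997, replicates = 3,
                              grid = NULL, bank = NULL,
                              rounding = "half-even") {
  stopifnot(inherits(config, "meth_config"), inherits(error, "error_model"),
            n >= 1, replicates >= 1)
  if (is.null(grid)) grid <- build_grid(config)
  if (is.null(bank)) bank <- build_trace_bank(grid, config)
  times <- attr(bank, "times")
  ncombo <- nrow(grid$combos)
  scale_rep <- sqrt(replicates) / replicates

  ci_de <- ci_me <- border <- numeric(ncombo)
  for (i in seq_len(ncombo)) {
    counts <- pseudo_counts_from_trace(
      meth_trace(times, bank[i, ]), n = n, rounding = rounding
    )
    fit <- fit_replicate(counts, bank, error)
    ci_de[i] <- credible_interval(fit$marginal_de, grid$values,
                                  config$ci_level)$width_log10 * scale_rep
    ci_me[i] <- credible_interval(fit$marginal_me, grid$values,
                                  config$ci_level)$width_log10 * scale_rep
    flag <- is_identifiable(fit, config$border_threshold_landscape)
    border[i] <- attr(flag, "border_mass")
  }
  out <- data.frame(
    k_de = grid$combos$k_de,
    k_me = grid$combos$k_me,
    steady_state = steady_state(grid$combos$k_me, grid$combos$k_de),
    ci_de = ci_de,
    ci_me = ci_me,
    border_mass = border,
    identifiable = border < config$border_threshold_landscape
  )
  attr(out, "n") <- n
  attr(out, "replicates") <- replicates
  attr(out, "error") <- error
  class(out) <- c("meth_landscape", "data.frame")
  out
}

#' Write a landscape table to TSV
#'
#' @param landscape A [compute_landscape()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "meth_landscape"))
  hdr <- sprintf(
    "# methkinetics %s identifiability landscape; n=%s replicates=%s error=%s gamma=%s",
    as.character(utils::packageVersion("methkinetics")),
    attr(landscape, "n"), attr(landscape, "replicates"),
    attr(landscape, "error")$kind, attr(landscape, "error")$gamma
  )
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    as.data.frame(landscape), path, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE
  ))
  invisible(path)
}
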