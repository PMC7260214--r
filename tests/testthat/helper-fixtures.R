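# Shared fixtures and independent oracles. The default 80x80 grid/bank are
# built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

default_config <- function() {
  if (is.null(.fixtures$cfg)) .fixtures$cfg <- model_config()
  .fixtures$cfg
}

default_grid <- function() {
  if (is.null(.fixtures$grid)) .fixtures$grid <- build_grid(default_config())
  .fixtures$grid
}

default_bank <- function() {
  if (is.null(.fixtures$bank)) {
    .fixtures$bank <- build_trace_bank(default_grid(), default_config())
  }
  .fixtures$bank
}

# Independent oracle for the dampened ODE via the integrating factor:
#   mu(t) = exp(k_de * t + (k_me / k_E) * (1 - exp(-k_E * t)))
#   m(t)  = (m0 + int_0^t mu(s) k_me exp(-k_E s) ds) / mu(t)
# with the inner integral evaluated by adaptive quadrature. Fully independent
# of the RK45 path under test.
quad_trace_oracle <- function(k_me, k_de, k_E, m0, times) {
  stopifnot(k_E > 0)
  mu <- function(t) exp(k_de * t + (k_me / k_E) * (1 - exp(-k_E * t)))
  vapply(times, function(t) {
    if (t == 0) return(m0)
    I <- stats::integrate(function(s) mu(s) * k_me * exp(-k_E * s), 0, t,
                          rel.tol = 1e-11, abs.tol = 1e-13)$value
    (m0 + I) / mu(t)
  }, numeric(1))
}

# Tiny valid count table builder for IO / filtering tests.
make_counts <- function(cpg_id = "cpg1", chrom = "chr1", pos = 100L,
                        condition = "cre", replicate = 1L,
                        day = c(0, 4, 8, 10, 13, 17, 29),
                        coverage = 200L, meth_count = 50L) {
  df <- expand.grid(day = day, replicate = replicate, cpg_id = cpg_id,
                    condition = condition, stringsAsFactors = FALSE)
  df$chrom <- chrom
  df$pos <- rep_len(pos, nrow(df))
  df$coverage <- rep_len(coverage, nrow(df))
  df$meth_count <- rep_len(meth_count, nrow(df))
  df[, c("cpg_id", "chrom", "pos", "condition", "replicate", "day",
         "coverage", "meth_count")]
}
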