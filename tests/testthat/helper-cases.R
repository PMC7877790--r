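# Shared fixtures for the test suite.  Everything is generated in code;
# seeds are fixed so runs are reproducible.

cond_low <- function() qc_conditions(kpt = 0.1, mf = 0.001, kf = 1, Pb = 1)

phys_rates <- function(cond = cond_low()) {
  assemble_rates("PHYS", cond, c(kc = 100, kg = 10, kmg = 0.01, kd = 0.1))
}

full_rates <- function(cond = cond_low()) {
  assemble_rates("FULL", cond,
                 c(kc = 50, kmc = 2, kmr = 0.5, kg = 5, kmg = 0.3,
                   kd = 0.7))
}

# fixtures across all variants, n per variant
all_variant_fixtures <- function(seed, n_per_variant) {
  vs <- c("FULL", "PHYS", "WB", "WBSV", "OS", "NTM", "CNSV")
  out <- list()
  for (i in seq_along(vs)) {
    out <- c(out, random_rate_fixture(vs[i], seed = seed + i,
                                      n = n_per_variant))
  }
  out
}

expect_state_close <- function(a, b, tol) {
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))), tol)
}
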