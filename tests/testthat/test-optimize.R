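# Optimizer behavior on small multistart budgets; the full-budget runs live
# in the acceptance suite.

test_that("maximum folding fraction is a fraction and rises with folding speed", {
  fs <- c(0.1, 1)
  last <- -Inf
  for (kf in fs) {
    pr <- qc_problem("PHYS", qc_conditions(0.1, 0.001, kf, 1),
                     starts = 4L, seed = 0L)
    res <- max_folding_fraction(pr)
    expect_lte(res$objective, 1)
    expect_gte(res$objective, 0)
    expect_true(res$steady$exists)
    expect_gte(res$objective, last - 1e-6)
    last <- res$objective
  }
})

test_that("optima respect bounds and are locally optimal", {
  pr <- qc_problem("PHYS", cond_low(), starts = 6L, seed = 0L)
  res <- max_folding_fraction(pr)
  expect_true(all(res$best_rates >= pr$bounds[1] - 1e-12))
  expect_true(all(res$best_rates <= pr$bounds[2] + 1e-12))
  # perturbing each free rate by +/-5 % (projected to bounds) never
  # improves the objective by more than the convergence tolerance
  tmpl <- erqc:::.make_template(pr$variant, pr$conditions)
  for (nm in names(res$best_rates)) {
    for (fac in c(0.95, 1.05)) {
      pert <- res$best_rates
      pert[nm] <- min(max(pert[nm] * fac, pr$bounds[1]), pr$bounds[2])
      m <- erqc:::.metrics_at(log10(pert), tmpl)
      if (m$exists) expect_lte(m$f, res$objective + 1e-6)
    }
  }
})

test_that("minimum unfolded protein meets its folding-fraction constraint", {
  pr <- qc_problem("PHYS", cond_low(), starts = 6L, seed = 0L)
  targets <- c(0.3, 0.6, 0.9)
  prev <- -Inf
  for (ft in targets) {
    res <- min_unfolded_given_f(pr, ft)
    expect_identical(res$status, "ok")
    expect_lt(abs(res$f - ft), 1e-4)
    expect_gte(res$objective, prev - 1e-6)   # Pareto monotonicity
    prev <- res$objective
  }
})

test_that("tiny folding targets demand less unfolded protein than large ones", {
  pr <- qc_problem("PHYS", cond_low(), starts = 4L, seed = 0L)
  lo <- min_unfolded_given_f(pr, 1e-3)
  hi <- min_unfolded_given_f(pr, 0.9)
  expect_lt(lo$objective, hi$objective)
})

test_that("folding efficiency honors the unit-load acceptance window", {
  pr <- qc_problem("PHYS", qc_conditions(0.5, 0.001, 1, 1),
                   starts = 6L, seed = 0L)
  res <- folding_efficiency(pr)
  expect_identical(res$status, "ok")
  # at kpt = 0.5 the load constraint binds: the achieved minimum load
  # must land in the window
  expect_gt(res$Pu, 0.99)
  expect_lt(res$Pu, 1.01)
  expect_true(res$steady$exists)
  expect_equal(res$f, res$objective, tolerance = 2e-4)
})

test_that("identical seeds reproduce optimization results exactly", {
  pr <- qc_problem("PHYS", cond_low(), starts = 4L, seed = 7L)
  a <- max_folding_fraction(pr)
  b <- max_folding_fraction(pr)
  expect_identical(a$objective, b$objective)
  expect_identical(a$best_rates, b$best_rates)
})

test_that("degradation-rate adaptation finds and reports the load window", {
  fe <- folding_efficiency(qc_problem("PHYS",
                                      qc_conditions(0.5, 0.001, 1, 1),
                                      starts = 6L, seed = 0L))
  vp <- variant_pin(qc_variant("PHYS"),
                    fe$best_rates[c("kc", "kg", "kmg")])

  # re-running at the original conditions recovers a kd inside the window
  rts <- assemble_rates(vp, qc_conditions(0.5, 0.001, 1, 1),
                        fe$best_rates["kd"])
  ad <- adjust_kd(rts)
  expect_true(ad$in_window)
  expect_gt(ad$Pu, 0.99)
  expect_lt(ad$Pu, 1.01)

  # at five-fold the production the window is out of reach: kd saturates
  # at its upper bound, minimizing the excess load
  rts5 <- assemble_rates(vp, qc_conditions(5, 0.001, 1, 1),
                         fe$best_rates["kd"])
  ad5 <- adjust_kd(rts5)
  expect_false(ad5$in_window)
  expect_equal(ad5$kd, 1e3)
  expect_gt(ad5$Pu, 1.01)
})

test_that("single-point grids reduce the Pareto driver to one constrained solve", {
  pr <- qc_problem("PHYS", cond_low(), starts = 4L, seed = 0L)
  tab <- pareto_frontier(pr, 0.5)
  expect_equal(nrow(tab), 1L)
  single <- min_unfolded_given_f(pr, 0.5)
  expect_equal(tab$P_unfolded, single$objective, tolerance = 1e-6)
  expect_error(pareto_frontier(pr, numeric(0)), "at least one")
})

test_that("tag-memory and safety-valve designs match the physiological cycle where expected", {
  # with few unfoldable proteins the no-tag-memory design performs
  # equivalently; with many it cannot exploit the tag as memory
  f_phys <- folding_efficiency(qc_problem("PHYS",
                                          qc_conditions(0.3, 0.001, 1, 1),
                                          starts = 6L, seed = 0L))$objective
  f_ntm <- folding_efficiency(qc_problem("NTM",
                                         qc_conditions(0.3, 0.001, 1, 1),
                                         starts = 6L, seed = 0L))$objective
  expect_lt(abs(f_phys - f_ntm), 0.02)

  f_phys_hi <- folding_efficiency(qc_problem("PHYS",
                                             qc_conditions(0.3, 0.4, 1, 1),
                                             starts = 6L, seed = 0L))$objective
  f_ntm_hi <- folding_efficiency(qc_problem("NTM",
                                            qc_conditions(0.3, 0.4, 1, 1),
                                            starts = 6L, seed = 0L))$objective
  expect_gte(f_phys_hi, f_ntm_hi - 1e-3)

  # without the safety valve the cycle matches the physiological design at
  # low production
  f_cnsv <- folding_efficiency(qc_problem("CNSV",
                                          qc_conditions(0.5, 0.001, 1, 1),
                                          starts = 6L, seed = 0L))$objective
  f_phys5 <- folding_efficiency(qc_problem("PHYS",
                                           qc_conditions(0.5, 0.001, 1, 1),
                                           starts = 6L, seed = 0L))$objective
  expect_lt(abs(f_cnsv - f_phys5), 0.02)
})
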