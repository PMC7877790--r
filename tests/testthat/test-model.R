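test_that("assemble_rates applies variant masks and production split", {
  cond <- qc_conditions(kpt = 0.1, mf = 0.001, kf = 1, Pb = 1)
  r <- assemble_rates("PHYS", cond, c(kc = 10, kg = 1, kmg = 0.1, kd = 0.5))
  expect_equal(r[["kmc"]], 0)
  expect_equal(r[["kmr"]], 0)
  expect_equal(r[["kr"]], 1)
  expect_equal(r[["kp"]], 0.0999)
  expect_equal(r[["kps"]], 0.0001)

  r2 <- assemble_rates("OS", cond, c(kc = 10, kd = 0.5))
  expect_equal(unname(r2[c("kmc", "kmr", "kg", "kmg")]), rep(0, 4))

  r3 <- assemble_rates("NTM", cond, c(kc = 10, kg = 1, kmg = 0.1, kd = 0.5))
  expect_equal(r3[["kr"]], 0)
  expect_equal(r3[["kmc"]], 1)

  # a rate that is not free under the variant is rejected
  expect_error(
    assemble_rates("PHYS", cond,
                   c(kmr = 0.5, kc = 10, kg = 1, kd = 0.5)),
    "free_values")
  # bounds are enforced
  expect_error(
    assemble_rates("PHYS", cond,
                   c(kc = 1e4, kg = 1, kmg = 0.1, kd = 0.5)),
    "within")
})

test_that("conditions and state constructors validate their invariants", {
  expect_error(qc_conditions(kpt = -1), "kpt")
  expect_error(qc_conditions(kpt = 1, mf = 1.2), "mf")
  expect_error(qc_conditions(kpt = 1, Pb = -1), "Pb")
  expect_error(qc_state(Pg = -0.1), ">= 0")
})

test_that("dynamics_rhs has only source terms at the empty state", {
  r <- assemble_rates("PHYS", qc_conditions(0.101, 0.001, 1, 1),
                      c(kc = 10, kg = 1, kmg = 0.1, kd = 0.5))
  d <- dynamics_rhs(qc_state(), r)
  expect_equal(d[["Pg"]], r[["kp"]])
  expect_equal(d[["Pgs"]], r[["kps"]])
  expect_equal(unname(d[c("Pc", "Pcf", "P", "Pcs", "Ps", "Pcb")]),
               rep(0, 6))
  expect_error(dynamics_rhs(c(Pg = -1, Pc = 0, Pcf = 0, P = 0, Pgs = 0,
                              Pcs = 0, Ps = 0, Pcb = 0), r),
               ">= 0")
})

test_that("dynamics_rhs vanishes at a solved steady state", {
  for (rts in list(phys_rates(), full_rates())) {
    ss <- solve_steady_state(rts)
    expect_true(ss$exists)
    expect_lt(max(abs(dynamics_rhs(ss$state, rts))), 1e-8)
  }
})

test_that("chaperone bookkeeping closes for every solved state", {
  fx <- all_variant_fixtures(seed = 11, n_per_variant = 4)
  checked <- 0L
  for (f in fx) {
    ss <- suppressWarnings(solve_steady_state(f$rates))
    if (!ss$exists) next
    checked <- checked + 1L
    tot <- ss$state[["Pc"]] + ss$state[["Pcf"]] + ss$state[["Pcs"]] +
      ss$state[["Pcb"]] + available_chaperone(ss$state)
    expect_equal(tot, 1, tolerance = 1e-10)
    expect_equal(available_chaperone(ss$state), ss$CA, tolerance = 1e-10)
  }
  expect_gte(checked, 10L)
})

test_that("available_chaperone is total minus bound", {
  expect_equal(available_chaperone(qc_state()), 1)
  expect_equal(available_chaperone(
    qc_state(Pc = 0.3, Pcf = 0.2, Pcs = 0.1, Pcb = 0.1)), 0.3)
  expect_equal(available_chaperone(
    qc_state(Pc = 0.5, Pcf = 0.25, Pcs = 0.15, Pcb = 0.1)), 0)
})

test_that("cycle energy follows the forward/reverse rate ratio", {
  cond <- qc_conditions(0.1, 0.001, 1, 1)
  r_eq <- assemble_rates("FULL", cond,
                         c(kc = 1, kmc = 1, kmr = 1, kg = 1, kmg = 1,
                           kd = 0.5))
  expect_equal(cycle_energy(r_eq)$E, 0)

  r_dr <- assemble_rates("FULL", cond,
                         c(kc = 10, kmc = 0.1, kmr = 0.1, kg = 10,
                           kmg = 0.1, kd = 0.5))
  expect_equal(cycle_energy(r_dr)$E, log(1e5), tolerance = 1e-12)

  # vanishing reverse rate: unbounded driving, not an error
  r_ub <- phys_rates()
  en <- cycle_energy(r_ub)
  expect_true(en$unbounded)
  expect_identical(en$E, Inf)

  # antisymmetry under exchanging each forward rate with its reverse
  set.seed(3)
  for (i in 1:20) {
    r <- 10^runif(6, -2, 2)
    names(r) <- c("kc", "kmc", "kr", "kmr", "kg", "kmg")
    swapped <- r
    swapped[c("kc", "kmc", "kr", "kmr", "kg", "kmg")] <-
      r[c("kmc", "kc", "kmr", "kr", "kmg", "kg")]
    expect_equal(cycle_energy(r)$E, -cycle_energy(swapped)$E,
                 tolerance = 1e-10)
  }

  # a vanishing forward rate is a domain error
  expect_error(cycle_energy(c(kc = 0, kr = 1, kg = 1, kmc = 1, kmr = 1,
                              kmg = 1)),
               "forward")
})

test_that("folding fraction is the folding flux over foldable production", {
  cond <- qc_conditions(0.1, 0, 1, 1)   # kp = 0.1
  r <- assemble_rates("PHYS", cond, c(kc = 10, kg = 1, kmg = 0.1,
                                      kd = 0.5))
  st <- qc_state(Pc = 0.05)
  expect_equal(folding_fraction(st, r), 0.5)

  cond0 <- qc_conditions(0.1, 0, 0, 1)  # kf = 0
  r0 <- assemble_rates("PHYS", cond0, c(kc = 10, kg = 1, kmg = 0.1,
                                        kd = 0.5))
  expect_equal(folding_fraction(st, r0), 0)

  cond1 <- qc_conditions(0.1, 1, 1, 1)  # mf = 1 so kp = 0
  r1 <- assemble_rates("PHYS", cond1, c(kc = 10, kg = 1, kmg = 0.1,
                                        kd = 0.5))
  expect_error(folding_fraction(st, r1), "kp")
})

test_that("total unfolded protein excludes folded and background pools", {
  expect_equal(total_unfolded(qc_state()), 0)
  st <- qc_state(Pg = 0.1, Pc = 0.1, P = 0.1, Pgs = 0.05, Pcs = 0.05,
                 Ps = 0.05, Pcf = 0.4, Pcb = 0.2)
  expect_equal(total_unfolded(st), 0.45)
  expect_equal(total_unfolded(qc_state(Pcf = 1)), 0)
})

test_that("variant_pin moves a free rate to the fixed set", {
  vp <- variant_pin(qc_variant("FULL"), c(kmr = 0.5))
  expect_false("kmr" %in% vp$free_rates)
  expect_equal(vp$fixed_other[["kmr"]], 0.5)
  cond <- qc_conditions(0.1, 0.001, 1, 1)
  r <- assemble_rates(vp, cond, c(kc = 10, kmc = 1, kg = 1, kmg = 0.1,
                                  kd = 0.5))
  expect_equal(r[["kmr"]], 0.5)
  expect_error(variant_pin(qc_variant("PHYS"), c(kmr = 1)), "not free")
})
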