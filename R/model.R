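# Core model objects: external conditions, rate sets, pathway variants, and the
# dimensionless mass-action dynamics of the chaperone binding cycle.
#
# Non-dimensionalization: times are measured in units of 1/k_r (glucose trimming
# of chaperone-bound proteins) and concentrations in units of the total
# chaperone concentration C_tot.  Hence kr = 1 (except the no-tag-memory
# variant, where the trimming-release transition is absent and kr = 0) and
# Ctot = 1 throughout.

.RATE_NAMES  <- c("kc", "kmc", "kr", "kmr", "kg", "kmg", "kd",
                  "kf", "kp", "kps", "Pb")
.STATE_NAMES <- c("Pg", "Pc", "Pcf", "P", "Pgs", "Pcs", "Ps", "Pcb")
.FREEABLE    <- c("kc", "kmc", "kmr", "kg", "kmg", "kd")

#' External input conditions of the quality-control cycle
#'
#' The cycle is driven by protein production and characterized by the folding
#' speed of its substrates; both are treated as inputs the pathway cannot
#' choose.  All quantities are dimensionless: rates relative to the glucose
#' trimming rate of chaperone-bound proteins, concentrations relative to total
#' chaperone.
#'
#' @param kpt Total protein production rate (foldable + unfoldable), > 0.
#' @param mf Fraction of produced proteins that are terminally unfoldable,
#'   in \[0, 1\].  Foldable production is `kp = (1 - mf) * kpt`, unfoldable
#'   production `kps = mf * kpt`.
#' @param kf Folding rate constant of chaperone-bound foldable proteins, >= 0.
#' @param Pb Concentration of background proteins that can occupy chaperones
#'   through untagged binding, >= 0.
#' @return An object of class `qc_conditions`.
#' @examples
#' qc_conditions(kpt = 0.1, mf = 0.001, kf = 1, Pb = 1)
#' @export
qc_conditions <- function(kpt, mf = 0.001, kf = 1, Pb = 1) {
  stopifnot(is.numeric(kpt), length(kpt) == 1L, is.finite(kpt),
            is.numeric(mf), length(mf) == 1L, is.finite(mf),
            is.numeric(kf), length(kf) == 1L, is.finite(kf),
            is.numeric(Pb), length(Pb) == 1L, is.finite(Pb))
  if (kpt <= 0) stop("'kpt' must be > 0")
  if (mf < 0 || mf > 1) stop("'mf' must lie in [0, 1]")
  if (kf < 0) stop("'kf' must be >= 0")
  if (Pb < 0) stop("'Pb' must be >= 0")
  structure(list(kpt = kpt, mf = mf, kf = kf, Pb = Pb),
            class = "qc_conditions")
}

#' @export
print.qc_conditions <- function(x, ...) {
  cat(sprintf("Cycle conditions: kpt = %g, mf = %g, kf = %g, Pb = %g\n",
              x$kpt, x$mf, x$kf, x$Pb))
  invisible(x)
}

#' Pathway-architecture variants
#'
#' Each variant fixes a subset of the adjustable cycle rate constants to zero
#' (removing the corresponding transition) and leaves the remainder free:
#'
#' * `FULL`: all six cycle rates free (`kc, kmc, kmr, kg, kmg, kd`).
#' * `PHYS`: consensus physiological cycle; no chaperone unbinding without
#'   trimming (`kmc = 0`) and no untagged rebinding (`kmr = 0`).
#' * `WB`: weak binding, non-cyclic; no reglucosylation or safety valve
#'   (`kmr = kg = kmg = 0`).
#' * `WBSV`: weak binding plus the deglucosylation safety valve
#'   (`kmr = kg = 0`).
#' * `OS`: one shot; binding and trimming irreversible, a single folding
#'   attempt per protein (`kmc = kmr = kg = kmg = 0`).
#' * `NTM`: no tag memory; chaperone release does not trim the tag (`kr = 0`,
#'   `kmc = 1`), so deglucosylation and chaperone binding are independent.
#' * `CNSV`: the physiological cycle without the safety valve
#'   (`kmc = kmr = kmg = 0`).
#'
#' @param name One of `"FULL"`, `"PHYS"`, `"WB"`, `"WBSV"`, `"OS"`, `"NTM"`,
#'   `"CNSV"`.
#' @return An object of class `qc_variant` with elements `name`, `free_rates`,
#'   `fixed_zero`, `fixed_other` (named numeric, includes `kr`).
#' @export
qc_variant <- function(name = c("FULL", "PHYS", "WB", "WBSV", "OS", "NTM",
                                "CNSV")) {
  name <- match.arg(name)
  v <- .VARIANTS[[name]]
  structure(v, class = "qc_variant")
}

.VARIANTS <- list(
  FULL = list(name = "FULL",
              free_rates = c("kc", "kmc", "kmr", "kg", "kmg", "kd"),
              fixed_zero = character(0), fixed_other = c(kr = 1)),
  PHYS = list(name = "PHYS",
              free_rates = c("kc", "kg", "kmg", "kd"),
              fixed_zero = c("kmc", "kmr"), fixed_other = c(kr = 1)),
  WB   = list(name = "WB",
              free_rates = c("kc", "kmc", "kd"),
              fixed_zero = c("kmr", "kg", "kmg"), fixed_other = c(kr = 1)),
  WBSV = list(name = "WBSV",
              free_rates = c("kc", "kmc", "kmg", "kd"),
              fixed_zero = c("kmr", "kg"), fixed_other = c(kr = 1)),
  OS   = list(name = "OS",
              free_rates = c("kc", "kd"),
              fixed_zero = c("kmc", "kmr", "kg", "kmg"), fixed_other = c(kr = 1)),
  NTM  = list(name = "NTM",
              free_rates = c("kc", "kg", "kmg", "kd"),
              fixed_zero = c("kmr"), fixed_other = c(kr = 0, kmc = 1)),
  CNSV = list(name = "CNSV",
              free_rates = c("kc", "kg", "kd"),
              fixed_zero = c("kmc", "kmr", "kmg"), fixed_other = c(kr = 1))
)

#' @export
print.qc_variant <- function(x, ...) {
  cat(sprintf("Variant %s: free {%s}; zero {%s}; fixed {%s}\n", x$name,
              paste(x$free_rates, collapse = ", "),
              paste(x$fixed_zero, collapse = ", "),
              paste(sprintf("%s=%g", names(x$fixed_other), x$fixed_other),
                    collapse = ", ")))
  invisible(x)
}

#' Pin selected free rates of a variant to fixed values
#'
#' Removes `names(pins)` from the variant's free rates and fixes them at the
#' given values, e.g. to sweep the untagged rebinding rate `kmr` while the
#' remaining rates are optimized.
#'
#' @param variant A `qc_variant`.
#' @param pins Named numeric vector of rates to pin (must be free in
#'   `variant`).
#' @return A modified `qc_variant`.
#' @export
variant_pin <- function(variant, pins) {
  stopifnot(inherits(variant, "qc_variant"), is.numeric(pins),
            !is.null(names(pins)))
  bad <- setdiff(names(pins), variant$free_rates)
  if (length(bad))
    stop("cannot pin rate(s) not free in variant ", variant$name, ": ",
         paste(bad, collapse = ", "))
  if (any(pins < 0)) stop("pinned rates must be >= 0")
  variant$free_rates <- setdiff(variant$free_rates, names(pins))
  variant$fixed_other <- c(variant$fixed_other, pins)
  variant
}

#' Assemble a full rate set from a variant, conditions, and free-rate values
#'
#' Applies the variant mask (zeros and fixed values), derives the production
#' split `kp = (1 - mf) * kpt`, `kps = mf * kpt`, and returns the complete
#' dimensionless rate vector used by the dynamics and the steady-state solver.
#'
#' @param variant A `qc_variant` (or variant name).
#' @param conditions A `qc_conditions` object.
#' @param free_values Named numeric vector whose names exactly match
#'   `variant$free_rates`.
#' @param bounds Length-2 numeric, admissible range for free rates
#'   (default `c(1e-3, 1e3)`).
#' @return A named numeric vector of class `qc_rates` with elements
#'   `kc, kmc, kr, kmr, kg, kmg, kd, kf, kp, kps, Pb`.
#' @examples
#' cond <- qc_conditions(kpt = 0.1, mf = 0.001, kf = 1, Pb = 1)
#' assemble_rates("PHYS", cond, c(kc = 10, kg = 1, kmg = 0.1, kd = 0.5))
#' @export
assemble_rates <- function(variant, conditions, free_values,
                           bounds = c(1e-3, 1e3)) {
  if (is.character(variant)) variant <- qc_variant(variant)
  stopifnot(inherits(variant, "qc_variant"),
            inherits(conditions, "qc_conditions"))
  fn <- names(free_values)
  if (is.null(fn) || !setequal(fn, variant$free_rates) ||
      anyDuplicated(fn)) {
    stop(sprintf("free_values must name exactly {%s} for variant %s",
                 paste(variant$free_rates, collapse = ", "), variant$name))
  }
  if (any(!is.finite(free_values)))
    stop("free rate values must be finite")
  if (any(free_values < bounds[1] | free_values > bounds[2]))
    stop(sprintf("free rate values must lie within [%g, %g]",
                 bounds[1], bounds[2]))
  r <- stats::setNames(numeric(length(.RATE_NAMES)), .RATE_NAMES)
  r["kr"] <- 1
  r[names(variant$fixed_other)] <- variant$fixed_other
  r[variant$fixed_zero] <- 0
  r[fn] <- free_values
  r["kf"]  <- conditions$kf
  r["kp"]  <- (1 - conditions$mf) * conditions$kpt
  r["kps"] <- conditions$mf * conditions$kpt
  r["Pb"]  <- conditions$Pb
  if (r[["kd"]] <= 0) stop("'kd' must be > 0")
  structure(r, class = "qc_rates")
}

#' @export
print.qc_rates <- function(x, ...) {
  cat("Quality-control cycle rates (dimensionless):\n")
  print(unclass(round(x, 6)))
  invisible(x)
}

#' Construct a concentration state vector
#'
#' @param Pg,Pc,Pcf,P Foldable protein concentrations: glucose tagged,
#'   chaperone bound, chaperone bound and folded, untagged.
#' @param Pgs,Pcs,Ps Unfoldable ("misfolded") counterparts of `Pg`, `Pc`, `P`.
#' @param Pcb Chaperone-bound background protein.
#' @return Named numeric vector of class `qc_state`.
#' @export
qc_state <- function(Pg = 0, Pc = 0, Pcf = 0, P = 0,
                     Pgs = 0, Pcs = 0, Ps = 0, Pcb = 0) {
  s <- c(Pg = Pg, Pc = Pc, Pcf = Pcf, P = P,
         Pgs = Pgs, Pcs = Pcs, Ps = Ps, Pcb = Pcb)
  if (any(!is.finite(s)) || any(s < 0))
    stop("state concentrations must be finite and >= 0")
  structure(s, class = "qc_state")
}

#' Available chaperone concentration
#'
#' `C_A = 1 - Pc - Pcf - Pcs - Pcb` (total chaperone is 1 in dimensionless
#' units).  May be negative for infeasible states; callers check.
#'
#' @param state A state vector (`qc_state` or named numeric).
#' @return Scalar available chaperone.
#' @export
available_chaperone <- function(state) {
  1 - state[["Pc"]] - state[["Pcf"]] - state[["Pcs"]] - state[["Pcb"]]
}

#' Time derivatives of the cycle dynamics
#'
#' Mass-action right-hand sides for the eight concentrations.  Chaperone
#' binding is bimolecular in the available chaperone `C_A`; the background
#' pool `Pb` is a fixed reservoir (no depletion).  Degradation removes
#' untagged proteins at rate `kd` (a loss term for both `P` and `Ps`).
#'
#' @param state State vector (named numeric, see [qc_state()]).
#' @param rates Rate set from [assemble_rates()].
#' @return Named numeric vector of time derivatives, same order as `state`.
#' @export
dynamics_rhs <- function(state, rates) {
  if (any(state < 0)) stop("state concentrations must be >= 0")
  .rhs_core(as.numeric(state[.STATE_NAMES]), as.numeric(rates[.RATE_NAMES]))
}

# state: Pg Pc Pcf P Pgs Pcs Ps Pcb; rates: kc kmc kr kmr kg kmg kd kf kp kps Pb
.rhs_core <- function(s, r) {
  kc <- r[1L]; kmc <- r[2L]; kr <- r[3L]; kmr <- r[4L]; kg <- r[5L]
  kmg <- r[6L]; kd <- r[7L]; kf <- r[8L]; kp <- r[9L]; kps <- r[10L]
  Pb <- r[11L]
  Pg <- s[1L]; Pc <- s[2L]; Pcf <- s[3L]; P <- s[4L]
  Pgs <- s[5L]; Pcs <- s[6L]; Ps <- s[7L]; Pcb <- s[8L]
  CA <- 1 - Pc - Pcf - Pcs - Pcb
  c(Pg  = kg * P + kmc * Pc - (kc * CA + kmg) * Pg + kp,
    Pc  = (kc * Pg + kmr * P) * CA - (kr + kmc + kf) * Pc,
    Pcf = kf * Pc - (kr + kmc) * Pcf,
    P   = kr * Pc + kmg * Pg - (kg + kmr * CA + kd) * P,
    Pgs = kg * Ps + kmc * Pcs - (kc * CA + kmg) * Pgs + kps,
    Pcs = (kc * Pgs + kmr * Ps) * CA - (kr + kmc) * Pcs,
    Ps  = kr * Pcs + kmg * Pgs - (kg + kmr * CA + kd) * Ps,
    Pcb = kmr * CA * Pb - kr * Pcb)
}

#' Free energy driving the quality-control cycle
#'
#' `E = log((kc * kr * kg) / (kmc * kmr * kmg))` in units of kT.  The cycle is
#' at detailed balance when `E = 0`; a vanishing reverse rate corresponds to
#' unbounded (infinite) driving.
#'
#' @param rates Rate set.
#' @return A list with `E` (numeric, `Inf` when unbounded) and `unbounded`
#'   (logical).
#' @export
cycle_energy <- function(rates) {
  fwd <- c(rates[["kc"]], rates[["kr"]], rates[["kg"]])
  rev <- c(rates[["kmc"]], rates[["kmr"]], rates[["kmg"]])
  if (any(fwd <= 0))
    stop("cycle energy requires positive forward rates kc, kr, kg")
  if (any(rev == 0)) return(list(E = Inf, unbounded = TRUE))
  list(E = log(prod(fwd) / prod(rev)), unbounded = FALSE)
}

#' Folding fraction
#'
#' Fraction of foldable proteins that fold rather than degrade,
#' `f = kf * Pc / kp`.  Meaningful at steady state, where `kf * Pc` is the
#' folding flux out of the total foldable influx `kp`.
#'
#' @param state Steady-state vector.
#' @param rates Rate set with `kp > 0`.
#' @return Scalar folding fraction.
#' @export
folding_fraction <- function(state, rates) {
  if (rates[["kp"]] <= 0) stop("folding fraction undefined for kp <= 0")
  rates[["kf"]] * state[["Pc"]] / rates[["kp"]]
}

#' Total unfolded protein
#'
#' `P_unfolded = Pg + Pgs + Pc + Pcs + P + Ps`: all not-yet-folded proteins in
#' the cycle, excluding folded chaperone-bound (`Pcf`) and background (`Pcb`)
#' proteins.
#'
#' @param state State vector.
#' @return Scalar total unfolded protein concentration.
#' @export
total_unfolded <- function(state) {
  state[["Pg"]] + state[["Pgs"]] + state[["Pc"]] + state[["Pcs"]] +
    state[["P"]] + state[["Ps"]]
}
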