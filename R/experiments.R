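# Reproducible sweep drivers: tidy tables of folding efficiency, optimal
# rates, variant comparisons, robustness to production changes, and
# energy-constrained performance, composing the steady-state solver and the
# optimizers.  Per-point failures are recorded in-row; rows are never
# silently dropped.

.cond_with <- function(conditions, name, value) {
  args <- list(kpt = conditions$kpt, mf = conditions$mf,
               kf = conditions$kf, Pb = conditions$Pb)
  args[[name]] <- value
  do.call(qc_conditions, args)
}

#' Sweep a condition and re-optimize the pathway at each point
#'
#' Runs [folding_efficiency()] at each value of the swept input condition,
#' recording the efficiency `f*max` and the optimal free rates.
#'
#' @param problem Base `qc_problem`; its conditions supply the non-swept
#'   inputs.
#' @param sweep Which condition to sweep: `"kpt"`, `"kf"`, or `"mf"`.
#' @param grid Strictly increasing vector of swept values.
#' @return Data frame with one row per grid point: swept value, `fmax_star`,
#'   `Pu`, `status`, and the optimal free rates (NA on per-point failure).
#' @export
sweep_optimal <- function(problem, sweep = c("kpt", "kf", "mf"), grid) {
  sweep <- match.arg(sweep)
  stopifnot(length(grid) >= 1L, all(diff(grid) > 0) || length(grid) == 1L)
  free <- problem$variant$free_rates
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    pr <- problem
    pr$conditions <- .cond_with(problem$conditions, sweep, grid[i])
    res <- tryCatch(folding_efficiency(pr), error = function(e) NULL)
    rates <- stats::setNames(rep(NA_real_, length(free)), free)
    if (!is.null(res)) rates[names(res$best_rates)] <- res$best_rates
    row <- data.frame(value = grid[i],
                      fmax_star = if (is.null(res)) NA_real_ else
                        res$objective,
                      Pu = if (is.null(res)) NA_real_ else res$Pu,
                      status = if (is.null(res)) "error" else res$status)
    names(row)[1L] <- sweep
    rows[[i]] <- cbind(row, as.list(rates))
  }
  out <- do.call(rbind, rows)
  attr(out, "conditions") <- problem$conditions
  attr(out, "variant") <- problem$variant$name
  attr(out, "seed") <- problem$seed
  out
}

#' Compare variant efficiencies against the physiological model
#'
#' Computes the folding efficiency `f*max` for each variant across a grid of
#' production rates and reports the ratio to the physiological (PHYS)
#' reference.
#'
#' @param kpt_grid Vector of total production rates.
#' @param variants Variant names to compare (PHYS is added if absent).
#' @param kf,mf,Pb Remaining conditions, shared by all points.
#' @param starts,seed Multistart settings passed to each optimization.
#' @return Data frame with columns `kpt`, `variant`, `fmax_star`, `status`,
#'   and `ratio_to_phys`.
#' @export
compare_variants <- function(kpt_grid,
                             variants = c("PHYS", "WB", "WBSV", "OS",
                                          "NTM", "CNSV"),
                             kf = 1, mf = 0.001, Pb = 1,
                             starts = 20L, seed = 0L) {
  variants <- union("PHYS", variants)
  rows <- list()
  for (kpt in kpt_grid) {
    cond <- qc_conditions(kpt = kpt, mf = mf, kf = kf, Pb = Pb)
    fm <- stats::setNames(rep(NA_real_, length(variants)), variants)
    stt <- stats::setNames(rep("error", length(variants)), variants)
    for (vn in variants) {
      res <- tryCatch(
        folding_efficiency(qc_problem(vn, cond, starts = starts,
                                      seed = seed)),
        error = function(e) NULL)
      if (!is.null(res)) {
        fm[vn] <- res$objective
        stt[vn] <- res$status
      }
    }
    for (vn in variants) {
      rows[[length(rows) + 1L]] <- data.frame(
        kpt = kpt, variant = vn, fmax_star = fm[vn], status = stt[vn],
        ratio_to_phys = fm[vn] / fm["PHYS"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Robustness of a fixed parameter set to changing production
#'
#' Optimizes the pathway at each anchor production rate, freezes the
#' resulting rates, and evaluates performance over an evaluation grid of
#' production rates, optionally letting only the degradation rate `kd`
#' re-adapt ([adjust_kd()]).  The optimal efficiency reference `f_max` is
#' recomputed at every evaluation point.
#'
#' @param anchors Production rates at which the rates are optimized.
#' @param eval_grid Production rates at which the frozen system is evaluated.
#' @param adapt_kd If TRUE, `kd` is re-fit at each evaluation point to hold
#'   `P_unfolded` at one.
#' @param variant Variant name (default PHYS).
#' @param kf,mf,Pb Remaining conditions.
#' @param starts,seed Multistart settings.
#' @return Data frame with columns `anchor_kpt`, `kpt`, `f`, `fmax_star`,
#'   `f_rel` (= f / fmax_star), `Pu`, `kd`, `exists`.
#' @export
robustness <- function(anchors, eval_grid, adapt_kd = FALSE,
                       variant = "PHYS", kf = 1, mf = 0.001, Pb = 1,
                       starts = 20L, seed = 0L) {
  v <- qc_variant(variant)
  # reference efficiency at each evaluation point (shared across anchors)
  ref <- stats::setNames(rep(NA_real_, length(eval_grid)),
                         format(eval_grid))
  for (j in seq_along(eval_grid)) {
    res <- tryCatch(
      folding_efficiency(qc_problem(v, qc_conditions(eval_grid[j], mf, kf,
                                                     Pb),
                                    starts = starts, seed = seed)),
      error = function(e) NULL)
    if (!is.null(res)) ref[j] <- res$objective
  }
  rows <- list()
  for (a in anchors) {
    opt <- folding_efficiency(qc_problem(v, qc_conditions(a, mf, kf, Pb),
                                         starts = starts, seed = seed))
    fixed <- opt$best_rates
    for (j in seq_along(eval_grid)) {
      cond <- qc_conditions(eval_grid[j], mf, kf, Pb)
      other <- fixed[setdiff(names(fixed), "kd")]
      vp <- variant_pin(v, other)
      rts <- assemble_rates(vp, cond, fixed["kd"])
      if (adapt_kd) {
        ad <- adjust_kd(rts)
        kd_used <- ad$kd
        ss <- ad$steady
      } else {
        kd_used <- fixed[["kd"]]
        ss <- solve_steady_state(rts)
      }
      f <- if (ss$exists) folding_fraction(ss$state, rts) else NA_real_
      pu <- if (ss$exists) {
        if (adapt_kd) ad$Pu else total_unfolded(ss$state)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        anchor_kpt = a, kpt = eval_grid[j], f = f, fmax_star = ref[j],
        f_rel = f / ref[j], Pu = pu, kd = kd_used, exists = ss$exists)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Folding efficiency as a function of cycle driving energy
#'
#' Runs [energy_constrained_efficiency()] over an energy grid for each
#' supplied condition set (full model), producing the data behind
#' energy-performance curves.
#'
#' @param conditions_list List of `qc_conditions`.
#' @param E_grid Vector of cycle energies (kT).
#' @param starts,seed Multistart settings.
#' @return Data frame with the conditions, `E`, `fmax_star`, achieved
#'   constraint residual and status per row.
#' @export
energy_curves <- function(conditions_list, E_grid, starts = 20L, seed = 0L) {
  if (inherits(conditions_list, "qc_conditions"))
    conditions_list <- list(conditions_list)
  rows <- list()
  for (cond in conditions_list) {
    pr <- qc_problem("FULL", cond, starts = starts, seed = seed)
    for (E in E_grid) {
      res <- tryCatch(energy_constrained_efficiency(pr, E),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        kpt = cond$kpt, mf = cond$mf, kf = cond$kf, Pb = cond$Pb, E = E,
        fmax_star = if (is.null(res)) NA_real_ else res$objective,
        constraint_residual = if (is.null(res)) NA_real_ else
          res$constraint_residual,
        status = if (is.null(res)) "error" else res$status)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Steady-state populations along a single-rate sweep
#'
#' Holds all rates fixed except one, which is swept over a grid; returns the
#' steady-state concentrations at each value (e.g. chaperone occupancy by
#' unfolded versus already-folded proteins as the untrimmed unbinding rate
#' `kmc` varies).
#'
#' @param rates Full rate set.
#' @param name Rate to sweep (one of the adjustable rate names).
#' @param grid Values for the swept rate.
#' @return Data frame with the swept value, the eight concentrations, `CA`,
#'   and `exists`.
#' @export
sweep_states <- function(rates, name, grid) {
  stopifnot(name %in% .RATE_NAMES)
  r <- as.numeric(rates[.RATE_NAMES])
  i <- match(name, .RATE_NAMES)
  rows <- vector("list", length(grid))
  for (j in seq_along(grid)) {
    r[i] <- grid[j]
    core <- .steady_core(r)
    s <- if (core$exists) core$state else rep(NA_real_, 8L)
    row <- data.frame(value = grid[j], t(s), CA = core$CA,
                      exists = core$exists)
    names(row) <- c(name, .STATE_NAMES, "CA", "exists")
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}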