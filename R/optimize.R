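# Constrained optimization of cycle performance.
#
# All optimizations run over log10-transformed free rates inside the
# admissible box (default [1e-3, 1e3]), with Latin-hypercube multistarts and
# a Nelder-Mead search polished by L-BFGS-B.  Equality constraints (fixed
# folding fraction, fixed cycle energy) are handled by an augmented
# Lagrangian; the protein-load constraint P_unfolded = 1 is imposed through
# bisection on the folding-fraction target, mirroring the two-regime
# structure of the feasible set.

#' Define an optimization problem
#'
#' @param variant A `qc_variant` or variant name.
#' @param conditions A `qc_conditions` object.
#' @param bounds Length-2 admissible range for every free rate
#'   (default `c(1e-3, 1e3)`).
#' @param starts Number of Latin-hypercube multistarts (default 20).
#' @param seed RNG seed controlling the multistarts (default 0).
#' @return Object of class `qc_problem`.
#' @export
qc_problem <- function(variant, conditions, bounds = c(1e-3, 1e3),
                       starts = 20L, seed = 0L) {
  if (is.character(variant)) variant <- qc_variant(variant)
  stopifnot(inherits(variant, "qc_variant"),
            inherits(conditions, "qc_conditions"),
            length(bounds) == 2L, bounds[1] > 0, bounds[2] > bounds[1],
            starts >= 1L)
  structure(list(variant = variant, conditions = conditions,
                 bounds = bounds, starts = as.integer(starts),
                 seed = as.integer(seed)),
            class = "qc_problem")
}

# Precomputed template for fast objective evaluation: full rate vector with
# fixed entries filled, plus indices of the free rates.
.make_template <- function(variant, conditions) {
  r0 <- stats::setNames(numeric(length(.RATE_NAMES)), .RATE_NAMES)
  r0["kr"] <- 1
  r0[names(variant$fixed_other)] <- variant$fixed_other
  r0[variant$fixed_zero] <- 0
  r0["kf"]  <- conditions$kf
  r0["kp"]  <- (1 - conditions$mf) * conditions$kpt
  r0["kps"] <- conditions$mf * conditions$kpt
  r0["Pb"]  <- conditions$Pb
  list(r0 = as.numeric(r0), idx = match(variant$free_rates, .RATE_NAMES),
       free = variant$free_rates, kp = r0[["kp"]], kf = r0[["kf"]])
}

# Steady-state metrics at log10 free-rate values; exists=FALSE on
# infeasibility.
.metrics_at <- function(theta, tmpl) {
  r <- tmpl$r0
  r[tmpl$idx] <- 10^theta
  core <- .steady_core(r)
  if (!core$exists) return(list(exists = FALSE))
  s <- core$state
  list(exists = TRUE,
       f = tmpl$kf * s[2L] / tmpl$kp,
       Pu = s[1L] + s[2L] + s[4L] + s[5L] + s[6L] + s[7L],
       E = {
         revr <- r[c(2L, 4L, 6L)]
         if (any(revr == 0)) Inf else
           log(r[1L] * r[3L] * r[5L] / prod(revr))
       },
       core = core, rates = r)
}

# Latin-hypercube multistart of a scalar objective over the log10 box.
# Returns list(par, value, n_converged, values).
.multistart <- function(fn, d, lb, ub, starts, seed, warm = NULL) {
  set.seed(seed)
  pts <- lhs::randomLHS(max(starts, 1L), d)
  pts <- sweep(sweep(pts, 2L, ub - lb, "*"), 2L, lb, "+")
  if (!is.null(warm)) pts <- rbind(matrix(warm, ncol = d, byrow = TRUE), pts)
  clamp <- function(x) pmin(pmax(x, lb), ub)
  best <- NULL
  values <- numeric(0)
  n_conv <- 0L
  for (i in seq_len(nrow(pts))) {
    fit <- tryCatch({
      nm <- stats::optim(pts[i, ], function(x) fn(clamp(x)),
                         method = "Nelder-Mead",
                         control = list(maxit = 500L, reltol = 1e-12))
      p0 <- clamp(nm$par)
      pol <- tryCatch(
        stats::optim(p0, fn, method = "L-BFGS-B", lower = lb, upper = ub,
                     control = list(maxit = 200L, factr = 1e4,
                                    ndeps = rep(1e-7, d))),
        error = function(e) NULL)
      if (!is.null(pol) && pol$value < nm$value)
        list(par = pol$par, value = pol$value)
      else list(par = p0, value = nm$value)
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    n_conv <- n_conv + 1L
    values <- c(values, fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed: no start converged")
  c(best, list(n_converged = n_conv, values = values))
}

.opt_result <- function(tmpl, theta, problem, objective, constraint_residual,
                        status = "ok") {
  m <- .metrics_at(theta, tmpl)
  steady <- .make_result(m$core)
  structure(list(
    best_rates = stats::setNames(10^theta, tmpl$free),
    objective = objective, f = m$f, Pu = m$Pu,
    constraint_residual = constraint_residual,
    steady = steady, status = status,
    variant = problem$variant$name, conditions = problem$conditions,
    starts = problem$starts, seed = problem$seed),
    class = "qc_opt")
}

#' @export
print.qc_opt <- function(x, ...) {
  cat(sprintf("%s optimization (%s): objective = %.6g, f = %.6g, Pu = %.6g\n",
              x$variant, x$status, x$objective, x$f, x$Pu))
  cat("rates:", paste(sprintf("%s=%.4g", names(x$best_rates), x$best_rates),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Maximum folding fraction, unconstrained by protein load
#'
#' Maximizes the steady-state folding fraction `f` over the variant's free
#' rates, with no constraint on the total unfolded protein.
#'
#' @param problem A `qc_problem`.
#' @return A `qc_opt` result with `objective = f`.
#' @export
max_folding_fraction <- function(problem) {
  tmpl <- .make_template(problem$variant, problem$conditions)
  d <- length(tmpl$idx)
  lb <- rep(log10(problem$bounds[1]), d)
  ub <- rep(log10(problem$bounds[2]), d)
  fn <- function(theta) {
    m <- .metrics_at(theta, tmpl)
    if (!m$exists) return(2)
    -m$f
  }
  fit <- .multistart(fn, d, lb, ub, problem$starts, problem$seed)
  res <- .opt_result(tmpl, fit$par, problem, objective = -fit$value,
                     constraint_residual = 0)
  res$n_converged <- fit$n_converged
  res
}

# Augmented-Lagrangian minimization of `base` subject to equality
# constraints given as list of functions returning (achieved - target),
# with per-constraint tolerances.  Returns the .multistart fit augmented
# with achieved violations.
.auglag <- function(base_fn, cons_fns, tols, d, lb, ub, starts, seed,
                    warm = NULL, rounds = 8L, w0 = 1e3) {
  k <- length(cons_fns)
  lam <- numeric(k)
  w <- rep(w0, k)
  # combined evaluation used by the inner solver
  make_fn <- function(lam, w) {
    function(theta) {
      ev <- base_fn(theta)
      if (!is.finite(ev$base)) return(1e8)
      pen <- 0
      for (j in seq_len(k)) {
        cj <- ev$cons[j]
        pen <- pen + lam[j] * cj + 0.5 * w[j] * cj^2
      }
      ev$base + pen
    }
  }
  best <- NULL
  prev_viol <- rep(Inf, k)
  cur_warm <- warm
  cur_starts <- starts
  for (round in seq_len(rounds)) {
    fit <- .multistart(make_fn(lam, w), d, lb, ub, cur_starts,
                       seed + round - 1L, warm = cur_warm)
    ev <- base_fn(fit$par)
    viol <- abs(ev$cons)
    if (is.null(best) ||
        (all(viol <= pmax(tols, best$viol)) &&
         (any(best$viol > tols) || ev$base < best$base))) {
      best <- list(par = fit$par, base = ev$base, viol = viol,
                   n_converged = fit$n_converged)
    }
    if (all(viol <= tols)) break
    lam <- lam + w * ev$cons
    w <- ifelse(viol > 0.3 * prev_viol, w * 8, w)
    prev_viol <- viol
    cur_warm <- rbind(cur_warm, fit$par)
    cur_starts <- max(4L, starts %/% 4L)
  }
  best
}

#' Minimum unfolded protein at fixed folding fraction
#'
#' Minimizes `P_unfolded` over the free rates subject to the equality
#' `f = f_target` (tolerance `1e-4`), one point of the accuracy-speed Pareto
#' frontier.
#'
#' @param problem A `qc_problem`.
#' @param f_target Target folding fraction in (0, max f\].
#' @param warm Optional matrix of warm-start points in log10 space
#'   (internal use by the bisection driver).
#' @return A `qc_opt` result with `objective = P_unfolded`; an unattainable
#'   target is reported with `status = "infeasible"`, not an error.
#' @export
min_unfolded_given_f <- function(problem, f_target, warm = NULL) {
  stopifnot(is.numeric(f_target), length(f_target) == 1L, f_target > 0)
  tmpl <- .make_template(problem$variant, problem$conditions)
  d <- length(tmpl$idx)
  lb <- rep(log10(problem$bounds[1]), d)
  ub <- rep(log10(problem$bounds[2]), d)
  base_fn <- function(theta) {
    m <- .metrics_at(theta, tmpl)
    if (!m$exists) return(list(base = Inf, cons = 1))
    list(base = m$Pu, cons = m$f - f_target)
  }
  fit <- .auglag(base_fn, list(NULL), tols = 1e-4, d = d, lb = lb, ub = ub,
                 starts = problem$starts, seed = problem$seed, warm = warm)
  status <- if (fit$viol <= 1e-4) "ok" else "infeasible"
  res <- .opt_result(tmpl, fit$par, problem, objective = fit$base,
                     constraint_residual = fit$viol, status = status)
  res$n_converged <- fit$n_converged
  res
}

#' Folding efficiency: maximum f at unit unfolded-protein load
#'
#' Computes `f*max`, the maximum folding fraction subject to
#' `P_unfolded = 1`, by bisection on the folding-fraction target: each
#' candidate target is checked by minimizing `P_unfolded` at that fixed `f`
#' ([min_unfolded_given_f()]) until the minimized load falls in the
#' acceptance window `(0.99, 1.01)`.  If even the unconstrained maximum
#' folding fraction can be reached with `P_unfolded <= 1.01`, the load
#' constraint is slack and that maximum is returned.
#'
#' @param problem A `qc_problem`.
#' @param window Acceptance window on the achieved `P_unfolded`
#'   (default `c(0.99, 1.01)`).
#' @param max_iter Maximum bisection iterations (default 60).
#' @return A `qc_opt` result with `objective = f*max`; if the pathway cannot
#'   bring `P_unfolded` near 1 the result carries `status = "infeasible"`
#'   with a diagnosis.
#' @export
folding_efficiency <- function(problem, window = c(0.99, 1.01),
                               max_iter = 60L) {
  unc <- max_folding_fraction(problem)
  f_hi <- unc$objective
  theta_hi <- log10(unc$best_rates)
  at_hi <- min_unfolded_given_f(problem, f_hi, warm = rbind(theta_hi))
  if (at_hi$status == "ok" && at_hi$objective <= window[2]) {
    at_hi$objective <- f_hi
    at_hi$status <- "ok"
    return(at_hi)
  }
  lo <- 0
  hi <- f_hi
  best <- NULL
  warm <- rbind(theta_hi, log10(at_hi$best_rates))
  sub <- problem
  sub$starts <- max(4L, problem$starts %/% 4L)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    res <- min_unfolded_given_f(sub, mid, warm = warm)
    if (res$status != "ok") {
      # an unattainable target can lie below the pathway's feasible
      # folding-fraction floor (e.g. designs where every bound protein
      # folds with probability >= kf/(kf+kr)) as well as above its
      # ceiling; the achieved f tells the two apart
      if (is.finite(res$f) && res$f > mid) lo <- mid else hi <- mid
      next
    }
    warm <- utils::tail(rbind(warm, log10(res$best_rates)), 6L)
    if (res$objective > window[2]) {
      hi <- mid
    } else {
      lo <- mid
      best <- res
      if (res$objective > window[1]) {
        best$objective <- mid
        return(best)
      }
    }
    if (hi - lo < 1e-8) break
  }
  if (is.null(best)) {
    res <- min_unfolded_given_f(sub, lo + (hi - lo) / 2, warm = warm)
    res$status <- "infeasible"
    res$objective <- NA_real_
    return(res)
  }
  # the window was never hit exactly; report the largest target whose
  # minimized load stays below the upper edge
  best$objective <- lo
  best$status <- if (best$Pu > window[1] || best$Pu <= window[2]) "ok" else
    "infeasible"
  best
}

#' Energy-constrained folding efficiency
#'
#' Maximizes the folding fraction of the full cycle subject to a fixed cycle
#' driving energy `E` (tolerance `1e-3`) and unit unfolded-protein load
#' (`P_unfolded` within `(0.99, 1.01)`), via an augmented Lagrangian over
#' all six free cycle rates.
#'
#' @param problem A `qc_problem` with the `FULL` variant (all reverse rates
#'   free, so the energy is finite).
#' @param E Target cycle energy in kT, >= 0.
#' @return A `qc_opt` result with `objective = f`.
#' @export
energy_constrained_efficiency <- function(problem, E) {
  stopifnot(problem$variant$name == "FULL", is.numeric(E), E >= 0)
  tmpl <- .make_template(problem$variant, problem$conditions)
  d <- length(tmpl$idx)
  lb <- rep(log10(problem$bounds[1]), d)
  ub <- rep(log10(problem$bounds[2]), d)
  base_fn <- function(theta) {
    m <- .metrics_at(theta, tmpl)
    if (!m$exists || !is.finite(m$E))
      return(list(base = Inf, cons = c(1, 1)))
    list(base = -m$f, cons = c(m$E - E, m$Pu - 1))
  }
  # warm starts satisfying the energy constraint exactly: solve for kmg
  ikmg <- match("kmg", tmpl$free)
  ikc <- match("kc", tmpl$free); ikmc <- match("kmc", tmpl$free)
  ikmr <- match("kmr", tmpl$free); ikg <- match("kg", tmpl$free)
  set.seed(problem$seed + 1000L)
  w0 <- lhs::randomLHS(problem$starts, d)
  w0 <- sweep(sweep(w0, 2L, ub - lb, "*"), 2L, lb, "+")
  kmg_e <- w0[, ikc] + w0[, ikg] - w0[, ikmc] - w0[, ikmr] - E / log(10)
  w0[, ikmg] <- pmin(pmax(kmg_e, lb[ikmg]), ub[ikmg])
  fit <- .auglag(base_fn, list(NULL, NULL), tols = c(1e-3, 1e-2),
                 d = d, lb = lb, ub = ub, starts = problem$starts,
                 seed = problem$seed, warm = w0)
  status <- if (all(fit$viol <= c(1e-3, 1e-2))) "ok" else "infeasible"
  res <- .opt_result(tmpl, fit$par, problem, objective = -fit$base,
                     constraint_residual = max(fit$viol), status = status)
  res$n_converged <- fit$n_converged
  res$E_target <- E
  res
}

#' Adapt the degradation rate to hold the unfolded-protein load at one
#'
#' With all other rates frozen, bisects the degradation rate `kd` over
#' `[1e-3, 1e3]` (in log space) to bring `P_unfolded` into the window
#' `(0.99, 1.01)`, exploiting the monotone decrease of the load in `kd`
#' (verified on the bracket; a grid search is used as fallback if the
#' endpoints are non-monotone).  When the window is unattainable, `kd` is
#' set to the value minimizing `P_unfolded`: the upper bound when even
#' maximal degradation leaves the load above one.
#'
#' @param rates Full rate set; its `kd` entry is replaced by the search.
#' @param bounds Search range for `kd` (default `c(1e-3, 1e3)`).
#' @param window Target window for `P_unfolded`.
#' @return List with `kd`, `Pu`, `in_window` (logical), and `steady`
#'   (the `qc_steady` at the returned `kd`).
#' @export
adjust_kd <- function(rates, bounds = c(1e-3, 1e3), window = c(0.99, 1.01)) {
  r <- as.numeric(rates[.RATE_NAMES])
  ikd <- match("kd", .RATE_NAMES)
  pu_at <- function(lkd) {
    r[ikd] <- 10^lkd
    core <- .steady_core(r)
    if (!core$exists) return(Inf)
    s <- core$state
    s[1L] + s[2L] + s[4L] + s[5L] + s[6L] + s[7L]
  }
  lo <- log10(bounds[1]); hi <- log10(bounds[2])
  pu_lo <- pu_at(lo); pu_hi <- pu_at(hi)
  finish <- function(lkd) {
    r[ikd] <- 10^lkd
    core <- .steady_core(r)
    pu <- if (core$exists) {
      s <- core$state
      s[1L] + s[2L] + s[4L] + s[5L] + s[6L] + s[7L]
    } else Inf
    list(kd = 10^lkd, Pu = pu,
         in_window = is.finite(pu) && pu > window[1] && pu < window[2],
         steady = .make_result(core))
  }
  if (!is.finite(pu_hi)) {
    # no steady state even at maximal degradation
    res <- finish(hi)
    res$in_window <- FALSE
    return(res)
  }
  if (pu_hi > window[2]) return(finish(hi))   # minimize the excess load
  if (pu_lo < window[1]) return(finish(lo))   # load below target everywhere
  if (pu_lo < pu_hi) {
    # non-monotone bracket: locate the crossing by grid scan
    grid <- seq(lo, hi, length.out = 61L)
    pu_g <- vapply(grid, pu_at, numeric(1))
    k <- which(pu_g > window[1] & pu_g < window[2])
    if (length(k)) return(finish(grid[k[1L]]))
    k <- which.min(abs(log(pmax(pu_g, 1e-300))))
    return(finish(grid[k]))
  }
  for (it in seq_len(80L)) {
    mid <- (lo + hi) / 2
    pu <- pu_at(mid)
    if (is.finite(pu) && pu > window[1] && pu < window[2])
      return(finish(mid))
    if (!is.finite(pu) || pu > 1) lo <- mid else hi <- mid
  }
  finish((lo + hi) / 2)
}

#' Pareto frontier of folding fraction versus unfolded protein
#'
#' Minimizes `P_unfolded` at each folding-fraction target of an increasing
#' grid; infeasible targets are flagged in the output, never dropped.
#'
#' @param problem A `qc_problem`.
#' @param f_grid Increasing vector of folding-fraction targets in (0, 1).
#' @return A data frame with columns `f_target`, `P_unfolded`, `feasible`,
#'   the optimal free rates, and `constraint_residual`.
#' @export
pareto_frontier <- function(problem, f_grid) {
  if (!length(f_grid)) stop("'f_grid' must contain at least one target")
  stopifnot(all(diff(f_grid) > 0) || length(f_grid) == 1L,
            all(f_grid > 0), all(f_grid < 1))
  warm <- NULL
  rows <- vector("list", length(f_grid))
  for (i in seq_along(f_grid)) {
    res <- min_unfolded_given_f(problem, f_grid[i], warm = warm)
    if (res$status == "ok") warm <- rbind(warm, log10(res$best_rates))
    rows[[i]] <- data.frame(
      f_target = f_grid[i],
      P_unfolded = if (res$status == "ok") res$objective else NA_real_,
      feasible = res$status == "ok",
      constraint_residual = res$constraint_residual,
      as.list(res$best_rates))
  }
  do.call(rbind, rows)
}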