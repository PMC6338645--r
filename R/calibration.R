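# Constraint-based calibration: the published fold-changes are encoded as
# model-readout targets and one parameter set per system is fitted by
# bounded multistart least squares in log-parameter space.

#' Built-in calibration constraints
#'
#' The published quantitative statements of each experimental system as
#' fitting targets. Human cell line (100 uM TBHP, sustained): AMPK mRNA down
#' to 41\% and NRF2 mRNA up to 194\% of control at 4 h; a 5-fold
#' autophagosome peak returning to at most 1.5x basal by 4 h; peak total AMPK
#' protein between 4- and 9-fold (two inequality rows); 7-fold higher basal
#' AMPK under NRF2 silencing. Worm (1 mM TBHP, 3 h): GFP::LGG-1 readout at
#' 20\% (wild type), 60\% (aak-2 null) and 67\% (skn-1 RNAi) of the untreated
#' level.
#'
#' @param system \code{"human_cell"} or \code{"worm"}.
#' @return data.frame with columns \code{id}, \code{system}, \code{condition},
#'   \code{readout}, \code{time}, \code{target}, \code{tol}, \code{weight},
#'   \code{cmp} (\code{eq}, \code{ge} or \code{le}).
#' @export
builtin_constraints <- function(system) {
  if (length(system) != 1 || !system %in% c("human_cell", "worm")) {
    stop("unknown system '", paste(system, collapse = ","),
         "'; valid systems: human_cell, worm")
  }
  if (system == "human_cell") {
    data.frame(
      id = c("hc_mA_4h", "hc_mN_4h", "hc_L_peak", "hc_L_return",
             "hc_A_peak_lo", "hc_A_peak_hi", "hc_basalA_ratio"),
      system = "human_cell",
      condition = c("WT", "WT", "WT", "WT", "WT", "WT", "siNRF2"),
      readout = c("rel_mA", "rel_mN", "peak_rel_L", "rel_L", "peak_rel_A",
                  "peak_rel_A", "basal_A_ratio"),
      time = c(4, 4, NA, 4, NA, NA, NA),
      target = c(0.41, 1.94, 5, 1.5, 4, 9, 7),
      tol = 0.10,
      weight = 1,
      cmp = c("eq", "eq", "eq", "le", "ge", "le", "eq"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      id = c("wm_L_3h_WT", "wm_L_3h_aak2", "wm_L_3h_skn1"),
      system = "worm",
      condition = c("WT", "aak2_null", "skn1_RNAi"),
      readout = "rel_L",
      time = 3,
      target = c(0.20, 0.60, 0.67),
      tol = 0.10,
      weight = 1,
      cmp = "eq",
      stringsAsFactors = FALSE
    )
  }
}

# Evaluate every constraint readout for one parameter set. Conditions are
# simulated once each; basal_A_ratio uses closed-form steady states.
eval_constraints <- function(params, constraints, dose = 1, dt = 0.01) {
  t_end <- max(c(constraints$time,
                 if (any(grepl("^peak_", constraints$readout))) 4), na.rm = TRUE)
  grid <- seq(0, t_end, by = dt)
  conds <- unique(constraints$condition[constraints$readout != "basal_A_ratio"])
  trajs <- lapply(conds, function(cc) {
    simulate_model(params, strsplit(cc, "+", fixed = TRUE)[[1]],
                   dose = dose, t_grid = grid)
  })
  names(trajs) <- conds
  basal_WT <- NULL
  vapply(seq_len(nrow(constraints)), function(i) {
    ci <- constraints[i, ]
    if (ci$readout == "basal_A_ratio") {
      if (is.null(basal_WT)) {
        basal_WT <<- steady_state(apply_condition(params, "WT"))[["A"]]
      }
      ss <- steady_state(apply_condition(
        params, strsplit(ci$condition, "+", fixed = TRUE)[[1]]))
      ss[["A"]] / basal_WT
    } else {
      readout(trajs[[ci$condition]], ci$readout,
              t = if (is.na(ci$time)) NULL else ci$time)
    }
  }, numeric(1))
}

# Signed weighted residual per constraint; inequality rows contribute zero
# when satisfied.
constraint_residuals <- function(values, constraints) {
  vapply(seq_len(nrow(constraints)), function(i) {
    ci <- constraints[i, ]
    relerr <- (values[i] - ci$target) / ci$target
    r <- switch(ci$cmp,
      eq = relerr,
      ge = min(0, relerr),
      le = max(0, relerr),
      stop("unknown cmp '", ci$cmp, "'")
    )
    sqrt(ci$weight) * r
  }, numeric(1))
}

#' Calibration objective
#'
#' Weighted sum of squared relative residuals over the constraints; an
#' inequality constraint contributes zero when satisfied. Integration
#' failures are mapped to a large finite penalty (1e6).
#'
#' @param params A \code{param_set}.
#' @param constraints Constraint table (see \code{\link{builtin_constraints}}).
#' @param dose Stress dose for the constraint simulations.
#' @return Nonnegative scalar.
#' @export
calibration_objective <- function(params, constraints, dose = 1) {
  values <- tryCatch(eval_constraints(params, constraints, dose = dose),
                     error = function(e) NULL)
  if (is.null(values)) return(1e6)
  sum(constraint_residuals(values, constraints)^2)
}

# default free (identifiable) parameter subsets, one knob per equality target
default_free_params <- function(system) {
  switch(system,
    human_cell = c("d_mA", "c_N", "u0", "K_N"),
    worm = c("e_L", "d_A", "e_A"),
    stop("unknown system '", system, "'")
  )
}

#' Fit the feedback model to calibration constraints
#'
#' Multistart bounded least squares (Levenberg-Marquardt via
#' \code{minpack.lm::nls.lm}) in log-parameter space over a declared free
#' (identifiable) parameter subset; the remaining parameters stay at
#' \code{start}. The first start is \code{start} itself; subsequent starts
#' are log-normal jitters of it, deterministic given \code{seed}. The fit is
#' converged iff every equality constraint lies within its relative tolerance
#' and every inequality is satisfied.
#'
#' @param system \code{"human_cell"} or \code{"worm"}.
#' @param constraints Constraint table; defaults to
#'   \code{builtin_constraints(system)}.
#' @param start Starting \code{param_set}; defaults to
#'   \code{default_parameters(system)}.
#' @param free Names of parameters to fit.
#' @param n_starts Number of multistarts (>= 1).
#' @param seed Integer seed for the multistart jitter.
#' @param lower,upper Box bounds on every free rate.
#' @param dose Stress dose used in the constraint simulations.
#' @return A \code{feedback_fit} object.
#' @export
feedback_fit <- function(system, constraints = builtin_constraints(system),
                         start = default_parameters(system),
                         free = default_free_params(system),
                         n_starts = 5, seed = 20181002,
                         lower = 1e-3, upper = 1e3, dose = 1) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  stopifnot(all(free %in% MODEL_PARAMS), all(start[free] > 0))
  resid_fun <- function(logp) {
    p <- start
    p[free] <- exp(logp)
    values <- tryCatch(eval_constraints(p, constraints, dose = dose),
                       error = function(e) NULL)
    if (is.null(values)) return(rep(1e3, nrow(constraints)))
    constraint_residuals(values, constraints)
  }
  log_lo <- rep(log(lower), length(free))
  log_hi <- rep(log(upper), length(free))
  base_log <- pmin(pmax(log(start[free]), log_lo), log_hi)
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(k) {
    if (k == 1) return(base_log)
    pmin(pmax(base_log + stats::rnorm(length(free), 0, 0.7), log_lo), log_hi)
  }))
  best <- NULL
  for (k in seq_len(n_starts)) {
    ans <- minpack.lm::nls.lm(
      par = starts[[k]], fn = resid_fun, lower = log_lo, upper = log_hi,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-10))
    obj <- sum(ans$fvec^2)
    if (is.null(best) || obj < best$obj) best <- list(ans = ans, obj = obj)
    if (best$obj < 1e-10) break
  }
  fitted <- start
  fitted[free] <- exp(best$ans$par)
  values <- eval_constraints(fitted, constraints, dose = dose)
  resid <- constraint_residuals(values, constraints)
  ok_eq <- constraints$cmp != "eq" |
    abs(values - constraints$target) / constraints$target <= constraints$tol
  ok_ge <- constraints$cmp != "ge" | values >= constraints$target * (1 - 1e-9)
  ok_le <- constraints$cmp != "le" | values <= constraints$target * (1 + 1e-9)
  structure(list(
    system = system, params = param_set(fitted), start = start, free = free,
    constraints = transform(constraints, value = values, residual = resid),
    objective = sum(resid^2),
    converged = all(ok_eq & ok_ge & ok_le),
    n_starts = n_starts, seed = seed, dose = dose,
    niter = best$ans$niter
  ), class = "feedback_fit")
}

#' @export
print.feedback_fit <- function(x, ...) {
  cat(sprintf("<feedback_fit> system %s: %d constraints, objective %.3e, %s\n",
              x$system, nrow(x$constraints), x$objective,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.feedback_fit <- function(object, ...) {
  cat(sprintf("Feedback-model calibration, system '%s'\n", object$system))
  cat(sprintf("Free parameters (%d): %s\n", length(object$free),
              paste(object$free, collapse = ", ")))
  cat(sprintf("Objective %.3e over %d constraints; %s after %d starts\n\n",
              object$objective, nrow(object$constraints),
              if (object$converged) "converged" else "NOT converged",
              object$n_starts))
  print(object$constraints[, c("id", "condition", "readout", "time", "cmp",
                               "target", "value", "residual")],
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.feedback_fit <- function(object, ...) {
  unclass(object$params)
}

#' @export
residuals.feedback_fit <- function(object, ...) {
  stats::setNames(object$constraints$residual, object$constraints$id)
}

#' Predict (simulate) trajectories from a calibrated fit
#'
#' @param object A \code{feedback_fit}.
#' @param condition Condition name(s).
#' @param dose Stress dose.
#' @param t_grid Output time grid (hours).
#' @param ... Unused.
#' @return A \code{model_trajectory}.
#' @export
predict.feedback_fit <- function(object, condition = "WT", dose = 1,
                                 t_grid = seq(0, 6, by = 0.01), ...) {
  simulate_model(object$params, condition, dose = dose, t_grid = t_grid)
}

#' Plot calibrated trajectories
#'
#' Base-graphics time courses of the relative state variables under sustained
#' stress for one or more conditions.
#'
#' @param x A \code{feedback_fit}.
#' @param condition Conditions to draw.
#' @param dose Stress dose.
#' @param t_end Simulation horizon (hours).
#' @param vars States to draw (relative to their own t = 0 level).
#' @param ... Passed to \code{matplot}.
#' @export
plot.feedback_fit <- function(x, condition = "WT", dose = 1, t_end = 6,
                              vars = c("mA", "A", "Ap", "N", "U", "L"), ...) {
  old <- graphics::par(mfrow = c(1, length(condition)))
  on.exit(graphics::par(old))
  for (cc in condition) {
    tr <- predict(x, cc, dose = dose, t_grid = seq(0, t_end, by = 0.01))
    rel <- sweep(as.matrix(tr[vars]), 2, as.numeric(tr[1, vars]), "/")
    graphics::matplot(tr$time, rel, type = "l", lty = 1, lwd = 2,
                      xlab = "time (h)", ylab = "level relative to t = 0",
                      main = paste(cc, "dose", dose), ...)
    graphics::legend("topright", legend = vars, col = seq_along(vars),
                     lty = 1, lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Simulate synthetic densitometry replicates from a fit
#'
#' Draws seeded lognormal-noise densitometry tables (see
#' \code{\link{gen_densitometry}}) from the calibrated model under WT and
#' NRF2-silenced conditions.
#'
#' @param object A \code{feedback_fit}.
#' @param nsim Number of tables.
#' @param seed Integer seed.
#' @param noise_sd Lognormal sigma.
#' @param dose Stress dose.
#' @param ... Unused.
#' @return A list of densitometry data.frames (length \code{nsim}).
#' @export
simulate.feedback_fit <- function(object, nsim = 1, seed = 1, noise_sd = 0.2,
                                  dose = 1, ...) {
  grid <- seq(0, 4, by = 0.01)
  sil <- if (object$system == "human_cell") "siNRF2" else "skn1_RNAi"
  trajs <- list(WT = predict(object, "WT", dose = dose, t_grid = grid))
  trajs[[sil]] <- predict(object, sil, dose = dose, t_grid = grid)
  lapply(seq_len(nsim), function(k) {
    gen_densitometry(trajs, noise_sd = noise_sd,
                     seed = derive_seed(seed, k))
  })
}

#' Parameter-recovery experiment
#'
#' Standard practice for a reconstructed model: equality-constraint targets
#' are recomputed from a known parameter set, perturbed with multiplicative
#' lognormal noise, and the identifiable subset is refitted from a jittered
#' start; the relative error of each recovered parameter is recorded.
#'
#' @param theta_star True \code{param_set}.
#' @param system System the constraints belong to.
#' @param noise_sd Lognormal sigma on the targets (0 = noiseless).
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param free Identifiable subset to recover.
#' @param constraints Constraint table whose equality targets are regenerated
#'   from \code{theta_star}.
#' @return data.frame (rep x parameter) of relative errors, with the median
#'   absolute relative error as attribute \code{"median_rel_error"}.
#' @export
recovery_experiment <- function(theta_star, system, noise_sd = 0.1,
                                n_reps = 20, seed = 1,
                                free = default_free_params(system),
                                constraints = builtin_constraints(system)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  true_vals <- eval_constraints(theta_star, constraints)
  eq <- constraints$cmp == "eq"
  rows <- lapply(seq_len(n_reps), function(r) {
    cons_r <- constraints
    cons_r$target[eq] <- with_seed(derive_seed(seed, 2 * r), {
      true_vals[eq] * exp(stats::rnorm(sum(eq), 0, noise_sd))
    })
    start_r <- theta_star
    start_r[free] <- with_seed(derive_seed(seed, 2 * r + 1), {
      theta_star[free] * exp(stats::rnorm(length(free), 0, 0.2))
    })
    fit <- feedback_fit(system, constraints = cons_r, start = start_r,
                        free = free, n_starts = 1, seed = derive_seed(seed, r))
    rel_err <- (fit$params[free] - theta_star[free]) / theta_star[free]
    as.data.frame(as.list(stats::setNames(rel_err, free)))
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(rep = seq_len(n_reps), tab)
  attr(tab, "median_rel_error") <- stats::median(abs(unlist(tab[, free])))
  tab
}
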