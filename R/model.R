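# Deterministic ODE model of the stress -> AMPK -> NRF2 -> (delayed AMPK
# repression) -> autophagy network, with genotype/knockdown perturbations.
#
# State variables (arbitrary units, normalised so the wild-type stress-free
# steady state has mA = A = 1):
#   mA  AMPK mRNA
#   A   total AMPK protein
#   Ap  phospho-AMPK (Thr172-active sub-pool, Ap <= A)
#   mN  NRF2 mRNA
#   N   active NRF2 protein
#   U   ULK1 phosphorylated at Ser555 (U <= U_T)
#   L   autophagosome abundance (LC3-II / GFP::LGG-1 proxy)
#   P   p62
#
# Time unit: hours. The stress input s(t) is a step of amplitude `dose`
# switched on at t = 0 and held (sustained TBHP exposure).

MODEL_STATES <- c("mA", "A", "Ap", "mN", "N", "U", "L", "P")

MODEL_PARAMS <- c(
  "k_mA", "d_mA",                       # AMPK transcription / mRNA decay
  "k_A", "e_A", "d_A",                  # AMPK translation, stress boost, decay
  "k_p", "k_dp", "s0", "a_S", "h_S",    # Thr172 (de)phosphorylation, basal
                                        #  tone, NRF2-dependent signal detox
                                        #  (strength and cooperativity)
  "k_mN", "c_N", "d_mN", "K_s",         # NRF2 transcription (saturating)
  "k_N", "k_N0", "k_N1", "k_N2", "d_N", # NRF2 activation (KEAP1 release,
                                        #  AMPK-P drive), decay
  "K_N", "h",                           # repression threshold / Hill exponent
  "k_U", "u0", "U_T", "d_U",            # ULK1-S555 activation, basal drive
  "k_L", "d_L", "e_L", "K_c",           # autophagosome formation / clearance
  "k_P", "b_P", "d_P0", "d_P1"          # p62 synthesis / decay
)

#' Construct and validate a model parameter set
#'
#' @param ... Named rates overriding the base set, or a single named numeric
#'   vector/list.
#' @param base Named numeric vector to start from (defaults to all parameters
#'   required among \code{...}).
#' @return Named numeric vector of class \code{param_set}.
#' @export
param_set <- function(..., base = NULL) {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) &&
      (is.numeric(dots[[1]]) || is.list(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  p <- if (is.null(base)) numeric() else unlist(base)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  missing <- setdiff(MODEL_PARAMS, names(p))
  if (length(missing) > 0) {
    stop("missing parameters: ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(p), MODEL_PARAMS)
  if (length(unknown) > 0) {
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  }
  p <- unlist(p)[MODEL_PARAMS]
  if (any(p < 0, na.rm = TRUE)) {
    stop("all rates must be nonnegative: ",
         paste(names(p)[p < 0], collapse = ", "))
  }
  if (p[["K_N"]] <= 0 || p[["h"]] < 1 || p[["U_T"]] <= 0) {
    stop("require K_N > 0, h >= 1, U_T > 0")
  }
  degr <- c("d_mA", "d_A", "d_mN", "d_N", "d_U", "d_L", "d_P0", "k_dp")
  if (any(p[degr] <= 0)) {
    stop("all degradation/deactivation rates must be positive for a finite ",
         "stress-free steady state")
  }
  class(p) <- c("param_set", "numeric")
  p
}

#' Calibrated default parameter sets
#'
#' Returns the shipped parameter set jointly calibrated to the published
#' fold-changes of the corresponding experimental system (see
#' \code{\link{builtin_constraints}} and \code{\link{feedback_fit}}).
#'
#' @param system \code{"human_cell"} (HEK293T, 100 uM TBHP) or \code{"worm"}
#'   (C. elegans, 1 mM TBHP reference dose).
#' @return A \code{param_set}.
#' @export
default_parameters <- function(system) {
  if (length(system) != 1 || !system %in% c("human_cell", "worm")) {
    stop("unknown system '", paste(system, collapse = ","),
         "'; valid systems: human_cell, worm")
  }
  param_set(.default_param_values[[system]])
}

#' Experimental conditions
#'
#' @return Character vector of supported condition names.
#' @export
model_conditions <- function() {
  c("WT", "siNRF2", "skn1_RNAi", "skn1_GOF", "aak2_null", "atg11_null")
}

#' Apply a perturbation condition to a parameter set
#'
#' Conditions act as multipliers: \code{siNRF2} and \code{skn1_RNAi} scale
#' NRF2/SKN-1 synthesis (\code{k_mN}) by the knockdown factor; \code{skn1_GOF}
#' scales it up by \code{gof_factor}; \code{aak2_null} sets \code{k_A = 0};
#' \code{atg11_null} sets \code{k_L = 0}; \code{WT} is the identity. Several
#' conditions may be combined (e.g. \code{c("aak2_null", "skn1_RNAi")});
#' multipliers compose.
#'
#' @param params A \code{param_set}.
#' @param condition Character vector of condition names.
#' @param knockdown RNAi/siRNA knockdown factor on NRF2 synthesis.
#' @param gof_factor Gain-of-function fold-increase of SKN-1 synthesis.
#' @return The perturbed \code{param_set}.
#' @export
apply_condition <- function(params, condition, knockdown = 0.05,
                            gof_factor = 3) {
  p <- param_set(params)
  for (cond in condition) {
    if (!cond %in% model_conditions()) {
      stop("unknown condition '", cond, "'; valid: ",
           paste(model_conditions(), collapse = ", "))
    }
    p <- switch(cond,
      WT         = p,
      siNRF2     = { p[["k_mN"]] <- p[["k_mN"]] * knockdown; p },
      skn1_RNAi  = { p[["k_mN"]] <- p[["k_mN"]] * knockdown; p },
      skn1_GOF   = { p[["k_mN"]] <- p[["k_mN"]] * gof_factor; p },
      aak2_null  = { p[["k_A"]] <- 0; p },
      atg11_null = { p[["k_L"]] <- 0; p }
    )
  }
  p
}

#' Disable NRF2 feedback onto the AMPK axis
#'
#' Removes both arms of the NRF2 -> AMPK negative feedback: transcriptional
#' repression (\code{K_N -> Inf}) and NRF2-dependent neutralisation of the
#' AMPK-activating stress signal (\code{a_S = 0}). Used to test that the
#' transient (peak-and-decline) autophagy profile requires the feedback.
#'
#' @param params A \code{param_set}.
#' @return The modified \code{param_set}.
#' @export
disable_feedback <- function(params) {
  p <- param_set(params)
  p[["K_N"]] <- Inf
  p[["a_S"]] <- 0
  p
}

# Right-hand side of the ODE system; `s` is the momentary stress input.
model_rhs_core <- function(state, p, s) {
  mA <- state[[1]]; A <- state[[2]]; Ap <- state[[3]]; mN <- state[[4]]
  N <- state[[5]]; U <- state[[6]]; L <- state[[7]]; P <- state[[8]]
  hill <- if (is.finite(p[["K_N"]])) 1 / (1 + (N / p[["K_N"]])^p[["h"]]) else 1
  s_sat <- if (is.finite(p[["K_s"]])) s / (1 + s / p[["K_s"]]) else s
  s_cl  <- if (is.finite(p[["K_c"]])) s / (1 + s / p[["K_c"]]) else s
  # stress signal as sensed by the AMPK axis: neutralised by the
  # NRF2-induced antioxidant program (NQO1/HO-1 arm), with cooperativity h_S
  s_amp <- s / (1 + (p[["a_S"]] * N)^p[["h_S"]])
  c(
    mA = p[["k_mA"]] * hill - p[["d_mA"]] * mA,
    A  = p[["k_A"]] * (1 + p[["e_A"]] * s_amp) * mA - p[["d_A"]] * A,
    Ap = p[["k_p"]] * (p[["s0"]] + s_amp) * (A - Ap) - p[["k_dp"]] * Ap,
    mN = p[["k_mN"]] * (1 + p[["c_N"]] * s_sat) - p[["d_mN"]] * mN,
    N  = p[["k_N"]] * mN *
           (p[["k_N0"]] + p[["k_N1"]] * s_sat + p[["k_N2"]] * Ap) -
           p[["d_N"]] * N,
    U  = p[["k_U"]] * (p[["u0"]] + Ap) * (p[["U_T"]] - U) - p[["d_U"]] * U,
    L  = p[["k_L"]] * U - p[["d_L"]] * (1 + p[["e_L"]] * s_cl) * L,
    P  = p[["k_P"]] * (1 + p[["b_P"]] * N) - p[["d_P0"]] * P -
           p[["d_P1"]] * L * P
  )
}

#' Model right-hand side
#'
#' Time derivative of the model state. The stress input may be a constant
#' dose or a function of time.
#'
#' @param state Named nonnegative state vector (order \code{mA, A, Ap, mN, N,
#'   U, L, P}).
#' @param t Time (hours).
#' @param params A \code{param_set}.
#' @param stress Constant dose or function \code{s(t)}.
#' @return Named vector of derivatives.
#' @export
model_rhs <- function(state, t, params, stress = 0) {
  s <- if (is.function(stress)) stress(t) else stress
  if (min(state) < -1e-6) {
    stop("negative state component beyond tolerance at t = ", t)
  }
  model_rhs_core(state, params, s)
}

#' Stress-free steady state
#'
#' At s = 0 the system reduces to a one-dimensional fixed-point equation in
#' basal AMPK mRNA (all other basal levels are explicit functions of it),
#' which is monotone and solved by \code{uniroot}; the remaining states follow
#' in closed form.
#'
#' @param params A \code{param_set}.
#' @return Named state vector at the stress-free steady state.
#' @export
steady_state <- function(params) {
  p <- params
  mN0 <- p[["k_mN"]] / p[["d_mN"]]
  frac0 <- p[["k_p"]] * p[["s0"]] / (p[["k_p"]] * p[["s0"]] + p[["k_dp"]])
  n_of_mA <- function(mA) {
    A <- p[["k_A"]] * mA / p[["d_A"]]
    Ap <- frac0 * A
    (p[["k_N"]] / p[["d_N"]]) * mN0 * (p[["k_N0"]] + p[["k_N2"]] * Ap)
  }
  mA_max <- p[["k_mA"]] / p[["d_mA"]]
  if (!is.finite(p[["K_N"]])) {
    mA0 <- mA_max
  } else {
    f <- function(mA) {
      N <- n_of_mA(mA)
      p[["k_mA"]] / (p[["d_mA"]] * (1 + (N / p[["K_N"]])^p[["h"]])) - mA
    }
    if (mA_max == 0) {
      mA0 <- 0
    } else if (f(mA_max) >= 0) {
      mA0 <- mA_max
    } else {
      mA0 <- stats::uniroot(f, c(0, mA_max), tol = 1e-14)$root
    }
  }
  A0 <- p[["k_A"]] * mA0 / p[["d_A"]]
  Ap0 <- frac0 * A0
  N0 <- n_of_mA(mA0)
  drive <- p[["k_U"]] * (p[["u0"]] + Ap0)
  U0 <- drive * p[["U_T"]] / (drive + p[["d_U"]])
  L0 <- p[["k_L"]] * U0 / p[["d_L"]]
  P0 <- p[["k_P"]] * (1 + p[["b_P"]] * N0) /
    (p[["d_P0"]] + p[["d_P1"]] * L0)
  c(mA = mA0, A = A0, Ap = Ap0, mN = mN0, N = N0, U = U0, L = L0, P = P0)
}

#' Simulate the model
#'
#' Integrates the system with a stiff-capable solver (\code{deSolve::lsoda},
#' relative tolerance 1e-8) under a sustained stress step of amplitude
#' \code{dose} from t = 0. The initial state defaults to the
#' condition-specific stress-free steady state. Nonnegativity is checked (not
#' clipped) after integration.
#'
#' @param params A \code{param_set} (pre-perturbation).
#' @param condition Condition name(s) passed to \code{\link{apply_condition}}.
#' @param dose Stress amplitude (1 = the system's reference dose).
#' @param t_grid Strictly increasing output time grid (hours), starting at 0.
#' @param init Optional initial state (defaults to the steady state).
#' @param rtol,atol Integrator tolerances.
#' @return A \code{model_trajectory}: data.frame with columns \code{time} and
#'   the eight states, with the condition, dose and parameters as attributes.
#' @export
simulate_model <- function(params, condition = "WT", dose = 1,
                           t_grid = seq(0, 6, by = 0.01), init = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  p <- apply_condition(params, condition)
  if (is.null(init)) init <- steady_state(p)
  if (min(init) < 0) stop("initial state must be nonnegative")
  func <- function(t, y, parms) list(model_rhs_core(y, parms, dose))
  sol <- deSolve::lsoda(y = init, times = t_grid, func = func, parms = p,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed at t = ", max(sol[, 1]))
  }
  traj <- as.data.frame(sol)
  names(traj)[1] <- "time"
  low <- vapply(traj[MODEL_STATES], min, numeric(1))
  if (min(low) < -1e-6) {
    stop("negative state beyond tolerance in trajectory: ",
         names(low)[which.min(low)])
  }
  structure(traj, class = c("model_trajectory", "data.frame"),
            condition = condition, dose = dose, params = p)
}

#' Scalar readouts of a trajectory
#'
#' Relative readouts divide the state at time \code{t} by the trajectory's
#' own t = 0 value (linear interpolation between grid points). \code{basal_A}
#' is the absolute initial AMPK protein level; cross-condition ratios are
#' formed by the caller (see \code{\link{builtin_constraints}}).
#'
#' @param traj A \code{model_trajectory}.
#' @param name One of \code{rel_mA}, \code{rel_mN}, \code{rel_A},
#'   \code{rel_Ap}, \code{rel_L}, \code{rel_P} (require \code{t}),
#'   \code{peak_rel_A}, \code{peak_rel_L}, \code{basal_A}.
#' @param t Time (hours) for the \code{rel_*} readouts.
#' @return Finite scalar.
#' @export
readout <- function(traj, name, t = NULL) {
  rel <- function(var, tt) {
    if (is.null(tt)) stop("readout '", name, "' requires a time t")
    if (tt < min(traj$time) || tt > max(traj$time)) {
      stop("t = ", tt, " outside trajectory grid [", min(traj$time), ", ",
           max(traj$time), "]")
    }
    v <- stats::approx(traj$time, traj[[var]], xout = tt)$y
    v0 <- traj[[var]][1]
    if (v0 == 0) stop("relative readout undefined: ", var, "(0) = 0")
    v / v0
  }
  val <- switch(name,
    rel_mA = rel("mA", t), rel_mN = rel("mN", t), rel_A = rel("A", t),
    rel_Ap = rel("Ap", t), rel_L = rel("L", t), rel_P = rel("P", t),
    peak_rel_A = max(traj$A) / traj$A[1],
    peak_rel_L = max(traj$L) / traj$L[1],
    basal_A = traj$A[1],
    stop("unknown readout '", name, "'")
  )
  if (!is.finite(val)) stop("readout '", name, "' is not finite")
  val
}

#' @export
print.model_trajectory <- function(x, ...) {
  cat(sprintf(
    "<model_trajectory> condition %s, dose %g, t in [%g, %g] h (%d points)\n",
    paste(attr(x, "condition"), collapse = "+"), attr(x, "dose"),
    min(x$time), max(x$time), nrow(x)))
  invisible(x)
}

#' Write a trajectory as TSV
#'
#' @param traj A \code{model_trajectory}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
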