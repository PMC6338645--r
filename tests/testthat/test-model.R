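test_that("parameter sets are validated", {
  p <- default_parameters("human_cell")
  expect_s3_class(p, "param_set")
  expect_error(default_parameters("yeast"), "human_cell, worm")
  expect_error(param_set(p[-1]), "missing parameters")
  expect_error(tweak_params(p, d_mA = -1), "nonnegative")
  expect_error(tweak_params(p, d_L = 0), "degradation")
  expect_error(tweak_params(p, h = 0.5), "h >= 1")
})

test_that("perturbation conditions act as the defined multipliers", {
  p <- default_parameters("human_cell")
  expect_equal(apply_condition(p, "WT"), p)
  psi <- apply_condition(p, "siNRF2")
  expect_equal(psi[["k_mN"]], 0.05 * p[["k_mN"]])
  expect_equal(psi[names(psi) != "k_mN"], p[names(p) != "k_mN"])
  expect_equal(apply_condition(p, "skn1_GOF")[["k_mN"]], 3 * p[["k_mN"]])
  pa <- apply_condition(p, "aak2_null")
  expect_equal(pa[["k_A"]], 0)
  expect_equal(pa[names(pa) != "k_A"], p[names(p) != "k_A"])
  expect_equal(apply_condition(p, "atg11_null")[["k_L"]], 0)
  # combinations compose
  pc <- apply_condition(p, c("aak2_null", "skn1_RNAi"))
  expect_equal(pc[["k_A"]], 0)
  expect_equal(pc[["k_mN"]], 0.05 * p[["k_mN"]])
  expect_error(apply_condition(p, "daf16_null"), "unknown condition")
})

test_that("the stress-free steady state is a fixed point of the dynamics", {
  for (sys in c("human_cell", "worm")) {
    p <- default_parameters(sys)
    ss <- steady_state(p)
    expect_lt(max(abs(model_rhs(ss, 0, p, 0))), 1e-9)
    expect_true(all(ss >= 0))
    expect_lte(ss[["Ap"]], ss[["A"]] + 1e-12)
    expect_lte(ss[["U"]], p[["U_T"]])
    # normalisation convention
    expect_equal(unname(ss[c("mA", "A", "L")]), c(1, 1, 1), tolerance = 1e-6)
    # conditions reach their own fixed points too
    for (cond in c("siNRF2", "aak2_null", "atg11_null", "skn1_GOF")) {
      pc <- apply_condition(p, cond)
      expect_lt(max(abs(model_rhs(steady_state(pc), 0, pc, 0))), 1e-9)
    }
  }
})

test_that("without stress the trajectory stays at the steady state", {
  p <- default_parameters("human_cell")
  tr <- simulate_model(p, "WT", dose = 0, t_grid = seq(0, 24, 0.5))
  ss <- steady_state(p)
  for (v in names(ss)) {
    expect_lt(max(abs(tr[[v]] - ss[[v]])) / max(ss[[v]], 1e-12), 1e-6)
  }
})

test_that("decoupled linear subsystems match their closed forms", {
  p <- default_parameters("human_cell")
  ss <- steady_state(p)
  # Ap: with s = 0 and s0 = 0, dAp/dt = -k_dp * Ap
  init <- ss; init[["Ap"]] <- 0.5
  tr <- simulate_model(p, "WT", dose = 0, t_grid = seq(0, 2, 0.01),
                       init = init)
  expect_lt(max(abs(tr$Ap - 0.5 * exp(-p[["k_dp"]] * tr$time))), 1e-6)
  # mN: step input, linear first-order rise
  trs <- simulate_model(p, "WT", dose = 1, t_grid = seq(0, 4, 0.01))
  mN_inf <- p[["k_mN"]] * (1 + p[["c_N"]]) / p[["d_mN"]]
  mN_exact <- mN_inf + (ss[["mN"]] - mN_inf) * exp(-p[["d_mN"]] * trs$time)
  expect_lt(max(abs(trs$mN - mN_exact)), 1e-6)
  # L: with production switched off, pure exponential decay
  p0 <- tweak_params(p, k_L = 0)
  init <- steady_state(p0); init[["L"]] <- 2
  trl <- simulate_model(p0, "WT", dose = 0, t_grid = seq(0, 2, 0.01),
                        init = init)
  expect_lt(max(abs(trl$L - 2 * exp(-p[["d_L"]] * trl$time))), 1e-6)
})

test_that("full repression limit: mA production vanishes as N grows", {
  p <- default_parameters("human_cell")
  st <- steady_state(p)
  st[["N"]] <- 1e9
  d <- model_rhs(st, 0, p, 0)
  expect_equal(d[["mA"]], -p[["d_mA"]] * st[["mA"]], tolerance = 1e-6)
})

test_that("trajectories stay nonnegative and bounded for random parameters", {
  set.seed(2026)
  base <- default_parameters("human_cell")
  for (k in 1:25) {
    p <- base
    rates <- setdiff(names(p), c("h", "h_S", "K_s", "K_c", "U_T", "s0"))
    p[rates] <- as.numeric(p[rates]) * exp(rnorm(length(rates), 0, 0.5))
    p[["h"]] <- sample(1:4, 1)
    p[["U_T"]] <- runif(1, 1, 50)
    p <- param_set(p)
    dose <- runif(1, 0, 3)
    init <- abs(rnorm(8, 1, 0.5))
    names(init) <- c("mA", "A", "Ap", "mN", "N", "U", "L", "P")
    init[["Ap"]] <- min(init[["Ap"]], init[["A"]])
    init[["U"]] <- min(init[["U"]], p[["U_T"]])
    tr <- simulate_model(p, "WT", dose = dose, t_grid = seq(0, 10, 0.1),
                         init = init)
    expect_true(all(as.matrix(tr[, -1]) > -1e-8))
    # computable bound per state from production caps / degradation floors
    mA_max <- max(init[["mA"]], p[["k_mA"]] / p[["d_mA"]])
    A_max <- max(init[["A"]],
                 p[["k_A"]] * (1 + p[["e_A"]] * dose) * mA_max / p[["d_A"]])
    mN_max <- max(init[["mN"]], p[["k_mN"]] * (1 + p[["c_N"]] * dose) /
                    p[["d_mN"]])
    expect_lte(max(tr$mA), mA_max * (1 + 1e-6))
    expect_lte(max(tr$A), A_max * (1 + 1e-6))
    expect_lte(max(tr$Ap), A_max * (1 + 1e-6))
    expect_lte(max(tr$mN), mN_max * (1 + 1e-6))
    expect_lte(max(tr$U), max(init[["U"]], p[["U_T"]]) * (1 + 1e-6))
    expect_true(all(is.finite(as.matrix(tr[, -1]))))
  }
})

test_that("readouts self-normalise, interpolate, and reject out-of-grid times", {
  p <- default_parameters("human_cell")
  tr <- simulate_model(p, "WT", dose = 1, t_grid = seq(0, 4, 0.01))
  expect_equal(readout(tr, "rel_mA", 0), 1)
  expect_equal(readout(tr, "rel_L", 0), 1)
  expect_error(readout(tr, "rel_mA", 5), "outside")
  expect_error(readout(tr, "peak_rel_L", 2), NA)  # t ignored for peaks
  expect_error(readout(tr, "nope"), "unknown readout")
  # peak of a monotone-decreasing trajectory is the t = 0 value
  fake <- tr
  fake$L <- exp(-fake$time)
  expect_equal(readout(fake, "peak_rel_L"), 1)
  # interpolation between grid points
  mid <- readout(tr, "rel_mN", 0.015)
  expect_gt(mid, readout(tr, "rel_mN", 0.01) - 1e-12)
  expect_lt(mid, readout(tr, "rel_mN", 0.02) + 1e-12)
})

test_that("halving integrator tolerances leaves readouts unchanged to 1e-4", {
  p <- default_parameters("human_cell")
  g <- seq(0, 4, 0.01)
  tr1 <- simulate_model(p, "WT", 1, g)
  tr2 <- simulate_model(p, "WT", 1, g, rtol = 5e-9, atol = 5e-11)
  for (nm in c("rel_mA", "rel_mN", "rel_L")) {
    expect_lt(abs(readout(tr1, nm, 4) - readout(tr2, nm, 4)) /
                readout(tr1, nm, 4), 1e-4)
  }
  expect_lt(abs(readout(tr1, "peak_rel_L") - readout(tr2, "peak_rel_L")) /
              readout(tr1, "peak_rel_L"), 1e-4)
})

test_that("simulation input validation", {
  p <- default_parameters("human_cell")
  expect_error(simulate_model(p, "WT", 1, c(0, 1, 1)), "strictly increasing")
  init <- steady_state(p); init[["L"]] <- -1
  expect_error(simulate_model(p, "WT", 1, c(0, 1), init = init),
               "nonnegative")
})
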