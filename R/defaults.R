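# Shipped calibrated parameter sets. Produced by running feedback_fit() on
# the builtin constraint tables (the release-gate fit); concentrations are
# normalised so the WT stress-free steady state has mA = A = 1 and L = 1.
# Units: h^-1 for rates, dimensionless for factors and Hill terms.

.default_param_values <- list(
  human_cell = c(
    k_mA = 1.699964007, d_mA = 0.2392000912,
    k_A = 1.2, e_A = 8, d_A = 1.2,
    k_p = 8, k_dp = 6, s0 = 0, a_S = 0.12, h_S = 6,
    k_mN = 0.5, c_N = 1.087126584, d_mN = 0.5, K_s = Inf,
    k_N = 4, k_N0 = 0.1, k_N1 = 0.9, k_N2 = 0.1, d_N = 0.4,
    K_N = 0.4046603514, h = 2,
    k_U = 0.3, u0 = 0.5411010793, U_T = 25, d_U = 3.6,
    k_L = 2.781240302, d_L = 3, e_L = 0, K_c = Inf,
    k_P = 1, b_P = 0.5, d_P0 = 1, d_P1 = 0.5
  ),
  worm = c(
    k_mA = 1.163412811, d_mA = 1.1,
    k_A = 1.438355276, e_A = 0.03773920421, d_A = 1.438355276,
    k_p = 5, k_dp = 1, s0 = 1, a_S = 0, h_S = 1,
    k_mN = 0.8, c_N = 2, d_mN = 0.8, K_s = 2,
    k_N = 40, k_N0 = 0.12, k_N1 = 1.5, k_N2 = 0.01, d_N = 2,
    K_N = 3.666666667, h = 8,
    k_U = 0.15, u0 = 0.02, U_T = 25, d_U = 3,
    k_L = 1.46625, d_L = 1.5, e_L = 1.112133458, K_c = 1.5,
    k_P = 1, b_P = 0.5, d_P0 = 1, d_P1 = 0.5
  )
)
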