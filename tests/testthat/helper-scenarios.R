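# Shared fixtures, built in code.

# Default titration scenario: 150 uL of 1e-3 M complex stock in 1.0 mL
# buffer (C0 = 1.304e-4 M in 1.15 mL), titrated with 2e-3 M protein in
# 8.2 uL steps.
sim_titration <- function(K = 1e4, n = 1, delta_eps = -5000, sigma_A = 0,
                          seed = NULL, ...) {
  simulate_titration(K = K, n = n, delta_eps = delta_eps,
                     sigma_A = sigma_A, seed = seed, ...)
}

# Isotherm at the free-band maximum (378 nm), where the generator's
# absorptivity change equals delta_eps exactly.
sim_isotherm <- function(...) {
  build_isotherm(sim_titration(...), lambda_star = 378)
}

# Independent oracle for the mass-action equilibrium: bisection on the
# residual K (C_L - x)(n C_P - x) - x = 0 ... rearranged as
# f(x) = K (C_L - x)(n C_P - x) - x, monotone decreasing on the physical
# branch [0, min(C_L, n C_P)].
bisect_equilibrium <- function(C_L, C_P, K, n = 1, iters = 200) {
  f <- function(x) K * (C_L - x) * (n * C_P - x) - x
  lo <- 0
  hi <- min(C_L, n * C_P)
  if (hi == 0 || K == 0) return(0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Fragment left on the protein when complex 1/2 loses its halide.
pt_fragment <- function(q = 2) {
  fragment_spec("Pt(phterpy)", "PtC21H15N3", charge_displaced = q,
                note = "phenyl-terpyridine Pt fragment, halide lost")
}

new_chem_formula_for_test <- function(syms, counts) {
  parse_formula(paste0(syms, counts, collapse = ""))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
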