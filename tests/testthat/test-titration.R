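test_that("equilibrium solver matches a bisection oracle", {
  set.seed(11)
  for (i in 1:30) {
    K <- 10^runif(1, 1, 7)
    n <- sample(c(0.5, 1, 2), 1)
    CL <- 10^runif(1, -5, -3.5)
    CP <- 10^runif(1, -5, -3)
    x <- solve_equilibrium(CL, CP, K, n)
    xo <- bisect_equilibrium(CL, CP, K, n)
    expect_lt(abs(x - xo) / max(xo, 1e-300), 1e-10)
    expect_gte(x, 0)
    expect_lte(x, min(CL, n * CP) * (1 + 1e-12))
  }
})

test_that("equilibrium solver limits: no binding and stoichiometric", {
  expect_identical(solve_equilibrium(1e-5, 2e-5, 0), 0)
  expect_equal(solve_equilibrium(1e-5, 2e-5, 1e15, 1), 1e-5,
               tolerance = 1e-6)
  expect_equal(solve_equilibrium(2e-5, 1e-5, 1e15, 1), 1e-5,
               tolerance = 1e-6)
  # specific case frozen from the bisection oracle
  x <- solve_equilibrium(1e-5, 1e-4, 1e4, 1)
  expect_equal(x, bisect_equilibrium(1e-5, 1e-4, 1e4, 1),
               tolerance = 1e-12)
  expect_error(solve_equilibrium(1e-5, 1e-4, -1), "K")
  expect_error(solve_equilibrium(1e-5, 1e-4, 1e4, 0), "n")
})

test_that("isotherm construction: point zero, saturation, interpolation", {
  # dA at the protein-free point is 0 by construction of epsilon_PtL
  iso <- sim_isotherm(K = 1e4)
  expect_identical(iso$dA[1], 0)
  expect_equal(attr(iso, "lambda_star"), 378)

  # near-stoichiometric binding: dA saturates at delta_eps * C_PtL * l
  ser <- sim_titration(K = 1e6, additions = 25)
  isoS <- build_isotherm(ser, lambda_star = 378)
  i_last <- nrow(isoS)
  expect_rel(isoS$dA[i_last], -5000 * isoS$C_PtL[i_last], 0.01)

  # analysis wavelength between grid points is interpolated
  iso_h <- build_isotherm(sim_titration(K = 1e4), lambda_star = 378.5)
  s <- sim_titration(K = 1e4)
  a_lo <- build_isotherm(s, lambda_star = 378)$dA
  a_hi <- build_isotherm(s, lambda_star = 379)$dA
  expect_equal(iso_h$dA, (a_lo + a_hi) / 2, tolerance = 1e-9)

  # default analysis wavelength is the max |change| wavelength
  expect_equal(default_lambda_star(s),
               diff_spectra(s$spectra[[1]],
                            s$spectra[[length(s$spectra)]])$lambda_max)
})

test_that("isotherm magnitude grows monotonically with protein", {
  for (K in c(1e3, 1e4, 1e5)) {
    iso <- sim_isotherm(K = K)
    expect_true(all(diff(abs(iso$dA)) > -1e-12))
  }
})

test_that("series invariants are enforced", {
  s <- sim_titration(K = 1e4)
  expect_error(build_isotherm(
    titration_series(s$spectra[1:3], s$C_PtL[1:3], s$C_protein[1:3])),
    "at least 4")
  expect_error(titration_series(s$spectra, s$C_PtL,
                                rev(s$C_protein)), "protein-free|non-decreasing")
})
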