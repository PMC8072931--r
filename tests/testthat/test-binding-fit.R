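test_that("iterative linearized fit recovers K and delta_eps exactly on
           model data", {
  iso <- sim_isotherm(K = 1e4, delta_eps = -5000)
  f <- fit_binding(iso)
  expect_rel(f$K, 1e4, 1e-3)
  expect_rel(f$delta_eps, -5000, 1e-3)
  expect_true(f$converged)
  expect_lte(f$iterations, 20)
  expect_false(f$K_unreliable)
})

test_that("iterative fit and direct NLS fit agree on noiseless data
           across four decades of K", {
  for (K in c(1e2, 1e3, 1e4, 1e5)) {
    iso <- sim_isotherm(K = K, delta_eps = -5000)
    a <- suppressWarnings(fit_binding(iso))
    b <- suppressWarnings(fit_binding_nls(iso))
    expect_lt(abs(a$K - b$K) / b$K, 1e-3)
    expect_rel(b$K, K, 1e-3)
  }
})

test_that("delta_eps trace is monotone after iteration 2 and converges
           within 20 iterations on noiseless data", {
  for (K in c(1e3, 1e4, 1e5)) {
    f <- fit_binding(sim_isotherm(K = K))
    expect_true(f$converged)
    expect_lte(f$iterations, 20)
    if (f$iterations > 2) {
      steps <- diff(f$trace[-1])
      expect_true(all(steps >= -1e-9) || all(steps <= 1e-9))
    }
  }
})

test_that("unsaturated noisy isotherms flag K as unreliable", {
  # K * C_protein << 1 throughout: amplitude and K are not separable
  # once measurement noise swamps the curvature
  ser <- suppressWarnings(
    simulate_titration(K = 20, delta_eps = -5000, sigma_A = 0.002,
                       seed = 8))
  iso <- build_isotherm(ser, lambda_star = 378)
  w <- capture_warnings(f <- fit_binding(iso))
  expect_match(w, "unreliable", all = FALSE)
  expect_true(f$K_unreliable)
})

test_that("NLS fit round-trips exact forward data and flags
           information-free input", {
  iso <- sim_isotherm(K = 5e3, delta_eps = -4000)
  f <- fit_binding_nls(iso)
  expect_rel(f$K, 5e3, 1e-5)
  expect_rel(f$delta_eps, -4000, 1e-5)

  # zero protein throughout carries no binding information
  ser <- sim_titration(K = 5e3)
  ser$C_protein[] <- 0
  ser$C_protein[1] <- 0
  iso0 <- build_isotherm(ser, lambda_star = 378)
  expect_error(suppressWarnings(fit_binding_nls(iso0)), "usable|points")
})

test_that("median recovered K over noisy replicates is close to truth", {
  # sigma_A = 0.002 AU, 15 additions - the instrument-realistic regime
  K0 <- 5e3
  Ks <- vapply(1:60, function(i) {
    iso <- sim_isotherm(K = K0, delta_eps = -5000, sigma_A = 0.002,
                        seed = 300 + i)
    f <- tryCatch(suppressWarnings(fit_binding(iso)),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$K
  }, numeric(1))
  expect_gt(sum(!is.na(Ks)), 55)
  expect_rel(median(Ks, na.rm = TRUE), K0, 0.15)
})

test_that("points with sign flips or zero dA are dropped with warnings", {
  iso <- sim_isotherm(K = 1e4)
  iso$dA[3] <- -iso$dA[3]
  expect_warning(f <- fit_binding(iso), "sign")
  expect_rel(f$K, 1e4, 0.05)
  iso2 <- sim_isotherm(K = 1e4)
  iso2$dA[5] <- 0
  expect_warning(fit_binding(iso2), "dA = 0")
})
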