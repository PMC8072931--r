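test_that("simulators are deterministic under a fixed seed", {
  a <- simulate_titration(sigma_A = 0.002, seed = 7)
  b <- simulate_titration(sigma_A = 0.002, seed = 7)
  expect_identical(a, b)
  expect_identical(simulate_dsc(sigma_frac = 0.01, seed = 3),
                   simulate_dsc(sigma_frac = 0.01, seed = 3))
  expect_identical(
    simulate_esi_spectrum(14304, sigma_rel = 0.02, seed = 11),
    simulate_esi_spectrum(14304, sigma_rel = 0.02, seed = 11))
  # noiseless output is seed-independent
  expect_identical(simulate_titration(sigma_A = 0, seed = 1)$spectra,
                   simulate_titration(sigma_A = 0, seed = 2)$spectra)
})

test_that("titration spectra show a fixed isosbestic point after
           dilution correction", {
  lam <- attr(simulate_titration(K = 1e4, sigma_A = 0),
              "truth")$lambda_iso
  # regenerate with the crossing wavelength on the grid so no
  # interpolation error enters
  ser <- simulate_titration(K = 1e4, sigma_A = 0,
                            wavelengths = sort(c(seq(300, 500, 1), lam)))
  A_iso <- vapply(seq_along(ser$spectra), function(i) {
    s <- correct_dilution(ser$spectra[[i]], ser$V0, ser$volume_added[i])
    s$absorbance[s$wavelength == lam]
  }, numeric(1))
  expect_lt(max(A_iso) - min(A_iso), 1e-6)
})

test_that("the noiseless generator is exactly the fitted forward model", {
  # absorbance at any wavelength decomposes on the free/bound basis with
  # the mass-action bound fraction - no hidden model mismatch
  ser <- simulate_titration(K = 2e4, n = 1, sigma_A = 0)
  tr <- attr(ser, "truth")
  i <- 9
  x <- solve_equilibrium(ser$C_PtL[i], ser$C_protein[i], 2e4, 1)
  recon <- tr$eps_free * (ser$C_PtL[i] - x) + tr$eps_bound * x
  expect_equal(ser$spectra[[i]]$absorbance, recon, tolerance = 1e-12)
})

test_that("the titration approaches saturation once C_protein exceeds
           ~3/K", {
  ser <- simulate_titration(K = 1e4, sigma_A = 0, additions = 25)
  iso <- build_isotherm(ser, lambda_star = 378)
  expect_gt(max(iso$C_protein), 3 / 1e4)
  # bound fraction of the complex; ligand depletion keeps it slightly
  # below the depletion-free K C_P / (1 + K C_P)
  sat <- abs(iso$dA) / (5000 * iso$C_PtL)
  expect_gt(max(sat), 0.65)
  expect_true(all(diff(sat) > 0))
})

test_that("unsaturated scenarios and bad population weights are
           reported", {
  expect_warning(simulate_titration(K = 10, sigma_A = 0), "unsaturated")
  expect_error(simulate_dsc(populations = data.frame(
    weight = c(0.7, 0.6), T_d = c(350, 345), dH = c(450, 450))),
    "sum to 1")
  expect_error(simulate_dsc(step = 0.5), "step")
})

test_that("ESI envelope peaks stay inside the acquisition window", {
  sp <- simulate_esi_spectrum(14304, z_range = 8:14, sigma_rel = 0)
  expect_true(all(sp$mz >= 1000 & sp$mz <= 2600))
  pk <- sp$mz[which(diff(sign(diff(sp$intensity))) == -2) + 1]
  expect_equal(length(pk), 7)  # one peak per charge state 8..14
  expect_warning(simulate_esi_spectrum(1e6, z_range = 8:14), "window")
  sp0 <- simulate_esi_spectrum(c(14304, 15000), c(1, 0), z_range = 8:14,
                               sigma_rel = 0)
  # zero-abundance species contributes nothing
  sp1 <- simulate_esi_spectrum(14304, 1, z_range = 8:14, sigma_rel = 0)
  expect_identical(sp0$intensity, sp1$intensity)
})
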