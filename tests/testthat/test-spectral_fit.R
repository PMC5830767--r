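test_that("detailed balance ratio matches its closed form", {
  expect_equal(detailed_balance_ratio(0), 1)
  expect_equal(detailed_balance_ratio(1.5, 303.15),
               exp(-1.5 / (0.0861733 * 303.15)), tolerance = 1e-12)
  expect_equal(detailed_balance_ratio(1.5, 303.15), 0.94420, tolerance = 1e-4)
  expect_equal(detailed_balance_ratio(thermal_energy(303.15), 303.15),
               exp(-1), tolerance = 1e-12)
})

test_that("evaluate_spectrum matches hand-summed oracles", {
  # no modes, zero slope: I(0) = A_el + A_inc + intercept
  m0 <- spectral_model(A_el = 100, A_inc = 20, sigma_inc = 1, slope = 0,
                       intercept = 7)
  expect_equal(evaluate_spectrum(m0, 0), 127)

  # one mode, zero backgrounds: hand-summed two-Lorentzian oracle,
  # including the Stokes cross-tail at -mu
  mu <- 1.5; sg <- 0.2; ap <- 100
  db <- exp(-mu / thermal_energy(303.15))
  m1 <- spectral_model(A_el = 0, A_inc = 0, sigma_inc = 1, slope = 0,
                       intercept = 0,
                       modes = data.frame(mu = mu, sigma = sg, amp_plus = ap))
  oracle <- function(w) ap / (1 + (w - mu)^2 / sg^2) +
    ap * db / (1 + (w + mu)^2 / sg^2)
  expect_equal(evaluate_spectrum(m1, c(-1.5, 1.5)), oracle(c(-1.5, 1.5)),
               tolerance = 1e-12)
  expect_equal(evaluate_spectrum(m1, -1.5) / evaluate_spectrum(m1, 1.5),
               oracle(-1.5) / oracle(1.5), tolerance = 1e-12)
  # the dominant term of that ratio is the detailed-balance factor
  expect_equal(evaluate_spectrum(m1, -1.5) / evaluate_spectrum(m1, 1.5),
               0.9442, tolerance = 2e-3)

  # infinite-temperature limit restores Stokes/anti-Stokes symmetry
  m_inf <- spectral_model(A_el = 0, A_inc = 0, sigma_inc = 1, slope = 0,
                          intercept = 0, temperature = 1e12,
                          modes = data.frame(mu = mu, sigma = sg,
                                             amp_plus = ap))
  expect_lt(abs(evaluate_spectrum(m_inf, -mu) - evaluate_spectrum(m_inf, mu)),
            1e-6)
})

test_that("detailed balance holds in integrated peak areas", {
  mu <- 1.2; sg <- 0.15
  m <- spectral_model(A_el = 0, A_inc = 0, sigma_inc = 1, slope = 0,
                      intercept = 0,
                      modes = data.frame(mu = mu, sigma = sg, amp_plus = 50))
  stokes <- integrate(function(w) evaluate_spectrum(m, w), 0.3, 2.1,
                      rel.tol = 1e-10)$value
  anti <- integrate(function(w) evaluate_spectrum(m, w), -2.1, -0.3,
                    rel.tol = 1e-10)$value
  # cross-tails are symmetric in this window, so the area ratio tracks
  # exp(-mu/kT) to a fraction of a percent
  expect_equal(anti / stokes, detailed_balance_ratio(mu), tolerance = 5e-3)
})

test_that("noiseless single-doublet scan is a zero-residual fixed point", {
  m <- spectral_model(A_el = 5000, A_inc = 300, sigma_inc = 1, slope = -2,
                      intercept = 30, sigma_el = 0.2,
                      modes = data.frame(mu = 0.514, sigma = 0.14,
                                         amp_plus = 300))
  ft <- fit_constant_q_scan(noiseless_scan(m), 1)
  expect_true(ft$converged)
  expect_lt(ft$chi2, 1e-6)
  expect_equal(ft$modes$mu, 0.514, tolerance = 1e-6)
  expect_equal(ft$modes$sigma, 0.14, tolerance = 1e-6)
  expect_equal(ft$modes$amp_plus, 300, tolerance = 1e-6)

  # refitting from the optimum leaves chi2 unchanged (idempotence)
  ft2 <- fit_constant_q_scan(noiseless_scan(m), 1, init = ft$model)
  expect_lt(abs(ft2$chi2 - ft$chi2), 1e-8 * max(ft$chi2, 1))
})

test_that("three-mode synthetic scans are recovered within 3 SE", {
  spec <- dispersion_spec_separated()
  sc <- simulate_constant_q_scan(spec, q = 1.4, seed = 7)
  ft <- fit_constant_q_scan(sc, 3)
  expect_true(ft$converged)
  truth <- attr(sc, "truth")$model$modes
  expect_true(all(abs(ft$modes$mu - truth$mu) <= 3 * ft$modes$se_mu))
  expect_equal(ft$modes$fwhm, 2 * ft$modes$sigma)
  # modes sorted ascending by energy
  expect_equal(ft$modes$mu, sort(ft$modes$mu))
})

test_that("zero-amplitude phonons are reported as not detected", {
  spec <- dispersion_spec("custom", branches = data.frame(
    branch = "lo", alpha = 4, q0 = 1.4, omega0 = 1.0, sigma = 0.2, amp = 0))
  sc <- simulate_constant_q_scan(spec, q = 1.4, seed = 4)
  ft <- suppressWarnings(fit_constant_q_scan(sc, 1))
  expect_false(isTRUE(ft$modes$detected[1]))
})

test_that("constant-E fits recover peak centres and the background", {
  spec <- dispersion_spec("custom", branches = data.frame(
    branch = "a", alpha = 10, q0 = 1.4, omega0 = 2.275, sigma = 0.2,
    amp = 300))
  sc <- simulate_constant_e_scan(spec, energy = 2.5, seed = 5)
  truth <- attr(sc, "truth")$peaks      # roots at 1.4 +/- 0.15
  expect_equal(sort(truth$q), c(1.25, 1.55), tolerance = 1e-12)
  ft <- fit_constant_e_scan(sc, 2)
  expect_true(ft$converged)
  expect_true(all(abs(ft$peaks$centre - sort(truth$q)) <=
                    3 * ft$peaks$se_centre))

  # displaced broad-background centre still recovered
  sc2 <- simulate_constant_e_scan(spec, energy = 2.5,
                                  backgrounds = list(B0 = 2000, B1 = 1.2,
                                                     A_bg = 150, c_bg = 2.2,
                                                     w_bg = 0.4), seed = 2)
  ft2 <- suppressWarnings(fit_constant_e_scan(sc2, 2))
  expect_equal(unname(ft2$background["c_bg"]), 2.2, tolerance = 0.1)

  # pure exponential background: the forced peak is consistent with 0
  sc0 <- simulate_constant_e_scan(dispersion_spec("custom", branches =
    data.frame(branch = "x", alpha = 5, q0 = 1.4, omega0 = 5, sigma = 0.2,
               amp = 0)), energy = 2.5, seed = 3)
  ft0 <- suppressWarnings(fit_constant_e_scan(sc0, 1))
  expect_true(!ft0$converged ||
                ft0$peaks$amp[1] <= 2 * ft0$peaks$se_amp[1] + 1e-9)
})

test_that("f_chi reproduces the printed formula and its invariances", {
  expect_equal(f_chi(500, 200, 108, 6), 300 / (200 / 101))
  expect_equal(f_chi(500, 200, 108, 6), 151.5)
  expect_equal(f_chi(200, 200, 108, 6), 0)
  # common rescaling of both chi2 leaves F_chi unchanged
  expect_equal(f_chi(1000, 400, 108, 6), f_chi(500, 200, 108, 6))
  expect_error(f_chi(100, 200, 108, 6), "nested")
  expect_error(f_chi(200, 0, 108, 6), "undefined")
  expect_error(f_chi(500, 200, 10, 6), "too few")
})

test_that("f_critical matches F-distribution quantile oracles", {
  expect_equal(f_critical(0.025, 4, 93), qf(0.975, 4, 93))
  expect_equal(f_critical(0.025, 4, 93), 2.93, tolerance = 0.01)
  expect_equal(f_critical(0.025, 1, 13), 6.41, tolerance = 0.01)
  expect_equal(f_critical(0.025, 1, Inf), qchisq(0.975, 1), tolerance = 1e-9)
  expect_equal(f_critical(0.025, 1, Inf), 5.02, tolerance = 0.01)
  expect_error(f_critical(0.6, 4, 93), "alpha")
})

test_that("decision logic accepts printed statistic/critical pairs in order", {
  d <- f_test_decision(c(94.25, 17.94), c(6.41, 6.04))
  expect_true(all(d$accepted))
  expect_equal(d$chosen_k, 3L)
  # sequential: a rejected increment stops the ladder
  d2 <- f_test_decision(c(94.25, 3.0), c(6.41, 6.04))
  expect_equal(d2$chosen_k, 2L)
  d3 <- f_test_decision(c(2.0, 50.0), c(6.41, 6.04))
  expect_equal(d3$chosen_k, 1L)
})

test_that("sequential selection finds the generated phonon count", {
  sel3 <- sequential_f_test(simulate_constant_q_scan(
    dispersion_spec_separated(), q = 1.4, seed = 12))
  expect_equal(sel3$chosen_k, 3L)
  # nested chi2 monotonicity
  chis <- vapply(sel3$fits, `[[`, 0, "chi2")
  expect_true(all(diff(chis) <= 1e-9))
  sel1 <- sequential_f_test(simulate_constant_q_scan(
    lo_only_spec(0.2, omega0 = 1.1), q = 1.4, seed = 12))
  expect_equal(sel1$chosen_k, 1L)
  expect_length(sel1$f_chi_values, length(sel1$fits) - 1L)
})

test_that("F_chi is invariant under common error rescaling", {
  sc <- simulate_constant_q_scan(dispersion_spec_separated(), q = 1.4,
                                 seed = 20)
  sc2 <- tas_scan(sc$kind, sc$fixed_value, sc$axis, sc$counts,
                  errors = 2 * sc$errors, temperature = sc$temperature,
                  sigma_el = sc$sigma_el)
  s1 <- sequential_f_test(sc)
  s2 <- sequential_f_test(sc2)
  expect_equal(s1$f_chi_values, s2$f_chi_values, tolerance = 1e-3)
})
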