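test_that("collect_points counts one point per detected mode", {
  spec <- dispersion_spec_separated()
  f_q <- fit_constant_q_scan(simulate_constant_q_scan(spec, q = 1.4,
                                                      seed = 5), 3)
  pts <- collect_points(list(f_q))
  expect_equal(nrow(pts), sum(f_q$modes$detected))
  expect_true(all(pts$q_par == 1.4))
  expect_true(all(pts$source == "constant_q"))

  f_e <- fit_constant_e_scan(simulate_constant_e_scan(
    dispersion_spec("custom", branches = data.frame(
      branch = "a", alpha = 10, q0 = 1.4, omega0 = 2.275, sigma = 0.2,
      amp = 300)), energy = 2.5, seed = 5), 2)
  pts_e <- collect_points(list(f_e))
  expect_equal(nrow(pts_e), sum(f_e$peaks$detected))
  expect_true(all(pts_e$energy == 2.5))

  both <- collect_points(list(f_q, f_e))
  expect_equal(nrow(both), nrow(pts) + nrow(pts_e))

  # a non-converged fit is skipped with a log message
  bad <- f_q; bad$converged <- FALSE
  expect_message(p2 <- collect_points(list(bad, f_e)), "skipping")
  expect_equal(nrow(p2), nrow(pts_e))
})

test_that("branch assignment is nearest-anchor with low-energy tie rule", {
  anchors <- list(lo = data.frame(q = 1.4, omega = 0.6),
                  fluid = data.frame(q = 1.4, omega = 1.1))
  pts <- data.frame(q_par = 1.4, energy = 0.55, energy_err = 0.05,
                    width = NA, source = "constant_q", branch = "unassigned")
  class(pts) <- c("dispersion_points", "data.frame")
  expect_equal(assign_branches(pts, anchors)$branch, "lo")

  # exactly equidistant between two anchors: lower-energy branch wins
  anchors2 <- list(gel = data.frame(q = 1.4, omega = 0.7),
                   fluid = data.frame(q = 1.4, omega = 1.3))
  pts$energy <- 1.0
  expect_equal(assign_branches(pts, anchors2)$branch, "gel")

  # beyond the cutoff: unassigned
  pts$energy <- 3.5
  expect_equal(assign_branches(pts, anchors2, cutoff = 0.5)$branch,
               "unassigned")
})

test_that("labelled synthetic point clouds are assigned correctly", {
  spec <- dispersion_spec_separated()
  pts <- simulate_dispersion_points(spec, energy_err = 0.05, seed = 3)
  lab <- assign_branches(pts, anchors_from_spec(spec))
  agree <- mean(lab$branch == lab$true_branch)
  expect_gte(agree, 0.95)
  # determinism: identical labels on a second run
  lab2 <- assign_branches(pts, anchors_from_spec(spec))
  expect_identical(lab$branch, lab2$branch)
})

test_that("quadratic minimum fit is exact on noiseless branch points", {
  for (p in list(c(4.8, 0.51), c(3.7, 0.66))) {   # the two l_o rows
    q <- seq(1.0, 2.0, by = 0.1)
    pts <- data.frame(q_par = q, energy = p[1] * (q - 1.4)^2 + p[2],
                      energy_err = 0.01, width = NA, source = "constant_q",
                      branch = "lo")
    bf <- fit_branch_minimum(pts)
    expect_equal(bf$alpha, p[1], tolerance = 1e-9)
    expect_equal(bf$q0, 1.4, tolerance = 1e-9)
    expect_equal(bf$omega0, p[2], tolerance = 1e-9)
  }
})

test_that("branch fit is equivariant under a shift in q", {
  q <- seq(1.0, 2.0, by = 0.1)
  set.seed(11)
  e <- 4.8 * (q - 1.4)^2 + 0.51 + rnorm(length(q), 0, 0.03)
  mk <- function(qq) {
    data.frame(q_par = qq, energy = e, energy_err = 0.03, width = NA,
               source = "constant_q", branch = "lo")
  }
  b0 <- fit_branch_minimum(mk(q), fit_range = c(1, 2))
  b1 <- fit_branch_minimum(mk(q + 0.3), fit_range = c(1.3, 2.3))
  expect_equal(b1$q0, b0$q0 + 0.3, tolerance = 1e-8)
  expect_equal(b1$alpha, b0$alpha, tolerance = 1e-8)
  expect_equal(b1$omega0, b0$omega0, tolerance = 1e-8)
})

test_that("branch fit guards small samples and downward curvature", {
  pts <- data.frame(q_par = c(1.1, 1.3, 1.5), energy = c(1, 0.6, 1),
                    energy_err = 0.05, width = NA, source = "constant_q",
                    branch = "lo")
  expect_error(fit_branch_minimum(pts), "at least 4")
  q <- seq(1, 2, by = 0.2)
  down <- data.frame(q_par = q, energy = -2 * (q - 1.4)^2 + 2,
                     energy_err = 0.05, width = NA, source = "constant_q",
                     branch = "x")
  expect_warning(bf <- fit_branch_minimum(down), "alpha")
  expect_true(bf$flagged)
})

test_that("noisy branch points recover truth within 2 SE per parameter", {
  q <- seq(1.0, 2.0, length.out = 12)
  hits <- c(alpha = 0, q0 = 0, omega0 = 0)
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    set.seed(i)
    pts <- data.frame(q_par = q,
                      energy = 4.8 * (q - 1.4)^2 + 0.51 +
                        rnorm(length(q), 0, 0.05),
                      energy_err = 0.05, width = NA, source = "constant_q",
                      branch = "lo")
    bf <- fit_branch_minimum(pts)
    hits <- hits + c(abs(bf$alpha - 4.8) <= 2 * bf$std_errors["alpha"],
                     abs(bf$q0 - 1.4) <= 2 * bf$std_errors["q0"],
                     abs(bf$omega0 - 0.51) <= 2 * bf$std_errors["omega0"])
  }
  expect_true(all(hits / n_rep >= 0.90))
})

test_that("two-sample z comparison reproduces the printed examples", {
  cmp <- compare_branch_parameters(table1_chol$lo, table1_asa$lo)
  w0 <- cmp[cmp$parameter == "omega0", ]
  al <- cmp[cmp$parameter == "alpha", ]
  expect_equal(w0$z, 0.15 / sqrt(0.02^2 + 0.07^2), tolerance = 1e-9)
  expect_equal(w0$z, 2.06, tolerance = 0.01)
  expect_true(w0$significant)
  expect_equal(al$z, 1.16, tolerance = 0.01)
  expect_false(al$significant)

  # identical fits give z = 0
  same <- compare_branch_parameters(table1_chol$fluid, table1_chol$fluid)
  expect_true(all(same$z == 0))
  expect_false(any(same$significant))

  # missing standard error: parameter skipped with warning
  broken <- table1_chol$lo
  broken$se["alpha"] <- NA
  expect_warning(cmp2 <- compare_branch_parameters(broken, table1_asa$lo),
                 "skipped")
  expect_false("alpha" %in% cmp2$parameter)
})
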