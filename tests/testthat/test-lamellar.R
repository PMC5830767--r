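test_that("lamellar spacing is 2 pi over the common peak separation", {
  pk <- data.frame(n = 1:7, q = 1:7 * 0.102832)
  expect_equal(lamellar_spacing(pk), 2 * pi / 0.102832, tolerance = 1e-9)
  expect_equal(lamellar_spacing(pk), 61.10, tolerance = 1e-3)
  expect_equal(lamellar_spacing(data.frame(n = 1:3, q = 1:3)), 2 * pi)
  expect_equal(lamellar_spacing(data.frame(n = 1:5, q = 1:5 * 0.103680)),
               60.60, tolerance = 1e-3)
  # invariant under intensity rescaling (positions only)
  expect_error(lamellar_spacing(data.frame(n = 1, q = 0.1)), "at least 2")
})

test_that("Bragg peaks are found, integrated, and labelled by order", {
  rs <- simulate_reflectivity(seed = 2)
  truth <- attr(rs, "truth")
  pk <- suppressWarnings(find_bragg_peaks(rs))
  expect_gte(nrow(pk$peaks), 5)
  expect_equal(pk$d_z, 61.1, tolerance = 1e-3)
  # integrated intensities recover the generator ratios within a few %
  common <- intersect(pk$peaks$n, truth$orders)
  meas <- pk$peaks$intensity[match(common, pk$peaks$n)]
  expect_equal(meas / meas[1], truth$I_n[common] / truth$I_n[common][1],
               tolerance = 0.05)
  # order labels survive a missing order (node orders are absent)
  expect_true(all(diff(pk$peaks$n) >= 1))

  # a single-order pattern is rejected
  q <- seq(0.05, 0.5, by = 0.001)
  one <- refl_scan(q, 50 + 5000 * exp(-(q - 0.1028)^2 / (2 * 0.004^2)))
  expect_error(find_bragg_peaks(one), "3")
})

test_that("ten-fold intensity ratios are integrated within 2%", {
  # two-component profile whose orders differ by an order of magnitude
  q <- seq(0.05, 0.45, by = 0.0005)
  dq <- 0.1
  lam <- 20 + 1e5 * exp(-(q - dq)^2 / (2 * 0.004^2)) +
    1e4 * exp(-(q - 2 * dq)^2 / (2 * 0.004^2)) +
    1e4 * exp(-(q - 3 * dq)^2 / (2 * 0.004^2))
  set.seed(8)
  rs <- refl_scan(q, rpois(length(q), lam))
  pk <- find_bragg_peaks(rs)
  r <- pk$peaks$intensity[1] / pk$peaks$intensity[2]
  expect_equal(r, 10, tolerance = 0.02)
})

test_that("SLD reconstruction has the standard amplitude and linearity", {
  pk <- data.frame(n = 1, q = 2 * pi / 61.1, intensity = 4)
  prof <- reconstruct_sld(pk, phases = 1)
  # single positive order: pure cosine, maximum at z = 0
  expect_equal(prof$z[which.max(prof$rho)], 0)
  expect_equal(max(prof$rho), sqrt(4 * 2 * pi / 61.1), tolerance = 1e-9)
  # flipping all phases negates the profile
  prof2 <- reconstruct_sld(pk, phases = -1)
  expect_equal(prof2$rho, -prof$rho)
  # phase array shorter than orders used is an error
  expect_error(reconstruct_sld(data.frame(n = 1:3, q = 1:3 * 0.1,
                                          intensity = 1), phases = c(1, -1)),
               "shorter")
})

test_that("forward/inverse round trip reproduces the band-limited profile", {
  rs <- simulate_reflectivity(seed = 6)
  truth <- attr(rs, "truth")
  pk <- suppressWarnings(find_bragg_peaks(rs))
  prof <- reconstruct_sld(pk, truth$phases)
  bl <- rep(0, length(prof$z))
  for (n in truth$orders)
    bl <- bl + sqrt(max(truth$I_n[n] * truth$q_n[n], 0)) * truth$phases[n] *
      cos(2 * pi * n * prof$z / truth$d_z)
  expect_gt(cor(prof$rho, bl), 0.99)
})

test_that("head-head spacing reads the interior minima with interpolation", {
  # analytic profile with minima placed at +/- 23.0 A
  z <- seq(-30.55, 30.55, by = 0.25)
  rho <- 1 - 2 * (exp(-(z - 23)^2 / (2 * 3^2)) + exp(-(z + 23)^2 / (2 * 3^2)))
  prof <- structure(list(z = z, rho = rho, phases = 1, d_z = 61.1),
                    class = "sld_profile")
  dhh <- head_head_spacing(prof)
  expect_equal(as.numeric(dhh), 46.0, tolerance = 0.02)

  # grid-offset minima: parabolic interpolation recovers within 0.1 A
  rho2 <- 1 - 2 * (exp(-(z - 22.87)^2 / 18) + exp(-(z + 22.87)^2 / 18))
  prof2 <- structure(list(z = z, rho = rho2, phases = 1, d_z = 61.1),
                     class = "sld_profile")
  expect_equal(as.numeric(head_head_spacing(prof2)), 2 * 22.87,
               tolerance = 0.1)

  # single-order cosine: minima on the boundary, not interior
  prof3 <- reconstruct_sld(data.frame(n = 1, q = 0.1028, intensity = 1),
                           phases = 1)
  expect_error(head_head_spacing(prof3), "interior")

  # asymmetric minima warn
  rho4 <- 1 - 2 * (exp(-(z - 24.5)^2 / 18) + exp(-(z + 22)^2 / 18))
  prof4 <- structure(list(z = z, rho = rho4, phases = 1, d_z = 61.1),
                     class = "sld_profile")
  expect_warning(head_head_spacing(prof4), "asymmetric")
})

test_that("area per tail follows the hexagonal packing relation", {
  expect_equal(area_per_tail(1.37), 8 * pi^2 / (sqrt(3) * 1.37^2),
               tolerance = 1e-12)
  expect_equal(area_per_tail(1.37), 24.29, tolerance = 1e-3)
  expect_equal(area_per_tail(1.381), 23.91, tolerance = 1e-3)
  # scaling law: doubling q_T divides the area by 4
  expect_equal(area_per_tail(2 * 1.37), area_per_tail(1.37) / 4)
  # strictly decreasing
  qs <- seq(0.5, 3, by = 0.1)
  expect_true(all(diff(area_per_tail(qs)) < 0))
  expect_error(area_per_tail(0), "> 0")
})

test_that("in-plane peak fit excludes contaminant windows", {
  q <- seq(1.0, 2.2, by = 0.002)
  lam <- 200 + 800 / (1 + (q - 1.37)^2 / 0.05^2) +
    600 * exp(-(q - 1.25)^2 / (2 * 0.004^2))   # silicon contaminant
  set.seed(5)
  sc <- refl_scan(q, rpois(length(q), lam))
  ip <- find_inplane_peak(sc)
  expect_equal(ip$q_T, 1.37, tolerance = 0.01)
  expect_equal(ip$A_T, area_per_tail(ip$q_T))
})
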