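test_that("lateral RDF is normalised to 1 for a homogeneous system", {
  set.seed(2)
  n <- 400
  pos <- cbind(runif(n, 0, 60), runif(n, 0, 60), 10)
  f <- membrane_frame(pos, rep("C1", n), rep("DMPC", n), 1:n, c(60, 60, 40))
  r <- lateral_rdf(list(f), 1:n, 1:n, r_max = 25, bin_width = 0.5,
                   same_leaflet = FALSE)
  expect_lt(mean(abs(r$g[r$r >= 10] - 1)), 0.05)
  # outer-quartile normalisation invariant
  outer_q <- r$r >= 0.75 * 25
  expect_true(mean(r$g[outer_q]) > 0.95 && mean(r$g[outer_q]) < 1.05)
})

test_that("hexagonal tail lattice gives the first RDF peak at its spacing", {
  fr <- build_membrane_frames(membrane_spec(n_lipids = 128,
                                            chol_fraction = 0,
                                            asa_fraction = 0),
                              n_frames = 2, seed = 1)
  r <- lateral_rdf(fr, list(resname = "DMPC", name = "^C[12]A$"),
                   list(resname = "DMPC", name = "^C[12]A$"),
                   r_max = 15, bin_width = 0.5)
  peak_bin <- r$r[which.max(r$g)]
  expect_true(4.8 >= peak_bin - 0.25 && 4.8 < peak_bin + 0.25)
})

test_that("r_max beyond the half box is rejected by name", {
  f <- uniform_square_frame()
  expect_error(lateral_rdf(list(f), list(resname = "DMPC"),
                           list(resname = "DMPC"), r_max = 40),
               "half the smallest")
})

test_that("grid areas are exact and conserved on a uniform lattice", {
  f <- uniform_square_frame()          # 100 lipids/leaflet, 70 x 70 box
  am <- grid_area_map(f)
  a <- lipid_areas(am)
  expect_equal(unique(round(a$area, 9)), 49.0)
  # conservation: claimed areas tile each leaflet exactly
  sums <- tapply(am$areas$area, am$areas$leaflet, sum)
  expect_equal(as.numeric(sums), c(4900, 4900))
})

test_that("displacing one lipid moves area between neighbours only", {
  f <- uniform_square_frame()
  # move lipid 1 towards lipid 2 (same row neighbours, upper leaflet);
  # the approached neighbour shrinks, the one left behind (periodic
  # image, lipid 10) grows, and the leaflet total is conserved
  f$positions[1, 1] <- f$positions[1, 1] + 2
  am <- grid_area_map(f)
  a <- am$areas[am$areas$leaflet == 1, ]
  expect_lt(a$area[a$res_id == 2], 49)
  expect_gt(a$area[a$res_id == 10], 49)
  expect_equal(sum(a$area), 4900)
})

test_that("generator frames recover the target DMPC area", {
  fr <- build_membrane_frames(membrane_spec(n_lipids = 128,
                                            chol_fraction = 0,
                                            asa_fraction = 0,
                                            apl_dmpc = 48.6),
                              n_frames = 1, seed = 3)
  m <- mean(lipid_areas(grid_area_map(fr[[1]]))$area)
  expect_equal(m, 48.6, tolerance = 1 / 48.6)   # within 1 A^2
})

test_that("area dilation near the drug appears in the distance profile", {
  fr <- build_membrane_frames(membrane_spec(n_lipids = 200,
                                            chol_fraction = 0,
                                            asa_fraction = 0.08,
                                            apl_dmpc = 48.6),
                              n_frames = 3, seed = 4)
  pr <- distance_resolved_area(fr, bins = seq(0, 30, by = 5))
  base <- mean(pr$statistic[pr$r_lo >= 10 & pr$counts > 0], na.rm = TRUE)
  ratio <- pr$statistic[1] / base
  expect_gt(ratio, 1.02)
  expect_lt(ratio, 1.08)
  # null case: no dilation, flat profile
  fr0 <- build_membrane_frames(membrane_spec(n_lipids = 200,
                                             chol_fraction = 0,
                                             asa_fraction = 0.08,
                                             apl_dmpc = 48.6,
                                             dilation = c(0, 5)),
                               n_frames = 3, seed = 4)
  pr0 <- distance_resolved_area(fr0, bins = seq(0, 30, by = 5))
  ok <- pr0$counts > 0
  expect_lt(diff(range(pr0$statistic[ok])), 0.02 * 48.6)
  expect_error(distance_resolved_area(
    build_membrane_frames(membrane_spec(n_lipids = 32, chol_fraction = 0,
                                        asa_fraction = 0), seed = 1)),
    "no ASA")
})

test_that("half-open distance bins put boundary values in the upper bin", {
  bins <- c(0, 5, 10)
  expect_equal(findInterval(5, bins, rightmost.closed = FALSE), 2L)
})

test_that("gauche fraction classifies both angle conventions", {
  expect_equal(gauche_fraction(c(180, 180, -180)), 0)
  expect_equal(gauche_fraction(c(60, -60, 180, 180)), 0.5)
  # sign-flip invariance
  set.seed(9)
  ang <- runif(500, -180, 180)
  expect_equal(gauche_fraction(ang), gauche_fraction(-ang))
  # Ryckaert-Bellemans convention: trans at 0
  expect_equal(gauche_fraction(c(0, 0, 120, -120), convention = "rb"), 0.5)
  expect_error(gauche_fraction(numeric(0)), "empty")
  expect_error(gauche_fraction(200), "degrees")
})

test_that("Bernoulli-sampled gauche states are recovered at rate 0.3", {
  set.seed(42)
  n <- 1e4
  ang <- ifelse(runif(n) < 0.3, sample(c(-60, 60), n, replace = TRUE), 180)
  expect_equal(gauche_fraction(ang), 0.3, tolerance = 0.02 / 0.3)
})

test_that("chain dihedrals computed from frames match the drawn states", {
  fr <- build_membrane_frames(membrane_spec(n_lipids = 64,
                                            chol_fraction = 0,
                                            asa_fraction = 0.1,
                                            gauche_near = 0.35,
                                            gauche_far = 0.25, jitter = 0),
                              n_frames = 1, seed = 9)
  truth <- attr(fr, "truth")$gauche
  f <- fr[[1]]
  for (rid in unique(f$res_ids[f$res_names == "DMPC"])[1:10]) {
    di <- lipidphonon:::chain_dihedrals(f, rid)
    for (ch in 1:2) {
      g <- sum(abs(di[[c("sn1", "sn2")[ch]]]) < 120)
      expect_equal(g, truth$n_gauche[truth$res_id == rid &
                                       truth$chain == ch])
    }
  }
})

test_that("distance-resolved gauche recovers near/far plateaus", {
  fr <- build_membrane_frames(membrane_spec(n_lipids = 200,
                                            chol_fraction = 0,
                                            asa_fraction = 0.1,
                                            gauche_near = 0.35,
                                            gauche_far = 0.25,
                                            gauche_radius = 6),
                              n_frames = 6, seed = 11)
  expect_message(
    pr <- distance_resolved_gauche(fr, bins = c(0, 6, 12, 18, 24, 30),
                                   stride = 50),
    "membership evaluated once")            # stride > frame count
  expect_equal(pr$statistic[1], 0.35, tolerance = 0.02 / 0.35)
  expect_equal(pr$statistic[3], 0.25, tolerance = 0.02 / 0.25)

  # uniform probability: flat profile
  fr0 <- build_membrane_frames(membrane_spec(n_lipids = 200,
                                             chol_fraction = 0,
                                             asa_fraction = 0.1,
                                             gauche_near = 0.25,
                                             gauche_far = 0.25),
                               n_frames = 6, seed = 12)
  pr0 <- distance_resolved_gauche(fr0, bins = c(0, 6, 12, 18, 24, 30),
                                  stride = 2)
  ok <- pr0$counts > 1000
  expect_lt(diff(range(pr0$statistic[ok])), 0.04)
})

test_that("density profiles conserve electrons and see deuteration", {
  fr <- build_membrane_frames(membrane_spec(n_lipids = 64,
                                            chol_fraction = 0.3,
                                            asa_fraction = 0.1,
                                            waters_per_lipid = 5),
                              n_frames = 2, seed = 5)
  dp <- density_profile(fr, list(SOL = list(resname = "SOL"),
                                 ASA = list(resname = "ASA")), "electron")
  f <- fr[[1]]
  n_w <- sum(f$res_names == "SOL" & f$atom_names == "OW")
  integral <- sum(dp$density[, "SOL"]) * dp$bin_width * prod(f$box[1:2])
  expect_equal(integral, n_w * 10, tolerance = 1e-3)  # 10 e- per water

  # drug density peaks at headgroup depth (d_hh / 2 = 23 A)
  z_max <- dp$z[which.max(dp$density[, "ASA"])]
  expect_lt(abs(abs(z_max) - 23), 2)

  # neutron mode: mapping tail H to D flips the tail-region contrast
  n <- 40
  pos <- cbind(runif(n, 0, 30), runif(n, 0, 30), rnorm(n, 30, 2))
  hf <- membrane_frame(pos, rep("HT", n), rep("DMPC", n), 1:n,
                       c(30, 30, 60), elements = rep("H", n))
  d_h <- density_profile(list(hf), list(tails = list(resname = "DMPC")),
                         "neutron_sl")
  d_d <- density_profile(list(hf), list(tails = list(resname = "DMPC")),
                         "neutron_sl",
                         deuteration_map = list(list(resname = "DMPC")))
  core <- abs(d_h$z) < 5
  expect_lt(sum(d_h$density[core, 1]), 0)   # b_H = -3.74 fm
  expect_gt(sum(d_d$density[core, 1]), 0)   # b_D = +6.67 fm
  expect_equal(sum(d_d$density[core, 1]) / sum(d_h$density[core, 1]),
               6.671 / -3.739, tolerance = 1e-6)
})

test_that("contact fractions count close residue pairs per frame", {
  mkf <- function(d) {
    pos <- rbind(c(10, 10, 30), c(10 + d, 10, 30))
    membrane_frame(pos, c("O1", "O2"), c("CHOL", "ASA"), 1:2, c(40, 40, 60))
  }
  # fixed 3.0 A contact in every frame
  cf <- contact_fraction(list(mkf(3), mkf(3)), list(resname = "CHOL"),
                         list(resname = "ASA"))
  expect_equal(cf$pairs$time_fraction, 1.0)
  # never closer than 8 A
  cf0 <- contact_fraction(list(mkf(8), mkf(8)), list(resname = "CHOL"),
                          list(resname = "ASA"))
  expect_equal(nrow(cf0$pairs), 0)
  # contact in exactly 30% of a constructed trajectory
  frames <- c(replicate(3, mkf(3), simplify = FALSE),
              replicate(7, mkf(9), simplify = FALSE))
  cf3 <- contact_fraction(frames, list(resname = "CHOL"),
                          list(resname = "ASA"))
  expect_equal(cf3$pairs$time_fraction, 0.3)
  expect_equal(sum(cf3$per_frame), 3)
})
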