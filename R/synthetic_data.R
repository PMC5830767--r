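# Synthetic-data generators with attached ground truth: noisy
# triple-axis scans from a parameterised three-branch dispersion,
# lamellar reflectivities from analytic SLD profiles, and coarse
# membrane frames with controlled lateral organization. Every
# generator is deterministic for a fixed seed, and every output
# carries machine-readable truth so analysis tests never re-derive it
# by eye.

#' Three-branch dispersion specification
#'
#' Quadratic-minimum parameters per coexisting-phase branch plus the
#' Lorentzian mode width and amplitude scale used when spectra are
#' synthesised. The built-in presets are the fitted parameter sets of
#' the two samples (30 mol% cholesterol; 29 mol% cholesterol + 10 mol%
#' drug), with liquid-ordered mode widths 0.14 and 0.31 meV
#' respectively.
#'
#' @param sample `"chol"`, `"asa"`, or `"custom"` (then supply
#'   `branches`).
#' @param branches Data frame with columns `branch`, `alpha`
#'   (meV A^2), `q0` (1/A), `omega0` (meV), `sigma` (meV HWHM), `amp`
#'   (counts), ordered by `omega0`.
#' @return An object of class `dispersion_spec`.
#' @export
dispersion_spec <- function(sample = c("chol", "asa", "custom"),
                            branches = NULL) {
  sample <- match.arg(sample)
  if (is.null(branches)) {
    branches <- switch(sample,
      chol = data.frame(
        branch = c("lo", "gel", "fluid"),
        alpha = c(4.8, 41, 14.9), q0 = c(1.4, 1.4, 1.4),
        omega0 = c(0.51, 0.72, 1.09), sigma = c(0.14, 0.25, 0.30),
        amp = c(300, 200, 250)),
      asa = data.frame(
        branch = c("lo", "gel", "fluid"),
        alpha = c(3.7, 1.5, 11.0), q0 = c(1.4, 1.4, 1.4),
        omega0 = c(0.66, 0.65, 1.12), sigma = c(0.31, 0.25, 0.30),
        amp = c(300, 200, 250)),
      custom = stop("sample = 'custom' requires a branches data frame"))
  }
  branches <- as.data.frame(branches)
  stopifnot(all(c("branch", "alpha", "q0", "omega0", "sigma", "amp") %in%
                  names(branches)))
  if (any(branches$omega0 <= 0) || any(branches$alpha <= 0))
    stop("omega0 and alpha must be > 0")
  branches <- branches[order(branches$omega0), ]
  rownames(branches) <- NULL
  structure(list(sample = sample, branches = branches),
            class = "dispersion_spec")
}

#' Well-separated three-mode spec for fitting exercises
#'
#' Branch minima at 0.6, 1.1 and 1.8 meV (all at q0 = 1.4 1/A), widths
#' 0.12-0.2 meV: a spectrum whose three doublets are individually
#' resolvable at realistic counting statistics.
#'
#' @return A [dispersion_spec].
#' @export
dispersion_spec_separated <- function() {
  dispersion_spec("custom", branches = data.frame(
    branch = c("lo", "fluid", "gel"),
    alpha = c(4.8, 11.0, 20.0), q0 = c(1.4, 1.4, 1.4),
    omega0 = c(0.6, 1.1, 1.8), sigma = c(0.12, 0.15, 0.2),
    amp = c(320, 280, 220)))
}

# branch mode energies at a given q (quadratic dispersion)
branch_energies <- function(spec, q) {
  b <- spec$branches
  data.frame(branch = b$branch, mu = b$alpha * (q - b$q0)^2 + b$omega0,
             sigma = b$sigma, amp = b$amp)
}

default_backgrounds <- function() {
  list(A_el = 5000, A_inc = 300, sigma_inc = 1.0, slope = -2, intercept = 30)
}

#' Simulate a constant-q energy scan
#'
#' Evaluates each branch's quadratic dispersion at `q` to place the
#' phonon doublets, builds the full spectral model (detailed balance
#' applied to the anti-Stokes side), and draws Poisson counts.
#'
#' @param spec A [dispersion_spec].
#' @param q Fixed in-plane momentum (1/A).
#' @param omega_grid Energy grid spanning both Stokes and anti-Stokes
#'   sides; the default gives 108 points from -1.5 to 3.85 meV.
#' @param counts_scale Multiplies all amplitudes (> 0).
#' @param backgrounds List with `A_el`, `A_inc`, `sigma_inc`, `slope`,
#'   `intercept`.
#' @param temperature Temperature (K).
#' @param sigma_el Elastic resolution width (meV).
#' @param seed Integer seed; identical seeds give identical counts.
#' @param noise `"poisson"` (counting statistics) or `"gaussian"` for
#'   high-count work.
#' @return A [tas_scan] with attribute `truth`: the generating
#'   [spectral_model] and the per-branch mode table.
#' @export
simulate_constant_q_scan <- function(spec, q = 1.37,
                                     omega_grid = seq(-1.5, 3.85, by = 0.05),
                                     counts_scale = 1,
                                     backgrounds = default_backgrounds(),
                                     temperature = lp_constants$default_temperature,
                                     sigma_el = 0.3, seed = 1L,
                                     noise = c("poisson", "gaussian")) {
  noise <- match.arg(noise)
  if (counts_scale <= 0) stop("counts_scale must be > 0")
  if (max(omega_grid) <= 0 || min(omega_grid) >= 0)
    stop("omega_grid must span both Stokes and anti-Stokes sides")
  be <- branch_energies(spec, q)
  be <- be[be$mu > 0, , drop = FALSE]
  modes <- data.frame(mu = be$mu, sigma = be$sigma,
                      amp_plus = be$amp * counts_scale)
  model <- spectral_model(A_el = backgrounds$A_el * counts_scale,
                          A_inc = backgrounds$A_inc * counts_scale,
                          sigma_inc = backgrounds$sigma_inc,
                          slope = backgrounds$slope * counts_scale,
                          intercept = backgrounds$intercept * counts_scale,
                          modes = modes, temperature = temperature,
                          sigma_el = sigma_el)
  lambda <- pmax(evaluate_spectrum(model, omega_grid), 0)
  counts <- with_seed(seed, {
    if (noise == "poisson") stats::rpois(length(lambda), lambda)
    else pmax(0, stats::rnorm(length(lambda), lambda, sqrt(pmax(lambda, 1))))
  })
  scan <- tas_scan("constant_q", fixed_value = q, axis = omega_grid,
                   counts = counts, temperature = temperature,
                   sigma_el = sigma_el)
  attr(scan, "truth") <- list(model = model, modes = cbind(be, counts_scale),
                              seed = seed)
  scan
}

#' Simulate a constant-energy q scan
#'
#' Phonon peaks sit at the two quadratic-dispersion roots
#' `q0 +/- sqrt((E - omega0) / alpha)` of every branch the energy
#' crosses (a tangent double root when `E = omega0`), on an empirical
#' exponential background plus a broad Lorentzian near 2.5 1/A. Peak
#' amplitudes are scaled by `1 / |domega/dq|` at the crossing (bounded
#' above), a density-of-states flavour.
#'
#' @param spec A [dispersion_spec].
#' @param energy Fixed energy transfer (meV).
#' @param q_grid Momentum grid (1/A).
#' @param backgrounds List with `B0`, `B1`, `A_bg`, `c_bg`, `w_bg`.
#' @param width_q Lorentzian peak HWHM in q (1/A).
#' @param counts_scale Amplitude multiplier.
#' @param seed Integer seed.
#' @return A [tas_scan] of kind `constant_E` with attribute `truth`
#'   (peak positions per branch). If no branch is crossed the scan is
#'   pure background and `truth$crossed` is `FALSE`.
#' @export
simulate_constant_e_scan <- function(spec, energy,
                                     q_grid = seq(0.8, 3.0, by = 0.02),
                                     backgrounds = list(B0 = 2000, B1 = 1.2,
                                                        A_bg = 150, c_bg = 2.5,
                                                        w_bg = 0.4),
                                     width_q = 0.05, counts_scale = 1,
                                     seed = 1L) {
  b <- spec$branches
  peaks <- list()
  for (i in seq_len(nrow(b))) {
    if (energy < b$omega0[i]) next
    dq <- sqrt((energy - b$omega0[i]) / b$alpha[i])
    for (s in if (dq > 0) c(-1, 1) else 0) {
      qc <- b$q0[i] + s * dq
      slope <- abs(2 * b$alpha[i] * dq)
      # density-of-states flavour: amplitude ~ 1 / |domega/dq| at the
      # crossing, bounded above so the tangency stays finite
      amp <- b$amp[i] * counts_scale * min(1, 3 / max(slope, 1e-6))
      peaks[[length(peaks) + 1L]] <- data.frame(
        branch = b$branch[i], q = qc, amp = amp, width = width_q)
      if (dq == 0) break
    }
  }
  lambda <- backgrounds$B0 * counts_scale * exp(-backgrounds$B1 * q_grid) +
    backgrounds$A_bg * counts_scale /
      (1 + (q_grid - backgrounds$c_bg)^2 / backgrounds$w_bg^2)
  crossed <- length(peaks) > 0L
  if (crossed) {
    pk <- do.call(rbind, peaks)
    pk <- pk[pk$q > min(q_grid) & pk$q < max(q_grid), , drop = FALSE]
    for (i in seq_len(nrow(pk)))
      lambda <- lambda + pk$amp[i] / (1 + (q_grid - pk$q[i])^2 / pk$width[i]^2)
  } else {
    pk <- data.frame(branch = character(), q = numeric(), amp = numeric(),
                     width = numeric())
    message("constant-E scan at ", energy,
            " meV crosses no branch: pure background")
  }
  counts <- with_seed(seed, stats::rpois(length(lambda), pmax(lambda, 0)))
  scan <- tas_scan("constant_E", fixed_value = energy, axis = q_grid,
                   counts = counts)
  attr(scan, "truth") <- list(peaks = pk, crossed = crossed,
                              backgrounds = backgrounds, seed = seed)
  scan
}

#' Analytic SLD profile of a chain-deuterated bilayer
#'
#' Returns `function(z)` on a relative scale: a deuterated-tail plateau
#' centred at z = 0, heavy-water maxima at the repeat boundary, and
#' headgroup dips (the profile minima) at `+/- d_hh / 2`.
#'
#' @param d_z Lamellar repeat (A).
#' @param d_hh Head-head spacing: separation of the two minima (A).
#' @param head_width Gaussian width of the headgroup dip (A).
#' @param head_depth Depth of the dip (relative units).
#' @return A vectorised function of z (A).
#' @export
bilayer_sld_spec <- function(d_z = 61.1, d_hh = 46, head_width = 2,
                             head_depth = 1.3) {
  force(d_z); force(d_hh); force(head_width); force(head_depth)
  function(z) {
    0.45 * (tanh((z + 14) / 1.2) - tanh((z - 14) / 1.2)) +
      0.8 * (exp(-(z - d_z / 2)^2 / (2 * 2^2)) +
               exp(-(z + d_z / 2)^2 / (2 * 2^2))) -
      head_depth * (exp(-(z - d_hh / 2)^2 / (2 * head_width^2)) +
                      exp(-(z + d_hh / 2)^2 / (2 * head_width^2)))
  }
}

#' Cosine form factors of a density profile
#'
#' `F_n = integral over one repeat of rho(z) cos(2 pi n z / d_z) dz`,
#' evaluated on a fine grid (trapezoid rule).
#'
#' @param rho_fn Vectorised density function of z.
#' @param d_z Repeat distance (A).
#' @param orders Integer orders.
#' @return Numeric vector of form factors.
#' @export
form_factors <- function(rho_fn, d_z, orders) {
  z <- seq(-d_z / 2, d_z / 2, length.out = 4001L)
  rho <- rho_fn(z)
  vapply(orders, function(n) {
    integrand <- rho * cos(2 * pi * n * z / d_z)
    sum((integrand[-1L] + integrand[-length(z)]) / 2) * diff(z[1:2])
  }, 0)
}

#' Simulate an out-of-plane reflectivity scan
#'
#' Forward-models a Bragg series from an analytic SLD profile:
#' `I_n = F_n^2 / q_n` (Lorentz factor for oriented multilayers),
#' rendered as Gaussian peaks on a smooth decaying background with
#' Poisson noise. The attached truth carries the form factors, the
#' phase vector `sign(F_n)`, the exact intensities, and the analytic
#' head-minimum separation.
#'
#' @param rho_fn Density profile `function(z)`, e.g.
#'   [bilayer_sld_spec()].
#' @param d_z Lamellar repeat (A).
#' @param n_orders Number of Bragg orders (>= 3).
#' @param peak_width Gaussian width of the rendered peaks (1/A).
#' @param counts_scale Scales the strongest peak to roughly this many
#'   counts (default 5000).
#' @param noise_scale 1 for Poisson counting noise; 0 disables noise.
#' @param seed Integer seed.
#' @return A [refl_scan] with attribute `truth`.
#' @export
simulate_reflectivity <- function(rho_fn = bilayer_sld_spec(), d_z = 61.1,
                                  n_orders = 9L, peak_width = 0.004,
                                  counts_scale = 20000, noise_scale = 1,
                                  seed = 1L) {
  if (n_orders < 3L) stop("need n_orders >= 3")
  orders <- seq_len(n_orders)
  q_n <- 2 * pi * orders / d_z
  Fn <- form_factors(rho_fn, d_z, orders)
  In <- Fn^2 / q_n
  scale <- counts_scale / max(In / (peak_width * sqrt(2 * pi)))
  q <- seq(0.5 * q_n[1L], q_n[n_orders] + 6 * 2 * pi / d_z / 10, by = 0.001)
  lambda <- 30 + 300 * exp(-4 * q)
  for (i in orders)
    lambda <- lambda + scale * In[i] / (peak_width * sqrt(2 * pi)) *
      exp(-(q - q_n[i])^2 / (2 * peak_width^2))
  counts <- if (noise_scale > 0)
    with_seed(seed, stats::rpois(length(lambda), lambda * noise_scale)) / noise_scale
  else lambda
  scan <- refl_scan(q, counts)
  z <- seq(-d_z / 2, d_z / 2, by = 0.01)
  interior <- abs(z) < 0.45 * d_z
  zl <- z[interior & z < 0]; zr <- z[interior & z > 0]
  d_hh_analytic <- zr[which.min(rho_fn(zr))] - zl[which.min(rho_fn(zl))]
  # what an N-order Fourier measurement can represent: the head-minimum
  # separation of the band-limited profile is the recoverable truth
  bl <- rep(0, length(z))
  for (n in orders)
    bl <- bl + sqrt(pmax(In[n] * q_n[n], 0)) * sign(Fn)[n] *
      cos(2 * pi * n * z / d_z)
  d_hh_bl <- zr[which.min(bl[match(zr, z)])] - zl[which.min(bl[match(zl, z)])]
  attr(scan, "truth") <- list(orders = orders, q_n = q_n, F_n = Fn,
                              I_n = In * scale, phases = sign(Fn),
                              d_z = d_z, d_hh = d_hh_bl,
                              d_hh_analytic = d_hh_analytic, seed = seed)
  scan
}

## ---- membrane frames ---------------------------------------------------

#' Membrane generator specification
#'
#' Defines the study conditions of the coarse membrane frames: a
#' jittered hexagonal tail lattice (first-neighbour spacing
#' `tail_spacing`, the chain-correlation distance), cholesterol on
#' single tail sites preferring rings at `chol_rings` around the drug,
#' drug molecules on an oblique superlattice at headgroup depth, a
#' local area dilation around each drug molecule, and chains grown
#' bead-by-bead with a per-dihedral gauche probability that may differ
#' near the drug.
#'
#' When `apl_dmpc` is supplied it overrides `tail_spacing` via the
#' hexagonal relation `apl_dmpc = sqrt(3) * s^2` (two tail sites per
#' lipid).
#'
#' @param n_lipids Total lipids (DMPC + CHOL), both leaflets.
#' @param chol_fraction,asa_fraction Mole fractions relative to
#'   `n_lipids` (sum <= 1).
#' @param tail_spacing Hexagonal tail-site spacing (A).
#' @param apl_dmpc Optional target DMPC area (A^2); overrides spacing.
#' @param superlattice `c(a, b, gamma)`: oblique drug lattice (A, A,
#'   degrees).
#' @param dilation `c(frac, radius)`: fractional area increase within
#'   `radius` (A) of a drug molecule.
#' @param gauche_near,gauche_far Per-dihedral gauche probabilities for
#'   lipids within / beyond `gauche_radius` of the nearest drug.
#' @param gauche_radius Distance threshold (A).
#' @param chol_rings Preferred CHOL distances from the drug (A);
#'   `NULL` disables the preference.
#' @param d_hh Head-head spacing (A): headgroup depth is `d_hh / 2`.
#' @param box_z Box height (A).
#' @param n_tail_beads Carbons per chain (default 14, myristoyl).
#' @param waters_per_lipid Water molecules per lipid (3-site, placed
#'   outside the headgroups).
#' @param jitter Gaussian positional noise per frame (A).
#' @return An object of class `membrane_spec`.
#' @export
membrane_spec <- function(n_lipids = 128L, chol_fraction = 0.3,
                          asa_fraction = 0.1, tail_spacing = 4.8,
                          apl_dmpc = NULL,
                          superlattice = c(a = 21.2, b = 18, gamma = 103),
                          dilation = c(frac = 0.05, radius = 5),
                          gauche_near = 0.25, gauche_far = 0.25,
                          gauche_radius = 6, chol_rings = c(11.5, 19),
                          d_hh = 46, box_z = 61.1, n_tail_beads = 14L,
                          waters_per_lipid = 0, jitter = 0.15) {
  if (chol_fraction < 0 || asa_fraction < 0 ||
      chol_fraction + asa_fraction > 1)
    stop("fractions must be in [0, 1] and sum to at most 1")
  if (!is.null(apl_dmpc)) tail_spacing <- sqrt(apl_dmpc / sqrt(3))
  if (tail_spacing <= 0 || d_hh <= 0 || box_z <= 0)
    stop("spacings and box dimensions must be > 0")
  structure(list(n_lipids = as.integer(n_lipids),
                 chol_fraction = chol_fraction, asa_fraction = asa_fraction,
                 tail_spacing = tail_spacing,
                 apl_dmpc = apl_dmpc %||% (sqrt(3) * tail_spacing^2),
                 superlattice = superlattice, dilation = dilation,
                 gauche_near = gauche_near, gauche_far = gauche_far,
                 gauche_radius = gauche_radius, chol_rings = chol_rings,
                 d_hh = d_hh, box_z = box_z,
                 n_tail_beads = as.integer(n_tail_beads),
                 waters_per_lipid = waters_per_lipid, jitter = jitter),
            class = "membrane_spec")
}

#' Build coarse membrane frames with known ground truth
#'
#' Two leaflets of a jittered hexagonal tail lattice. Each DMPC owns
#' two adjacent tail sites (chains grown bead-by-bead with the
#' configured gauche probability; the drawn dihedral states are
#' recorded), each CHOL one site, and drug molecules sit at headgroup
#' depth on the oblique superlattice; the lattice is radially dilated
#' around every drug molecule. Frames differ by their positional
#' jitter and freshly drawn dihedral states.
#'
#' @param spec A [membrane_spec].
#' @param n_frames Number of frames.
#' @param seed Integer seed; fixed seed gives identical frames.
#' @return List of [membrane_frame] objects with attribute `truth`
#'   (census, drug lattice points, per-frame gauche tables, dilation
#'   and area targets).
#' @export
build_membrane_frames <- function(spec, n_frames = 1L, seed = 1L) {
  stopifnot(inherits(spec, "membrane_spec"))
  with_seed(seed, build_frames_impl(spec, n_frames))
}

build_frames_impl <- function(spec, n_frames) {
  s <- spec$tail_spacing
  n_leaf <- spec$n_lipids %/% 2L
  n_chol <- round(spec$chol_fraction * n_leaf)
  n_dmpc <- n_leaf - n_chol
  n_asa <- round(spec$asa_fraction * n_leaf)
  # pair slots: two adjacent sites along x form one DMPC; chol fills
  # single sites of dedicated slots
  ring_mode <- !is.null(spec$chol_rings) && n_asa > 0L && n_chol > 0L
  # ring-placed cholesterol consumes one slot each; lattice-placed
  # cholesterol packs two per slot
  slots_needed <- n_dmpc + if (ring_mode) n_chol else ceiling(n_chol / 2)
  # pick lattice dimensions with minimal vacant slots (vacancies
  # inflate the claimed areas), near-square aspect as tie-break
  ny0 <- max(2L, round(sqrt(2 * slots_needed / 0.866)))
  best <- NULL
  for (ny_try in max(2L, ny0 - 6L):(ny0 + 6L)) {
    nxh <- ceiling(slots_needed / ny_try)
    excess <- nxh * ny_try - slots_needed
    aspect <- abs(2 * nxh - ny_try * 0.866)
    if (is.null(best) || excess < best$excess ||
        (excess == best$excess && aspect < best$aspect))
      best <- list(nx = 2L * nxh, ny = ny_try, excess = excess,
                   aspect = aspect)
  }
  nx <- best$nx; ny <- best$ny
  Lx <- nx * s
  Ly <- ny * s * sqrt(3) / 2
  if (spec$apl_dmpc * n_dmpc > Lx * Ly * 1.001)
    stop("infeasible packing: requested areas exceed the box")
  box <- c(Lx, Ly, spec$box_z)

  # hexagonal sites, row-major; odd rows offset by s/2
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  sx <- (ix + 0.5 * (iy %% 2L)) * s
  sy <- iy * s * sqrt(3) / 2
  slot_id <- (iy * (nx %/% 2L)) + (ix %/% 2L) + 1L   # pair slot per site

  # drug superlattice points (shared x,y pattern, one set per leaflet)
  asa_pts <- superlattice_points(spec$superlattice, Lx, Ly)
  truth_frames <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  leaf_layout <- list()
  for (lf in c(1L, -1L)) {
    pts <- if (n_asa > 0L && nrow(asa_pts)) {
      take <- min(n_asa, nrow(asa_pts))
      asa_pts[sample.int(nrow(asa_pts), take), , drop = FALSE]
    } else asa_pts[0L, , drop = FALSE]
    # nearest-drug distance per site (min image)
    dmin <- site_asa_distance(sx, sy, pts, Lx, Ly)
    # slot assignment: chol slots prefer sites whose distances to the
    # two nearest drug molecules both fall on the configured rings
    n_slots <- (nx %/% 2L) * ny
    chol_slots <- ceiling(n_chol / 2)
    chol_pos <- NULL
    if (!is.null(spec$chol_rings) && nrow(pts) && n_chol > 0L) {
      # cholesterol sits at the configured ring radii around the drug
      # (rings populated evenly, angles drawn at random); each
      # placement consumes the nearest pair slot so packing stays dense
      rings <- rep(spec$chol_rings, length.out = n_chol)
      host <- rep(seq_len(nrow(pts)), length.out = n_chol)
      ang <- stats::runif(n_chol, 0, 2 * pi)
      chol_pos <- cbind((pts[host, 1L] + rings * cos(ang)) %% Lx,
                        (pts[host, 2L] + rings * sin(ang)) %% Ly)
      chol_slot_ids <- integer(0)
      for (i in seq_len(n_chol)) {
        dx <- min_image(sx - chol_pos[i, 1L], Lx)
        dy <- min_image(sy - chol_pos[i, 2L], Ly)
        near_slots <- slot_id[order(dx^2 + dy^2)]
        chol_slot_ids <- c(chol_slot_ids,
                           setdiff(near_slots, chol_slot_ids)[1L])
      }
    } else if (n_chol > 0L) {
      chol_slot_ids <- order(stats::runif(n_slots))[seq_len(chol_slots)]
    } else {
      chol_slot_ids <- integer(0)
    }
    rest <- setdiff(seq_len(n_slots), chol_slot_ids)
    dmpc_slot_ids <- sort(sample(rest, n_dmpc))
    leaf_layout[[as.character(lf)]] <- list(
      pts = pts, dmin = dmin, chol_slot_ids = chol_slot_ids,
      chol_pos = chol_pos, dmpc_slot_ids = dmpc_slot_ids)
  }

  for (f in seq_len(n_frames)) {
    atoms <- list()
    gauche_tab <- list()
    rid <- 0L
    for (lf in c(1L, -1L)) {
      lay <- leaf_layout[[as.character(lf)]]
      pts <- lay$pts
      # radial dilation of sites around each drug molecule
      dil <- dilate_sites(sx, sy, pts, Lx, Ly,
                          spec$dilation[[1L]], spec$dilation[[2L]],
                          cell = spec$tail_spacing)
      dmin <- site_asa_distance(dil$x, dil$y, pts, Lx, Ly)
      z_head <- lf * spec$d_hh / 2
      z_start <- lf * (spec$d_hh / 2 - 3)
      for (sl in lay$dmpc_slot_ids) {
        sites <- which(slot_id == sl)
        rid <- rid + 1L
        near <- min(dmin[sites]) < spec$gauche_radius
        p_g <- if (near) spec$gauche_near else spec$gauche_far
        hx <- dil$x[sites[1L]] + min_image(dil$x[sites[2L]] - dil$x[sites[1L]], Lx) / 2
        hy <- dil$y[sites[1L]] + min_image(dil$y[sites[2L]] - dil$y[sites[1L]], Ly) / 2
        atoms[[length(atoms) + 1L]] <- data.frame(
          name = "P", res = "DMPC", rid = rid, x = hx, y = hy, z = z_head)
        for (ch in 1:2) {
          nd <- spec$n_tail_beads - 3L
          g_state <- stats::runif(nd) < p_g
          g_sign <- sample(c(-1, 1), nd, replace = TRUE)
          dihedrals <- ifelse(g_state, g_sign * 60, 180)
          chain <- grow_chain(c(dil$x[sites[ch]], dil$y[sites[ch]], z_start),
                              direction = -lf, dihedrals = dihedrals,
                              phase = stats::runif(1) * 360)
          atoms[[length(atoms) + 1L]] <- data.frame(
            name = sprintf("C%d%s", ch, LETTERS[seq_len(nrow(chain))]),
            res = "DMPC", rid = rid, x = chain[, 1L], y = chain[, 2L],
            z = chain[, 3L])
          gauche_tab[[length(gauche_tab) + 1L]] <- data.frame(
            frame = f, res_id = rid, chain = ch, near = near, p = p_g,
            n_gauche = sum(g_state), n_dihedral = nd)
        }
      }
      if (!is.null(lay$chol_pos)) {
        for (k in seq_len(nrow(lay$chol_pos))) {
          rid <- rid + 1L
          zz <- z_start - lf * c(0, 4, 8, 12)
          atoms[[length(atoms) + 1L]] <- data.frame(
            name = c("O3", "CA", "CB", "CC"), res = "CHOL", rid = rid,
            x = lay$chol_pos[k, 1L], y = lay$chol_pos[k, 2L], z = zz)
        }
      } else {
        placed_chol <- 0L
        for (sl in lay$chol_slot_ids) {
          sites <- which(slot_id == sl)
          for (k in seq_along(sites)) {
            if (placed_chol >= n_chol) break
            placed_chol <- placed_chol + 1L
            rid <- rid + 1L
            zz <- z_start - lf * c(0, 4, 8, 12)
            atoms[[length(atoms) + 1L]] <- data.frame(
              name = c("O3", "CA", "CB", "CC"), res = "CHOL", rid = rid,
              x = dil$x[sites[k]], y = dil$y[sites[k]], z = zz)
          }
        }
      }
      if (nrow(pts)) {
        for (k in seq_len(nrow(pts))) {
          rid <- rid + 1L
          atoms[[length(atoms) + 1L]] <- data.frame(
            name = "CM", res = "ASA", rid = rid, x = pts[k, 1L],
            y = pts[k, 2L], z = z_head)
        }
      }
    }
    if (spec$waters_per_lipid > 0) {
      n_w <- round(spec$waters_per_lipid * spec$n_lipids)
      for (k in seq_len(n_w)) {
        rid <- rid + 1L
        side <- sample(c(-1, 1), 1L)
        zo <- side * stats::runif(1, spec$d_hh / 2 + 2, spec$box_z / 2 - 1)
        xo <- stats::runif(1, 0, Lx); yo <- stats::runif(1, 0, Ly)
        atoms[[length(atoms) + 1L]] <- data.frame(
          name = c("OW", "HW1", "HW2"), res = "SOL", rid = rid,
          x = xo + c(0, 0.96, -0.3), y = yo + c(0, 0, 0.9),
          z = zo + c(0, 0, 0))
      }
    }
    at <- do.call(rbind, atoms)
    pos <- cbind(at$x, at$y, at$z + spec$box_z / 2)
    pos <- pos + matrix(stats::rnorm(length(pos), 0, spec$jitter), ncol = 3L)
    frames[[f]] <- membrane_frame(pos, at$name, at$res, at$rid, box)
    truth_frames[[f]] <- if (length(gauche_tab))
      do.call(rbind, gauche_tab) else NULL
  }
  census <- table(frames[[1L]]$res_names[!duplicated(frames[[1L]]$res_ids)])
  attr(frames, "truth") <- list(
    box = box, census = census, apl_dmpc = spec$apl_dmpc,
    tail_spacing = spec$tail_spacing,
    asa_points = lapply(leaf_layout, `[[`, "pts"),
    superlattice = spec$superlattice, dilation = spec$dilation,
    gauche = do.call(rbind, truth_frames),
    gauche_near = spec$gauche_near, gauche_far = spec$gauche_far,
    gauche_radius = spec$gauche_radius)
  frames
}

# oblique lattice points wrapped into the box, deduplicated
superlattice_points <- function(sl, Lx, Ly) {
  a <- sl[[1L]]; b <- sl[[2L]]; g <- sl[[3L]] * pi / 180
  v1 <- c(a, 0)
  v2 <- c(b * cos(g), b * sin(g))
  rng <- -ceiling(2 * (Lx + Ly) / min(a, b)):ceiling(2 * (Lx + Ly) / min(a, b))
  pts <- expand.grid(i = rng, j = rng)
  x <- pts$i * v1[1L] + pts$j * v2[1L]
  y <- pts$i * v1[2L] + pts$j * v2[2L]
  keep <- x >= -1e-9 & x < Lx - 1e-9 & y >= -1e-9 & y < Ly - 1e-9
  unique(round(cbind(x[keep], y[keep]), 6))
}

# mean deviation of a site's distances to its two nearest drug points
# from the closest configured ring radius
ring_deviation <- function(sx, sy, pts, Lx, Ly, rings) {
  dx <- min_image(outer(sx, pts[, 1L], "-"), Lx)
  dy <- min_image(outer(sy, pts[, 2L], "-"), Ly)
  d <- sqrt(dx^2 + dy^2)
  k <- min(2L, ncol(d))
  vapply(seq_along(sx), function(i) {
    di <- sort(d[i, ])[seq_len(k)]
    mean(vapply(di, function(x) min(abs(x - rings)), 0))
  }, 0)
}

site_asa_distance <- function(sx, sy, pts, Lx, Ly) {
  if (!nrow(pts)) return(rep(Inf, length(sx)))
  dx <- min_image(outer(sx, pts[, 1L], "-"), Lx)
  dy <- min_image(outer(sy, pts[, 2L], "-"), Ly)
  sqrt(apply(dx^2 + dy^2, 1L, min))
}

# radial dilation field: pure area scaling (1 + frac) out to
# `radius` plus one cell radius (so the full Voronoi cells of lipids
# within `radius` are inside the scaled region), tapered to zero over
# a further two cell spacings
dilate_sites <- function(sx, sy, pts, Lx, Ly, frac, radius, cell = 5) {
  if (!nrow(pts) || frac == 0) return(list(x = sx, y = sy))
  x <- sx; y <- sy
  c_scale <- sqrt(1 + frac) - 1
  r_in <- radius + cell
  r_out <- r_in + 2 * cell
  for (k in seq_len(nrow(pts))) {
    dx <- min_image(x - pts[k, 1L], Lx)
    dy <- min_image(y - pts[k, 2L], Ly)
    r <- sqrt(dx^2 + dy^2)
    u <- ifelse(r < r_in, c_scale * r,
                ifelse(r < r_out, c_scale * r_in * (r_out - r) / (2 * cell), 0))
    nz <- r > 1e-9
    x[nz] <- x[nz] + u[nz] * dx[nz] / r[nz]
    y[nz] <- y[nz] + u[nz] * dy[nz] / r[nz]
  }
  # left unwrapped: frame construction wraps atoms, and pair midpoints
  # must be computed from unwrapped partners
  list(x = x, y = y)
}

# grow an alkane chain by internal coordinates (NeRF): bond 1.54 A,
# angle 111 deg, supplied dihedrals (IUPAC, trans = 180); `phase`
# rotates the whole chain about z so tails are azimuthally random
grow_chain <- function(origin, direction, dihedrals, bond = 1.54,
                       angle = 111, phase = 0) {
  n <- length(dihedrals) + 3L
  p <- matrix(0, n, 3L)
  th <- (180 - angle) * pi / 180
  p[1L, ] <- c(0, 0, 0)
  p[2L, ] <- c(0, 0, -bond)
  p[3L, ] <- p[2L, ] + c(bond * sin(th), 0, -bond * cos(th))
  for (i in seq_along(dihedrals)) {
    p[i + 3L, ] <- nerf_place(p[i, ], p[i + 1L, ], p[i + 2L, ], bond,
                              angle * pi / 180, dihedrals[i] * pi / 180)
  }
  ph <- phase * pi / 180
  R <- matrix(c(cos(ph), -sin(ph), 0, sin(ph), cos(ph), 0, 0, 0, 1), 3L, 3L,
              byrow = TRUE)
  p <- p %*% t(R)
  if (direction > 0) p[, 3L] <- -p[, 3L]
  sweep(p, 2L, origin, "+")
}

nerf_place <- function(a, b, c, bond, angle, dihedral) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- vcross(matrix(ab, 1L), matrix(bc, 1L))[1L, ]
  n <- n / sqrt(sum(n^2))
  m <- vcross(matrix(n, 1L), matrix(bc, 1L))[1L, ]
  d2 <- c(-bond * cos(angle), bond * sin(angle) * cos(dihedral),
          bond * sin(angle) * sin(dihedral))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Simulate a labelled three-branch dispersion point cloud
#'
#' Points on each branch's quadratic with Gaussian energy noise and
#' truth labels, for branch-assignment and minimum-fit exercises.
#'
#' @param spec A [dispersion_spec].
#' @param q Momenta at which each branch is sampled.
#' @param energy_err Gaussian noise and quoted error on energies (meV).
#' @param seed Integer seed.
#' @return A `dispersion_points` data frame with a `true_branch`
#'   column.
#' @export
simulate_dispersion_points <- function(spec, q = seq(1.0, 2.0, by = 0.1),
                                       energy_err = 0.05, seed = 1L) {
  b <- spec$branches
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(b))) {
      e <- b$alpha[i] * (q - b$q0[i])^2 + b$omega0[i]
      rows[[length(rows) + 1L]] <- data.frame(
        q_par = q, energy = e + stats::rnorm(length(q), 0, energy_err),
        energy_err = energy_err, width = b$sigma[i], source = "constant_q",
        branch = "unassigned", true_branch = b$branch[i])
    }
  })
  pts <- do.call(rbind, rows)
  pts <- pts[pts$energy > 0, ]
  class(pts) <- c("dispersion_points", "data.frame")
  pts
}

# evaluate expr with a local RNG state; restores the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
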