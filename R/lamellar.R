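# Elastic lamellar analysis: Bragg-peak detection and integration,
# lamellar spacing d_z = 2*pi / dq_z, Fourier reconstruction of the
# relative scattering-length density
#   rho(z) = sum_n sqrt(I_n q_n) nu_n cos(2 pi n z / d_z),
# the head-head spacing d_HH from the headgroup minima, and the
# hexagonal-packing area per tail A_T = 8 pi^2 / (sqrt(3) q_T^2).

#' Detect and integrate lamellar Bragg peaks
#'
#' Local maxima well above the smooth background are refined one by one
#' with a Gaussian-plus-local-linear fit over a window of +/- 3 fitted
#' widths; the integrated intensity is the Gaussian area above
#' background. Orders are assigned by rounding `q_n / dq_z` after a
#' robust (median successive difference) estimate of the common
#' spacing, so a missing order does not shift the labels; `d_z` comes
#' from the weighted regression of `q_n` on `n` through the origin.
#'
#' @param scan A [refl_scan].
#' @param max_orders Keep at most this many orders (default 9).
#' @param min_snr Peak detection threshold in units of the local noise
#'   (default 5).
#' @return An object of class `bragg_peaks`: data frame `peaks` with
#'   `n`, `q`, `q_err`, `intensity`, `width`, plus `d_z` and `dq_z`.
#' @export
find_bragg_peaks <- function(scan, max_orders = 9L, min_snr = 5) {
  stopifnot(inherits(scan, "refl_scan"))
  q <- scan$q_z; y <- scan$counts
  n <- length(q)
  bg <- stats::runmed(y, k = odd_window(n, frac = 0.15))
  sig <- y - bg
  noise <- pmax(stats::mad(sig), sqrt(pmax(bg, 1)))
  is_max <- sig > c(-Inf, sig[-n]) & sig >= c(sig[-1L], -Inf)
  cand <- which(is_max & sig > min_snr * noise)
  # merge candidates closer than a few grid steps (one physical peak)
  cand <- merge_close(cand, min_gap = 4L, height = sig)
  if (length(cand) < 3L)
    stop("fewer than 3 resolvable Bragg peaks (found ", length(cand), ")")
  cand <- cand[order(q[cand])]

  dq_cand <- if (length(cand) > 1L) stats::median(diff(q[cand])) else
    diff(range(q)) / 4
  fits <- lapply(cand, function(i)
    fit_local_gaussian(q, y, scan$errors, i, half = 0.35 * dq_cand))
  ok <- !vapply(fits, is.null, TRUE) &
    vapply(fits, function(f) is.null(f) || f$area > 0, TRUE)
  fits <- fits[ok]
  if (length(fits) < 3L) stop("fewer than 3 Bragg peaks survived refinement")
  centres <- vapply(fits, `[[`, 0, "centre")
  ord <- order(centres)
  fits <- fits[ord]; centres <- centres[ord]
  # collapse near-duplicate refinements of the same physical peak
  widths <- vapply(fits, `[[`, 0, "width")
  keep <- rep(TRUE, length(fits))
  for (i in seq_along(fits)[-1L]) {
    if (centres[i] - centres[i - 1L] < 3 * max(widths[i], widths[i - 1L])) {
      drop <- if (fits[[i]]$area >= fits[[i - 1L]]$area) i - 1L else i
      keep[drop] <- FALSE
    }
  }
  fits <- fits[keep]; centres <- centres[keep]
  if (length(fits) < 3L) stop("fewer than 3 distinct Bragg peaks")

  # robust common spacing: successive differences may be integer
  # multiples of dq when an order is missing
  dd <- diff(centres)
  d0 <- min(dd)
  dq <- stats::median(dd / pmax(round(dd / d0), 1))
  orders <- round(centres / dq)
  dup <- duplicated(orders)
  fits <- fits[!dup]; centres <- centres[!dup]; orders <- orders[!dup]
  keep <- orders >= 1 & orders <= max_orders
  fits <- fits[keep]; centres <- centres[keep]; orders <- orders[keep]
  cerr <- vapply(fits, `[[`, 0, "centre_err")
  wgt <- 1 / pmax(cerr, 1e-6)^2
  slope <- sum(wgt * orders * centres) / sum(wgt * orders^2)
  if (any(abs(centres - orders * slope) > 0.02 * slope))
    warning("Bragg peaks deviate from equidistance by more than 2% of dq_z")
  peaks <- data.frame(n = as.integer(orders), q = centres, q_err = cerr,
                      intensity = vapply(fits, `[[`, 0, "area"),
                      width = vapply(fits, `[[`, 0, "width"))
  structure(list(peaks = peaks, dq_z = slope, d_z = 2 * pi / slope),
            class = "bragg_peaks")
}

odd_window <- function(n, frac) {
  k <- max(5L, as.integer(frac * n))
  if (k %% 2L == 0L) k <- k + 1L
  min(k, if (n %% 2L == 1L) n else n - 1L)
}

merge_close <- function(idx, min_gap, height) {
  if (length(idx) < 2L) return(idx)
  keep <- integer(0)
  grp <- split(idx, cumsum(c(1L, diff(idx) > min_gap)))
  for (g in grp) keep <- c(keep, g[which.max(height[g])])
  keep
}

# Gaussian + local linear background around index i; the window spans
# a fraction of the candidate spacing so the peak sits on a flat
# stretch of background, and the refined window is +/- 3 fitted widths
fit_local_gaussian <- function(q, y, err, i, half) {
  n <- length(q)
  step <- stats::median(diff(q))
  w0 <- 2 * step
  ft <- NULL
  for (pass in 1:2) {
    win <- which(q >= q[i] - half & q <= q[i] + half)
    if (length(win) < 8L) win <- max(1L, i - 6L):min(n, i + 6L)
    qq <- q[win]; yy <- y[win]; ee <- err[win]
    b0 <- min(yy); a0 <- max(yy) - b0
    p0 <- c(A = a0, c = q[i], s = w0, m = 0, b = b0)
    fn <- function(p) (yy - (p[1L] * exp(-(qq - p[2L])^2 / (2 * p[3L]^2)) +
                              p[4L] * (qq - q[i]) + p[5L])) / ee
    ft <- wls_fit(fn, p0, lower = c(0, q[i] - half / 2, step / 4, -Inf, -Inf),
                  upper = c(Inf, q[i] + half / 2, half / 2, Inf, Inf))
    if (!ft$converged) return(NULL)
    w0 <- ft$par[3L]
    half <- max(3 * w0, 5 * step)
  }
  list(centre = unname(ft$par[2L]),
       centre_err = unname(if (is.finite(ft$se[2L])) ft$se[2L] else step / 2),
       width = unname(ft$par[3L]),
       area = unname(ft$par[1L] * ft$par[3L] * sqrt(2 * pi)))
}

#' Lamellar repeat spacing from a Bragg series
#'
#' `d_z = 2 pi / dq_z` with the common spacing from a weighted
#' regression of peak positions on their orders through the origin.
#' Invariant under uniform intensity rescaling (positions only).
#'
#' @param peaks A `bragg_peaks` object, or a data frame with columns
#'   `n` and `q` (at least 2 rows).
#' @return d_z in Angstrom.
#' @export
lamellar_spacing <- function(peaks) {
  pk <- if (inherits(peaks, "bragg_peaks")) peaks$peaks else as.data.frame(peaks)
  if (nrow(pk) < 2L) stop("need at least 2 Bragg peaks")
  w <- if ("q_err" %in% names(pk)) 1 / pmax(pk$q_err, 1e-6)^2 else rep(1, nrow(pk))
  slope <- sum(w * pk$n * pk$q) / sum(w * pk$n^2)
  2 * pi / slope
}

#' Fourier reconstruction of the scattering-length density profile
#'
#' `rho(z) = sum_n sqrt(I_n q_n) nu_n cos(2 pi n z / d_z)` on a uniform
#' grid spanning one repeat, `[-d_z/2, d_z/2]`, on a relative scale.
#' The amplitude uses the Lorentz-corrected form factor magnitude
#' `sqrt(I_n q_n)` appropriate for oriented multilayers; the phases
#' `nu_n` (+/- 1 per order) are supplied, not determined.
#'
#' @param peaks A `bragg_peaks` object or data frame with `n`, `q`,
#'   `intensity`.
#' @param phases Integer vector of +/- 1, one entry per order `1..N`
#'   with `N >=` the highest order used.
#' @param dz_step Grid step in Angstrom (<= 0.25).
#' @return An object of class `sld_profile` with `z`, `rho`, `phases`,
#'   `d_z`.
#' @export
reconstruct_sld <- function(peaks, phases, dz_step = 0.25) {
  pk <- if (inherits(peaks, "bragg_peaks")) peaks$peaks else as.data.frame(peaks)
  d_z <- if (inherits(peaks, "bragg_peaks")) peaks$d_z else
    2 * pi * sum(pk$n * pk$q) / sum(pk$q^2) # q_n = 2 pi n / d_z regression
  if (!all(phases %in% c(-1, 1))) stop("phases must be +/- 1")
  if (length(phases) < max(pk$n))
    stop("phase array shorter than the number of orders used (need ",
         max(pk$n), ")")
  if (dz_step > 0.25) stop("dz_step must be <= 0.25 A")
  # symmetric grid with an odd point count so z = 0 is sampled exactly
  half_n <- ceiling(d_z / (2 * dz_step))
  z <- seq(-d_z / 2, d_z / 2, length.out = 2L * half_n + 1L)
  rho <- rep(0, length(z))
  for (i in seq_len(nrow(pk))) {
    n <- pk$n[i]
    amp <- sqrt(max(pk$intensity[i], 0) * pk$q[i])
    rho <- rho + amp * phases[n] * cos(2 * pi * n * z / d_z)
  }
  structure(list(z = z, rho = rho, phases = phases[seq_len(max(pk$n))],
                 d_z = d_z),
            class = "sld_profile")
}

#' Head-head spacing from an SLD profile
#'
#' For chain-deuterated bilayers the headgroups appear as the two
#' interior minima of the profile near |z| ~ 20 A. Each minimum is
#' refined by parabolic interpolation over three grid points and
#' `d_HH = z_plus - z_minus`. Asymmetry beyond 1 A triggers a warning;
#' missing interior minima (e.g. a single-order cosine whose minima sit
#' on the repeat boundary) are an error.
#'
#' @param profile An `sld_profile`.
#' @param edge_exclude Fraction of the half-repeat excluded at each end
#'   so boundary minima are not mistaken for headgroups (default 0.08).
#' @return d_HH in Angstrom, with attribute `minima` giving the two
#'   refined positions.
#' @export
head_head_spacing <- function(profile, edge_exclude = 0.08) {
  z <- profile$z; r <- profile$rho
  n <- length(z)
  inner <- which(abs(z) < (1 - edge_exclude) * max(abs(z)))
  is_min <- r < c(Inf, r[-n]) & r <= c(r[-1L], Inf)
  cand <- intersect(which(is_min), inner)
  cand <- cand[cand > 1L & cand < n]
  neg <- cand[z[cand] < 0]; pos <- cand[z[cand] > 0]
  if (!length(neg) || !length(pos))
    stop("no interior minima on both sides of z = 0; cannot locate headgroups")
  i_neg <- neg[which.min(r[neg])]
  i_pos <- pos[which.min(r[pos])]
  zm <- parabolic_min(z, r, i_neg)
  zp <- parabolic_min(z, r, i_pos)
  if (abs(zp + zm) > 1)
    warning(sprintf("headgroup minima asymmetric: z = %.2f and %.2f A", zm, zp))
  structure(zp - zm, minima = c(zm, zp))
}

parabolic_min <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom <= 0) return(x[i])
  x[i] + 0.5 * (y1 - y3) / denom * (x[i + 1L] - x[i])
}

#' Area per acyl chain from the chain-correlation peak
#'
#' Hexagonal-packing relation `A_T = 8 pi^2 / (sqrt(3) q_T^2)` at the
#' in-plane chain-correlation peak position `q_T`. Strictly decreasing
#' in `q_T`.
#'
#' @param q_T Peak position in 1/A (> 0).
#' @return Area per tail in A^2.
#' @examples
#' area_per_tail(1.37) # ~24.3 A^2
#' @export
area_per_tail <- function(q_T) {
  if (any(q_T <= 0)) stop("q_T must be > 0")
  8 * pi^2 / (sqrt(3) * q_T^2)
}

#' Locate the in-plane chain-correlation peak
#'
#' Lorentzian plus linear background fit over `fit_range` (default
#' 1.2-1.6 1/A), after excluding configurable contaminant windows
#' around the silicon/aluminium reflections near 1.25, 1.7 and
#' 1.95 1/A.
#'
#' @param scan A [refl_scan]-like object measured along q_par (fields
#'   `q_z` read as q_par) or a [tas_scan] of kind `constant_E`.
#' @param fit_range Fit interval in 1/A.
#' @param exclude List of `c(lo, hi)` windows to drop.
#' @return List with `q_T`, `q_T_err`, and `A_T = area_per_tail(q_T)`.
#' @export
find_inplane_peak <- function(scan, fit_range = c(1.2, 1.6),
                              exclude = list(c(1.23, 1.27), c(1.68, 1.72),
                                             c(1.93, 1.97))) {
  if (inherits(scan, "refl_scan")) {
    q <- scan$q_z; y <- scan$counts; e <- scan$errors
  } else {
    q <- scan$axis; y <- scan$counts; e <- scan$errors
  }
  keep <- q >= fit_range[1L] & q <= fit_range[2L]
  for (win in exclude) keep <- keep & !(q >= win[1L] & q <= win[2L])
  if (sum(keep) < 6L) stop("too few points in the in-plane fit range")
  qq <- q[keep]; yy <- y[keep]; ee <- e[keep]
  p0 <- c(A = max(yy) - min(yy), c = qq[which.max(yy)], w = 0.05,
          m = 0, b = min(yy))
  fn <- function(p) (yy - (p[1L] / (1 + (qq - p[2L])^2 / p[3L]^2) +
                             p[4L] * qq + p[5L])) / ee
  ft <- wls_fit(fn, p0, lower = c(0, fit_range[1L], 0.005, -Inf, -Inf),
                upper = c(Inf, fit_range[2L], 1, Inf, Inf))
  if (!ft$converged) warning("in-plane peak fit did not converge")
  q_T <- unname(ft$par[2L])
  list(q_T = q_T, q_T_err = unname(ft$se[2L]), A_T = area_per_tail(q_T))
}

#' @export
print.bragg_peaks <- function(x, ...) {
  cat(sprintf("<bragg_peaks> %d orders, dq_z = %.5f 1/A, d_z = %.2f A\n",
              nrow(x$peaks), x$dq_z, x$d_z))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Plot an SLD profile
#'
#' @param x An `sld_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sld_profile <- function(x, ...) {
  graphics::plot(x$z, x$rho, type = "l", xlab = "z [A]",
                 ylab = "rho(z) [rel.]", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
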