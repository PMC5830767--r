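# Multi-phonon spectral model and weighted fitting.
#
# A constant-q energy scan is modelled as an elastic Gaussian fixed at
# zero energy transfer (width = instrument resolution), an incoherent
# Lorentzian fixed at zero, a linear background, and up to three
# phonon Lorentzian doublets at +/-mu_i whose anti-Stokes amplitude is
# tied to the Stokes amplitude by detailed balance,
# A_minus = A_plus * exp(-mu / (k_B T)). Positive energy transfer is
# neutron energy loss, so the Stokes side is the stronger one.
# Phonon widths sigma_i are Lorentzian HWHM; FWHM = 2 sigma_i.

#' Detailed-balance amplitude ratio
#'
#' Ratio of anti-Stokes to Stokes amplitude for a mode at energy `mu`,
#' `exp(-mu / (k_B T))`.
#'
#' @param mu Mode energy in meV (>= 0 for a ratio in (0, 1]).
#' @param temperature Temperature in K.
#' @return Dimensionless amplitude ratio.
#' @export
detailed_balance_ratio <- function(mu, temperature = lp_constants$default_temperature) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  exp(-mu / thermal_energy(temperature))
}

#' Construct a spectral model for a constant-q energy scan
#'
#' @param A_el Elastic Gaussian amplitude (counts, >= 0); centre fixed
#'   at 0, width fixed at `sigma_el`.
#' @param A_inc,sigma_inc Incoherent Lorentzian amplitude (>= 0) and
#'   HWHM (meV, > 0); centre fixed at 0.
#' @param slope,intercept Linear background `slope * omega + intercept`.
#' @param modes Data frame with columns `mu`, `sigma`, `amp_plus`
#'   (0 to 3 rows); stored sorted by `mu` ascending. The anti-Stokes
#'   amplitude is always derived by detailed balance, never stored.
#' @param temperature Temperature in K.
#' @param sigma_el Fixed elastic Gaussian width (meV).
#' @return An object of class `spectral_model`.
#' @export
spectral_model <- function(A_el, A_inc, sigma_inc, slope, intercept,
                           modes = empty_modes(),
                           temperature = lp_constants$default_temperature,
                           sigma_el = 0.3) {
  modes <- as.data.frame(modes)
  if (nrow(modes)) {
    stopifnot(all(c("mu", "sigma", "amp_plus") %in% names(modes)))
    if (nrow(modes) > 3L) stop("at most 3 phonon modes are supported")
    if (any(modes$mu <= 0) || any(modes$sigma <= 0) || any(modes$amp_plus < 0))
      stop("modes need mu > 0, sigma > 0, amp_plus >= 0")
    modes <- modes[order(modes$mu), c("mu", "sigma", "amp_plus")]
    rownames(modes) <- NULL
  }
  if (A_el < 0 || A_inc < 0) stop("amplitudes must be >= 0")
  if (sigma_inc <= 0 || sigma_el <= 0) stop("widths must be > 0")
  structure(list(A_el = A_el, A_inc = A_inc, sigma_inc = sigma_inc,
                 slope = slope, intercept = intercept, modes = modes,
                 temperature = temperature, sigma_el = sigma_el),
            class = "spectral_model")
}

empty_modes <- function() {
  data.frame(mu = numeric(), sigma = numeric(), amp_plus = numeric())
}

#' Evaluate the spectral model on an energy grid
#'
#' @param model A [spectral_model].
#' @param omega Energy transfer grid (meV); positive omega is neutron
#'   energy loss.
#' @return Model intensity at each `omega`.
#' @export
evaluate_spectrum <- function(model, omega) {
  stopifnot(inherits(model, "spectral_model"))
  I <- model$A_el * exp(-omega^2 / (2 * model$sigma_el^2)) +
    model$slope * omega + model$intercept +
    model$A_inc / (1 + omega^2 / model$sigma_inc^2)
  if (nrow(model$modes)) {
    for (i in seq_len(nrow(model$modes))) {
      mu <- model$modes$mu[i]; sg <- model$modes$sigma[i]
      ap <- model$modes$amp_plus[i]
      am <- ap * detailed_balance_ratio(mu, model$temperature)
      I <- I + ap / (1 + (omega - mu)^2 / sg^2) +
        am / (1 + (omega + mu)^2 / sg^2)
    }
  }
  I
}

## ---- parameter packing -------------------------------------------------

pack_q_model <- function(model) {
  p <- c(model$A_el, model$A_inc, model$sigma_inc, model$slope, model$intercept)
  nm <- c("A_el", "A_inc", "sigma_inc", "slope", "intercept")
  k <- nrow(model$modes)
  if (k) {
    for (i in seq_len(k)) {
      p <- c(p, model$modes$mu[i], model$modes$sigma[i], model$modes$amp_plus[i])
      nm <- c(nm, paste0(c("mu", "sigma", "amp"), i))
    }
  }
  names(p) <- nm
  p
}

unpack_q_model <- function(p, k, temperature, sigma_el) {
  modes <- empty_modes()
  if (k) {
    idx <- 5L + seq_len(3L * k)
    m <- matrix(p[idx], ncol = 3L, byrow = TRUE)
    modes <- data.frame(mu = m[, 1L], sigma = m[, 2L], amp_plus = m[, 3L])
    modes <- modes[order(modes$mu), ]
    rownames(modes) <- NULL
  }
  spectral_model(A_el = max(p[1L], 0), A_inc = max(p[2L], 0),
                 sigma_inc = max(p[3L], 1e-6), slope = p[4L],
                 intercept = p[5L], modes = modes,
                 temperature = temperature, sigma_el = sigma_el)
}

q_model_bounds <- function(k, axis) {
  lo <- c(0, 0, 0.01, -Inf, -Inf)
  # a quasi-elastic Lorentzian wider than the scan is indistinguishable
  # from a constant background; cap it at the energy range
  hi <- c(Inf, Inf, max(abs(axis)), Inf, Inf)
  if (k) {
    lo <- c(lo, rep(c(0.01, 0.02, 0), k))
    hi <- c(hi, rep(c(max(axis), max(axis), Inf), k))
  }
  list(lower = lo, upper = hi)
}

## ---- weighted least squares core --------------------------------------

# run nls.lm on weighted residuals; returns par, chi2, converged,
# std errors from the numerical jacobian at the optimum
wls_fit <- function(resid_fn, p0, lower, upper) {
  ctl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12, ptol = 1e-12)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                       control = ctl),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(par = p0, chi2 = sum(resid_fn(p0)^2), converged = FALSE,
                se = rep(NA_real_, length(p0)), singular = TRUE))
  }
  par <- stats::coef(fit)
  chi2 <- fit$deviance
  converged <- fit$info %in% 1:4
  J <- num_jacobian(resid_fn, par)
  JTJ <- crossprod(J)
  se <- rep(NA_real_, length(par))
  singular <- FALSE
  cv <- tryCatch(solve(JTJ), error = function(e) NULL)
  if (is.null(cv) || any(!is.finite(diag(cv))) || any(diag(cv) < 0)) {
    singular <- TRUE
  } else {
    se <- sqrt(diag(cv))
  }
  list(par = par, chi2 = chi2, converged = converged, se = se,
       singular = singular)
}

num_jacobian <- function(fn, p, eps = 1e-6) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pj <- p; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

## ---- constant-q fitting ------------------------------------------------

#' Fit a constant-q energy scan with k phonon doublets
#'
#' Bounded weighted least squares of the spectral model against the
#' scan, minimising `sum(((counts - model) / errors)^2)`. The elastic
#' centre and width and the incoherent centre are held fixed; all other
#' parameters are free. Initial mode positions are seeded from
#' smoothed-residual peak picking after a background-only fit, with a
#' deterministic set of perturbed restarts; the best chi-squared is
#' kept. Modes are returned sorted by energy, and a mode whose fitted
#' amplitude falls below twice its standard error is marked not
#' detected.
#'
#' @param scan A constant-q [tas_scan].
#' @param k Number of phonon doublets (1 to 3; 0 fits background only).
#' @param init Optional [spectral_model] used as an additional start
#'   (e.g. the optimum of a simpler nested fit).
#' @return An object of class `spectral_fit`: the fitted model,
#'   per-parameter standard errors, `chi2`, `n_points`, `n_params`
#'   (free parameters of the implemented model), a `converged` flag,
#'   and a `modes` data frame with standard errors and detection flags.
#' @export
fit_constant_q_scan <- function(scan, k, init = NULL) {
  stopifnot(inherits(scan, "tas_scan"))
  if (scan$kind != "constant_q") stop("fit_constant_q_scan needs a constant_q scan")
  if (k < 0 || k > 3) stop("k must be between 0 and 3")
  omega <- scan$axis; y <- scan$counts; w <- scan$errors
  resid_for <- function(kk) function(p) {
    m <- eval_raw_q(p, kk, omega, scan$temperature, scan$sigma_el)
    (y - m) / w
  }
  bd <- q_model_bounds(k, omega)

  # background-only fit seeds everything
  bg0 <- c(A_el = max(y) - stats::median(y), A_inc = stats::median(y) / 2,
           sigma_inc = 1, slope = 0, intercept = min(y))
  bgfit <- wls_fit(resid_for(0L), pmax(bg0, c(0, 0, 0.01, -Inf, -Inf)),
                   q_model_bounds(0L, omega)$lower, q_model_bounds(0L, omega)$upper)
  if (k == 0L) {
    return(build_spectral_fit(bgfit, 0L, scan))
  }
  bgmod <- eval_raw_q(bgfit$par, 0L, omega, scan$temperature, scan$sigma_el)
  seeds <- residual_peaks(omega, (y - bgmod) / w, k)
  # positions are picked on the weighted residual; amplitudes are
  # counts, so read them off the unweighted one
  seeds$amp <- pmax(approx_at(omega, y - bgmod, seeds$mu), 1)

  # build up through the nested simpler fit when no start is supplied:
  # its optimum (plus a fresh mode) is the most reliable seed
  if (is.null(init) && k > 1L) {
    simpler <- fit_constant_q_scan(scan, k - 1L)
    init <- simpler$model
  }

  starts <- list()
  # background variants: the fitted background plus an
  # elastic-dominated one (the near-degenerate elastic Gaussian /
  # narrow incoherent Lorentzian pair has local minima)
  y0 <- approx_at(omega, y, 0)
  bg_variants <- list(
    bgfit$par,
    c(max(y0 - min(y), 1), 0.1 * max(y0 - min(y), 1), 1, 0, min(y)),
    c(max(y0 - min(y), 1), 0.3 * max(y0 - min(y), 1), 0.5, 0, min(y)))
  jitter_set <- c(0, -0.15, 0.15, -0.3, 0.3)
  for (bg in bg_variants) {
    for (j in jitter_set) {
      mu0 <- pmin(pmax(seeds$mu * (1 + j), 0.05), max(omega) * 0.95)
      p0 <- c(bg, as.vector(rbind(mu0, seeds$sigma, seeds$amp)))
      starts[[length(starts) + 1L]] <- p0
    }
  }
  if (!is.null(init) && inherits(init, "spectral_model")) {
    ki <- nrow(init$modes)
    p0 <- pack_q_model(init)
    if (ki < k) {
      # seed the extra modes from the residual left by the init model
      r_init <- y - evaluate_spectrum(init, omega)
      sx <- residual_peaks(omega, r_init / w, k - ki)
      sx$amp <- pmax(approx_at(omega, r_init, sx$mu), 1)
      p0 <- c(p0, as.vector(rbind(sx$mu, sx$sigma, sx$amp)))
      # a second variant with zero-amplitude extras: chi2 equals the
      # simpler optimum, guaranteeing nested monotonicity
      starts[[length(starts) + 1L]] <-
        unname(c(pack_q_model(init), as.vector(rbind(sx$mu, sx$sigma,
                                                     rep(0, k - ki)))))
    } else if (ki > k) {
      p0 <- p0[seq_len(5L + 3L * k)]
    }
    starts[[length(starts) + 1L]] <- unname(p0)
  }

  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, bd$lower), bd$upper)
    ft <- wls_fit(resid_for(k), p0, bd$lower, bd$upper)
    if (is.null(best) || ft$chi2 < best$chi2) best <- ft
  }
  build_spectral_fit(best, k, scan)
}

# model values from a raw parameter vector (no sorting: keeps the
# residual function smooth for the optimiser)
eval_raw_q <- function(p, k, omega, temperature, sigma_el) {
  I <- p[1L] * exp(-omega^2 / (2 * sigma_el^2)) + p[4L] * omega + p[5L] +
    p[2L] / (1 + omega^2 / p[3L]^2)
  if (k) {
    kT <- lp_constants$kB_meV * temperature
    for (i in seq_len(k)) {
      o <- 5L + 3L * (i - 1L)
      mu <- p[o + 1L]; sg <- p[o + 2L]; ap <- p[o + 3L]
      am <- ap * exp(-mu / kT)
      I <- I + ap / (1 + (omega - mu)^2 / sg^2) +
        am / (1 + (omega + mu)^2 / sg^2)
    }
  }
  I
}

# peak picking on smoothed weighted residuals, positive-energy side
residual_peaks <- function(omega, r, k) {
  pos <- omega > 0.1
  x <- omega[pos]; v <- r[pos]
  if (length(v) >= 3L) v <- stats::filter(v, rep(1 / 3, 3L), sides = 2L)
  v[is.na(v)] <- 0
  n <- length(v)
  is_max <- v > c(-Inf, v[-n]) & v >= c(v[-1L], -Inf)
  cand <- which(is_max & v > 0)
  cand <- cand[order(v[cand], decreasing = TRUE)]
  mu <- x[cand]
  if (length(mu) < k) {
    fill <- stats::quantile(x, probs = seq(0.25, 0.75, length.out = k))
    mu <- c(mu, fill[!fill %in% mu])[seq_len(k)]
  } else {
    mu <- mu[seq_len(k)]
  }
  mu <- sort(as.numeric(mu))
  amp <- pmax(approx_at(x, as.numeric(v), mu), 1)
  list(mu = mu, sigma = rep(0.2, k), amp = amp)
}

approx_at <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

build_spectral_fit <- function(ft, k, scan) {
  model <- unpack_q_model(ft$par, k, scan$temperature, scan$sigma_el)
  # sorting can permute mode blocks; permute the standard errors with it
  se <- ft$se
  names(se) <- names(pack_q_model(model))
  mode_se <- NULL
  if (k) {
    raw_modes <- matrix(ft$par[5L + seq_len(3L * k)], ncol = 3L, byrow = TRUE)
    raw_se <- matrix(se[5L + seq_len(3L * k)], ncol = 3L, byrow = TRUE)
    ord <- order(raw_modes[, 1L])
    mode_se <- raw_se[ord, , drop = FALSE]
    se[5L + seq_len(3L * k)] <- as.vector(t(mode_se))
  }
  modes <- model$modes
  if (k) {
    modes$se_mu <- mode_se[, 1L]
    modes$se_sigma <- mode_se[, 2L]
    modes$se_amp <- mode_se[, 3L]
    modes$fwhm <- 2 * modes$sigma
    modes$detected <- is.finite(modes$se_amp) &
      modes$amp_plus >= 2 * modes$se_amp
  }
  converged <- ft$converged && !ft$singular
  if (ft$singular)
    warning("singular covariance at the optimum; the requested phonon count ",
            "may exceed what the data support")
  structure(list(model = model, std_errors = se, chi2 = ft$chi2,
                 n_points = length(scan$axis),
                 n_params = 5L + 3L * k, n_params_nominal = 6L + 4L * k,
                 converged = converged, modes = modes, kind = scan$kind,
                 fixed_value = scan$fixed_value),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> %s at %.4g: k=%d phonons, chi2=%.4g (N=%d), %s\n",
              x$kind, x$fixed_value,
              if (is.data.frame(x$modes)) nrow(x$modes) else 0L,
              x$chi2, x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  if (is.data.frame(x$modes) && nrow(x$modes)) {
    for (i in seq_len(nrow(x$modes)))
      cat(sprintf("  mode %d: mu = %.3f +/- %.3f meV, sigma(HWHM) = %.3f +/- %.3f meV%s\n",
                  i, x$modes$mu[i], x$modes$se_mu[i], x$modes$sigma[i],
                  x$modes$se_sigma[i],
                  if (isTRUE(x$modes$detected[i])) "" else "  [not detected]"))
  }
  invisible(x)
}

## ---- constant-E fitting ------------------------------------------------

#' Fit a constant-energy q scan
#'
#' Model: empirical exponential background `B0 * exp(-B1 * q)`, a broad
#' background Lorentzian whose centre starts at 2.5 1/A but is free,
#' and `k` Lorentzian phonon peaks in q. All parameters are free.
#'
#' @param scan A constant-E [tas_scan].
#' @param k Number of phonon peaks (1 to 3).
#' @return An object of class `spectral_fit_e` with fitted `peaks`
#'   (centre, width, amp, standard errors, detection flag), background
#'   parameters, `chi2`, `n_points`, `n_params` and `converged`.
#' @export
fit_constant_e_scan <- function(scan, k) {
  stopifnot(inherits(scan, "tas_scan"))
  if (scan$kind != "constant_E") stop("fit_constant_e_scan needs a constant_E scan")
  if (k < 1 || k > 3) stop("k must be between 1 and 3")
  q <- scan$axis; y <- scan$counts; w <- scan$errors

  model_at <- function(p) {
    # p = B0, B1, A_bg, c_bg, w_bg, then (c_j, w_j, A_j) per peak
    I <- p[1L] * exp(-p[2L] * q) + p[3L] / (1 + (q - p[4L])^2 / p[5L]^2)
    for (i in seq_len(k)) {
      o <- 5L + 3L * (i - 1L)
      I <- I + p[o + 3L] / (1 + (q - p[o + 1L])^2 / p[o + 2L]^2)
    }
    I
  }
  resid_fn <- function(p) (y - model_at(p)) / w

  # seed the exponential from a log-linear regression on positive counts
  pos <- y > 0
  lf <- stats::lm(log(y[pos]) ~ q[pos])
  B1 <- max(-stats::coef(lf)[2L], 0.01)
  B0 <- exp(stats::coef(lf)[1L])
  base <- B0 * exp(-B1 * q)
  seeds <- residual_peaks_q(q, (y - base) / w, k)
  seeds$amp <- pmax(approx_at(q, y - base, seeds$centre), 1)
  # the broad background Lorentzian must stay a bump within the scan:
  # unbounded it degenerates into the exponential term
  lower <- c(0, -Inf, 0, min(q), 0.1, rep(c(min(q), 0.005, 0), k))
  upper <- c(Inf, Inf, Inf, max(q) + 0.5, 1.2, rep(c(max(q), 0.6, Inf), k))

  # the broad-background centre starts at 2.5 but also from the
  # largest smoothed residual in the upper half of the scan
  upper_half <- q > stats::median(q)
  r_sm <- stats::filter((y - base) / w, rep(1 / 3, 3L), sides = 2L)
  r_sm[is.na(r_sm)] <- 0
  cbg_seeds <- unique(round(c(2.5, q[upper_half][which.max(r_sm[upper_half])]), 3))
  best <- NULL
  for (cbg in cbg_seeds) {
    A_bg0 <- max(approx_at(q, y - base, cbg), 1)
    for (j in c(0, -0.1, 0.1, -0.2, 0.2)) {
      c0 <- pmin(pmax(seeds$centre * (1 + j), min(q)), max(q))
      p0 <- c(B0, B1, A_bg0, cbg, 0.5,
              as.vector(rbind(c0, seeds$width, seeds$amp)))
      p0 <- pmin(pmax(p0, lower), upper)
      ft <- wls_fit(resid_fn, p0, lower, upper)
      if (is.null(best) || ft$chi2 < best$chi2) best <- ft
    }
  }
  p <- best$par; se <- best$se
  pk <- matrix(p[5L + seq_len(3L * k)], ncol = 3L, byrow = TRUE)
  pk_se <- matrix(se[5L + seq_len(3L * k)], ncol = 3L, byrow = TRUE)
  ord <- order(pk[, 1L])
  peaks <- data.frame(centre = pk[ord, 1L], width = pk[ord, 2L],
                      amp = pk[ord, 3L], se_centre = pk_se[ord, 1L],
                      se_width = pk_se[ord, 2L], se_amp = pk_se[ord, 3L])
  peaks$detected <- is.finite(peaks$se_amp) & peaks$amp >= 2 * peaks$se_amp
  if (best$singular)
    warning("singular covariance in constant-E fit")
  structure(list(background = stats::setNames(p[1:5],
                   c("B0", "B1", "A_bg", "c_bg", "w_bg")),
                 background_se = stats::setNames(se[1:5],
                   c("B0", "B1", "A_bg", "c_bg", "w_bg")),
                 peaks = peaks, chi2 = best$chi2, n_points = length(q),
                 n_params = 5L + 3L * k,
                 converged = best$converged && !best$singular,
                 kind = scan$kind, fixed_value = scan$fixed_value),
            class = "spectral_fit_e")
}

residual_peaks_q <- function(q, r, k) {
  v <- if (length(r) >= 3L) stats::filter(r, rep(1 / 3, 3L), sides = 2L) else r
  v[is.na(v)] <- 0
  v <- as.numeric(v)
  n <- length(v)
  is_max <- v > c(-Inf, v[-n]) & v >= c(v[-1L], -Inf)
  cand <- which(is_max & v > 0)
  cand <- cand[order(v[cand], decreasing = TRUE)]
  centre <- q[cand]
  if (length(centre) < k) {
    fill <- stats::quantile(q, probs = seq(0.3, 0.7, length.out = k))
    centre <- c(centre, fill[!fill %in% centre])[seq_len(k)]
  } else {
    centre <- centre[seq_len(k)]
  }
  centre <- sort(as.numeric(centre))
  amp <- pmax(approx_at(q, v, centre), 1)
  list(centre = centre, width = rep(0.04, k), amp = amp)
}

## ---- F-test ------------------------------------------------------------

#' Nested-model F statistic for an added phonon
#'
#' `F_chi = (chi2_m - chi2_m4) / (chi2_m4 / (N - m - 1))`, where
#' `chi2_m` is the weighted residual sum of squares of the simpler
#' model with `m` free parameters and `chi2_m4` that of the richer
#' model with four more (one phonon doublet in the nominal counting).
#'
#' @param chi2_m Chi-squared of the simpler model (>= `chi2_m4`).
#' @param chi2_m4 Chi-squared of the richer model (> 0).
#' @param n_points Number of data points N.
#' @param m Free-parameter count of the simpler model.
#' @return The F_chi value.
#' @export
f_chi <- function(chi2_m, chi2_m4, n_points, m) {
  if (chi2_m4 < 0 || chi2_m < chi2_m4)
    stop("need chi2_m >= chi2_m4 >= 0 (nested models)")
  if (n_points <= m + 5) stop("too few points: need N > m + 5")
  if (chi2_m4 == 0) stop("chi2 of the richer model is zero; F_chi undefined")
  (chi2_m - chi2_m4) / (chi2_m4 / (n_points - m - 1))
}

#' Upper-tail critical value of the F distribution
#'
#' @param alpha Upper-tail probability (0 < alpha <= 0.5).
#' @param df1,df2 Degrees of freedom (`df2` may be `Inf`).
#' @return `qf(1 - alpha, df1, df2)`.
#' @export
f_critical <- function(alpha, df1, df2) {
  if (alpha <= 0 || alpha > 0.5) stop("alpha must be in (0, 0.5]")
  stats::qf(1 - alpha, df1, df2)
}

#' Accept/reject decisions from (F_chi, critical) pairs
#'
#' Applies the sequential decision rule to already-computed statistics:
#' increment i is accepted iff `f_chi_values[i] > critical_values[i]`,
#' and the chosen phonon count is one plus the number of consecutive
#' initial acceptances.
#'
#' @param f_chi_values F_chi per added phonon (increment 1 -> 2, ...).
#' @param critical_values Matching critical values.
#' @return List with `accepted` (logical) and `chosen_k`.
#' @export
f_test_decision <- function(f_chi_values, critical_values) {
  stopifnot(length(f_chi_values) == length(critical_values))
  accepted <- f_chi_values > critical_values
  chosen_k <- 1L
  for (a in accepted) {
    if (!isTRUE(a)) break
    chosen_k <- chosen_k + 1L
  }
  list(accepted = accepted, chosen_k = chosen_k)
}

#' Sequential F-test selection of the phonon count
#'
#' Fits the scan with 1..`k_max` phonon doublets (each fit seeded from
#' the previous optimum so chi-squared is non-increasing), computes
#' F_chi for every increment with `N` = scan length and
#' `m = 6 + 4 k` for the simpler model with `k` phonons (six background
#' parameters plus four per phonon in the nominal counting), and
#' accepts an increment when F_chi exceeds the critical value under the
#' configured degrees-of-freedom policy:
#'
#' * `"standard"` (default): the decision is the standard partial
#'   F-test with df1 = 4 added parameters and df2 = N - m - 5. Because
#'   F_chi is not divided by df1, the equivalent critical value on the
#'   F_chi scale is `4 * qf(1 - alpha, 4, df2) * (N - m - 1) / (N - m - 5)`.
#' * `"tabulated"`: compares raw F_chi with `qf(1 - alpha, 1, N - m - 1)`,
#'   matching the critical values of older printed F tabulations.
#' * a numeric `c(df1, df2)`: compares raw F_chi with
#'   `qf(1 - alpha, df1, df2)`.
#'
#' @param scan A constant-q [tas_scan].
#' @param k_max Maximum phonon count (default 3).
#' @param alpha Tail probability (default 0.025).
#' @param df_policy `"standard"`, `"tabulated"`, or `c(df1, df2)`.
#' @return An object of class `model_selection`: `fits` (one
#'   [fit_constant_q_scan()] result per k), `f_chi_values`,
#'   `f_critical_values` (on the F_chi comparison scale), `accepted`,
#'   and `chosen_k`.
#' @export
sequential_f_test <- function(scan, k_max = 3L, alpha = 0.025,
                              df_policy = "standard") {
  stopifnot(inherits(scan, "tas_scan"))
  fits <- vector("list", k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    fits[[k]] <- fit_constant_q_scan(scan, k, init = prev)
    if (!fits[[k]]$converged && k > 1L) {
      fits <- fits[seq_len(k)]
      break
    }
    prev <- fits[[k]]$model
  }
  n_fit <- length(fits)
  N <- length(scan$axis)
  fchi <- fcrit <- numeric(0)
  accepted <- logical(0)
  for (k in seq_len(n_fit - 1L)) {
    m <- 6L + 4L * k
    chi_a <- fits[[k]]$chi2; chi_b <- fits[[k + 1L]]$chi2
    # nested fits are seeded from the simpler optimum; enforce monotone
    if (chi_b > chi_a) chi_b <- chi_a
    fv <- if (chi_b > 0) f_chi(chi_a, chi_b, N, m) else Inf
    crit <- fchi_critical(alpha, df_policy, N, m)
    fchi <- c(fchi, fv)
    fcrit <- c(fcrit, crit)
    accepted <- c(accepted, isTRUE(fv > crit) && fits[[k + 1L]]$converged)
  }
  chosen_k <- 1L
  for (a in accepted) {
    if (!a) break
    chosen_k <- chosen_k + 1L
  }
  structure(list(fits = fits, f_chi_values = fchi, f_critical_values = fcrit,
                 accepted = accepted, chosen_k = chosen_k, alpha = alpha,
                 df_policy = df_policy),
            class = "model_selection")
}

# critical value on the F_chi scale under a dof policy
fchi_critical <- function(alpha, df_policy, N, m) {
  if (is.numeric(df_policy) && length(df_policy) == 2L) {
    return(f_critical(alpha, df_policy[1L], df_policy[2L]))
  }
  switch(match.arg(df_policy, c("standard", "tabulated")),
    standard = 4 * f_critical(alpha, 4, N - m - 5) * (N - m - 1) / (N - m - 5),
    tabulated = f_critical(alpha, 1, N - m - 1))
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> chosen k = %d (alpha = %.3g, policy = %s)\n",
              x$chosen_k, x$alpha,
              if (is.numeric(x$df_policy))
                paste(x$df_policy, collapse = ",") else x$df_policy))
  for (i in seq_along(x$f_chi_values))
    cat(sprintf("  adding phonon %d: F_chi = %.2f vs critical %.2f -> %s\n",
                i + 1L, x$f_chi_values[i], x$f_critical_values[i],
                if (x$accepted[i]) "accept" else "reject"))
  invisible(x)
}
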