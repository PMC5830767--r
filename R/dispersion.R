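# Dispersion relations: points from spectral fits, branch assignment,
# and the quadratic fit around the minimum,
#   hbar*omega = alpha * (q_par - q0)^2 + omega0,
# where omega0 is the minimum energy (a lipid-order metric) and alpha
# the curvature (an empirical softness metric).

#' Collect dispersion points from spectral fits
#'
#' Constant-q fits contribute one point per detected mode at the scan's
#' fixed q with the fitted energy; constant-E fits contribute points at
#' the fitted q centres with the scan's fixed energy. Non-converged
#' fits are skipped with a message.
#'
#' @param fits A list of results from [fit_constant_q_scan()] and/or
#'   [fit_constant_e_scan()].
#' @return A data frame of class `dispersion_points` with columns
#'   `q_par`, `energy`, `energy_err`, `width`, `source`, `branch`.
#' @export
collect_points <- function(fits) {
  rows <- list()
  for (f in fits) {
    if (!isTRUE(f$converged)) {
      message("skipping non-converged fit at fixed value ", f$fixed_value)
      next
    }
    if (inherits(f, "spectral_fit")) {
      m <- f$modes
      if (is.data.frame(m) && nrow(m)) {
        m <- m[isTRUE_vec(m$detected), , drop = FALSE]
        if (nrow(m))
          rows[[length(rows) + 1L]] <- data.frame(
            q_par = f$fixed_value, energy = m$mu,
            energy_err = pmax(m$se_mu, 1e-6, na.rm = TRUE),
            width = m$sigma, source = "constant_q")
      }
    } else if (inherits(f, "spectral_fit_e")) {
      p <- f$peaks[isTRUE_vec(f$peaks$detected), , drop = FALSE]
      if (nrow(p))
        rows[[length(rows) + 1L]] <- data.frame(
          q_par = p$centre, energy = f$fixed_value,
          energy_err = pmax(0.5 * abs(p$se_centre) + 0.02, 0.02),
          width = NA_real_, source = "constant_E")
    } else stop("unrecognised fit object")
  }
  pts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(q_par = numeric(), energy = numeric(),
               energy_err = numeric(), width = numeric(),
               source = character())
  pts$branch <- rep("unassigned", nrow(pts))
  class(pts) <- c("dispersion_points", "data.frame")
  pts
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Default branch anchor curves
#'
#' Anchor (q, omega) polylines describing the morphology of the three
#' coexisting-phase branches: a steep gel branch with its minimum near
#' 1.4 1/A, a broad fluid branch with a minimum near 1.1 meV, and the
#' liquid-ordered branch with the lowest minimum (0.5-0.7 meV).
#'
#' @return Named list of data frames with columns `q` and `omega`.
#' @export
default_branch_anchors <- function() {
  q <- seq(1.0, 2.0, by = 0.05)
  list(gel = data.frame(q = q, omega = 30 * (q - 1.4)^2 + 0.7),
       fluid = data.frame(q = q, omega = 13 * (q - 1.4)^2 + 1.1),
       lo = data.frame(q = q, omega = 4.5 * (q - 1.4)^2 + 0.55))
}

#' Anchor curves from a dispersion specification
#'
#' Samples each branch's quadratic densely over `q_range`, giving
#' assignment anchors that match a known (e.g. generator) dispersion.
#'
#' @param spec A [dispersion_spec].
#' @param q_range Range of q (1/A) to sample.
#' @param step Sampling step.
#' @return Named list of anchor data frames for [assign_branches()].
#' @export
anchors_from_spec <- function(spec, q_range = c(1.0, 2.0), step = 0.02) {
  q <- seq(q_range[1L], q_range[2L], by = step)
  b <- spec$branches
  out <- list()
  for (i in seq_len(nrow(b)))
    out[[b$branch[i]]] <- data.frame(
      q = q, omega = b$alpha[i] * (q - b$q0[i])^2 + b$omega0[i])
  out
}

#' Assign dispersion points to phase branches
#'
#' Each point is labelled with the branch whose piecewise-linear anchor
#' curve is nearest in the scaled coordinates (q / 1 (1/A), omega / 1
#' meV); ties go to the branch with the lower anchor energy at the
#' point's q. Points farther than `cutoff` from every anchor curve stay
#' `"unassigned"`. Deterministic: no randomness is involved.
#'
#' @param points A `dispersion_points` data frame.
#' @param anchors Named list of anchor data frames (columns `q`,
#'   `omega`), one entry per branch; default [default_branch_anchors()].
#' @param cutoff Maximum scaled distance for assignment (default 0.6).
#' @param q_scale,omega_scale Per-axis normalisation (1 1/A, 1 meV).
#' @return `points` with the `branch` column filled in.
#' @export
assign_branches <- function(points, anchors = default_branch_anchors(),
                            cutoff = 0.6, q_scale = 1, omega_scale = 1) {
  stopifnot(length(anchors) >= 1L, !is.null(names(anchors)))
  if (!nrow(points)) return(points)
  d <- sapply(anchors, function(a)
    polyline_distance(points$q_par / q_scale, points$energy / omega_scale,
                      a$q / q_scale, a$omega / omega_scale))
  d <- matrix(d, nrow = nrow(points))
  # anchor energy at the point's q, for tie-breaking
  e_at <- sapply(anchors, function(a) {
    if (nrow(a) == 1L) rep(a$omega, nrow(points))
    else stats::approx(a$q, a$omega, xout = points$q_par, rule = 2)$y
  })
  e_at <- matrix(e_at, nrow = nrow(points))
  lab <- character(nrow(points))
  for (i in seq_len(nrow(points))) {
    di <- d[i, ]
    best <- which(di <= min(di) + 1e-12)
    j <- if (length(best) > 1L) best[which.min(e_at[i, best])] else best
    lab[i] <- if (di[j] <= cutoff) names(anchors)[j] else "unassigned"
  }
  points$branch <- lab
  points
}

# min distance from points (x, y) to the polyline (px, py)
polyline_distance <- function(x, y, px, py) {
  n <- length(px)
  if (n == 1L) return(sqrt((x - px)^2 + (y - py)^2))
  dmin <- rep(Inf, length(x))
  for (s in seq_len(n - 1L)) {
    ax <- px[s]; ay <- py[s]; bx <- px[s + 1L]; by <- py[s + 1L]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- pmin(pmax(((x - ax) * vx + (y - ay) * vy) / L2, 0), 1)
    d <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
    dmin <- pmin(dmin, d)
  }
  dmin
}

#' Fit the quadratic dispersion minimum of one branch
#'
#' Weighted least squares of `omega = alpha * (q - q0)^2 + omega0`
#' over points inside `fit_range`. The model is refit as a quadratic
#' polynomial in q (exactly equivalent), and (alpha, q0, omega0) and
#' their standard errors are recovered by the delta method, so a
#' noiseless quadratic is reproduced to machine precision.
#'
#' @param points A `dispersion_points` data frame (typically one
#'   branch).
#' @param fit_range Interval of q (1/A) used for the fit; default
#'   `c(1.0, 2.0)`, around the dispersion minimum.
#' @param branch Optional branch label to filter on.
#' @return An object of class `branch_fit` with `alpha`, `q0`,
#'   `omega0`, `std_errors`, `fit_range`, `branch`, `n_points`, and a
#'   `flagged` field set when the fitted parabola does not open
#'   upwards.
#' @export
fit_branch_minimum <- function(points, fit_range = c(1.0, 2.0), branch = NULL) {
  pts <- as.data.frame(points)
  if (!is.null(branch)) pts <- pts[pts$branch == branch, , drop = FALSE]
  pts <- pts[pts$q_par >= fit_range[1L] & pts$q_par <= fit_range[2L], , drop = FALSE]
  if (nrow(pts) < 4L)
    stop("need at least 4 points inside the fit range; got ", nrow(pts))
  w <- 1 / pts$energy_err^2
  fit <- stats::lm(energy ~ q_par + I(q_par^2), data = pts, weights = w)
  cf <- stats::coef(fit)            # c, b, a for omega = a q^2 + b q + c
  # per-point errors are known, so the parameter covariance is
  # (X' W X)^-1 directly, not lm's residual-variance-scaled version
  X <- cbind(1, pts$q_par, pts$q_par^2)
  V <- solve(crossprod(X * sqrt(w)))
  a <- cf[[3L]]; b <- cf[[2L]]; cc <- cf[[1L]]
  alpha <- a
  q0 <- -b / (2 * a)
  omega0 <- cc - b^2 / (4 * a)
  # delta method: gradients wrt (c, b, a)
  g_q0 <- c(0, -1 / (2 * a), b / (2 * a^2))
  g_w0 <- c(1, -b / (2 * a), b^2 / (4 * a^2))
  g_al <- c(0, 0, 1)
  se <- sqrt(c(alpha = g_al %*% V %*% g_al,
               q0 = g_q0 %*% V %*% g_q0,
               omega0 = g_w0 %*% V %*% g_w0))
  names(se) <- c("alpha", "q0", "omega0")
  flagged <- !is.finite(alpha) || alpha <= 0
  if (flagged) warning("fitted dispersion does not open upwards (alpha <= 0)")
  structure(list(alpha = alpha, q0 = q0, omega0 = omega0, std_errors = se,
                 fit_range = fit_range,
                 branch = branch %||% unique(pts$branch)[1L],
                 n_points = nrow(pts), flagged = flagged),
            class = "branch_fit")
}

#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf("<branch_fit> %s: alpha = %.3g +/- %.2g meV.A^2, q0 = %.4g +/- %.2g 1/A, omega0 = %.3g +/- %.2g meV (n = %d)%s\n",
              x$branch, x$alpha, x$std_errors["alpha"], x$q0,
              x$std_errors["q0"], x$omega0, x$std_errors["omega0"],
              x$n_points, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Compare fitted parameters between two samples
#'
#' Two-sample z test per parameter:
#' `z = |p_a - p_b| / sqrt(se_a^2 + se_b^2)`, significant when
#' `z > 1.96` (5% two-sided). Accepts either two [fit_branch_minimum()]
#' results (compares `alpha`, `q0`, `omega0`) or two named lists of
#' `value`/`se` pairs (e.g. phonon widths). Parameters with a missing
#' standard error are skipped with a warning; huge uncertainties (as in
#' weakly constrained gel-branch fits) pass through untouched.
#'
#' @param fit_a,fit_b `branch_fit` objects, or lists with numeric
#'   vectors `value` and `se` sharing names.
#' @param z_threshold Significance threshold (default 1.96).
#' @return A data frame with columns `parameter`, `value_a`, `se_a`,
#'   `value_b`, `se_b`, `z`, `significant`.
#' @export
compare_branch_parameters <- function(fit_a, fit_b, z_threshold = 1.96) {
  as_vs <- function(f) {
    if (inherits(f, "branch_fit"))
      list(value = c(alpha = f$alpha, q0 = f$q0, omega0 = f$omega0),
           se = f$std_errors[c("alpha", "q0", "omega0")])
    else list(value = unlist(f$value), se = unlist(f$se))
  }
  a <- as_vs(fit_a); b <- as_vs(fit_b)
  pars <- intersect(names(a$value), names(b$value))
  out <- list()
  for (p in pars) {
    sa <- a$se[[p]]; sb <- b$se[[p]]
    if (!is.finite(sa) || !is.finite(sb)) {
      warning("missing standard error for parameter ", p, "; skipped")
      next
    }
    z <- abs(a$value[[p]] - b$value[[p]]) / sqrt(sa^2 + sb^2)
    out[[length(out) + 1L]] <- data.frame(
      parameter = p, value_a = a$value[[p]], se_a = sa,
      value_b = b$value[[p]], se_b = sb, z = z,
      significant = z > z_threshold)
  }
  do.call(rbind, out)
}

#' Plot dispersion points and optional branch fits
#'
#' @param x A `dispersion_points` data frame.
#' @param fits Optional list of `branch_fit` objects to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dispersion_points <- function(x, fits = NULL, ...) {
  cols <- c(gel = "darkgreen", fluid = "blue", lo = "red",
            unassigned = "grey50")
  graphics::plot(x$q_par, x$energy, pch = 19,
                 col = cols[x$branch],
                 xlab = "q_par [1/A]", ylab = "energy [meV]", ...)
  graphics::arrows(x$q_par, x$energy - x$energy_err, x$q_par,
                   x$energy + x$energy_err, angle = 90, code = 3,
                   length = 0.02, col = cols[x$branch])
  if (!is.null(fits)) {
    for (f in fits) {
      qq <- seq(f$fit_range[1L], f$fit_range[2L], length.out = 100)
      graphics::lines(qq, f$alpha * (qq - f$q0)^2 + f$omega0,
                      col = cols[f$branch] %||% "black")
    }
  }
  invisible(x)
}
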