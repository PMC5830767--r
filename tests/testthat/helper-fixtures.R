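# shared fixture builders

# single liquid-ordered branch spec with a chosen mode width
lo_only_spec <- function(sigma, omega0 = 0.51, alpha = 4) {
  dispersion_spec("custom", branches = data.frame(
    branch = "lo", alpha = alpha, q0 = 1.4, omega0 = omega0,
    sigma = sigma, amp = 300))
}

# noiseless constant-q scan from exact model values
noiseless_scan <- function(model, omega = seq(-1.5, 3.85, by = 0.05)) {
  y <- evaluate_spectrum(model, omega)
  tas_scan("constant_q", 1.37, omega, y, errors = pmax(1, sqrt(y)),
           temperature = model$temperature, sigma_el = model$sigma_el)
}

# two leaflets of n x n lipids on a square lattice, spacing 7 A
uniform_square_frame <- function(n = 10, spacing = 7, box_z = 60) {
  xs <- (rep(seq_len(n), n) - 0.5) * spacing
  ys <- (rep(seq_len(n), each = n) - 0.5) * spacing
  pos <- rbind(cbind(xs, ys, box_z * 0.75), cbind(xs, ys, box_z * 0.25))
  m <- nrow(pos)
  membrane_frame(pos, rep("P", m), rep("DMPC", m), seq_len(m),
                 c(n * spacing, n * spacing, box_z))
}

# Table-1-shaped branch parameter sets (value, se) for both samples
table1_chol <- list(
  gel = list(value = c(alpha = 41, omega0 = 0.72),
             se = c(alpha = 95, omega0 = 0.70)),
  fluid = list(value = c(alpha = 14.9, omega0 = 1.09),
               se = c(alpha = 3, omega0 = 0.28)),
  lo = list(value = c(alpha = 4.8, omega0 = 0.51),
            se = c(alpha = 0.3, omega0 = 0.02)))
table1_asa <- list(
  gel = list(value = c(alpha = 1.5, omega0 = 0.65),
             se = c(alpha = 28, omega0 = 1.49)),
  fluid = list(value = c(alpha = 11.0, omega0 = 1.12),
               se = c(alpha = 4, omega0 = 0.51)),
  lo = list(value = c(alpha = 3.7, omega0 = 0.66),
            se = c(alpha = 0.9, omega0 = 0.07)))
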