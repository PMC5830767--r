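#' Physical constants and unit conventions
#'
#' The package works in a single unit system throughout: lengths in
#' Angstrom, momentum transfer in inverse Angstrom, energy transfer in
#' meV, temperature in K, and intensities in detector counts.
#'
#' `kB_meV` is the Boltzmann constant in meV/K; `default_temperature`
#' is the fluid-phase measurement temperature (30 C).
#'
#' @format A named list with elements `kB_meV` (0.0861733 meV/K) and
#'   `default_temperature` (303.15 K).
#' @export
lp_constants <- local({
  x <- list(kB_meV = 0.0861733, default_temperature = 303.15)
  lockBinding("x", environment())
  x
})

#' Thermal energy k_B * T
#'
#' @param temperature Temperature in K (> 0).
#' @return Thermal energy in meV.
#' @examples
#' thermal_energy(303.15) # ~26.12 meV
#' @export
thermal_energy <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (K)")
  lp_constants$kB_meV * temperature
}
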