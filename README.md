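# lipidphonon

Analysis of collective lipid dynamics and lateral organization in
cholesterol-rich phospholipid membranes perturbed by small
amphiphilic drugs such as aspirin, from two kinds of evidence:

* **coherent inelastic neutron scattering** on oriented
  DMPC/cholesterol multilayers — constant-q and constant-energy
  triple-axis scans, fitted with a detailed-balance multi-phonon
  model and reduced to three-branch dispersion relations whose
  minima quantify lipid order and membrane softness;
* **membrane configuration frames** — per-leaflet radial
  distribution functions, grid-based area per lipid, gauche-defect
  statistics, density/SLD profiles, and close-contact analysis that
  resolve how the drug reorganises the bilayer plane.

It is aimed at membrane biophysicists who fit spectra of collective
lipid-tail fluctuations, reconstruct lamellar structure from Bragg
series, or quantify lateral order in bilayer simulations. Raw data
for the study system are not deposited anywhere public, so the
package ships synthetic generators that emulate every input with
attached ground truth; all quantitative tests run against that truth.

## The models

A constant-q energy scan is fitted with

    I(w) = A_el exp(-w^2 / 2 s_el^2) + m w + b
         + A_inc / (1 + w^2 / s_inc^2)
         + sum_i [ A+_i / (1 + (w - mu_i)^2 / s_i^2)
                 + A-_i / (1 + (w + mu_i)^2 / s_i^2) ],

with the elastic line fixed at the instrument resolution, the
incoherent Lorentzian fixed at zero energy transfer, and
`A-_i = A+_i exp(-mu_i / kB T)` by detailed balance. The number of
phonon doublets (1–3) is chosen by a sequential F-test on

    F_chi = (chi2(m) - chi2(m + 4)) / (chi2(m + 4) / (N - m - 1)),

with six background parameters plus four per phonon. Dispersion
minima follow `hw = alpha (q - q0)^2 + hw0`; `hw0` measures lipid
order, `alpha` softness, and samples are compared by two-sample z
tests. Elastic analysis uses `d_z = 2 pi / dq_z`, the Fourier
reconstruction `rho(z) = sum_n sqrt(I_n q_n) nu_n cos(2 pi n z /
d_z)` with supplied phases `nu_n`, the head–head spacing from the
headgroup minima, and the hexagonal area per tail
`A_T = 8 pi^2 / (sqrt(3) q_T^2)`.

## Worked example

```r
library(lipidphonon)

# a 108-point constant-q scan with three phonon doublets and Poisson noise
scan <- simulate_constant_q_scan(dispersion_spec_separated(), q = 1.4, seed = 42)

# how many phonons do the data support?
sel <- sequential_f_test(scan)
sel
#> <model_selection> chosen k = 3 (alpha = 0.025, policy = standard)
#>   adding phonon 2: F_chi = 152.51 vs critical 12.21 -> accept
#>   adding phonon 3: F_chi = 119.75 vs critical 12.26 -> accept
sel$fits[[sel$chosen_k]]
#> <spectral_fit> constant_q at 1.4: k=3 phonons, chi2=90.23 (N=108), converged
#>   mode 1: mu = 0.593 +/- 0.008 meV, sigma(HWHM) = 0.106 +/- 0.022 meV
#>   mode 2: mu = 1.107 +/- 0.005 meV, sigma(HWHM) = 0.125 +/- 0.013 meV
#>   mode 3: mu = 1.790 +/- 0.009 meV, sigma(HWHM) = 0.219 +/- 0.016 meV
```

Both F-statistics clear their critical values, so three phonon
excitations are statistically justified; the fitted mode energies
recover the generator's 0.6 / 1.1 / 1.8 meV branch minima within a
few standard errors, and chi-squared is compatible with the 108
points fitted.

```r
# lamellar chain: Bragg series -> d_z -> SLD profile -> d_HH
rs <- simulate_reflectivity(seed = 42)
pk <- find_bragg_peaks(rs)
sld <- reconstruct_sld(pk, attr(rs, "truth")$phases)
dhh <- head_head_spacing(sld)
c(d_z = pk$d_z, d_HH = dhh, A_T = area_per_tail(1.37))
#> d_z = 61.10 A, d_HH = 46.22 A, A_T = 24.29 A^2
```

Seven orders are detected (two fall on form-factor nodes), the
repeat distance comes back at 61.10 A, the head–head spacing at
46.2 A from the reconstructed profile's headgroup minima, and the
area per acyl chain evaluated at the chain-correlation peak
q_T = 1.37 1/A is 24.3 sq. A.

Higher-level entry points `run_neutron_workflow()` and
`run_md_workflow()` chain these stages for one or two samples and
write JSON/TSV report bundles; see the methods vignette
(`vignettes/membrane-dynamics-methods.Rmd`) for the models,
assumptions, and generator design.

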