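---
title: "Models and methods: collective lipid dynamics and lateral membrane organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: collective lipid dynamics and lateral membrane organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidphonon)
```

# Scope

`lipidphonon` analyses two complementary views of a
DMPC/cholesterol membrane perturbed by a small amphiphilic drug
(aspirin, ASA):

* **Collective dynamics**, measured by coherent inelastic neutron
  scattering on a triple-axis spectrometer: multi-phonon fitting of
  constant-q and constant-E scans, F-test selection of the phonon
  count, assembly of three-branch dispersion relations, and quadratic
  fits of their minima.
* **Static and lateral structure**: lamellar Bragg series and Fourier
  reconstruction of the scattering-length-density (SLD) profile, and
  configuration-frame analyses (radial distribution functions, grid
  area per lipid, gauche defects, density profiles, close contacts).

Because raw spectrometer data and simulation trajectories for this
system are not publicly deposited, every input is emulated by a
synthetic generator with machine-readable ground truth; all
quantitative tests read truth from these attachments.

Units are fixed package-wide: Angstrom, inverse Angstrom, meV, Kelvin,
detector counts.

# The spectral model

A constant-q energy scan is modelled as

$$I(\omega) = A_\mathrm{el}\, e^{-\omega^2/2\sigma_\mathrm{el}^2}
  + m\omega + b
  + \frac{A_\mathrm{inc}}{1+\omega^2/\sigma_\mathrm{inc}^2}
  + \sum_{i=1}^{k}\left[
      \frac{A_{+,i}}{1+(\omega-\mu_i)^2/\sigma_i^2}
    + \frac{A_{-,i}}{1+(\omega+\mu_i)^2/\sigma_i^2}\right],$$

with the elastic Gaussian centred at zero and its width
$\sigma_\mathrm{el}$ fixed at the instrument resolution (0.3 meV for
the low-resolution setup, 0.2 meV for the high-resolution one), the
incoherent Lorentzian centred at zero, and the anti-Stokes amplitude
tied by detailed balance, $A_{-,i} = A_{+,i}\,e^{-\mu_i/k_BT}$
($k_B = 0.0861733$ meV/K, $T = 303.15$ K by default). Positive
$\omega$ is neutron energy loss. $\sigma_i$ is the Lorentzian HWHM; the
FWHM $2\sigma_i$ is also reported because the width convention of
published phonon widths is often unstated.

**Fitting.** Bounded weighted least squares
(`minpack.lm`), minimising $\sum((y_j - I(\omega_j))/e_j)^2$ with
known per-point errors $e_j = \max(1, \sqrt{y_j})$; the unit floor on
zero-count errors keeps the weights finite. Because the fixed-width
elastic Gaussian and a free narrow incoherent Lorentzian are nearly
degenerate, the optimiser is multi-started: mode positions come from
peak picking on the smoothed residual of a background-only fit, with a
deterministic set of position perturbations and several structured
background variants; the incoherent width is capped at the scan's
energy range (a wider quasi-elastic line is indistinguishable from a
constant). A fit with $k>1$ doublets is additionally seeded from the
converged $k-1$ optimum with a zero-amplitude extra mode, which
guarantees non-increasing $\chi^2$ along the nested-model ladder.
Standard errors come from $(J^\top J)^{-1}$ at the optimum; a singular
covariance marks the fit non-converged (the requested phonon count
exceeds what the data support). A mode whose amplitude falls below
twice its standard error is reported "not detected".

Constant-E scans are fitted with an empirical exponential background,
a broad background Lorentzian whose centre starts at 2.5 1/A but is
free (bounded to remain a bump inside the scan window), and $k$
Lorentzian peaks in q, all parameters free.

# Phonon-count selection

The nested-model statistic for one added phonon is

$$F_\chi = \frac{\chi^2(m) - \chi^2(m+4)}{\chi^2(m+4)/(N-m-1)},$$

with $N$ data points and $m = 6 + 4k$ nominal free parameters for the
simpler model with $k$ phonons (six background parameters, four per
phonon). This statistic is *not* divided by the number of added
parameters, so it is $\mathrm{df}_1$ times a standard partial-F
statistic. The selector therefore supports explicit
degrees-of-freedom policies:

* `"standard"` (default): the decision is the calibrated partial
  F-test with $\mathrm{df}_1 = 4$ and $\mathrm{df}_2 = N-m-5$;
  on the $F_\chi$ scale the critical value is
  $4\,q_F(1-\alpha;4,N-m-5)\,(N-m-1)/(N-m-5)$. Under the null this
  accepts a spurious phonon at close to the nominal $\alpha$; comparing
  raw $F_\chi$ with $q_F(1-\alpha;4,\cdot)\approx 2.9$ instead would
  accept one more than half the time, which is why the calibrated form
  is the default.
* `"tabulated"`: compares raw $F_\chi$ with $q_F(1-\alpha;1,N-m-1)$,
  matching the critical values printed in older tabulations
  (6.41 at $\mathrm{df}_2=13$); provided for comparability, not
  calibration.
* a numeric `c(df1, df2)` for a user-supplied convention.

$\alpha$ defaults to 0.025. An increment is accepted when $F_\chi$
exceeds the critical value and the richer fit converged; the chosen
count is the largest consecutively accepted $k$. `f_test_decision()`
applies the same rule to externally supplied $(F_\chi,$ critical$)$
pairs.

# Dispersion relations

Detected modes from constant-q fits contribute points $(q, \mu)$;
constant-E fits contribute $(q_\mathrm{centre}, E)$. Points are
assigned to the gel, fluid, and liquid-ordered ($l_o$) branches by
nearest anchor polyline in scaled coordinates (q normalised by
1 1/A, energy by 1 meV), ties resolved toward the lower-energy branch,
with a configurable cutoff beyond which points stay unassigned. The
default anchors sample representative quadratics (steep gel branch,
broad fluid minimum near 1.1 meV, lowest $l_o$ minimum near
0.55 meV); `anchors_from_spec()` builds anchors from any known
dispersion, which is the recommended route when the branch shapes are
known. Assignment by proximity is inherently ambiguous where branches
cross; mislabels concentrate near crossings, where the branch energies
coincide, so their effect on the minimum fits is small.

Around its minimum each branch follows

$$\hbar\omega = \alpha\,(q_\parallel - q_{\parallel 0})^2 + \hbar\omega_0,$$

fitted by weighted least squares over $1.0 < q_\parallel < 2.0$ 1/A.
Internally the model is refit as a quadratic polynomial (an exact
reparameterisation, so noiseless inputs are recovered to machine
precision) and $(\alpha, q_0, \omega_0)$ with standard errors follow by
the delta method from $(X^\top W X)^{-1}$ — the supplied point errors
are taken as known rather than rescaled by the residual variance.
$\omega_0$ tracks lipid order; $\alpha$ is an empirical softness
metric. Samples are compared parameter-by-parameter with the
two-sample z statistic $|p_a-p_b|/\sqrt{se_a^2+se_b^2}$ against 1.96
(5% two-sided); the procedure is reported raw and, in the workflow
report, Bonferroni-adjusted, with the raw view the default. Hugely
uncertain parameters (weakly constrained gel fits) pass through
untouched and simply never reach significance.

# Lamellar analysis

Bragg peaks in the out-of-plane reflectivity are detected as local
maxima well above a running-median background, refined by local
Gaussian-plus-linear fits windowed by the candidate spacing, and
integrated as Gaussian area above background. The common spacing
$\Delta q_z$ is estimated robustly (successive differences divided by
their integer multiples), orders are labelled by rounding
$q_n/\Delta q_z$ — so a missing order does not shift labels — and
$d_z = 2\pi/\Delta q_z$ from a weighted regression of $q_n$ on $n$
through the origin.

The relative SLD profile is reconstructed as

$$\rho(z) = \sum_n \sqrt{I_n q_n}\,\nu_n \cos(2\pi n z/d_z),$$

the standard oriented-multilayer form with the Lorentz factor $q_n$
and harmonic index $n$; the phase signs $\nu_n = \pm 1$ are inputs
(for these chain-deuterated samples the literature phase set
[1 −1 −1 −1 −1 1 1 −1 1] is the workflow default). For
chain-deuterated bilayers the headgroups are the two interior minima
near $|z| \approx 20$ A; each is refined by parabolic interpolation
over three grid points and $d_{HH}$ is their separation. The area per
acyl chain follows from the chain-correlation peak position by the
hexagonal-packing relation $A_T = 8\pi^2/(\sqrt3\,q_T^2)$; $q_T$ is
fitted as a Lorentzian over 1.2–1.6 1/A with contaminant windows
(silicon/aluminium reflections near 1.25, 1.7, 1.95 1/A) excluded.

# Configuration-frame analyses

All analysis paths are deterministic. Frames hold coordinates in
Angstrom with z along the bilayer normal and an orthorhombic box;
lateral coordinates are wrapped on construction, and bonded chains are
unwrapped by minimum image before dihedral computation.

* **Lateral RDF**: in-plane minimum-image distances, same-leaflet
  pairs only by default (a flag restores cross-leaflet pairs),
  intramolecular pairs excluded, normalised by the ideal 2D density so
  $g \to 1$ for homogeneous systems; a 3D mode uses spherical shells.
* **Grid area per lipid**: the leaflet plane is tessellated into
  cells of at most 0.5 A; each cell is claimed by the nearest
  reference point (DMPC: phosphorus; cholesterol: hydroxyl oxygen)
  under the periodic minimum image, so claimed areas tile the leaflet
  exactly. The policy flag chooses whether cholesterol-claimed cells
  are excluded from the reported lipid areas (default) or reported
  alongside them.
* **Distance-resolved profiles**: each DMPC's lateral distance to the
  nearest same-leaflet drug reference (the drug's lateral centre of
  mass) selects a half-open bin $[a, b)$ of width 2 A by default;
  areas are averaged per bin over frames. For gauche profiles, shell
  membership is recomputed every `stride` frames (default 50,
  mirroring index-file regeneration in trajectory tools) while
  dihedrals are classified every frame, and the two acyl tails
  (atom-name prefixes `C1`/`C2`, overridable) are averaged.
* **Gauche criterion**: $|\phi| < 120°$ with trans at $\pm 180°$
  (IUPAC convention); Ryckaert–Bellemans input (trans at 0°) is
  converted before classification, so the cut is
  convention-independent. The threshold itself is a package choice —
  the field rarely states one — and sits at the potential maxima
  separating the trans and gauche wells.
* **Density profiles**: per-group histograms along z, bilayer-centred,
  weighted by electrons per element or coherent scattering length
  (with H→D substitution where a deuteration map applies,
  $b_H = -3.74$, $b_D = +6.67$ fm); electron-mode integrals conserve
  each group's electron count.
* **Contacts**: heavy-atom pairs within a 3.5 A 3D minimum-image
  cutoff, reported per residue pair as a time fraction. This is a
  distance proxy for hydrogen bonding; no angular criterion is
  applied, because the observation being emulated is reported
  visually, not geometrically.

# The synthetic generators

The generators' defaults are the study conditions, chosen once:

* **Dispersion presets** use the fitted branch parameters of the two
  samples (cholesterol-only and with drug), minima at
  $q_0 = 1.4$ 1/A, $l_o$ mode widths 0.14 and 0.31 meV respectively,
  and counting statistics sized to typical published spectra (elastic
  peak ≈ 5000 counts, phonon amplitudes 150–400, 108-point energy
  grids spanning −1.5 to 3.85 meV). Counts are Poisson draws (a
  Gaussian option exists for high-count work). A separated preset
  (minima 0.6/1.1/1.8 meV) provides the resolvable-mode regime used
  for parameter-recovery exercises; the realistic overlapping presets
  are deliberately hard, which is exactly why the F-test exists. For
  width-comparison exercises the single-branch generator is run at
  three-fold counting statistics, representing the long-counting
  high-resolution configuration used at the dispersion minimum.
* **Constant-E scans** place peaks at the quadratic-dispersion roots
  with amplitudes scaled by $1/|d\omega/dq|$ (bounded above), on an
  exponential background plus a broad Lorentzian near 2.5 1/A.
* **Reflectivity** forward-models $F_n = \int \rho(z)\cos(2\pi n
  z/d_z)\,dz$, $I_n = F_n^2/q_n$, rendered as Gaussians on a smooth
  background with Poisson noise. The built-in analytic profile has a
  deuterated-tail plateau, headgroup dips at $\pm d_{HH}/2$, and
  heavy-water maxima at the repeat boundary, with feature widths
  chosen so the profile is substantially representable by nine
  orders — as real smooth SLD profiles are; some orders fall on
  form-factor nodes, so about seven peaks are detectable, matching
  typical oriented-stack patterns. The attached head-minimum truth is
  the band-limited profile's minima separation, since that is what any
  Fourier measurement can recover (the analytic value is attached
  separately).
* **Membrane frames** place two leaflets of a jittered hexagonal tail
  lattice (spacing 4.8 A by default, the chain-correlation distance;
  a target DMPC area overrides the spacing via
  $A = \sqrt3 s^2$ with two tail sites per lipid). Each DMPC owns two
  adjacent sites with a phosphorus bead above their midpoint and two
  14-bead chains grown by internal coordinates (bond 1.54 A, angle
  111°, dihedrals drawn trans/gauche with the configured
  probabilities; the draws are recorded as ground truth). Drug
  molecules sit at headgroup depth ($\pm d_{HH}/2$, 23 A) on an
  oblique superlattice ($a = 21.2$, $b = 18$ A, $\gamma = 103°$ by
  default; the alternative 15 × 25 A geometry reported from
  simulation snapshots is equally accepted as configuration).
  Cholesterol is placed at the configured ring radii (11.5 and 19 A)
  around drug molecules — populated evenly across rings, angles
  random — and consumes the nearest lattice slot so packing stays
  dense; without a drug it occupies lattice sites directly. The
  lattice is radially dilated around each drug molecule: pure area
  scaling $1+\delta$ out to the dilation radius plus one cell radius
  (so the full Voronoi cells of "near" lipids are inside the scaled
  region), tapered over two further cell spacings. Waters are
  three-site molecules outside the headgroups. Frames differ by
  positional jitter (0.15 A) and freshly drawn dihedral states; a
  fixed seed reproduces frames exactly, and the generator restores
  the caller's RNG state.

**What the generator does not emulate**: excluded volume (chains can
overlap, so the all-carbon RDF does not show the 4.8 A packing peak —
the chain-anchor carbons `C1A`/`C2A` are the tail-position proxy used
by the tests and the workflow), molecular shape beyond coarse beads,
water structure, membrane undulations, and instrument resolution
convolution in q–energy space (the elastic Gaussian width stands in
for the energy resolution; phonon widths near the dispersion minimum
are closest to intrinsic, and no deconvolution is attempted). The
periodic box is generally incommensurate with the drug superlattice,
so lattice RDFs carry minor boundary artifacts. Passing tests
demonstrate correctness of the analysis algorithms under known ground
truth, not fidelity of the generator to real membranes.

# Problem sizes and numerical choices

Simulation-based checks run at sizes a desk analysis handles
comfortably: 108-point scans, 100-seed recovery studies,
128–220-lipid frames and a handful of frames per trajectory stand-in.
Grid cells are 0.5 A (areas), SLD grids 0.25 A, RDF bins 0.2–1 A,
density bins 1 A. Tolerances in tests reflect the statistics of each
estimator: 3-standard-error coverage for spectral parameters,
2-standard-error per-parameter coverage for dispersion minima, ±0.02
on gauche fractions at $10^4$ dihedrals. Degenerate inputs are
handled explicitly: zero-count errors floor at 1, below-8-point scans
are rejected, fits at boundaries flag singular covariances rather
than raise, tangent constant-E crossings merge to one peak, and
stride values beyond the frame count collapse to a single membership
evaluation with a log message.

# Known limitations

* Branch assignment is an artifact decision; the field assigns
  branches by visual correspondence with reference dispersions, and
  no algorithm is stated in the literature this package emulates.
* With cholesterol present, grid areas depend on the reference-point
  geometry (phosphorus vs hydroxyl), which biases the mixed-frame
  DMPC mean a few Ų below the lattice target; the pure-DMPC target
  is honoured exactly, and the dilation and distance profiles are
  computed in the pure-DMPC + drug configuration where the target is
  clean.
* Full synthetic two-sample workflows yield parameter uncertainties
  far smaller than real instruments produce (clean Poisson counting,
  no resolution convolution or mosaic spread), so between-sample z
  tests flag more parameters than the corresponding real-data
  analysis; the printed-value comparison (which reproduces the
  "liquid-ordered minimum only" significance pattern) is the
  benchmark for that claim.
* The workflow functions and exported analysis/generator functions
  are the package's interface; no shell entry point is shipped.
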