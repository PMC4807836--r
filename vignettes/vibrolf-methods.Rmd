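---
title: "Models and methods behind vibrolf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vibrolf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibrolf)
```

# The scientific problem

The vibrational hypothesis of olfaction proposes that odorant recognition
involves inelastic electron tunnelling: an electron moves from a donor to
an acceptor site inside the receptor, and the transfer is assisted by the
emission of a vibrational quantum into the bound odorant. Testing this
picture computationally requires three ingredients:

1. the odorant's vibrational modes, in vacuum and as perturbed by the
   protein environment;
2. the electron–phonon coupling of each mode to the *change* in the local
   electric field when the electron hops; and
3. the receptor's Marcus reorganization energy — if reorganization is
   large, the sharp energy-matching that inelastic tunnelling needs is
   washed out and the mechanism is implausible regardless of the
   couplings.

`vibrolf` implements this chain for inputs that are either produced by
external quantum-chemistry/MD engines (Hessians, optimized geometries,
embedding potentials, energy and coordinate time series) or generated
synthetically with exact ground truth.

# Unit conventions

All internal physics is done in atomic units (Hartree, Bohr, electron
mass, $e$), with the field's customary units at the interfaces: geometry
I/O in Å, masses in amu, vibrational frequencies in cm⁻¹ (meV where
shifts are compared, 1 cm⁻¹ = 0.12398 meV), MD energies in kcal/mol.
Every conversion goes through one CODATA table (`vibrolf_constants`), so
a round trip through any pair of units is an identity to 1e-10 relative
(tested).

# Harmonic analysis

`compute_normal_modes()` mass-weights the Cartesian Hessian,
$H^{mw}_{ij} = H_{ij}/\sqrt{m_i m_j}$, projects out rigid motion, and
diagonalizes. Rigid motion is removed by explicit projection of the six
(five for linear molecules) Eckart vectors — three mass-weighted
translations and three rotations about the center of mass, orthonormalized
by QR — rather than by discarding the smallest eigenvalues. Projection is
robust for geometries that are *not* exactly stationary, which is the
normal situation for a molecule embedded in a protein field; discarded
directions are exact zeros by construction, and a count of near-zero modes
exceeding the projected dimension triggers a "not at a stationary point"
warning instead of silently corrupting the mode count.

Conventions that matter downstream:

* **Normalization.** Cartesian mode vectors $y_\mu(n)$ satisfy
  $\sum_n m(n)\,|y_\mu(n)|^2 = 1$ with $m$ in amu, so $y$ carries
  amu$^{-1/2}$ and the normal-coordinate shift
  $\delta\Pi_\mu = \sum_n m(n)\, y_\mu(n)\cdot\Delta(n)$ carries
  amu$^{1/2}$·Bohr. This is the unique convention under which the coupling
  strength below is dimensionless.
* **Sign.** Each eigenvector is flipped so its largest-magnitude component
  is positive; eigenvector signs are otherwise arbitrary and would make
  $\delta\Pi$ signs platform-dependent.
* **Imaginary frequencies** are reported as negative wavenumbers with a
  warning and excluded from coupling and spectrum stages; the displaced
  harmonic oscillator formalism assumes real $\omega_\mu$.
* `zero_tol` (default 1 cm⁻¹) decides which post-projection modes count as
  translation/rotation remnants.

IR intensities use the double-harmonic expression
$I_\mu \propto |\sum_n (\partial\boldsymbol\mu/\partial \mathbf r_n)\cdot
y_\mu(n)|^2$ with the standard km/mol prefactor assembled from SI
constants; a finite-difference dipole oracle in the tests pins the whole
prefactor chain to 1e-6 relative.

**Mode matching.** When comparing vacuum and embedded mode sets, the
pairing is solved as a linear assignment problem maximizing the total
squared mass-weighted overlap (a compact Hungarian solver; the mode count
is ≤ a few dozen, so O(n³) in plain R is instant). Matching by sorted
frequency order would mis-pair modes that cross under the environmental
perturbation; the overlap criterion is basis-set- and
frequency-shift-proof. Reported shifts are
$\Delta\nu = \nu_{\text{embedded}} - \nu_{\text{vacuum}}$.

**Spectra.** `broaden_spectrum()` sums area-normalized Lorentzians. The
broadening width is a free parameter (default fwhm 10 cm⁻¹): no physical
linewidth is implied, and the integrated intensity equals the stick sum to
1% on a ±50·fwhm grid (tested), so the choice of fwhm only affects
presentation.

# Embedding fields

The environment is a set of expansion sites carrying monopoles, point
dipoles, traceless (Buckingham) quadrupoles and anisotropic dipole–dipole
polarizabilities. Quadrupoles are detraced on input with a warning —
distributed-multipole practice varies and a traced input would silently
shift the field. Field evaluation sums the analytic charge, dipole and
quadrupole field terms; the test suite checks the sum against a
central-difference gradient of the analytically summed potential.

Induced dipoles (`induce_dipoles()`) are iterated to self-consistency
under mutual interaction, with the convergence criterion on the largest
dipole-component change (default 1e-10 au) and a hard iteration cap whose
breach is reported as a polarization catastrophe rather than returning a
half-converged state. No Thole-style damping is applied: the intended
environments are pre-derived embedding potentials whose polarizabilities
were constructed to be stable at molecular separations. Fields are always
*environment-only*: the odorant's own multipoles never act on itself.

The "field at the center" of a molecule is the mass-weighted average of
the per-atom field vectors, consistent with the mass-weighted vibrational
formalism; a geometric mean is available via `weighting = "geometric"`.

# Electron–phonon coupling

The central quantities are, per mode $\mu$ and redox state $i \in \{D,A\}$:

$$\delta\Pi_\mu(\vec E_i) = \sum_n m(n)\, y_\mu(n)\cdot\Delta(\vec E_i, n),
\qquad
u_i(\mu) = -\sqrt{\frac{\omega_\mu}{2\hbar}}\;\delta\Pi_\mu(\vec E_i),$$

$$S = (u_D - u_A)^2, \qquad \sigma_n = \frac{S^n}{n!}\,e^{-S}.$$

Three modelling decisions deserve explanation:

* **How $\Delta$ is obtained.** Two interchangeable routes are provided.
  *Linear response*: the force on atom $n$ is $q_n \vec E(n)$ with the
  molecule's partial charges, and the equilibrium shift solves
  $H\Delta = F$ restricted to the internal subspace, via the Moore–Penrose
  pseudo-inverse of the Eckart-projected mass-weighted Hessian. This is
  self-contained and has closed-form oracles (for a diatomic with charges
  $\pm q$ in an axial field $E$, the bond-length change is $qE/k$).
  *Geometry difference*: when optimized structures in each embedding are
  available, $\Delta$ is the difference after mass-weighted Kabsch
  superposition, which removes the rigid-body component the same way the
  Eckart projection does in the linear-response route. Each state $i$ gets
  its own $\Delta(\vec E_i)$.
* **The coupling-strength prefactor** is fixed by dimensional analysis:
  with $\delta\Pi$ in (mass)$^{1/2}$·(length), only
  $\sqrt{\omega/2\hbar}\,\delta\Pi$ is dimensionless, and it reproduces
  the textbook displaced-oscillator result
  $|u| = \delta\sqrt{m\omega/2\hbar}$ for a 1-D oscillator shifted by
  $\delta$ (tested against that closed form and against an end-to-end
  pipeline oracle at 1e-8 relative).
* **The exponent sign** in $\sigma_n$ is negative: $\{\sigma_n\}$ is then
  the normalized Poisson (Franck–Condon) distribution,
  $\sum_n \sigma_n = 1$ to 1e-12 for $S \le 10$ (tested). The divergent
  positive-sign variant is computable via `normalized = FALSE` for
  inspection but is never used internally.

Summary tables report $\sigma_1$ (single-phonon emission), the quantity
relevant to the inelastic-tunnelling picture in which the electron
deposits exactly one vibrational quantum; `huang_rhys_table()` exposes the
full $\sigma_n$ ladder.

# Marcus theory and reorganization energy

`marcus_rate()` evaluates the standard nonadiabatic rate. One printed
variant of this formula circulating in the literature carries an extra
$\pi$ inside the exponent denominator ($4\pi\lambda k_B T$); the package
defaults to the standard exponent $4\lambda k_B T$ (the extra $\pi$
appears to be a typesetting artifact — it breaks the standard
detailed-balance limit) and keeps the literal variant behind
`literal_exponent = TRUE` so the difference is inspectable rather than
silent.

Reorganization from two-state sampling follows the binned protocol:
histogram the potential-energy samples with a fixed bin width (default
5 kcal/mol, the protocol value), least-squares fit the Gaussian density
$p(E) = (\omega\sqrt{\pi/2})^{-1}\exp(-2(E-\langle E\rangle)^2/\omega^2)$
(`minpack.lm` Levenberg–Marquardt; note the width convention
$\mathrm{SD} = \omega/2$), and form $G(E) = -RT\ln p(E)$ at $T = 310$ K
with $R = 0.001987$ kcal/(mol·K) — an exact parabola with minimum at
$\langle E\rangle$ and curvature $4RT/\omega^2$. Least squares on the
binned density reproduces the published protocol exactly; a
maximum-likelihood route (`method = "mle"`) is available and agrees to
Monte-Carlo error.

`estimate_reorganization()` reports two things and keeps them clearly
apart:

* the **descriptive** comparison: the separation of the two parabola
  minima, flagged *indistinguishable* when it is below the bin width —
  the argument that λ is very small (≪ 1 kcal/mol) when donor and
  acceptor distributions coincide;
* the **quantitative extension** $\lambda_w = \omega^2/8RT$, from the
  linear-response identity $\mathrm{var}(E) = 2\lambda RT$. This is only
  meaningful when the sampled energy is the electron-transfer gap
  coordinate. Applied to a *total* receptor potential energy, the width is
  dominated by the thermal variance of every degree of freedom
  ($\mathrm{var} \approx \tfrac12 N_{\mathrm{dof}} (RT)^2$ for harmonic
  DOF) and $\lambda_w$ grossly overestimates λ — which is precisely why
  the descriptive criterion, not $\lambda_w$, is the primary output for
  total-energy traces. The recovery test drives $\lambda_w$ with traces
  generated at the gap-coordinate width $\omega = \sqrt{8RT\lambda}$ and
  recovers $\lambda_{\mathrm{true}} = 5$ kcal/mol within 10% at $10^5$
  samples.

# Trajectory metrics

Frames are aligned by least-squares rigid superposition (SVD/Kabsch with
the proper-rotation determinant correction) over a selection, typically a
protein backbone; RMSD and distance series then read off directly.
Running means are centered with shrinking edge windows (default window 50
steps, the presentation convention for the raw-plus-smoothed overlays).

Interaction energies are analysis-grade direct pair sums:
Coulomb with $\varepsilon_r = 1$ and the constant 332.0636
kcal·Å/(mol·e²), and 12-6 Lennard-Jones in the
$\varepsilon, r_{\min}$ parameterization with CHARMM combination rules.
Both terms are multiplied by the CHARMM energy-switching function between
`switch_on` (default 10 Å) and `cutoff` (default 12 Å), which is $C^1$ at
both ends (numerically tested); pairs beyond the cutoff contribute
nothing. The underlying simulation's PME electrostatics cannot be
reproduced by pair sums and is out of scope; direct switched sums are
what standard pair-interaction post-processing reports. No periodic
minimum-image handling is applied — the supported trajectories are
non-periodic extracts.

# Synthetic data: what it does and does not show

Every generator emits its exact ground truth alongside the data, so
downstream tests compare against closed forms rather than re-derived
numbers:

* `make_toy_molecule()` — harmonic bond (plus angle, where a pure
  bond-spring topology would leave a zero-curvature bend) Hessians with
  analytic frequencies: $\omega = \sqrt{k/\mu}$ (diatomic), symmetric /
  antisymmetric stretches (linear A–B–A), and the free-chain closed form
  $\omega_j = 2\sqrt{k/m}\sin(j\pi/2N)$ (equal-mass chains). Defaults
  ($k = 0.3$ au ≈ 0.47 mdyn/Å, bond 1.1 Å, amu-scale masses) put the
  stretches in the few-thousand cm⁻¹ range of real covalent bonds.
* `make_two_state_environment()` — the electron transfer reduced to its
  electrostatic skeleton: the acceptor state adds $+q$ at the donor site
  and $-q$ at the acceptor site of a baseline environment. The field
  difference is then an exact two-point-charge field, which is the oracle.
* `make_energy_traces()` — independent Gaussians in the
  $\mathrm{SD} = \omega/2$ convention. The default preset (equal means
  and widths, $\langle E\rangle = -10^4$ kcal/mol, $\omega = 100$
  kcal/mol, $10^5$ samples) mimics the observed regime for a receptor
  model: two statistically indistinguishable total-energy distributions.
  A separated preset drives the recovery tests.
* `make_trajectory()` — static / drift / oscillate / random-walk scripts
  with closed-form RMSD and distance series attached.

What passing on these fixtures demonstrates: the algebra, unit chains,
projections, fits and estimators are correct, end to end. What it does
not demonstrate: anything about real receptors. Synthetic Hessians have
no anharmonicity and no environment-dependent force constants; point
charges stand in for polarizable multipole environments unless higher
orders are switched on; Gaussian traces have no autocorrelation, whereas
MD energy series are strongly correlated (effective sample sizes are much
smaller than $n$); scripted trajectories contain no solvent, membrane or
barostat artifacts. Conclusions about a real system require real Hessians,
embedding potentials and trajectories in the supported formats.

All randomness flows through a single seed argument per generator;
identical seeds give identical outputs byte for byte (tested).

# Pipeline, problem sizes, and determinism

`run_pipeline()` executes synth → modes → field → couple (and optionally
reorg, traj) from a YAML or list configuration, validates referenced
input files before any stage runs, and writes a manifest (package
version, seed, parameters, input MD5s, outputs). A completed run with an
unchanged fingerprint is a no-op without `force = TRUE`. Numeric defaults
equal the study-condition values: $T = 310$ K, bin width 5 kcal/mol,
cutoff 12 Å with switching from 10 Å, smoothing window 50.

The shipped test and acceptance workloads use problem sizes chosen so the
statistical claims are meaningful at desk scale: $10^5$ samples for
parameter-recovery checks (where the ±1 / ±2 kcal/mol recovery windows
and the 10% λ window are quoted), $10^3$–$10^4$ samples elsewhere,
17-atom molecules for mode-counting (3·17 − 6 = 45 internal modes), and
tens of frames for trajectory oracles.

# Known limitations

* Anharmonicity, Fermi resonances and isotope effects beyond
  user-supplied masses are out of scope (deuteration is expressed by
  editing masses).
* The electronic coupling $H_{DA}$ is an input, never computed; no
  tunnelling current or full inelastic-tunnelling spectrum is produced.
* Embedding potentials are consumed, not derived: no LoProp/MFCC, no
  wavefunction handling.
* Trajectory electrostatics are direct switched sums, not Ewald/PME; no
  periodic boundary conditions.
* The least-squares Gaussian fit inherits the bin-width sensitivity of
  the published protocol; bin widths that under-resolve the distribution
  (fewer than 3 nonempty bins) are rejected rather than silently fitted.
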