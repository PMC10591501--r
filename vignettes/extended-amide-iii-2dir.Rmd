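---
title: "Methods: localized-mode anharmonic 2D-IR spectra in the extended amide III region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localized-mode anharmonic 2D-IR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amideIR)
```

This vignette documents the models, numerical choices and limitations of
`amideIR` at the level a user needs to judge what the package's results do
and do not show.

## 1. The local-mode picture

The extended amide III region of a peptide (roughly 1200–1400 cm⁻¹)
contains, per peptide group, one classical amide III vibration (in-plane
N–H bend mixed with C–N stretch) and, per alpha carbon, two Cα–H bending
vibrations.  These local vibrations couple and delocalize into normal
modes.  The analysis chain inverts that delocalization: harmonic normal
modes in the window are transformed by an orthogonal matrix $U$ chosen to
maximize the atomic-contribution localization criterion

$$\xi(U) \;=\; \sum_{k}\sum_{A}\Big(\sum_{\alpha \in A} c_{k\alpha}^2\Big)^{\!2},$$

where $c_{k\alpha}$ are mass-weighted displacement components of mode $k$
on atom $A$.  The localized modes carry a frequency/coupling matrix
$\mathbf{J} = U^\top \mathrm{diag}(\nu)\, U$ (cm⁻¹): local-mode frequencies
on the diagonal, harmonic couplings off-diagonal.  $\mathbf{J}$ is an exact
similarity transform of the harmonic problem — its eigenvalues are the
normal-mode wavenumbers, its trace their sum; both are asserted on every
run of the test suite.

**Optimization.** $\xi$ is maximized by Jacobi sweeps over all mode pairs
in lexicographic order.  For each pair the optimal rotation angle has the
closed form $\theta = \tfrac14\,\mathrm{atan2}(B, -A)$ with
$A = \sum_A [Q_{ij}^2 - \tfrac14 (Q_{ii}-Q_{jj})^2]$,
$B = \sum_A Q_{ij}(Q_{ii}-Q_{jj})$ built from per-atom displacement
products; the gain per rotation, $A + \sqrt{A^2+B^2}$, is non-negative, so
$\xi$ increases monotonically.  Sweeps stop when the relative gain of a
full sweep drops below `tol = 1e-10` or after `max_sweeps = 100`.  Pairs
with $\sqrt{A^2+B^2}$ at numerical zero (no gradient, no curvature) are
skipped.  A brute-force scan over rotation angles is kept in the test suite
as the independent oracle for the analytic angle.

**Sign and ordering conventions.** Localized modes are sign-fixed (largest
displacement component positive) and ordered by dominant atom index with
frequency as tie-break.  Some canonical ordering is required so that
coupling matrices of different conformers average entry-by-entry in
`motif_statistics()`; there is no single established convention for mode correspondence
across conformers, so this rule is this package's own choice.

## 2. The synthetic generator

Quantum-chemical Hessians for tens of conformers are out of scope; the
generator replaces them with local-mode Hamiltonians whose *statistical
structure* matches what DFT-based local-mode analyses of alanine peptides
report.  A capped chain of $n$ residues carries $n+1$ peptide groups (both
caps form amide bonds — the dipeptide N-acetyl-alanine-N′-methylamide has
two) and $2n$ Cα–H bends.  Frequencies and couplings are independent
Gaussians — means and spreads are the level of detail such analyses provide —
with means per mode class and motif, plus:

* a deterministic linear dependence on $(\phi, \psi)$ about a motif
  reference point (`dphi`, `dpsi`, cm⁻¹/degree), emulating the smooth
  local-mode frequency map over the Ramachandran plot;
* deterministic end-group offsets (`cap_n`, `cap_c`): the acetyl and
  N-methylamide caps are chemically distinct from interior peptide groups,
  which splits the two amide III local modes of the dipeptide and prevents
  accidental degeneracy;
* couplings by topological separation — same group, adjacent, distant, and
  an `interchain` class connecting facing groups ($g \leftrightarrow
  n+2-g$) of two antiparallel strands.

The **default table is synthetic** and calibrated once, against the
qualitative orderings only: classical amide III local modes below
~1250 cm⁻¹, Cα–H bends at ~1260–1340 cm⁻¹; amideIII–amideIII adjacent
coupling 9.0 cm⁻¹ (α) vs 0.5 cm⁻¹ (β); CaH–amideIII same-group coupling
2.5 cm⁻¹ (α) vs 15.0 cm⁻¹ (β); larger β frequency scatter; Cα–H dipole
magnitudes 0.45 (α) vs 1.2 (β) encoding the much larger β-strand Cα–H
intensities.  Absolute peak positions, intensities in physical units, and
any quantity that requires an electronic-structure calculation are *not*
reproduced, only orderings and patterns.  Users with DFT-derived tables can
load them via `read_motif_params()`.

**Dipole orientation rule.** Local-mode analyses report no transition-dipole
geometry, so the rule here is a documented placeholder: amide III dipoles
lie on a 35° cone about the chain axis and rotate per group by an angle
derived from $\phi+\psi$; Cα–H dipoles lie perpendicular to the chain axis,
the two bends of one Cα at right angles; the antiparallel partner chain is
mirrored.  Only the *magnitude ratio* between motifs is load-bearing for
the qualitative claims.

**Reproducibility.** Every random number is addressed by a structural key
(seed, chain, mode class, position), mixed to a 31-bit integer that seeds
R's Mersenne–Twister for exactly one draw.  A fixed seed reproduces a model
bit-for-bit, adding modes never perturbs earlier entries, and zero-SD
tables make builders seed-independent.  Sample means and SDs over $10^4$
draws recover the table values within Monte-Carlo error (tested).

## 3. Anharmonic treatment (L-VSCF / L-VCISD)

**Units.** All energies are in cm⁻¹.  Local coordinates $q$ are
dimensionless: a harmonic mode of frequency $\omega$ has kinetic operator
$-(\omega/2)\,d^2/dq^2$ and potential $(\omega/2)q^2$, so the harmonic
ground state has $\langle q^2\rangle = 1/2$ and
$\langle 0|q|1\rangle = 1/\sqrt2$.  The speed of light used in conversions
is $2.997924580\times10^{-2}$ cm/ps to 10 significant digits.

**One-mode potentials** are Morse wells
$V(q) = D_e (1 - e^{-aq})^2$ solved in closed form from two conditions:
harmonic frequency at the minimum equal to the local frequency $\omega$,
and exact 0→1 transition equal to $\omega - s$ for a prescribed red shift
$s$.  This gives $a = \sqrt{s/\omega}$, $D_e = \omega^2/(2s)$, hence Morse
constants $\omega_e = \omega$, $\omega_e x_e = s/2$, levels
$E_n = \omega_e(n+\tfrac12) - \omega_e x_e (n+\tfrac12)^2$ and a diagonal
anharmonicity $2E_{01} - E_{02} = s$.  Shifts $s \ge \omega/2$ are rejected
(the well would hold too few states).  The tabulation grid always contains
$q = 0$, so the tabulated and analytic minima coincide and absolute DVR
levels match the closed form (tested to 0.1 cm⁻¹).

**One-mode solver.** Sine-type (Colbert–Miller) DVR on the uniform
tabulation grid; eigenfunctions are exact quadratures for any local
operator.  Doubling the grid density moves levels by < 0.01 cm⁻¹ at the
101-point default; an optional check warns when spacings move by more than
0.5 cm⁻¹.

**Two-mode potentials are strictly bilinear**, $k_{ij}\,q_i q_j$, because
the harmonic couplings are all the coupling matrix provides.  The
conversion from the frequency-matrix convention is $k_{ij} = 2 J_{ij}$:
with $\langle 0|q|1\rangle = 1/\sqrt2$ this makes the one-exciton block of
the VCI Hamiltonian reproduce $\mathbf{J}$ exactly at first order, and the
coupled-harmonic-pair fundamentals match the $2\times2$ eigenvalues of
$\mathbf{J}$ to ≤ 0.1 cm⁻¹ (tested; residual is the second-order
$J^2/\bar\nu$ difference between frequency- and force-constant couplings
plus VCISD truncation).

**VSCF** iterates the ground-state mean field
$V_i^{\rm eff}(q_i) = V_i(q_i) + q_i \sum_{j\ne i} k_{ij}\langle q_j\rangle$
to an energy change below $10^{-6}$ cm⁻¹ (at most 50 iterations;
non-convergence is flagged, not thrown).  For symmetric one-mode potentials
$\langle q_j\rangle = 0$ and VSCF reduces to the uncoupled solution — the
machinery matters for Morse potentials, where $\langle q\rangle \ne 0$.

**VCISD.** The configuration space contains every product configuration
with excitation level (= total quanta; an overtone counts as a double) up
to 2, so all excited-state-absorption target states — overtones and
two-mode combinations — are inside the space.  Basis functions per mode are
the eigenfunctions of that mode's own anharmonic one-mode problem (10
solved by default), not harmonic-oscillator functions.  Matrix elements
need only per-mode $\langle m|q|n\rangle$ quadratures; the dense symmetric
Hamiltonian is diagonalized exactly.  For a dipeptide that is 15
configurations, for polyalanine-10 (31 modes) 528.  A configurable cap
(20 000) refuses larger spaces with guidance.  States are labeled by their
dominant configuration when its weight exceeds 0.5, else flagged `mixed`
with the two largest configurations.  Transition dipoles use the
linear-dipole approximation $\mu(q) = \sum_i \mu_i q_i$.  Against an
untruncated two-mode product-grid diagonalization the VCISD energies agree
to ≤ 0.5 cm⁻¹ at the default settings (tested); raising the excitation cap
never raises a variational energy (tested).

## 4. 2D-IR response

The absorptive spectrum at waiting time $t_2 = 0$ is a sum over states in
the population (doorway–window) bookkeeping.  Pumping fundamental $a$
(weight $|\mu_{0a}|^2$) produces

* ground-state bleach at $(E_a, E_b)$ for every fundamental $b$,
* stimulated emission at $(E_a, E_a)$,
* excited-state absorption at $(E_a, E_c - E_a)$ for every two-quantum
  state $c$ reachable from $a$,

each weighted by the isotropic four-point orientational factor of its
dipole sequence and by the squared transition dipoles.  With this
bookkeeping the harmonic separable limit cancels *exactly*, including the
orientational factors and the $\sqrt2$ overtone dipole rule; the test suite
requires the residual to stay below $10^{-10}$ of the pathway amplitude.  A
formulation that attaches the ESA pathways to coherence pairs but keeps
squared-dipole weights would break that cancellation, which is why the
population form is used.  Surviving signal is therefore a direct image of
diagonal anharmonicities (negative/positive doublets split by
$\Delta_i = 2E(1_i) - E(2_i)$) and couplings (cross-peaks scaling with the
off-diagonal anharmonicity $\Delta_{ij}$), and the total peak amplitude
grows linearly with small $\Delta$ (tested).

**Lineshape.** Only a dephasing time is specified, so peaks are factorized
products of pump- and probe-axis Lorentzians with HWHM (not FWHM)
$\gamma = (2\pi c T_2)^{-1} = 5.308837459$ cm⁻¹ ps$/T_2$; no
inhomogeneous/Voigt broadening, no spectral diffusion.  The default axes
are 1150–1450 cm⁻¹ at 0.5 cm⁻¹.  The frequency prefactor per interaction is
a configuration switch, off by default for 2D and on for 1D spectra.  The
sign convention (bleach negative, ESA positive) is configurable because
published color conventions vary.

**Polarization.** $\langle ZZZZ\rangle$, $\langle ZZXX\rangle$,
$\langle ZXXZ\rangle$ (and $\langle ZXZX\rangle$) are the standard
isotropic four-point averages over the inter-dipole angles; the identity
$\langle ZZZZ\rangle = \langle ZZXX\rangle + \langle ZXZX\rangle + \langle
ZXXZ\rangle$ is asserted pixelwise on whole spectra, and the factors are
cross-checked against a $10^6$-rotation Monte-Carlo average.

**Cross-peak reporting.** With a 5.3 cm⁻¹ HWHM the features of a dipeptide
overlap heavily, and the extremum of the total amplitude inside a band
rectangle mostly measures Lorentzian tails of the strongest diagonal peak.
`cross_peak_report()` therefore classifies sticks physically — bleach/SE of
a single state and ESA into that state's own overtone are *diagonal*;
bleach across two states and ESA into combination bands are *cross* — and
reports extrema of the two classes rendered separately.  Cancelling
partners of a cross feature share positions, so uncoupled modes give
exactly zero cross values while diagonal doublets remain.

## 5. Pipeline, formats, reproducibility

`run_pipeline()` executes input → window selection → localization → VSCF →
VCISD → 1D/2D spectra, writing plain-text artifacts (coupling CSVs, model
JSON, state TSV, spectrum TSV/gnuplot triplets/JSON) whose headers carry a
digest of the scientific configuration (the output directory and log level
are excluded, so the same run in two places is bit-identical; asserted via
MD5 manifests in the tests).  Synthetic runs execute the localization
stage on an exact exciton embedding of the model (each local mode a unit
displacement of its own atom) — a closure check that re-derives the planted
coupling matrix — and then use the model's own potentials for the
anharmonic stages.  Molden runs take per-mode anharmonic shifts from the
configuration, since Molden files carry no one-mode scans.  Stage failures
abort with a condition object carrying the stage name; grid studies record
per-conformer failures and continue.

## 6. Problem sizes and defaults

The shipped examples and checks run dipeptides (4 modes, 15
configurations), polyalanine-10 (31 modes, 528 configurations) and
two-strand models (32 modes); 25-conformer grids run the dipeptide chain
per conformer.  Default numerical parameters: 101-point one-mode grids,
10 one-mode basis states, excitation level 2, per-mode quanta cap 4
(inactive at level 2), VSCF tolerance $10^{-6}$ cm⁻¹, localization
tolerance $10^{-10}$, $T_2 = 1$ ps, ⟨ZZZZ⟩.

## 7. What passing tests do and do not show

The generator emulates *statistics* of local-mode parameters, not
molecules: there is no geometry, no solvent, no Fermi resonance, no
three-mode coupling, no finite waiting-time dynamics, and the dipole
orientation rule is a placeholder.  Agreement of the qualitative α/β
cross-peak orderings on synthetic models shows that the spectroscopic
machinery (localization → VCISD → response) turns the assumed coupling
structure into the expected 2D-IR patterns; it does not validate the
assumed coupling values themselves, which in real applications must come
from electronic-structure calculations fed in through the Molden/parameter
interfaces.
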