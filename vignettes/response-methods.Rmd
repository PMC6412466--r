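---
title: "Condensed linear response of density and spin density: model, quadrature, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensed linear response of density and spin density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinlrf)
```

## The model

For a single-determinant ground state with spin-resolved orbitals
$\psi_{i\sigma}$ and energies $\varepsilon_{i\sigma}$, first-order
perturbation theory gives the bare response of the spin-channel density to a
local potential change,

$$\frac{\delta\rho_\sigma(\mathbf r)}{\delta v(\mathbf r')} =
\sum_i^{\mathrm{occ}}\sum_a^{\mathrm{virt}}
\frac{\psi_{i\sigma}(\mathbf r)\,\psi_{a\sigma}(\mathbf r)\,
      \psi_{i\sigma}(\mathbf r')\,\psi_{a\sigma}(\mathbf r')}
     {\varepsilon_{i\sigma}-\varepsilon_{a\sigma}} .$$

The density response sums the two channels; the spin-density response to a
virtual magnetic-field perturbation differences them,
$\delta\rho_z/\delta v_m = \delta\rho_\alpha/\delta v_m -
\delta\rho_\beta/\delta v_m$, each channel evaluated by the same formula.
For duplicated (restricted) channels the difference is identically zero and
the package short-circuits to an exact zero matrix.

Three structural facts follow directly from the formula and are enforced by
construction and verified by tests:

* **Symmetry** in $\mathbf r \leftrightarrow \mathbf r'$, hence a symmetric
  condensed matrix.
* **Negative semidefiniteness** of the density response: every denominator
  is occupied-minus-virtual, hence negative, so the condensed matrix is
  $-W^\top W$ for a real $W$. The package computes it in exactly that form,
  which makes symmetry and semidefiniteness exact in floating point, not
  just up to quadrature error.
* **Charge conservation**: each occupied-virtual product integrates to zero
  over all space (orbital orthogonality), so matrix columns sum to zero up
  to quadrature error.

This is the *uncoupled* (orbital-relaxation-free) response. No
coupled-perturbed terms, no frequency dependence; those are out of scope by
design, and the matrix should be read as the leading-order sensitivity map,
not a converged polarizability.

### Pair counting in the kernel

The kernel above counts each occupied$\to$virtual excitation once. The
conventional static response function carries an additional factor 2 (the
complex-conjugate term: perturbing an occupied orbital changes its square by
$2\psi_i\,\delta\psi_i$). We keep the single-counting normalization because
the two-site closed form used as the package's primary oracle,
$K = 2(\cos2\theta\, s)^2/(\varepsilon_b-\varepsilon_a)\,
\begin{pmatrix}1&-1\\-1&1\end{pmatrix}$, is stated in it (the leading 2 is
the spin sum). The finite-difference cross-check
(`finite_difference_oracle`) therefore divides its measured first-order
density change by $2\lambda$; its documentation states the conversion. Users
comparing against a coupled or doubled convention should multiply the
matrices by 2.

## Condensation: hard Wigner-Seitz cells

The two-point kernel is never formed. Per spin channel the package computes
cell-integrated transition moments $M_\sigma[i,a,A] = \int_{\text{cell }A}
\psi_{i\sigma}\psi_{a\sigma}\,d\mathbf r$ once (cost
$O(N_{occ} N_{virt} M_{points})$) and contracts them per atom pair,

$$K[I,J] = \sum_\sigma \sum_{i,a}
\frac{M_\sigma[i,a,I]\; M_\sigma[i,a,J]}
     {\varepsilon_{i\sigma}-\varepsilon_{a\sigma}} .$$

Cells are hard nearest-atom Voronoi (Wigner-Seitz) regions: perpendicular
bisector planes, no fuzzy weights. Each atom carries a product grid —
Euler-Maclaurin radial map $r = R_a q^2/(1-q)^2$, $q = k/n$, with weights
$2R_a^3 q^5/(1-q)^7/n$ absorbing the $r^2$ Jacobian, scaled by the
element's Bragg-Slater radius ($R_a$; hydrogen 0.35 Å as is customary in
molecular quadrature), times a Lebedev angular rule regenerated from the
published octahedral orbit constants. Defaults are $n_{rad} = 50$ and
$n_{ang} = 302$; supported Lebedev orders are 6, 26, 50, 110 and 302.

**Which points contribute.** Every atom's product grid covers all space, so
treating every grid point as a contributor to its nearest atom's cell would
integrate each region once per atom. The package therefore uses the hard
partition in which a point contributes if and only if it lies inside its
*parent* atom's cell; points parented by one atom but owned by another are
retained in the grid structure (with parent, owner and base weight) but
carry zero effective weight. This makes the per-atom integrals a true
partition: summed over atoms they equal the plain grid sum to machine
precision, and the electron count is recovered to well below $10^{-3}$ on
the fixtures.

**Accuracy at the cell boundary.** The price of hard cells is that each
atomic quadrature integrates a discontinuously truncated region; the error
scales with the integrand's magnitude at the bisector plane. Quadrature
error on the default grid is about $10^{-2}$ relative for site functions
with significant density at the midpoint (e.g. unit-exponent Gaussians 1.4
bohr apart) but below $10^{-7}$ for the compact site functions the toy
generators use. Doubling the radial order halves, roughly, the boundary
error; it does not remove it. Heavier elements with tighter densities are
less affected in relative terms.

**Ties.** A point exactly on a bisector (measure zero) goes to the lowest
atom index — a deterministic, documented tie-break.

## Toy systems and what they do (not) show

The generators realize the broken-symmetry two-site model exactly: two
s-Gaussian sites, symmetrically (Löwdin) orthogonalized, combined into
bonding/antibonding orbitals, and mixed by a prescribed angle $\theta$ per
channel ($\alpha$: $\cos\theta\,\phi_b + \sin\theta\,\phi_a$; $\beta$: the
sign-flipped partner). Because the model's identities ($T = \cos 2\theta$,
$b = \sum T_i$, the spin-density closed form
$\rho_z = \sqrt{1-b^2}(\chi_1^2 - \chi_2^2)$) neglect inter-site overlap,
the sites are orthogonalized *before* the combinations, making the
identities exact in the orthonormal site basis rather than approximate.

Defaults, chosen once as the study conditions: separation 3.2 bohr
(stretched-bond regime where broken-symmetry solutions exist), site exponent
2.5 bohr$^{-2}$, orbital gap 0.5 hartree ($\varepsilon_b = -0.25$,
$\varepsilon_a = +0.25$). The compact exponent keeps the residual inter-site
overlap near $3\times10^{-6}$ — consistent with the model's neglect of it —
and keeps hard-cell quadrature errors at or below $10^{-7}$ on the default
grid, so test tolerances probe the algebra rather than the grid.

Chain toys place s-Gaussian sites on a line (or regular ring), orthogonalize
them, and take tight-binding eigenvectors as closed-shell orbitals. Uniform
chains are *not* near-sighted: on a bipartite (alternant) chain the
end-to-end response stays comparable to nearest-neighbor couplings — real
conjugated-chain physics, not an artifact. The locality fixture therefore
uses a monotone gap profile: a deep well on site 1
(site energies $-0.5, 0.1, 0.3, 0.6$ hartree, uniform coupling $-0.1$, one
occupied orbital), which localizes the occupied orbital and makes the
occupied-virtual gap grow with distance; the condensed response then decays
monotonically along the chain, as the near-sightedness argument predicts.

What passing these tests shows: the sum-over-states contraction, the
condensation, the diagnostics and the selection logic are correct on
systems where every quantity has an independent closed form or quadrature
oracle. What they do not show: behavior on diffuse bases (cell-boundary
error grows), near-degenerate metal d-manifolds (the gap guard refuses
them), or the coupled response of a self-consistent calculation.

## Numerical choices

* **Gap guard.** Any occupied-virtual gap below $10^{-6}$ hartree aborts
  with an error naming the pair, rather than regularizing the denominator:
  a silently regularized matrix would look plausible and be wrong.
* **Virtual space.** All virtuals enter the sums by default; an optional
  energy cutoff exists for experiments and is recorded in every output's
  provenance block, never applied silently.
* **Occupations.** Exactly 0 or 1 per spin orbital (0/2 in restricted
  files, duplicated into channels). Fractional occupations are rejected at
  the door — the sum-over-states formula has no meaning for them here.
* **Overlaps.** AO overlaps are computed numerically on the same quadrature
  grid (documented accuracy about $10^{-6}$ for well-localized bases),
  doubling as a standing cross-check of basis evaluation and grid; toy
  systems also carry their analytic overlap for exact-arithmetic tests.
  Orbital validation reports $\max|C^\top S C - I|$ per channel and flags,
  but does not repair, deficient inputs.
* **Corresponding overlaps.** Singular values of
  $C_{\alpha,occ}^\top S\, C_{\beta,occ}$, sorted ascending so the magnetic
  pair is first; values are clipped to $[0,1]$ only within $10^{-10}$ of
  the bounds, and anything above $1 + 10^{-8}$ is treated as an
  inconsistent overlap matrix, not clipped.
* **Unequal spin counts.** With $N_\alpha \neq N_\beta$ the pair indices
  use the $\min(N_\alpha, N_\beta)$ singular values; the excess is reported
  as `n_unpaired_excess` and excluded from $b$, $B$, $y$ — the pairing
  picture applies to paired channels only.
* **Aggregate diradical character.** $y$ is reported per pair and, as the
  headline number, for the magnetic (smallest-$T$) pair; multi-pair
  aggregation conventions differ across the literature, so both are
  emitted.
* **Region selection.** The threshold criteria are stated as criteria, not
  an algorithm; the package implements the minimal reading: atom $J$ is
  selected iff $\max_{I\in RC}|K_\rho[I,J]| \ge \tau_\rho$ or
  $\max_{I\in RC}|K_z[I,J]| \ge \tau_m$, with reaction-center atoms always
  included. Optional fragment completion (off by default) expands the
  selection to whole covalent fragments using Cordero covalent radii and a
  1.3x bond criterion; bonds crossing the boundary are reported as a
  cut-bond list for capping, never edited into the geometry.
* **Model errors.** Reported as model minus full, stated in every report
  header, over an explicit injective atom map.

## Problem sizes

All shipped tests and the acceptance script run on the analytic fixtures:
two-atom toys and a four-site chain at the default $50\times302$ grid
(about 15,000 points per atom), an 11-point $\theta$ scan, and
finite-difference cross-checks over every matrix column. The full suite
completes in seconds on one core; no external orbital files are required.
An external-engine fixture hook exists (`make_molden_fixture`) and skips
cleanly when no SCF engine is present.

## Known limitations

* The bare response underestimates screening relative to coupled-perturbed
  response; thresholds calibrated on it are conservative in that specific
  sense only.
* Hard Voronoi condensation is one of several atoms-in-molecules
  conventions; populations condensed this way need not match Mulliken or
  Hirshfeld numbers, and enzyme-scale published per-atom values may use a
  different scheme.
* Molden dialects vary; the reader normalizes primitive coefficients,
  accepts spherical and Cartesian d/f/g markers, and rejects files whose
  shells are unnormalized beyond tolerance rather than guessing the
  convention.
* No effective core potentials, no gradients of fields, no periodic
  systems.
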