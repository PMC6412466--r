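# spinlrf

Linear response functions of electron density and spin density for choosing
QM/MM boundaries around open-shell reaction centers.

## The problem

Hybrid QM/MM calculations on metalloenzymes (heme cofactors, the Mn4O5Ca
oxygen-evolving cluster, and similar open-shell centers) stand or fall on
where the QM region is cut. Replacing a peripheral group by point charges
perturbs the external potential there; how much that perturbation corrupts
the density and spin density at the reaction center is governed by the
linear response function (LRF) of the ground state,

    delta rho(r) / delta v(r')        (electron density)
    delta rho_z(r) / delta v_m(r')    (spin density, rho_z = rho_a - rho_b)

`spinlrf` computes the bare (uncoupled) sum-over-states response from any
unrestricted Kohn-Sham or Hartree-Fock orbital set,

    K_sigma(r, r') = sum_{i occ} sum_{a virt}
        psi_i(r) psi_a(r) psi_i(r') psi_a(r') / (eps_i - eps_a),

sums it over spin channels (density) or differences it (spin density), and
condenses it onto atom pairs by double integration over hard Wigner-Seitz
cells (nearest-atom Voronoi cells, no fuzzy weights) on a 50-point
Euler-Maclaurin radial x 302-point Lebedev angular grid:

    K[I, J] = int_{cell I} dr int_{cell J} dr' K(r, r').

The atom-pair matrix `K[I, J]` is the quantitative answer to "if the model
error puts a spurious potential on atom J, how much density shifts at atom
I?" — thresholding it at 0.1 / 0.01 / 0.001 separates strong covalent/ionic
couplings, hydrogen bonds and hyperconjugation paths, and long-range
polarization, and directly suggests which atoms a QM region must keep.

Alongside the response machinery the package characterizes broken-symmetry
(BS) solutions: corresponding-orbital overlaps `T_i` (singular values of the
occupied alpha-beta overlap block), effective bond order `b = sum T_i`,
spin-projected bond order `B = sum 2 T_i / (1 + T_i^2)`, diradical character
`y = 1 - B`, natural occupations `1 +- T_i`, and the on-top pair density
`rho2_ab(r; r) = (rho^2 - rho_z^2) / 2`.

Orbitals come from Molden files written by any SCF engine (spherical or
Cartesian shells through g functions, restricted or unrestricted), or from
analytic toy generators that realize the two-site BS model exactly and are
used throughout the test suite.

## Worked example

A stretched two-site singlet with mixing angle `theta = pi/8` between the
bonding and antibonding orbitals (the textbook broken-symmetry model):

```r
library(spinlrf)

toy  <- build_two_site_toy(pi / 8)            # 2 sites, 3.2 bohr apart
grid <- assemble_ws_grid(toy$geometry)        # 50 x 302 Wigner-Seitz grid
ao   <- eval_basis(toy$shells, toy$geometry, grid$points)
tm   <- transition_moments(toy$mos, grid, ao)

condensed_lrf_density(tm)$matrix
#>            H(1)       H(2)
#> H(1) -0.4999997  0.4999997
#> H(2)  0.4999997 -0.4999997

bs_diagnostics(toy$mos, toy$overlap, grid = grid, ao_values = ao)
#> broken-symmetry diagnostics
#>  pair        T        y  n_bond   n_anti
#>     1 0.707107 0.057191 1.70711 0.292893
#>   b = 0.707107   B = 0.942809   y (magnetic pair) = 0.057191
#>   spin populations:
#>      H(1)      H(2)
#>  0.707107 -0.707107
```

The response matrix matches the closed form `K = 2 (cos(2 theta) s)^2 /
(eps_bond - eps_anti) * [[1, -1], [-1, 1]]` (here `s = 0.5`, gap 0.5
hartree): the diagonal is negative (an attractive perturbation at an atom
piles density onto it), the off-diagonal positive and equal (charge
conservation: columns sum to zero), and the whole matrix is negative
semidefinite. The diagnostics recover `T = cos(2 theta) = 0.7071`, bond
order 0.71, diradical character 0.057, and spin populations +-0.71 — the
partial localization the spin density develops as a bond stretches.

For QM-region suggestions, score every atom against a reaction center RC by
`max_{I in RC} |K[I, J]|` for both kinds and keep atoms exceeding the 0.01
thresholds:

```r
suggest_qm_region(condensed_lrf_density(tm), condensed_lrf_spin(tm),
                  rc = 1, tau_rho = 0.01, tau_m = 0.01)
#> QM region suggestion (tau_rho = 0.01, tau_m = 0.01): 2 of 2 atoms
#>   H(1)     reaction_center c_rho = 0.5  c_z = 7.678e-08
#>   H(2)     density         c_rho = 0.5  c_z = 0
```

A thin CLI wraps the same calls for shell use:

```sh
Rscript inst/cli/spinlrf.R lrf-matrix system.molden --grid 50x302 -o matrix.csv
Rscript inst/cli/spinlrf.R lrf-cube   system.molden --atom 1 -o field.cube
Rscript inst/cli/spinlrf.R qm-region  system.molden --rc 1,38 --tau-rho 0.01
Rscript inst/cli/spinlrf.R bs-diag    system.molden
```

Every run writes a `.provenance.json` log (input hashes, package version,
grid, thresholds).

## Scope

The response is the bare orbital (sum-over-states) response — no coupled-
perturbed self-consistency, no frequency dependence. SCF itself is out of
scope: orbitals are read from Molden files produced elsewhere. Cube files
are written for external isosurface viewers; heat-map rendering is delegated
to external tools via CSV + JSON export.
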