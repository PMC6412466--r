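Package: spinlrf
Title: Linear Response Functions of Electron and Spin Density for QM/MM
    Region Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes atom-condensed linear response functions of the
    electron density and the spin density from unrestricted Kohn-Sham or
    Hartree-Fock orbital sets by sum-over-states perturbation theory.
    Orbitals are read from Molden files or built as analytic
    broken-symmetry toy systems; densities and response kernels are
    condensed onto atoms by hard Wigner-Seitz (nearest-atom Voronoi) cell
    quadrature on Euler-Maclaurin radial times Lebedev angular grids.
    Includes broken-symmetry diagnostics (corresponding-orbital overlaps,
    effective and spin-projected bond orders, diradical character, on-top
    pair density), threshold section analysis of condensed response
    matrices, QM-region suggestion from reaction-center atoms, and
    model-error reports between cluster models and a full model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
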