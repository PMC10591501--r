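Package: amideIR
Title: Localized-Mode Anharmonic 1D and 2D Infrared Spectra of Peptides in the Extended Amide III Region
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates one- and two-dimensional infrared (2D-IR) spectra of
    peptides in the extended amide III region (ca. 1200-1400 cm^-1), where the
    classical amide III vibrations of the peptide groups mix with the C-alpha-H
    bending vibrations.  Provides a synthetic local-mode Hamiltonian generator
    for capped dipeptides and polyalanine chains on Ramachandran (phi, psi)
    grids, normal-mode selection and Jacobi localization with extraction of
    local-mode frequency/coupling matrices, localized-mode VSCF and VCI with
    singles and doubles (anharmonic one-mode Morse potentials plus bilinear
    two-mode couplings), and purely absorptive sum-over-states 2D-IR spectra
    with Lorentzian dephasing and isotropic orientational averaging for the
    ZZZZ, ZZXX and ZXXZ polarization conditions.  Reads Molden-format harmonic
    frequency files with a sidecar transition-dipole table, and reproduces the
    qualitative alpha-helix versus beta-strand cross-peak signatures of the
    extended amide III band on synthetic models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
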