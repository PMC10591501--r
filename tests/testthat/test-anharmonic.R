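test_that("DVR reproduces harmonic-oscillator levels to 0.1 cm^-1", {
  ev <- solve_one_mode(harmonic_potential(1300), 6)
  expect_equal(ev$values - ev$values[1], 1300 * (0:5), tolerance = 1e-6)
  expect_equal(ev$values[1], 650, tolerance = 1e-4)
})

test_that("Morse tabulation matches the closed-form level formula", {
  # parameterization: omega_e = freq, omega_e x_e = shift / 2
  for (case in list(c(1300, 10), c(1250, 4), c(1400, 25))) {
    freq <- case[1]; shift <- case[2]
    ev <- solve_one_mode(morse_potential(freq, shift), 4)
    exact <- morse_levels(freq, shift, 0:3)
    expect_equal(ev$values, exact, tolerance = 0.1 / 1300)
    # stated contract: exact 0->1 transition = freq - shift
    expect_equal(ev$values[2] - ev$values[1], freq - shift,
                 tolerance = 1e-4)
    # 0->2 via the Morse formula: 2*freq - 3*shift
    expect_equal(ev$values[3] - ev$values[1], 2 * freq - 3 * shift,
                 tolerance = 1e-3)
  }
})

test_that("shift = 0 gives the harmonic limit and bad shifts error", {
  pot <- morse_potential(1300, 0)
  ev <- solve_one_mode(pot, 3)
  expect_equal(diff(ev$values), c(1300, 1300), tolerance = 1e-6)
  expect_error(morse_potential(1300, 700), "shallow")
  expect_error(morse_potential(-5, 0), "positive")
})

test_that("grid refinement leaves levels unchanged for adequate grids and warns for coarse ones", {
  fine <- solve_one_mode(morse_potential(1300, 10, grid_points = 101), 5)
  finer <- solve_one_mode(morse_potential(1300, 10, grid_points = 201), 5)
  expect_lt(max(abs(fine$values - finer$values)), 0.01)
  expect_silent(solve_one_mode(morse_potential(1300, 10, grid_points = 101),
                               5, check = TRUE))
  expect_warning(solve_one_mode(morse_potential(1300, 10, grid_points = 12),
                                8, check = TRUE), "too coarse")
})

test_that("one_mode_potential validates its grid", {
  expect_error(one_mode_potential(1:5, (1:5)^2, 1300), "at least 8")
  expect_error(one_mode_potential(c(1:7, 7), ((1:8) - 4)^2, 1300),
               "strictly increasing")
  expect_error(one_mode_potential(seq(-2, 2, length.out = 9),
                                  seq(1, 9), 1300), "interior")
})

test_that("VSCF reduces to the uncoupled zero-point sum in the separable and symmetric cases", {
  # zero couplings, Morse potentials
  m0 <- make_model(diag(c(1250, 1320)), diag(1, 2, 3), shifts = c(10, 8))
  r0 <- vscf(m0)
  zpe <- sum(vapply(m0$potentials, function(p)
    solve_one_mode(p, 1)$values[1], numeric(1)))
  expect_true(r0$converged)
  expect_equal(r0$energy, zpe, tolerance = 1e-8)
  # harmonic (symmetric) potentials with bilinear couplings: <q> = 0
  J <- matrix(c(1250, 8, 8, 1320), 2)
  mh <- make_model(J, diag(1, 2, 3), shifts = 0)
  rh <- vscf(mh)
  zpe_h <- (1250 + 1320) / 2
  expect_equal(rh$energy, zpe_h, tolerance = 1e-6)
  expect_equal(rh$q_expect, c(0, 0), tolerance = 1e-8)
})

test_that("VSCF energy decreases monotonically and modal coefficients are orthonormal", {
  J <- matrix(c(1250, 7, 3, 7, 1300, 5, 3, 5, 1340), 3)
  m <- make_model(J, diag(1, 3, 3), shifts = c(10, 8, 8))
  r <- vscf(m)
  expect_true(r$converged)
  expect_true(all(diff(r$energy_history) <= 1e-6))
  for (cv in r$modal_coefficients)
    expect_equal(sum(cv^2), 1, tolerance = 1e-8)
})

test_that("VCI separable harmonic limit gives exact fundamentals and selection rules", {
  m <- make_model(diag(c(1250, 1320)), rbind(c(1, 0, 0), c(0, 2, 0)),
                  shifts = 0)
  st <- vci_sd(m)
  fund <- st$energies[st$quanta == 1]
  expect_equal(sort(fund), c(1250, 1320), tolerance = 1e-6)
  # sqrt(2) overtone dipole rule and vanishing two-quantum access from ground
  i1 <- which(st$labels == "1(m1)")
  i2 <- which(st$labels == "2(m1)")
  mu01 <- transition_dipole(st, 1, i1)
  mu12 <- transition_dipole(st, i1, i2)
  expect_equal(sqrt(sum(mu12^2)) / sqrt(sum(mu01^2)), sqrt(2),
               tolerance = 1e-6)
  expect_lt(sqrt(sum(transition_dipole(st, 1, i2)^2)), 1e-8)
  icomb <- which(st$labels == "1(m1)+1(m2)")
  expect_lt(sqrt(sum(transition_dipole(st, 1, icomb)^2)), 1e-8)
})

test_that("coupled harmonic pair reproduces the 2x2 frequency-matrix eigenvalues", {
  for (J12 in c(3, 6, 9)) {
    J <- matrix(c(1250, J12, J12, 1280), 2)
    m <- make_model(J, diag(1, 2, 3), shifts = 0)
    st <- vci_sd(m)
    fund <- sort(st$energies[st$quanta == 1])
    expect_equal(fund, sort(eigen(J, only.values = TRUE)$values),
                 tolerance = 0.1 / 1250)
  }
})

test_that("two-mode VCI matches the full product-grid diagonalization within 0.5 cm^-1", {
  J <- matrix(c(1250, 8, 8, 1310), 2)
  m <- make_model(J, diag(1, 2, 3), shifts = c(10, 8), grid_points = 36)
  st <- vci_sd(m)
  oracle <- two_mode_product_oracle(m$potentials[[1]], m$potentials[[2]],
                                    k = 2 * 8, n_eigen = 6)
  got <- st$energies[1:6] + st$ground_energy
  expect_equal(got, oracle, tolerance = 0.5 / 1250)
})

test_that("VCI is variational: below VSCF and monotone under space enlargement", {
  J <- matrix(c(1250, 7, 4, 7, 1300, 6, 4, 6, 1340), 3)
  m <- make_model(J, diag(1, 3, 3), shifts = c(10, 8, 8))
  scf <- vscf(m)
  st2 <- vci_sd(m, vscf = scf, max_level = 2)
  st3 <- vci_sd(m, vscf = scf, max_level = 3, max_quanta = 3)
  expect_lte(st2$ground_energy, scf$energy + 1e-8)
  # enlarging the configuration space never raises a variational energy
  expect_lte(st3$ground_energy, st2$ground_energy + 1e-10)
  n2 <- length(st2$energies)
  expect_true(all(st3$energies[seq_len(n2)] + st3$ground_energy <=
                  st2$energies + st2$ground_energy + 1e-8))
})

test_that("VCI refuses oversized configuration spaces with guidance", {
  conf <- peptide_conformer(-60, -40, n_residues = 10, motif = "alpha")
  m <- build_polyalanine_model(conf)
  expect_error(vci_sd(m, config_cap = 100), "cap")
})

test_that("dipole matrices are symmetric and energies ascend", {
  m <- build_dipeptide_model(alpha_conf(), seed = 2)
  st <- vci_sd(m)
  expect_equal(st$dipoles$x, t(st$dipoles$x), tolerance = 1e-10)
  expect_equal(st$dipoles$z, t(st$dipoles$z), tolerance = 1e-10)
  expect_true(!is.unsorted(st$energies))
  expect_equal(st$energies[1], 0)
})

test_that("anharmonicity report: harmonic zero, Morse diagonal, coupled-harmonic closure", {
  # harmonic separable: all anharmonicities vanish
  mh <- make_model(diag(c(1250, 1320)), diag(1, 2, 3), shifts = 0)
  rh <- anharmonicity_report(vci_sd(mh))
  expect_equal(rh$diagonal$delta, c(0, 0), tolerance = 1e-6)
  expect_equal(rh$offdiagonal$delta, 0, tolerance = 1e-6)
  # single Morse mode: diagonal anharmonicity = 2 * omega_e x_e = shift
  ms <- make_model(diag(1300, 1, 1), matrix(c(1, 0, 0), 1), shifts = 10)
  rs <- anharmonicity_report(vci_sd(ms))
  expect_equal(rs$diagonal$delta, 10, tolerance = 1e-3)
  # coupled harmonic pair: off-diagonal anharmonicity zero within truncation
  mc <- make_model(matrix(c(1250, 6, 6, 1320), 2), diag(1, 2, 3), shifts = 0)
  rc <- anharmonicity_report(vci_sd(mc))
  expect_lt(abs(rc$offdiagonal$delta), 0.05)
})

test_that("state labels flag strong mixing", {
  # three degenerate modes coupled symmetrically: the in-phase fundamental
  # spreads 1/3 over each configuration, below the 50% dominance threshold
  J <- matrix(10, 3, 3); diag(J) <- 1300
  m <- make_model(J, diag(1, 3, 3), shifts = 0)
  st <- vci_sd(m)
  fund_labels <- st$labels[st$quanta == 1]
  expect_true(any(grepl("mixed", fund_labels)))
})
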