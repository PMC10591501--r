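test_that("select_window filters by frequency with order preserved and errors when empty", {
  nm <- random_mode_set(6, freqs = c(900, 1250, 1320, 1650, 1700, 1800))
  sub <- select_window(nm, 1200, 1400)
  expect_equal(sub$frequencies, c(1250, 1320))
  all <- select_window(nm, 0, 1e9)
  expect_equal(all$frequencies, nm$frequencies)
  expect_error(select_window(nm, 2000, 2100), class = "amideIR_empty_window")
  expect_error(select_window(nm, 1400, 1200), "lo < hi")
})

test_that("the synthetic dipeptide embedding plants exactly 4 modes in the window", {
  m <- build_dipeptide_model(alpha_conf(), seed = 4)
  nm <- as_normal_modes(m)
  sub <- select_window(nm, 1200, 1400)
  expect_equal(length(sub$frequencies), 4L)
})

test_that("two-mode symmetric/antisymmetric combinations localize to single-atom motions", {
  # modes built as (e1 +/- e2)/sqrt(2) on two disjoint atoms
  d1 <- matrix(0, 2, 3); d1[1, 1] <- 1 / sqrt(2); d1[2, 1] <- 1 / sqrt(2)
  d2 <- matrix(0, 2, 3); d2[1, 1] <- 1 / sqrt(2); d2[2, 1] <- -1 / sqrt(2)
  atoms <- data.frame(element = "C", mass = 12.011, x = 0, y = 0, z = c(0, 4))
  nm <- normal_mode_set(c(1250, 1300), list(d1, d2), atoms,
                        mode_dipoles = diag(1, 2, 3))
  basis <- localize(nm)
  D <- basis$localized_displacements
  # each localized mode lives on a single atom (criterion value 2 = maximal)
  xi <- xi_of(D)
  expect_equal(xi, 2, tolerance = 1e-10)
  for (d in D) {
    per_atom <- rowSums(d^2)
    expect_equal(sort(per_atom), c(0, 1), tolerance = 1e-10)
  }
  # U is a 45-degree rotation up to sign/order
  expect_equal(abs(basis$transformation), matrix(1 / sqrt(2), 2, 2),
               tolerance = 1e-10)
})

test_that("already-localized input is a fixed point", {
  d1 <- matrix(0, 2, 3); d1[1, 1] <- 1
  d2 <- matrix(0, 2, 3); d2[2, 2] <- 1
  atoms <- data.frame(element = "C", mass = 12.011, x = 0, y = 0, z = c(0, 4))
  nm <- normal_mode_set(c(1250, 1300), list(d1, d2), atoms,
                        mode_dipoles = diag(1, 2, 3))
  basis <- localize(nm)
  expect_equal(abs(basis$transformation), diag(2), tolerance = 1e-10)
  expect_equal(basis$xi_history[length(basis$xi_history)],
               basis$xi_history[1], tolerance = 1e-10)
})

test_that("Jacobi angle matches a brute-force rotation scan on 2-mode cases", {
  for (seed in 1:4) {
    nm <- random_mode_set(2, seed = seed)
    basis <- localize(nm)
    xi_opt <- basis$xi_history[length(basis$xi_history)]
    D0 <- vapply(nm$displacements, identity,
                 matrix(0, nrow(nm$atoms), 3))
    xi_scan <- scan_pair_rotation(nm$displacements[[1]],
                                  nm$displacements[[2]])
    expect_equal(xi_opt, xi_scan, tolerance = 1e-6)
  }
})

test_that("localization preserves orthogonality, spectrum, trace and dipole norm on 4-31 mode fixtures", {
  for (n in c(4, 9, 31)) {
    nm <- random_mode_set(n, seed = n)
    basis <- localize(nm)
    U <- basis$transformation
    expect_equal(crossprod(U), diag(n), tolerance = 1e-10)
    J <- unclass(basis$coupling)
    expect_equal(J, t(J), tolerance = 1e-10)
    expect_equal(sort(eigen(J, only.values = TRUE)$values),
                 sort(nm$frequencies), tolerance = 1e-8)
    expect_equal(sum(diag(J)), sum(nm$frequencies), tolerance = 1e-8)
    # total squared dipole conserved under the orthogonal transform
    expect_equal(sum(basis$localized_dipoles^2), sum(nm$mode_dipoles^2),
                 tolerance = 1e-10)
    # criterion is non-decreasing across sweeps
    expect_true(all(diff(basis$xi_history) >= -1e-9))
  }
})

test_that("localization rejects non-orthonormal displacement sets", {
  nm <- random_mode_set(3, seed = 1)
  nm$displacements[[2]] <- nm$displacements[[1]]
  expect_error(localize(nm), "orthonormal")
})

test_that("relocalizing the exciton eigenvectors recovers the planted local modes", {
  # weak couplings relative to frequency gaps
  p0 <- zero_sd(default_motif_params())
  m <- build_dipeptide_model(alpha_conf(), p0)
  basis <- localize(select_window(as_normal_modes(m)))
  expect_equal(unclass(basis$coupling), unclass(m$coupling),
               tolerance = 1e-6, ignore_attr = TRUE)
  # localized dipoles recover the planted mode dipoles up to sign
  expect_equal(abs(basis$localized_dipoles), abs(m$dipoles),
               tolerance = 1e-6)
})

test_that("coupling_matrix trivials: identity transform, validation", {
  expect_error(coupling_matrix(matrix(c(1200, 5, 6, 1300), 2)), "symmetric")
  expect_error(coupling_matrix(matrix(c(-5, 1, 1, 1300), 2)), "positive")
  J <- coupling_matrix(matrix(c(1250, 4, 4, 1330), 2), labels = c("a", "b"))
  expect_equal(diag(unclass(J)), c(a = 1250, b = 1330))
})

test_that("motif statistics: entrywise mean/SD with canonical labels", {
  J1 <- coupling_matrix(matrix(c(1250, 4, 4, 1330), 2), labels = c("a", "b"))
  expect_error(motif_statistics(list(J1)), "at least 2")
  stats <- motif_statistics(list(J1, J1, J1))
  expect_equal(unclass(stats$mean), unclass(J1), ignore_attr = TRUE)
  expect_equal(max(abs(stats$sd)), 0)
  # two matrices differing by 2 cm^-1 in one entry: SD = sqrt(2) there
  J2m <- unclass(J1); J2m[1, 2] <- J2m[2, 1] <- J2m[1, 2] + 2
  stats2 <- motif_statistics(list(J1, coupling_matrix(J2m, labels = c("a", "b"))))
  expect_equal(stats2$sd[1, 2], sqrt(2), tolerance = 1e-12)
  expect_equal(stats2$sd[1, 1], 0)
  # zero-SD alpha grid: couplings are seed-independent, so their SD over
  # conformers vanishes (diagonal frequencies keep the deterministic
  # (phi, psi) dependence encoded in the table slopes)
  p0 <- zero_sd(default_motif_params())
  g <- alpha_grid()
  mats <- lapply(seq_len(5), function(i)
    build_dipeptide_model(g[i, ], p0, seed = i)$coupling)
  gs <- motif_statistics(mats)
  offd <- gs$sd; diag(offd) <- 0
  expect_true(all(offd < 1e-10))
  expect_true(any(diag(gs$sd) > 0))
  expect_error(motif_statistics(list(J1, coupling_matrix(
    matrix(c(1250, 4, 4, 1330), 2), labels = c("x", "y")))),
    "labeling")
})

test_that("Molden files round-trip through the reader with mass-weighting", {
  molden <- c(
    "[Molden Format]",
    "[FREQ]", "1250.0", "1320.5",
    "[FR-COORD]",
    " C  0.0 0.0 0.0",
    " O  0.0 0.0 2.28",
    "[FR-NORM-COORD]",
    "vibration 1",
    " 0.1 0.0 0.0", " 0.0 0.0 0.0",
    "vibration 2",
    " 0.0 0.0 0.0", " 0.0 0.1 0.0")
  fm <- withr::local_tempfile(fileext = ".molden")
  writeLines(molden, fm)
  fd <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mode,mux,muy,muz", "1,1,0,0", "2,0,0.5,0"), fd)
  nm <- read_molden(fm, fd)
  expect_equal(nm$frequencies, c(1250, 1320.5))
  expect_equal(nm$atoms$element, c("C", "O"))
  expect_equal(nm$atoms$mass, c(12.011, 15.999))
  # Bohr -> Angstrom conversion on coordinates
  expect_equal(nm$atoms$z[2], 2.28 * 0.529177210903, tolerance = 1e-10)
  # mass-weighted displacements are unit-normalized on the moving atom
  expect_equal(sum(nm$displacements[[1]]^2), 1, tolerance = 1e-12)
  expect_equal(nm$displacements[[1]][1, 1], 1)
  expect_equal(nm$mode_dipoles[2, ], c(0, 0.5, 0), ignore_attr = TRUE)
  expect_error(read_molden(fd), "FREQ")
})

test_that("coupling CSV round-trips with provenance headers", {
  J <- coupling_matrix(matrix(c(1250.123, 4.5, 4.5, 1330.7), 2),
                       labels = c("amideIII(1)", "CaH1(1)"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_coupling_csv(J, f, header = "config: abc123")
  expect_match(readLines(f)[1], "^# config")
  J2 <- read_coupling_csv(f)
  expect_equal(unclass(J2), unclass(J), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(attr(J2, "labels"), attr(J, "labels"))
})
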