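test_that("dephasing conversion gives the documented HWHM", {
  expect_equal(dephasing_hwhm(1), 5.308837459, tolerance = 1e-9)
  g <- lineshape_config(T2 = 2)$gamma
  expect_equal(g, 5.308837459 / 2, tolerance = 1e-8)
  expect_error(lineshape_config(t2 = 0.5), "t2 = 0")
})

test_that("orientational factors: parallel limit, isotropic identity, normalization warning", {
  z <- c(0, 0, 1)
  expect_equal(orientational_factor("ZZZZ", z, z, z, z), 1 / 5)
  expect_equal(orientational_factor("ZZXX", z, z, z, z), 1 / 15)
  expect_equal(orientational_factor("ZZZZ", z, z, z, z) /
               orientational_factor("ZZXX", z, z, z, z), 3)
  set.seed(11)
  for (i in 1:20) {
    ds <- lapply(1:4, function(j) { v <- rnorm(3); v / sqrt(sum(v^2)) })
    lhs <- do.call(orientational_factor, c(list("ZZZZ"), ds))
    rhs <- do.call(orientational_factor, c(list("ZZXX"), ds)) +
           do.call(orientational_factor, c(list("ZXXZ"), ds)) +
           do.call(orientational_factor, c(list("ZXZX"), ds))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_warning(orientational_factor("ZZZZ", 2 * z, z, z, z), "normalized")
})

test_that("orientational factors match the Monte-Carlo rotational-averaging oracle", {
  set.seed(5)
  ds <- lapply(1:4, function(j) { v <- rnorm(3); v / sqrt(sum(v^2)) })
  for (pol in c("ZZZZ", "ZZXX", "ZXXZ")) {
    mc <- mc_orientational(pol, ds[[1]], ds[[2]], ds[[3]], ds[[4]],
                           n = 2e4, seed = 7)
    an <- do.call(orientational_factor, c(list(pol), ds))
    expect_equal(mc, an, tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("1D spectrum: intensity prefactor, dark modes, unit-area broadening", {
  # two modes with equal |mu|^2: intensity ratio equals the frequency ratio
  m <- make_model(diag(c(1250, 1320)), rbind(c(1, 0, 0), c(0, 1, 0)),
                  shifts = 0)
  sp <- ir_1d(vci_sd(m), axis = seq(1000, 1600, 0.25))
  expect_equal(nrow(sp$sticks), 2L)
  expect_equal(sp$sticks$intensity[2] / sp$sticks$intensity[1],
               1320 / 1250, tolerance = 1e-6)
  # broadened integral equals summed stick intensity (unit-area Lorentzian)
  integral <- sum(sp$absorbance) * 0.25
  expect_equal(integral, sum(sp$sticks$intensity), tolerance = 0.02)
  # dark mode: |mu| = 0 contributes no stick
  md <- make_model(diag(c(1250, 1320)), rbind(c(0, 0, 0), c(0, 1, 0)),
                   shifts = 0)
  spd <- ir_1d(vci_sd(md))
  expect_equal(nrow(spd$sticks), 1L)
})

test_that("harmonic separable systems cancel to below 1e-10 of the pathway amplitude", {
  m <- make_model(diag(c(1250, 1320)), rbind(c(1, 0, 0), c(0.3, 0.9, 0)),
                  shifts = 0)
  st <- vci_sd(m)
  ax <- seq(1200, 1370, 0.5)
  s_all <- spectrum_2dir(st, pump = ax, probe = ax)
  s_esa <- spectrum_2dir(st, pump = ax, probe = ax, pathways = "esa")
  expect_gt(max(abs(s_esa$amplitude)), 0)
  expect_lt(max(abs(s_all$amplitude)) / max(abs(s_esa$amplitude)), 1e-10)
})

test_that("a single anharmonic mode shows the negative/positive doublet split by its anharmonicity", {
  m <- make_model(diag(1300, 1, 1), matrix(c(1, 0, 0), 1), shifts = 10)
  st <- vci_sd(m)
  ax <- seq(1240, 1340, 0.25)
  s <- spectrum_2dir(st, pump = ax, probe = ax)
  neg <- which(s$amplitude == min(s$amplitude), arr.ind = TRUE)[1, ]
  pos <- which(s$amplitude == max(s$amplitude), arr.ind = TRUE)[1, ]
  nu01 <- 1290
  expect_equal(s$pump_axis[neg["col"]], nu01, tolerance = 1)
  expect_equal(s$probe_axis[neg["row"]], nu01, tolerance = 1)
  expect_equal(s$pump_axis[pos["col"]], nu01, tolerance = 1)
  # ESA probe position red-shifted by the diagonal anharmonicity (10 cm^-1)
  expect_equal(s$probe_axis[neg["row"]] - s$probe_axis[pos["row"]], 10,
               tolerance = 1)
  expect_lt(min(s$amplitude), 0)
  expect_gt(max(s$amplitude), 0)
})

test_that("total 2D signal scales linearly with small diagonal anharmonicity", {
  peak_max <- vapply(c(1, 2, 4), function(sh) {
    m <- make_model(diag(1300, 1, 1), matrix(c(1, 0, 0), 1), shifts = sh)
    s <- spectrum_2dir(vci_sd(m), pump = seq(1260, 1330, 0.5),
                       probe = seq(1260, 1330, 0.5))
    max(abs(s$amplitude))
  }, numeric(1))
  expect_equal(peak_max[2] / peak_max[1], 2, tolerance = 0.08)
  expect_equal(peak_max[3] / peak_max[2], 2, tolerance = 0.12)
})

test_that("cross-peak amplitude grows monotonically from zero with the coupling", {
  ax <- seq(1220, 1350, 0.5)
  cross_amp <- vapply(c(0, 2, 4, 8), function(J12) {
    J <- matrix(c(1260, J12, J12, 1320), 2)
    m <- make_model(J, rbind(c(1, 0, 0), c(0, 1, 0)), shifts = c(8, 8))
    s <- spectrum_2dir(vci_sd(m), pump = ax, probe = ax)
    rep <- cross_peak_report(s, list(lo = c(1230, 1290), hi = c(1291, 1350)))
    band_value(rep, "lo", "hi", "cross")
  }, numeric(1))
  expect_lt(cross_amp[1], 1e-10)
  expect_true(all(diff(cross_amp) > 0))
})

test_that("polarization identity holds pixelwise on whole spectra", {
  m <- build_dipeptide_model(beta_conf(), seed = 6)
  st <- vci_sd(m)
  ax <- seq(1180, 1400, 1)
  sp <- lapply(c("ZZZZ", "ZZXX", "ZXXZ", "ZXZX"), function(p)
    spectrum_2dir(st, pol = p, pump = ax, probe = ax)$amplitude)
  expect_equal(sp[[1]], sp[[2]] + sp[[3]] + sp[[4]], tolerance = 1e-10)
})

test_that("amplitudes scale as the fourth power of a uniform dipole scaling", {
  m <- build_dipeptide_model(alpha_conf(), seed = 9)
  m2 <- m
  m2$dipoles <- 2 * m$dipoles
  ax <- seq(1180, 1400, 1)
  s1 <- spectrum_2dir(vci_sd(m), pump = ax, probe = ax)
  s2 <- spectrum_2dir(vci_sd(m2), pump = ax, probe = ax)
  expect_equal(s2$amplitude, 16 * s1$amplitude, tolerance = 1e-8)
})

test_that("GSB-only pump marginal aligns with the 1D stick positions", {
  m <- build_dipeptide_model(beta_conf(), seed = 2)
  st <- vci_sd(m)
  ax <- seq(1150, 1450, 0.5)
  gsb <- spectrum_2dir(st, pump = ax, probe = ax, pathways = "gsb")
  marginal <- colSums(-gsb$amplitude)
  sticks <- ir_1d(st, axis = ax, prefactor = FALSE)$sticks
  # every strong 1D stick coincides with a local maximum of the marginal
  for (w in sticks$wavenumber[sticks$intensity > 0.1 * max(sticks$intensity)]) {
    i <- which.min(abs(ax - w))
    window <- marginal[max(1, i - 6):min(length(ax), i + 6)]
    expect_gt(marginal[i], 0.85 * max(window))
  }
})

test_that("symmetric band pairs give matching cross extrema", {
  J <- matrix(c(1260, 7, 7, 1320), 2)
  m <- make_model(J, rbind(c(1, 0, 0), c(0.5, 0.85, 0)), shifts = c(8, 8))
  ax <- seq(1220, 1360, 0.25)
  s <- spectrum_2dir(vci_sd(m), pump = ax, probe = ax)
  rep <- cross_peak_report(s, list(lo = c(1230, 1290), hi = c(1291, 1355)))
  up <- band_value(rep, "lo", "hi", "cross")
  dn <- band_value(rep, "hi", "lo", "cross")
  expect_equal(up, dn, tolerance = 0.05)
})

test_that("cross peaks of uncoupled modes stay below 1e-6 of the diagonal", {
  m <- make_model(diag(c(1260, 1320)), rbind(c(1, 0, 0), c(0, 1, 0)),
                  shifts = c(8, 8))
  ax <- seq(1220, 1350, 0.5)
  s <- spectrum_2dir(vci_sd(m), pump = ax, probe = ax)
  rep <- cross_peak_report(s, list(lo = c(1230, 1290), hi = c(1291, 1350)))
  diag_max <- max(band_value(rep, "lo", "lo", "diagonal"),
                  band_value(rep, "hi", "hi", "diagonal"))
  cross_max <- max(band_value(rep, "lo", "hi", "cross"),
                   band_value(rep, "hi", "lo", "cross"))
  expect_lt(cross_max, 1e-6 * diag_max)
})

test_that("missing two-quantum manifold skips ESA with a warning", {
  m <- make_model(diag(c(1260, 1320)), rbind(c(1, 0, 0), c(0, 1, 0)),
                  shifts = 0)
  st <- vci_sd(m, max_level = 1)
  expect_warning(s <- spectrum_2dir(st, pump = seq(1220, 1350, 1),
                                    probe = seq(1220, 1350, 1)),
                 "ESA")
  expect_true(all(s$amplitude <= 0))
})

test_that("band validation and out-of-axis warnings", {
  m <- make_model(diag(1300, 1, 1), matrix(c(1, 0, 0), 1), shifts = 10)
  s <- spectrum_2dir(vci_sd(m), pump = seq(1260, 1340, 1),
                     probe = seq(1260, 1340, 1))
  expect_error(cross_peak_report(s, list(a = c(1300, 1200))), "lo < hi")
  expect_error(cross_peak_report(s, list(a = c(1200, 1300),
                                         b = c(1250, 1350))),
               "non-overlapping")
  w <- testthat::capture_warnings(
    cross_peak_report(s, list(a = c(1260, 1340), b = c(2000, 2100))))
  expect_true(length(w) >= 1 && all(grepl("outside", w)))
})

test_that("spectra serialize to TSV and gnuplot/JSON containers", {
  m <- make_model(diag(1300, 1, 1), matrix(c(1, 0, 0), 1), shifts = 10)
  st <- vci_sd(m)
  sp1 <- ir_1d(st, axis = seq(1260, 1340, 1))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum1d(sp1, f1, header = "config: x")
  tab <- utils::read.delim(f1, comment.char = "#")
  expect_equal(nrow(tab), length(sp1$axis))
  expect_equal(tab$absorbance, sp1$absorbance, tolerance = 1e-8)

  s2 <- spectrum_2dir(st, pump = seq(1280, 1310, 1), probe = seq(1280, 1310, 1))
  f2 <- withr::local_tempfile(fileext = ".dat")
  fj <- withr::local_tempfile(fileext = ".json")
  write_spectrum2d(s2, f2, json = fj)
  lines <- readLines(f2)
  first <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  expect_equal(as.numeric(first[1:2]), c(1280, 1280))
  obj <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(obj$polarization, "ZZZZ")
  expect_equal(matrix(unlist(obj$amplitude), nrow = length(obj$probe_axis),
                      byrow = TRUE)[1, 1],
               s2$amplitude[1, 1], tolerance = 1e-10)
})
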