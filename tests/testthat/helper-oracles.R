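# Independent oracles and small fixtures used across the suite.

# assemble a local_mode_model directly from matrices (bypassing the
# synthetic builders), with Morse (or harmonic) one-mode potentials
make_model <- function(J, dipoles, shifts = 0, grid_points = 101,
                       labels = NULL) {
  n <- nrow(J)
  shifts <- rep_len(shifts, n)
  if (is.null(labels)) labels <- paste0("m", seq_len(n))
  structure(
    list(coupling = coupling_matrix(J, labels = labels),
         dipoles = as.matrix(dipoles),
         potentials = lapply(seq_len(n), function(i)
           morse_potential(J[i, i], shifts[i], grid_points = grid_points)),
         modes = data.frame(chain = 1L, class = "test", cls_id = 1L,
                            position = seq_len(n), sub = 0L, label = labels,
                            stringsAsFactors = FALSE),
         conformer = NULL, seed = NA_integer_, chains = 1L),
    class = "local_mode_model"
  )
}

# brute-force oracle: exact eigenvalues of a two-mode Hamiltonian
# H = h1 x 1 + 1 x h2 + k q1 q2 on the full product DVR grid (no
# configuration truncation).  k is the bilinear constant in energy
# convention (k = 2 J12 for a frequency-convention coupling J12).
two_mode_product_oracle <- function(pot1, pot2, k, n_eigen = 12) {
  h_mat <- function(pot) {
    n <- length(pot$grid)
    dx <- (pot$grid[n] - pot$grid[1]) / (n - 1)
    dij <- outer(seq_len(n), seq_len(n), "-")
    Tm <- (-1)^dij * 2 / ifelse(dij == 0, Inf, dij^2)
    diag(Tm) <- pi^2 / 3
    Tm * pot$kinetic_scale / (2 * dx^2) + diag(pot$energies)
  }
  h1 <- h_mat(pot1); h2 <- h_mat(pot2)
  n1 <- length(pot1$grid); n2 <- length(pot2$grid)
  H <- kronecker(h1, diag(n2)) + kronecker(diag(n1), h2) +
    k * kronecker(diag(pot1$grid), diag(pot2$grid))
  sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)[seq_len(n_eigen)]
}

# brute-force localization oracle: scan the rotation angle of a 2-mode set
# and return the maximal criterion value
xi_of <- function(displacements) {
  sum(vapply(displacements, function(d) sum(rowSums(d^2)^2), numeric(1)))
}
scan_pair_rotation <- function(d1, d2, n_angles = 20001) {
  angles <- seq(-pi / 4, pi / 4, length.out = n_angles)
  best <- -Inf
  for (a in angles) {
    r1 <- cos(a) * d1 + sin(a) * d2
    r2 <- -sin(a) * d1 + cos(a) * d2
    best <- max(best, xi_of(list(r1, r2)))
  }
  best
}

# random orthonormal mode set on one atom per mode (x displacements mixed
# by a random orthogonal matrix)
random_mode_set <- function(n, freqs = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(freqs)) freqs <- sort(1200 + 200 * runif(n))
  V <- qr.Q(qr(matrix(rnorm(n * n), n)))
  disp <- lapply(seq_len(n), function(k) {
    d <- matrix(0, n, 3)
    d[, 1] <- V[, k]
    d
  })
  atoms <- data.frame(element = "C", mass = 12.011, x = 0, y = 0,
                      z = 3.8 * seq_len(n), stringsAsFactors = FALSE)
  dip <- matrix(rnorm(3 * n), n, 3)
  normal_mode_set(freqs, disp, atoms, mode_dipoles = dip)
}

# Monte-Carlo rotational-averaging oracle: sample uniform rotations
# (random unit quaternions) and average products of lab-frame dipole
# components; fully vectorized so 10^6 rotations stay cheap
mc_orientational <- function(pol, d1, d2, d3, d4, n = 1e5, seed = 1) {
  set.seed(seed)
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; qv <- q[, 2:4]
  rot_apply <- function(v) {
    # v' = v + 2 w (qv x v) + 2 qv x (qv x v), vectorized over rotations
    cx <- cbind(qv[, 2] * v[3] - qv[, 3] * v[2],
                qv[, 3] * v[1] - qv[, 1] * v[3],
                qv[, 1] * v[2] - qv[, 2] * v[1])
    cx2 <- cbind(qv[, 2] * cx[, 3] - qv[, 3] * cx[, 2],
                 qv[, 3] * cx[, 1] - qv[, 1] * cx[, 3],
                 qv[, 1] * cx[, 2] - qv[, 2] * cx[, 1])
    cbind(v[1] + 2 * (w * cx[, 1] + cx2[, 1]),
          v[2] + 2 * (w * cx[, 2] + cx2[, 2]),
          v[3] + 2 * (w * cx[, 3] + cx2[, 3]))
  }
  r1 <- rot_apply(d1); r2 <- rot_apply(d2)
  r3 <- rot_apply(d3); r4 <- rot_apply(d4)
  comp <- switch(pol,
    ZZZZ = r1[, 3] * r2[, 3] * r3[, 3] * r4[, 3],
    ZZXX = r1[, 3] * r2[, 3] * r3[, 1] * r4[, 1],
    ZXXZ = r1[, 3] * r2[, 1] * r3[, 1] * r4[, 3],
    ZXZX = r1[, 3] * r2[, 1] * r3[, 3] * r4[, 1])
  mean(comp)
}

# canonical test conformers
alpha_conf <- function(psi = -20) peptide_conformer(-80, psi, motif = "alpha")
beta_conf <- function(psi = 140) peptide_conformer(-120, psi, motif = "beta")

# band definitions matching the default synthetic tables: amide III states
# lie below ~1255, C-alpha-H bends above ~1265
test_bands <- function() list(amideIII = c(1185, 1260), CaH = c(1261, 1400))

band_value <- function(report, pump, probe, kind) {
  i <- report$pump_band == pump & report$probe_band == probe &
    report$kind == kind
  abs(report$amplitude[i])
}
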