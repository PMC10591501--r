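# Normal-mode localization by Jacobi 2x2 rotations.
#
# The criterion is the atomic-contribution localization measure
#   xi(U) = sum_modes sum_atoms ( sum_{xyz on atom} c^2 )^2 ,
# the mass-weighted analogue of the Pipek-Mezey orbital criterion: it is
# maximal when every mode concentrates its displacement on few atoms.  Each
# mode pair is rotated by the analytically optimal angle; full sweeps repeat
# until the criterion gain per sweep falls below a relative tolerance.

.localization_xi <- function(D, atom_id) {
  sum(rowsum(D^2, atom_id)^2)
}

#' Localize a set of normal modes
#'
#' Finds the orthogonal transformation \code{U} of the input modes that
#' maximizes the atomic-contribution localization criterion
#' \eqn{\xi(U) = \sum_k \sum_A (\sum_{\alpha \in A} c_{k\alpha}^2)^2}
#' by Jacobi sweeps over all mode pairs in lexicographic order, each pair
#' rotated by its closed-form optimal angle.  \eqn{\xi} is non-decreasing
#' across rotations; iteration stops when the relative criterion gain of a
#' full sweep drops below \code{tol} or after \code{max_sweeps} sweeps.
#' Localized modes are sign-fixed (largest-magnitude displacement component
#' positive) and put in a canonical order (by the index of their dominant
#' atom, ties by local frequency) so that coupling matrices of different
#' conformers can be averaged entry by entry.
#'
#' @param modes a [normal_mode_set()] (>= 1 mode) with orthonormal
#'   mass-weighted displacements; typically the output of [select_window()].
#' @param max_sweeps maximum number of full Jacobi sweeps (default 100).
#' @param tol relative criterion-gain tolerance per sweep (default 1e-10).
#' @return an object of class \code{local_mode_basis}: \code{transformation}
#'   (orthogonal \code{U}; column \code{k} holds the expansion of localized
#'   mode \code{k} in the input modes), \code{localized_displacements},
#'   \code{localized_dipoles}, \code{coupling} (the [coupling_matrix()]
#'   \eqn{U^T \mathrm{diag}(\nu) U}), \code{subset_frequencies},
#'   \code{xi_history}, \code{sweeps}, \code{labels}.
#' @examples
#' conf <- peptide_conformer(-80, -20, motif = "alpha")
#' nm <- as_normal_modes(build_dipeptide_model(conf, zero_sd(default_motif_params())))
#' basis <- localize(select_window(nm))
#' basis$coupling
#' @export
localize <- function(modes, max_sweeps = 100, tol = 1e-10) {
  stopifnot(inherits(modes, "normal_mode_set"))
  n <- length(modes$frequencies)
  n_atoms <- nrow(modes$atoms)
  atom_id <- rep(seq_len(n_atoms), each = 3L)
  # 3N x n matrix of mass-weighted displacement coefficients
  D <- vapply(modes$displacements, function(d) as.numeric(t(d)),
              numeric(3L * n_atoms))
  D <- matrix(D, nrow = 3L * n_atoms, ncol = n)
  G <- crossprod(D)
  if (max(abs(G - diag(n))) > 1e-8)
    stop("input displacements are not orthonormal (within 1e-8); ",
         "localization requires a normal-mode basis")

  U <- diag(n)
  xi <- .localization_xi(D, atom_id)
  xi_hist <- xi
  sweeps <- 0L
  if (n >= 2) {
    repeat {
      sweeps <- sweeps + 1L
      xi_before <- xi
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ci <- D[, i]; cj <- D[, j]
        Qii <- rowsum(ci * ci, atom_id)
        Qjj <- rowsum(cj * cj, atom_id)
        Qij <- rowsum(ci * cj, atom_id)
        A <- sum(Qij^2 - 0.25 * (Qii - Qjj)^2)
        B <- sum(Qij * (Qii - Qjj))
        r <- sqrt(A^2 + B^2)
        gain <- A + r
        if (!is.finite(r) || r < 1e-14 || gain <= 1e-14 * max(1, xi))
          next  # zero gradient and curvature: skip degenerate pair
        ang <- 0.25 * atan2(B, -A)
        cs <- cos(ang); sn <- sin(ang)
        D[, i] <- cs * ci + sn * cj
        D[, j] <- -sn * ci + cs * cj
        ui <- U[, i]; uj <- U[, j]
        U[, i] <- cs * ui + sn * uj
        U[, j] <- -sn * ui + cs * uj
        xi <- xi + gain
      }
      xi <- .localization_xi(D, atom_id)  # re-evaluate to avoid drift
      xi_hist <- c(xi_hist, xi)
      if (sweeps >= max_sweeps) break
      if (xi - xi_before < tol * max(1, abs(xi_before))) break
    }
  }

  # sign convention: largest-magnitude displacement component positive
  for (k in seq_len(n)) {
    m <- which.max(abs(D[, k]))
    if (D[m, k] < 0) { D[, k] <- -D[, k]; U[, k] <- -U[, k] }
  }
  # canonical ordering: dominant atom index, ties broken by local frequency
  part <- rowsum(D^2, atom_id)                  # n_atoms x n participation
  dom <- apply(part, 2, which.max)
  local_freq <- colSums(U * (modes$frequencies * U))  # diag of U' diag(f) U
  ord <- order(dom, local_freq)
  D <- D[, ord, drop = FALSE]
  U <- U[, ord, drop = FALSE]

  labels <- paste0("loc", seq_len(n))
  loc_disp <- lapply(seq_len(n), function(k)
    matrix(D[, k], ncol = 3, byrow = TRUE))
  loc_dip <- if (!is.null(modes$mode_dipoles))
    t(U) %*% modes$mode_dipoles else NULL

  basis <- structure(
    list(transformation = U,
         localized_displacements = loc_disp,
         localized_dipoles = loc_dip,
         subset_frequencies = modes$frequencies,
         atoms = modes$atoms,
         xi_history = xi_hist, sweeps = sweeps,
         labels = labels),
    class = "local_mode_basis"
  )
  basis$coupling <- coupling_matrix(basis)
  basis
}

#' @export
print.local_mode_basis <- function(x, ...) {
  cat(sprintf(
    "local-mode basis: %d modes, %d Jacobi sweep(s), xi %.4f -> %.4f\n",
    nrow(x$transformation), x$sweeps,
    x$xi_history[1], x$xi_history[length(x$xi_history)]))
  invisible(x)
}

#' Build a local-mode model from a localized basis
#'
#' Packages a [localize()] result (coupling matrix plus localized transition
#' dipoles) together with Morse one-mode potentials into a
#' \code{local_mode_model}, ready for [vscf()]/[vci_sd()].  Molden inputs
#' carry no anharmonic one-mode scan, so the one-mode potentials are Morse
#' wells with a per-mode fundamental red shift.
#'
#' @param basis a \code{local_mode_basis} with localized dipoles.
#' @param anharmonic_shift fundamental red shift(s) in cm^-1, recycled over
#'   modes.
#' @param grid_points tabulation points per one-mode potential.
#' @return a \code{local_mode_model}.
#' @export
model_from_basis <- function(basis, anharmonic_shift = 10,
                             grid_points = 101) {
  stopifnot(inherits(basis, "local_mode_basis"))
  if (is.null(basis$localized_dipoles))
    stop("basis carries no dipoles; supply a dipole sidecar when reading")
  n <- nrow(basis$transformation)
  shift <- rep_len(anharmonic_shift, n)
  freqs <- diag(unclass(basis$coupling))
  pots <- lapply(seq_len(n), function(i)
    morse_potential(freqs[i], shift[i], grid_points = grid_points))
  modes <- data.frame(chain = 1L, class = "localized", cls_id = NA_integer_,
                      position = seq_len(n), sub = 0L,
                      label = basis$labels, stringsAsFactors = FALSE)
  structure(
    list(coupling = basis$coupling, dipoles = basis$localized_dipoles,
         potentials = pots, modes = modes, conformer = NULL,
         seed = NA_integer_, chains = 1L),
    class = "local_mode_model"
  )
}
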