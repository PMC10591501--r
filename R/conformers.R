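#' Create a peptide conformer
#'
#' A conformer is described by its backbone dihedral angles \eqn{\phi},
#' \eqn{\psi} and \eqn{\omega} (degrees, wrapped to (-180, 180]), the number
#' of residues and a secondary-structure motif label.  A capped chain of
#' \code{n_residues} residues carries \code{n_residues + 1} peptide groups
#' (both caps form amide bonds) and one alpha carbon per residue.
#'
#' @param phi,psi backbone dihedrals in degrees.
#' @param omega peptide-bond dihedral in degrees (default 180, trans).
#' @param n_residues number of residues (>= 1).
#' @param motif one of \code{"alpha"}, \code{"beta"}, \code{"other"}.
#' @return an object of class \code{peptide_conformer} (a named list).
#' @examples
#' peptide_conformer(-80, -40, motif = "alpha")
#' @export
peptide_conformer <- function(phi, psi, omega = 180, n_residues = 1L,
                              motif = c("alpha", "beta", "other")) {
  motif <- match.arg(motif)
  stopifnot(is.numeric(phi), is.numeric(psi), is.numeric(omega),
            length(phi) == 1L, length(psi) == 1L, length(omega) == 1L)
  if (!is.numeric(n_residues) || n_residues < 1 ||
      n_residues != round(n_residues))
    stop("n_residues must be a positive integer")
  structure(
    list(phi = .wrap_angle(phi), psi = .wrap_angle(psi),
         omega = .wrap_angle(omega), n_residues = as.integer(n_residues),
         motif = motif),
    class = "peptide_conformer"
  )
}

#' @export
print.peptide_conformer <- function(x, ...) {
  cat(sprintf(
    "peptide conformer: phi = %.1f, psi = %.1f, omega = %.1f deg; %d residue(s); motif %s\n",
    x$phi, x$psi, x$omega, x$n_residues, x$motif))
  invisible(x)
}

#' Generate a rectangular Ramachandran conformer grid
#'
#' Enumerates all \eqn{(\phi, \psi)} lattice points of a rectangular grid,
#' inclusive of both endpoints, in row-major order (\eqn{\phi} outer,
#' \eqn{\psi} inner), with \eqn{\omega = 180} degrees.  The canonical
#' alpha-helix grid is \eqn{\phi = -100, \ldots, -60} and
#' \eqn{\psi = -40, \ldots, 0} in steps of 10 degrees (25 conformers); the
#' beta-strand grid is \eqn{\phi = -140, \ldots, -100},
#' \eqn{\psi = +120, \ldots, +160} (25 conformers).
#'
#' @param phi_start,phi_stop,psi_start,psi_stop grid limits in degrees; each
#'   span must be a nonnegative integer multiple of \code{step}.
#' @param step grid spacing in degrees (default 10).
#' @param motif motif label applied to every conformer.
#' @param n_residues residues per conformer (default 1, the dipeptide).
#' @return a \code{data.frame} of class \code{ramachandran_grid} with columns
#'   \code{phi}, \code{psi}, \code{omega}, \code{n_residues}, \code{motif}.
#' @examples
#' g <- ramachandran_grid(-100, -60, -40, 0, step = 10, motif = "alpha")
#' nrow(g)  # 25
#' @seealso [alpha_grid()], [beta_grid()] for the two canonical grids.
#' @export
ramachandran_grid <- function(phi_start, phi_stop, psi_start, psi_stop,
                              step = 10, motif = c("alpha", "beta", "other"),
                              n_residues = 1L) {
  motif <- match.arg(motif)
  if (step <= 0) stop("step must be positive")
  for (span in c(phi_stop - phi_start, psi_stop - psi_start)) {
    if (span < 0)
      stop("grid ranges must be nondecreasing (start <= stop)")
    if (abs(span / step - round(span / step)) > 1e-9)
      stop("grid range is not commensurate with the step size")
  }
  phis <- seq(phi_start, phi_stop, by = step)
  psis <- seq(psi_start, psi_stop, by = step)
  out <- data.frame(
    phi = rep(phis, each = length(psis)),
    psi = rep(psis, times = length(phis)),
    omega = 180,
    n_residues = as.integer(n_residues),
    motif = motif,
    stringsAsFactors = FALSE
  )
  out$phi <- .wrap_angle(out$phi)
  out$psi <- .wrap_angle(out$psi)
  class(out) <- c("ramachandran_grid", "data.frame")
  out
}

#' @rdname ramachandran_grid
#' @export
alpha_grid <- function(step = 10)
  ramachandran_grid(-100, -60, -40, 0, step = step, motif = "alpha")

#' @rdname ramachandran_grid
#' @export
beta_grid <- function(step = 10)
  ramachandran_grid(-140, -100, 120, 160, step = step, motif = "beta")

# one grid row -> peptide_conformer
.grid_conformer <- function(grid, i) {
  peptide_conformer(grid$phi[i], grid$psi[i], grid$omega[i],
                    grid$n_residues[i], grid$motif[i])
}

#' Read or write conformer lists as CSV
#'
#' Plain CSV with columns \code{phi}, \code{psi}, \code{omega},
#' \code{n_residues}, \code{motif} (angles in degrees).
#'
#' @param grid a \code{ramachandran_grid} / conformer data frame.
#' @param file path to a CSV file.
#' @return \code{read_conformers} returns a \code{ramachandran_grid} data
#'   frame; \code{write_conformers} returns \code{file} invisibly.
#' @export
write_conformers <- function(grid, file) {
  utils::write.csv(as.data.frame(grid), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_conformers
#' @export
read_conformers <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("phi", "psi", "omega", "n_residues", "motif")
  if (!all(need %in% names(out)))
    stop("conformer CSV must have columns: ", paste(need, collapse = ", "))
  class(out) <- c("ramachandran_grid", "data.frame")
  out
}
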