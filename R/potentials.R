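#' Tabulated one-mode potential
#'
#' A one-mode potential is tabulated on a strictly increasing, uniformly
#' spaced grid of the dimensionless mass-weighted local coordinate \eqn{q}
#' (the harmonic ground state of a mode with frequency \eqn{\omega} has
#' \eqn{\langle q^2 \rangle = 1/2}), with energies in cm^-1 relative to the
#' minimum.  The kinetic operator associated with the coordinate is
#' \eqn{-(\omega_{ref}/2)\, d^2/dq^2} with \code{kinetic_scale}
#' \eqn{= \omega_{ref}} in cm^-1.
#'
#' @param grid strictly increasing numeric vector (>= 8 points), uniformly
#'   spaced; the minimum of \code{energies} must be interior to the grid.
#' @param energies potential values in cm^-1.
#' @param kinetic_scale reference frequency \eqn{\omega_{ref}} in cm^-1.
#' @return an object of class \code{one_mode_potential}.
#' @seealso [morse_potential()], [harmonic_potential()], [solve_one_mode()].
#' @export
one_mode_potential <- function(grid, energies, kinetic_scale) {
  stopifnot(is.numeric(grid), is.numeric(energies),
            length(grid) == length(energies))
  if (length(grid) < 8) stop("one-mode potential needs at least 8 grid points")
  d <- diff(grid)
  if (any(d <= 0)) stop("grid must be strictly increasing")
  if (max(d) - min(d) > 1e-8 * mean(d))
    stop("grid must be uniformly spaced")
  imin <- which.min(energies)
  if (imin == 1L || imin == length(energies))
    stop("potential minimum must be interior to the grid")
  if (!is.numeric(kinetic_scale) || kinetic_scale <= 0)
    stop("kinetic_scale must be a positive frequency in cm^-1")
  structure(
    list(grid = as.numeric(grid),
         energies = as.numeric(energies - min(energies)),
         kinetic_scale = as.numeric(kinetic_scale)),
    class = "one_mode_potential"
  )
}

#' @export
print.one_mode_potential <- function(x, ...) {
  cat(sprintf(
    "one-mode potential: %d points on [%.2f, %.2f], depth-top %.1f cm^-1, kinetic scale %.2f cm^-1\n",
    length(x$grid), min(x$grid), max(x$grid), max(x$energies),
    x$kinetic_scale))
  invisible(x)
}

# q range that encloses the classical turning points of the first
# `n_states` levels with a margin, for a Morse/harmonic potential
.morse_range <- function(freq, shift, n_states = 12) {
  if (shift <= 0) {
    half <- sqrt(2 * (n_states + 0.5)) * 1.6
    return(c(-half, half))
  }
  a <- sqrt(shift / freq)
  De <- freq^2 / (2 * shift)
  Etop <- min(0.9 * De, (n_states + 0.5) * freq)
  r <- sqrt(Etop / De)
  qlo <- -log(1 + r) / a
  qhi <- -log(1 - r) / a
  c(qlo - 1.5, qhi + 1.5)
}

#' Morse one-mode potential with prescribed fundamental red shift
#'
#' Tabulates a Morse potential \eqn{V(q) = D_e (1 - e^{-a q})^2} whose
#' harmonic frequency at the minimum equals \code{freq} and whose exact
#' 0-to-1 transition equals \code{freq - shift}.  With the dimensionless
#' kinetic convention (\code{kinetic_scale = freq}) the closed-form solution
#' is \eqn{a = \sqrt{shift/freq}} and \eqn{D_e = freq^2 / (2\, shift)}, which
#' gives Morse constants \eqn{\omega_e = freq} and
#' \eqn{\omega_e x_e = shift/2}, hence levels
#' \eqn{E_n = \omega_e (n + 1/2) - \omega_e x_e (n + 1/2)^2} and a diagonal
#' anharmonicity \eqn{2 E_{01} - E_{02} = shift}.  \code{shift = 0} returns
#' the harmonic tabulation.
#'
#' @param freq harmonic frequency at the minimum, cm^-1 (> 0).
#' @param shift fundamental red shift \eqn{\omega_{harm} - \omega_{0\to1}},
#'   cm^-1 (>= 0); must satisfy \code{shift < freq/2}.
#' @param grid_points number of tabulation points (default 101, >= 8).
#' @param n_states number of bound levels the grid range should support.
#' @return a [one_mode_potential()].
#' @examples
#' pot <- morse_potential(1300, 10)
#' ev <- solve_one_mode(pot, 3)
#' ev$values[2] - ev$values[1]   # 1290 cm^-1
#' @export
morse_potential <- function(freq, shift = 0, grid_points = 101,
                            n_states = 12) {
  if (freq <= 0) stop("freq must be positive")
  if (shift < 0) stop("shift must be >= 0")
  if (shift >= freq / 2)
    stop("anharmonic shift must be smaller than freq/2 ",
         "(Morse well too shallow otherwise)")
  rng <- .morse_range(freq, shift, n_states)
  # place the grid so that q = 0 (the potential minimum) is a grid point:
  # the tabulated minimum then equals the true minimum and absolute level
  # positions match the closed-form Morse energies
  dq <- (rng[2] - rng[1]) / (grid_points - 1)
  n_neg <- ceiling(-rng[1] / dq)
  q <- dq * seq.int(-n_neg, grid_points - 1L - n_neg)
  if (shift <= 0) {
    V <- 0.5 * freq * q^2
  } else {
    a <- sqrt(shift / freq)
    De <- freq^2 / (2 * shift)
    V <- De * (1 - exp(-a * q))^2
  }
  one_mode_potential(q, V, kinetic_scale = freq)
}

#' @rdname morse_potential
#' @export
harmonic_potential <- function(freq, grid_points = 101, n_states = 12)
  morse_potential(freq, 0, grid_points, n_states)

#' Closed-form Morse levels
#'
#' \eqn{E_n = \omega_e (n + 1/2) - \omega_e x_e (n + 1/2)^2} in cm^-1, for
#' the parameterization used by [morse_potential()]
#' (\eqn{\omega_e =} \code{freq}, \eqn{\omega_e x_e =} \code{shift}/2).
#'
#' @param freq,shift as in [morse_potential()].
#' @param n vector of quantum numbers (0-based).
#' @return energies in cm^-1 (absolute, from the well minimum).
#' @export
morse_levels <- function(freq, shift, n) {
  we <- freq; wexe <- shift / 2
  we * (n + 0.5) - wexe * (n + 0.5)^2
}
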