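# Synthetic local-mode Hamiltonians for capped alanine peptides.
#
# A capped chain with n residues carries n+1 peptide groups (one amide III
# local mode each) and n alpha carbons (two C-alpha-H bending local modes
# each).  Local-mode frequencies and pairwise couplings are drawn from the
# motif parameter table (independent Gaussians; the table provides only
# means and SDs) with counter-based draws keyed on structural indices, so a
# fixed seed gives bit-identical models and adding modes never perturbs
# earlier entries.

# enumerate the local modes of `chains` chains with n residues each;
# canonical order: per chain, amide III by group index, then bends by
# (residue, bend) -- i.e. descending amide III character, then sequence
.mode_table <- function(n_residues, chains = 1L) {
  one <- function(chain) {
    rbind(
      data.frame(chain = chain, class = "amide_III", cls_id = 1L,
                 position = seq_len(n_residues + 1L), sub = 0L,
                 stringsAsFactors = FALSE),
      if (n_residues >= 1L)
        data.frame(chain = chain,
                   class = rep(c("CaH_bend_1", "CaH_bend_2"), n_residues),
                   cls_id = 2L,
                   position = rep(seq_len(n_residues), each = 2L),
                   sub = rep(1:2, n_residues), stringsAsFactors = FALSE)
    )
  }
  tab <- do.call(rbind, lapply(seq_len(chains), one))
  pre <- if (chains > 1L) paste0("c", tab$chain, ":") else ""
  tab$label <- ifelse(tab$cls_id == 1L,
                      paste0(pre, "amideIII(", tab$position, ")"),
                      paste0(pre, "CaH", tab$sub, "(", tab$position, ")"))
  rownames(tab) <- NULL
  tab
}

# topological separation class between two local modes
.separation <- function(mi, mj, n_residues) {
  if (mi$chain != mj$chain) {
    # antiparallel registry: group g faces group n + 2 - g of the other chain
    if (mi$cls_id == 1L && mj$cls_id == 1L &&
        mj$position == (n_residues + 2L) - mi$position)
      return("interchain")
    return(NA_character_)  # no coupling drawn across chains otherwise
  }
  if (mi$cls_id == 1L && mj$cls_id == 1L) {
    d <- abs(mi$position - mj$position)
    return(if (d == 1L) "adjacent" else "distant")
  }
  if (mi$cls_id == 2L && mj$cls_id == 2L) {
    d <- abs(mi$position - mj$position)
    return(if (d == 0L) "same_group" else if (d == 1L) "adjacent" else "distant")
  }
  # amide III (group g) vs C-alpha-H bend (residue r): flanking groups are
  # r and r + 1
  g <- if (mi$cls_id == 1L) mi$position else mj$position
  r <- if (mi$cls_id == 1L) mj$position else mi$position
  if (g == r || g == r + 1L) return("same_group")
  if (g == r - 1L || g == r + 2L) return("adjacent")
  "distant"
}

# deterministic dipole orientation rule (placeholder contract: the
# underlying electronic-structure dipole geometry is not modeled).  Chain
# axis = z; amide III dipoles lie on a cone about the axis and rotate with a
# per-group twist derived from (phi, psi); C-alpha-H dipoles lie
# perpendicular to the axis, the two bends of one C-alpha at right angles.
.mode_dipole <- function(mode, conf, magnitude) {
  tau <- (conf$phi + conf$psi) * pi / 180
  flip <- if (mode$chain %% 2L == 0L) -1 else 1   # antiparallel partner chain
  if (mode$cls_id == 1L) {
    beta <- 35 * pi / 180
    ang <- flip * mode$position * tau
    v <- c(sin(beta) * cos(ang), sin(beta) * sin(ang), flip * cos(beta))
  } else {
    ang <- flip * mode$position * tau + (mode$sub - 1L) * pi / 2
    v <- c(cos(ang), sin(ang), 0)
  }
  magnitude * v
}

#' Build a synthetic local-mode model for a capped polyalanine chain
#'
#' Generates the local-mode Hamiltonian of a methyl-capped polyalanine chain
#' (or of two antiparallel chains): \code{n_residues + 1} amide III local
#' modes (one per peptide group, both caps included) and
#' \code{2 * n_residues} C-alpha-H bending modes (two per alpha carbon),
#' with frequencies, couplings, transition dipoles and Morse one-mode
#' potentials drawn from a motif parameter table.  Couplings are assigned by
#' topological separation (same group / adjacent / distant, plus an
#' interchain class coupling facing peptide groups of two antiparallel
#' chains).  All random draws are counter-based on (seed, structural key):
#' the same seed reproduces the model exactly, and tables with all SDs equal
#' to zero give seed-independent deterministic models.
#'
#' @param conf a [peptide_conformer()] (or one row of a
#'   [ramachandran_grid()]).
#' @param params a [motif_params()] table (default
#'   [default_motif_params()]).
#' @param seed integer seed for the counter-based draws.
#' @param chains 1 for a single chain, 2 for the antiparallel two-chain
#'   variant.
#' @param grid_points tabulation points per one-mode potential.
#' @return an object of class \code{local_mode_model} with elements
#'   \code{coupling} (a [coupling_matrix()]), \code{dipoles} (n x 3 matrix),
#'   \code{potentials} (list of [one_mode_potential()]), \code{modes} (a
#'   data frame of mode labels/classes/positions), \code{conformer},
#'   \code{seed}.
#' @examples
#' conf <- peptide_conformer(-80, -20, motif = "alpha")
#' m <- build_dipeptide_model(conf, seed = 1)
#' m$coupling
#' @export
build_polyalanine_model <- function(conf, params = default_motif_params(),
                                    seed = 1L, chains = 1L,
                                    grid_points = 101) {
  if (inherits(conf, "ramachandran_grid") || is.data.frame(conf)) {
    stopifnot(nrow(conf) == 1L)
    conf <- .grid_conformer(conf, 1L)
  }
  stopifnot(inherits(conf, "peptide_conformer"))
  if (!chains %in% c(1L, 2L)) stop("chains must be 1 or 2")
  validate_motif_params(params)
  n <- conf$n_residues
  modes <- .mode_table(n, chains)
  nm <- nrow(modes)
  motif <- conf$motif

  .with_preserved_rng({
    freqs <- numeric(nm)
    for (i in seq_len(nm)) {
      m <- modes[i, ]
      npos <- if (m$cls_id == 1L) n + 1L else n
      mu <- .freq_mean_at(params, m$class, motif, conf$phi, conf$psi,
                          position = m$position, n_positions = npos)
      sd <- .freq_sd(params, m$class, motif)
      z <- if (sd > 0)
        .counter_rnorm(seed, c(1L, m$chain, m$cls_id, m$position, m$sub))
      else 0
      freqs[i] <- mu + sd * z
    }
    J <- diag(freqs, nrow = nm)
    for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
      sep <- .separation(modes[i, ], modes[j, ], n)
      if (is.na(sep)) next
      row <- .coupling_row(params, modes$class[i], modes$class[j], sep, motif)
      if (row$mean == 0 && row$sd == 0) next
      z <- if (row$sd > 0)
        .counter_rnorm(seed, c(2L,
                               modes$chain[i], modes$cls_id[i],
                               modes$position[i], modes$sub[i],
                               modes$chain[j], modes$cls_id[j],
                               modes$position[j], modes$sub[j]))
      else 0
      J[i, j] <- J[j, i] <- row$mean + row$sd * z
    }
  })

  dip <- t(vapply(seq_len(nm), function(i) {
    mag <- .dipole_magnitude(params, modes$class[i], motif)
    .mode_dipole(modes[i, ], conf, mag)
  }, numeric(3)))

  pots <- lapply(seq_len(nm), function(i) {
    shift <- .anharmonic_shift(params, modes$class[i], motif)
    morse_potential(freqs[i], shift, grid_points = grid_points)
  })

  structure(
    list(coupling = coupling_matrix(J, labels = modes$label),
         dipoles = dip, potentials = pots, modes = modes,
         conformer = conf, seed = as.integer(seed), chains = chains),
    class = "local_mode_model"
  )
}

#' @rdname build_polyalanine_model
#' @export
build_dipeptide_model <- function(conf, params = default_motif_params(),
                                  seed = 1L, grid_points = 101) {
  if (inherits(conf, "ramachandran_grid") || is.data.frame(conf)) {
    stopifnot(nrow(conf) == 1L)
    conf <- .grid_conformer(conf, 1L)
  }
  stopifnot(inherits(conf, "peptide_conformer"))
  if (conf$n_residues != 1L)
    stop("the capped dipeptide topology requires n_residues = 1")
  build_polyalanine_model(conf, params, seed, chains = 1L,
                          grid_points = grid_points)
}

#' @export
print.local_mode_model <- function(x, ...) {
  cat(sprintf(
    "synthetic local-mode model: %d modes (%d amide III, %d CaH bends), motif %s\n",
    nrow(x$modes), sum(x$modes$cls_id == 1L), sum(x$modes$cls_id == 2L),
    x$conformer$motif))
  cat(sprintf("  phi = %.1f, psi = %.1f deg; seed %d; %d chain(s)\n",
              x$conformer$phi, x$conformer$psi, x$seed, x$chains))
  invisible(x)
}

#' Number of local modes of a model
#' @param model a \code{local_mode_model}.
#' @return integer mode count.
#' @export
n_modes <- function(model) nrow(model$modes)

#' Embed a local-mode model as a synthetic normal-mode set
#'
#' Diagonalizes the model's coupling matrix and expresses the resulting
#' normal modes in a synthetic Cartesian embedding: each local mode is a
#' unit x-displacement of its own carbon atom, atoms placed along z.  The
#' returned [normal_mode_set()] has the coupling-matrix eigenvalues as
#' frequencies and dipoles rotated accordingly -- the exact exciton picture
#' of the model, useful for exercising window selection and localization on
#' inputs whose answer is known.
#'
#' @param model a \code{local_mode_model}.
#' @param spacing atom spacing along z in Angstrom.
#' @return a [normal_mode_set()].
#' @export
as_normal_modes <- function(model, spacing = 3.8) {
  J <- unclass(model$coupling)
  es <- eigen(J, symmetric = TRUE)
  ord <- order(es$values)                 # frequencies ascending
  vals <- es$values[ord]
  V <- es$vectors[, ord, drop = FALSE]
  nm <- nrow(J)
  disp <- lapply(seq_len(nm), function(k) {
    d <- matrix(0, nm, 3)
    d[, 1] <- V[, k]
    d
  })
  dip <- t(V) %*% model$dipoles
  atoms <- data.frame(
    element = "C", mass = 12.011,
    x = 0, y = 0, z = spacing * (seq_len(nm) - 1),
    stringsAsFactors = FALSE
  )
  normal_mode_set(frequencies = vals, displacements = disp, atoms = atoms,
                  mode_dipoles = dip)
}
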