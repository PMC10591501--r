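# Localized-mode VCI with singles and doubles (VCISD).
#
# Configuration space: all product configurations with excitation level
# (= total quanta; an overtone counts as a double) up to `max_level`
# (default 2) and per-mode quanta up to `max_quanta`.  Basis functions per
# mode are the eigenfunctions of that mode's own anharmonic one-mode
# problem (solved on the DVR grid), so one-mode integrals are exact
# quadratures; two-mode terms are strictly bilinear, k_ij q_i q_j with
# k_ij = 2 J_ij from the coupling matrix.  Transition dipoles use the
# linear-dipole approximation mu(q) = sum_i mu_i q_i.

# all quanta vectors with sum <= max_level, entries <= max_quanta
.vci_configs <- function(n_modes, max_level, max_quanta) {
  cfgs <- list(integer(n_modes))
  add_level <- function(total) {
    # compositions of `total` over modes, per-mode cap
    out <- list()
    rec <- function(prefix, remaining, start) {
      if (remaining == 0) { out[[length(out) + 1L]] <<- prefix; return() }
      if (start > n_modes) return()
      for (i in start:n_modes) {
        for (q in seq_len(min(remaining, max_quanta))) {
          p <- prefix; p[i] <- q
          if (remaining - q == 0) out[[length(out) + 1L]] <<- p
          else if (i < n_modes) rec(p, remaining - q, i + 1L)
        }
      }
    }
    rec(integer(n_modes), total, 1L)
    out
  }
  for (t in seq_len(max_level)) cfgs <- c(cfgs, add_level(t))
  do.call(rbind, cfgs)
}

.config_label <- function(q, mode_labels) {
  exc <- which(q > 0)
  if (!length(exc)) return("0")
  paste(vapply(exc, function(i) sprintf("%d(%s)", q[i], mode_labels[i]), ""),
        collapse = "+")
}

#' Localized-mode VCI with singles and doubles
#'
#' Diagonalizes the localized-mode vibrational Hamiltonian (anharmonic
#' one-mode potentials plus bilinear two-mode couplings) in the space of all
#' product configurations with total quanta up to \code{max_level} (2 =
#' singles and doubles; overtones and two-mode combinations are doubles, so
#' all excited-state-absorption target states are inside the space).
#' Returns anharmonic state energies relative to the VCI ground state,
#' state labels by dominant configuration, and transition-dipole 3-vectors
#' between all state pairs in the linear-dipole approximation.
#'
#' @param model a \code{local_mode_model}.
#' @param vscf optional [vscf()] result; stored for the variational
#'   comparison (the VCI basis itself is built from the bare one-mode
#'   eigenfunctions).
#' @param n_basis one-mode eigenstates solved per mode (default 10; only
#'   states up to \code{max_quanta} enter the configuration space).
#' @param max_quanta per-mode quanta cap (default 4).
#' @param max_level total-quanta (excitation) cap; default 2 (VCISD).
#' @param config_cap refuse configuration spaces larger than this
#'   (default 20000).
#' @return an object of class \code{vci_states}: \code{energies} (cm^-1,
#'   relative to ground state, ascending), \code{quanta} (manifold of the
#'   dominant configuration), \code{labels}, \code{dipoles} (list of three
#'   state-basis matrices \code{x}, \code{y}, \code{z}; symmetric),
#'   \code{ground_energy} (absolute, cm^-1), \code{mode_labels},
#'   \code{configs}, \code{coefficients}.
#' @examples
#' conf <- peptide_conformer(-80, -20, motif = "alpha")
#' st <- vci_sd(build_dipeptide_model(conf, seed = 1))
#' head(state_table(st))
#' @export
vci_sd <- function(model, vscf = NULL, n_basis = 10, max_quanta = 4,
                   max_level = 2, config_cap = 20000) {
  stopifnot(inherits(model, "local_mode_model"))
  n <- n_modes(model)
  qcap <- min(max_quanta, max_level)
  cfg <- .vci_configs(n, max_level, qcap)
  ncfg <- nrow(cfg)
  if (ncfg > config_cap)
    stop("configuration space has ", ncfg, " configurations (cap ",
         config_cap, "); reduce max_level/max_quanta or split the system ",
         "into smaller mode windows")
  if (n_basis < qcap + 1) stop("n_basis must exceed the per-mode quanta cap")

  bare <- lapply(model$potentials, solve_one_mode, n_states = n_basis)
  # per-mode energies and q-matrices over the used quanta (0..qcap)
  eps <- vapply(bare, function(b) b$values[seq_len(qcap + 1L)],
                numeric(qcap + 1L))                  # (qcap+1) x n
  Q <- lapply(seq_len(n), function(i) {
    v <- bare[[i]]$vectors[, seq_len(qcap + 1L), drop = FALSE]
    crossprod(v, model$potentials[[i]]$grid * v)     # <m|q|n>, exact on DVR
  })
  K <- .bilinear_k(model)
  dip <- model$dipoles

  # cached per-config quantities
  Ediag <- numeric(ncfg)
  Vd <- matrix(0, ncfg, n)     # Vd[A, i] = <q_i>_{(A_i)} = Q_i[a+1, a+1]
  for (i in seq_len(n)) Vd[, i] <- diag(Q[[i]])[cfg[, i] + 1L]
  for (A in seq_len(ncfg)) Ediag[A] <- sum(eps[cbind(cfg[A, ] + 1L, seq_len(n))])
  exc <- apply(cfg, 1L, function(q) which(q > 0L), simplify = FALSE)

  H <- matrix(0, ncfg, ncfg)
  mux <- matrix(0, ncfg, ncfg)
  muy <- matrix(0, ncfg, ncfg)
  muz <- matrix(0, ncfg, ncfg)

  for (A in seq_len(ncfg)) {
    vA <- Vd[A, ]
    Kv <- as.numeric(K %*% vA)
    # diagonal
    H[A, A] <- Ediag[A] + 0.5 * sum(vA * Kv)
    mA <- as.numeric(t(dip) %*% vA)
    mux[A, A] <- mA[1]; muy[A, A] <- mA[2]; muz[A, A] <- mA[3]
    if (A == ncfg) break
    qA <- cfg[A, ]
    eA <- exc[[A]]
    for (B in (A + 1L):ncfg) {
      cand <- unique(c(eA, exc[[B]]))
      qB <- cfg[B, ]
      d <- cand[qA[cand] != qB[cand]]
      nd <- length(d)
      if (nd == 1L) {
        i <- d
        qi <- Q[[i]][qA[i] + 1L, qB[i] + 1L]
        h <- qi * (Kv[i] - K[i, i] * vA[i])
        H[A, B] <- H[B, A] <- h
        mux[A, B] <- mux[B, A] <- dip[i, 1] * qi
        muy[A, B] <- muy[B, A] <- dip[i, 2] * qi
        muz[A, B] <- muz[B, A] <- dip[i, 3] * qi
      } else if (nd == 2L) {
        i <- d[1]; j <- d[2]
        h <- K[i, j] * Q[[i]][qA[i] + 1L, qB[i] + 1L] *
                       Q[[j]][qA[j] + 1L, qB[j] + 1L]
        H[A, B] <- H[B, A] <- h
      }
    }
  }

  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)
  evals <- es$values[ord]
  V <- es$vectors[, ord, drop = FALSE]

  # labels and manifolds by dominant configuration
  mode_labels <- model$modes$label
  dom <- apply(V^2, 2, which.max)
  domw <- V[cbind(dom, seq_len(ncfg))]^2
  labels <- character(ncfg)
  for (s in seq_len(ncfg)) {
    if (domw[s] > 0.5) {
      labels[s] <- .config_label(cfg[dom[s], ], mode_labels)
    } else {
      o <- order(V[, s]^2, decreasing = TRUE)[1:2]
      labels[s] <- sprintf("mixed(%s~%s)",
                           .config_label(cfg[o[1], ], mode_labels),
                           .config_label(cfg[o[2], ], mode_labels))
    }
  }
  quanta <- rowSums(cfg)[dom]

  MU <- list(x = crossprod(V, mux %*% V),
             y = crossprod(V, muy %*% V),
             z = crossprod(V, muz %*% V))

  structure(
    list(energies = evals - evals[1], ground_energy = evals[1],
         quanta = quanta, labels = labels, dipoles = MU,
         coefficients = V, configs = cfg, dominant = dom,
         mode_labels = mode_labels,
         vscf_energy = if (!is.null(vscf)) vscf$energy else NA_real_,
         max_level = max_level),
    class = "vci_states"
  )
}

#' @export
print.vci_states <- function(x, ...) {
  cat(sprintf(
    "VCI state set: %d states (%d fundamentals, %d two-quantum), ground at %.2f cm^-1\n",
    length(x$energies), sum(x$quanta == 1), sum(x$quanta == 2),
    x$ground_energy))
  invisible(x)
}

#' Transition dipole between two VCI states
#' @param states a \code{vci_states} object.
#' @param a,b state indices (1-based, ground state = 1).
#' @return a 3-vector.
#' @export
transition_dipole <- function(states, a, b) {
  c(states$dipoles$x[a, b], states$dipoles$y[a, b], states$dipoles$z[a, b])
}

#' Human-readable state table
#'
#' One row per VCI state: relative energy, dominant-configuration label,
#' manifold (total quanta) and squared transition dipole from the ground
#' state.
#'
#' @param states a \code{vci_states} object.
#' @return a data frame (energy in cm^-1, \code{mu2} in squared dipole
#'   units).
#' @export
state_table <- function(states) {
  mu2 <- states$dipoles$x[1, ]^2 + states$dipoles$y[1, ]^2 +
         states$dipoles$z[1, ]^2
  data.frame(energy = states$energies, quanta = states$quanta,
             label = states$labels, mu2 = mu2, stringsAsFactors = FALSE)
}

#' Write the state table as TSV
#' @param states a \code{vci_states} object.
#' @param file output path.
#' @param header optional \code{#}-prefixed comment lines.
#' @return \code{file}, invisibly.
#' @export
write_state_table <- function(states, file, header = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  tab <- state_table(states)
  writeLines("energy\tquanta\tlabel\tmu2", con)
  for (i in seq_len(nrow(tab)))
    writeLines(sprintf("%.6f\t%d\t%s\t%.8g", tab$energy[i], tab$quanta[i],
                       tab$label[i], tab$mu2[i]), con)
  invisible(file)
}

# state index whose dominant configuration equals `q`, NA if absent
.state_of_config <- function(states, q) {
  hit <- which(apply(states$configs[states$dominant, , drop = FALSE], 1L,
                     function(x) all(x == q)))
  if (!length(hit)) return(NA_integer_)
  hit[1]
}

#' Diagonal and off-diagonal anharmonicities from a VCI state set
#'
#' Computes the per-mode diagonal anharmonicity
#' \eqn{\Delta_i = 2 E(1_i) - E(2_i)} and the pairwise off-diagonal
#' anharmonicity \eqn{\Delta_{ij} = E(1_i) + E(1_j) - E(1_i 1_j)}
#' (cm^-1).  These set, respectively, the split of the negative/positive
#' 2D-IR doublet on the diagonal and the strength of cross-peaks.  A missing
#' two-quantum state is reported as \code{NA}, not zero.
#'
#' @param states a \code{vci_states} object with one- and two-quantum
#'   manifolds.
#' @return a list of data frames \code{diagonal} (mode, delta) and
#'   \code{offdiagonal} (mode_i, mode_j, delta).
#' @export
anharmonicity_report <- function(states) {
  stopifnot(inherits(states, "vci_states"))
  if (!any(states$quanta == 2))
    stop("two-quantum manifold missing; run vci_sd with max_level >= 2")
  n <- ncol(states$configs)
  base <- integer(n)
  fund <- vapply(seq_len(n), function(i) {
    q <- base; q[i] <- 1L; .state_of_config(states, q)
  }, integer(1))
  diag_tab <- data.frame(mode = states$mode_labels, delta = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    q <- base; q[i] <- 2L
    ov <- .state_of_config(states, q)
    if (!is.na(fund[i]) && !is.na(ov))
      diag_tab$delta[i] <- 2 * states$energies[fund[i]] - states$energies[ov]
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  off_tab <- data.frame(mode_i = states$mode_labels[pairs[, 1]],
                        mode_j = states$mode_labels[pairs[, 2]],
                        delta = rep(NA_real_, nrow(pairs)),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    q <- base; q[i] <- 1L; q[j] <- 1L
    cmb <- .state_of_config(states, q)
    if (!is.na(fund[i]) && !is.na(fund[j]) && !is.na(cmb))
      off_tab$delta[r] <- states$energies[fund[i]] + states$energies[fund[j]] -
        states$energies[cmb]
  }
  list(diagonal = diag_tab, offdiagonal = off_tab)
}
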