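# mode classes and coupling classes of the synthetic generator
.mode_classes <- c("amide_III", "CaH_bend_1", "CaH_bend_2")
# couplings are parameterized on the reduced classes (both bends behave alike)
.coupling_class <- function(class)
  ifelse(class == "amide_III", "amide_III", "CaH_bend")
.coupling_rank <- c(amide_III = 1L, CaH_bend = 2L)

#' Motif parameter tables for the synthetic local-mode generator
#'
#' A \code{motif_params} object collects, per local-mode class
#' (\code{amide_III}, \code{CaH_bend_1}, \code{CaH_bend_2}) and motif
#' (\code{alpha}, \code{beta}, \code{other}):
#' \itemize{
#'   \item mean local-mode frequency and SD (cm^-1), plus linear slopes of the
#'     mean with \eqn{\phi} and \eqn{\psi} (cm^-1 per degree) about a motif
#'     reference point \eqn{(\phi_0, \psi_0)}, encoding a smooth deterministic
#'     dependence of local-mode frequencies on the backbone dihedrals;
#'   \item mean harmonic coupling and SD (cm^-1) per unordered pair of reduced
#'     coupling classes (\code{amide_III}, \code{CaH_bend}) and topological
#'     separation (\code{same_group}, \code{adjacent}, \code{distant},
#'     \code{interchain}); pairs not listed couple with mean 0, SD 0;
#'   \item a transition-dipole magnitude per mode class (arbitrary consistent
#'     units) and a diagonal anharmonicity (fundamental red shift, cm^-1) per
#'     mode class, which parameterizes the Morse one-mode potentials.
#' }
#'
#' The default values shipped by [default_motif_params()] are SYNTHETIC: they
#' are not quantum-chemical data, but were chosen once so that the generator
#' reproduces the qualitative structure of DFT-derived local-mode analyses of
#' alanine peptides: classical amide III local modes up to about 1250 cm^-1,
#' C-alpha-H bends between about 1260 and 1340 cm^-1, an amide III/amide III
#' nearest-group coupling that is large for alpha-helical and small for
#' beta-strand backbones, a C-alpha-H/amide III same-group coupling with the
#' opposite ordering, larger frequency scatter in the beta region, and larger
#' C-alpha-H transition-dipole magnitudes (hence IR intensity) for beta
#' strands.  Users with their own (e.g. DFT-derived) tables can supply them
#' through [motif_params()] or [read_motif_params()].
#'
#' @param frequency data frame with columns \code{class}, \code{motif},
#'   \code{mean}, \code{sd}, \code{dphi}, \code{dpsi}, \code{cap_n},
#'   \code{cap_c} (the last two are deterministic end-group offsets, cm^-1,
#'   applied to the first and last position of a chain -- the capping
#'   acetyl/N-methylamide groups are chemically distinct from interior
#'   peptide groups).
#' @param coupling data frame with columns \code{class_a}, \code{class_b}
#'   (canonical order: \code{amide_III} before \code{CaH_bend}),
#'   \code{separation}, \code{motif}, \code{mean}, \code{sd}.
#' @param dipole data frame with columns \code{class}, \code{motif},
#'   \code{magnitude}.
#' @param anharmonicity data frame with columns \code{class}, \code{motif},
#'   \code{shift} (cm^-1).
#' @param reference data frame with columns \code{motif}, \code{phi0},
#'   \code{psi0} (degrees).
#' @return an object of class \code{motif_params}.
#' @seealso [read_motif_params()], [write_motif_params()] for YAML I/O.
#' @export
motif_params <- function(frequency, coupling, dipole, anharmonicity,
                         reference) {
  x <- structure(
    list(frequency = frequency, coupling = coupling, dipole = dipole,
         anharmonicity = anharmonicity, reference = reference),
    class = "motif_params"
  )
  validate_motif_params(x)
  x
}

#' @rdname motif_params
#' @export
validate_motif_params <- function(x) {
  stopifnot(inherits(x, "motif_params"))
  fr <- x$frequency
  if (!all(c("class", "motif", "mean", "sd", "dphi", "dpsi",
             "cap_n", "cap_c") %in% names(fr)))
    stop("frequency table misses columns")
  if (any(fr$sd < 0)) stop("frequency SDs must be >= 0")
  if (any(fr$mean < 1150 | fr$mean > 1450))
    stop("mean local-mode frequencies must lie within [1150, 1450] cm^-1")
  cp <- x$coupling
  if (!all(c("class_a", "class_b", "separation", "motif", "mean", "sd")
           %in% names(cp)))
    stop("coupling table misses columns")
  if (any(cp$sd < 0)) stop("coupling SDs must be >= 0")
  if (any(.coupling_rank[cp$class_a] > .coupling_rank[cp$class_b]))
    stop("coupling rows must list the pair in canonical order ",
         "(amide_III before CaH_bend)")
  key <- paste(cp$class_a, cp$class_b, cp$separation, cp$motif)
  if (anyDuplicated(key)) stop("duplicate coupling table rows")
  if (any(x$anharmonicity$shift < 0)) stop("anharmonic shifts must be >= 0")
  if (any(x$dipole$magnitude < 0)) stop("dipole magnitudes must be >= 0")
  invisible(x)
}

#' @rdname motif_params
#' @export
default_motif_params <- function() {
  f <- function(class, motif, mean, sd, dphi, dpsi, cap_n = 0, cap_c = 0)
    data.frame(class = class, motif = motif, mean = mean, sd = sd,
               dphi = dphi, dpsi = dpsi, cap_n = cap_n, cap_c = cap_c,
               stringsAsFactors = FALSE)
  frequency <- rbind(
    f("amide_III",  "alpha", 1245, 3,  0.08, 0.05, 0, -2),
    f("CaH_bend_1", "alpha", 1295, 4,  0.05, 0.04),
    f("CaH_bend_2", "alpha", 1325, 5,  0.05, 0.04),
    f("amide_III",  "beta",  1238, 3,  0.08, 0.05, 12, -16),
    f("CaH_bend_1", "beta",  1278, 6, 0.10, 0.08),
    f("CaH_bend_2", "beta",  1332, 7,  0.08, 0.06),
    f("amide_III",  "other", 1242, 6,  0, 0, 0, -4),
    f("CaH_bend_1", "other", 1298, 10, 0, 0),
    f("CaH_bend_2", "other", 1328, 10, 0, 0)
  )
  cp <- function(a, b, sep, motif, mean, sd)
    data.frame(class_a = a, class_b = b, separation = sep, motif = motif,
               mean = mean, sd = sd, stringsAsFactors = FALSE)
  coupling <- rbind(
    # amide III -- amide III (adjacent peptide groups): alpha >> beta
    cp("amide_III", "amide_III", "adjacent",   "alpha", 9.0, 1.2),
    cp("amide_III", "amide_III", "adjacent",   "beta",  0.5, 0.3),
    cp("amide_III", "amide_III", "adjacent",   "other", 4.0, 2.0),
    cp("amide_III", "amide_III", "distant",    "alpha", 1.0, 0.5),
    cp("amide_III", "amide_III", "distant",    "beta",  0.4, 0.3),
    cp("amide_III", "amide_III", "distant",    "other", 0.5, 0.4),
    # facing groups of two antiparallel strands
    cp("amide_III", "amide_III", "interchain", "alpha", 0.5, 0.3),
    cp("amide_III", "amide_III", "interchain", "beta",  4.0, 1.0),
    cp("amide_III", "amide_III", "interchain", "other", 1.0, 0.5),
    # C-alpha-H -- amide III (flanking groups of the same C-alpha): beta >> alpha
    cp("amide_III", "CaH_bend", "same_group", "alpha", 2.5, 0.8),
    cp("amide_III", "CaH_bend", "same_group", "beta",  15.0, 1.5),
    cp("amide_III", "CaH_bend", "same_group", "other", 4.0, 2.0),
    cp("amide_III", "CaH_bend", "adjacent",   "alpha", 1.0, 0.5),
    cp("amide_III", "CaH_bend", "adjacent",   "beta",  2.5, 1.0),
    cp("amide_III", "CaH_bend", "adjacent",   "other", 1.5, 0.8),
    cp("amide_III", "CaH_bend", "distant",    "alpha", 0.3, 0.2),
    cp("amide_III", "CaH_bend", "distant",    "beta",  0.3, 0.2),
    cp("amide_III", "CaH_bend", "distant",    "other", 0.3, 0.2),
    # C-alpha-H -- C-alpha-H
    cp("CaH_bend", "CaH_bend", "same_group", "alpha", 4.0, 1.0),
    cp("CaH_bend", "CaH_bend", "same_group", "beta",  5.0, 1.5),
    cp("CaH_bend", "CaH_bend", "same_group", "other", 4.5, 1.5),
    cp("CaH_bend", "CaH_bend", "adjacent",   "alpha", 0.8, 0.4),
    cp("CaH_bend", "CaH_bend", "adjacent",   "beta",  1.0, 0.5),
    cp("CaH_bend", "CaH_bend", "adjacent",   "other", 0.9, 0.5),
    cp("CaH_bend", "CaH_bend", "distant",    "alpha", 0.2, 0.1),
    cp("CaH_bend", "CaH_bend", "distant",    "beta",  0.2, 0.1),
    cp("CaH_bend", "CaH_bend", "distant",    "other", 0.2, 0.1)
  )
  dp <- function(class, motif, magnitude)
    data.frame(class = class, motif = motif, magnitude = magnitude,
               stringsAsFactors = FALSE)
  dipole <- rbind(
    dp("amide_III",  "alpha", 1.00), dp("amide_III",  "beta", 1.00),
    dp("amide_III",  "other", 1.00),
    dp("CaH_bend_1", "alpha", 0.45), dp("CaH_bend_1", "beta", 1.20),
    dp("CaH_bend_1", "other", 0.70),
    dp("CaH_bend_2", "alpha", 0.45), dp("CaH_bend_2", "beta", 1.20),
    dp("CaH_bend_2", "other", 0.70)
  )
  an <- function(class, motif, shift)
    data.frame(class = class, motif = motif, shift = shift,
               stringsAsFactors = FALSE)
  anharmonicity <- rbind(
    an("amide_III",  "alpha", 10), an("amide_III",  "beta", 6),
    an("amide_III",  "other", 10),
    an("CaH_bend_1", "alpha", 8),  an("CaH_bend_1", "beta", 12),
    an("CaH_bend_1", "other", 8),
    an("CaH_bend_2", "alpha", 8),  an("CaH_bend_2", "beta", 12),
    an("CaH_bend_2", "other", 8)
  )
  reference <- data.frame(
    motif = c("alpha", "beta", "other"),
    phi0 = c(-80, -120, 0), psi0 = c(-20, 140, 0),
    stringsAsFactors = FALSE
  )
  motif_params(frequency, coupling, dipole, anharmonicity, reference)
}

#' Scale all SDs of a motif parameter table
#'
#' Convenience for deterministic runs: \code{zero_sd(params)} sets every
#' frequency and coupling SD to zero, so model builders become independent of
#' the random seed.
#'
#' @param params a \code{motif_params} object.
#' @param factor multiplier applied to all SDs (default 0).
#' @return a \code{motif_params} object.
#' @export
zero_sd <- function(params, factor = 0) {
  stopifnot(inherits(params, "motif_params"))
  params$frequency$sd <- params$frequency$sd * factor
  params$coupling$sd <- params$coupling$sd * factor
  validate_motif_params(params)
  params
}

# ---- lookups -----------------------------------------------------------

.freq_row <- function(params, class, motif) {
  fr <- params$frequency
  i <- which(fr$class == class & fr$motif == motif)
  if (length(i) != 1L)
    stop("no frequency entry for class ", class, ", motif ", motif)
  fr[i, ]
}

# deterministic part of the local-mode frequency at (phi, psi); `position`
# and `n_positions` locate the mode along the chain for the end-group offsets
.freq_mean_at <- function(params, class, motif, phi, psi,
                          position = NA, n_positions = NA) {
  row <- .freq_row(params, class, motif)
  ref <- params$reference
  j <- which(ref$motif == motif)
  phi0 <- if (length(j)) ref$phi0[j] else 0
  psi0 <- if (length(j)) ref$psi0[j] else 0
  cap <- 0
  if (!is.na(position) && !is.na(n_positions)) {
    if (position == 1) cap <- cap + row$cap_n
    if (position == n_positions) cap <- cap + row$cap_c
  }
  row$mean + row$dphi * (phi - phi0) + row$dpsi * (psi - psi0) + cap
}

.freq_sd <- function(params, class, motif) .freq_row(params, class, motif)$sd

.coupling_row <- function(params, class_a, class_b, separation, motif) {
  ca <- .coupling_class(class_a); cb <- .coupling_class(class_b)
  if (.coupling_rank[ca] > .coupling_rank[cb]) { t <- ca; ca <- cb; cb <- t }
  cp <- params$coupling
  i <- which(cp$class_a == ca & cp$class_b == cb &
             cp$separation == separation & cp$motif == motif)
  if (length(i) != 1L) return(list(mean = 0, sd = 0))
  list(mean = cp$mean[i], sd = cp$sd[i])
}

.dipole_magnitude <- function(params, class, motif) {
  dp <- params$dipole
  i <- which(dp$class == class & dp$motif == motif)
  if (length(i) != 1L) stop("no dipole entry for ", class, "/", motif)
  dp$magnitude[i]
}

.anharmonic_shift <- function(params, class, motif) {
  an <- params$anharmonicity
  i <- which(an$class == class & an$motif == motif)
  if (length(i) != 1L) stop("no anharmonicity entry for ", class, "/", motif)
  an$shift[i]
}

# ---- YAML I/O ----------------------------------------------------------

#' Read or write motif parameter tables as YAML
#'
#' The YAML layout mirrors the five tables of [motif_params()] and records
#' the units explicitly (\code{cm^-1} for frequencies, couplings and
#' anharmonic shifts; degrees for the reference dihedrals).
#'
#' @param params a \code{motif_params} object.
#' @param file path to a YAML file.
#' @return \code{read_motif_params} returns a \code{motif_params} object;
#'   \code{write_motif_params} returns \code{file} invisibly.
#' @export
write_motif_params <- function(params, file) {
  stopifnot(inherits(params, "motif_params"))
  obj <- list(
    units = list(frequency = "cm^-1", coupling = "cm^-1",
                 anharmonicity = "cm^-1", angles = "degrees",
                 dipole = "arbitrary"),
    frequency = params$frequency, coupling = params$coupling,
    dipole = params$dipole, anharmonicity = params$anharmonicity,
    reference = params$reference
  )
  obj <- lapply(obj, function(x) if (is.data.frame(x)) unname(split(x, seq_len(nrow(x)))) else x)
  obj <- rapply(obj, as.list, classes = "data.frame", how = "replace")
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname write_motif_params
#' @export
read_motif_params <- function(file) {
  obj <- yaml::read_yaml(file)
  tab <- function(name) {
    rows <- obj[[name]]
    if (is.null(rows)) stop("YAML parameter file misses table: ", name)
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  motif_params(tab("frequency"), tab("coupling"), tab("dipole"),
               tab("anharmonicity"), tab("reference"))
}

#' @export
print.motif_params <- function(x, ...) {
  cat("motif parameter table (synthetic local-mode generator)\n")
  cat(sprintf("  %d frequency rows, %d coupling rows, %d dipole rows\n",
              nrow(x$frequency), nrow(x$coupling), nrow(x$dipole)))
  invisible(x)
}
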