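# standard atomic masses (amu) for the elements that occur in peptides
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, Cl = 35.45, Na = 22.990, K = 39.098, Ca = 40.078
)
.bohr_to_angstrom <- 0.529177210903

#' Harmonic normal-mode set
#'
#' Container for a harmonic vibrational analysis: frequencies (cm^-1,
#' ascending), mass-weighted displacement vectors (each mode normalized to
#' unit Euclidean norm), atoms (element, mass, Cartesian coordinates in
#' Angstrom) and optional per-mode transition-dipole 3-vectors.
#'
#' @param frequencies numeric vector, cm^-1.
#' @param displacements list with one \code{n_atoms x 3} matrix per mode
#'   (mass-weighted); normalized to unit norm by the constructor when
#'   \code{normalize = TRUE}.
#' @param atoms data frame with columns \code{element}, \code{mass},
#'   \code{x}, \code{y}, \code{z}.
#' @param mode_dipoles optional \code{n_modes x 3} matrix.
#' @param normalize normalize displacement vectors to unit norm.
#' @return an object of class \code{normal_mode_set}.
#' @seealso [read_molden()], [select_window()], [localize()].
#' @export
normal_mode_set <- function(frequencies, displacements, atoms,
                            mode_dipoles = NULL, normalize = TRUE) {
  n <- length(frequencies)
  stopifnot(is.list(displacements), length(displacements) == n,
            is.data.frame(atoms),
            all(c("element", "mass", "x", "y", "z") %in% names(atoms)))
  displacements <- lapply(displacements, function(d) {
    d <- as.matrix(d)
    if (nrow(d) != nrow(atoms) || ncol(d) != 3)
      stop("each displacement must be an n_atoms x 3 matrix")
    if (normalize) d <- d / sqrt(sum(d^2))
    d
  })
  for (d in displacements)
    if (abs(sqrt(sum(d^2)) - 1) > 1e-8)
      stop("displacement vectors must have unit Euclidean norm within 1e-8")
  if (is.unsorted(frequencies)) {
    ord <- order(frequencies)
    frequencies <- frequencies[ord]
    displacements <- displacements[ord]
    if (!is.null(mode_dipoles)) mode_dipoles <- mode_dipoles[ord, , drop = FALSE]
  }
  if (!is.null(mode_dipoles)) {
    mode_dipoles <- as.matrix(mode_dipoles)
    if (nrow(mode_dipoles) != n || ncol(mode_dipoles) != 3)
      stop("mode_dipoles must be an n_modes x 3 matrix")
  }
  structure(
    list(frequencies = as.numeric(frequencies),
         displacements = displacements, atoms = atoms,
         mode_dipoles = mode_dipoles),
    class = "normal_mode_set"
  )
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat(sprintf("normal-mode set: %d modes on %d atoms, %.1f - %.1f cm^-1%s\n",
              length(x$frequencies), nrow(x$atoms),
              min(x$frequencies), max(x$frequencies),
              if (is.null(x$mode_dipoles)) " (no dipoles)" else ""))
  invisible(x)
}

#' Read a Molden-format harmonic frequency file
#'
#' Parses the \code{[FREQ]}, \code{[FR-COORD]} and \code{[FR-NORM-COORD]}
#' sections of a Molden vibrational file.  Coordinates and displacements are
#' taken in Bohr unless the section is flagged \code{Angs}.  Cartesian
#' displacement vectors are mass-weighted (multiplied by the square root of
#' the atomic mass) and normalized, which is the convention required by
#' [localize()].  Molden files carry at most IR intensities, not dipole
#' vectors, so per-mode transition dipoles are read from a sidecar CSV with
#' columns \code{mode}, \code{mux}, \code{muy}, \code{muz}
#' ([read_mode_dipoles()]).
#'
#' @param file path to a Molden file.
#' @param dipole_file optional path to a sidecar dipole CSV.
#' @return a [normal_mode_set()].
#' @export
read_molden <- function(file, dipole_file = NULL) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  sec_at <- grep("^\\[", lines)
  sec_name <- toupper(sub("^\\[([^]]+)\\].*$", "\\1", lines[sec_at]))
  sec_flag <- toupper(sub("^\\[[^]]+\\]\\s*", "", lines[sec_at]))
  get_section <- function(name) {
    i <- which(sec_name == name)
    if (!length(i)) return(NULL)
    from <- sec_at[i[1]] + 1L
    to <- if (any(sec_at > sec_at[i[1]])) min(sec_at[sec_at > sec_at[i[1]]]) - 1L
          else length(lines)
    list(lines = if (from <= to) lines[from:to] else character(),
         flag = sec_flag[i[1]])
  }
  freq_sec <- get_section("FREQ")
  coord_sec <- get_section("FR-COORD")
  norm_sec <- get_section("FR-NORM-COORD")
  if (is.null(freq_sec) || is.null(coord_sec) || is.null(norm_sec))
    stop("Molden file must contain [FREQ], [FR-COORD] and [FR-NORM-COORD]")
  freqs <- as.numeric(freq_sec$lines)
  if (anyNA(freqs)) stop("could not parse [FREQ] section")

  coord_unit <- if (grepl("ANGS", coord_sec$flag)) 1 else .bohr_to_angstrom
  toks <- strsplit(coord_sec$lines, "\\s+")
  elements <- vapply(toks, `[`, "", 1L)
  elements <- paste0(toupper(substr(elements, 1, 1)),
                     tolower(substr(elements, 2, nchar(elements))))
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  masses <- .atomic_masses[elements]
  if (anyNA(masses))
    stop("unknown element(s) in [FR-COORD]: ",
         paste(unique(elements[is.na(masses)]), collapse = ", "))
  atoms <- data.frame(element = elements, mass = unname(masses),
                      x = xyz[, 1] * coord_unit, y = xyz[, 2] * coord_unit,
                      z = xyz[, 3] * coord_unit, stringsAsFactors = FALSE)
  n_atoms <- nrow(atoms)

  vib_at <- grep("^[Vv]ibration", norm_sec$lines)
  if (length(vib_at) != length(freqs))
    stop("[FR-NORM-COORD] must contain one 'vibration' block per frequency")
  displacements <- vector("list", length(freqs))
  for (k in seq_along(vib_at)) {
    from <- vib_at[k] + 1L
    to <- if (k < length(vib_at)) vib_at[k + 1L] - 1L else length(norm_sec$lines)
    vals <- as.numeric(unlist(strsplit(norm_sec$lines[from:to], "\\s+")))
    if (length(vals) != 3L * n_atoms)
      stop("vibration block ", k, " has ", length(vals),
           " values, expected ", 3L * n_atoms)
    cart <- matrix(vals, ncol = 3, byrow = TRUE)
    displacements[[k]] <- cart * sqrt(atoms$mass)   # mass-weight
  }

  dip <- if (!is.null(dipole_file)) read_mode_dipoles(dipole_file, length(freqs))
         else NULL
  normal_mode_set(freqs, displacements, atoms, mode_dipoles = dip,
                  normalize = TRUE)
}

#' @rdname read_molden
#' @param n_modes expected number of modes (checked when given).
#' @export
read_mode_dipoles <- function(file, n_modes = NULL) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("mode", "mux", "muy", "muz")
  if (!all(need %in% names(tab)))
    stop("dipole sidecar CSV must have columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$mode), ]
  if (!is.null(n_modes) && nrow(tab) != n_modes)
    stop("dipole sidecar has ", nrow(tab), " rows, expected ", n_modes)
  as.matrix(tab[, c("mux", "muy", "muz")])
}

#' Select normal modes in a wavenumber window
#'
#' Returns the subset of modes with \code{lo <= frequency <= hi}, order
#' preserved.  The defaults delimit the extended amide III region
#' (1200--1400 cm^-1).  An empty selection is an error (condition class
#' \code{amideIR_empty_window}), since every downstream stage needs at least
#' one mode.
#'
#' @param modes a [normal_mode_set()].
#' @param lo,hi window limits in cm^-1, \code{lo < hi}.
#' @return a [normal_mode_set()] restricted to the window.
#' @export
select_window <- function(modes, lo = 1200, hi = 1400) {
  stopifnot(inherits(modes, "normal_mode_set"))
  if (!(lo < hi)) stop("window requires lo < hi")
  keep <- which(modes$frequencies >= lo & modes$frequencies <= hi)
  if (!length(keep))
    .stop_stage("select_window",
                sprintf("no normal modes in window [%g, %g] cm^-1", lo, hi),
                class = "amideIR_empty_window")
  normal_mode_set(
    modes$frequencies[keep], modes$displacements[keep], modes$atoms,
    mode_dipoles = if (!is.null(modes$mode_dipoles))
      modes$mode_dipoles[keep, , drop = FALSE],
    normalize = FALSE
  )
}
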