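#' Lineshape configuration for sum-over-states spectra
#'
#' Homogeneous Lorentzian dephasing with HWHM
#' \eqn{\gamma = (2\pi c T_2)^{-1}} (about 5.309 cm^-1 for
#' \eqn{T_2 = 1} ps).  Only zero waiting time (\code{t2 = 0}) is supported:
#' population dynamics and spectral diffusion during the waiting time are
#' out of scope.
#'
#' @param T2 dephasing time in ps (default 1).
#' @param t2 waiting time in ps; must be 0.
#' @return an object of class \code{lineshape_config} with element
#'   \code{gamma} (HWHM, cm^-1).
#' @export
lineshape_config <- function(T2 = 1.0, t2 = 0.0) {
  stopifnot(T2 > 0)
  if (t2 != 0) stop("only t2 = 0 is supported (no waiting-time dynamics)")
  structure(list(T2 = T2, t2 = t2, gamma = dephasing_hwhm(T2)),
            class = "lineshape_config")
}

.unit3 <- function(v) {
  n2 <- sum(v^2)
  if (n2 == 0) return(c(0, 0, 0))
  v / sqrt(n2)
}

#' Isotropic four-point orientational factor
#'
#' Standard isotropic averages of four linearly polarized field interactions
#' over molecular orientations, expressed through the angles
#' \eqn{\theta_{ij}} between the four transition-dipole unit vectors:
#' \deqn{\langle ZZZZ \rangle = \tfrac{1}{15}(c_{12} c_{34} + c_{13} c_{24} + c_{14} c_{23})}
#' \deqn{\langle ZZXX \rangle = \tfrac{1}{30}(4 c_{12} c_{34} - c_{13} c_{24} - c_{14} c_{23})}
#' \deqn{\langle ZXXZ \rangle = \tfrac{1}{30}(-c_{12} c_{34} - c_{13} c_{24} + 4 c_{14} c_{23})}
#' \deqn{\langle ZXZX \rangle = \tfrac{1}{30}(-c_{12} c_{34} + 4 c_{13} c_{24} - c_{14} c_{23})}
#' with \eqn{c_{ij} = \cos\theta_{ij}}; they satisfy
#' \eqn{\langle ZZZZ \rangle = \langle ZZXX \rangle + \langle ZXZX \rangle +
#' \langle ZXXZ \rangle}.  Non-unit inputs are normalized with a warning.
#'
#' @param pol one of \code{"ZZZZ"}, \code{"ZZXX"}, \code{"ZXXZ"},
#'   \code{"ZXZX"}.
#' @param d1,d2,d3,d4 dipole direction 3-vectors (unit length).
#' @return the scalar orientational weight.
#' @examples
#' z <- c(0, 0, 1)
#' orientational_factor("ZZZZ", z, z, z, z)  # 1/5
#' orientational_factor("ZZXX", z, z, z, z)  # 1/15
#' @export
orientational_factor <- function(pol = c("ZZZZ", "ZZXX", "ZXXZ", "ZXZX"),
                                 d1, d2, d3, d4) {
  pol <- match.arg(pol)
  vs <- list(d1, d2, d3, d4)
  for (k in seq_along(vs)) {
    if (abs(sum(vs[[k]]^2) - 1) > 1e-8) {
      warning("non-unit dipole direction normalized", call. = FALSE)
      vs[[k]] <- .unit3(vs[[k]])
    }
  }
  c12 <- sum(vs[[1]] * vs[[2]]); c34 <- sum(vs[[3]] * vs[[4]])
  c13 <- sum(vs[[1]] * vs[[3]]); c24 <- sum(vs[[2]] * vs[[4]])
  c14 <- sum(vs[[1]] * vs[[4]]); c23 <- sum(vs[[2]] * vs[[3]])
  switch(pol,
    ZZZZ = (c12 * c34 + c13 * c24 + c14 * c23) / 15,
    ZZXX = (4 * c12 * c34 - c13 * c24 - c14 * c23) / 30,
    ZXXZ = (-c12 * c34 - c13 * c24 + 4 * c14 * c23) / 30,
    ZXZX = (-c12 * c34 + 4 * c13 * c24 - c14 * c23) / 30
  )
}

# unit-area Lorentzian (for 1D) and peak-normalized Lorentzian (for 2D)
.lorentz_area <- function(x, x0, gamma) (gamma / pi) / ((x - x0)^2 + gamma^2)
.lorentz_peak <- function(x, x0, gamma) gamma^2 / ((x - x0)^2 + gamma^2)

# render a stick list as a (probe x pump) matrix of factorized 2D Lorentzians
.render_sticks <- function(sticks, pump, probe, gamma) {
  amp <- matrix(0, length(probe), length(pump))
  if (is.null(sticks) || !nrow(sticks)) return(amp)
  reach <- 40 * gamma   # sticks beyond this cannot contribute visibly
  keep <- sticks$pump > min(pump) - reach & sticks$pump < max(pump) + reach &
          sticks$probe > min(probe) - reach & sticks$probe < max(probe) + reach
  st <- sticks[keep, , drop = FALSE]
  if (!nrow(st)) return(amp)
  P <- outer(pump, st$pump, function(x, x0) .lorentz_peak(x, x0, gamma))
  Qm <- outer(probe, st$probe, function(x, x0) .lorentz_peak(x, x0, gamma))
  Qm %*% (st$amp * t(P))
}

#' One-dimensional IR spectrum from a VCI state set
#'
#' Stick intensities are \eqn{\nu_f\, |\mu_{0f}|^2} over the one-quantum
#' manifold (the frequency prefactor can be disabled), broadened with a
#' unit-area Lorentzian of HWHM \eqn{\gamma}, so the integral of the
#' broadened spectrum equals the summed stick intensity.
#'
#' @param states a \code{vci_states} object.
#' @param cfg a [lineshape_config()].
#' @param axis wavenumber axis, cm^-1.
#' @param prefactor include the frequency prefactor (default TRUE).
#' @param normalize scale the broadened maximum to 1.
#' @return an object of class \code{spectrum1d}: \code{sticks} (data frame
#'   \code{wavenumber}, \code{intensity}, \code{label}), \code{axis},
#'   \code{absorbance}, \code{normalized}.
#' @export
ir_1d <- function(states, cfg = lineshape_config(),
                  axis = seq(1150, 1450, by = 0.5), prefactor = TRUE,
                  normalize = FALSE) {
  stopifnot(inherits(states, "vci_states"), inherits(cfg, "lineshape_config"))
  oneq <- which(states$quanta == 1)
  if (!length(oneq)) stop("no one-quantum states (fundamentals) present")
  mu2 <- states$dipoles$x[1, oneq]^2 + states$dipoles$y[1, oneq]^2 +
         states$dipoles$z[1, oneq]^2
  nu <- states$energies[oneq]
  inten <- if (prefactor) nu * mu2 else mu2
  keep <- inten > 0
  sticks <- data.frame(wavenumber = nu[keep], intensity = inten[keep],
                       label = states$labels[oneq][keep],
                       stringsAsFactors = FALSE)
  absb <- numeric(length(axis))
  for (i in seq_len(nrow(sticks)))
    absb <- absb + sticks$intensity[i] *
      .lorentz_area(axis, sticks$wavenumber[i], cfg$gamma)
  if (normalize && max(absb) > 0) absb <- absb / max(absb)
  structure(list(sticks = sticks, axis = axis, absorbance = absb,
                 normalized = normalize, gamma = cfg$gamma),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("1D IR spectrum: %d stick(s), axis %.0f-%.0f cm^-1\n",
              nrow(x$sticks), min(x$axis), max(x$axis)))
  invisible(x)
}

#' @export
plot.spectrum1d <- function(x, ...) {
  graphics::plot(x$axis, x$absorbance, type = "l",
                 xlab = expression(tilde(nu) / cm^-1),
                 ylab = "absorbance (arb.)", ...)
  if (nrow(x$sticks)) {
    sc <- if (max(x$sticks$intensity) > 0)
      max(x$absorbance) / max(x$sticks$intensity) else 1
    graphics::segments(x$sticks$wavenumber, 0, x$sticks$wavenumber,
                       x$sticks$intensity * sc, col = "grey50")
  }
  invisible(x)
}

# stick list of the absorptive t2 = 0 sum-over-states signal.
# Population (doorway-window) bookkeeping: pumping fundamental a prepares
# |a><a| (weight |mu_0a|^2); the probe then sees ground-state bleach on all
# fundamentals b, stimulated emission on a itself, and excited-state
# absorption a -> c into every two-quantum state, each weighted by the
# isotropic orientational factor of its four dipole interactions.  In the
# harmonic separable limit ESA cancels GSB + SE exactly (sqrt(2) dipole
# rule, zero anharmonic shift), so any surviving signal measures
# anharmonicity.
.sticks_2dir <- function(states, pol, pathways, bleach_sign, esa_sign,
                         prefactor) {
  oneq <- which(states$quanta == 1)
  twoq <- which(states$quanta == 2)
  mu0 <- function(s) transition_dipole(states, 1L, s)
  # dominant mode of a fundamental (NA when strongly mixed over modes)
  dom_mode <- function(s) {
    q <- states$configs[states$dominant[s], ]
    if (sum(q) == 1L) which(q == 1L) else NA_integer_
  }
  # is two-quantum state cc the overtone of mode i?
  is_overtone_of <- function(cc, i) {
    if (is.na(i)) return(FALSE)
    q <- states$configs[states$dominant[cc], ]
    q[i] == 2L && sum(q) == 2L
  }
  out <- vector("list", 4 * length(oneq) * (length(oneq) + length(twoq)))
  z <- 0L
  push <- function(pump, probe, amp, pathway, diag) {
    z <<- z + 1L
    out[[z]] <<- c(pump = pump, probe = probe, amp = amp, path = pathway,
                   diag = diag)
  }
  for (a in oneq) {
    mua <- mu0(a)
    wa <- sum(mua^2)
    if (wa == 0) next
    ua <- .unit3(mua)
    Ea <- states$energies[a]
    ma <- dom_mode(a)
    pref_a <- if (prefactor) Ea else 1
    if (any(pathways %in% c("gsb", "all"))) {
      for (b in oneq) {
        mub <- mu0(b)
        wb <- sum(mub^2)
        if (wb == 0) next
        F <- orientational_factor(pol, ua, ua, .unit3(mub), .unit3(mub))
        push(Ea, states$energies[b],
             bleach_sign * pref_a * F * wa * wb, 1, as.integer(b == a))
      }
    }
    if (any(pathways %in% c("se", "all"))) {
      F <- orientational_factor(pol, ua, ua, ua, ua)
      push(Ea, Ea, bleach_sign * pref_a * F * wa^2, 2, 1L)
    }
    if (any(pathways %in% c("esa", "all"))) {
      for (cc in twoq) {
        muc <- transition_dipole(states, a, cc)
        wc <- sum(muc^2)
        if (wc < 1e-14 * wa) next
        F <- orientational_factor(pol, ua, ua, .unit3(muc), .unit3(muc))
        push(Ea, states$energies[cc] - Ea,
             esa_sign * pref_a * F * wa * wc, 3,
             as.integer(is_overtone_of(cc, ma)))
      }
    }
  }
  if (z == 0L)
    return(data.frame(pump = numeric(0), probe = numeric(0),
                      amp = numeric(0), path = integer(0),
                      diag = logical(0)))
  m <- do.call(rbind, out[seq_len(z)])
  data.frame(pump = m[, 1], probe = m[, 2], amp = m[, 3],
             path = as.integer(m[, 4]), diag = as.logical(m[, 5]))
}

#' Purely absorptive 2D-IR spectrum at zero waiting time
#'
#' Sum-over-states absorptive 2D-IR signal with ground-state bleach (GSB),
#' stimulated emission (SE) and excited-state absorption (ESA) pathways,
#' isotropic orientational averaging for the chosen polarization condition,
#' and a factorized 2D Lorentzian lineshape (peak-normalized product of a
#' pump- and a probe-axis Lorentzian, HWHM \eqn{\gamma} each).  Sign
#' convention (configurable): bleach/SE negative, ESA positive.  In the
#' harmonic separable limit the three pathway families cancel exactly, so
#' peaks report diagonal and off-diagonal anharmonicities; the negative
#' diagonal peak and its positive ESA partner are split by the diagonal
#' anharmonicity.
#'
#' @param states a \code{vci_states} object with one- and two-quantum
#'   manifolds (a missing two-quantum manifold skips ESA with a warning).
#' @param cfg a [lineshape_config()] (\code{t2 = 0} enforced there).
#' @param pol polarization condition, see [orientational_factor()].
#' @param pump,probe wavenumber axes in cm^-1 (default 1150--1450 at 0.5);
#'   pump is \eqn{\omega_1} (columns), probe is \eqn{\omega_3} (rows).
#' @param pathways subset of \code{c("gsb", "se", "esa")} or \code{"all"}.
#' @param bleach_sign,esa_sign signs of the pathway families (defaults -1
#'   and +1).
#' @param prefactor multiply each pathway by the pump transition wavenumber
#'   (default FALSE).
#' @return an object of class \code{spectrum2d}: \code{pump_axis},
#'   \code{probe_axis}, \code{amplitude} (probe x pump matrix),
#'   \code{sticks}, \code{polarization}, \code{lineshape},
#'   \code{sign_convention}.
#' @export
spectrum_2dir <- function(states, cfg = lineshape_config(), pol = "ZZZZ",
                          pump = seq(1150, 1450, by = 0.5), probe = pump,
                          pathways = "all", bleach_sign = -1, esa_sign = 1,
                          prefactor = FALSE) {
  stopifnot(inherits(states, "vci_states"), inherits(cfg, "lineshape_config"))
  if (is.unsorted(pump, strictly = TRUE) || is.unsorted(probe, strictly = TRUE))
    stop("pump and probe axes must be strictly increasing")
  if (!any(states$quanta == 1)) stop("one-quantum manifold missing")
  if (!any(states$quanta == 2) && any(pathways %in% c("esa", "all")))
    warning("two-quantum manifold missing: ESA pathways skipped",
            call. = FALSE)
  sticks <- .sticks_2dir(states, pol, pathways, bleach_sign, esa_sign,
                         prefactor)
  amp <- .render_sticks(sticks, pump, probe, cfg$gamma)
  structure(
    list(pump_axis = pump, probe_axis = probe, amplitude = amp,
         sticks = sticks, polarization = pol, lineshape = cfg,
         sign_convention = c(bleach = bleach_sign, esa = esa_sign),
         pathway_max = if (nrow(sticks)) max(abs(sticks$amp)) else 0),
    class = "spectrum2d"
  )
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf(
    "2D-IR spectrum <%s>: %d x %d grid, %d stick(s), |amp|max %.3g\n",
    x$polarization, length(x$probe_axis), length(x$pump_axis),
    nrow(x$sticks), max(abs(x$amplitude))))
  invisible(x)
}

#' @export
plot.spectrum2d <- function(x, n_levels = 12, ...) {
  m <- max(abs(x$amplitude))
  if (m == 0) m <- 1
  pal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(64)
  graphics::image(x$pump_axis, x$probe_axis, t(x$amplitude),
                  zlim = c(-m, m), col = pal,
                  xlab = expression(omega[1] / cm^-1),
                  ylab = expression(omega[3] / cm^-1), ...)
  graphics::contour(x$pump_axis, x$probe_axis, t(x$amplitude),
                    nlevels = n_levels, add = TRUE, drawlabels = FALSE,
                    col = "grey30")
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Diagonal and cross-peak extrema per band pair
#'
#' Scans a 2D spectrum over rectangles defined by labeled wavenumber bands
#' (e.g. classical amide III vs C-alpha-H bending) and reports, per ordered
#' (pump band, probe band) pair, the extremal amplitude (largest magnitude,
#' signed) and its location.  Diagonal features are identified physically,
#' not purely geometrically: a stick is diagonal when it is the bleach or
#' stimulated emission of a single fundamental, or the excited-state
#' absorption into that fundamental's own overtone (the anharmonically
#' shifted partner of the diagonal peak); all other sticks -- bleach across
#' two different fundamentals and absorption into combination states -- are
#' cross features.  The two classes are rendered as separate component maps
#' with the spectrum's own lineshape, and each band-pair value is the
#' extremal amplitude of the matching component map inside the rectangle.
#' Working on component maps makes the report read the physics rather than
#' lineshape overlap: the cancelling pathway partners of a cross feature
#' (bleach across a state pair vs absorption into the combination band)
#' share positions, so for uncoupled modes every cross value is zero by
#' construction while diagonal peaks remain, and overlapping tails of
#' strong diagonal doublets never masquerade as cross-peaks.  A band paired
#' with itself reports both the diagonal and the within-band cross
#' extremum.  Bands outside the axes are ignored with a warning.
#'
#' @param spec a [spectrum_2dir()] result.
#' @param bands named list of \code{c(lo, hi)} wavenumber intervals
#'   (non-overlapping).
#' @return a data frame with columns \code{pump_band}, \code{probe_band},
#'   \code{kind} (\code{diagonal}/\code{cross}), \code{amplitude} (signed,
#'   largest magnitude), \code{pump}, \code{probe}.
#' @export
cross_peak_report <- function(spec, bands) {
  stopifnot(inherits(spec, "spectrum2d"), is.list(bands),
            !is.null(names(bands)))
  iv <- do.call(rbind, bands)
  if (any(iv[, 1] >= iv[, 2])) stop("each band must be c(lo, hi) with lo < hi")
  o <- order(iv[, 1])
  if (any(iv[o, 2][-length(o)] > iv[o, 1][-1]))
    stop("bands must be non-overlapping")
  gamma <- spec$lineshape$gamma
  st <- spec$sticks
  comp <- list(
    diagonal = .render_sticks(st[st$diag %in% TRUE, , drop = FALSE],
                              spec$pump_axis, spec$probe_axis, gamma),
    cross = .render_sticks(st[st$diag %in% FALSE, , drop = FALSE],
                           spec$pump_axis, spec$probe_axis, gamma)
  )
  inside <- function(axis, b) which(axis >= b[1] & axis <= b[2])
  rows <- list()
  for (pb in names(bands)) for (qb in names(bands)) {
    ip <- inside(spec$pump_axis, bands[[pb]])
    iq <- inside(spec$probe_axis, bands[[qb]])
    if (!length(ip) || !length(iq)) {
      warning("band outside spectrum axes ignored: ", pb, " x ", qb,
              call. = FALSE)
      next
    }
    for (kind in if (identical(pb, qb)) c("diagonal", "cross") else "cross") {
      sub <- comp[[kind]][iq, ip, drop = FALSE]
      k <- which.max(abs(sub))
      rc <- arrayInd(k, dim(sub))
      rows[[length(rows) + 1L]] <-
        data.frame(pump_band = pb, probe_band = qb, kind = kind,
                   amplitude = sub[k],
                   pump = spec$pump_axis[ip[rc[2]]],
                   probe = spec$probe_axis[iq[rc[1]]],
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write spectra to plain-text files
#'
#' \code{write_spectrum1d} writes a two-column TSV (wavenumber,
#' absorbance); \code{write_spectrum2d} writes gnuplot-style
#' whitespace-delimited triplets (pump, probe, amplitude; blank line
#' between pump blocks) and, when \code{json} is given, a matrix container
#' with the axis vectors.
#'
#' @param spec a \code{spectrum1d} or \code{spectrum2d}.
#' @param file output path (TSV / gnuplot triplets).
#' @param json optional output path for the JSON matrix container (2D only).
#' @param header optional \code{#}-prefixed comment lines.
#' @return \code{file}, invisibly.
#' @export
write_spectrum1d <- function(spec, file, header = character()) {
  stopifnot(inherits(spec, "spectrum1d"))
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  writeLines("wavenumber\tabsorbance", con)
  writeLines(sprintf("%.4f\t%.10g", spec$axis, spec$absorbance), con)
  invisible(file)
}

#' @rdname write_spectrum1d
#' @export
write_spectrum2d <- function(spec, file, json = NULL, header = character()) {
  stopifnot(inherits(spec, "spectrum2d"))
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  writeLines("# pump probe amplitude", con)
  for (j in seq_along(spec$pump_axis)) {
    writeLines(sprintf("%.4f %.4f %.10g", spec$pump_axis[j],
                       spec$probe_axis, spec$amplitude[, j]), con)
    writeLines("", con)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(pump_axis = spec$pump_axis, probe_axis = spec$probe_axis,
           amplitude = spec$amplitude, polarization = spec$polarization,
           gamma = spec$lineshape$gamma,
           sign_convention = as.list(spec$sign_convention),
           comment = as.list(header)),
      json, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  }
  invisible(file)
}
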