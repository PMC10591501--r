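#' Local-mode frequency/coupling matrix
#'
#' The central container of the local-mode picture: a symmetric matrix in
#' cm^-1 with the local-mode frequencies on the diagonal and the harmonic
#' couplings in the off-diagonal (frequency-matrix convention: its
#' eigenvalues are the normal-mode wavenumbers of the selected window).
#'
#' \code{coupling_matrix()} is generic: applied to a plain matrix it
#' validates and wraps it; applied to a [localize()] result it forms
#' \eqn{U^T \mathrm{diag}(\nu) U} from the localization transform and the
#' normal-mode frequencies of the selected subset.
#'
#' @param x a symmetric numeric matrix, or a \code{local_mode_basis}.
#' @param frequencies normal-mode frequencies (cm^-1) of the selected subset
#'   (only for the \code{local_mode_basis} method; defaults to those stored
#'   in the basis).
#' @param labels optional character labels, one per local mode.
#' @param ... unused.
#' @return an object of class \code{coupling_matrix} (a matrix with a
#'   \code{labels} attribute).
#' @examples
#' J <- coupling_matrix(matrix(c(1245, 9, 9, 1245), 2),
#'                      labels = c("amideIII(1)", "amideIII(2)"))
#' eigen(unclass(J))$values
#' @export
coupling_matrix <- function(x, ...) UseMethod("coupling_matrix")

#' @rdname coupling_matrix
#' @export
coupling_matrix.default <- function(x, labels = NULL, ...) {
  m <- as.matrix(x)
  if (nrow(m) != ncol(m)) stop("coupling matrix must be square")
  if (max(abs(m - t(m))) > 1e-10)
    stop("coupling matrix must be symmetric within 1e-10")
  m <- (m + t(m)) / 2
  if (any(diag(m) <= 0))
    stop("diagonal local-mode frequencies must be positive")
  if (is.null(labels)) labels <- paste0("mode", seq_len(nrow(m)))
  if (length(labels) != nrow(m)) stop("one label per mode required")
  dimnames(m) <- list(labels, labels)
  structure(m, labels = as.character(labels), class = "coupling_matrix")
}

#' @rdname coupling_matrix
#' @export
coupling_matrix.local_mode_basis <- function(x, frequencies = NULL,
                                             labels = NULL, ...) {
  U <- x$transformation
  if (is.null(frequencies)) frequencies <- x$subset_frequencies
  if (length(frequencies) != nrow(U))
    stop("need one frequency per mode of the localization subset")
  m <- t(U) %*% diag(frequencies, nrow = length(frequencies)) %*% U
  if (is.null(labels)) labels <- x$labels
  coupling_matrix(m, labels = labels)
}

#' @export
print.coupling_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("local-mode coupling matrix (%d modes, cm^-1)\n", nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Entrywise mean and standard deviation over a set of coupling matrices
#'
#' Averages corresponding entries of coupling matrices collected over a set
#' of conformers (the motif-statistics analysis: mean local-mode frequencies
#' on the diagonal, mean couplings off-diagonal, with entrywise sample SDs,
#' n - 1 denominator).  All matrices must share dimension and mode ordering;
#' the builders and [localize()] emit a canonical ordering (amide III modes
#' by sequence position, then C-alpha-H bends) precisely so that
#' corresponding entries are averaged.
#'
#' @param matrices a list of at least two [coupling_matrix()] objects.
#' @return a list with \code{mean} (a \code{coupling_matrix}), \code{sd}
#'   (a plain matrix) and \code{n}.
#' @export
motif_statistics <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2)
    stop("motif_statistics needs at least 2 matrices (sample SD undefined)")
  dims <- vapply(matrices, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stop("all coupling matrices must have the same dimension")
  labs <- attr(matrices[[1]], "labels")
  for (m in matrices)
    if (!identical(attr(m, "labels"), labs))
      stop("inconsistent mode labeling/ordering across matrices")
  arr <- simplify2array(lapply(matrices, unclass))
  mu <- apply(arr, c(1, 2), mean)
  sdm <- apply(arr, c(1, 2), stats::sd)
  list(mean = coupling_matrix(mu, labels = labs), sd = sdm,
       n = length(matrices))
}

#' Read or write a coupling matrix as labeled CSV
#'
#' @param cm a [coupling_matrix()].
#' @param file path to a CSV file.
#' @param header optional comment lines (each written prefixed with
#'   \code{#}) carrying provenance such as a config digest.
#' @return \code{read_coupling_csv} returns a \code{coupling_matrix};
#'   \code{write_coupling_csv} returns \code{file} invisibly.
#' @export
write_coupling_csv <- function(cm, file, header = character()) {
  stopifnot(inherits(cm, "coupling_matrix"))
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  labs <- attr(cm, "labels")
  writeLines(paste(c("mode", labs), collapse = ","), con)
  for (i in seq_len(nrow(cm)))
    writeLines(paste(c(labs[i], sprintf("%.10g", unclass(cm)[i, ])),
                     collapse = ","), con)
  invisible(file)
}

#' @rdname write_coupling_csv
#' @export
read_coupling_csv <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  tab <- utils::read.csv(text = paste(lines, collapse = "\n"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  labs <- tab$mode
  m <- as.matrix(tab[, -1, drop = FALSE])
  coupling_matrix(m, labels = labs)
}
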