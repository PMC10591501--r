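# End-to-end orchestration: config validation, staged execution with
# machine-readable error records, plain-text artifacts with provenance
# headers, and a manifest with content digests for reproducibility checks.

.digest_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Serialize a local-mode model to JSON
#'
#' Documented plain-text container holding the coupling matrix, labels,
#' transition dipoles, tabulated one-mode potentials and conformer metadata;
#' [read_model_json()] restores a fully functional \code{local_mode_model}.
#'
#' @param model a \code{local_mode_model}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_model_json <- function(model, file) {
  stopifnot(inherits(model, "local_mode_model"))
  obj <- list(
    format = "amideIR-local-mode-model", version = 1L,
    units = list(energy = "cm^-1", coordinate = "dimensionless mass-weighted"),
    labels = model$modes$label,
    modes = model$modes,
    coupling = unclass(model$coupling),
    dipoles = model$dipoles,
    potentials = lapply(model$potentials, function(p)
      list(grid = p$grid, energies = p$energies,
           kinetic_scale = p$kinetic_scale)),
    conformer = if (!is.null(model$conformer)) unclass(model$conformer),
    seed = model$seed, chains = model$chains
  )
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", dataframe = "columns")
  invisible(file)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(obj$format, "amideIR-local-mode-model"))
    stop("not an amideIR local-mode model container")
  conf <- if (!is.null(obj$conformer))
    peptide_conformer(obj$conformer$phi, obj$conformer$psi,
                      obj$conformer$omega, obj$conformer$n_residues,
                      obj$conformer$motif)
  structure(
    list(coupling = coupling_matrix(obj$coupling, labels = obj$labels),
         dipoles = matrix(unlist(obj$dipoles), ncol = 3,
                          byrow = is.list(obj$dipoles)),
         potentials = lapply(seq_len(nrow(obj$coupling)), function(i) {
           p <- if (is.data.frame(obj$potentials))
             lapply(obj$potentials, `[[`, i) else obj$potentials[[i]]
           one_mode_potential(unlist(p$grid), unlist(p$energies),
                              p$kinetic_scale)
         }),
         modes = as.data.frame(obj$modes, stringsAsFactors = FALSE),
         conformer = conf,
         seed = if (is.null(obj$seed)) NA_integer_ else as.integer(obj$seed),
         chains = if (is.null(obj$chains)) 1L else as.integer(obj$chains)),
    class = "local_mode_model"
  )
}

.known_cfg_keys <- list(
  top = c("input", "window", "localization", "vci", "lineshape",
          "polarization", "axis", "output_dir", "seed", "log_level"),
  input = c("type", "model", "path", "dipoles", "phi", "psi", "omega",
            "n_residues", "motif", "chains", "params_file",
            "anharmonic_shift"),
  window = c("lo", "hi"),
  localization = c("max_sweeps", "tol"),
  vci = c("n_basis", "max_quanta", "max_level", "config_cap"),
  lineshape = c("T2", "t2"),
  axis = c("lo", "hi", "step")
)

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file path) with blocks
#' \code{input} (synthetic model spec or Molden path + dipole sidecar),
#' \code{window}, \code{localization}, \code{vci}, \code{lineshape},
#' \code{polarization}, \code{axis}, \code{output_dir} and \code{seed}.
#' Unknown keys are rejected (fail fast); referenced paths must exist.
#'
#' @param cfg a named list or a YAML file path.
#' @return the validated configuration list (class \code{run_config}).
#' @export
run_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg))
  chk <- function(block, name) {
    bad <- setdiff(names(block), .known_cfg_keys[[name]])
    if (length(bad))
      stop("unknown config key(s) in ", name, ": ",
           paste(bad, collapse = ", "))
  }
  chk(cfg, "top")
  for (b in intersect(names(cfg), names(.known_cfg_keys)[-1])) chk(cfg[[b]], b)
  if (is.null(cfg$input$type) ||
      !cfg$input$type %in% c("synthetic", "molden"))
    stop("input$type must be 'synthetic' or 'molden'")
  if (cfg$input$type == "molden") {
    if (is.null(cfg$input$path) || !file.exists(cfg$input$path))
      stop("input$path does not exist")
    if (!is.null(cfg$input$dipoles) && !file.exists(cfg$input$dipoles))
      stop("input$dipoles does not exist")
  }
  if (!is.null(cfg$input$params_file) && !file.exists(cfg$input$params_file))
    stop("input$params_file does not exist")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (cfg$seed != round(cfg$seed)) stop("seed must be an integer")
  if (is.null(cfg$output_dir)) stop("output_dir is required")
  if (is.null(cfg$window)) cfg$window <- list(lo = 1200, hi = 1400)
  if (is.null(cfg$polarization)) cfg$polarization <- "ZZZZ"
  if (is.null(cfg$axis)) cfg$axis <- list(lo = 1150, hi = 1450, step = 0.5)
  structure(cfg, class = c("run_config", "list"))
}

.cfg_model <- function(cfg) {
  inp <- cfg$input
  params <- if (!is.null(inp$params_file)) read_motif_params(inp$params_file)
            else default_motif_params()
  conf <- peptide_conformer(
    phi = inp$phi, psi = inp$psi,
    omega = if (is.null(inp$omega)) 180 else inp$omega,
    n_residues = if (is.null(inp$n_residues)) 1L else inp$n_residues,
    motif = if (is.null(inp$motif)) "other" else inp$motif
  )
  chains <- if (is.null(inp$chains)) 1L else as.integer(inp$chains)
  if (identical(inp$model, "dipeptide"))
    build_dipeptide_model(conf, params, seed = cfg$seed)
  else
    build_polyalanine_model(conf, params, seed = cfg$seed, chains = chains)
}

#' Run the full pipeline from a configuration
#'
#' Executes input preparation, window selection, localization, VSCF, VCI
#' and 1D/2D spectrum calculation in order, writing every intermediate
#' (selected-mode summary, coupling matrix CSV, model JSON, state table
#' TSV, 1D TSV, 2D triplets + JSON) into \code{output_dir} plus a
#' \code{manifest.json} with the config echo, package version, per-stage
#' wall-clock notes and MD5 digests of every artifact.  Identical
#' configuration and seed give bit-identical artifacts (equal digests).
#' Stage failures abort with the stage name attached to the condition
#' (classes \code{amideIR_stage_error}).
#'
#' @param cfg a [run_config()] (list or YAML path).
#' @return the manifest, invisibly (class \code{run_manifest}).
#' @export
run_pipeline <- function(cfg) {
  cfg <- run_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  # digest the scientific configuration only: where the artifacts land (or
  # the log level) must not change their content
  sci <- unclass(cfg)
  sci$output_dir <- NULL
  sci$log_level <- NULL
  cfg_json <- jsonlite::toJSON(sci, digits = NA, auto_unbox = TRUE)
  digest <- .digest_string(as.character(cfg_json))
  hdr <- c(paste("config:", digest),
           paste("amideIR", as.character(utils::packageVersion("amideIR"))))
  stages <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      if (inherits(e, "amideIR_stage_error")) stop(e)
      .stop_stage(name, conditionMessage(e))
    })
    stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  out <- function(f) file.path(cfg$output_dir, f)

  # ---- input + localization ------------------------------------------
  prepared <- t_stage("input", {
    if (cfg$input$type == "synthetic") {
      model <- .cfg_model(cfg)
      list(model = model, modes = as_normal_modes(model))
    } else {
      modes <- read_molden(cfg$input$path, cfg$input$dipoles)
      list(model = NULL, modes = modes)
    }
  })
  subset <- t_stage("select_window",
    select_window(prepared$modes, cfg$window$lo, cfg$window$hi))
  basis <- t_stage("localize", {
    loc <- cfg$localization
    localize(subset,
             max_sweeps = if (is.null(loc$max_sweeps)) 100 else loc$max_sweeps,
             tol = if (is.null(loc$tol)) 1e-10 else loc$tol)
  })
  model <- t_stage("model", {
    if (!is.null(prepared$model)) prepared$model
    else {
      sh <- cfg$input$anharmonic_shift
      model_from_basis(basis, if (is.null(sh)) 10 else sh)
    }
  })
  write_coupling_csv(model$coupling, out("coupling.csv"), header = hdr)
  write_coupling_csv(basis$coupling, out("coupling_localized.csv"),
                     header = hdr)
  write_model_json(model, out("model.json"))

  # ---- anharmonic ----------------------------------------------------
  vci_cfg <- cfg$vci
  gv <- function(key, default)
    if (is.null(vci_cfg[[key]])) default else vci_cfg[[key]]
  scf <- t_stage("vscf", vscf(model, n_basis = gv("n_basis", 10)))
  states <- t_stage("vci", vci_sd(model, vscf = scf,
                                  n_basis = gv("n_basis", 10),
                                  max_quanta = gv("max_quanta", 4),
                                  max_level = gv("max_level", 2),
                                  config_cap = gv("config_cap", 20000)))
  write_state_table(states, out("states.tsv"), header = hdr)

  # ---- spectra -------------------------------------------------------
  ls_cfg <- t_stage("lineshape", {
    l <- cfg$lineshape
    lineshape_config(T2 = if (is.null(l$T2)) 1 else l$T2,
                     t2 = if (is.null(l$t2)) 0 else l$t2)
  })
  axis <- seq(cfg$axis$lo, cfg$axis$hi, by = cfg$axis$step)
  sp1 <- t_stage("ir_1d", ir_1d(states, ls_cfg, axis))
  write_spectrum1d(sp1, out("spectrum1d.tsv"), header = hdr)
  sp2 <- t_stage("spectrum_2dir",
    spectrum_2dir(states, ls_cfg, pol = cfg$polarization,
                  pump = axis, probe = axis))
  write_spectrum2d(sp2, out("spectrum2d.dat"), json = out("spectrum2d.json"),
                   header = hdr)

  files <- c("coupling.csv", "coupling_localized.csv", "model.json",
             "states.tsv", "spectrum1d.tsv", "spectrum2d.dat",
             "spectrum2d.json")
  manifest <- list(
    config = unclass(cfg), config_digest = digest,
    version = as.character(utils::packageVersion("amideIR")),
    stages = stages,
    digests = as.list(tools::md5sum(file.path(cfg$output_dir, files)))
  )
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(structure(manifest, class = c("run_manifest", "list")))
}

#' Coupling-matrix statistics and spectra over a Ramachandran grid
#'
#' Runs the synthetic-model stage per conformer of a grid, collects the
#' per-conformer coupling matrices, their entrywise mean/SD (the
#' motif-statistics analysis) and an overlay-ready bundle of anharmonic 1D
#' spectra.  Per-conformer failures are recorded and the study continues;
#' a single-conformer grid yields spectra but records the sample-SD error.
#'
#' @param grid a [ramachandran_grid()].
#' @param params a [motif_params()] table.
#' @param seed integer seed (each conformer uses \code{seed}; draws are
#'   keyed structurally, conformers differ through the deterministic
#'   \eqn{(\phi, \psi)} dependence and the per-conformer offset).
#' @param lineshape a [lineshape_config()].
#' @param axis wavenumber axis for the 1D spectra.
#' @param spectra compute per-conformer VCI + 1D spectra (default TRUE).
#' @return a list with \code{coupling_matrices}, \code{statistics} (or
#'   \code{NULL} with the error under \code{errors$statistics}),
#'   \code{spectra}, \code{errors}, \code{grid}.
#' @export
grid_study <- function(grid, params = default_motif_params(), seed = 1L,
                       lineshape = lineshape_config(),
                       axis = seq(1150, 1450, by = 0.5), spectra = TRUE) {
  stopifnot(inherits(grid, "ramachandran_grid") || is.data.frame(grid))
  n <- nrow(grid)
  mats <- vector("list", n)
  specs <- if (spectra) vector("list", n) else NULL
  errors <- list(conformers = list(), statistics = NULL)
  for (i in seq_len(n)) {
    res <- tryCatch({
      conf <- .grid_conformer(grid, i)
      model <- build_polyalanine_model(conf, params, seed = seed + i - 1L)
      mats[[i]] <- model$coupling
      if (spectra) {
        st <- vci_sd(model)
        specs[[i]] <- ir_1d(st, lineshape, axis)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res))
      errors$conformers[[as.character(i)]] <- res
  }
  ok <- !vapply(mats, is.null, logical(1))
  stats <- tryCatch(motif_statistics(mats[ok]),
                    error = function(e) {
                      errors$statistics <<- conditionMessage(e)
                      NULL
                    })
  list(coupling_matrices = mats, statistics = stats, spectra = specs,
       errors = errors, grid = grid)
}
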