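# End-to-end design workflow: grid -> field -> reduced-alphabet QUBO ->
# solve -> decode -> full-alphabet refinement, with provenance and a
# term-by-term energy report.

#' Design run configuration
#'
#' All tunables with their defaults. `A = 20` and `w = A` are the
#' validation-scale settings; `A = "auto"` raises the penalty above the
#' total soft-coefficient mass, which is advisable whenever the raw
#' lattice-scale repulsions are large. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return A list of class `design_config`.
#' @export
design_config <- function(...) {
  cfg <- list(
    spacing = 3.8, include_radius = 7.6, exclude_radius = 1.5,
    cutoff = 8.5, lambda_scale = 0.159, e0 = -2.27,
    A = 20, w = NULL, p = NULL, L0 = 10, D = 5,
    ablate_E0 = FALSE, Nc = NULL,
    solver = "sa", n_runs = 20, sweeps = 3000, seed = 1,
    refine = TRUE, refine_runs = 20, refine_sweeps = 2000,
    contact_table = NULL, residue_table = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "design_config")
}

#' Read / write a design configuration as JSON
#' @param cfg a `design_config`; @param path file path.
#' @export
write_config_json <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  do.call(design_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full design workflow
#'
#' Stage 1 jointly optimizes the lattice pose and the reduced-alphabet
#' sequence; stage 2 freezes the best valid geometry and refines the
#' sequence over all 20 residues. Fails with a stage-named diagnostic when
#' a stage cannot proceed.
#'
#' @param receptor a [receptor()] (or PDB path).
#' @param reference reference-region coordinates (`m x 3`).
#' @param endpoints `2 x 3` anchor endpoint coordinates.
#' @param config a [design_config()].
#' @return List of class `design_result`: `grid`, `field`, `model`
#'   (clustered), `qubo`, `spectrum`, `chain` (best valid decode),
#'   `family_sequence`, `sequence` (refined residues), `energies`
#'   (term-by-term breakdown), `config`.
#' @export
run_design <- function(receptor, reference, endpoints, config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  if (is.character(receptor)) receptor <- read_receptor_pdb(receptor)
  if (config$D >= 11)
    warning("stage-1 family count D = ", config$D,
            " exceeds the recommended range (5 <= D <= 10)")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  full <- stage("model", mj_model(contact_table = config$contact_table,
                                  residue_table = config$residue_table,
                                  lambda_scale = config$lambda_scale,
                                  e0 = config$e0, cutoff = config$cutoff))
  cmodel <- stage("cluster", cluster_model(full, config$D, seed = config$seed))
  grid <- stage("grid", build_grid(receptor, reference, endpoints,
                                   spacing = config$spacing,
                                   include_radius = config$include_radius,
                                   exclude_radius = config$exclude_radius))
  field <- stage("field", external_field(grid, receptor, cmodel,
                                         Nc = config$Nc))
  qubo <- stage("encode", assemble(grid, field, cmodel, L0 = config$L0,
                                   A = config$A, w = config$w, p = config$p,
                                   ablate_E0 = config$ablate_E0))
  spectrum <- stage("solve", if (identical(config$solver, "chains"))
    chain_enumeration(qubo) else
    solve_qubo(qubo, backend = config$solver, n_runs = config$n_runs,
               sweeps = config$sweeps, seed = config$seed))
  chain <- stage("decode", {
    best <- NULL
    for (r in order(spectrum$energies)) {
      d <- decode(spectrum$states[r, ], qubo$registry, grid)
      if (d$flags$valid_path) { best <- d; break }
    }
    if (is.null(best))
      stop("no valid chain among ", length(spectrum$energies),
           " solver runs; increase sweeps/n_runs or the penalty A")
    best
  })
  seq20 <- NULL; refined <- NULL
  if (isTRUE(config$refine)) {
    refined <- stage("refine", {
      prob <- build_refinement(chain, grid, receptor, full,
                               Nc = if (is.null(config$Nc)) field$Nc else
                                 config$Nc)
      refine_sequence(prob, method = if (length(chain$path) <= 4)
        "exhaustive" else "anneal",
        n_runs = config$refine_runs, sweeps = config$refine_sweeps,
        seed = config$seed)
    })
    seq20 <- refined$sequence
  }
  energies <- list(
    stage1_qubo = min(spectrum$energies),
    stage1_chain = chain_energy(chain, field, cmodel, grid,
                                ablate_E0 = config$ablate_E0),
    stage2 = if (!is.null(refined)) refined$energy else NA_real_,
    Nc = field$Nc)
  structure(list(grid = grid, field = field, model = cmodel, qubo = qubo,
                 spectrum = spectrum, chain = chain,
                 family_sequence = cmodel$codes[chain$sequence],
                 sequence = seq20, energies = energies, config = config),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result>\n")
  cat("  grid:", nrow(x$grid$sites), "sites | Nc =",
      format(x$energies$Nc, digits = 3), "\n")
  cat("  chain:", length(x$chain$path), "residues (",
      x$chain$length, "bonds )\n")
  cat("  families:", paste(x$family_sequence, collapse = "-"), "\n")
  if (!is.null(x$sequence))
    cat("  refined :", paste(x$sequence, collapse = ""),
        "| E =", format(x$energies$stage2, digits = 4), "kBT\n")
  invisible(x)
}

#' Write design outputs (FASTA + JSON report + chain PDB)
#'
#' @param result a `design_result`; @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_design_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$sequence))
    write_fasta(paste(result$sequence, collapse = ""),
                file.path(dir, "designed.fasta"), names = "designed_peptide")
  write_beads_pdb(if (!is.null(result$sequence)) result$sequence else
    rep("G", length(result$chain$path)),
    result$chain$coords, file.path(dir, "chain.pdb"))
  report <- list(
    config = unclass(result$config),
    grid = list(n_sites = nrow(result$grid$sites),
                n_edges = nrow(result$grid$edges),
                s_index = result$grid$s_index, t_index = result$grid$t_index),
    Nc = result$energies$Nc,
    family_sequence = result$family_sequence,
    sequence = result$sequence,
    energies = result$energies[c("stage1_qubo", "stage1_chain", "stage2")])
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
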