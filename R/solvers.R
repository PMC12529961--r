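# Ground-state search: exhaustive enumeration (the correctness oracle for
# everything else), seeded simulated annealing, and MEV spectrum summaries.
# External backends plug in through solve_qubo()'s function contract.

#' Exhaustive ground-state search
#'
#' Enumerates every bitstring by Gray code and returns the exact ground
#' energy with all attaining states. Intended as a correctness oracle on
#' tiny instances; refuses models above `max_vars`.
#'
#' @param model a `qubo_model`.
#' @param max_vars refusal bound (default 22).
#' @param tol degeneracy tolerance on the ground energy (default 1e-9).
#' @return List of class `bf_result`: `energy`, `states` (0/1 matrix, one
#'   ground state per row, deterministic order), `energies`.
#' @export
brute_force <- function(model, max_vars = 22, tol = 1e-9) {
  n <- model$registry$n_vars
  if (n > max_vars)
    stop(n, " variables exceed the exhaustive bound (", max_vars,
         "); use simulated_annealing() or raise max_vars")
  out <- bf_ground_cpp(n, model$linear, model$quad$i - 1L, model$quad$j - 1L,
                       model$quad$v, model$offset, tol, 200000L)
  structure(list(energy = out$energy, states = out$states,
                 energies = out$energies, solver = "brute_force"),
            class = "bf_result")
}

#' Seeded simulated annealing
#'
#' Single-spin Metropolis sweeps in fixed variable order under a geometric
#' inverse-temperature schedule, auto-scaled from the coefficient
#' magnitudes (hot acceptance ~0.8 on a typical move, cold ~0.01 on the
#' smallest move). Fully reproducible for a given seed.
#'
#' @param model a `qubo_model`.
#' @param n_runs independent restarts (default 20).
#' @param sweeps Metropolis sweeps per run (default 2000).
#' @param seed integer seed.
#' @param beta_range optional `c(beta_hot, beta_cold)` override.
#' @return Object of class `qubo_spectrum`: `energies` (best-of-trajectory
#'   per run), `states` (matrix), `solver`, `seed`, plus decoded sequences
#'   when the model carries a grid (filled by [decode()] on demand).
#' @export
simulated_annealing <- function(model, n_runs = 20, sweeps = 2000, seed = 1,
                                beta_range = NULL) {
  stopifnot(n_runs >= 1, sweeps >= 1)
  n <- model$registry$n_vars
  if (is.null(beta_range)) {
    # per-variable total field bounds the single-flip energy change
    fmax <- abs(model$linear)
    if (nrow(model$quad)) {
      for (r in seq_len(nrow(model$quad))) {
        fmax[model$quad$i[r]] <- fmax[model$quad$i[r]] + abs(model$quad$v[r])
        fmax[model$quad$j[r]] <- fmax[model$quad$j[r]] + abs(model$quad$v[r])
      }
    }
    dmax <- max(fmax, 1e-9)
    dmin <- max(min(fmax[fmax > 0], dmax), 1e-9)
    beta_range <- c(-log(0.8) / dmax, -log(0.01) / dmin)
  }
  out <- sa_cpp(n, model$linear, model$quad$i - 1L, model$quad$j - 1L,
                model$quad$v, model$offset, as.integer(n_runs),
                as.integer(sweeps), beta_range[1], beta_range[2],
                as.numeric(seed))
  structure(list(energies = as.numeric(out$energies), states = out$states,
                 solver = "sa", seed = seed, sweeps = sweeps,
                 model = model), class = "qubo_spectrum")
}

#' Solve a QUBO with a pluggable backend
#'
#' `backend` is either one of the built-in labels or a function
#' `function(model, ...)` returning a list with `energies` and `states` —
#' the contract external solvers (branch-and-bound packages, annealing
#' hardware) must satisfy. Built-ins: `"sa"`, `"brute_force"`.
#'
#' @param model a `qubo_model`; @param backend label or function;
#' @param ... passed through to the backend.
#' @return A `qubo_spectrum` (or `bf_result` for the exact backend).
#' @export
solve_qubo <- function(model, backend = "sa", ...) {
  if (is.function(backend)) {
    out <- backend(model, ...)
    stopifnot(is.list(out), !is.null(out$energies), !is.null(out$states))
    return(structure(c(out, list(model = model)), class = "qubo_spectrum"))
  }
  switch(backend,
         sa = simulated_annealing(model, ...),
         chains = chain_enumeration(model, ...),
         brute_force = brute_force(model, ...),
         stop("unknown backend: ", backend))
}

#' Spectrum summary statistics
#'
#' @param spectrum a `qubo_spectrum` (or any list with `energies` and
#'   optionally decoded `sequences`).
#' @return List: `lowest`, `mean`, `n_runs`, `n_distinct` (distinct decoded
#'   sequences when available, else distinct bitstrings).
#' @export
spectrum_stats <- function(spectrum) {
  e <- spectrum$energies
  if (!length(e)) stop("empty spectrum")
  keys <- if (!is.null(spectrum$sequences)) {
    vapply(spectrum$sequences, paste, "", collapse = "")
  } else if (!is.null(spectrum$states)) {
    apply(spectrum$states, 1, paste, collapse = "")
  } else as.character(e)
  list(lowest = min(e), mean = mean(e), n_runs = length(e),
       n_distinct = length(unique(keys)))
}

#' @export
print.qubo_spectrum <- function(x, ...) {
  s <- spectrum_stats(x)
  cat("<qubo_spectrum>", s$n_runs, "runs | lowest", format(s$lowest),
      "| mean", format(s$mean), "| distinct", s$n_distinct, "\n")
  invisible(x)
}

#' Write a spectrum as CSV (run, energy, sequence)
#' @param spectrum a `qubo_spectrum`; @param path output file.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  seqs <- if (!is.null(spectrum$sequences))
    vapply(spectrum$sequences, paste, "", collapse = "") else NA
  df <- data.frame(run = seq_along(spectrum$energies),
                   energy = spectrum$energies, sequence = seqs)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
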