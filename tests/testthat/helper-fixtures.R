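# Shared fixture builders. Everything is generated in code; no data files.

# Single-family toy model whose LJ minimum sits exactly at the lattice
# spacing, so nearest-neighbour contacts are attractive (HP-model flavour).
toy_model_1 <- function(eps = -1, spacing = 3.8, cutoff = 8.5) {
  pair_model(matrix(eps, 1, 1, dimnames = list("F1", "F1")),
             c(F1 = spacing / 2^(1 / 6)), c(F1 = 1), cutoff = cutoff)
}

# Two-family toy model (hydrophobic-like F1, polar-like F2).
toy_model_2 <- function(spacing = 3.8, cutoff = 8.5) {
  eps <- matrix(c(-1, -0.3, -0.3, 0.1), 2, 2,
                dimnames = list(c("F1", "F2"), c("F1", "F2")))
  s <- spacing / 2^(1 / 6)
  pair_model(eps, c(F1 = s, F2 = s), c(F1 = 0.3, F2 = 0.7), cutoff = cutoff)
}

# Synthetic external field over a grid for a given model (seeded).
toy_field <- function(grid, model, seed = 1, lo = -3, hi = 0, Nc = 1) {
  set.seed(seed)
  D <- length(model$codes)
  E <- matrix(runif(nrow(grid$sites) * D, lo, hi), nrow(grid$sites), D,
              dimnames = list(NULL, model$codes))
  structure(list(E = E, E0 = mean_field_offset(NULL, Nc, model),
                 Nc = Nc, types = model$codes), class = "external_field")
}

# Line/box grid with anchors at opposite corners.
anchored_grid <- function(dims, spacing = 3.8) {
  g <- lattice_grid(dims, spacing)
  g$s_index <- 1L
  g$t_index <- nrow(g$sites)
  g
}

# Standalone random QUBO (not tied to any grid) for solver/Ising tests.
make_random_qubo <- function(n, seed = 1, density = 0.5, scale = 1) {
  set.seed(seed)
  registry <- structure(list(n_sites = NA, n_edges = NA, D = NA,
                             names = paste0("q", seq_len(n)), n_vars = n,
                             edges = matrix(integer(), 0, 2)),
                        class = "var_registry")
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(), 2, 0)
  keep <- runif(ncol(pairs)) < density
  structure(list(registry = registry,
                 linear = runif(n, -scale, scale),
                 quad = data.frame(i = pairs[1, keep], j = pairs[2, keep],
                                   v = runif(sum(keep), -scale, scale)),
                 offset = runif(1, -1, 1), params = list()),
            class = "qubo_model")
}

# All bitstrings over n variables (rows), n <= 20.
all_bits <- function(n) as.matrix(expand.grid(rep(list(0:1), n)))

# Independent self-avoiding s-t path oracle: plain recursive enumeration
# over the grid adjacency, no pruning, no shared code with the package's
# chain solver.
oracle_st_paths <- function(grid, n_bonds) {
  n <- nrow(grid$sites)
  adj <- vector("list", n)
  for (r in seq_len(nrow(grid$edges))) {
    i <- grid$edges[r, 1]; j <- grid$edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == grid$t_index) {
      if (length(path) == n_bonds + 1) out[[length(out) + 1]] <<- path
      return()
    }
    if (length(path) > n_bonds) return()
    for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
  }
  walk(grid$s_index)
  out
}

# Independent physical energy of a chain: field terms plus nonbonded pair
# interactions between non-consecutive positions, straight from the
# definitions (pair_potential is the shared primitive under test elsewhere).
oracle_chain_energy <- function(path, fams, grid, field, model,
                                ablate_E0 = FALSE) {
  e <- 0
  for (p in seq_along(path)) {
    e <- e + field$E[path[p], fams[p]]
    if (!ablate_E0) e <- e - field$E0[fams[p]]
  }
  np <- length(path)
  if (np > 2) {
    for (p in 1:(np - 2)) for (q in (p + 2):np) {
      r <- sqrt(sum((grid$sites[path[p], ] - grid$sites[path[q], ])^2))
      if (r < model$cutoff)
        e <- e + pair_potential(model$codes[fams[p]], model$codes[fams[q]],
                                r, model)
    }
  }
  unname(e)
}
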