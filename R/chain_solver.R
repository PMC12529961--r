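# Exact feasible-sector solver: enumerate every self-avoiding s-t path in a
# bond-count window (depth-first search pruned by graph distance and lattice
# parity), score every family assignment by evaluating the QUBO itself, and
# return the best states. When the penalty A dominates the soft terms, the
# optimum over this sector is the exact ground state of the full Hamiltonian
# (all penalty terms vanish on encoded chains), without any stochastic
# search. Complements simulated_annealing(): exact but only viable while the
# path count stays modest.

#' Enumerate self-avoiding s-t paths
#'
#' All simple paths from the grid's `s` anchor to `t` whose bond count lies
#' in `[min_len, max_len]`. The search prunes branches that cannot reach
#' `t` within the remaining budget (breadth-first distances from `t`, plus
#' bipartite-lattice parity).
#'
#' @param grid a `pocket_grid` with anchors set.
#' @param min_len,max_len bond-count window.
#' @param max_paths safety bound (error beyond it).
#' @return List of integer site-index vectors (each a path s..t).
#' @export
enumerate_st_paths <- function(grid, min_len, max_len, max_paths = 200000) {
  s <- grid$s_index; t <- grid$t_index
  stopifnot(!is.na(s), !is.na(t))
  adj <- grid_adjacency(grid)
  n <- nrow(grid$sites)
  dist_t <- rep(Inf, n)  # BFS distance from t
  dist_t[t] <- 0
  queue <- t
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.infinite(dist_t[w])) {
      dist_t[w] <- dist_t[v] + 1; queue <- c(queue, w)
    }
  }
  paths <- list()
  visited <- logical(n)
  path <- integer(max_len + 1)
  rec <- function(v, depth) {  # depth = bonds used so far
    if (v == t) {
      if (depth >= min_len) {
        paths[[length(paths) + 1]] <<- path[seq_len(depth + 1)]
        if (length(paths) > max_paths)
          stop("more than ", max_paths, " paths; narrow the length window")
      }
      return()
    }
    rem <- max_len - depth
    if (dist_t[v] > rem || (rem - dist_t[v]) %% 2 != 0) return()
    for (w in adj[[v]]) {
      if (visited[w]) next
      visited[w] <<- TRUE
      path[depth + 2] <<- w
      rec(w, depth + 1)
      visited[w] <<- FALSE
    }
  }
  visited[s] <- TRUE
  path[1] <- s
  rec(s, 0L)
  paths
}

#' Exact chain-space solver
#'
#' Scores every admissible chain (path x family assignment) by evaluating
#' the assembled QUBO on its encoding and returns the `keep` best states as
#' a spectrum. The default window is the exact target length `L0`; widen it
#' (e.g. to the band `L0(1-p) .. L0(1+p)` of the chain-length term) when
#' the stiffness `w` admits length fluctuations — out-of-target lengths are
#' scored including their chain-length penalty, so the returned optimum is
#' exact over the window.
#'
#' @param model an assembled `qubo_model` (must carry its grid).
#' @param min_len,max_len bond-count window (default both `L0`).
#' @param keep number of best states to return (default 10).
#' @param max_paths forwarded to [enumerate_st_paths()].
#' @return A `qubo_spectrum` with exact energies, best first; attribute
#'   `n_chains` records the number of configurations scored.
#' @export
chain_enumeration <- function(model, min_len = NULL, max_len = NULL,
                              keep = 10, max_paths = 200000) {
  grid <- model$grid
  if (is.null(grid)) stop("model carries no grid; assemble() it first")
  L0 <- model$params$L0
  if (is.null(min_len)) min_len <- L0
  if (is.null(max_len)) max_len <- L0
  D <- model$registry$D
  paths <- enumerate_st_paths(grid, min_len, max_len, max_paths)
  if (!length(paths)) stop("no s-t path with the requested length window")
  best_e <- numeric(0); best_bits <- NULL
  n_scored <- 0
  for (p in paths) {
    npos <- length(p)
    assigns <- as.matrix(expand.grid(rep(list(seq_len(D)), npos)))
    bits <- matrix(0L, nrow(assigns), model$registry$n_vars)
    base <- encode_chain(p, rep(1L, npos), model$registry)
    bond_cols <- which(base == 1L)
    bond_cols <- bond_cols[bond_cols %in% model$registry$bond_idx]
    bits[, bond_cols] <- 1L
    for (pos in seq_len(npos)) {
      for (k in seq_len(D))
        bits[assigns[, pos] == k, model$registry$site_idx[p[pos], k]] <- 1L
    }
    # ancillas: for each path edge, copy the family bit of the lower endpoint
    edge_key <- paste(model$registry$edges[, 1], model$registry$edges[, 2],
                      sep = ",")
    for (q in seq_len(npos - 1)) {
      i <- min(p[q], p[q + 1]); j <- max(p[q], p[q + 1])
      e <- match(paste(i, j, sep = ","), edge_key)
      ipos <- if (p[q] == i) q else q + 1
      for (k in seq_len(D))
        bits[, model$registry$anc_idx[e, k]] <-
          as.integer(assigns[, ipos] == k)
    }
    e <- qubo_energy(model, bits)
    n_scored <- n_scored + length(e)
    ord <- order(e)[seq_len(min(keep, length(e)))]
    best_e <- c(best_e, e[ord])
    best_bits <- rbind(best_bits, bits[ord, , drop = FALSE])
    sel <- order(best_e)[seq_len(min(keep, length(best_e)))]
    best_e <- best_e[sel]
    best_bits <- best_bits[sel, , drop = FALSE]
  }
  structure(list(energies = best_e, states = best_bits,
                 solver = "chains", seed = NA, model = model,
                 n_chains = n_scored),
            class = "qubo_spectrum")
}
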