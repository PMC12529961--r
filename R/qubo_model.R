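# Design Hamiltonian over binary variables: site occupation q_i^(k), bond
# q_ij, and ancilla q_ij^(k) (ancilla attached to the lower-indexed endpoint
# of each edge, encoding "type-k residue at i is bonded across {i,j}").
# Terms accumulate as sparse triplets and merge additively at assembly.

#' Variable registry for a grid and family count
#'
#' Index layout: site variables first (`site_idx[i, k]`), then bond
#' variables per edge, then ancilla variables per (edge, family). The total
#' count is `n_sites * D + n_edges + n_edges * D`.
#'
#' @param grid a `pocket_grid`; @param D family count.
#' @return Object of class `var_registry` with index arrays, variable
#'   names, and the originating grid dimensions.
#' @export
variable_registry <- function(grid, D) {
  n <- nrow(grid$sites); m <- nrow(grid$edges)
  site_idx <- matrix(seq_len(n * D), n, D)
  bond_idx <- n * D + seq_len(m)
  anc_idx <- if (m > 0) matrix(n * D + m + seq_len(m * D), m, D) else
    matrix(integer(), 0, D)
  names <- character(n * D + m + m * D)
  for (k in seq_len(D)) names[site_idx[, k]] <- sprintf("s%d.k%d", seq_len(n), k)
  if (m > 0) {
    names[bond_idx] <- sprintf("b%d.%d", grid$edges[, 1], grid$edges[, 2])
    for (k in seq_len(D))
      names[anc_idx[, k]] <- sprintf("a%d.%d.k%d", grid$edges[, 1],
                                     grid$edges[, 2], k)
  }
  structure(list(n_sites = n, n_edges = m, D = D, site_idx = site_idx,
                 bond_idx = bond_idx, anc_idx = anc_idx, names = names,
                 n_vars = length(names), edges = grid$edges),
            class = "var_registry")
}

# --- term accumulator -------------------------------------------------------

new_terms <- function(registry) {
  structure(list(registry = registry, linear = numeric(registry$n_vars),
                 qi = integer(), qj = integer(), qv = numeric(),
                 offset = 0), class = "qubo_terms")
}

add_quad <- function(tm, i, j, v) {
  if (!length(i)) return(tm)
  if (any(i == j)) stop("self-pair in quadratic term")
  lo <- pmin(i, j); hi <- pmax(i, j)
  tm$qi <- c(tm$qi, lo); tm$qj <- c(tm$qj, hi); tm$qv <- c(tm$qv, v)
  tm
}

# (c + sum a_l q_l)^2 expanded with q^2 = q.
add_square <- function(tm, idx, a, c) {
  tm$offset <- tm$offset + c^2
  tm$linear[idx] <- tm$linear[idx] + a^2 + 2 * c * a
  if (length(idx) > 1) {
    pr <- utils::combn(seq_along(idx), 2)
    tm <- add_quad(tm, idx[pr[1, ]], idx[pr[2, ]], 2 * a[pr[1, ]] * a[pr[2, ]])
  }
  tm
}

merge_terms <- function(...) {
  parts <- list(...)
  out <- parts[[1]]
  for (p in parts[-1]) {
    stopifnot(identical(p$registry$n_vars, out$registry$n_vars))
    out$linear <- out$linear + p$linear
    out$qi <- c(out$qi, p$qi); out$qj <- c(out$qj, p$qj)
    out$qv <- c(out$qv, p$qv)
    out$offset <- out$offset + p$offset
  }
  out
}

# --- Hamiltonian terms ------------------------------------------------------

#' External-field term
#'
#' Linear coefficients `E_i^(k) - E0^(k)` on each site variable; the
#' mean-field offset can be ablated to reproduce the selectivity-off
#' variant of the design.
#'
#' @param field an [external_field()]; @param registry a [variable_registry()].
#' @param ablate_E0 drop the `E0` offset (default FALSE).
#' @return A `qubo_terms` partial model.
#' @export
external_term <- function(field, registry, ablate_E0 = FALSE) {
  stopifnot(inherits(field, "external_field"),
            nrow(field$E) == registry$n_sites,
            ncol(field$E) == registry$D)
  tm <- new_terms(registry)
  for (k in seq_len(registry$D)) {
    coef <- field$E[, k] - if (ablate_E0) 0 else field$E0[k]
    tm$linear[registry$site_idx[, k]] <-
      tm$linear[registry$site_idx[, k]] + coef
  }
  tm
}

#' Nonbonded intrachain term
#'
#' For every unordered site pair within the interaction cutoff and every
#' family pair (k, l), adds `u_kl(r_ij) q_i^(k) q_j^(l)`. For lattice-edge
#' pairs the bonded interaction is cancelled through the ancilla:
#' the factor `(q_i^(k) - q_ij^(k)) q_j^(l)` contributes an additional
#' `-u_kl(r_ij) q_ij^(k) q_j^(l)`, which is exactly zero net when residues
#' i and j are covalently bonded.
#'
#' @param grid a `pocket_grid`; @param model a `pair_model`;
#' @param registry a [variable_registry()].
#' @return A `qubo_terms` partial model.
#' @export
intrachain_term <- function(grid, model, registry) {
  stopifnot(length(model$codes) == registry$D)
  tm <- new_terms(registry)
  n <- registry$n_sites
  if (n < 2) return(tm)
  edge_key <- paste(grid$edges[, 1], grid$edges[, 2], sep = ",")
  edge_of <- setNames(seq_len(registry$n_edges), edge_key)
  D <- registry$D
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((grid$sites[i, ] - grid$sites[j, ])^2))
    if (r >= model$cutoff) next
    e <- edge_of[paste(i, j, sep = ",")]
    for (k in seq_len(D)) for (l in seq_len(D)) {
      u <- lj_piecewise(model$epsilon[k, l],
                        unname((model$sigma[k] + model$sigma[l]) / 2),
                        r, model$cutoff)
      if (u == 0) next
      tm <- add_quad(tm, registry$site_idx[i, k], registry$site_idx[j, l], u)
      if (!is.na(e))  # neighbor pair: ancilla cancels the bonded interaction
        tm <- add_quad(tm, registry$anc_idx[e, k], registry$site_idx[j, l], -u)
    }
  }
  tm
}

#' Ancilla consistency term
#'
#' Standard AND penalty `A (3 q_ij^(k) + q_i^(k) q_ij - 2 q_i^(k) q_ij^(k)
#' - 2 q_ij q_ij^(k))` per edge and family; minimum 0 attained exactly when
#' `q_ij^(k) = q_i^(k) AND q_ij` (i the lower-indexed endpoint).
#'
#' @param registry a [variable_registry()]; @param A penalty scale, > 0.
#' @return A `qubo_terms` partial model.
#' @export
ancilla_term <- function(registry, A) {
  stopifnot(A > 0)
  tm <- new_terms(registry)
  if (registry$n_edges == 0) return(tm)
  for (k in seq_len(registry$D)) {
    anc <- registry$anc_idx[, k]
    si <- registry$site_idx[registry$edges[, 1], k]
    bnd <- registry$bond_idx
    tm$linear[anc] <- tm$linear[anc] + 3 * A
    tm <- add_quad(tm, si, bnd, rep(A, length(anc)))
    tm <- add_quad(tm, si, anc, rep(-2 * A, length(anc)))
    tm <- add_quad(tm, bnd, anc, rep(-2 * A, length(anc)))
  }
  tm
}

#' Single-occupancy term
#'
#' `A q_i^(k) q_i^(l)` for every site and unordered family pair, so each
#' grid point holds at most one residue type.
#'
#' @inheritParams ancilla_term
#' @export
occupancy_term <- function(registry, A) {
  stopifnot(A > 0)
  tm <- new_terms(registry)
  D <- registry$D
  if (D < 2) return(tm)
  pr <- utils::combn(D, 2)
  for (p in seq_len(ncol(pr))) {
    tm <- add_quad(tm, registry$site_idx[, pr[1, p]],
                   registry$site_idx[, pr[2, p]], rep(A, registry$n_sites))
  }
  tm
}

#' Linear-topology (path) term
#'
#' Enforces a self-avoiding chain between the anchors: each terminal holds
#' exactly one residue with exactly one bond, and every other occupied site
#' has exactly two bonds:
#' `h_s = (1 - sum_k q_s^(k))^2 + (sum_k q_s^(k) - sum_j q_sj)^2` (and h_t
#' alike), `h_r = sum_{r != s,t} (2 sum_k q_r^(k) - sum_j q_rj)^2`.
#'
#' @param registry a [variable_registry()]; @param s,t anchor site indices;
#' @param A penalty scale.
#' @return A `qubo_terms` partial model.
#' @export
path_term <- function(registry, s, t, A) {
  stopifnot(A > 0, s != t, s >= 1, t >= 1,
            s <= registry$n_sites, t <= registry$n_sites)
  tm <- new_terms(registry)
  bonds_at <- lapply(seq_len(registry$n_sites), function(i)
    registry$bond_idx[registry$edges[, 1] == i | registry$edges[, 2] == i])
  for (v in c(s, t)) {
    svars <- registry$site_idx[v, ]
    part <- new_terms(registry)
    part <- add_square(part, svars, rep(-1, length(svars)), 1)
    part <- add_square(part, c(svars, bonds_at[[v]]),
                       c(rep(1, length(svars)), rep(-1, length(bonds_at[[v]]))),
                       0)
    part$linear <- part$linear * A; part$qv <- part$qv * A
    part$offset <- part$offset * A
    tm <- merge_terms(tm, part)
  }
  for (v in seq_len(registry$n_sites)) {
    if (v == s || v == t) next
    svars <- registry$site_idx[v, ]
    part <- new_terms(registry)
    part <- add_square(part, c(svars, bonds_at[[v]]),
                       c(rep(2, length(svars)), rep(-1, length(bonds_at[[v]]))),
                       0)
    part$linear <- part$linear * A; part$qv <- part$qv * A
    part$offset <- part$offset * A
    tm <- merge_terms(tm, part)
  }
  tm
}

#' Chain-length term
#'
#' `w (L0 - sum_edges q_ij)^2`: pins the bond count near `L0`. Setting
#' `w = A / (L0^2 p^2)` admits relative length fluctuations of order `p`,
#' i.e. chains in `[L0 (1 - p), L0 (1 + p)]`.
#'
#' @param registry a [variable_registry()]; @param L0 target bond count;
#' @param w stiffness weight, > 0.
#' @return A `qubo_terms` partial model.
#' @export
chain_length_term <- function(registry, L0, w) {
  stopifnot(L0 >= 1, w > 0)
  tm <- new_terms(registry)
  part <- add_square(new_terms(registry), registry$bond_idx,
                     rep(-1, registry$n_edges), L0)
  part$linear <- part$linear * w; part$qv <- part$qv * w
  part$offset <- part$offset * w
  merge_terms(tm, part)
}

#' Chain-length tolerance semantics
#'
#' Under `w = A / (L0^2 p^2)`, the admissible chain lengths are
#' `[L0 (1 - p), L0 (1 + p)]`. These helpers convert between the stiffness
#' `w` and the relative tolerance `p` and report the admissible bounds.
#'
#' @param L0 target bond count; @param p relative tolerance; @param A,w
#'   penalty/stiffness scales.
#' @return `chain_w_for_p`: the stiffness; `chain_p_for_w`: the tolerance;
#'   `chain_length_bounds`: `c(lower, upper) = L0 * (1 -+ p)`.
#' @export
chain_w_for_p <- function(L0, p, A) A / (L0^2 * p^2)

#' @rdname chain_w_for_p
#' @export
chain_p_for_w <- function(L0, w, A) sqrt(A / w) / L0

#' @rdname chain_w_for_p
#' @export
chain_length_bounds <- function(L0, p) c(lower = L0 * (1 - p),
                                         upper = L0 * (1 + p))

# --- assembly and conversion ------------------------------------------------

#' Assemble the full design Hamiltonian
#'
#' Merges external, intrachain, ancilla, occupancy, path and chain-length
#' terms over one registry into a single quadratic model. `A = "auto"`
#' chooses a penalty safely above the total soft-coefficient mass so hard
#' constraints dominate every soft term.
#'
#' @param grid a `pocket_grid` with anchors set; @param field an
#'   [external_field()]; @param model the `pair_model` used for intrachain
#'   couplings.
#' @param L0 target bond count.
#' @param A hard-constraint penalty (default 20) or `"auto"`.
#' @param w chain stiffness; defaults to `A`; alternatively give `p`.
#' @param p relative length tolerance; used when `w` is NULL as
#'   `w = A / (L0^2 p^2)`.
#' @param ablate_E0 drop the mean-field offset in the external term.
#' @return Object of class `qubo_model`: `registry`, `linear`, `quad`
#'   (data frame i, j, v with i < j, aggregated), `offset`, `params`.
#' @export
assemble <- function(grid, field, model, L0, A = 20, w = NULL, p = NULL,
                     ablate_E0 = FALSE) {
  if (is.na(grid$s_index) || is.na(grid$t_index))
    stop("grid anchors not set; call set_anchors() first")
  registry <- variable_registry(grid, length(model$codes))
  soft <- merge_terms(external_term(field, registry, ablate_E0),
                      intrachain_term(grid, model, registry))
  if (identical(A, "auto")) {
    # a single flip out of a feasible configuration can gain at most the
    # soft mass incident to that variable; any single constraint violation
    # then costs at least A > that gain
    inc <- abs(soft$linear)
    for (t in seq_along(soft$qv)) {
      inc[soft$qi[t]] <- inc[soft$qi[t]] + abs(soft$qv[t])
      inc[soft$qj[t]] <- inc[soft$qj[t]] + abs(soft$qv[t])
    }
    A <- max(1, 1.25 * max(inc))
  }
  if (is.null(w)) w <- if (is.null(p)) A else chain_w_for_p(L0, p, A)
  tm <- merge_terms(soft,
                    ancilla_term(registry, A),
                    occupancy_term(registry, A),
                    path_term(registry, grid$s_index, grid$t_index, A),
                    chain_length_term(registry, L0, w))
  finalize_qubo(tm, params = list(A = A, w = w, L0 = L0, D = registry$D,
                                  ablate_E0 = ablate_E0),
                grid = grid, types = model$codes)
}

finalize_qubo <- function(tm, params = list(), grid = NULL, types = NULL) {
  quad <- aggregate_quad(tm$qi, tm$qj, tm$qv, tm$registry$n_vars)
  structure(list(registry = tm$registry, linear = tm$linear, quad = quad,
                 offset = tm$offset, params = params, grid = grid,
                 types = types),
            class = "qubo_model")
}

aggregate_quad <- function(qi, qj, qv, n_vars) {
  if (!length(qi))
    return(data.frame(i = integer(), j = integer(), v = numeric()))
  key <- (qi - 1) * n_vars + qj
  v <- rowsum(qv, key)
  key_u <- as.numeric(rownames(v))
  i <- floor((key_u - 1) / n_vars) + 1
  j <- key_u - (i - 1) * n_vars
  keep <- abs(v[, 1]) > 0
  data.frame(i = as.integer(i[keep]), j = as.integer(j[keep]),
             v = unname(v[keep, 1]))
}

#' Convert a partial term to a standalone model (mostly for tests)
#' @param tm a `qubo_terms`; @param ... passed to finalize.
#' @export
as_qubo <- function(tm, ...) finalize_qubo(tm, ...)

#' @export
print.qubo_model <- function(x, ...) {
  cat("<qubo_model>", x$registry$n_vars, "variables,",
      nrow(x$quad), "quadratic terms, offset", format(x$offset), "\n")
  invisible(x)
}

#' Evaluate a QUBO model on bitstrings
#'
#' @param model a `qubo_model`; @param bits 0/1 vector (or matrix, one
#'   bitstring per row) over the registry.
#' @return Energy (vector) in kBT.
#' @export
qubo_energy <- function(model, bits) {
  if (is.vector(bits)) bits <- matrix(bits, 1)
  stopifnot(ncol(bits) == model$registry$n_vars)
  qubo_eval_cpp(model$registry$n_vars, model$linear,
                model$quad$i - 1L, model$quad$j - 1L, model$quad$v,
                model$offset, storage_as_int(bits))
}

storage_as_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' QUBO to Ising transformation
#'
#' Substitutes `q = (sigma + 1) / 2`, yielding
#' `H = offset + sum h_l sigma_l + sum_{l<m} J_lm sigma_l sigma_m` with
#' `H_Ising(2q - 1) = H_QUBO(q)` identically.
#'
#' @param model a `qubo_model`.
#' @return Object of class `ising_model`: `h`, `J` (data frame i, j, v),
#'   `offset`.
#' @export
to_ising <- function(model) {
  n <- model$registry$n_vars
  h <- model$linear / 2
  offset <- model$offset + sum(model$linear) / 2
  J <- model$quad
  if (nrow(J)) {
    for (r in seq_len(nrow(J))) {
      h[J$i[r]] <- h[J$i[r]] + J$v[r] / 4
      h[J$j[r]] <- h[J$j[r]] + J$v[r] / 4
    }
    offset <- offset + sum(J$v) / 4
    J$v <- J$v / 4
  }
  structure(list(h = h, J = J, offset = offset, registry = model$registry),
            class = "ising_model")
}

#' Evaluate an Ising model on spin configurations
#' @param model an `ising_model`; @param sigma vector/matrix of +-1 spins.
#' @export
ising_energy <- function(model, sigma) {
  if (is.vector(sigma)) sigma <- matrix(sigma, 1)
  e <- model$offset + as.vector(sigma %*% model$h)
  if (nrow(model$J))
    e <- e + as.vector((sigma[, model$J$i, drop = FALSE] *
                        sigma[, model$J$j, drop = FALSE]) %*% model$J$v)
  e
}

#' Binary-variable count for a full box
#'
#' For a full `Lx x Ly x Lz` cubic lattice with `D` families: the exact
#' registry count `sites * D + edges * (1 + D)` and the closed-form
#' estimate `Lx Ly Lz (4D + 3)`.
#'
#' @param Lx,Ly,Lz box dimensions in lattice units; @param D family count.
#' @return List with `exact` and `estimate`.
#' @export
variable_count <- function(Lx, Ly, Lz, D) {
  stopifnot(Lx >= 1, Ly >= 1, Lz >= 1, D >= 1)
  sites <- Lx * Ly * Lz
  edges <- (Lx - 1) * Ly * Lz + Lx * (Ly - 1) * Lz + Lx * Ly * (Lz - 1)
  list(exact = sites * D + edges * (1 + D), estimate = sites * (4 * D + 3))
}

#' Serialize a QUBO model to JSON
#' @param model a `qubo_model`; @param path output file.
#' @export
write_qubo_json <- function(model, path) {
  quad <- setNames(as.list(model$quad$v),
                   paste(model$quad$i, model$quad$j, sep = ","))
  lin <- model$linear
  nz <- which(lin != 0)
  jsonlite::write_json(
    list(variables = model$registry$names,
         linear = setNames(as.list(lin[nz]), model$registry$names[nz]),
         quadratic = quad, offset = model$offset, params = model$params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a JSON-serialized QUBO (registry names only; for external use)
#' @param path JSON file written by [write_qubo_json()].
#' @return A list with `variables`, `linear`, `quadratic`, `offset`, `params`.
#' @export
read_qubo_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
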