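# Decoding solver bitstrings into lattice peptides, and stage-2 sequence
# refinement over the full 20-letter alphabet on the frozen geometry.

#' Decode a bitstring into a lattice chain
#'
#' Builds the bond graph among occupied sites from the set bond variables,
#' extracts the component containing the anchor `s` by walking from `s`
#' along the unique unvisited bonded neighbor, and flags validity: the s-t
#' component must be a simple path ending at `t`, every occupied site must
#' carry exactly one family, and every ancilla must equal
#' `q_i^(k) AND q_ij`. Other bonded components are recorded as rings and
#' removed (a known artifact of the encoding); they do not invalidate the
#' chain.
#'
#' @param bits 0/1 vector over the registry.
#' @param registry a [variable_registry()].
#' @param grid the `pocket_grid` with anchors set.
#' @return Object of class `chain_decode`: `path` (site indices s..t),
#'   `sequence` (family index per position), `coords`, `length` (bond
#'   count), `flags` (`valid_path`, `had_rings`, `ring_components`,
#'   `diagnostic`).
#' @export
decode <- function(bits, registry, grid) {
  stopifnot(length(bits) == registry$n_vars)
  s <- grid$s_index; t <- grid$t_index
  D <- registry$D
  occ <- matrix(bits[registry$site_idx], registry$n_sites, D)
  n_fam <- rowSums(occ)
  bond_on <- which(bits[registry$bond_idx] == 1)
  adj <- vector("list", registry$n_sites)
  for (e in bond_on) {
    i <- registry$edges[e, 1]; j <- registry$edges[e, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  fail <- function(msg) structure(
    list(path = integer(), sequence = integer(), coords = NULL,
         length = 0L,
         flags = list(valid_path = FALSE, had_rings = FALSE,
                      ring_components = list(), diagnostic = msg)),
    class = "chain_decode")
  anc_ok <- TRUE
  if (registry$n_edges > 0) {
    for (k in seq_len(D)) {
      expect <- occ[registry$edges[, 1], k] * bits[registry$bond_idx]
      if (any(bits[registry$anc_idx[, k]] != expect)) { anc_ok <- FALSE; break }
    }
  }
  if (n_fam[s] == 0) return(fail("anchor s unoccupied"))
  # walk from s
  path <- s; prev <- 0L
  repeat {
    cur <- path[length(path)]
    nxt <- setdiff(adj[[cur]], prev)
    if (length(nxt) == 0) break
    if (length(nxt) > 1) return(fail(paste0("branch at site ", cur)))
    if (nxt %in% path) return(fail("s-t component contains a cycle"))
    prev <- cur
    path <- c(path, nxt)
    if (nxt == t) break
  }
  valid <- path[length(path)] == t &&
    length(adj[[s]]) == 1 && length(adj[[t]]) == 1 &&
    all(n_fam[path] == 1) && anc_ok
  diagnostic <- if (valid) "ok"
    else if (path[length(path)] != t) "walk from s does not reach t"
    else if (!anc_ok) "ancilla inconsistent with site/bond variables"
    else "occupancy inconsistent on the path"
  # components not touching the path: rings (and stray bonded fragments)
  seen <- logical(registry$n_sites); seen[path] <- TRUE
  rings <- list()
  for (v in seq_len(registry$n_sites)) {
    if (seen[v] || length(adj[[v]]) == 0) next
    comp <- v; queue <- v; seen[v] <- TRUE
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      for (wv in adj[[x]]) if (!seen[wv]) {
        seen[wv] <- TRUE; queue <- c(queue, wv); comp <- c(comp, wv)
      }
    }
    rings[[length(rings) + 1]] <- comp
  }
  orphans <- which(n_fam > 0 & !seen)
  structure(list(
    path = path,
    sequence = if (all(n_fam[path] == 1)) apply(
      occ[path, , drop = FALSE], 1, which.max) else integer(),
    coords = grid$sites[path, , drop = FALSE],
    length = length(path) - 1L,
    flags = list(valid_path = valid, had_rings = length(rings) > 0,
                 ring_components = rings, orphan_sites = orphans,
                 diagnostic = diagnostic)),
    class = "chain_decode")
}

#' @export
print.chain_decode <- function(x, ...) {
  cat("<chain_decode>", if (x$flags$valid_path) "valid" else
    paste0("INVALID (", x$flags$diagnostic, ")"),
    "| sites", length(x$path), "| bonds", x$length,
    if (x$flags$had_rings) "| rings removed" else "", "\n")
  invisible(x)
}

#' Physical energy of a decoded chain
#'
#' Independent of the QUBO machinery: sum of per-residue field terms
#' `E_i^(k) - E0^(k)` plus nonbonded intrachain pair interactions between
#' non-consecutive positions within the cutoff. Equals the QUBO energy of
#' the encoding bitstring for every valid chain (the constraint terms all
#' vanish there).
#'
#' @param chain a valid `chain_decode`; @param field an [external_field()];
#' @param model the `pair_model` used at assembly; @param grid the grid.
#' @param ablate_E0 must match the assembled model.
#' @return Energy in kBT.
#' @export
chain_energy <- function(chain, field, model, grid, ablate_E0 = FALSE) {
  stopifnot(chain$flags$valid_path)
  n <- length(chain$path)
  e <- 0
  for (p in seq_len(n)) {
    k <- chain$sequence[p]
    e <- e + field$E[chain$path[p], k] - if (ablate_E0) 0 else field$E0[k]
  }
  if (n > 2) {
    for (p in seq_len(n - 2)) for (q in (p + 2):n) {
      r <- sqrt(sum((grid$sites[chain$path[p], ] -
                     grid$sites[chain$path[q], ])^2))
      if (r >= model$cutoff) next
      k <- model$codes[chain$sequence[p]]; l <- model$codes[chain$sequence[q]]
      e <- e + pair_potential(k, l, r, model)
    }
  }
  unname(e)
}

#' Encode a chain back into a registry bitstring
#'
#' Inverse of [decode()] for valid chains; used by oracle tests.
#'
#' @param path site indices; @param families family index per position;
#' @param registry a [variable_registry()].
#' @return 0/1 vector.
#' @export
encode_chain <- function(path, families, registry) {
  bits <- integer(registry$n_vars)
  for (p in seq_along(path))
    bits[registry$site_idx[path[p], families[p]]] <- 1L
  edge_key <- paste(registry$edges[, 1], registry$edges[, 2], sep = ",")
  for (p in seq_len(length(path) - 1)) {
    i <- min(path[p], path[p + 1]); j <- max(path[p], path[p + 1])
    e <- match(paste(i, j, sep = ","), edge_key)
    if (is.na(e)) stop("consecutive path sites are not lattice neighbors")
    bits[registry$bond_idx[e]] <- 1L
  }
  # ancillas: q_ij^(k) = q_i^(k) AND q_ij (i the lower-indexed endpoint)
  for (e in which(bits[registry$bond_idx] == 1L)) {
    i <- registry$edges[e, 1]
    for (k in seq_len(registry$D))
      bits[registry$anc_idx[e, k]] <- bits[registry$site_idx[i, k]]
  }
  bits
}

#' Build the stage-2 refinement problem
#'
#' With the geometry frozen to a decoded chain, sequence refinement over
#' the full 20-letter alphabet needs only one-hot position variables
#' `q_n^(a)`: linear terms are the full-alphabet field at the path sites
#' (minus the mean-field offset), quadratic terms the nonbonded couplings
#' between non-consecutive positions within the cutoff, and an
#' exactly-one-per-position penalty `A (1 - sum_a q_n^(a))^2`.
#'
#' @param chain a valid `chain_decode`; @param grid the `pocket_grid`;
#' @param receptor the [receptor()]; @param model full-alphabet
#'   `pair_model`; @param A one-hot penalty or `"auto"`; @param Nc mean
#'   contact count for the offset (default: recomputed on the full grid).
#' @return A `qubo_model` whose registry is a position-by-residue one-hot
#'   layout (kind `"refine"`).
#' @export
build_refinement <- function(chain, grid, receptor, model, A = "auto",
                             Nc = NULL) {
  stopifnot(chain$flags$valid_path, is.null(model$map))
  n <- length(chain$path)
  codes <- model$codes
  nA <- length(codes)
  sub <- grid
  sub$sites <- grid$sites[chain$path, , drop = FALSE]
  sub$edges <- matrix(integer(), 0, 2)
  if (is.null(Nc)) Nc <- external_field(grid, receptor, model)$Nc
  fld <- external_field(sub, receptor, model, Nc = Nc)
  registry <- structure(list(
    n_sites = n, n_edges = 0L, D = nA,
    site_idx = matrix(seq_len(n * nA), n, nA),
    bond_idx = integer(), anc_idx = matrix(integer(), 0, nA),
    names = as.vector(outer(seq_len(n), codes,
                            function(p, a) sprintf("p%d.%s", p, a))),
    n_vars = n * nA, edges = matrix(integer(), 0, 2),
    kind = "refine"), class = "var_registry")
  tm <- new_terms(registry)
  soft_mass <- 0
  for (a in seq_len(nA)) {
    coef <- fld$E[, a] - fld$E0[a]
    tm$linear[registry$site_idx[, a]] <- coef
  }
  if (n > 2) {
    for (p in seq_len(n - 2)) for (q in (p + 2):n) {
      r <- sqrt(sum((sub$sites[p, ] - sub$sites[q, ])^2))
      if (r >= model$cutoff) next
      for (a in seq_len(nA)) for (b in seq_len(nA)) {
        u <- lj_piecewise(model$epsilon[a, b],
                          unname((model$sigma[a] + model$sigma[b]) / 2),
                          r, model$cutoff)
        if (u != 0)
          tm <- add_quad(tm, registry$site_idx[p, a],
                         registry$site_idx[q, b], u)
      }
    }
  }
  if (identical(A, "auto")) {
    soft_mass <- sum(abs(tm$linear)) + sum(abs(tm$qv))
    A <- max(1, 1.1 * soft_mass)
  }
  for (p in seq_len(n)) {
    part <- add_square(new_terms(registry), registry$site_idx[p, ],
                       rep(-1, nA), 1)
    part$linear <- part$linear * A; part$qv <- part$qv * A
    part$offset <- part$offset * A
    tm <- merge_terms(tm, part)
  }
  q <- finalize_qubo(tm, params = list(A = A, Nc = Nc, kind = "refine"),
                     grid = sub, types = codes)
  q$chain <- chain
  q
}

#' Decode a refinement bitstring into a residue sequence
#'
#' @param bits 0/1 vector over the refinement registry.
#' @param problem the `qubo_model` from [build_refinement()].
#' @return Character vector of residue codes, or NULL when one-hot is
#'   violated.
#' @export
decode_refinement <- function(bits, problem) {
  reg <- problem$registry
  occ <- matrix(bits[reg$site_idx], reg$n_sites, reg$D)
  if (any(rowSums(occ) != 1)) return(NULL)
  problem$types[apply(occ, 1, which.max)]
}

#' Refine a sequence on the frozen geometry
#'
#' Solves the refinement problem by exhaustive enumeration over residue
#' labelings (exact; bounded to few positions), by seeded annealing in
#' labeling space (proposal = change one position's residue; every visited
#' state satisfies one-hot by construction, and the labeling energy equals
#' the one-hot QUBO energy), or by raw simulated annealing on the one-hot
#' QUBO bits. Labeling-space annealing is the default: bit-level annealing
#' freezes through the one-hot penalty barrier and rarely ends feasible.
#'
#' @param problem from [build_refinement()].
#' @param method `"auto"` (exhaustive for <= 4 positions, annealing
#'   otherwise), `"exhaustive"`, `"anneal"`, or `"sa"` (bit-level).
#' @param n_runs,sweeps,seed annealing controls.
#' @param ... passed to [simulated_annealing()] for `method = "sa"`.
#' @return List: `sequence` (residue codes), `energy` (physical, kBT).
#' @export
refine_sequence <- function(problem,
                            method = c("auto", "exhaustive", "anneal", "sa"),
                            n_runs = 20, sweeps = 500, seed = 1, ...) {
  method <- match.arg(method)
  n <- problem$registry$n_sites
  if (method == "auto") method <- if (n <= 4) "exhaustive" else "anneal"
  if (method == "exhaustive") {
    if (n > 6) stop("exhaustive refinement limited to 6 positions")
    return(refine_exhaustive(problem))
  }
  if (method == "anneal")
    return(refine_anneal(problem, n_runs = n_runs, sweeps = sweeps,
                         seed = seed))
  sp <- simulated_annealing(problem, n_runs = n_runs, sweeps = sweeps,
                            seed = seed, ...)
  for (r in order(sp$energies)) {
    seq <- decode_refinement(sp$states[r, ], problem)
    if (!is.null(seq))  # QUBO energy equals the physical energy at one-hot
      return(list(sequence = seq, energy = sp$energies[r]))
  }
  stop("no one-hot-consistent refinement state found; increase sweeps/runs")
}

# Labeling-space structures shared by the exact and annealing solvers:
# per-position linear energies and cross-position coupling tables.
refine_tables <- function(problem) {
  reg <- problem$registry
  n <- reg$n_sites; nA <- reg$D
  pos_of <- ((seq_len(n * nA) - 1) %% n) + 1
  alt_of <- ((seq_len(n * nA) - 1) %/% n) + 1
  cross <- problem$quad[pos_of[problem$quad$i] != pos_of[problem$quad$j], ,
                        drop = FALSE]
  pairs <- unique(cbind(pos_of[cross$i], pos_of[cross$j]))
  coup <- lapply(seq_len(nrow(pairs)), function(r) {
    m <- matrix(0, nA, nA)
    sel <- pos_of[cross$i] == pairs[r, 1] & pos_of[cross$j] == pairs[r, 2]
    sub <- cross[sel, , drop = FALSE]
    m[cbind(alt_of[sub$i], alt_of[sub$j])] <- sub$v
    m
  })
  list(n = n, nA = nA, lin = matrix(problem$linear[reg$site_idx], n, nA),
       pairs = pairs, coup = coup, offset = problem$offset)
}

refine_label_energy <- function(tb, idx) {
  e <- tb$offset + sum(tb$lin[cbind(seq_len(tb$n), idx)])
  for (r in seq_len(nrow(tb$pairs)))
    e <- e + tb$coup[[r]][idx[tb$pairs[r, 1]], idx[tb$pairs[r, 2]]]
  e
}

refine_anneal <- function(problem, n_runs, sweeps, seed) {
  tb <- refine_tables(problem)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  # per-position incidence of coupling tables, for local energy updates
  inc <- lapply(seq_len(tb$n), function(p)
    which(tb$pairs[, 1] == p | tb$pairs[, 2] == p))
  local_e <- function(idx, p, a) {
    e <- tb$lin[p, a]
    for (r in inc[[p]]) {
      e <- e + if (tb$pairs[r, 1] == p)
        tb$coup[[r]][a, idx[tb$pairs[r, 2]]] else
        tb$coup[[r]][idx[tb$pairs[r, 1]], a]
    }
    e
  }
  scale <- max(abs(tb$lin)) + 1e-9
  best_e <- Inf; best_idx <- NULL
  for (run in seq_len(n_runs)) {
    idx <- sample(tb$nA, tb$n, replace = TRUE)
    temp <- scale
    for (s in seq_len(sweeps)) {
      for (p in sample(tb$n)) {
        a <- sample(tb$nA, 1)
        if (a == idx[p]) next
        dE <- local_e(idx, p, a) - local_e(idx, p, idx[p])
        if (dE <= 0 || runif(1) < exp(-dE / temp)) idx[p] <- a
      }
      temp <- temp * (0.01)^(1 / max(sweeps - 1, 1))
    }
    # greedy descent to the local optimum
    repeat {
      improved <- FALSE
      for (p in seq_len(tb$n)) for (a in seq_len(tb$nA)) {
        if (a == idx[p]) next
        dE <- local_e(idx, p, a) - local_e(idx, p, idx[p])
        if (dE < -1e-12) { idx[p] <- a; improved <- TRUE }
      }
      if (!improved) break
    }
    e <- refine_label_energy(tb, idx)
    if (e < best_e) { best_e <- e; best_idx <- idx }
  }
  list(sequence = problem$types[best_idx], energy = best_e)
}

# Exact enumeration over labelings using the labeling-level energies (the
# one-hot penalty vanishes on every labeling, so this equals the QUBO energy).
refine_exhaustive <- function(problem) {
  reg <- problem$registry
  n <- reg$n_sites; nA <- reg$D
  lin <- matrix(problem$linear[reg$site_idx], n, nA)
  coup <- problem$quad
  # keep only couplings between one-hot blocks (drop the penalty quadratics);
  # site_idx is seq_len(n*nA) filled column-major, so variable v maps to:
  pos_of <- ((seq_len(n * nA) - 1) %% n) + 1
  alt_of <- ((seq_len(n * nA) - 1) %/% n) + 1
  cross <- coup[pos_of[coup$i] != pos_of[coup$j], , drop = FALSE]
  idx <- rep(1L, n)
  best_e <- Inf; best_seq <- NULL
  repeat {
    # offset restores the vanished one-hot penalty constant, so e is the
    # QUBO (= physical) energy of the labeling
    e <- problem$offset + sum(lin[cbind(seq_len(n), idx)])
    if (nrow(cross)) {
      sel_i <- idx[pos_of[cross$i]] == alt_of[cross$i]
      sel_j <- idx[pos_of[cross$j]] == alt_of[cross$j]
      e <- e + sum(cross$v[sel_i & sel_j])
    }
    if (e < best_e) { best_e <- e; best_seq <- idx }
    p <- 1L
    repeat {
      idx[p] <- idx[p] + 1L
      if (idx[p] <= nA) break
      idx[p] <- 1L; p <- p + 1L
      if (p > n) break
    }
    if (p > n) break
  }
  list(sequence = problem$types[best_seq], energy = best_e)
}

#' Uniform random peptide sequences
#'
#' I.i.d. uniform draws over the 20 residues, seeded and reproducible;
#' the random-peptide baseline of the pose validation.
#'
#' @param length residues per sequence; @param n number of sequences;
#' @param seed integer seed; @param codes alphabet (default the 20 types).
#' @return Character vector of sequences.
#' @export
random_sequences <- function(length, n, seed = 1, codes = NULL) {
  stopifnot(length >= 1, n >= 0)
  if (is.null(codes)) codes <- residue_alphabet()$code
  if (n == 0) return(character())
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(codes, length, replace = TRUE), collapse = ""), "")
}

#' Export sequences as FASTA (60-column wrap)
#' @param seqs character vector of sequences; @param path output file;
#' @param names sequence names (default seq_1..n).
#' @export
write_fasta <- function(seqs, path, names = NULL) {
  if (is.null(names)) names <- paste0("seq_", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names[i]), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ends <- c(hdr[-1] - 1, length(lines))
  out <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1):ends[i]], collapse = ""), "")
  names(out) <- sub("^>\\s*", "", lines[hdr])
  out
}
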