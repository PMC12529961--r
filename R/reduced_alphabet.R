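# Reduction of the 20-letter alphabet to D chemical families by least-squares
# clustering of the contact-energy matrix, and the effective clustered model.

#' Cluster-mean effective energy matrix
#'
#' `e'_IJ` is the mean of `e_kl` over all ordered member pairs (k in I,
#' l in J); diagonal blocks include k = l pairs, so singleton families
#' reproduce `e` exactly.
#'
#' @param e symmetric matrix (any alphabet size).
#' @param map a `cluster_map` (or bare assignment vector over `rownames(e)`).
#' @return Symmetric `D x D` matrix.
#' @export
clustered_energy <- function(e, map) {
  a <- assignment_of(map, rownames(e))
  D <- max(a)
  ep <- matrix(0, D, D)
  for (I in seq_len(D)) for (J in seq_len(I)) {
    block <- e[a == I, a == J, drop = FALSE]
    ep[I, J] <- ep[J, I] <- mean(block)
  }
  dimnames(ep) <- list(family_labels(D), family_labels(D))
  ep
}

#' Effective per-family diameter and frequency
#'
#' Diameters average (unweighted mean over members); frequencies aggregate
#' by summation so the family frequencies remain a probability distribution.
#'
#' @param alphabet a [residue_alphabet()].
#' @param map a `cluster_map`.
#' @return Named numeric vector over families.
#' @export
clustered_sigma <- function(alphabet, map) {
  a <- assignment_of(map, alphabet$code)
  out <- tapply(alphabet$sigma, a, mean)
  setNames(as.vector(out), family_labels(max(a)))
}

#' @rdname clustered_sigma
#' @export
clustered_freq <- function(alphabet, map) {
  a <- assignment_of(map, alphabet$code)
  out <- tapply(alphabet$surface_freq, a, sum)
  setNames(as.vector(out), family_labels(max(a)))
}

#' Least-squares residue clustering
#'
#' Finds the assignment `a(i)` of residue types to `D` families minimizing
#' `L = sum_ij (e_ij - e'_a(i)a(j))^2`, where `e'` is the cluster-mean matrix
#' of [clustered_energy()]. Small assignment spaces are searched exhaustively
#' (all surjective labelings up to family relabeling); larger ones by seeded
#' multi-restart simulated annealing over single-type reassignments followed
#' by greedy descent. Family labels are canonicalized by ascending mean
#' self-energy (`diag(e')`), making results reproducible.
#'
#' @param e symmetric energy matrix with type codes as dimnames.
#' @param D number of families, `2 <= D <= nrow(e)`.
#' @param method `"auto"` (exhaustive when feasible), `"exhaustive"`, or
#'   `"anneal"`.
#' @param restarts annealing restarts (default 50).
#' @param max_exhaustive largest number of labelings enumerated exhaustively.
#' @param seed RNG seed for the heuristic search.
#' @return A list of class `cluster_map`: `assignment` (named integer
#'   vector), `D`, `loss`, `method`.
#' @export
fit_cluster_map <- function(e, D, method = c("auto", "exhaustive", "anneal"),
                            restarts = 50, max_exhaustive = 2^20, seed = 1) {
  method <- match.arg(method)
  n <- nrow(e)
  stopifnot(isTRUE(all.equal(e, t(e))), n == ncol(e))
  if (D < 2 || D > n) stop("D must lie in [2, ", n, "]")
  codes <- rownames(e)
  if (D == n) {
    a <- seq_len(n)
  } else {
    use_ex <- method == "exhaustive" ||
      (method == "auto" && D^n <= max_exhaustive)
    if (method == "exhaustive" && D^n > max_exhaustive)
      stop("assignment space too large for exhaustive search")
    a <- if (use_ex) exhaustive_assign(e, D) else
      anneal_assign(e, D, restarts, seed)
  }
  a <- canonicalize_families(e, a)
  map <- structure(list(assignment = setNames(a, codes), D = D,
                        loss = cluster_loss(e, a), method = method),
                   class = "cluster_map")
  map
}

#' Clustering loss of an assignment
#'
#' @param e symmetric matrix; @param a integer assignment vector.
#' @return `sum_ij (e_ij - e'_a(i)a(j))^2`.
#' @export
cluster_loss <- function(e, a) {
  # sum_ij (e_ij - e'_a(i)a(j))^2 = sum(e^2) - sum_IJ S_IJ^2 / (n_I n_J),
  # with S the block sums: the block mean minimizes the within-block square
  cluster_loss_cpp(e, as.integer(a), max(a))
}

# Unlabelled fast path used in search loops.
clustered_energy_raw <- function(e, a) {
  S <- rowsum(t(rowsum(e, a)), a)
  n <- tabulate(a, max(a))
  S / outer(n, n)
}

exhaustive_assign <- function(e, D) {
  n <- nrow(e)
  best <- NULL
  best_loss <- Inf
  # enumerate labelings in restricted-growth form (canonical up to relabeling)
  a <- integer(n)
  rec <- function(i, kmax) {
    if (i > n) {
      if (kmax != D) return()
      l <- cluster_loss(e, a)
      if (l < best_loss) { best_loss <<- l; best <<- a }
      return()
    }
    for (k in seq_len(min(kmax + 1, D))) {
      a[i] <<- k
      rec(i + 1, max(kmax, k))
    }
  }
  rec(1L, 0L)
  best
}

anneal_assign <- function(e, D, restarts, seed) {
  n <- nrow(e)
  best <- NULL
  best_loss <- Inf
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (rep in seq_len(restarts)) {
    a <- c(sample(seq_len(D)), sample(seq_len(D), n - D, replace = TRUE))
    a <- a[sample(n)]
    loss <- cluster_loss(e, a)
    temp <- stats::sd(e) * n
    for (sweep in 1:60) {
      for (i in sample(n)) {
        new_fam <- sample(seq_len(D), 1)
        if (new_fam == a[i] || sum(a == a[i]) == 1L) next  # keep families nonempty
        a2 <- a; a2[i] <- new_fam
        l2 <- cluster_loss(e, a2)
        if (l2 < loss || runif(1) < exp((loss - l2) / max(temp, 1e-12))) {
          a <- a2; loss <- l2
        }
      }
      temp <- temp * 0.8
    }
    repeat {  # greedy descent to the local optimum
      improved <- FALSE
      for (i in seq_len(n)) for (k in seq_len(D)) {
        if (k == a[i] || sum(a == a[i]) == 1L) next
        a2 <- a; a2[i] <- k
        l2 <- cluster_loss(e, a2)
        if (l2 < loss - 1e-12) { a <- a2; loss <- l2; improved <- TRUE }
      }
      if (!improved) break
    }
    if (loss < best_loss) { best_loss <- loss; best <- a }
  }
  best
}

canonicalize_families <- function(e, a) {
  ep <- clustered_energy_raw(e, a)
  ord <- order(diag(ep))
  relabel <- integer(max(a))
  relabel[ord] <- seq_along(ord)
  relabel[a]
}

family_labels <- function(D) paste0("F", seq_len(D))

assignment_of <- function(map, codes) {
  a <- if (inherits(map, "cluster_map")) map$assignment else map
  if (!is.null(names(a)) && !is.null(codes)) {
    if (!all(codes %in% names(a)))
      stop("cluster map does not cover the alphabet")
    a <- a[codes]
  }
  a <- as.integer(a)
  if (any(tabulate(a, max(a)) == 0L)) stop("cluster map has an empty family")
  a
}

#' Reduced-alphabet effective model
#'
#' Builds the `pair_model` over `D` families implied by a cluster map:
#' effective energies from the raw contact table (rescaled after averaging),
#' mean diameters and summed frequencies.
#'
#' @param model full-alphabet `pair_model` from [mj_model()].
#' @param map a `cluster_map`, or an integer `D` to fit one here.
#' @param ... passed to [fit_cluster_map()] when `map` is a count.
#' @return A `pair_model` over families, with `map` attached.
#' @export
cluster_model <- function(model, map, ...) {
  stopifnot(inherits(model, "pair_model"))
  tab <- attr(model, "contact_table")
  if (is.null(tab)) stop("model carries no raw contact table")
  if (is.numeric(map) && length(map) == 1L)
    map <- fit_cluster_map(tab$e, D = map, ...)
  ep_raw <- clustered_energy(tab$e, map)
  alpha <- attr(model, "alphabet")
  pm <- pair_model(epsilon = tab$lambda_scale * (ep_raw - tab$e0),
                   sigma = clustered_sigma(alpha, map),
                   freq = clustered_freq(alpha, map),
                   cutoff = model$cutoff,
                   map = map$assignment)
  attr(pm, "cluster_map") <- map
  pm
}

#' Read / write cluster maps as two-column text
#'
#' @param map a `cluster_map`; @param path file path.
#' @export
write_cluster_map <- function(map, path) {
  stopifnot(inherits(map, "cluster_map"))
  df <- data.frame(code = names(map$assignment),
                   family = as.integer(map$assignment))
  write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cluster_map
#' @export
read_cluster_map <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  a <- setNames(as.integer(df$family), df$code)
  structure(list(assignment = a, D = max(a), loss = NA_real_,
                 method = "file"), class = "cluster_map")
}
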