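# Cubic pocket lattice: grid construction clipped to the pocket, anchor
# selection, and the precomputed per-site per-type external field.

#' Build the cubic pocket grid
#'
#' Lays a cubic lattice (spacing = peptide-bond length, 3.8 A) over the
#' pocket: the lattice origin is the centroid of the reference region, axes
#' aligned with the input frame. A candidate point is retained when it lies
#' within `include_radius` of at least one reference coordinate and farther
#' than `exclude_radius` from every receptor bead. Edges join axis-aligned
#' nearest neighbors.
#'
#' @param receptor a [receptor()].
#' @param reference matrix `m x 3` of reference C-alpha coordinates (e.g. an
#'   experimentally bound peptide) delimiting the pocket.
#' @param endpoints optional `2 x 3` matrix of anchor endpoint coordinates;
#'   when given, anchors are selected and s-t connectivity is verified.
#' @param spacing lattice constant in Angstrom (default 3.8).
#' @param include_radius retain points within this distance of the reference
#'   region (default 7.6).
#' @param exclude_radius drop points within this distance of any receptor
#'   bead (default 1.5).
#' @return Object of class `pocket_grid`: `sites` (`n x 3`), `edges`
#'   (`m x 2`, lower index first), `spacing`, `s_index`/`t_index` (or NA),
#'   `provenance`.
#' @export
build_grid <- function(receptor, reference, endpoints = NULL, spacing = 3.8,
                       include_radius = 7.6, exclude_radius = 1.5) {
  stopifnot(inherits(receptor, "receptor"))
  reference <- as.matrix(reference)
  if (!nrow(reference)) stop("reference region is empty")
  origin <- colMeans(reference)
  lo <- floor((apply(reference, 2, min) - include_radius - origin) / spacing)
  hi <- ceiling((apply(reference, 2, max) + include_radius - origin) / spacing)
  ix <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  pts <- sweep(ix * spacing, 2, origin, "+")
  keep <- min_dist_to(pts, reference) <= include_radius &
          min_dist_to(pts, receptor$coords) > exclude_radius
  if (!any(keep))
    stop("empty grid: widen include_radius or shrink exclude_radius")
  sites <- pts[keep, , drop = FALSE]
  ix <- ix[keep, , drop = FALSE]
  edges <- lattice_edges(ix)
  g <- structure(list(sites = sites, edges = edges, spacing = spacing,
                      s_index = NA_integer_, t_index = NA_integer_,
                      provenance = list(receptor = receptor$id,
                                        spacing = spacing,
                                        include_radius = include_radius,
                                        exclude_radius = exclude_radius,
                                        origin = origin)),
                 class = "pocket_grid")
  if (!is.null(endpoints)) {
    st <- pick_anchors(g, endpoints)
    g$s_index <- st[1]; g$t_index <- st[2]
    if (!grid_connected(g, st[1], st[2]))
      stop("anchor sites are not connected on the grid; widen radii")
  }
  g
}

#' Full-box lattice grid
#'
#' A bare `Lx x Ly x Lz` cubic grid with no pocket clipping; the workhorse
#' of toy instances and exhaustive oracle checks.
#'
#' @param dims integer vector (Lx, Ly, Lz); @param spacing lattice constant.
#' @param origin coordinate of the (1,1,1) corner.
#' @return A `pocket_grid` (anchors unset).
#' @export
lattice_grid <- function(dims, spacing = 3.8, origin = c(0, 0, 0)) {
  stopifnot(length(dims) == 3, all(dims >= 1))
  ix <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                              0:(dims[3] - 1)))
  sites <- sweep(ix * spacing, 2, origin, "+")
  structure(list(sites = sites, edges = lattice_edges(ix), spacing = spacing,
                 s_index = NA_integer_, t_index = NA_integer_,
                 provenance = list(receptor = "none", dims = dims,
                                   spacing = spacing)),
            class = "pocket_grid")
}

min_dist_to <- function(pts, ref) {
  # rowwise min Euclidean distance from pts (n x 3) to ref (m x 3)
  n <- nrow(pts)
  out <- rep(Inf, n)
  for (j in seq_len(nrow(ref))) {
    d2 <- (pts[, 1] - ref[j, 1])^2 + (pts[, 2] - ref[j, 2])^2 +
          (pts[, 3] - ref[j, 3])^2
    out <- pmin(out, d2)
  }
  sqrt(out)
}

lattice_edges <- function(ix) {
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  lookup <- setNames(seq_len(nrow(ix)), key(ix))
  shifts <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  out <- NULL
  for (s in 1:3) {
    nb <- lookup[key(sweep(ix, 2, shifts[s, ], "+"))]
    ok <- !is.na(nb)
    if (any(ok))
      out <- rbind(out, cbind(which(ok), unname(nb[ok])))
  }
  if (is.null(out) || nrow(out) == 0) return(matrix(integer(), 0, 2))
  out <- cbind(pmin(out[, 1], out[, 2]), pmax(out[, 1], out[, 2]))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

grid_adjacency <- function(grid) {
  n <- nrow(grid$sites)
  adj <- vector("list", n)
  for (r in seq_len(nrow(grid$edges))) {
    i <- grid$edges[r, 1]; j <- grid$edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

grid_connected <- function(grid, s, t) {
  adj <- grid_adjacency(grid)
  seen <- logical(nrow(grid$sites))
  queue <- s; seen[s] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  seen[t]
}

#' @export
print.pocket_grid <- function(x, ...) {
  cat("<pocket_grid>", nrow(x$sites), "sites,", nrow(x$edges), "edges,",
      "spacing", x$spacing, "A\n")
  if (!is.na(x$s_index)) cat("  anchors s =", x$s_index, " t =", x$t_index, "\n")
  invisible(x)
}

#' Select the anchor sites s and t
#'
#' Each endpoint maps to the nearest grid site (Euclidean); ties break to
#' the lowest site index.
#'
#' @param grid a `pocket_grid`; @param endpoints `2 x 3` coordinate matrix.
#' @return Integer vector `c(s_index, t_index)`.
#' @export
pick_anchors <- function(grid, endpoints) {
  endpoints <- as.matrix(endpoints)
  stopifnot(nrow(endpoints) == 2, ncol(endpoints) == 3)
  nearest <- function(p) {
    d <- sqrt((grid$sites[, 1] - p[1])^2 + (grid$sites[, 2] - p[2])^2 +
              (grid$sites[, 3] - p[3])^2)
    which(d <= min(d) + 1e-9)[1]  # lowest index among ties
  }
  s <- nearest(endpoints[1, ]); t <- nearest(endpoints[2, ])
  if (s == t) stop("both endpoints map to the same grid site")
  c(s, t)
}

#' Attach anchors to a grid
#' @param grid a `pocket_grid`; @param endpoints `2 x 3` coordinate matrix.
#' @return The grid with `s_index`/`t_index` set.
#' @export
set_anchors <- function(grid, endpoints) {
  st <- pick_anchors(grid, endpoints)
  grid$s_index <- st[1]; grid$t_index <- st[2]
  grid
}

#' Precompute the external field over the grid
#'
#' For every grid site i and model type k, `E_i^(k)` is the energy an
#' isolated residue of type k would experience at site i from all receptor
#' beads (pair potential, cutoff applies). Receptor types are mapped through
#' the model's cluster map when the model is a reduced alphabet. `Nc`
#' defaults to the mean over grid sites of the number of receptor beads
#' within the cutoff, and `E0^(k)` is the mean-field offset at that `Nc`.
#'
#' @param grid a `pocket_grid`; @param receptor a [receptor()];
#' @param model a `pair_model` (full or clustered).
#' @param Nc override for the mean contact count (default: computed).
#' @return Object of class `external_field`: `E` (`sites x types`), `E0`
#'   (per type), `Nc`, `types`.
#' @export
external_field <- function(grid, receptor, model, Nc = NULL) {
  stopifnot(inherits(grid, "pocket_grid"), inherits(model, "pair_model"))
  n <- nrow(grid$sites)
  types <- model$codes
  D <- length(types)
  m <- length(receptor$types)
  if (m == 0L) {
    E <- matrix(0, n, D, dimnames = list(NULL, types))
    return(structure(list(E = E, E0 = setNames(rep(0, D), types),
                          Nc = 0, types = types), class = "external_field"))
  }
  bead_types <- receptor$types
  if (!is.null(model$map)) {
    if (any(!bead_types %in% names(model$map)))
      stop("receptor contains types outside the cluster map")
    bead_types <- family_labels(max(model$map))[model$map[bead_types]]
  }
  if (any(!bead_types %in% types))
    stop("receptor types not covered by the model alphabet")
  dmat <- matrix(0, n, m)  # site x bead distances
  for (j in seq_len(m)) {
    dmat[, j] <- sqrt((grid$sites[, 1] - receptor$coords[j, 1])^2 +
                      (grid$sites[, 2] - receptor$coords[j, 2])^2 +
                      (grid$sites[, 3] - receptor$coords[j, 3])^2)
  }
  E <- matrix(0, n, D, dimnames = list(NULL, types))
  for (k in seq_len(D)) {
    acc <- numeric(n)
    for (j in seq_len(m)) {
      eps <- model$epsilon[types[k], bead_types[j]]
      sij <- (model$sigma[types[k]] + model$sigma[bead_types[j]]) / 2
      acc <- acc + lj_piecewise(eps, unname(sij), dmat[, j], model$cutoff)
    }
    E[, k] <- acc
  }
  if (is.null(Nc)) Nc <- mean(rowSums(dmat < model$cutoff))
  structure(list(E = E, E0 = mean_field_offset(NULL, Nc, model),
                 Nc = Nc, types = types), class = "external_field")
}

#' Serialize a grid to JSON
#' @param grid a `pocket_grid`; @param path output file.
#' @export
write_grid_json <- function(grid, path) {
  jsonlite::write_json(list(sites = grid$sites, edges = grid$edges,
                            spacing = grid$spacing,
                            s_index = grid$s_index, t_index = grid$t_index,
                            provenance = grid$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
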