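# Seeded synthetic pockets and binder sets. A groove receptor emulates an
# amphiphilic binding channel: a dense hydrophobic floor ("core" beads)
# under the grid corridor and sparse polar "rim" beads flanking its top.
# Distances are engineered around the pair potential: with bead diameters
# near 6 A the LJ minimum sits near 7 A, so the floor lies 7.6 A below the
# corridor layer (attractive contact range) and the rim 7.6 A from the top
# sites. Everything is deterministic given the spec (seed included).

#' Synthetic groove receptor
#'
#' Builds a channel pocket: reference region of `dims` lattice units
#' (x width, y height, z length) at 7.6 A above a hydrophobic floor plane
#' (bead spacing 1.9 A, so several beads fall in the attractive shell of
#' every corridor site), flanked by polar rim rows at the top corners.
#' Returns the receptor with ground-truth bead labels plus the reference
#' coordinates and anchor endpoints for [build_grid()].
#'
#' Odd `dims` keep the lattice origin (the reference centroid) aligned with
#' the floor bead pattern; even values shift it by half a spacing, which is
#' legal but makes field values less symmetric.
#'
#' @param dims integer vector (x, y, z) extent of the reference region in
#'   lattice units (default `c(3, 3, 6)`).
#' @param seed RNG seed for bead type sampling.
#' @param spacing lattice constant (default 3.8 A).
#' @param core_types,rim_types residue pools for floor and rim beads.
#' @return List: `receptor` (with `labels` "core"/"rim"), `reference`
#'   (`m x 3` coordinates), `endpoints` (`2 x 3`: corridor ends), `spec`.
#' @export
make_groove_receptor <- function(dims = c(3, 3, 6), seed = 1, spacing = 3.8,
                                 core_types = c("L", "I", "V", "F", "M", "C"),
                                 rim_types = c("S", "T", "N", "Q", "D", "E",
                                               "K", "R")) {
  stopifnot(length(dims) == 3, all(dims >= 1))
  w <- dims[1]; h <- dims[2]; l <- dims[3]
  xs <- (seq_len(w) - (w + 1) / 2) * spacing
  ys <- 2 * spacing + (seq_len(h) - 1) * spacing
  zs <- (seq_len(l) - 1) * spacing
  reference <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  # dense hydrophobic floor at y = 0 under the corridor, margin one spacing
  fx <- seq(min(xs) - spacing, max(xs) + spacing, by = spacing / 2)
  fz <- seq(min(zs) - spacing, max(zs) + spacing, by = spacing / 2)
  floor_xyz <- as.matrix(expand.grid(x = fx, y = 0, z = fz))
  # sparse polar rim rows flanking the top layer at contact range
  top <- max(ys) + spacing
  rim_x <- c(min(xs) - 2 * spacing, max(xs) + 2 * spacing)
  rim_z <- seq(min(zs) - spacing, max(zs) + spacing, by = spacing)
  rim_xyz <- as.matrix(expand.grid(x = rim_x, y = top, z = rim_z))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  types <- c(sample(core_types, nrow(floor_xyz), replace = TRUE),
             sample(rim_types, nrow(rim_xyz), replace = TRUE))
  rec <- receptor(types, rbind(floor_xyz, rim_xyz),
                  id = sprintf("groove_%dx%dx%d_seed%d", w, h, l, seed),
                  labels = c(rep("core", nrow(floor_xyz)),
                             rep("rim", nrow(rim_xyz))))
  endpoints <- rbind(c(xs[(w + 1) %/% 2], ys[1], min(zs)),
                     c(xs[(w + 1) %/% 2], ys[1], max(zs)))
  list(receptor = rec, reference = reference, endpoints = endpoints,
       spec = list(dims = dims, seed = seed, spacing = spacing))
}

#' Classify grid sites by receptor context
#'
#' `"floor"`: at least one core bead in the attractive contact shell
#' (between 0.75 cutoff and cutoff); `"rim"`: no core bead within the
#' cutoff; `"other"`: everything else (including sterically squeezed sites
#' close to the floor).
#'
#' @param grid a `pocket_grid`; @param rec a labelled groove [receptor()];
#' @param cutoff contact cutoff (default 8.5).
#' @return Character vector over grid sites.
#' @export
classify_groove_sites <- function(grid, rec, cutoff = 8.5) {
  core <- rec$coords[rec$labels == "core", , drop = FALSE]
  d <- min_dist_to(grid$sites, core)
  ifelse(d >= 0.75 * cutoff & d < cutoff, "floor",
         ifelse(d >= cutoff, "rim", "other"))
}

#' Sample reference binder sequences from a position profile
#'
#' Each sequence draws every position independently from that position's
#' residue distribution; emulates the per-position conservation of a
#' curated binder data set.
#'
#' @param profile `L x 20` matrix of per-position probabilities (columns
#'   named by one-letter code), rows summing to 1.
#' @param n number of sequences; @param seed RNG seed.
#' @return Character vector of `n` sequences of length `L`.
#' @export
make_reference_binders <- function(profile, n, seed = 1) {
  profile <- as.matrix(profile)
  if (is.null(colnames(profile)))
    stop("profile columns must be named by residue code")
  if (any(abs(rowSums(profile) - 1) > 1e-9) || any(profile < 0))
    stop("profile rows must be probability vectors")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(vapply(seq_len(nrow(profile)), function(p)
      sample(colnames(profile), 1, prob = profile[p, ]), ""), collapse = ""),
    "")
}
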