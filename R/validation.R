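# Assessment statistics: fraction-of-native-contacts precision-recall over
# ranked pose lists, and reduced-alphabet per-position frequency comparison
# between designed and reference sequence sets.

#' Peptide-receptor contact set
#'
#' Contacts are (peptide position, receptor residue index) pairs whose
#' C-alpha beads lie within the cutoff (default 8.5 A, matching the energy
#' model; configurable for comparison with docking conventions).
#'
#' @param pep_coords `n x 3` matrix of peptide C-alpha coordinates.
#' @param receptor a [receptor()].
#' @param cutoff contact distance in Angstrom.
#' @return Object of class `contact_set`: `pairs` (2-column matrix),
#'   `cutoff`.
#' @export
native_contacts <- function(pep_coords, receptor, cutoff = 8.5) {
  pep_coords <- as.matrix(pep_coords)
  pairs <- NULL
  for (p in seq_len(nrow(pep_coords))) {
    d <- sqrt((receptor$coords[, 1] - pep_coords[p, 1])^2 +
              (receptor$coords[, 2] - pep_coords[p, 2])^2 +
              (receptor$coords[, 3] - pep_coords[p, 3])^2)
    hit <- which(d < cutoff)
    if (length(hit)) pairs <- rbind(pairs, cbind(p, hit))
  }
  if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
  dimnames(pairs) <- list(NULL, c("position", "residue"))
  structure(list(pairs = pairs, cutoff = cutoff), class = "contact_set")
}

contact_keys <- function(x) {
  if (inherits(x, "contact_set")) x <- x$pairs
  if (!nrow(x)) return(character())
  unique(paste(x[, 1], x[, 2], sep = ":"))
}

#' Fraction of native contacts
#'
#' `f_nat = |pose contacts  intersect  native contacts| / |native contacts|`.
#'
#' @param pose,native `contact_set`s (or bare 2-column pair matrices).
#' @return Value in `[0, 1]`.
#' @export
f_nat <- function(pose, native) {
  nat <- contact_keys(native)
  if (!length(nat)) stop("native contact set is empty: f_nat undefined")
  length(intersect(contact_keys(pose), nat)) / length(nat)
}

#' Label ranked poses by the CAPRI criterion
#'
#' Positive iff `f_nat > threshold` (strict inequality; exactly 0.5 is
#' negative).
#'
#' @param poses list of `contact_set`s in rank order (best first), or a
#'   numeric vector of precomputed f_nat values.
#' @param native reference `contact_set` (ignored for numeric input).
#' @param threshold default 0.5.
#' @return Logical vector in rank order.
#' @export
label_poses <- function(poses, native = NULL, threshold = 0.5) {
  fn <- if (is.numeric(poses)) poses else
    vapply(poses, f_nat, 0, native = native)
  fn > threshold
}

#' Area under the precision-recall curve
#'
#' Average-precision step rule over a ranked binary label list: the mean,
#' over positives, of the precision at that positive's rank. Deterministic
#' and free of interpolation ambiguity at duplicate recalls; invariant to
#' trailing negatives.
#'
#' @param labels logical/0-1 vector in rank order (best-ranked first).
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(labels) {
  labels <- as.logical(labels)
  if (!any(labels))
    stop("no positive labels: AUPRC undefined (check the f_nat threshold)")
  ranks <- which(labels)
  prec_at <- cumsum(labels)[ranks] / ranks
  mean(prec_at)
}

#' Per-position family histograms of two sequence sets
#'
#' Maps every residue through the cluster map and tabulates per-position
#' family frequencies for the designed and reference sets.
#'
#' @param designed,reference character vectors of equal-length sequences.
#' @param map a `cluster_map` (identity map over 20 singleton families
#'   reproduces raw residue frequencies).
#' @return Object of class `position_histograms`: `designed` and
#'   `reference` (`length x D` row-stochastic matrices), `D`.
#' @export
family_histograms <- function(designed, reference, map) {
  a <- if (inherits(map, "cluster_map")) map$assignment else map
  D <- max(a)
  len <- unique(nchar(c(designed, reference)))
  if (length(len) != 1)
    stop("all sequences must share one length")
  if (!length(designed) || !length(reference)) stop("empty sequence set")
  hist_of <- function(seqs) {
    m <- matrix(0, len, D)
    for (s in seqs) {
      res <- strsplit(s, "")[[1]]
      if (any(!res %in% names(a)))
        stop("sequence contains residues outside the cluster map")
      fam <- a[res]
      for (p in seq_len(len)) m[p, fam[p]] <- m[p, fam[p]] + 1
    }
    m / length(seqs)
  }
  structure(list(designed = hist_of(designed), reference = hist_of(reference),
                 D = D), class = "position_histograms")
}

#' Top-2 family overlap count
#'
#' Number of positions at which the reference set's modal family is among
#' the two most frequent families of the designed set. Ties order by
#' (-frequency, family index), i.e. the lower family index wins a tie.
#'
#' @param h a `position_histograms`.
#' @return Integer count of positions.
#' @export
top2_overlap <- function(h) {
  stopifnot(inherits(h, "position_histograms"))
  len <- nrow(h$designed)
  count <- 0L
  for (p in seq_len(len)) {
    ref_mode <- order(-h$reference[p, ], seq_len(h$D))[1]
    des_top2 <- order(-h$designed[p, ], seq_len(h$D))[1:2]
    if (ref_mode %in% des_top2) count <- count + 1L
  }
  count
}

#' Read a ranked pose list from a CSV manifest
#'
#' Manifest columns: `rank`, `file` (PDB of peptide C-alpha beads),
#' optional `score`. Files resolve relative to the manifest directory.
#'
#' @param manifest CSV path; @param receptor a [receptor()];
#' @param cutoff contact cutoff.
#' @return List of `contact_set`s in rank order.
#' @export
read_ranked_poses <- function(manifest, receptor, cutoff = 8.5) {
  df <- read.table(manifest, header = TRUE, sep = ",",
                   stringsAsFactors = FALSE)
  df <- df[order(df$rank), , drop = FALSE]
  lapply(df$file, function(f) {
    p <- if (file.exists(f)) f else file.path(dirname(manifest), f)
    pose <- read_receptor_pdb(p)
    native_contacts(pose$coords, receptor, cutoff)
  })
}
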