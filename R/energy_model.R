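# Coarse-grained residue-level energy model: a Miyazawa-Jernigan style
# contact-energy table rescaled to Lennard-Jones well depths, one bead per
# residue at the C-alpha position, energies in kBT throughout.

#' Residue alphabet with per-type parameters
#'
#' Loads (or validates) the table of one- and three-letter residue codes,
#' van der Waals bead diameters sigma_i (Angstrom) and relative surface
#' frequencies f_i. The packaged table ships under
#' `inst/extdata/residue_params.txt` and can be replaced by any file or
#' data frame with the same columns.
#'
#' @param residue_table path to a whitespace-delimited table with columns
#'   `code`, `code3`, `sigma`, `surface_freq`, or a data frame with those
#'   columns; `NULL` loads the packaged table.
#' @return A data frame of class `residue_alphabet` with 20 rows.
#' @export
residue_alphabet <- function(residue_table = NULL) {
  if (is.null(residue_table)) {
    residue_table <- system.file("extdata", "residue_params.txt",
                                 package = "pepqubo", mustWork = TRUE)
  }
  tab <- if (is.data.frame(residue_table)) residue_table else
    read.table(residue_table, header = TRUE, comment.char = "#",
               stringsAsFactors = FALSE)
  need <- c("code", "code3", "sigma", "surface_freq")
  if (!all(need %in% names(tab)))
    stop("residue table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) != 20L || anyDuplicated(tab$code))
    stop("residue alphabet must have exactly 20 distinct residue types")
  if (any(tab$sigma <= 0)) stop("all vdW diameters must be positive")
  if (abs(sum(tab$surface_freq) - 1) > 1e-9)
    stop("surface frequencies must sum to 1")
  rownames(tab) <- tab$code
  class(tab) <- c("residue_alphabet", "data.frame")
  tab
}

#' Contact-energy table
#'
#' A 20x20 symmetric matrix of raw residue-residue contact energies e_ij
#' (kBT units) together with the rescaling parameters: overall scale
#' `lambda_scale` and offset `e0`, so that well depths are
#' `epsilon_ij = lambda_scale * (e_ij - e0)`.
#'
#' @param e path to a whitespace-delimited matrix file (header row of
#'   one-letter codes, then 20 rows of 20 numbers), a 20x20 matrix, or
#'   `NULL` for the packaged table.
#' @param lambda_scale dimensionless overall scale (default 0.159).
#' @param e0 energy offset in kBT (default -2.27).
#' @return A list of class `contact_energy_table` with elements `e`,
#'   `lambda_scale`, `e0`.
#' @export
contact_energy_table <- function(e = NULL, lambda_scale = 0.159, e0 = -2.27) {
  if (is.null(e)) {
    e <- system.file("extdata", "mj_contact_energies.txt",
                     package = "pepqubo", mustWork = TRUE)
  }
  if (is.character(e)) {
    lines <- readLines(e)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    codes <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    vals <- do.call(rbind, lapply(lines[-1], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    dimnames(vals) <- list(codes, codes)
    e <- vals
  }
  if (!is.matrix(e) || nrow(e) != 20L || ncol(e) != 20L)
    stop("contact-energy matrix must be 20x20")
  if (max(abs(e - t(e))) > 1e-12)
    stop("contact-energy matrix must be symmetric")
  structure(list(e = e, lambda_scale = lambda_scale, e0 = e0),
            class = "contact_energy_table")
}

#' Lennard-Jones well depths from a contact-energy table
#'
#' Applies the elementwise rescaling `epsilon_ij = lambda * (e_ij - e0)`.
#' Negative epsilon marks an attractive pair, positive a repulsive one.
#'
#' @param table a [contact_energy_table()].
#' @return A symmetric 20x20 matrix of well depths in kBT.
#' @export
epsilon_from_mj <- function(table) {
  stopifnot(inherits(table, "contact_energy_table"))
  table$lambda_scale * (table$e - table$e0)
}

#' Pair interaction-range diameter
#'
#' Arithmetic-mean combination rule `sigma_ij = (sigma_i + sigma_j) / 2`.
#'
#' @param i,j residue type codes (or indices into the alphabet); vectorized.
#' @param alphabet a [residue_alphabet()] or any `pair_model`.
#' @return sigma_ij in Angstrom.
#' @export
sigma_pair <- function(i, j, alphabet) {
  sig <- if (inherits(alphabet, "pair_model")) alphabet$sigma else
    setNames(alphabet$sigma, alphabet$code)
  if (is.character(i) && any(!i %in% names(sig)))
    stop("unknown residue type: ", paste(setdiff(i, names(sig)), collapse = ","))
  if (is.character(j) && any(!j %in% names(sig)))
    stop("unknown residue type: ", paste(setdiff(j, names(sig)), collapse = ","))
  (sig[i] + sig[j]) / 2
}

#' Assemble a pairwise interaction model
#'
#' Bundles a well-depth matrix, per-type diameters, surface frequencies and
#' the interaction cutoff into the container consumed by grids, fields and
#' Hamiltonians. [mj_model()] builds the packaged full-alphabet instance;
#' [cluster_model()] builds reduced-alphabet instances.
#'
#' @param epsilon symmetric matrix of well depths (kBT), dimnames = type codes.
#' @param sigma named per-type diameters (Angstrom).
#' @param freq named per-type frequencies summing to 1.
#' @param cutoff interaction cutoff in Angstrom (default 8.5); the pair
#'   potential is exactly zero at and beyond it.
#' @param map optional named integer vector mapping full-alphabet codes to
#'   family indices (present on clustered models).
#' @return An object of class `pair_model`.
#' @export
pair_model <- function(epsilon, sigma, freq, cutoff = 8.5, map = NULL) {
  codes <- rownames(epsilon)
  stopifnot(!is.null(codes), identical(codes, colnames(epsilon)),
            max(abs(epsilon - t(epsilon))) <= 1e-9,
            all(codes %in% names(sigma)), all(codes %in% names(freq)))
  if (abs(sum(freq[codes]) - 1) > 1e-9) stop("frequencies must sum to 1")
  structure(list(codes = codes, epsilon = epsilon,
                 sigma = sigma[codes], freq = freq[codes],
                 cutoff = cutoff, map = map),
            class = "pair_model")
}

#' Packaged full-alphabet model
#'
#' @param contact_table see [contact_energy_table()]; `NULL` for packaged.
#' @param residue_table see [residue_alphabet()]; `NULL` for packaged.
#' @param lambda_scale,e0 rescaling parameters passed to the contact table.
#' @param cutoff interaction cutoff in Angstrom.
#' @return A `pair_model` over the 20 natural residues, with the raw table
#'   kept in attribute `contact_table`.
#' @export
mj_model <- function(contact_table = NULL, residue_table = NULL,
                     lambda_scale = 0.159, e0 = -2.27, cutoff = 8.5) {
  tab <- if (inherits(contact_table, "contact_energy_table")) contact_table
         else contact_energy_table(contact_table, lambda_scale, e0)
  alpha <- if (inherits(residue_table, "residue_alphabet")) residue_table
           else residue_alphabet(residue_table)
  codes <- rownames(tab$e)
  if (!setequal(codes, alpha$code))
    stop("contact table and residue table use different alphabets")
  m <- pair_model(epsilon = epsilon_from_mj(tab),
                  sigma = setNames(alpha$sigma, alpha$code),
                  freq = setNames(alpha$surface_freq, alpha$code),
                  cutoff = cutoff)
  attr(m, "contact_table") <- tab
  attr(m, "alphabet") <- alpha
  m
}

#' Residue-residue pair potential
#'
#' Lennard-Jones style potential keyed on the sign of the well depth
#' epsilon_ij, with minimum distance `r0 = 2^(1/6) sigma_ij`:
#' attractive pairs (epsilon < 0) follow a plain LJ curve with well depth
#' -|epsilon| at r0; repulsive pairs (epsilon > 0) follow a shifted LJ for
#' r < r0 and its mirrored (repulsive) tail for r >= r0, continuous at r0
#' with value epsilon. The potential is truncated to exactly zero at
#' distances at or beyond the cutoff, without shifting.
#'
#' @param i,j residue type codes in the model alphabet (scalars).
#' @param r distance(s) in Angstrom, all positive; vectorized.
#' @param params a `pair_model`.
#' @return Energy in kBT, same length as `r`.
#' @export
pair_potential <- function(i, j, r, params) {
  stopifnot(inherits(params, "pair_model"))
  if (any(r <= 0)) stop("distances must be positive")
  if (!i %in% params$codes || !j %in% params$codes)
    stop("unknown residue type")
  eps <- params$epsilon[i, j]
  sij <- unname((params$sigma[i] + params$sigma[j]) / 2)
  lj_piecewise(eps, sij, r, params$cutoff)
}

# Vectorized over r for fixed (eps, sigma); shared by pair_potential and the
# field/intrachain builders (which call it with matrix r).
lj_piecewise <- function(eps, sij, r, cutoff) {
  x6 <- (sij / r)^6
  core <- 4 * abs(eps) * (x6 * x6 - x6)
  u <- if (eps < 0) {
    core
  } else if (eps > 0) {
    r0 <- 2^(1 / 6) * sij
    ifelse(r < r0, core + 2 * eps, -core)
  } else {
    r * 0
  }
  u[r >= cutoff] <- 0
  u
}

#' Mean-field average-interaction offset
#'
#' Per-residue contribution of a chain's average interaction with generic
#' protein surfaces: `E0_k = Nc * sum_j f_j epsilon_kj`, where f_j are the
#' surface frequencies carried by the model and Nc is the mean number of
#' contacts a peptide residue forms. Subtracting it from the pocket field
#' rewards selectivity for the target over a typical surface.
#'
#' @param k residue type code(s); `NULL` returns the full named vector.
#' @param Nc mean contact count, >= 0.
#' @param model a `pair_model`.
#' @return Offset(s) in kBT.
#' @export
mean_field_offset <- function(k = NULL, Nc, model) {
  stopifnot(inherits(model, "pair_model"), Nc >= 0)
  e0 <- Nc * as.vector(model$epsilon %*% model$freq)
  names(e0) <- model$codes
  if (is.null(k)) return(e0)
  if (any(!k %in% model$codes)) stop("unknown residue type")
  e0[k]
}
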