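# Molecular similarity-index (CoMSIA-style) fields. Five field kinds are
# evaluated on a shared rectangular lattice over the aligned molecule set:
# steric (S, vdW volume proxy r^3), electrostatic (E, Gasteiger charge),
# hydrophobic (H, atomic logP increment), H-bond donor (D) and acceptor
# (A) flags. At grid point j the similarity index to a probe atom with
# unit properties is A_k(j) = -sum_i w_probe * w_ik * exp(-alpha * d_ij^2):
# Gaussian attenuation, additive over atoms, no singularities.

#' Build a lattice over a set of aligned molecules
#'
#' Axis-aligned bounding box of all atoms, expanded by \code{margin} on
#' every side and discretized at \code{spacing}.
#'
#' @param mols list of \code{pae_mol} objects (aligned to one frame).
#' @param margin box margin (Angstrom).
#' @param spacing lattice spacing (Angstrom).
#' @return list of class \code{comsia_grid}: \code{origin}, \code{spacing},
#'   \code{counts} (nx, ny, nz).
#' @export
build_grid <- function(mols, margin = 2, spacing = 2) {
  if (inherits(mols, "pae_mol")) mols <- list(mols)
  if (!length(mols)) stop("empty molecule set")
  if (spacing <= 0) stop("spacing must be positive")
  xyz <- do.call(rbind, lapply(mols, coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  structure(list(origin = lo, spacing = spacing, counts = counts),
            class = "comsia_grid")
}

#' Lattice point coordinates
#' @param grid a \code{comsia_grid}.
#' @return matrix (n points x 3), x varying fastest.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(d) grid$origin[d] +
                 grid$spacing * (seq_len(grid$counts[d]) - 1L))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

.field_kinds <- c("S", "E", "H", "D", "A")

#' Per-atom field weights
#'
#' Weight of each atom in a similarity field: steric uses the cubed vdW
#' radius (a volume proxy), electrostatic the Gasteiger partial charge,
#' hydrophobic the atomic logP increment, donor/acceptor the 0/1 flags.
#'
#' @param mol a parameterized \code{pae_mol} (see
#'   [assign_atom_parameters()]).
#' @param kind one of \code{"S"}, \code{"E"}, \code{"H"}, \code{"D"},
#'   \code{"A"}.
#' @return numeric vector, one weight per atom.
#' @export
atom_weights <- function(mol, kind) {
  kind <- match.arg(kind, .field_kinds)
  at <- mol$atoms
  need <- c(S = "radius", E = "charge", H = "logp_inc",
            D = "donor", A = "acceptor")[[kind]]
  if (is.null(at[[need]])) {
    stop("atom parameters missing ('", need,
         "'); run assign_atom_parameters() first")
  }
  switch(kind,
         S = at$radius^3,
         E = at$charge,
         H = at$logp_inc,
         D = at$donor,
         A = at$acceptor)
}

#' Similarity-index field of one molecule on a lattice
#'
#' @param mol parameterized \code{pae_mol} in the lattice frame.
#' @param grid a \code{comsia_grid}.
#' @param kind field kind (see [atom_weights()]).
#' @param alpha Gaussian attenuation factor (1/Angstrom^2).
#' @param probe probe-atom weight (field-kind units).
#' @param clamp optional symmetric cap on absolute field values; \code{Inf}
#'   leaves the Gaussian fields untouched (the default for similarity
#'   indices — energy-style cutoffs belong to Lennard-Jones/Coulomb
#'   fields).
#' @return numeric vector of field values, one per lattice point.
#' @export
similarity_field <- function(mol, grid, kind, alpha = 0.3, probe = 1,
                             clamp = Inf) {
  if (alpha <= 0) stop("alpha must be positive")
  w <- atom_weights(mol, kind)
  pts <- grid_points(grid)
  xyz <- coords(mol)
  # squared distances atoms x points without forming cross products twice
  d2 <- outer(rowSums(xyz^2), rowSums(pts^2), "+") - 2 * xyz %*% t(pts)
  d2[d2 < 0] <- 0
  a <- -drop(crossprod(exp(-alpha * d2), probe * w))
  if (is.finite(clamp)) a <- pmin(pmax(a, -clamp), clamp)
  a
}

#' Assemble the descriptor block for a molecule set
#'
#' Evaluates the requested field kinds for every molecule on a shared grid
#' and stacks them into the descriptor matrix X (rows = molecules, columns
#' = grid point x kind). Each kind's block is column-centered and divided
#' by its block-wide pooled standard deviation (the root of the mean
#' column variance), so every block contributes unit pooled variance; the
#' scaling metadata is retained for predicting new molecules.
#'
#' @param mols list of parameterized, aligned \code{pae_mol} objects.
#' @param grid shared \code{comsia_grid}.
#' @param kinds subset of S/E/H/D/A.
#' @param alpha Gaussian attenuation (1/Angstrom^2).
#' @param probe probe weight.
#' @param clamp optional symmetric field cap (see [similarity_field()]).
#' @param scale block-scale the matrix (disable for raw fields).
#' @return list of class \code{comsia_block}: \code{X}, \code{col_kind},
#'   \code{centers}, \code{scales} (per kind), \code{grid}, \code{alpha},
#'   \code{probe}, \code{clamp}, \code{kinds}, \code{keep} (surviving
#'   column indices into the unfiltered block).
#' @export
assemble_descriptors <- function(mols, grid, kinds = .field_kinds,
                                 alpha = 0.3, probe = 1, clamp = Inf,
                                 scale = TRUE) {
  kinds <- match.arg(kinds, .field_kinds, several.ok = TRUE)
  for (m in mols) {
    if (!identical(class(m), "pae_mol")) stop("mols must be pae_mol objects")
  }
  raw <- lapply(kinds, function(k) {
    t(vapply(mols, similarity_field, numeric(prod(grid$counts)),
             grid = grid, kind = k, alpha = alpha, probe = probe,
             clamp = clamp))
  })
  centers <- list()
  scales <- numeric(0)
  blocks <- list()
  for (i in seq_along(kinds)) {
    b <- raw[[i]]
    mu <- colMeans(b)
    bc <- sweep(b, 2, mu)
    pooled <- sqrt(mean(apply(b, 2, stats::var)))
    s <- if (is.na(pooled) || pooled == 0) 1 else pooled
    blocks[[i]] <- if (scale) bc / s else b
    centers[[kinds[i]]] <- mu
    scales[kinds[i]] <- if (scale) s else 1
  }
  X <- do.call(cbind, blocks)
  npts <- prod(grid$counts)
  colnames(X) <- paste0(rep(kinds, each = npts), "_", seq_len(npts))
  rownames(X) <- vapply(mols, `[[`, character(1), "name")
  structure(list(X = X, col_kind = rep(kinds, each = npts),
                 centers = centers, scales = scales, grid = grid,
                 alpha = alpha, probe = probe, clamp = clamp,
                 kinds = kinds, scaled = scale,
                 keep = seq_len(ncol(X))),
            class = "comsia_block")
}

#' Descriptor rows for new molecules under a fitted block's scaling
#'
#' Computes raw fields for new molecules on the block's grid and applies
#' the stored centering/scaling and column filter, yielding rows
#' comparable with the training descriptor matrix.
#'
#' @param block a \code{comsia_block}.
#' @param mols list of parameterized \code{pae_mol} objects aligned to the
#'   block's frame.
#' @return matrix with one row per molecule.
#' @export
transform_descriptors <- function(block, mols) {
  npts <- prod(block$grid$counts)
  rows <- lapply(block$kinds, function(k) {
    b <- t(vapply(mols, similarity_field, numeric(npts),
                  grid = block$grid, kind = k, alpha = block$alpha,
                  probe = block$probe, clamp = block$clamp))
    if (block$scaled) sweep(b, 2, block$centers[[k]]) / block$scales[[k]]
    else b
  })
  X <- do.call(cbind, rows)
  rownames(X) <- vapply(mols, `[[`, character(1), "name")
  X[, block$keep, drop = FALSE]
}

#' Drop low-variance descriptor columns
#'
#' Removes columns whose standard deviation falls below \code{min_sigma}
#' (in block-scaled units), the similarity-field analogue of a
#' minimum-sigma filter. \code{min_sigma = 0} keeps everything.
#'
#' @param block a \code{comsia_block}.
#' @param min_sigma threshold; columns with sd < \code{min_sigma} are
#'   dropped.
#' @return the filtered \code{comsia_block}; \code{keep} records surviving
#'   column indices into the original unfiltered block.
#' @export
filter_columns <- function(block, min_sigma = 0.05) {
  sds <- apply(block$X, 2, stats::sd)
  keep <- which(sds >= min_sigma)
  if (!length(keep)) stop("minimum-sigma filter dropped every column")
  block$X <- block$X[, keep, drop = FALSE]
  block$col_kind <- block$col_kind[keep]
  block$keep <- block$keep[keep]
  block
}

#' Export one field as a volumetric grid file
#'
#' Plain-text cube-like format: a header with origin/spacing/counts and
#' one value per line in grid order (x fastest). Suitable for external
#' visualization tools.
#'
#' @param values field values in grid order.
#' @param grid the \code{comsia_grid}.
#' @param path output file.
#' @param comment header comment line.
#' @return \code{path}, invisibly.
#' @export
write_field_grid <- function(values, grid, path, comment = "similarity field") {
  stopifnot(length(values) == prod(grid$counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#", comment),
               paste("# origin", paste(grid$origin, collapse = " ")),
               paste("# spacing", grid$spacing),
               paste("# counts", paste(grid$counts, collapse = " "))), con)
  writeLines(format(values, digits = 10, trim = TRUE, scientific = TRUE), con)
  invisible(path)
}
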