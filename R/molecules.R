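# Molecule construction and parameterization. 3D embedding, MMFF94
# minimization, Gasteiger PEOE charges and Wildman-Crippen atomic logP
# contributions are delegated to RDKit through inst/python/rdkit_embed.py;
# vdW radii and H-bond donor/acceptor flags are assigned here by rule.

.rdkit_script <- function() {
  system.file("python", "rdkit_embed.py", package = "paedesign",
              mustWork = TRUE)
}

#' Invoke the bundled RDKit helper
#'
#' Low-level bridge used by [load_structures()], [embed_and_minimize()] and
#' the derivative enumerator. Writes the job as JSON, runs
#' \code{python rdkit_embed.py job.json out.json} and parses the result.
#'
#' @param job named list describing the helper action.
#' @return parsed JSON result (a list).
#' @keywords internal
run_rdkit <- function(job) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(job, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- suppressWarnings(
    system2("python", c(shQuote(.rdkit_script()), shQuote(fin),
                        shQuote(fout)),
            stdout = TRUE, stderr = TRUE))
  if (!file.exists(fout)) {
    stop("RDKit helper failed: ", paste(status, collapse = "\n"))
  }
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

.mol_from_helper <- function(rec, seed) {
  at <- rec$atoms
  atoms <- data.frame(
    elem = vapply(at$element, identity, character(1)),
    x = vapply(at$x, as.numeric, numeric(1)),
    y = vapply(at$y, as.numeric, numeric(1)),
    z = vapply(at$z, as.numeric, numeric(1)),
    formal = vapply(at$formal_charge, as.numeric, numeric(1)),
    charge = vapply(at$gasteiger, as.numeric, numeric(1)),
    logp_inc = vapply(at$crippen_logp, as.numeric, numeric(1)),
    aromatic = vapply(at$aromatic, isTRUE, logical(1)),
    n_h = vapply(at$n_h, as.numeric, numeric(1)),
    stringsAsFactors = FALSE)
  bd <- rec$bonds
  bonds <- data.frame(
    a1 = vapply(bd$begin, as.numeric, numeric(1)),
    a2 = vapply(bd$end, as.numeric, numeric(1)),
    order = vapply(bd$order, as.numeric, numeric(1)))
  structure(list(
    name = rec$name,
    smiles = rec$smiles_canonical,
    atoms = atoms,
    bonds = bonds,
    meta = list(seed = seed,
                minimized = isTRUE(rec$converged) || !is.null(rec$energy_after),
                converged = rec$converged,
                energy_before = rec$energy_before,
                energy_after = rec$energy_after)),
    class = "pae_mol")
}

.prepare_molecules <- function(smiles, names, seed, minimize,
                               max_iter = 10000, grad_tol = 1e-4) {
  job <- list(action = "embed", seed = seed, minimize = minimize,
              max_iter = max_iter, grad_tol = grad_tol,
              molecules = unname(Map(function(n, s) list(name = n, smiles = s),
                                     names, smiles)))
  res <- run_rdkit(job)
  mols <- vector("list", length(res))
  for (i in seq_along(res)) {
    if (!is.null(res[[i]]$error)) {
      stop("record ", i, " ('", names[i], "'): ", res[[i]]$error)
    }
    mols[[i]] <- .mol_from_helper(res[[i]], seed)
  }
  names(mols) <- names
  mols
}

#' Load molecules from SMILES or an SDF file
#'
#' Parses each record, adds explicit hydrogens, sanitizes valences and
#' embeds a single 3D conformer with a seeded distance-geometry method, so
#' repeated runs with the same seed give identical coordinates. Energy
#' minimization is a separate step ([embed_and_minimize()]).
#'
#' @param source character vector of SMILES (optionally named), or the path
#'   to an SDF/MOL V2000 file.
#' @param names molecule names; defaults to names of \code{source} or
#'   \code{mol<i>}.
#' @param seed integer embedding seed recorded in each molecule's metadata.
#' @return list of \code{pae_mol} objects. Each carries an atom table
#'   (element, coordinates in Angstrom, formal and Gasteiger partial
#'   charges, atomic logP increment, aromaticity, attached-H count) and a
#'   bond table (1-based atom pair, order; 1.5 for aromatic).
#' @export
load_structures <- function(source, names = NULL, seed = 20220309) {
  if (length(source) == 1L && grepl("\\.(sdf|mol)$", source, ignore.case = TRUE)) {
    return(read_sdf(source, seed = seed))
  }
  if (length(source) == 0L) return(list())
  if (is.null(names)) {
    names <- if (!is.null(base::names(source))) base::names(source)
             else paste0("mol", seq_along(source))
  }
  .prepare_molecules(as.character(source), names, seed, minimize = FALSE)
}

#' Embed and energy-minimize a molecule
#'
#' Re-embeds the molecule from its topology with the recorded seed and
#' minimizes it with the MMFF94 force field until the gradient convergence
#' criterion \code{grad_tol} is met or \code{max_iter} iterations are
#' reached; which of the two stopped the run is reported in
#' \code{$meta$converged}. Deterministic for a fixed seed.
#'
#' @param mol a \code{pae_mol}.
#' @param max_iter iteration cap.
#' @param grad_tol force tolerance (kcal/mol/A) for convergence.
#' @param seed embedding seed; defaults to the molecule's own.
#' @return minimized \code{pae_mol} with \code{energy_before},
#'   \code{energy_after} (kcal/mol) and \code{converged} in \code{$meta}.
#' @export
embed_and_minimize <- function(mol, max_iter = 10000, grad_tol = 1e-4,
                               seed = NULL) {
  stopifnot(inherits(mol, "pae_mol"))
  if (nrow(mol$atoms) < 1L) stop("molecule has no atoms")
  seed <- if (is.null(seed)) mol$meta$seed else seed
  out <- .prepare_molecules(mol$smiles, mol$name, seed, minimize = TRUE,
                            max_iter = max_iter, grad_tol = grad_tol)[[1]]
  # re-attach rule-based parameters if they had been assigned
  if (!is.null(mol$atoms$radius)) out <- assign_atom_parameters(out)
  out
}

# Bondi van der Waals radii (Angstrom)
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

#' Assign per-atom physicochemical parameters
#'
#' Completes the per-atom parameter set used by the similarity-field
#' engine: van der Waals radii from the Bondi element table, hydrogen-bond
#' donor flags (H atoms bound to N or O), acceptor flags (N or O with an
#' available lone pair: nonpositive formal charge and, for N, fewer than
#' four connections). Gasteiger partial charges and atomic logP increments
#' are already present from molecule loading. For a neutral molecule the
#' partial charges must sum to ~0; this is checked.
#'
#' @param mol a \code{pae_mol}.
#' @return the molecule with \code{radius}, \code{donor} and
#'   \code{acceptor} columns added to its atom table.
#' @export
assign_atom_parameters <- function(mol) {
  stopifnot(inherits(mol, "pae_mol"))
  at <- mol$atoms
  unknown <- setdiff(unique(at$elem), names(.vdw_radii))
  if (length(unknown)) {
    stop("unparameterized element(s): ", paste(unknown, collapse = ", "))
  }
  at$radius <- unname(.vdw_radii[at$elem])

  # heavy-neighbor bookkeeping from the bond table
  nb <- vector("list", nrow(at))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  degree <- lengths(nb)
  at$donor <- as.numeric(
    at$elem == "H" &
      vapply(nb, function(v) any(at$elem[v] %in% c("N", "O")), logical(1)))
  at$acceptor <- as.numeric(
    at$elem %in% c("N", "O") & at$formal <= 0 &
      !(at$elem == "N" & degree >= 4))

  net <- sum(at$formal)
  if (net == 0 && abs(sum(at$charge)) > 1e-3) {
    stop("partial charges of a neutral molecule must sum to ~0 (got ",
         signif(sum(at$charge), 3), ")")
  }
  mol$atoms <- at
  mol
}

#' Write molecules to an SDF (MOL V2000) file
#'
#' @param mols list of \code{pae_mol} objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "pae_mol")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    at <- mol$atoms; bd <- mol$bonds
    writeLines(c(mol$name, "  paedesign", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(bd)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       at$x, at$y, at$z, at$elem), con)
    # aromatic bonds carry MOL-file type 4
    btype <- ifelse(bd$order == 1.5, 4L, as.integer(bd$order))
    writeLines(sprintf("%3d%3d%3d  0", bd$a1, bd$a2, btype), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read molecules from an SDF (MOL V2000) file
#'
#' Records are parsed and sanitized by the RDKit helper; existing
#' coordinates are kept (no re-embedding).
#'
#' @param path SDF file.
#' @param seed seed recorded in metadata (embedding is not rerun).
#' @return list of \code{pae_mol} objects.
#' @export
read_sdf <- function(path, seed = 20220309) {
  txt <- readLines(path)
  ends <- grep("^\\$\\$\\$\\$", txt)
  if (!length(ends)) stop("no records in ", path)
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- mapply(function(s, e) paste(txt[s:(e - 1L)], collapse = "\n"),
                   starts, ends)
  nms <- vapply(starts, function(s) {
    nm <- trimws(txt[s]); if (nzchar(nm)) nm else paste0("mol", s)
  }, character(1))
  job <- list(action = "embed", seed = seed, minimize = FALSE,
              molecules = unname(Map(function(n, b) list(name = n, molblock = b),
                                     nms, blocks)))
  res <- run_rdkit(job)
  mols <- vector("list", length(res))
  for (i in seq_along(res)) {
    if (!is.null(res[[i]]$error)) {
      stop("record ", i, " in ", path, ": ", res[[i]]$error)
    }
    mols[[i]] <- .mol_from_helper(res[[i]], seed)
  }
  names(mols) <- nms
  mols
}

#' @export
print.pae_mol <- function(x, ...) {
  cat("<pae_mol> ", x$name, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds", sep = "")
  if (isTRUE(x$meta$minimized)) {
    cat(sprintf(" (MMFF94 %.2f -> %.2f kcal/mol)",
                x$meta$energy_before, x$meta$energy_after))
  }
  cat("\n")
  invisible(x)
}

#' Atom coordinate matrix of a molecule
#' @param mol a \code{pae_mol}.
#' @return numeric matrix with one row per atom, columns x/y/z (Angstrom).
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}
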