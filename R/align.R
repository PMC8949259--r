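# Scaffold matching and rigid-body superposition. Every phthalate shares
# the benzene-1,2-dicarboxylate (phthalate diester) core; matching that
# core between a molecule and the template gives the atom pairing for a
# least-squares (Kabsch) alignment.

# Heavy-atom graph with element/connectivity colors: C = 1, terminal O
# (one heavy neighbor, i.e. carbonyl O) = 2, bridging O = 3, N = 4,
# other = 5+. Colors let the matcher distinguish ester from carbonyl
# oxygens so the pairing is chemically meaningful.
.heavy_graph <- function(mol) {
  at <- mol$atoms
  heavy <- which(at$elem != "H")
  idx <- match(seq_len(nrow(at)), heavy)   # full index -> heavy index
  bd <- mol$bonds
  keep <- at$elem[bd$a1] != "H" & at$elem[bd$a2] != "H"
  el <- cbind(idx[bd$a1[keep]], idx[bd$a2[keep]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  hdeg <- igraph::degree(g)
  elem <- at$elem[heavy]
  color <- ifelse(elem == "C", 1L,
           ifelse(elem == "O" & hdeg == 1L, 2L,
           ifelse(elem == "O", 3L,
           ifelse(elem == "N", 4L, 5L + match(elem, names(.vdw_radii))))))
  igraph::V(g)$color <- color
  list(graph = g, heavy = heavy)
}

# The 12-atom phthalate diester core as a colored pattern graph:
# ring carbons 1-6, carbonyl carbons 7 and 10, carbonyl oxygens 8 and 11,
# ester (bridging) oxygens 9 and 12.
.phthalate_pattern <- function() {
  el <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1),
              c(1, 7), c(7, 8), c(7, 9),
              c(2, 10), c(10, 11), c(10, 12))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$color <- c(rep(1L, 6), 1L, 2L, 3L, 1L, 2L, 3L)
  g
}

.core_match <- function(mol) {
  hg <- .heavy_graph(mol)
  pat <- .phthalate_pattern()
  maps <- igraph::subgraph_isomorphisms(pattern = pat, target = hg$graph,
                                        method = "vf2")
  if (!length(maps)) return(NULL)
  cand <- lapply(maps, function(m) hg$heavy[as.integer(m)])
  # deterministic tie-break among symmetry-equivalent matches
  ord <- order(vapply(cand, function(v) paste(sprintf("%05d", v),
                                              collapse = ""), character(1)))
  cand[[ord[1]]]
}

#' Map the phthalate diester core of a molecule onto a template's
#'
#' Finds the 12-atom benzene-1,2-dicarboxylate core (ring, carbonyl
#' carbons, carbonyl and ester oxygens) in both molecules by colored
#' subgraph isomorphism and pairs the matched atoms. Symmetry-equivalent
#' matches are resolved by a deterministic canonical order.
#'
#' @param mol,template \code{pae_mol} objects.
#' @return data frame with columns \code{template} and \code{target}
#'   (1-based atom indices), class \code{scaffold_match}.
#' @export
scaffold_match <- function(mol, template) {
  mt <- .core_match(template)
  if (is.null(mt)) stop("template '", template$name,
                        "' has no phthalate diester core")
  mm <- .core_match(mol)
  if (is.null(mm)) stop("molecule '", mol$name,
                        "' has no phthalate diester core")
  structure(data.frame(template = mt, target = mm),
            class = c("scaffold_match", "data.frame"))
}

#' Least-squares rigid superposition onto a template
#'
#' Kabsch alignment: the optimal rotation (via singular value
#' decomposition, determinant-corrected to a proper rotation) and
#' translation minimizing the RMSD over the mapped atom pairs. The full
#' molecule is transformed with the fitted map.
#'
#' @param mol \code{pae_mol} to move.
#' @param template \code{pae_mol} providing the reference frame.
#' @param match atom pairing from [scaffold_match()], or any data frame
#'   with \code{template}/\code{target} index columns (>= 3 non-collinear
#'   pairs, injective).
#' @return list of class \code{pae_alignment}: \code{mol} (transformed
#'   molecule), \code{rotation} (3x3, det +1), \code{translation} (length
#'   3, Angstrom) and \code{rmsd} (Angstrom over mapped atoms). The fit
#'   maps target coordinates as \code{x \%*\% rotation + translation}.
#' @export
align_to_template <- function(mol, template, match = scaffold_match(mol, template)) {
  if (nrow(match) < 3L) stop("need at least 3 mapped atoms")
  if (anyDuplicated(match$template) || anyDuplicated(match$target)) {
    stop("scaffold match must be injective")
  }
  P <- coords(template)[match$template, , drop = FALSE]
  Q <- coords(mol)[match$target, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2L || qr(Qc)$rank < 2L) {
    stop("mapped atoms are collinear; superposition is underdetermined")
  }
  H <- crossprod(Qc, Pc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- cp - drop(cq %*% R)
  rmsd <- sqrt(mean(rowSums((Qc %*% R - Pc)^2)))
  xyz <- coords(mol) %*% R + rep(tr, each = nrow(mol$atoms))
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  structure(list(mol = mol, rotation = R, translation = tr, rmsd = rmsd,
                 n_mapped = nrow(match)),
            class = "pae_alignment")
}

#' @export
print.pae_alignment <- function(x, ...) {
  cat(sprintf("<pae_alignment> %s: RMSD %.4f A over %d mapped atoms\n",
              x$mol$name, x$rmsd, x$n_mapped))
  invisible(x)
}

#' Export an alignment transform as JSON
#' @param alignment a \code{pae_alignment}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  jsonlite::write_json(
    list(name = alignment$mol$name,
         rotation = alignment$rotation,
         translation = alignment$translation,
         rmsd = alignment$rmsd),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
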