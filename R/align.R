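# Rigid-body template alignment (Kabsch superposition + element-graph
# substructure matching via igraph's VF2).

#' Kabsch superposition
#'
#' Finds the rigid rotation/translation minimising the RMSD between paired
#' point sets and returns the transform together with the minimised RMSD.
#'
#' @param moving,fixed n x 3 coordinate matrices with row i of `moving`
#'   corresponding to row i of `fixed`.
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `moving %*% t(rotation) + translation` superposes onto `fixed`, and
#'   `rmsd` (Angstrom).
#' @export
kabsch <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3L, ncol(fixed) == 3L)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2L, cm); Q <- sweep(fixed, 2L, cf)
  s <- svd(crossprod(P, Q)) # H = P'Q
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = as.numeric(cf - cm %*% t(R)), rmsd = rmsd)
}

# molecule -> igraph with element vertex colours (heavy atoms only when
# heavy = TRUE); vertex attribute `atom` holds the original atom index
.mol_graph <- function(mol, heavy = TRUE) {
  keep <- if (heavy) which(mol$atoms$element != "H") else seq_len(nrow(mol$atoms))
  remap <- match(seq_len(nrow(mol$atoms)), keep)
  b <- mol$bonds
  if (nrow(b)) {
    sel <- !is.na(remap[b$from]) & !is.na(remap[b$to])
    edges <- rbind(remap[b$from[sel]], remap[b$to[sel]])
  } else edges <- matrix(integer(), 2L, 0L)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (ncol(edges)) g <- igraph::add_edges(g, as.vector(edges))
  igraph::V(g)$element <- mol$atoms$element[keep]
  igraph::V(g)$atom <- keep
  g
}

# integer colour codes shared across two graphs
.element_colors <- function(...) {
  els <- unique(unlist(list(...)))
  function(e) match(e, els)
}

#' Find substructure matches of a template in a molecule
#'
#' The template is an element-labelled connectivity pattern: either a plain
#' SMILES/SMARTS-subset string (elements and ring closures only; parsed with
#' ChemmineR) or a `mol3d`. Matching is VF2 subgraph isomorphism on the
#' heavy-atom graphs with element identity as the vertex constraint; bond
#' orders are not constrained.
#'
#' @param mol target `mol3d`.
#' @param template pattern (character SMILES or `mol3d`).
#' @return list of integer vectors; each maps template heavy atom i to an
#'   atom index of `mol`. Ordered by the atom-index tuple.
#' @export
match_template <- function(mol, template) {
  tmol <- if (is.character(template)) .template_to_mol(template) else template
  gp <- .mol_graph(tmol); gt <- .mol_graph(mol)
  col <- .element_colors(igraph::V(gp)$element, igraph::V(gt)$element)
  maps <- igraph::subgraph_isomorphisms(
    pattern = gp, target = gt, method = "vf2",
    vertex.color1 = col(igraph::V(gp)$element),
    vertex.color2 = col(igraph::V(gt)$element))
  matches <- lapply(maps, function(m) igraph::V(gt)$atom[as.integer(m)])
  if (length(matches) > 1L) {
    ord <- order(vapply(matches, function(v) paste(sprintf("%06d", v), collapse = ""),
                        character(1)))
    matches <- matches[ord]
  }
  matches
}

.template_to_mol <- function(smiles) {
  sdf <- tryCatch(ChemmineR::smiles2sdf(smiles),
                  error = function(e) stop("cannot parse template: ", smiles))
  .sdf_to_mol3d(sdf[[1]], id = "template")
}

#' Align a molecule onto a reference via a common template
#'
#' Matches `template` in both `mol` and `reference`, superposes the matched
#' atoms of `mol` onto those of `reference` by the Kabsch rigid transform,
#' and applies that transform to the whole molecule. When several matches
#' exist the one minimising RMSD is used (ties broken by the lowest
#' atom-index tuple, which is the enumeration order).
#'
#' Instead of a pattern, `template` may be a list
#' `list(mol_idx =, ref_idx =)` giving an explicit atom correspondence.
#'
#' @param mol `mol3d` to align.
#' @param template pattern (SMILES string or `mol3d`) present in both
#'   molecules, or an explicit index correspondence.
#' @param reference `mol3d` defining the target frame.
#' @return the aligned `mol3d`, with the minimised template RMSD stored in
#'   its `rmsd` field.
#' @export
align_to_template <- function(mol, template, reference) {
  if (is.list(template) && !inherits(template, "mol3d")) {
    pairs <- list(list(mol_idx = template$mol_idx, ref_idx = template$ref_idx))
  } else {
    mm <- match_template(mol, template)
    rm_ <- match_template(reference, template)
    if (!length(mm)) stop("template does not match molecule ", mol$id)
    if (!length(rm_)) stop("template does not match reference ", reference$id)
    pairs <- lapply(mm, function(mi) list(mol_idx = mi, ref_idx = rm_[[1L]]))
  }
  refxyz <- mol_coords(reference)
  molxyz <- mol_coords(mol)
  best <- NULL
  for (p in pairs) {
    k <- kabsch(molxyz[p$mol_idx, , drop = FALSE],
                refxyz[p$ref_idx, , drop = FALSE])
    if (is.null(best) || k$rmsd < best$rmsd - 1e-12) best <- k
  }
  out <- mol_transform(mol, best$rotation, best$translation)
  out$rmsd <- best$rmsd
  out
}

#' Align a whole congeneric series to one reference
#'
#' @param molecules list of `mol3d`.
#' @param template shared substructure pattern.
#' @param reference reference `mol3d`; defaults to the first molecule.
#' @return list of aligned molecules (each with an `rmsd` field).
#' @export
align_series <- function(molecules, template, reference = molecules[[1L]]) {
  lapply(molecules, align_to_template, template = template, reference = reference)
}
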