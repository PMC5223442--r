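# Pharmacophore feature perception.
#
# Six feature kinds: A hydrogen-bond acceptor, D hydrogen-bond donor,
# H hydrophobic group, N negatively ionizable, P positively ionizable,
# R aromatic ring. Rules are deliberately small and documented here:
#   A: N/O not positively charged (direction: idealised lone pair, the
#      negated mean of bond unit vectors)
#   D: each O-H / N-H bond (position at the heavy atom, direction X->H)
#   P: nitrogen with formal charge +1
#   N: carboxylate/sulfonate/phosphate-style group - C/S/P bearing >= 2
#      oxygens at least one of which carries formal charge -1 (position at
#      the oxygen centroid); other formally negative atoms individually
#   R: aromatic 5/6-ring (all bonds aromatic, or every ring atom sp2 with
#      O/S/N members allowed when flanked by sp2 ring neighbours); position
#      at the ring centroid, direction along the ring normal
#   H: connected groups of non-aromatic carbons/halogens with no N/O/S
#      neighbour (position at the group centroid)

.ring_cycles <- function(mol, max_len = 6L) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  if (nrow(mol$bonds))
    for (i in seq_len(nrow(mol$bonds))) {
      f <- mol$bonds$from[i]; t_ <- mol$bonds$to[i]
      adj[[f]] <- c(adj[[f]], t_); adj[[t_]] <- c(adj[[t_]], f)
    }
  cycles <- list()
  # DFS from each start vertex, only visiting larger-indexed vertices, so
  # each cycle is found from its smallest member
  dfs <- function(start, path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3L) {
        cycles[[length(cycles) + 1L]] <<- path
      } else if (w > start && !(w %in% path) && length(path) < max_len) {
        dfs(start, c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s, s)
  keys <- vapply(cycles, function(cy) paste(sort(cy), collapse = "-"), character(1))
  cycles[!duplicated(keys)]
}

.is_aromatic_ring <- function(mol, ring, hyb) {
  el <- mol$atoms$element[ring]
  if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
  b <- mol$bonds
  in_ring <- function(i, j) any((b$from == i & b$to == j) | (b$from == j & b$to == i))
  ring_bonds <- b[(b$from %in% ring) & (b$to %in% ring), , drop = FALSE]
  if (nrow(ring_bonds) && all(ring_bonds$order == 4)) return(TRUE)
  ok <- vapply(seq_along(ring), function(i) {
    a <- ring[i]
    if (hyb[a] == "sp2") return(TRUE)
    if (!mol$atoms$element[a] %in% c("N", "O", "S")) return(FALSE)
    nb <- ring[ring != a & vapply(ring, in_ring, logical(1), j = a)]
    length(nb) > 0L && all(hyb[nb] == "sp2")
  }, logical(1))
  all(ok)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) return(c(NA_real_, NA_real_, NA_real_))
  v / n
}

.feature_row <- function(kind, pos, dir = c(NA, NA, NA), source = integer()) {
  data.frame(kind = kind, x = pos[1], y = pos[2], z = pos[3],
             dx = dir[1], dy = dir[2], dz = dir[3],
             source = I(list(as.integer(source))))
}

#' Perceive pharmacophore features of a molecule
#'
#' @param mol a `mol3d` with explicit hydrogens and 3D coordinates.
#' @return data.frame of class `pharma_features` with columns `kind`
#'   (A/D/H/N/P/R), position `x,y,z` (Angstrom), optional unit direction
#'   `dx,dy,dz` (A/D/R), and the source atom indices.
#' @export
perceive_features <- function(mol) {
  stopifnot(inherits(mol, "mol3d"))
  xyz <- mol_coords(mol)
  el <- mol$atoms$element
  hyb <- atom_hybridization(mol)
  b <- mol$bonds
  nbrs <- function(i) c(b$to[b$from == i], b$from[b$to == i])
  rows <- list()

  # aromatic rings
  rings <- Filter(function(r) length(r) %in% c(5L, 6L), .ring_cycles(mol))
  aromatic_atoms <- integer(0)
  for (r in rings) {
    if (!.is_aromatic_ring(mol, r, hyb)) next
    aromatic_atoms <- union(aromatic_atoms, r)
    ctr <- colMeans(xyz[r, , drop = FALSE])
    cen <- sweep(xyz[r, , drop = FALSE], 2L, ctr)
    normal <- svd(cen)$v[, 3L]
    rows[[length(rows) + 1L]] <- .feature_row("R", ctr, .unit(normal), r)
  }

  # donors: each O-H / N-H bond
  for (i in which(el %in% c("O", "N"))) {
    for (h in nbrs(i)) if (el[h] == "H")
      rows[[length(rows) + 1L]] <-
        .feature_row("D", xyz[i, ], .unit(xyz[h, ] - xyz[i, ]), c(i, h))
  }

  # acceptors: N/O not positively charged; lone-pair direction
  for (i in which(el %in% c("O", "N"))) {
    if (mol$atoms$formal[i] > 0L) next
    if (el[i] == "N" && length(nbrs(i)) >= 4L) next
    nb <- nbrs(i)
    dir <- if (length(nb)) .unit(-rowSums(matrix(
      apply(xyz[nb, , drop = FALSE], 1L, function(p) .unit(p - xyz[i, ])),
      nrow = 3L))) else c(NA, NA, NA)
    rows[[length(rows) + 1L]] <- .feature_row("A", xyz[i, ], dir, i)
  }

  # positively ionizable
  for (i in which(el == "N" & mol$atoms$formal > 0L))
    rows[[length(rows) + 1L]] <- .feature_row("P", xyz[i, ], source = i)

  # negatively ionizable groups
  used_neg <- integer(0)
  for (i in which(el %in% c("C", "S", "P"))) {
    ox <- intersect(nbrs(i), which(el == "O"))
    if (length(ox) >= 2L && any(mol$atoms$formal[ox] < 0L)) {
      rows[[length(rows) + 1L]] <-
        .feature_row("N", colMeans(xyz[ox, , drop = FALSE]), source = c(i, ox))
      used_neg <- union(used_neg, ox)
    }
  }
  for (i in setdiff(which(mol$atoms$formal < 0L & el != "C"), used_neg))
    rows[[length(rows) + 1L]] <- .feature_row("N", xyz[i, ], source = i)

  # hydrophobic groups: non-aromatic C/halogen clusters with no polar contact
  hydro_ok <- which(el %in% c("C", "F", "Cl", "Br", "I"))
  hydro_ok <- setdiff(hydro_ok, aromatic_atoms)
  hydro_ok <- hydro_ok[vapply(hydro_ok, function(i)
    !any(el[nbrs(i)] %in% c("N", "O", "S")), logical(1))]
  if (length(hydro_ok)) {
    sub <- b[b$from %in% hydro_ok & b$to %in% hydro_ok, , drop = FALSE]
    g <- igraph::make_empty_graph(n = length(hydro_ok), directed = FALSE)
    if (nrow(sub))
      g <- igraph::add_edges(g, rbind(match(sub$from, hydro_ok),
                                      match(sub$to, hydro_ok)))
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      atoms <- hydro_ok[comp == cid]
      if (!any(el[atoms] == "C")) next
      rows[[length(rows) + 1L]] <-
        .feature_row("H", colMeans(xyz[atoms, , drop = FALSE]), source = atoms)
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    .feature_row("A", c(NA, NA, NA))[0L, ]
  out <- out[order(out$kind, out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pharma_features", "data.frame")
  attr(out, "molecule_id") <- mol$id
  out
}

#' @export
print.pharma_features <- function(x, ...) {
  cat("Pharmacophore features of", attr(x, "molecule_id") %||% "?", ":",
      paste(x$kind, collapse = ""), "\n")
  print.data.frame(x[, c("kind", "x", "y", "z")], digits = 3)
  invisible(x)
}
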