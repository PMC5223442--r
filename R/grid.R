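#' Rectangular field grid
#'
#' The probe grid on which steric and electrostatic molecular-field
#' descriptors are evaluated. Defaults are CoMFA-style: an sp3-carbon probe
#' (radius 1.70 A, well depth 0.1094 kcal/mol, charge +1 e), dielectric 1,
#' and a +-30 kcal/mol energy truncation.
#'
#' @param origin numeric length-3, grid corner (Angstrom).
#' @param spacing grid step in Angstrom (> 0).
#' @param dims integer length-3 point counts per axis (>= 1).
#' @param probe list with `radius`, `eps`, `charge`.
#' @param dielectric dimensionless dielectric constant.
#' @param truncation energy clamp in kcal/mol (> 0).
#' @return object of class `field_grid`.
#' @export
field_grid <- function(origin, spacing, dims,
                       probe = list(radius = 1.70, eps = 0.1094, charge = 1.0),
                       dielectric = 1.0, truncation = 30.0) {
  stopifnot(length(origin) == 3L, length(dims) == 3L,
            spacing > 0, all(dims >= 1L), truncation > 0)
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = as.integer(dims), probe = probe,
                 dielectric = dielectric, truncation = truncation),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d x %d x %d points, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  probe r %.2f A, eps %.4f, q %+.1f e; dielectric %.1f; clamp +-%.1f kcal/mol\n",
              x$probe$radius, x$probe$eps, x$probe$charge, x$dielectric, x$truncation))
  invisible(x)
}

#' Build a grid covering a set of aligned molecules
#'
#' The grid spans the union bounding box of all atoms extended by `margin`
#' on each side, with `dims = ceiling(extent / spacing) + 1` per axis.
#'
#' @param molecules list of `mol3d` in the common alignment frame.
#' @param margin padding in Angstrom.
#' @param spacing grid step in Angstrom.
#' @param ... further arguments for [field_grid()].
#' @return a `field_grid`.
#' @export
build_grid <- function(molecules, margin = 4.0, spacing = 2.0, ...) {
  if (length(molecules) == 0L) stop("cannot build a grid for an empty molecule set")
  xyz <- do.call(rbind, lapply(molecules, mol_coords))
  lo <- apply(xyz, 2L, min) - margin
  hi <- apply(xyz, 2L, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  field_grid(origin = lo, spacing = spacing, dims = dims, ...)
}

#' Cartesian coordinates of all grid points
#'
#' Points are ordered by the flattened index `k = ix + nx*(iy + ny*iz)` with
#' 0-based `(ix, iy, iz)`, the same numbering used in descriptor labels.
#'
#' @param grid a `field_grid`.
#' @return (nx*ny*nz) x 3 matrix.
#' @export
grid_points <- function(grid) {
  d <- grid$dims
  ix <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  iy <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  iz <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  cbind(grid$origin[1] + ix * grid$spacing,
        grid$origin[2] + iy * grid$spacing,
        grid$origin[3] + iz * grid$spacing)
}

#' Decode a descriptor label to its grid point
#'
#' Labels have the form `S_k` or `E_k` where `k` is the 0-based flattened
#' grid index `k = ix + nx*(iy + ny*iz)`.
#'
#' @param label character vector of labels.
#' @param grid the `field_grid` the labels refer to.
#' @return data.frame with columns `field` ("S"/"E"), `k`, `ix`, `iy`, `iz`,
#'   `x`, `y`, `z`.
#' @export
decode_label <- function(label, grid) {
  m <- regmatches(label, regexec("^([SE])_([0-9]+)$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed descriptor label(s): ",
                     paste(label[bad], collapse = ", "))
  field <- vapply(m, `[`, character(1), 2L)
  k <- as.integer(vapply(m, `[`, character(1), 3L))
  d <- grid$dims
  if (any(k < 0L | k >= prod(d))) stop("label index outside grid dims")
  ix <- k %% d[1]
  iy <- (k %/% d[1]) %% d[2]
  iz <- k %/% (d[1] * d[2])
  data.frame(field = field, k = k, ix = ix, iy = iy, iz = iz,
             x = grid$origin[1] + ix * grid$spacing,
             y = grid$origin[2] + iy * grid$spacing,
             z = grid$origin[3] + iz * grid$spacing,
             stringsAsFactors = FALSE)
}

# point-to-atom distance matrix, npoints x natoms
.point_atom_dist <- function(pts, xyz) {
  d2 <- outer(rowSums(pts^2), rowSums(xyz^2), "+") - 2 * (pts %*% t(xyz))
  sqrt(pmax(d2, 0))
}

#' Steric probe field
#'
#' Lennard-Jones 6-12 interaction of the grid probe with every atom,
#' `sum_atoms eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with
#' Lorentz-Berthelot-style mixing `rmin_ij = r_probe + r_atom`,
#' `eps_ij = sqrt(eps_probe * eps_atom)`, clamped to the grid truncation.
#' A grid point within 1e-6 A of an atom reports `+truncation`.
#'
#' @param mol a `mol3d` (radii are looked up per element).
#' @param grid a `field_grid`.
#' @return numeric vector, one kcal/mol value per grid point.
#' @export
steric_field <- function(mol, grid) {
  xyz <- mol_coords(mol)
  rmin <- grid$probe$radius + .element_lookup(mol$atoms$element, "radius")
  eps <- sqrt(grid$probe$eps * .element_lookup(mol$atoms$element, "eps"))
  r <- .point_atom_dist(grid_points(grid), xyz)
  sing <- r < 1e-6
  r[sing] <- 1 # placeholder; singular points forced to +truncation below
  sr6 <- (matrix(rmin, nrow(r), ncol(r), byrow = TRUE) / r)^6
  e <- sweep(sr6^2 - 2 * sr6, 2L, eps, "*")
  e[sing] <- grid$truncation
  v <- rowSums(e)
  pmin(pmax(v, -grid$truncation), grid$truncation)
}

#' Electrostatic probe field
#'
#' Coulomb interaction `sum_atoms 332.06 * q_atom * q_probe /
#' (dielectric * r)` in kcal/mol, clamped to the truncation; a point
#' coincident with an atom clamps toward the sign of that atom's charge.
#'
#' @inheritParams steric_field
#' @return numeric vector of kcal/mol values per grid point.
#' @export
electrostatic_field <- function(mol, grid) {
  xyz <- mol_coords(mol)
  q <- mol$atoms$charge * grid$probe$charge * 332.06 / grid$dielectric
  r <- .point_atom_dist(grid_points(grid), xyz)
  sing <- r < 1e-6
  r[sing] <- 1e-6
  e <- sweep(1 / r, 2L, q, "*")
  v <- rowSums(e)
  pmin(pmax(v, -grid$truncation), grid$truncation)
}

#' Molecular-field descriptor matrix
#'
#' One row per molecule, columns `S_0 ... S_{n-1}` then `E_0 ... E_{n-1}`
#' (flattened grid order). All molecules must carry alignment metadata (an
#' `rmsd` field set by [align_to_template()] or the synthetic generator),
#' since field values are only comparable in a common frame.
#'
#' @param molecules list of aligned `mol3d` with partial charges.
#' @param grid a `field_grid`.
#' @return numeric matrix of class `descriptor_matrix` with molecule ids as
#'   rownames, labels as colnames, and the grid stored in attribute `grid`.
#' @export
compute_descriptor_matrix <- function(molecules, grid) {
  if (length(molecules) == 0L) stop("empty molecule set")
  unaligned <- vapply(molecules, function(m) is.null(m$rmsd), logical(1))
  if (any(unaligned))
    stop("molecule(s) without alignment metadata: ",
         paste(vapply(molecules[unaligned], `[[`, character(1), "id"),
               collapse = ", "))
  n <- prod(grid$dims)
  rows <- lapply(molecules, function(m)
    c(steric_field(m, grid), electrostatic_field(m, grid)))
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(molecules, `[[`, character(1), "id")
  colnames(x) <- c(paste0("S_", seq_len(n) - 1L), paste0("E_", seq_len(n) - 1L))
  structure(x, class = c("descriptor_matrix", class(x)), grid = grid)
}

#' Drop invariant descriptor columns
#'
#' Removes columns whose population variance (over training rows, when
#' given) falls below `variance_cutoff`, mirroring the elimination of
#' "static" grid points that cannot explain activity differences.
#'
#' @param x a `descriptor_matrix` (or plain matrix).
#' @param variance_cutoff minimum population variance (kcal^2/mol^2).
#' @param train_ids optional rownames over which variance is computed.
#' @return the filtered matrix (attributes preserved).
#' @export
drop_invariant_columns <- function(x, variance_cutoff = 1.0, train_ids = NULL) {
  if (nrow(x) < 2L) stop("need at least 2 rows to assess column variance")
  sub <- if (is.null(train_ids)) x else x[train_ids, , drop = FALSE]
  m <- colMeans(sub)
  v <- colMeans(sweep(sub, 2L, m)^2) # population variance
  keep <- v >= variance_cutoff & v > 0
  if (!any(keep))
    stop("all columns removed; lower variance_cutoff (currently ",
         variance_cutoff, ")")
  out <- x[, keep, drop = FALSE]
  attr(out, "grid") <- attr(x, "grid")
  class(out) <- class(x)
  out
}

#' Write a descriptor matrix and its grid sidecar
#' @param x a `descriptor_matrix`.
#' @param path CSV output path; the grid is written to `<path>.grid.yaml`.
#' @export
write_descriptors <- function(x, path) {
  df <- data.frame(molecule_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  g <- attr(x, "grid")
  if (!is.null(g))
    yaml::write_yaml(list(origin = g$origin, spacing = g$spacing,
                          dims = g$dims, probe = g$probe,
                          dielectric = g$dielectric, truncation = g$truncation),
                     paste0(path, ".grid.yaml"))
  invisible(path)
}

#' Read a descriptor matrix written by [write_descriptors()]
#' @param path CSV path.
#' @return `descriptor_matrix` (with grid attribute when the sidecar exists).
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  rownames(x) <- df[[1L]]
  side <- paste0(path, ".grid.yaml")
  g <- NULL
  if (file.exists(side)) {
    y <- yaml::read_yaml(side)
    g <- field_grid(y$origin, y$spacing, y$dims, probe = y$probe,
                    dielectric = y$dielectric, truncation = y$truncation)
  }
  structure(x, class = c("descriptor_matrix", class(x)), grid = g)
}
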