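#' 3D molecule container
#'
#' `mol3d()` builds the light-weight molecule representation used throughout
#' the package: a set of atoms with Cartesian coordinates (Angstrom), partial
#' charges (e) and formal charges, plus a bond table. It is the unit of all
#' geometry and field computation.
#'
#' @param id character molecule identifier.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (partial charge, e) and `formal` (formal charge).
#' @param bonds data.frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (1, 2, 3; 4 denotes aromatic). May be `NULL` for
#'   disconnected point sets.
#' @param conformer_tag integer conformer label.
#' @return an object of class `mol3d`.
#' @export
mol3d <- function(id, atoms, bonds = NULL, conformer_tag = 1L) {
  stopifnot(is.character(id), length(id) == 1L)
  atoms <- as.data.frame(atoms)
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns element, x, y, z")
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$formal)) atoms$formal <- 0L
  atoms$element <- as.character(atoms$element)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in molecule ", id)
  if (is.null(bonds)) {
    bonds <- data.frame(from = integer(), to = integer(), order = numeric())
  } else {
    bonds <- as.data.frame(bonds)
    if (!all(c("from", "to", "order") %in% names(bonds)))
      stop("bonds must have columns from, to, order")
    if (nrow(bonds) && (max(bonds$from, bonds$to) > nrow(atoms) ||
                        min(bonds$from, bonds$to) < 1L))
      stop("bond atom index out of range in molecule ", id)
  }
  structure(
    list(id = id, atoms = atoms, bonds = bonds,
         conformer_tag = as.integer(conformer_tag)),
    class = "mol3d")
}

#' @export
print.mol3d <- function(x, ...) {
  comp <- table(x$atoms$element)
  formula <- paste0(names(comp), ifelse(comp > 1L, comp, ""), collapse = "")
  cat("<mol3d> ", x$id, ": ", nrow(x$atoms), " atoms (", formula, "), ",
      nrow(x$bonds), " bonds", sep = "")
  if (!is.null(x$rmsd)) cat(sprintf(", alignment rmsd %.4f A", x$rmsd))
  cat("\n")
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param mol a `mol3d`.
#' @return numeric n x 3 matrix.
#' @export
mol_coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Apply a rigid transform to a molecule
#'
#' Coordinates become `coords %*% t(rotation) + translation`.
#'
#' @param mol a `mol3d`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return the transformed `mol3d` (all other fields preserved).
#' @export
mol_transform <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- mol_coords(mol) %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, "+")
  mol$atoms$x <- xyz[, 1L]
  mol$atoms$y <- xyz[, 2L]
  mol$atoms$z <- xyz[, 3L]
  mol
}

#' Validate a molecule's internal invariants
#'
#' Checks coordinate finiteness, bond index range, and (when partial charges
#' have been assigned) that they sum to the net formal charge within `tol`.
#'
#' @param mol a `mol3d`.
#' @param tol charge-conservation tolerance in e.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_mol3d <- function(mol, tol = 1e-3) {
  stopifnot(inherits(mol, "mol3d"))
  if (!all(is.finite(mol_coords(mol))))
    stop("non-finite coordinates in ", mol$id)
  if (nrow(mol$bonds)) {
    idx <- c(mol$bonds$from, mol$bonds$to)
    if (any(idx < 1L | idx > nrow(mol$atoms)))
      stop("bond index out of range in ", mol$id)
  }
  if (isTRUE(attr(mol, "charged"))) {
    dq <- abs(sum(mol$atoms$charge) - sum(mol$atoms$formal))
    if (dq > tol)
      stop(sprintf("charge sum deviates from net formal charge by %.2e e in %s",
                   dq, mol$id))
  }
  invisible(TRUE)
}

# rotation matrix about an arbitrary axis (Rodrigues), used in tests and the
# synthetic generator
#' Rotation matrix about an axis
#' @param axis length-3 axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
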