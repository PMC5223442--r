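#' Atom hybridisation from the bond table
#'
#' sp for a triple bond or two+ double bonds, sp2 for any double or aromatic
#' bond, sp3 otherwise. Used to select Gasteiger-Marsili parameters.
#'
#' @param mol a `mol3d`.
#' @return character vector ("sp", "sp2", "sp3") per atom.
#' @export
atom_hybridization <- function(mol) {
  n <- nrow(mol$atoms)
  ndouble <- ntriple <- narom <- integer(n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[i, ]
      if (b$order == 2) { ndouble[b$from] <- ndouble[b$from] + 1L
                          ndouble[b$to] <- ndouble[b$to] + 1L }
      if (b$order == 3) { ntriple[b$from] <- ntriple[b$from] + 1L
                          ntriple[b$to] <- ntriple[b$to] + 1L }
      if (b$order == 4) { narom[b$from] <- narom[b$from] + 1L
                          narom[b$to] <- narom[b$to] + 1L }
    }
  }
  ifelse(ntriple > 0L | ndouble >= 2L, "sp",
         ifelse(ndouble > 0L | narom > 0L, "sp2", "sp3"))
}

#' Gasteiger-Marsili partial charges
#'
#' Iterative partial equalisation of orbital electronegativity (PEOE).
#' Electronegativity of atom i at charge q is `chi_i = a + b q + c q^2`;
#' in iteration k each bond transfers
#' `dq = (chi_j - chi_i) / chi_donor_plus * (1/2)^k`
#' from the less to the more electronegative atom, where `chi_plus` is the
#' cation electronegativity `a + b + c` of the donor (20.02 for hydrogen).
#' Seed charges are the formal charges, so the total charge is conserved
#' exactly.
#'
#' @param mol a `mol3d` with explicit hydrogens and a bond table.
#' @param n_iter number of damping iterations (6 suffices for convergence to
#'   well below 1e-3 e).
#' @return the molecule with `atoms$charge` filled in and attribute
#'   `charged = TRUE`.
#' @export
assign_partial_charges <- function(mol, n_iter = 6L) {
  el <- mol$atoms$element
  hyb <- atom_hybridization(mol)
  key <- ifelse(el %in% c("C", "N", "O"), paste(el, hyb, sep = "."), el)
  idx <- match(key, .gasteiger_params$key)
  if (anyNA(idx))
    stop("no Gasteiger parameters for element(s): ",
         paste(unique(el[is.na(idx)]), collapse = ", "))
  a <- .gasteiger_params$a[idx]
  b <- .gasteiger_params$b[idx]
  cc <- .gasteiger_params$c[idx]
  chi_plus <- ifelse(el == "H", 20.02, a + b + cc)

  q <- as.numeric(mol$atoms$formal)
  bf <- mol$bonds$from; bt <- mol$bonds$to
  for (k in seq_len(n_iter)) {
    chi <- a + b * q + cc * q^2
    damp <- 0.5^k
    if (length(bf)) {
      dchi <- chi[bt] - chi[bf]
      denom <- ifelse(dchi > 0, chi_plus[bf], chi_plus[bt])
      dq <- dchi / denom * damp
      # accumulate transfers simultaneously within an iteration
      dq_atom <- numeric(length(q))
      for (i in seq_along(bf)) {
        dq_atom[bf[i]] <- dq_atom[bf[i]] + dq[i]
        dq_atom[bt[i]] <- dq_atom[bt[i]] - dq[i]
      }
      q <- q + dq_atom
    }
  }
  mol$atoms$charge <- q
  attr(mol, "charged") <- TRUE
  validate_mol3d(mol)
  mol
}
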