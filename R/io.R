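# Molecule, activity and library ingestion.
#
# SDF V2000 is parsed with ChemmineR; SMILES input is embedded to a single
# 3D conformer with the openbabel CLI (deterministic for a given input), with
# hydrogens added explicitly. Formal charges are taken from M CHG lines.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.sdf_to_mol3d <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(element = el, x = ab[, 1L], y = ab[, 2L], z = ab[, 3L],
                      charge = 0, formal = 0L)
  bonds <- if (is.null(bb) || nrow(bb) == 0L) NULL else
    data.frame(from = as.integer(bb[, 1L]), to = as.integer(bb[, 2L]),
               order = as.numeric(bb[, 3L]))
  mol3d(id = id, atoms = atoms, bonds = bonds)
}

# formal charges from "M  CHG" property lines, which ChemmineR does not expose
.read_mchg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_end <- grep("^\\$\\$\\$\\$", lines)
  rec_start <- c(1L, utils::head(rec_end, -1L) + 1L)
  lapply(seq_along(rec_end), function(i) {
    blk <- lines[rec_start[i]:rec_end[i]]
    chg <- grep("^M  CHG", blk, value = TRUE)
    out <- list()
    for (l in chg) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
      n <- f[1L]
      for (j in seq_len(n)) out[[length(out) + 1L]] <- f[c(2L * j, 2L * j + 1L)]
    }
    out
  })
}

#' Read molecules from SDF or SMILES
#'
#' SDF records are parsed with ChemmineR; invalid records are skipped with a
#' warning. SMILES files (`.smi`/`.smiles`, one molecule per line with an
#' optional id after whitespace) are embedded to a single 3D conformer with
#' explicit hydrogens via the openbabel command-line tool.
#'
#' @param path input file.
#' @return list of [mol3d()] objects; ids are taken from the file.
#' @export
read_molecules <- function(path) {
  if (!file.exists(path)) stop("cannot read molecule file: ", path)
  if (grepl("\\.(smi|smiles)$", path, ignore.case = TRUE))
    return(.read_smiles_3d(path))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdfset)
  if (any(!ok))
    warning(sum(!ok), " unparsable SDF record(s) skipped in ", basename(path))
  chgs <- tryCatch(.read_mchg(path), error = function(e) NULL)
  ids <- ChemmineR::sdfid(sdfset)
  mols <- vector("list", sum(ok))
  kept <- which(ok)
  for (j in seq_along(kept)) {
    i <- kept[j]
    id <- if (!is.na(ids[i]) && nzchar(trimws(ids[i]))) trimws(ids[i]) else
      paste0("mol_", i)
    m <- .sdf_to_mol3d(sdfset[[i]], id)
    if (!is.null(chgs) && length(chgs) >= i)
      for (fc in chgs[[i]]) m$atoms$formal[fc[1L]] <- fc[2L]
    # carry an alignment rmsd SD tag back in, if present from a previous write
    db <- ChemmineR::datablock(sdfset[[i]])
    if (!is.null(db) && "rmsd" %in% names(db)) m$rmsd <- as.numeric(db[["rmsd"]])
    mols[[j]] <- m
  }
  mols
}

.read_smiles_3d <- function(path) {
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel))
    stop("openbabel (obabel) is required to embed SMILES to 3D")
  out <- tempfile(fileext = ".sdf")
  res <- suppressWarnings(system2(obabel, c(path, "-osdf", "-h", "--gen3d", "-O", out),
                                  stdout = TRUE, stderr = TRUE))
  if (!file.exists(out) || file.size(out) == 0L)
    stop("openbabel failed to embed ", path, ": ", paste(res, collapse = " "))
  smi <- readLines(path, warn = FALSE)
  smi <- smi[nzchar(trimws(smi))]
  mols <- read_molecules(out)
  if (length(mols) < length(smi))
    warning(length(smi) - length(mols), " SMILES record(s) could not be embedded")
  mols
}

#' Write molecules to an SDF V2000 file
#'
#' Alignment RMSDs (when present) are written as an `rmsd` SD tag; formal
#' charges as `M CHG` lines.
#'
#' @param molecules list of `mol3d`.
#' @param path output file.
#' @export
write_molecules <- function(molecules, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in molecules) {
    a <- m$atoms; b <- m$bonds
    writeLines(c(m$id, "  qsarpharm", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nrow(b))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$from, b$to, b$order), con)
    chg <- which(a$formal != 0L)
    if (length(chg))
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, a$formal[chg]),
                               collapse = "")), con)
    writeLines("M  END", con)
    if (!is.null(m$rmsd))
      writeLines(c("> <rmsd>", format(m$rmsd, digits = 10), ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Read an activity table
#'
#' Expects a CSV with header `molecule_id,pIC50`, or `molecule_id,ic50_nM`
#' which is converted as `pIC50 = 9 - log10(ic50_nM)`.
#'
#' @param path CSV path.
#' @return data.frame with columns `molecule_id`, `pIC50`.
#' @export
read_activities <- function(path) {
  if (!file.exists(path)) stop("cannot read activity file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("pIC50" %in% names(df)) {
    out <- data.frame(molecule_id = as.character(df$molecule_id),
                      pIC50 = as.numeric(df$pIC50))
  } else if ("ic50_nM" %in% names(df)) {
    out <- data.frame(molecule_id = as.character(df$molecule_id),
                      pIC50 = 9 - log10(as.numeric(df$ic50_nM)))
  } else stop("activity file needs a pIC50 or ic50_nM column")
  if (anyDuplicated(out$molecule_id)) stop("duplicate molecule ids in ", path)
  if (!all(is.finite(out$pIC50))) stop("non-finite pIC50 values in ", path)
  out
}

#' Random train/test split of activity records
#'
#' Training size is `n * train_fraction` rounded half up. A diagnostic checks
#' the interpolation criterion for external validation (the test-set
#' activity range must lie inside the training range) and warns when it is
#' violated.
#'
#' @param records data.frame with `molecule_id` and `pIC50`.
#' @param train_fraction fraction assigned to training (0 < f < 1).
#' @param seed integer RNG seed; the split is reproducible for a fixed seed.
#' @return list with `train` and `test` data.frames (disjoint, exhaustive)
#'   and logical `interpolative`.
#' @export
split_train_test <- function(records, train_fraction = 0.85, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(records)
  if (n < 4L) stop("need at least 4 records to split")
  n_train <- floor(n * train_fraction + 0.5) # round half up
  idx <- .with_seed(seed, sample.int(n, n_train))
  train <- records[sort(idx), , drop = FALSE]
  test <- records[setdiff(seq_len(n), idx), , drop = FALSE]
  interp <- min(test$pIC50) >= min(train$pIC50) &&
            max(test$pIC50) <= max(train$pIC50)
  if (!interp)
    warning("test set is not interpolative: its activity range extends beyond the training range")
  list(train = train, test = test, interpolative = interp)
}

#' Unicolumn statistics of an activity column
#'
#' The standard training/test summary: mean, max, min, sample standard
#' deviation, sum and count.
#'
#' @param activities numeric pIC50 vector.
#' @return object of class `unicolumn_stats`.
#' @export
unicolumn_stats <- function(activities) {
  x <- as.numeric(activities)
  if (length(x) == 0L) stop("empty activity vector")
  structure(list(mean = mean(x), max = max(x), min = min(x),
                 sd = if (length(x) > 1L) stats::sd(x) else 0,
                 sum = sum(x), n = length(x)),
            class = "unicolumn_stats")
}

#' @export
print.unicolumn_stats <- function(x, ...) {
  cat(sprintf("n %d  mean %.4f  max %.4f  min %.4f  sd %.4f  sum %.4f\n",
              x$n, x$mean, x$max, x$min, x$sd, x$sum))
  invisible(x)
}

#' Retain aligned molecules below an RMSD cutoff
#'
#' Keeps molecules whose template-alignment RMSD is less than or equal to
#' `cutoff` (inclusive boundary), preserving order. Compounds with high
#' alignment RMSD adopt alternative binding modes and are dropped before
#' field computation.
#'
#' @param molecules list of `mol3d`, each carrying an `rmsd` field.
#' @param cutoff RMSD threshold in Angstrom.
#' @return the retained sublist.
#' @export
cull_by_rmsd <- function(molecules, cutoff = 2.0) {
  rmsds <- vapply(molecules, function(m) {
    if (is.null(m$rmsd)) stop("molecule ", m$id, " has no alignment rmsd")
    m$rmsd
  }, numeric(1))
  keep <- rmsds <= cutoff
  if (!any(keep)) warning("no molecules retained at rmsd cutoff ", cutoff)
  molecules[keep]
}
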