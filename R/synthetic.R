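# Synthetic congeneric series and screening libraries.
#
# The series generator emulates a di-aryl cyclopropane hydroxamic acid
# chemotype: a cyclopropane core carrying two phenyl rings and a hydroxamic
# acid arm, decorated with small substituents (halogens, methyl, hydroxyl,
# methoxy, amino) at three ring positions. Geometry is built from idealised
# bond lengths/angles directly in a common scaffold frame, so the series is
# aligned by construction; activities are planted as a linear model in the
# molecules' own grid-field descriptors plus Gaussian noise, which makes
# ground truth exact and recoverable.

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# incremental molecule builder
.new_builder <- function() {
  env <- new.env()
  env$el <- character(0); env$xyz <- matrix(numeric(0), 0L, 3L)
  env$formal <- integer(0)
  env$bonds <- data.frame(from = integer(), to = integer(), order = numeric())
  env$atom <- function(element, pos, formal = 0L) {
    env$el <- c(env$el, element)
    env$xyz <- rbind(env$xyz, as.numeric(pos))
    env$formal <- c(env$formal, as.integer(formal))
    length(env$el)
  }
  env$bond <- function(i, j, order = 1) {
    env$bonds <- rbind(env$bonds, data.frame(from = i, to = j, order = order))
  }
  env$mol <- function(id) {
    mol3d(id, data.frame(element = env$el, x = env$xyz[, 1L],
                         y = env$xyz[, 2L], z = env$xyz[, 3L],
                         charge = 0, formal = env$formal),
          env$bonds)
  }
  env
}

# benzene ring fused to an attachment atom: ipso at `p`, ring extending
# along `d`, ring plane spanned by (d, v); returns ring atom indices and
# adds ring hydrogens/substituents at positions 2..6 (ortho..ortho)
.add_phenyl <- function(b, attach_idx, p, d, v, subs = rep("H", 5L)) {
  ctr <- p + 1.39 * d
  w <- v # in-plane perpendicular
  ring <- integer(6)
  for (k in 0:5) {
    ang <- pi + k * pi / 3
    pos <- ctr + 1.39 * (cos(ang) * d + sin(ang) * w)
    ring[k + 1L] <- if (k == 0L) b$atom("C", p) else b$atom("C", pos)
  }
  for (k in 1:6) b$bond(ring[k], ring[k %% 6L + 1L], 4) # aromatic
  b$bond(attach_idx, ring[1L])
  for (k in 2:6) {
    out <- .unit(b$xyz[ring[k], ] - ctr)
    .add_substituent(b, ring[k], out, .cross3(out, .cross3(d, v)), subs[k - 1L])
  }
  ring
}

# small substituent grown from atom `i` along unit direction `d`
# (perpendicular helper `v` for multi-atom groups)
.add_substituent <- function(b, i, d, v, kind) {
  v <- .unit(v); if (anyNA(v)) v <- c(0, 0, 1)
  w <- .cross3(d, v)
  tet <- function(base, dir) { # three tetrahedral H on a carbon
    for (k in 0:2) {
      u <- cos(1.23) * dir + sin(1.23) * (cos(2 * pi * k / 3) * v +
                                          sin(2 * pi * k / 3) * w)
      hb <- b$atom("H", base + 1.09 * u); hb
    }
  }
  switch(kind,
    H = b$bond(i, b$atom("H", b$xyz[i, ] + 1.09 * d)),
    F = b$bond(i, b$atom("F", b$xyz[i, ] + 1.35 * d)),
    Cl = b$bond(i, b$atom("Cl", b$xyz[i, ] + 1.73 * d)),
    Br = b$bond(i, b$atom("Br", b$xyz[i, ] + 1.90 * d)),
    CH3 = {
      c1 <- b$atom("C", b$xyz[i, ] + 1.50 * d); b$bond(i, c1)
      n0 <- nrow(b$xyz); tet(b$xyz[c1, ], d)
      for (h in (n0 + 1L):nrow(b$xyz)) b$bond(c1, h)
    },
    OH = {
      o <- b$atom("O", b$xyz[i, ] + 1.36 * d); b$bond(i, o)
      h <- b$atom("H", b$xyz[o, ] + 0.96 * (cos(1.3) * d + sin(1.3) * v))
      b$bond(o, h)
    },
    OCH3 = {
      o <- b$atom("O", b$xyz[i, ] + 1.36 * d); b$bond(i, o)
      cd <- .unit(cos(1.2) * d + sin(1.2) * v)
      c1 <- b$atom("C", b$xyz[o, ] + 1.43 * cd); b$bond(o, c1)
      n0 <- nrow(b$xyz); tet(b$xyz[c1, ], cd)
      for (h in (n0 + 1L):nrow(b$xyz)) b$bond(c1, h)
    },
    NH2 = {
      nn <- b$atom("N", b$xyz[i, ] + 1.39 * d); b$bond(i, nn)
      for (s in c(1, -1)) {
        h <- b$atom("H", b$xyz[nn, ] + 1.01 * (cos(1.1) * d + s * sin(1.1) * v))
        b$bond(nn, h)
      }
    },
    stop("unknown substituent fragment: ", kind))
  invisible(NULL)
}

# one series member: cyclopropane + 2 aryl rings + hydroxamic arm;
# subs = substituents at (ring A meta, ring A para, ring B para)
.build_diaryl_hydroxamate <- function(id, subs = c("H", "H", "H")) {
  b <- .new_builder()
  side <- 1.51
  c1 <- b$atom("C", c(0, 0, 0))
  c2 <- b$atom("C", c(side, 0, 0))
  c3 <- b$atom("C", c(side / 2, side * sqrt(3) / 2, 0))
  b$bond(c1, c2); b$bond(c2, c3); b$bond(c1, c3)
  ctr <- c(side / 2, side * sqrt(3) / 6, 0)
  # ring hydrogens on the cyclopropane
  for (ci in c(c1, c2, c3)) {
    d <- .unit(b$xyz[ci, ] - ctr)
    for (s in c(1, -1)) {
      u <- .unit(0.5 * d + s * c(0, 0, 0.866))
      if (ci == c3 && s == 1) next # this valence carries the hydroxamic arm
      if (ci %in% c(c1, c2) && s == 1) next # these carry the aryl rings
      b$bond(ci, b$atom("H", b$xyz[ci, ] + 1.09 * u))
    }
  }
  # aryl rings (in tilted planes so the two rings do not collide)
  dA <- .unit(c(-0.7, -0.3, 0.65)); vA <- .unit(.cross3(dA, c(0, 1, 0)))
  ringA <- .add_phenyl(b, c1, b$xyz[c1, ] + 1.50 * dA, dA, vA,
                       subs = c("H", subs[1L], subs[2L], "H", "H"))
  dB <- .unit(c(0.7, -0.3, 0.65)); vB <- .unit(.cross3(dB, c(0, 1, 0)))
  ringB <- .add_phenyl(b, c2, b$xyz[c2, ] + 1.50 * dB, dB, vB,
                       subs = c("H", "H", subs[3L], "H", "H"))
  # hydroxamic acid arm: C3-C(=O)-N(H)-O-H
  dC <- .unit(c(0, 0.65, 0.65)); vC <- c(1, 0, 0)
  cc <- b$atom("C", b$xyz[c3, ] + 1.52 * dC); b$bond(c3, cc)
  o1 <- b$atom("O", b$xyz[cc, ] + 1.23 * .unit(cos(1.05) * dC + sin(1.05) * vC))
  b$bond(cc, o1, 2)
  nn <- b$atom("N", b$xyz[cc, ] + 1.34 * .unit(cos(1.05) * dC - sin(1.05) * vC))
  b$bond(cc, nn)
  dn <- .unit(b$xyz[nn, ] - b$xyz[cc, ])
  b$bond(nn, b$atom("H", b$xyz[nn, ] + 1.01 * .unit(dn - 0.5 * vC)))
  o2 <- b$atom("O", b$xyz[nn, ] + 1.40 * .unit(dn + 0.6 * dC)); b$bond(nn, o2)
  b$bond(o2, b$atom("H", b$xyz[o2, ] + 0.96 * .unit(dn + 0.3 * vC)))
  m <- b$mol(id)
  attr(m, "scaffold_atoms") <- c(c1, c2, c3, ringA, ringB, cc, o1, nn, o2)
  m
}

#' Generate a synthetic congeneric QSAR series with planted field signal
#'
#' Enumerates substituent decorations of the di-aryl cyclopropane
#' hydroxamate scaffold, builds 3D structures in a common frame, assigns
#' Gasteiger-Marsili charges, aligns on the scaffold, computes the grid
#' descriptor matrix, and plants the activity model
#' `pIC50 = intercept + sum(coef_j * descriptor_j) + N(0, noise_sd)`.
#' Planted descriptors default to three spatially separated high-variance
#' grid columns; their coefficients are scaled so the noise-free activity
#' spread matches a realistic congeneric series (pIC50 about 5-8, sd about
#' 0.7).
#'
#' @param n_molecules series size (>= 8; default 44 as in a culled
#'   hydroxamate series).
#' @param substituents fragment names drawn for the three variable ring
#'   positions.
#' @param noise_sd activity noise, pIC50 units.
#' @param seed RNG seed (substituent draws and noise).
#' @param spacing,margin grid geometry (Angstrom).
#' @param planted optional list(labels=, coefficients=) overriding the
#'   automatic choice.
#' @param n_planted number of auto-planted descriptors.
#' @param intercept baseline pIC50.
#' @param target_sd noise-free activity standard deviation to aim for.
#' @return list with `molecules`, `activities` (molecule_id, pIC50),
#'   `descriptors` (full `descriptor_matrix`), `grid`, and `truth`
#'   (planted labels, coefficients, intercept, noise_sd, seed).
#' @export
generate_series <- function(n_molecules = 44L,
                            substituents = c("H", "F", "Cl", "Br", "CH3",
                                             "OH", "OCH3", "NH2"),
                            noise_sd = 0.15, seed = 1L,
                            spacing = 2.0, margin = 4.0,
                            planted = NULL, n_planted = 3L,
                            intercept = 6.5, target_sd = 0.7) {
  stopifnot(n_molecules >= 8L)
  combos <- expand.grid(a = substituents, b = substituents, c = substituents,
                        stringsAsFactors = FALSE)
  if (n_molecules > nrow(combos))
    stop("n_molecules exceeds the ", nrow(combos), " available decorations")
  pick <- .with_seed(seed, sample.int(nrow(combos), n_molecules))
  mols <- lapply(seq_len(n_molecules), function(i)
    .build_diaryl_hydroxamate(sprintf("cmpd_%02d", i),
                              unlist(combos[pick[i], ], use.names = FALSE)))
  mols <- lapply(mols, assign_partial_charges)
  # align on the shared scaffold (identical atom indices across the series)
  scaf <- attr(mols[[1L]], "scaffold_atoms")
  mols <- lapply(mols, function(m)
    align_to_template(m, list(mol_idx = attr(m, "scaffold_atoms"),
                              ref_idx = scaf), mols[[1L]]))
  grid <- build_grid(mols, margin = margin, spacing = spacing)
  X <- compute_descriptor_matrix(mols, grid)

  if (is.null(planted)) {
    # plant two steric + one electrostatic descriptor (the class mix typical
    # of published field equations), spatially separated by >= 3 cells so the
    # signal is identifiable, with decaying contribution shares
    v <- apply(X, 2L, function(col) mean((col - mean(col))^2))
    info <- decode_label(colnames(X), grid)
    classes <- rep_len(c("S", "S", "E"), n_planted)
    shares <- rep_len(c(0.5, 0.3, 0.2), n_planted)
    shares <- shares / sum(shares) * (n_planted / 3) * 1.0
    chosen <- integer(0)
    for (cls in classes) {
      cand <- which(info$field == cls & v >= 1.0)
      cand <- setdiff(cand[order(v[cand], decreasing = TRUE)], chosen)
      hit <- NA_integer_
      for (j in cand) {
        pj <- as.numeric(info[j, c("x", "y", "z")])
        far <- all(vapply(chosen, function(cj)
          sqrt(sum((pj - as.numeric(info[cj, c("x", "y", "z")]))^2)) >=
            3 * spacing, logical(1)))
        if (far) { hit <- j; break }
      }
      if (is.na(hit))
        stop("could not find ", n_planted, " separated high-variance descriptors")
      chosen <- c(chosen, hit)
    }
    labels <- colnames(X)[chosen]
    signs <- rep_len(c(1, 1, -1), n_planted)
    coefs <- signs * shares * target_sd /
      apply(X[, labels, drop = FALSE], 2L, stats::sd)
  } else {
    labels <- planted$labels
    coefs <- planted$coefficients
  }
  lin <- drop(X[, labels, drop = FALSE] %*% coefs) + intercept
  noise <- .with_seed(seed + 1L, stats::rnorm(n_molecules, 0, noise_sd))
  activities <- data.frame(molecule_id = vapply(mols, `[[`, character(1), "id"),
                           pIC50 = lin + noise)
  list(molecules = mols, activities = activities, descriptors = X,
       grid = grid,
       truth = list(labels = labels,
                    coefficients = stats::setNames(coefs, labels),
                    intercept = intercept, noise_sd = noise_sd, seed = seed))
}

# ---- screening library ---------------------------------------------------

.default_planted_hypothesis <- function() {
  sites <- rbind(
    .feature_row("A", c(0, 0, 0), c(0, 0, -1)),
    .feature_row("D", c(4.2, 0, 0), c(0, 0, 1)),
    .feature_row("D", c(0, 4.5, 0), c(0, 0, 1)),
    .feature_row("R", c(4.0, 4.0, 1.0), c(0, 0, 1)),
    .feature_row("R", c(2.0, 1.8, 3.5), c(0, 0, 1)))
  pharmacophore_hypothesis(sites, reference_id = "planted", id = "ADDRR.planted")
}

# fragments whose perceived feature of the given kind sits exactly at `p`
.add_feature_fragment <- function(b, kind, p) {
  switch(kind,
    A = { # formaldehyde: acceptor at the carbonyl O, lone pair along -z
      o <- b$atom("O", p); cc <- b$atom("C", p + c(0, 0, 1.23))
      b$bond(cc, o, 2)
      h1 <- b$atom("H", p + c(0.94, 0, 1.77)); b$bond(cc, h1)
      h2 <- b$atom("H", p + c(-0.94, 0, 1.77)); b$bond(cc, h2)
    },
    D = { # methanol: donor at O, O-H along +z
      o <- b$atom("O", p); h <- b$atom("H", p + c(0, 0, 0.96))
      cc <- b$atom("C", p + c(1.10, 0, -0.90))
      b$bond(o, h); b$bond(o, cc)
      for (u in list(c(0.6, 0.8, -0.2), c(0.6, -0.8, -0.2), c(1.0, 0, 1.0)))
        b$bond(cc, b$atom("H", b$xyz[cc, ] + 1.09 * .unit(u)))
    },
    R = { # benzene centred at p in the xy-plane (normal +z)
      ring <- integer(6)
      for (k in 0:5) {
        ang <- k * pi / 3
        ring[k + 1L] <- b$atom("C", p + 1.39 * c(cos(ang), sin(ang), 0))
      }
      for (k in 1:6) b$bond(ring[k], ring[k %% 6L + 1L], 4)
      for (k in 1:6)
        b$bond(ring[k], b$atom("H", p + 2.48 * c(cos((k - 1) * pi / 3),
                                                 sin((k - 1) * pi / 3), 0)))
    },
    H = { # methane: hydrophobic centroid at the carbon
      cc <- b$atom("C", p)
      hs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
      for (k in 1:4) b$bond(cc, b$atom("H", p + 1.09 * hs[k, ]))
    },
    stop("unsupported planted feature kind: ", kind))
  invisible(NULL)
}

#' Generate a synthetic actives/decoys screening library
#'
#' Actives are built to contain the planted hypothesis' feature arrangement
#' (feature-bearing fragments placed at the site positions with Gaussian
#' positional jitter); decoys carry at most 3 kind-compatible features at
#' random positions and therefore cannot satisfy a 4-of-5 match. The
#' default scale (1,000 molecules) is a desk-scale stand-in for a large
#' screening database.
#'
#' @param n_actives,n_decoys library composition.
#' @param hypothesis planted `pharmacophore_hypothesis` (default: a 5-site
#'   ADDRR arrangement).
#' @param jitter_sd positional jitter of active features, Angstrom.
#' @param seed RNG seed.
#' @return list with `library` (list of `mol3d`), `active_ids`,
#'   `hypothesis`, and `truth` (jitter, seed).
#' @export
generate_screening_library <- function(n_actives = 100L, n_decoys = 900L,
                                       hypothesis = NULL, jitter_sd = 0.3,
                                       seed = 1L) {
  stopifnot(n_actives >= 1L, n_decoys >= 1L, jitter_sd >= 0)
  if (is.null(hypothesis)) hypothesis <- .default_planted_hypothesis()
  ns <- nrow(hypothesis$sites)
  stopifnot(ns >= 4L, ns <= 5L)
  lib <- vector("list", n_actives + n_decoys)
  .with_seed(seed, {
    for (i in seq_len(n_actives)) {
      b <- .new_builder()
      for (j in seq_len(ns)) {
        p <- as.numeric(hypothesis$sites[j, c("x", "y", "z")]) +
          stats::rnorm(3L, 0, jitter_sd)
        .add_feature_fragment(b, hypothesis$sites$kind[j], p)
      }
      lib[[i]] <- b$mol(sprintf("active_%04d", i))
    }
    decoy_kinds <- c("A", "D", "H", "R")
    need <- table(hypothesis$sites$kind)
    # kinds implied by each fragment (a hydroxyl donor is also an acceptor)
    implied <- function(kinds)
      unlist(lapply(kinds, function(k) if (k == "D") c("D", "A") else k))
    for (i in seq_len(n_decoys)) {
      b <- .new_builder()
      repeat {
        nk <- sample(1:3, 1L)
        kinds <- sample(decoy_kinds, nk, replace = TRUE)
        have <- table(implied(kinds))
        compat <- sum(pmin(as.integer(have[names(need)]), as.integer(need)),
                      na.rm = TRUE)
        if (compat <= 3L) break # decoys must stay below a 4-site match
      }
      for (k in kinds)
        .add_feature_fragment(b, k, stats::runif(3L, -4, 8))
      lib[[n_actives + i]] <- b$mol(sprintf("decoy_%04d", i))
    }
  })
  list(library = lib,
       active_ids = sprintf("active_%04d", seq_len(n_actives)),
       hypothesis = hypothesis,
       truth = list(jitter_sd = jitter_sd, seed = seed))
}
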