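# Common pharmacophore hypothesis generation, scoring and k-of-n screening.

#' Construct a pharmacophore hypothesis
#'
#' @param sites `pharma_features` data.frame (4 or 5 rows) giving feature
#'   kinds, positions and optional directions.
#' @param reference_id id of the ligand the sites were materialised from.
#' @param reference_mol optional `mol3d` of that ligand (needed for volume
#'   scoring).
#' @param id hypothesis identifier (e.g. "ADDRR.20").
#' @return object of class `pharmacophore_hypothesis`.
#' @export
pharmacophore_hypothesis <- function(sites, reference_id = NA_character_,
                                     reference_mol = NULL, id = NULL) {
  sites <- as.data.frame(sites)
  ord <- order(sites$kind)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  variant <- paste(sites$kind, collapse = "")
  d <- as.matrix(stats::dist(sites[, c("x", "y", "z")]))
  structure(list(sites = sites, variant = variant,
                 id = id %||% variant, reference_id = reference_id,
                 reference_mol = reference_mol, distances = d,
                 scores = NULL),
            class = "pharmacophore_hypothesis")
}

#' @export
print.pharmacophore_hypothesis <- function(x, ...) {
  cat("<pharmacophore_hypothesis>", x$id, "(", nrow(x$sites), "sites,",
      "reference", x$reference_id, ")\n")
  if (!is.null(x$scores))
    cat(sprintf("  survival %.3f (site %.3f, vector %.3f, volume %.3f, selectivity %.3f); survival-inactive %.3f\n",
                x$scores$survival, x$scores$site, x$scores$vector,
                x$scores$volume, x$scores$selectivity, x$scores$survival_inactive))
  invisible(x)
}

#' Site alignment score
#'
#' `max(0, 1 - rmsd / cutoff_rmsd)`: 1 for perfect superposition of matched
#' site points, 0 at (or beyond) the cutoff.
#'
#' @param rmsd site-point RMSD in Angstrom.
#' @param cutoff_rmsd cutoff in Angstrom (default 1.2).
#' @export
site_score <- function(rmsd, cutoff_rmsd = 1.2) {
  stopifnot(all(rmsd >= 0))
  pmax(0, 1 - rmsd / cutoff_rmsd)
}

#' Vector alignment score
#'
#' Average cosine of the angles between corresponding direction vectors of
#' the aligned and reference pharmacophores: `(1/n_v) * sum cos(theta_ij)`.
#' With no vector-bearing pairs the score is 1 by convention (no penalty).
#'
#' @param theta angles between corresponding vectors.
#' @param unit "degrees" (default) or "radians".
#' @export
vector_score <- function(theta, unit = c("degrees", "radians")) {
  unit <- match.arg(unit)
  if (length(theta) == 0L) {
    message("no vector-bearing site pairs; vector score 1 by convention")
    return(1.0)
  }
  if (unit == "degrees") theta <- theta * pi / 180
  mean(cos(theta))
}

#' Shared van der Waals volume score
#'
#' Tanimoto of van der Waals volumes, `V(A & B) / V(A | B)`, estimated by
#' seeded Monte-Carlo integration over the union bounding box of the two
#' atom-sphere sets.
#'
#' @param molA,molB `mol3d` objects in the same frame (A already aligned
#'   onto B).
#' @param n_points Monte-Carlo sample size.
#' @param seed RNG seed (fixed default keeps screening deterministic).
#' @param radii optional named radius overrides per element (Angstrom).
#' @return overlap fraction in [0, 1].
#' @export
volume_score <- function(molA, molB, n_points = 20000L, seed = 7L, radii = NULL) {
  rad <- function(mol) {
    r <- .element_lookup(mol$atoms$element, "radius")
    if (!is.null(radii)) {
      hit <- mol$atoms$element %in% names(radii)
      r[hit] <- radii[mol$atoms$element[hit]]
    }
    r
  }
  ra <- rad(molA); rb <- rad(molB)
  xa <- mol_coords(molA); xb <- mol_coords(molB)
  lo <- pmin(apply(xa - ra, 2L, min), apply(xb - rb, 2L, min))
  hi <- pmax(apply(xa + ra, 2L, max), apply(xb + rb, 2L, max))
  pts <- .with_seed(seed, matrix(stats::runif(3L * n_points), ncol = 3L))
  pts <- sweep(sweep(pts, 2L, hi - lo, "*"), 2L, lo, "+")
  inside <- function(xyz, r) {
    d <- .point_atom_dist(pts, xyz)
    rowSums(d <= matrix(r, nrow(d), ncol(d), byrow = TRUE)) > 0L
  }
  ia <- inside(xa, ra); ib <- inside(xb, rb)
  un <- sum(ia | ib)
  if (un == 0L) return(0)
  sum(ia & ib) / un
}

#' Survival score of a hypothesis
#'
#' Weighted aggregate `S = W_site S_site + W_vec S_vec + W_vol S_vol +
#' W_sel S_sel - W_E dE + W_act A` over component scores averaged across the
#' non-reference actives. The energy and activity terms default to weight 0
#' (hooks only). `survival_inactive = survival - W_inactive * S_inactive`
#' where `S_inactive` is the mean match score over known inactives.
#'
#' @param site,vector,volume,selectivity component scores.
#' @param weights named numeric weights (site, vector, volume, selectivity).
#' @param energy,w_energy,activity,w_activity optional extra terms.
#' @param inactive_match mean match score over known inactives.
#' @param w_inactive weight of the inactive penalty.
#' @return list with `survival` and `survival_inactive`.
#' @export
survival_score <- function(site, vector, volume, selectivity = 0,
                           weights = c(site = 1, vector = 1, volume = 1,
                                       selectivity = 1),
                           energy = 0, w_energy = 0,
                           activity = 0, w_activity = 0,
                           inactive_match = 0, w_inactive = 1) {
  s <- weights[["site"]] * site + weights[["vector"]] * vector +
    weights[["volume"]] * volume + weights[["selectivity"]] * selectivity -
    w_energy * energy + w_activity * activity
  list(survival = unname(s),
       survival_inactive = unname(s - w_inactive * inactive_match))
}

# ---- matching ------------------------------------------------------------

# backtracking search for injective kind- and distance-compatible
# assignments of molecule features onto a site subset; returns list of
# integer vectors (feature index per site) -- brute force by construction
.site_assignments <- function(feat, sites, site_idx, tol) {
  k <- length(site_idx)
  dsite <- as.matrix(stats::dist(sites[site_idx, c("x", "y", "z")]))
  dfeat <- as.matrix(stats::dist(feat[, c("x", "y", "z")]))
  out <- list()
  assign <- integer(k)
  bt <- function(level) {
    if (level > k) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    kind <- sites$kind[site_idx[level]]
    for (f in which(feat$kind == kind)) {
      if (f %in% assign[seq_len(level - 1L)]) next
      ok <- TRUE
      for (j in seq_len(level - 1L)) {
        if (abs(dfeat[f, assign[j]] - dsite[level, j]) > tol) { ok <- FALSE; break }
      }
      if (ok) { assign[level] <<- f; bt(level + 1L); assign[level] <<- 0L }
    }
  }
  bt(1L)
  out
}

#' Match a molecule against a pharmacophore hypothesis
#'
#' Searches kind-compatible assignments of the molecule's features onto at
#' least `must_match` hypothesis sites whose intersite distances agree
#' within `tol`, then superposes the matched features onto the sites
#' (Kabsch) and scores
#' `fitness = w_site * site_score + w_vector * vector_score +
#' w_volume * volume_score` (each component at most 1, so fitness <= 3).
#' The volume component requires the hypothesis to carry its reference
#' ligand; without one the component is dropped from the fitness.
#'
#' @param mol a `mol3d`, or a precomputed `pharma_features` table.
#' @param hypothesis a `pharmacophore_hypothesis`.
#' @param must_match minimum number of matched sites (default 4, the
#'   "four out of five" rule).
#' @param tol intersite distance tolerance in Angstrom.
#' @param weights numeric length-3 (site, vector, volume).
#' @param cutoff_rmsd site-score cutoff (Angstrom).
#' @param volume_points Monte-Carlo points for the volume component.
#' @return object of class `pharma_match`: list with `molecule_id`,
#'   `matched`, `n_matched`, `rmsd`, component scores, `fitness`, the rigid
#'   `rotation`/`translation`, and the site `assignment`.
#' @export
match_molecule <- function(mol, hypothesis, must_match = 4L, tol = 2.0,
                           weights = c(site = 1, vector = 1, volume = 1),
                           cutoff_rmsd = 1.2, volume_points = 5000L) {
  feat <- if (inherits(mol, "pharma_features")) mol else perceive_features(mol)
  molid <- attr(feat, "molecule_id") %||% NA_character_
  sites <- hypothesis$sites
  ns <- nrow(sites)
  must_match <- min(must_match, ns)
  no_match <- structure(list(molecule_id = molid, matched = FALSE,
                             n_matched = 0L, rmsd = NA_real_, site = NA_real_,
                             vector = NA_real_, volume = NA_real_,
                             fitness = NA_real_, rotation = NULL,
                             translation = NULL, assignment = NULL),
                        class = "pharma_match")
  # quick kind-count necessary condition
  have <- table(feat$kind); need <- table(sites$kind)
  compat <- sum(pmin(as.integer(have[names(need)]), as.integer(need)), na.rm = TRUE)
  if (compat < must_match) return(no_match)

  best <- NULL
  for (m in seq(ns, must_match)) {
    subsets <- utils::combn(ns, m, simplify = FALSE)
    for (s in subsets) {
      for (a in .site_assignments(feat, sites, s, tol)) {
        kb <- kabsch(as.matrix(feat[a, c("x", "y", "z")]),
                     as.matrix(sites[s, c("x", "y", "z")]))
        if (is.null(best) || m > best$m ||
            (m == best$m && kb$rmsd < best$kb$rmsd - 1e-12))
          best <- list(m = m, s = s, a = a, kb = kb)
      }
    }
    if (!is.null(best)) break # larger subsets take precedence
  }
  if (is.null(best)) return(no_match)

  # component scores on the best superposition
  sc_site <- site_score(best$kb$rmsd, cutoff_rmsd)
  ang <- .matched_angles(feat, sites, best$a, best$s, best$kb$rotation)
  sc_vec <- if (length(ang)) mean(cos(ang)) else 1.0
  sc_vol <- NA_real_
  fitness <- weights[[1L]] * sc_site + weights[[2L]] * sc_vec
  if (!is.null(hypothesis$reference_mol) && inherits(mol, "mol3d")) {
    aligned <- mol_transform(mol, best$kb$rotation, best$kb$translation)
    sc_vol <- volume_score(aligned, hypothesis$reference_mol,
                           n_points = volume_points)
    fitness <- fitness + weights[[3L]] * sc_vol
  }
  structure(list(molecule_id = molid, matched = TRUE, n_matched = best$m,
                 rmsd = best$kb$rmsd, site = sc_site, vector = sc_vec,
                 volume = sc_vol, fitness = fitness,
                 rotation = best$kb$rotation, translation = best$kb$translation,
                 assignment = stats::setNames(best$a, sites$kind[best$s])),
            class = "pharma_match")
}

# angles (radians) between rotated feature directions and site directions;
# ring normals are sign-ambiguous, so their angle uses |cos|
.matched_angles <- function(feat, sites, a, s, rotation) {
  ang <- numeric(0)
  for (i in seq_along(s)) {
    sd_ <- as.numeric(sites[s[i], c("dx", "dy", "dz")])
    fd <- as.numeric(feat[a[i], c("dx", "dy", "dz")])
    if (anyNA(sd_) || anyNA(fd)) next
    fr <- as.numeric(rotation %*% fd)
    cs <- sum(fr * sd_)
    if (sites$kind[s[i]] == "R") cs <- abs(cs)
    ang <- c(ang, acos(pmin(1, pmax(-1, cs))))
  }
  ang
}

#' @export
print.pharma_match <- function(x, ...) {
  if (!x$matched) {
    cat("<pharma_match>", x$molecule_id, ": no match\n")
  } else {
    cat(sprintf("<pharma_match> %s: %d sites, rmsd %.3f, fitness %.3f (site %.3f, vector %.3f, volume %s)\n",
                x$molecule_id, x$n_matched, x$rmsd, x$fitness, x$site,
                x$vector, ifelse(is.na(x$volume), "-", sprintf("%.3f", x$volume))))
  }
  invisible(x)
}

# ---- hypothesis enumeration and scoring ----------------------------------

#' Enumerate common pharmacophore hypotheses over a set of actives
#'
#' Every k-site feature combination (k in `min_sites:max_sites`) of every
#' active is tried as a candidate hypothesis; a candidate survives when all
#' other actives can match all of its sites within the distance tolerance.
#' Hypothesis ids are `<variant>.<running index>` in deterministic order.
#'
#' @param actives list of `mol3d` (>= 2).
#' @param min_sites,max_sites hypothesis size range (default 4-5).
#' @param tol intersite distance tolerance (Angstrom).
#' @param features optional precomputed list of `pharma_features`.
#' @return list of `pharmacophore_hypothesis` (possibly empty, with a
#'   warning when no common variant exists).
#' @export
enumerate_hypotheses <- function(actives, min_sites = 4L, max_sites = 5L,
                                 tol = 2.0, features = NULL) {
  stopifnot(length(actives) >= 2L)
  if (is.null(features)) features <- lapply(actives, perceive_features)
  ids <- vapply(actives, `[[`, character(1), "id")
  out <- list()
  counter <- new.env()
  for (r in seq_along(actives)) {
    fr <- features[[r]]
    nf <- nrow(fr)
    for (k in seq(min_sites, max_sites)) {
      if (nf < k) next
      for (comb in utils::combn(nf, k, simplify = FALSE)) {
        sites <- fr[comb, , drop = FALSE]
        ok <- all(vapply(seq_along(actives)[-r], function(j) {
          m <- match_molecule(features[[j]],
                              pharmacophore_hypothesis(sites, ids[r]),
                              must_match = k, tol = tol)
          isTRUE(m$matched) && m$n_matched == k
        }, logical(1)))
        if (!ok) next
        hyp <- pharmacophore_hypothesis(sites, reference_id = ids[r],
                                        reference_mol = actives[[r]])
        cnt <- (get0(hyp$variant, envir = counter, ifnotfound = 0L)) + 1L
        assign(hyp$variant, cnt, envir = counter)
        hyp$id <- paste0(hyp$variant, ".", cnt)
        out[[length(out) + 1L]] <- hyp
      }
    }
  }
  if (!length(out)) warning("no common pharmacophore variant across the actives")
  out
}

#' Score a hypothesis over actives (and optionally inactives/decoys)
#'
#' Component scores are averaged over the non-reference actives: site score
#' from each active's full-site match RMSD, vector score from direction
#' agreement, volume score against the reference ligand. Selectivity is
#' `-log10` of the fraction of a reference decoy library matching the
#' hypothesis (floored at 0); inactive matches feed `survival_inactive`.
#'
#' @param hypothesis a `pharmacophore_hypothesis`.
#' @param actives list of `mol3d` used to build the hypothesis.
#' @param decoys optional list of `mol3d` known inactives.
#' @param weights survival weights, see [survival_score()].
#' @param tol,cutoff_rmsd,volume_points matching parameters.
#' @return the hypothesis with its `scores` field filled in.
#' @export
score_hypothesis <- function(hypothesis, actives, decoys = NULL,
                             weights = c(site = 1, vector = 1, volume = 1,
                                         selectivity = 1),
                             tol = 2.0, cutoff_rmsd = 1.2,
                             volume_points = 5000L) {
  others <- Filter(function(m) m$id != hypothesis$reference_id, actives)
  k <- nrow(hypothesis$sites)
  comp <- lapply(others, function(m)
    match_molecule(m, hypothesis, must_match = k, tol = tol,
                   cutoff_rmsd = cutoff_rmsd, volume_points = volume_points))
  matched <- Filter(function(m) m$matched, comp)
  s_site <- if (length(matched)) mean(vapply(matched, `[[`, numeric(1), "site")) else 0
  s_vec <- if (length(matched)) mean(vapply(matched, `[[`, numeric(1), "vector")) else 0
  vols <- vapply(matched, `[[`, numeric(1), "volume")
  s_vol <- if (length(vols) && !all(is.na(vols))) mean(vols, na.rm = TRUE) else 0
  s_sel <- 0
  inact <- 0
  if (!is.null(decoys) && length(decoys)) {
    dm <- vapply(decoys, function(m)
      match_molecule(m, hypothesis, must_match = min(4L, k), tol = tol)$matched,
      logical(1))
    frac <- mean(dm)
    s_sel <- if (frac > 0) max(0, -log10(frac)) else -log10(1 / (2 * length(decoys)))
    inact <- mean(vapply(decoys, function(m) {
      mm <- match_molecule(m, hypothesis, must_match = min(4L, k), tol = tol)
      if (mm$matched) mm$site else 0
    }, numeric(1)))
  }
  sv <- survival_score(s_site, s_vec, s_vol, s_sel, weights,
                       inactive_match = inact)
  hypothesis$scores <- list(site = s_site, vector = s_vec, volume = s_vol,
                            selectivity = s_sel, survival = sv$survival,
                            survival_inactive = sv$survival_inactive,
                            n_matched_actives = length(matched))
  hypothesis
}

#' Pick the best-surviving hypothesis
#' @param hypotheses list of scored hypotheses.
#' @return the hypothesis with maximal survival score (ties by id).
#' @export
select_hypothesis <- function(hypotheses) {
  stopifnot(length(hypotheses) > 0L)
  sc <- vapply(hypotheses, function(h) h$scores$survival, numeric(1))
  ids <- vapply(hypotheses, `[[`, character(1), "id")
  hypotheses[[order(-sc, ids)[1L]]]
}

# ---- screening -----------------------------------------------------------

#' Screen a library against a pharmacophore hypothesis
#'
#' Mirrors the two-pass screening contract: pass 1 searches each molecule
#' for a kind/intersite-distance compatible site arrangement and records it
#' in a match file; pass 2 aligns the recorded matches to the hypothesis and
#' computes fitness. Hits are molecules with fitness at or above
#' `threshold`, sorted by fitness descending (ties by id).
#'
#' @param library list of `mol3d`.
#' @param hypothesis a `pharmacophore_hypothesis`.
#' @param must_match minimum matched sites (default 4 of 5).
#' @param threshold fitness retention threshold (default 1.0).
#' @param tol,weights,cutoff_rmsd,volume_points see [match_molecule()].
#' @return object of class `screen_result`: data.frame (id, matched,
#'   n_sites, rmsd, site, vector, volume, fitness, hit) with the pass-1
#'   match table in attribute `match_file`.
#' @export
screen_library <- function(library, hypothesis, must_match = 4L,
                           threshold = 1.0, tol = 2.0,
                           weights = c(site = 1, vector = 1, volume = 1),
                           cutoff_rmsd = 1.2, volume_points = 5000L) {
  if (!length(library))
    return(structure(data.frame(id = character(), matched = logical(),
                                n_sites = integer(), rmsd = numeric(),
                                site = numeric(), vector = numeric(),
                                volume = numeric(), fitness = numeric(),
                                hit = logical()),
                     class = c("screen_result", "data.frame"),
                     match_file = data.frame(), threshold = threshold))
  # pass 1: feature perception + match search, recorded to the match file
  feats <- lapply(library, perceive_features)
  matches <- lapply(seq_along(library), function(i)
    match_molecule(feats[[i]], hypothesis, must_match = must_match, tol = tol,
                   cutoff_rmsd = cutoff_rmsd))
  ids <- vapply(library, `[[`, character(1), "id")
  mf <- do.call(rbind, lapply(seq_along(matches), function(i) {
    m <- matches[[i]]
    if (!m$matched) return(NULL)
    data.frame(molecule_id = ids[i],
               sites = paste(names(m$assignment), collapse = ""),
               assignment = paste(m$assignment, collapse = ","),
               rmsd_pass1 = m$rmsd)
  }))
  if (is.null(mf)) mf <- data.frame(molecule_id = character())
  # pass 2: align the matched molecules and compute full fitness
  rows <- lapply(seq_along(library), function(i) {
    m <- matches[[i]]
    if (!m$matched)
      return(data.frame(id = ids[i], matched = FALSE, n_sites = 0L,
                        rmsd = NA_real_, site = NA_real_, vector = NA_real_,
                        volume = NA_real_, fitness = NA_real_, hit = FALSE))
    full <- match_molecule(library[[i]], hypothesis, must_match = must_match,
                           tol = tol, weights = weights,
                           cutoff_rmsd = cutoff_rmsd,
                           volume_points = volume_points)
    data.frame(id = ids[i], matched = TRUE, n_sites = full$n_matched,
               rmsd = full$rmsd, site = full$site, vector = full$vector,
               volume = full$volume, fitness = full$fitness,
               hit = full$fitness >= threshold)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-ifelse(is.na(res$fitness), -Inf, res$fitness), res$id), ]
  rownames(res) <- NULL
  structure(res, class = c("screen_result", "data.frame"),
            match_file = mf, threshold = threshold)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screen result:", nrow(x), "molecules,", sum(x$matched), "matched,",
      sum(x$hit), "hits at fitness >=", attr(x, "threshold"), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L), digits = 3)
  invisible(x)
}

#' Write the pass-1 match file as TSV
#' @param result a `screen_result`.
#' @param path output path.
#' @export
write_match_file <- function(result, path) {
  utils::write.table(attr(result, "match_file"), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a hypothesis as YAML
#' @param hypothesis a `pharmacophore_hypothesis`.
#' @param path YAML path.
#' @export
save_hypothesis <- function(hypothesis, path) {
  s <- hypothesis$sites
  yaml::write_yaml(list(id = hypothesis$id, variant = hypothesis$variant,
                        reference_id = hypothesis$reference_id,
                        sites = lapply(seq_len(nrow(s)), function(i)
                          list(kind = s$kind[i],
                               position = as.numeric(s[i, c("x", "y", "z")]),
                               direction = {
                                 d <- as.numeric(s[i, c("dx", "dy", "dz")])
                                 if (anyNA(d)) NULL else d
                               })),
                        scores = hypothesis$scores), path, precision = 15L)
  invisible(path)
}

#' @rdname save_hypothesis
#' @export
load_hypothesis <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- do.call(rbind, lapply(y$sites, function(s)
    .feature_row(s$kind, as.numeric(s$position),
                 if (is.null(s$direction)) c(NA, NA, NA) else as.numeric(s$direction))))
  h <- pharmacophore_hypothesis(sites, reference_id = y$reference_id %||% NA_character_,
                                id = y$id)
  h$scores <- y$scores
  h
}
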