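planted_hyp <- function() {
  gen <- generate_screening_library(n_actives = 1, n_decoys = 1, jitter_sd = 0,
                                    seed = 1)
  gen$hypothesis
}

test_that("site score is the linear cutoff ramp, monotone in rmsd", {
  expect_equal(site_score(0), 1.0)
  expect_equal(site_score(1.2), 0.0)
  expect_equal(site_score(0.6), 0.5)
  expect_equal(site_score(5), 0.0) # floored
  r <- seq(0, 3, by = 0.1)
  expect_true(all(diff(site_score(r)) <= 0))
})

test_that("vector score averages cosines with the no-vector convention", {
  expect_equal(vector_score(c(0, 0, 0)), 1.0)
  expect_equal(vector_score(c(90, 90)), 0.0, tolerance = 1e-12)
  expect_equal(vector_score(c(0, 60)), 0.75)
  expect_message(v <- vector_score(numeric(0)), "convention")
  expect_equal(v, 1.0)
  # invariance under a common rotation of both vector sets: angles between
  # corresponding vectors are preserved, so the score is too
  set.seed(3)
  u <- matrix(rnorm(9), 3); v2 <- matrix(rnorm(9), 3)
  ang <- function(a, b) acos(pmin(1, pmax(-1, rowSums(a * b) /
    sqrt(rowSums(a^2) * rowSums(b^2))))) * 180 / pi
  R <- random_rotation()
  expect_equal(vector_score(ang(u, v2)),
               vector_score(ang(u %*% t(R), v2 %*% t(R))), tolerance = 1e-9)
})

test_that("volume score: identity, disjoint, and the sphere-cap oracle", {
  m <- toy_benzene()
  expect_equal(volume_score(m, m), 1.0, tolerance = 1e-12)
  far <- mol_transform(m, diag(3), c(50, 0, 0))
  expect_equal(volume_score(m, far), 0.0)

  # two single H atoms (spheres r = 1.2) at centre distance 1:
  # analytic lens volume V = pi (2r - d)^2 (d^2 + 4 d r) / (12 d)
  a <- toy_points(matrix(c(0, 0, 0), 1), element = "H")
  b <- toy_points(matrix(c(1, 0, 0), 1), element = "H")
  r <- 1.2; d <- 1
  lens <- pi * (2 * r - d)^2 * (d^2 + 4 * d * r) / (12 * d)
  sphere <- 4 / 3 * pi * r^3
  expected <- lens / (2 * sphere - lens)
  expect_equal(volume_score(a, b, n_points = 40000L), expected,
               tolerance = 0.02)
})

test_that("survival score is the weighted sum with documented defaults", {
  s <- survival_score(1, 1, 1, 1)
  expect_equal(s$survival, 4.0)
  expect_equal(survival_score(1, 1, 1, 1,
    weights = c(site = 0, vector = 0, volume = 0, selectivity = 0))$survival, 0)
  expect_equal(survival_score(0.9, 1.0, 0.85, 0.5)$survival, 3.25)
  # linear in each weight
  w0 <- c(site = 1, vector = 1, volume = 1, selectivity = 1)
  base <- survival_score(0.7, 0.8, 0.6, 0.3, w0)$survival
  for (comp in names(w0)) {
    w <- w0; w[comp] <- 3
    vals <- c(site = 0.7, vector = 0.8, volume = 0.6, selectivity = 0.3)
    expect_equal(survival_score(0.7, 0.8, 0.6, 0.3, w)$survival,
                 base + 2 * vals[[comp]], tolerance = 1e-12)
  }
  # inactive penalty
  s2 <- survival_score(1, 1, 1, 0, inactive_match = 0.4, w_inactive = 1)
  expect_equal(s2$survival - s2$survival_inactive, 0.4)
})

test_that("matching self and counting-limited failures behave as specified", {
  hyp <- planted_hyp()
  gen <- generate_screening_library(n_actives = 2, n_decoys = 1, jitter_sd = 0,
                                    seed = 5)
  act <- gen$library[[1]]
  m <- match_molecule(act, gen$hypothesis, must_match = 5)
  expect_true(m$matched)
  expect_equal(m$n_matched, 5L)
  expect_lt(m$rmsd, 1e-6)
  expect_equal(m$site, 1.0, tolerance = 1e-6)
  expect_equal(m$vector, 1.0, tolerance = 1e-6)

  # only 3 compatible kinds present -> cannot satisfy 4-of-5
  b <- qsarpharm:::.new_builder()
  qsarpharm:::.add_feature_fragment(b, "D", c(0, 0, 0))
  qsarpharm:::.add_feature_fragment(b, "R", c(4, 0, 0))
  poor <- b$mol("poor")
  expect_false(match_molecule(poor, hyp, must_match = 4)$matched)
})

test_that("match search equals brute-force assignment enumeration", {
  # independent oracle: exhaustive loop over site subsets and injective
  # kind-compatible feature assignments, distance-filtered, best by
  # (matched count, rmsd)
  brute_match <- function(feat, hyp, must_match, tol = 2.0) {
    sites <- hyp$sites; ns <- nrow(sites)
    best <- NULL
    for (m in ns:must_match) {
      for (sub in utils::combn(ns, m, simplify = FALSE)) {
        cand <- lapply(sub, function(s) which(feat$kind == sites$kind[s]))
        if (any(vapply(cand, length, 1L) == 0L)) next
        grid <- expand.grid(cand)
        for (r in seq_len(nrow(grid))) {
          a <- as.integer(grid[r, ])
          if (anyDuplicated(a)) next
          df <- as.matrix(dist(feat[a, c("x", "y", "z")]))
          ds <- as.matrix(dist(sites[sub, c("x", "y", "z")]))
          if (any(abs(df - ds) > tol)) next
          rmsd <- kabsch(as.matrix(feat[a, c("x", "y", "z")]),
                         as.matrix(sites[sub, c("x", "y", "z")]))$rmsd
          if (is.null(best) || m > best$m ||
              (m == best$m && rmsd < best$rmsd - 1e-12))
            best <- list(m = m, rmsd = rmsd)
        }
      }
      if (!is.null(best)) break
    }
    best
  }
  hyp <- planted_hyp()
  gen <- generate_screening_library(n_actives = 6, n_decoys = 2,
                                    jitter_sd = 0.4, seed = 9)
  for (mol in gen$library) {
    feat <- perceive_features(mol)
    if (nrow(feat) > 8L) next
    ours <- match_molecule(feat, hyp, must_match = 4)
    oracle <- brute_match(feat, hyp, 4L)
    expect_equal(ours$matched, !is.null(oracle))
    if (ours$matched) {
      expect_equal(ours$n_matched, oracle$m)
      expect_equal(ours$rmsd, oracle$rmsd, tolerance = 1e-9)
    }
  }
})

test_that("hypothesis enumeration covers self-matches and fails disjoint kinds", {
  gen <- generate_screening_library(n_actives = 2, n_decoys = 1, jitter_sd = 0,
                                    seed = 2)
  twins <- gen$library[1:2] # identical feature arrangements at jitter 0
  hyps <- enumerate_hypotheses(twins, 4, 5)
  f <- perceive_features(twins[[1]])
  n_expected <- choose(nrow(f), 4) + choose(nrow(f), 5)
  # every k-subset of the first molecule's features appears (once per
  # reference molecule)
  expect_equal(length(hyps), 2 * n_expected)
  expect_true("ADDRR" %in% vapply(hyps, `[[`, character(1), "variant"))

  # no shared kinds -> empty with a warning
  expect_warning(
    none <- enumerate_hypotheses(list(toy_benzene("b1"), toy_acetate("a1")),
                                 min_sites = 1, max_sites = 2),
    "no common")
  expect_length(none, 0L)
})

test_that("every hypothesis-building active matches its own hypothesis", {
  gen <- generate_screening_library(n_actives = 4, n_decoys = 2,
                                    jitter_sd = 0, seed = 3)
  act <- gen$library[1:4]
  hyps <- enumerate_hypotheses(act, 5, 5)
  hyp <- hyps[[1]]
  for (a in act) {
    m <- match_molecule(a, hyp, must_match = nrow(hyp$sites))
    expect_true(m$matched)
    expect_lt(m$rmsd, 1e-6)
  }
})

test_that("scored hypotheses expose survival components and decoy selectivity", {
  gen <- generate_screening_library(n_actives = 4, n_decoys = 10,
                                    jitter_sd = 0.2, seed = 4)
  act <- gen$library[1:4]; dec <- gen$library[5:14]
  hyps <- enumerate_hypotheses(act, 5, 5)
  # score the ADDRR variant: its direction-bearing sites map unambiguously
  hyps <- hyps[vapply(hyps, `[[`, character(1), "variant") == "ADDRR"]
  h <- score_hypothesis(hyps[[1]], act, decoys = dec, volume_points = 2000L)
  s <- h$scores
  expect_true(s$site > 0 && s$site <= 1)
  expect_true(s$vector > 0.8)
  expect_true(s$volume > 0 && s$volume <= 1)
  expect_equal(s$survival,
               s$site + s$vector + s$volume + s$selectivity, tolerance = 1e-9)
  # W_sel = 0 removes the decoy dependence
  h0 <- score_hypothesis(hyps[[1]], act, decoys = dec,
                         weights = c(site = 1, vector = 1, volume = 1,
                                     selectivity = 0),
                         volume_points = 2000L)
  hnod <- score_hypothesis(hyps[[1]], act, decoys = NULL,
                           weights = c(site = 1, vector = 1, volume = 1,
                                       selectivity = 0),
                           volume_points = 2000L)
  expect_equal(h0$scores$survival, hnod$scores$survival, tolerance = 1e-9)
  # selection: maximal survival wins
  scored <- lapply(hyps[1:3], score_hypothesis, actives = act,
                   volume_points = 1000L)
  best <- select_hypothesis(scored)
  expect_equal(best$scores$survival,
               max(vapply(scored, function(x) x$scores$survival, numeric(1))))
})

test_that("library screening honours the two-pass contract and ordering", {
  gen <- generate_screening_library(n_actives = 6, n_decoys = 14,
                                    jitter_sd = 0.2, seed = 6)
  res <- screen_library(gen$library, gen$hypothesis, must_match = 4,
                        threshold = 1.0)
  expect_s3_class(res, "screen_result")
  # all actives matched, decoys cannot reach 4 compatible kinds
  expect_true(all(res$matched[res$id %in% gen$active_ids]))
  expect_false(any(res$matched[!res$id %in% gen$active_ids]))
  # sorted by fitness descending
  fi <- res$fitness[res$matched]
  expect_true(all(diff(fi) <= 1e-12))
  # match file lists exactly the matched molecules
  mf <- attr(res, "match_file")
  expect_setequal(mf$molecule_id, res$id[res$matched])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_match_file(res, f)
  expect_true(file.exists(f))
  # empty library: empty result, no crash
  empty <- screen_library(list(), gen$hypothesis)
  expect_equal(nrow(empty), 0L)
})

test_that("hypothesis YAML round trip preserves sites and scores", {
  gen <- generate_screening_library(n_actives = 2, n_decoys = 1,
                                    jitter_sd = 0, seed = 8)
  h <- gen$hypothesis
  h$scores <- list(site = 1, vector = 1, volume = 0.9, selectivity = 0,
                   survival = 2.9, survival_inactive = 2.9)
  f <- withr::local_tempfile(fileext = ".yaml")
  save_hypothesis(h, f)
  back <- load_hypothesis(f)
  expect_equal(back$variant, h$variant)
  expect_equal(back$sites$kind, h$sites$kind)
  expect_equal(as.matrix(back$distances), as.matrix(h$distances),
               tolerance = 1e-9)
  expect_equal(back$scores$survival, 2.9)
})
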