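single_atom <- function(el = "C", pos = c(0, 0, 0), charge = 0) {
  m <- mol3d("atom", data.frame(element = el, x = pos[1], y = pos[2],
                                z = pos[3], charge = charge))
  m$rmsd <- 0
  m
}

test_that("grid construction covers the padded bounding box", {
  g <- build_grid(list(single_atom()), margin = 4, spacing = 2)
  expect_equal(g$dims, c(5L, 5L, 5L))
  expect_equal(g$origin, c(-4, -4, -4))

  # union of two molecules
  g2 <- build_grid(list(single_atom(), single_atom(pos = c(10, 0, 0))),
                   margin = 4, spacing = 2)
  pts <- grid_points(g2)
  expect_true(min(pts[, 1]) <= -4 && max(pts[, 1]) >= 14)

  # degenerate: margin 0, spacing = extent
  g3 <- build_grid(list(toy_points(rbind(c(0, 0, 0), c(3, 3, 3)))),
                   margin = 0, spacing = 3)
  expect_equal(g3$dims, c(2L, 2L, 2L))
  expect_error(build_grid(list()), "empty")
})

test_that("steric field obeys clamp, decay and the closed-form LJ minimum", {
  m <- single_atom("C")
  # point at the atom centre clamps to +truncation
  g0 <- field_grid(c(0, 0, 0), 1, c(1, 1, 1))
  expect_equal(steric_field(m, g0), 30.0)
  # at r = rmin the LJ energy is exactly -eps_ij = -sqrt(0.1094 * 0.1094)
  rmin <- 1.70 + 1.70
  g1 <- field_grid(c(rmin, 0, 0), 1, c(1, 1, 1))
  expect_equal(steric_field(m, g1), -0.1094, tolerance = 1e-12)
  # beyond 12 A the interaction has decayed away
  g2 <- field_grid(c(12.5, 0, 0), 1, c(1, 1, 1))
  expect_lt(abs(steric_field(m, g2)), 1e-3)
})

test_that("electrostatic field is Coulombic, linear and clamped", {
  m <- single_atom("C", charge = 1)
  g <- field_grid(c(332.06, 0, 0), 1, c(1, 1, 1))
  expect_equal(electrostatic_field(m, g), 1.0, tolerance = 1e-12)
  # 1 A from a +1 charge: 332.06 kcal/mol clamps to +30
  g1 <- field_grid(c(1, 0, 0), 1, c(1, 1, 1))
  expect_equal(electrostatic_field(m, g1), 30.0)
  # zero charges give a zero field
  m0 <- single_atom("C", charge = 0)
  g3 <- build_grid(list(m0), margin = 4, spacing = 2)
  expect_true(all(electrostatic_field(m0, g3) == 0))
  # doubling the probe charge doubles unclamped values (25 A keeps both
  # evaluations below the clamp)
  g4 <- field_grid(c(25, 0, 0), 1, c(1, 1, 1))
  e1 <- electrostatic_field(m, g4)
  g4$probe$charge <- 2
  expect_equal(electrostatic_field(m, g4), 2 * e1, tolerance = 1e-12)
})

test_that("descriptor matrix layout, labels and determinism", {
  g <- field_grid(c(-1, -1, -1), 2, c(2, 2, 2))
  m1 <- assign_partial_charges(toy_water("w1")); m1$rmsd <- 0
  m2 <- assign_partial_charges(toy_water("w2")); m2$rmsd <- 0
  X <- compute_descriptor_matrix(list(m1, m2), g)
  expect_equal(ncol(X), 16L) # 8 S + 8 E
  expect_equal(colnames(X)[1:2], c("S_0", "S_1"))
  expect_equal(unname(X["w1", ]), unname(X["w2", ])) # identical molecules
  expect_true(all(abs(X) <= g$truncation) && all(is.finite(X)))

  # label decoding: S_5 on dims (2,2,2) -> (ix,iy,iz) = (1,0,1)
  d <- decode_label("S_5", g)
  expect_equal(unlist(d[, c("ix", "iy", "iz")]), c(ix = 1, iy = 0, iz = 1))

  # unaligned molecules are rejected
  m3 <- toy_water("w3")
  expect_error(compute_descriptor_matrix(list(m3), g), "w3")
})

test_that("fields are covariant under a common rigid motion", {
  m <- assign_partial_charges(toy_methanol()); m$rmsd <- 0
  R <- rotation_matrix(c(1, 2, 3), 0.7); tr <- c(1, -2, 0.5)
  mt <- mol_transform(m, R, tr)
  pts <- rbind(c(2, 0, 0), c(0, 3, 1), c(-1, -1, 2))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]; pt <- as.numeric(R %*% p + tr)
    for (fld in list(steric_field, electrostatic_field)) {
      v0 <- fld(m, field_grid(p, 1, c(1, 1, 1)))
      v1 <- fld(mt, field_grid(pt, 1, c(1, 1, 1)))
      expect_equal(v1, v0, tolerance = 1e-6)
    }
  }
})

test_that("invariant-column filtering matches a brute-force variance oracle", {
  X <- cbind(S_0 = c(1, 1, 1, 1), S_1 = c(0, 10, 0, 10), S_2 = c(0, 1, 0, 1))
  rownames(X) <- paste0("m", 1:4)
  out <- drop_invariant_columns(X, 1.0)
  # population variances: 0, 25, 0.25 -> only S_1 survives cutoff 1.0
  v <- apply(X, 2, function(col) mean((col - mean(col))^2))
  expect_equal(colnames(out), names(v)[v >= 1.0])
  expect_equal(colnames(out), "S_1")
  expect_error(drop_invariant_columns(X, 1e6), "lower variance_cutoff")
  expect_error(drop_invariant_columns(X[1, , drop = FALSE]), "2 rows")
})

test_that("descriptor CSV round trip preserves values and grid", {
  g <- field_grid(c(0, 0, 0), 2, c(2, 2, 2))
  m <- assign_partial_charges(toy_water()); m$rmsd <- 0
  X <- compute_descriptor_matrix(list(m), g)
  f <- withr::local_tempfile(fileext = ".csv")
  write_descriptors(X, f)
  back <- read_descriptors(f)
  expect_equal(unclass(back), unclass(X), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(back, "grid")$dims, g$dims)
})
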