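test_that("AQVN reproduces the published descriptor values", {
  expect_equal(aqvn("C18H12Cl2N2O"), 2.9142, tolerance = 5e-4)   # boscalid
  expect_equal(aqvn("C48H72O14"), 2.5970, tolerance = 5e-4)      # abamectin B1A
  expect_equal(aqvn("C47H70O14"), 2.6107, tolerance = 5e-4)      # abamectin B1B
  expect_identical(aqvn("C18H14BrCl2N5O2"), 3)                   # exact integer ratio
  expect_equal(aqvn("C18H12Cl2N2O"), 102 / 35, tolerance = 1e-15)
})

test_that("AQVN is the exact weighted mean and scale-invariant", {
  expect_equal(aqvn(molecularComposition(c(C = 1))), 4)
  expect_equal(aqvn("H2O"), 8 / 3, tolerance = 1e-15)
  set.seed(99)
  vt <- defaultValenceTable()
  for (i in 1:30) {
    counts <- randomComposition()
    comp <- molecularComposition(counts)
    z <- aqvn(comp)
    vals <- vt@valences[names(counts)]
    expect_gte(z, min(vals)); expect_lte(z, max(vals))            # mean bounds
    k <- sample(2:5, 1)
    expect_equal(aqvn(molecularComposition(counts * k)), z, tolerance = 1e-14)
  }
})

test_that("missing valence entries are reported by element", {
  expect_error(aqvn("NaCl"), "Na")
  vt <- valenceTable(c(C = 4, H = 1))
  expect_error(aqvn("H2O", vt), "O")
})

test_that("EIIP matches published values and its analytic structure", {
  expect_lt(abs(abs(eiip(aqvn("C18H12Cl2N2O"))) - 0.0112), 5e-4)
  expect_lt(eiip(aqvn("C18H12Cl2N2O")), 0)                        # signed: negative
  expect_lt(abs(eiip(2.5970) - 0.0834), 5e-4)
  expect_lt(abs(eiip(2.6107) - 0.0810), 5e-4)
  # zeros at Z* = j/1.04, with a sign change across each
  for (j in 1:5) {
    z0 <- j / 1.04
    expect_lt(abs(eiip(z0)), 1e-10)
    expect_lt(eiip(z0 - 1e-3) * eiip(z0 + 1e-3), 0)
  }
  # sine bound on a dense grid
  zg <- seq(0.01, 8, by = 0.001)
  expect_true(all(abs(eiip(zg)) <= zg / (8 * pi) + 1e-15))
  expect_error(eiip(0), "positive")
  expect_error(eiip(-1), "positive")
})

test_that("describeCompound fills every descriptor field consistently", {
  d <- describeCompound("C18H12Cl2N2O", id = "boscalid")
  expect_lt(abs(d@aqvn - 2.9143), 5e-5)
  expect_lt(abs(d@eiipSigned - -0.0112), 5e-4)
  expect_lt(abs(d@eiipAbs - 0.0112), 5e-4)
  expect_identical(d@nAtoms, 35L)
  expect_identical(d@quasiValenceSum, 102)
  expect_identical(d@formula, "C18H12Cl2N2O")

  d2 <- describeCompound("C47H70O14")
  expect_lt(abs(d2@aqvn - 2.6107), 5e-5)
  expect_lt(abs(d2@eiipAbs - 0.0810), 5e-4)
  expect_identical(d2@nAtoms, 131L)
  expect_identical(d2@quasiValenceSum, 342)
})

test_that("descriptor core matches a brute-force atom-by-atom oracle", {
  set.seed(2024)
  for (i in 1:100) {
    counts <- randomComposition()
    d <- describeCompound(molecularComposition(counts))
    ref <- bruteForceDescriptor(counts, defaultValenceMap)
    expect_lt(abs(d@aqvn - ref$aqvn), 1e-12)
    expect_lt(abs(d@eiipSigned - ref$eiip), 1e-12)
    expect_identical(d@nAtoms, as.integer(ref$nAtoms))
    expect_equal(d@quasiValenceSum, ref$qvs)
  }
})

test_that("batchDescribe keeps input order and accounts for bad rows", {
  res <- batchDescribe(referenceCompounds())
  expect_equal(nrow(res), 4L)
  expect_identical(res$id[1], "boscalid")
  expect_equal(res$aqvn, c(102 / 35, 348 / 134, 342 / 131, 3), tolerance = 1e-12)
  expect_equal(nrow(attr(res, "errors")), 0L)

  tab <- data.frame(id = c("a", "bad", "c"),
                    formula = c("H2O", "Qq9", "CH4"))
  expect_warning(res2 <- batchDescribe(tab), "1 row")
  expect_equal(nrow(res2), 2L)
  expect_identical(res2$id, c("a", "c"))
  errs <- attr(res2, "errors")
  expect_equal(errs$row, 2L)
  expect_match(errs$message, "unknown element")

  empty <- data.frame(id = character(), formula = character())
  expect_warning(res3 <- batchDescribe(empty), "empty")
  expect_equal(nrow(res3), 0L)
  expect_identical(names(res3),
                   c("id", "formula", "n_atoms", "quasi_valence_sum",
                     "aqvn", "eiip_signed", "eiip_abs"))
})

test_that("AQVN similarity ranking orders by |delta| with id tie-break", {
  desc <- batchDescribe(referenceCompounds())
  rk <- rankByAqvn(desc, "boscalid")
  expect_identical(rk$id[1], "boscalid")
  expect_identical(rk$id[2], "chlorantraniliprole")    # |0.0857| < |0.3036|
  expect_equal(rk$delta_aqvn[1], 0)
  expect_true(all(diff(rk$delta_aqvn) >= 0))

  self <- rankByAqvn(desc[desc$id == "boscalid", ], "boscalid")
  expect_equal(nrow(self), 1L)
  expect_equal(self$delta_aqvn, 0)

  tied <- data.frame(id = c("zeta", "alpha", "ref"), aqvn = c(2.5, 2.5, 3.0))
  rkt <- rankByAqvn(tied, "ref")
  expect_identical(rkt$id, c("ref", "alpha", "zeta"))

  expect_error(rankByAqvn(desc, "nope"), "not found")
})
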