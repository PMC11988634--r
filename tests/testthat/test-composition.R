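test_that("formulas parse to the expected element counts", {
  cases <- list(
    list(f = "C18H12Cl2N2O", want = c(C = 18L, H = 12L, Cl = 2L, N = 2L, O = 1L)),
    list(f = "H2O",          want = c(H = 2L, O = 1L)),
    list(f = "CH3(CH2)2OH",  want = c(C = 3L, H = 8L, O = 1L)),
    list(f = "C48H72O14",    want = c(C = 48L, H = 72L, O = 14L)),
    list(f = " C18 H12 Cl2 N2 O ", want = c(C = 18L, H = 12L, Cl = 2L, N = 2L, O = 1L))
  )
  for (cs in cases) {
    comp <- parseFormula(cs$f)
    expect_equal(comp@elements[sort(names(comp@elements))],
                 cs$want[sort(names(cs$want))], info = cs$f)
  }
})

test_that("repeated element tokens are summed", {
  comp <- parseFormula("CH3CH2OH")
  expect_equal(sort(comp@elements),
               sort(c(C = 2L, H = 6L, O = 1L)))
})

test_that("malformed formulas raise informative parse errors", {
  expect_error(parseFormula("C18X2"), "unknown element 'X'")
  expect_error(parseFormula("C6H5("), "unbalanced")
  expect_error(parseFormula("C6H5)2"), "unbalanced")
  expect_error(parseFormula("C((H2))"), "nested")
  expect_error(parseFormula("CuSO4.5H2O"), "hydrate")
  expect_error(parseFormula("[13C]H4"), "isotope")
  expect_error(parseFormula("NH4+"), "charges")
  expect_error(parseFormula(""), "empty")
  expect_error(parseFormula("()3"), "empty group")
})

test_that("parse/canonicalise round-trips random compositions", {
  set.seed(421)
  for (i in 1:50) {
    counts <- randomComposition()
    comp <- molecularComposition(counts)
    back <- parseFormula(canonicalFormula(comp))
    expect_equal(back@elements[sort(names(back@elements))],
                 comp@elements[sort(names(comp@elements))])
  }
})

test_that("Hill notation puts C then H first, else alphabetical", {
  expect_identical(canonicalFormula("H12C18ON2Cl2"), "C18H12Cl2N2O")
  expect_identical(canonicalFormula("O1H2"), "H2O")       # no carbon: alphabetical
  expect_identical(canonicalFormula("ClNa"), "ClNa")
})

test_that("molecular weights reproduce reference values at 1 decimal", {
  expect_equal(round(molecularWeight("C18H12Cl2N2O"), 1), 343.2)
  expect_equal(round(molecularWeight("C48H72O14"), 1), 873.1)
  expect_equal(round(molecularWeight("C47H70O14"), 1), 859.1)
  expect_equal(molecularWeight("H2O"), 18.015, tolerance = 1e-6)
})

test_that("molecular weight is additive over merged compositions", {
  set.seed(77)
  for (i in 1:20) {
    a <- randomComposition(); b <- randomComposition()
    merged <- tapply(c(a, b), c(names(a), names(b)), sum)
    mw <- molecularWeight(molecularComposition(merged))
    expect_equal(mw, molecularWeight(molecularComposition(a)) +
                     molecularWeight(molecularComposition(b)),
                 tolerance = 1e-10)
  }
})

test_that("missing mass entries are reported by element", {
  masses <- new("AtomicMassTable",
                masses = c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                           S = 32.06, P = 30.974, F = 18.998, Cl = 35.45,
                           Br = 79.904, I = 126.904))
  expect_error(molecularWeight(parseFormula("NaCl"), masses), "Na")
})

test_that("structure notation yields the same composition as the formula", {
  skip_if_not_installed("ChemmineOB")
  expect_equal(sort(compositionFromStructure("O")@elements),
               sort(c(H = 2L, O = 1L)))
  expect_equal(sort(compositionFromStructure("C")@elements),
               sort(c(C = 1L, H = 4L)))
  boscalidSmiles <- "C1=CC=C(C(=C1)C2=CC=C(C=C2)Cl)NC(=O)C3=C(N=CC=C3)Cl"
  expect_identical(canonicalFormula(compositionFromStructure(boscalidSmiles)),
                   canonicalFormula(parseFormula("C18H12Cl2N2O")))
})
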