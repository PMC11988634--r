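test_that("initial rate is the exact OLS slope in AU/min", {
  t <- seq(0, 300, by = 15)
  cv <- progressCurve("w1", t, 0.10 + 0.02 * t / 60)
  expect_equal(initialRate(cv), 0.02, tolerance = 1e-12)
  expect_equal(initialRate(progressCurve("w2", t, rep(0.3, length(t)))), 0)
  expect_equal(initialRate(cv, window = 60), 0.02, tolerance = 1e-12)
  expect_error(initialRate(cv, window = 20), "fewer than 3 points")
  expect_warning(initialRate(progressCurve("w3", t, 0.5 - 0.001 * t)),
                 class = "eiipScreen_negative_rate")
})

test_that("percent inhibition follows 100(1 - v/v0)", {
  expect_equal(percentInhibition(0.02, 0.02), 0)
  expect_equal(percentInhibition(0, 0.02), 100)
  expect_equal(percentInhibition(0.01, 0.02), 50)
  expect_equal(percentInhibition(c(0.02, 0.01, 0), 0.02), c(0, 50, 100))
  expect_error(percentInhibition(0.01, 0), "positive")
  expect_error(percentInhibition(0.01, -0.1), "positive")
})

test_that("IC50 fit recovers model-generated data exactly", {
  conc <- c(10, 30, 100, 300, 1000)
  res <- fitIC50(conc, 100 * conc / (conc + 100))
  expect_true(res@converged)
  expect_equal(ic50(res), 100, tolerance = 1e-6)
  expect_equal(hillSlope(res), 1, tolerance = 1e-6)
  # 50% at exactly c*, log-symmetric points around it
  conc2 <- c(25, 50, 100, 200, 400)
  inh2 <- 100 / (1 + (100 / conc2)^1.7)
  res2 <- fitIC50(conc2, inh2)
  expect_equal(ic50(res2), 100, tolerance = 1e-6)
  expect_equal(hillSlope(res2), 1.7, tolerance = 1e-5)
})

test_that("IC50 fit rejects degenerate series", {
  expect_error(fitIC50(c(10, 100), c(10, 90)), "4 distinct")
  expect_error(fitIC50(c(10, 30, 100, 300), rep(0, 4)), "no transition")
  expect_error(fitIC50(c(10, 30, 100, 300), rep(100, 4)), "no transition")
})

test_that("simulated noise-free curves are linear and recover the forward rate", {
  pl <- simulatePlate(simulationSpec(ic50 = 300, noiseSD = 0, seed = 1))
  cond <- conditions(pl)
  roles <- vapply(curves(pl), function(x) x@role, character(1))
  ctl <- curves(pl)[roles == "negative-control"][[1]]
  # Beer-Lambert forward computation as oracle:
  # v0 = Vmax [S]/(Km+[S]) in mM/min; slope = eps * l * v0 (M/min)
  v0 <- cond@enzymeActivity * cond@substrateConc / (cond@Km + cond@substrateConc)
  expected <- cond@extinctionCoef * cond@pathLength * v0 / 1000
  expect_equal(initialRate(ctl), expected, tolerance = 0.01)
  # perfectly linear: residuals of a straight line vanish
  fitres <- resid(lm(ctl@absorbance ~ ctl@times))
  expect_lt(max(abs(fitres)), 1e-12)
})

test_that("a fixed seed reproduces a plate byte for byte", {
  s <- simulationSpec(ic50 = 300, seed = 11)
  expect_identical(simulatePlate(s), simulatePlate(s))
  s2 <- simulationSpec(ic50 = 300, seed = 12)
  expect_false(identical(simulatePlate(s), simulatePlate(s2)))
})

test_that("excess substrate depletion is flagged", {
  fast <- assayConditions(enzymeActivity = 0.05)  # ~27% depletion in 5 min
  expect_warning(simulatePlate(simulationSpec(ic50 = 300, noiseSD = 0,
                                              conditions = fast)),
                 "substrate")
})

test_that("noise-free inhibition is non-decreasing in concentration", {
  for (mode in c("competitive", "noncompetitive")) {
    pl <- simulatePlate(simulationSpec(ic50 = 300, mode = mode,
                                       noiseSD = 0, seed = 1))
    res <- analyzePlate(pl)
    tab <- inhibitionTable(res)
    expect_true(all(diff(tab$inhibition_pct[order(tab$conc_uM)]) >= -1e-9))
  }
})

test_that("blank correction is idempotent and preserves the analysis", {
  pl <- simulatePlate(simulationSpec(ic50 = 300, seed = 5))
  c1 <- blankCorrect(pl)
  c2 <- blankCorrect(c1)
  expect_identical(c1, c2)
  # rate-level and trace-level corrections agree on the fitted IC50
  expect_equal(ic50(analyzePlate(c1)), ic50(analyzePlate(pl)), tolerance = 1e-6)
})

test_that("plate analysis requires blanks and an uninhibited control", {
  pl <- simulatePlate(simulationSpec(ic50 = 300, seed = 5))
  roles <- vapply(curves(pl), function(x) x@role, character(1))
  noBlank <- pl; noBlank@curves <- curves(pl)[roles != "blank"]
  expect_error(analyzePlate(noBlank), "blank")
  noCtl <- pl; noCtl@curves <- curves(pl)[roles != "negative-control"]
  expect_error(analyzePlate(noCtl), "negative-control")
})

test_that("simulated plates recover the true IC50", {
  errs <- vapply(1:5, function(s) {
    r <- analyzePlate(simulatePlate(simulationSpec(ic50 = 300, seed = s)))
    expect_true(r@converged)
    expect_gt(ic50SE(r), 0)
    abs(ic50(r) - 300) / 300
  }, numeric(1))
  expect_lt(median(errs), 0.15)
  r0 <- analyzePlate(simulatePlate(simulationSpec(ic50 = 300, noiseSD = 0, seed = 1)))
  expect_equal(ic50(r0), 300, tolerance = 1e-6)
  expect_equal(hillSlope(r0), 1, tolerance = 1e-6)   # reversible MM gives Hill 1
})

test_that("a compound with no effect yields the censored no-activity outcome", {
  # test wells behave exactly like the uninhibited control
  pl <- simulatePlate(simulationSpec(ic50 = 1e9, noiseSD = 0, seed = 1,
                                     concentrations = c(10, 30, 100, 300)))
  res <- analyzePlate(pl)
  expect_true(isCensored(res))
  expect_identical(res@censored, "gt:300")
  expect_true(is.na(ic50(res)))
})

test_that("well order in a plate file does not change the result", {
  pl <- simulatePlate(simulationSpec(ic50 = 300, seed = 9))
  f <- tempfile(fileext = ".csv")
  writePlate(pl, f)
  df <- read.csv(f)
  shuffled <- df[rev(seq_len(nrow(df))), ]
  f2 <- tempfile(fileext = ".csv")
  write.csv(shuffled, f2, row.names = FALSE)
  r1 <- analyzePlate(readPlate(f))
  r2 <- analyzePlate(readPlate(f2))
  expect_equal(ic50(r1), ic50(r2), tolerance = 1e-9)
  expect_equal(inhibitionTable(r1), inhibitionTable(r2))
})
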