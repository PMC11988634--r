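#' Construct assay conditions for the Ellman microplate protocol
#'
#' Defaults are the final in-well values implied by the common 200 uL
#' format: 50 uL inhibitor + 100 uL substrate/chromogen mix + 50 uL enzyme,
#' i.e. 1 mM acetylthiocholine stock -> 0.5 mM final, 0.5 mM DTNB -> 0.25 mM
#' final, 0.0075 U/mL enzyme stock -> 0.001875 U/mL final; TNB extinction
#' coefficient 13600 1/(M cm) at 405 nm; 0.58 cm path for 200 uL in a
#' standard 96-well; Km 0.1 mM (typical order of magnitude for
#' cholinesterase/acetylthiocholine); 5 min read at 15 s intervals.
#'
#' @param substrateConc final substrate concentration, mM
#' @param chromogenConc final DTNB concentration, mM
#' @param enzymeActivity final enzyme activity, U/mL
#' @param finalVolume final well volume, uL
#' @param pathLength optical path length, cm
#' @param extinctionCoef TNB extinction coefficient, 1/(M cm)
#' @param Km Michaelis constant, mM
#' @param duration read duration, s
#' @param readInterval read interval, s
#' @return an [AssayConditions-class]
#' @export
assayConditions <- function(substrateConc = 0.5, chromogenConc = 0.25,
                            enzymeActivity = 0.001875, finalVolume = 200,
                            pathLength = 0.58, extinctionCoef = 13600,
                            Km = 0.1, duration = 300, readInterval = 15) {
  new("AssayConditions", substrateConc = substrateConc,
      chromogenConc = chromogenConc, enzymeActivity = enzymeActivity,
      finalVolume = finalVolume, pathLength = pathLength,
      extinctionCoef = extinctionCoef, Km = Km, duration = duration,
      readInterval = readInterval)
}

#' Construct a ProgressCurve
#'
#' @param well well identifier
#' @param times seconds from reaction start
#' @param absorbance AU at 405 nm
#' @param conc final inhibitor concentration, uM
#' @param role "test", "blank", "positive-control" or "negative-control"
#' @return a [ProgressCurve-class]
#' @export
progressCurve <- function(well, times, absorbance, conc = 0, role = "test") {
  new("ProgressCurve", well = as.character(well), role = role,
      conc = as.numeric(conc), times = as.numeric(times),
      absorbance = as.numeric(absorbance))
}

#' Construct a simulation specification
#'
#' Exactly one of `ic50` or `ki` is given; the other is derived through the
#' Cheng-Prusoff relation for the chosen mode (competitive:
#' IC50 = Ki (1 + [S]/Km); noncompetitive: IC50 = Ki).
#'
#' @param ic50 true IC50, uM
#' @param ki true inhibition constant, uM
#' @param mode "competitive" or "noncompetitive"
#' @param concentrations inhibitor series, uM; default is an 8-point 2-fold
#'   geometric series centred on the true IC50
#' @param replicates technical replicates per concentration
#' @param noiseSD additive Gaussian absorbance noise per read, AU
#' @param seed integer seed for reproducible noise
#' @param baseline absorbance offset A0, AU
#' @param conditions an [AssayConditions-class]
#' @return a [SimulationSpec-class]
#' @export
simulationSpec <- function(ic50 = NA_real_, ki = NA_real_,
                           mode = c("competitive", "noncompetitive"),
                           concentrations = NULL, replicates = 3L,
                           noiseSD = 0.005, seed = 1L, baseline = 0.05,
                           conditions = assayConditions()) {
  mode <- match.arg(mode)
  if (is.null(concentrations)) {
    centre <- if (is.finite(ic50)) ic50 else {
      sOverKm <- conditions@substrateConc / conditions@Km
      if (mode == "competitive") ki * (1 + sOverKm) else ki
    }
    if (!is.finite(centre)) stop("give ic50 or ki to derive a default series")
    concentrations <- centre * 2^seq(-3.5, 3.5, by = 1)
  }
  new("SimulationSpec", ic50 = as.numeric(ic50), ki = as.numeric(ki),
      mode = mode, concentrations = as.numeric(concentrations),
      replicates = as.integer(replicates), noiseSD = noiseSD,
      seed = as.integer(seed), baseline = baseline, conditions = conditions)
}

# Michaelis-Menten rate with reversible inhibition, in mM product / min.
# alpha multiplies Km (competitive component), alphaPrime multiplies [S]
# (uncompetitive component); classical noncompetitive sets both.
.wellVelocity <- function(inhibConc, kiUM, mode, cond) {
  a <- 1 + inhibConc / kiUM
  alpha <- a
  alphaPrime <- if (mode == "noncompetitive") a else 1
  s <- cond@substrateConc
  cond@enzymeActivity * s / (cond@Km * alpha + s * alphaPrime)
}

# mM/min product -> AU/min via Beer-Lambert
.velocityToSlope <- function(vmMperMin, cond) {
  cond@extinctionCoef * cond@pathLength * (vmMperMin / 1000)
}

.specKi <- function(spec) {
  cond <- spec@conditions
  sOverKm <- cond@substrateConc / cond@Km
  if (is.finite(spec@ki)) return(spec@ki)
  if (spec@mode == "competitive") spec@ic50 / (1 + sOverKm) else spec@ic50
}

#' Simulate an Ellman inhibition plate
#'
#' Generates progress curves for every inhibitor concentration x replicate,
#' plus uninhibited negative-control wells and enzyme-free blank wells
#' (replicated the same way). Each well follows Michaelis-Menten kinetics
#' with reversible inhibition; absorbance is the Beer-Lambert conversion of
#' the product formation rate plus a constant baseline and i.i.d. Gaussian
#' read noise. A fixed seed gives a byte-identical plate; each well draws
#' from its own deterministic substream, so well order does not couple the
#' noise. If the uninhibited reaction would consume more than 10 percent of
#' the substrate over the run, a warning is attached (the progress curves
#' are then not trustworthy as initial rates).
#'
#' @param spec a [SimulationSpec-class]
#' @return a [PlateAssay-class]; ground truth is stored in the `truth` slot
#' @examples
#' plate <- simulatePlate(simulationSpec(ic50 = 300, seed = 7))
#' analyzePlate(plate)
#' @export
simulatePlate <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  cond <- spec@conditions
  kiUM <- .specKi(spec)
  times <- seq(0, cond@duration, by = cond@readInterval)

  v0 <- .wellVelocity(0, kiUM, spec@mode, cond)           # mM/min uninhibited
  depletion <- v0 * cond@duration / 60 / cond@substrateConc
  if (depletion > 0.10)
    warning(sprintf(paste0("uninhibited reaction consumes %.1f%% of the ",
                           "substrate over the run (>10%%); initial rates ",
                           "will be biased"), 100 * depletion))

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })

  mkCurve <- function(well, conc, role, slopeAUmin, substream) {
    set.seed((spec@seed * 2039L + substream * 101L) %% .Machine$integer.max)
    noise <- if (spec@noiseSD > 0) stats::rnorm(length(times), 0, spec@noiseSD)
             else numeric(length(times))
    progressCurve(well, times,
                  spec@baseline + slopeAUmin * times / 60 + noise,
                  conc = conc, role = role)
  }

  curvesList <- list()
  sub <- 0L
  for (r in seq_len(spec@replicates)) {
    sub <- sub + 1L
    curvesList[[length(curvesList) + 1L]] <-
      mkCurve(sprintf("blk_r%d", r), 0, "blank", 0, sub)
  }
  for (r in seq_len(spec@replicates)) {
    sub <- sub + 1L
    curvesList[[length(curvesList) + 1L]] <-
      mkCurve(sprintf("ctl_r%d", r), 0, "negative-control",
              .velocityToSlope(v0, cond), sub)
  }
  for (ci in seq_along(spec@concentrations)) {
    conc <- spec@concentrations[ci]
    slope <- .velocityToSlope(.wellVelocity(conc, kiUM, spec@mode, cond), cond)
    for (r in seq_len(spec@replicates)) {
      sub <- sub + 1L
      curvesList[[length(curvesList) + 1L]] <-
        mkCurve(sprintf("tst_c%02d_r%d", ci, r), conc, "test", slope, sub)
    }
  }

  sOverKm <- cond@substrateConc / cond@Km
  ic50True <- if (spec@mode == "competitive") kiUM * (1 + sOverKm) else kiUM
  new("PlateAssay", curves = curvesList, conditions = cond, corrected = FALSE,
      truth = list(ki_uM = kiUM, ic50_uM = ic50True, mode = spec@mode,
                   noise_sd_AU = spec@noiseSD, seed = spec@seed,
                   baseline_AU = spec@baseline))
}

#' @describeIn initialRate least-squares slope of one progress curve
#' @export
setMethod("initialRate", "ProgressCurve", function(curve, window = NULL) {
  t <- curve@times; a <- curve@absorbance
  if (!is.null(window)) {
    keep <- t <= t[1] + window
    if (sum(keep) < 3L)
      stop("fewer than 3 points inside the ", window, " s window for well ",
           curve@well)
    t <- t[keep]; a <- a[keep]
  }
  slopePerSec <- stats::cov(t, a) / stats::var(t)
  rate <- slopePerSec * 60
  if (rate < 0)
    warning(warningCondition(
      sprintf("negative rate (%.4g AU/min) in well %s", rate, curve@well),
      class = "eiipScreen_negative_rate"))
  rate
})

#' Percent inhibition from rates
#'
#' 100 (1 - v_test / v_0) where v_0 is the (blank-corrected) uninhibited
#' rate. Values are not clipped: noise can legitimately place them slightly
#' below 0 or above 100 and the IC50 fit must see that.
#'
#' @param rateTest rate(s) in the presence of inhibitor, AU/min
#' @param rateUninhibited uninhibited control rate, AU/min, must be positive
#' @return percent inhibition, same length as `rateTest`
#' @export
percentInhibition <- function(rateTest, rateUninhibited) {
  if (length(rateUninhibited) != 1L || !is.finite(rateUninhibited) ||
      rateUninhibited <= 0)
    stop("uninhibited rate must be a single positive value (assay failure?)")
  100 * (1 - rateTest / rateUninhibited)
}

#' @describeIn blankCorrect subtract the mean blank trace from every well
#' @export
setMethod("blankCorrect", "PlateAssay", function(plate) {
  if (plate@corrected) return(plate)
  isBlank <- vapply(plate@curves, function(x) x@role == "blank", logical(1))
  if (!any(isBlank)) stop("plate has no blank wells; cannot blank-correct")
  refTimes <- plate@curves[[1]]@times
  same <- vapply(plate@curves, function(x)
    length(x@times) == length(refTimes) && all(x@times == refTimes), logical(1))
  if (!all(same))
    stop("blank correction requires all wells on a common time grid")
  blankMean <- rowMeans(vapply(plate@curves[isBlank],
                               function(x) x@absorbance,
                               numeric(length(refTimes))))
  plate@curves <- lapply(plate@curves, function(x) {
    x@absorbance <- x@absorbance - blankMean
    x
  })
  plate@corrected <- TRUE
  plate
})

#' Fit an IC50 to a percent-inhibition series
#'
#' Four-parameter log-logistic model
#' \eqn{y = b + (T - b) / (1 + (IC50/c)^h)} fitted by unweighted (or
#' user-weighted) least squares, parameterised in log(IC50) for stability.
#' The bottom and top asymptotes are fixed at 0 and 100 by default and can
#' be released. The IC50 standard error comes from the covariance of the
#' log-IC50 parameter by the delta method. Points at zero concentration are
#' excluded from the fit (the uninhibited control defines the 0 percent
#' level, not a point on the log-concentration axis).
#'
#' @param concentrations inhibitor concentrations, uM
#' @param inhibition percent inhibition, paired with `concentrations`
#' @param weights optional least-squares weights
#' @param fixBottom keep the bottom asymptote at 0
#' @param fixTop keep the top asymptote at 100
#' @return an [InhibitionResult-class]
#' @examples
#' conc <- c(10, 30, 100, 300, 1000)
#' fitIC50(conc, 100 * conc / (conc + 100))   # recovers IC50 = 100, h = 1
#' @export
fitIC50 <- function(concentrations, inhibition, weights = NULL,
                    fixBottom = TRUE, fixTop = TRUE) {
  stopifnot(length(concentrations) == length(inhibition))
  keep <- concentrations > 0 & is.finite(inhibition)
  conc <- concentrations[keep]; inh <- inhibition[keep]
  w <- if (is.null(weights)) rep(1, length(conc)) else weights[keep]
  if (length(unique(conc)) < 4L)
    stop("need >= 4 distinct positive concentrations to fit an IC50")
  if (stats::sd(inh) < 1e-9 || diff(range(inh)) < 1)
    stop("no transition observed: inhibition is flat across the series")

  # crude start: log-linear interpolation of the 50% crossing
  ord <- order(conc)
  mInh <- tapply(inh, conc, mean)
  uConc <- as.numeric(names(mInh))
  cross <- which(mInh >= 50)[1]
  p0 <- if (!is.na(cross) && cross > 1) {
    f <- (50 - mInh[cross - 1]) / (mInh[cross] - mInh[cross - 1])
    log(uConc[cross - 1]) + f * (log(uConc[cross]) - log(uConc[cross - 1]))
  } else mean(log(uConc))

  df <- data.frame(conc = conc, inh = inh)
  model <- if (fixBottom && fixTop)
    inh ~ 100 / (1 + exp(h * (p - log(conc))))
  else if (fixBottom)
    inh ~ top / (1 + exp(h * (p - log(conc))))
  else if (fixTop)
    inh ~ bottom + (100 - bottom) / (1 + exp(h * (p - log(conc))))
  else
    inh ~ bottom + (top - bottom) / (1 + exp(h * (p - log(conc))))
  start <- list(p = unname(p0), h = 1)
  if (!fixTop) start$top <- 100
  if (!fixBottom) start$bottom <- 0

  fit <- tryCatch(
    minpack.lm::nlsLM(model, data = df, start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  inhTab <- data.frame(conc_uM = uConc, inhibition_pct = as.numeric(mInh),
                       sd_pct = as.numeric(tapply(inh, conc, stats::sd)),
                       n = as.integer(table(conc)))
  if (inherits(fit, "error")) {
    warning("IC50 fit did not converge: ", conditionMessage(fit))
    return(new("InhibitionResult", inhibition = inhTab, ic50 = NA_real_,
               ic50SE = NA_real_, hill = NA_real_, residuals = numeric(),
               converged = FALSE, censored = NA_character_, ki = NA_real_))
  }
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  seP <- if (!is.null(vc)) sqrt(vc["p", "p"]) else NA_real_
  ic50Hat <- exp(unname(est["p"]))
  new("InhibitionResult", inhibition = inhTab, ic50 = ic50Hat,
      ic50SE = ic50Hat * seP, hill = unname(est["h"]),
      residuals = as.numeric(stats::residuals(fit)), converged = TRUE,
      censored = NA_character_, ki = NA_real_)
}

#' @describeIn analyzePlate full analysis of a plate assay
#' @export
setMethod("analyzePlate", "PlateAssay", function(plate, window = NULL, ...) {
  roles <- vapply(plate@curves, function(x) x@role, character(1))
  if (!any(roles == "blank")) stop("plate has no blank wells")
  if (!any(roles == "negative-control"))
    stop("plate has no negative-control (uninhibited) wells")

  quietRate <- function(cv) withCallingHandlers(
    initialRate(cv, window),
    eiipScreen_negative_rate = function(w) invokeRestart("muffleWarning"))
  rates <- vapply(plate@curves, quietRate, numeric(1))

  blankRate <- if (plate@corrected) 0 else mean(rates[roles == "blank"])
  v0 <- mean(rates[roles == "negative-control"]) - blankRate
  if (!is.finite(v0) || v0 <= 0)
    stop("blank-corrected uninhibited rate is not positive; assay failure")

  isTest <- roles == "test"
  if (!any(isTest)) stop("plate has no test wells")
  conc <- vapply(plate@curves[isTest], function(x) x@conc, numeric(1))
  inh <- percentInhibition(rates[isTest] - blankRate, v0)

  ord <- order(conc)
  conc <- conc[ord]; inh <- inh[ord]
  mInh <- tapply(inh, conc, mean)
  inhTab <- data.frame(conc_uM = as.numeric(names(mInh)),
                       inhibition_pct = as.numeric(mInh),
                       sd_pct = as.numeric(tapply(inh, conc, stats::sd)),
                       n = as.integer(table(conc)))

  cMax <- max(conc)
  topInh <- mInh[[as.character(cMax)]]
  if (topInh < 50) {
    return(new("InhibitionResult", inhibition = inhTab, ic50 = NA_real_,
               ic50SE = NA_real_, hill = NA_real_, residuals = numeric(),
               converged = TRUE, censored = sprintf("gt:%g", cMax),
               ki = NA_real_))
  }
  res <- fitIC50(conc, inh, ...)
  res@inhibition <- inhTab
  res
})

#' @rdname inhibition-accessors
#' @export
setMethod("ic50", "InhibitionResult", function(object) object@ic50)
#' @rdname inhibition-accessors
#' @export
setMethod("ic50SE", "InhibitionResult", function(object) object@ic50SE)
#' @rdname inhibition-accessors
#' @export
setMethod("hillSlope", "InhibitionResult", function(object) object@hill)
#' @rdname inhibition-accessors
#' @export
setMethod("isCensored", "InhibitionResult", function(object) !is.na(object@censored))
#' @rdname inhibition-accessors
#' @export
setMethod("inhibitionTable", "InhibitionResult", function(object) object@inhibition)

#' @rdname plate-accessors
#' @export
setMethod("curves", "PlateAssay", function(object) object@curves)
#' @rdname plate-accessors
#' @export
setMethod("wells", "PlateAssay", function(object)
  vapply(object@curves, function(x) x@well, character(1)))
#' @rdname plate-accessors
#' @export
setMethod("conditions", "PlateAssay", function(object) object@conditions)

setMethod("show", "PlateAssay", function(object) {
  roles <- vapply(object@curves, function(x) x@role, character(1))
  cat("PlateAssay with", length(object@curves), "wells (",
      paste(sprintf("%s: %d", names(table(roles)), table(roles)), collapse = ", "),
      ")\n")
  cat("  corrected:", object@corrected, "\n")
  if (length(object@truth))
    cat(sprintf("  simulated ground truth: IC50 = %g uM (%s), Ki = %g uM\n",
                object@truth$ic50_uM, object@truth$mode, object@truth$ki_uM))
})

setMethod("show", "InhibitionResult", function(object) {
  cat("InhibitionResult over", nrow(object@inhibition), "concentrations\n")
  if (isCensored(object)) {
    cMax <- sub("^gt:", "", object@censored)
    cat("  no activity: IC50 >", cMax, "uM",
        "(top tested concentration below 50% inhibition)\n")
  } else if (!object@converged) {
    cat("  fit did not converge\n")
  } else {
    cat(sprintf("  IC50 = %.4g +/- %.2g uM, Hill slope = %.3g\n",
                object@ic50, object@ic50SE, object@hill))
  }
})
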