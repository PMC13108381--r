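## Sodium-fluorescein (NaFl) tracer fluorometry: linear standard curve,
## concentration inversion, and brain-to-blood permeability ratios.

#' Fit a linear fluorescence standard curve
#'
#' Ordinary least squares of reading on concentration. The fitted
#' concentration range is recorded so later inversions can flag
#' extrapolation.
#'
#' @param concentrations standard concentrations (>= 2 distinct values).
#' @param readings matching fluorescence readings.
#' @return a [StandardCurve].
#' @export
fitStandardCurve <- function(concentrations, readings) {
  if (length(concentrations) != length(readings))
    stop("concentrations and readings must have equal length")
  if (length(unique(concentrations)) < 2)
    stop("at least 2 distinct concentrations are required")
  fit <- stats::lm(readings ~ concentrations)
  ss <- sum((readings - mean(readings))^2)
  r2 <- if (ss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss
  new("StandardCurve", slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]), r2 = r2,
      range = range(concentrations))
}

#' Invert a fluorescence reading to a concentration
#'
#' @param curve a [StandardCurve] with non-zero slope.
#' @param reading fluorescence reading(s).
#' @return data.frame with `concentration` and `extrapolated` (TRUE
#'   when the value falls outside the fitted range).
#' @export
invertConcentration <- function(curve, reading) {
  stopifnot(is(curve, "StandardCurve"))
  if (curve@slope == 0) stop("standard curve slope is zero")
  conc <- (reading - curve@intercept) / curve@slope
  data.frame(concentration = conc,
             extrapolated = conc < curve@range[1] | conc > curve@range[2])
}

#' Mass-normalized tissue tracer content
#'
#' Converts a fluorescence reading into tracer amount per unit tissue
#' mass: concentration (from the standard curve) times the total
#' extract volume, divided by the tissue mass.
#'
#' @param reading fluorescence reading of the tissue extract.
#' @param curve a [StandardCurve].
#' @param extractVolume total extract volume (e.g. ml).
#' @param mass tissue (or blood) mass (> 0, e.g. mg).
#' @return list with `concentration`, `amount`, `perMass` and
#'   `extrapolated`.
#' @export
tissueConcentration <- function(reading, curve, extractVolume, mass) {
  if (mass <= 0) stop("tissue mass must be > 0")
  if (extractVolume <= 0) stop("extract volume must be > 0")
  inv <- invertConcentration(curve, reading)
  amount <- inv$concentration * extractVolume
  list(concentration = inv$concentration, amount = amount,
       perMass = amount / mass, extrapolated = inv$extrapolated)
}

#' Brain-to-blood tracer permeability ratio
#'
#' The blood-brain-barrier readout: ratio of mass-normalized NaFl
#' content in brain tissue to that in blood, both quantified through
#' the same standard curve. Multiplying all readings by a constant
#' (with a refit curve) leaves the ratio unchanged.
#'
#' @param brainReading,bloodReading fluorescence readings.
#' @param curve a [StandardCurve].
#' @param brainMass,bloodMass tissue masses (> 0).
#' @param brainVolume,bloodVolume extract volumes (default 1, i.e.
#'   readings already per common volume).
#' @return list with `ratio` and the per-tissue components.
#' @export
permeabilityRatio <- function(brainReading, bloodReading, curve,
                              brainMass, bloodMass,
                              brainVolume = 1, bloodVolume = 1) {
  brain <- tissueConcentration(brainReading, curve, brainVolume, brainMass)
  blood <- tissueConcentration(bloodReading, curve, bloodVolume, bloodMass)
  if (blood$perMass <= .Machine$double.eps^0.5 * abs(brain$perMass) ||
      blood$perMass <= 0)
    stop("blood concentration is zero or negative")
  list(ratio = brain$perMass / blood$perMass,
       brain = brain, blood = blood)
}
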