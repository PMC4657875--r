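#' Assay constants for nitrophenol-based colorimetric conversions
#'
#' @param epsilonNitrophenol molar extinction coefficient of nitrophenol
#'   at 410 nm, per M per cm (default 17700).
#' @param pathlengthCm optical path length in cm (default 1.0; plate-well
#'   path length is the dominant systematic unknown of the absolute scale).
#' @param nitrophenolMW g/mol, used only for mass-unit views (139.11).
#' @return list of class "assay_constants".
#' @export
#' @examples
#' assayConstants()
assayConstants <- function(epsilonNitrophenol = 17700, pathlengthCm = 1.0,
                           nitrophenolMW = 139.11) {
  if (epsilonNitrophenol <= 0 || pathlengthCm <= 0)
    stop("epsilonNitrophenol and pathlengthCm must be > 0")
  structure(list(epsilonNitrophenol = epsilonNitrophenol,
                 pathlengthCm = pathlengthCm,
                 nitrophenolMW = nitrophenolMW),
            class = "assay_constants")
}

#' Convert a blank-corrected A410 delta to enzyme activity
#'
#' Beer-Lambert conversion of released nitrophenol: delta A410 /
#' (epsilon x pathlength) gives molar product concentration; expressed
#' as nmol/ml (= uM) and normalized by elapsed time and culture OD600.
#' Small negative deltas (blank over-subtraction) clip to 0 with a
#' warning.
#'
#' @param deltaA410 blank-corrected absorbance change at 410 nm.
#' @param minutes elapsed assay time (> 0).
#' @param od600 culture optical density used for normalization (> 0).
#' @param constants an \code{\link{assayConstants}} list.
#' @return Activity in nmol product/ml/min/OD600.
#' @export
#' @examples
#' absorbanceToActivity(0.177, minutes = 10, od600 = 1) # 1 nmol/ml/min/OD
absorbanceToActivity <- function(deltaA410, minutes, od600,
                                 constants = assayConstants()) {
  if (any(minutes <= 0)) stop("minutes must be > 0")
  if (any(od600 <= 0)) stop("od600 must be > 0")
  if (any(deltaA410 < 0)) {
    warning("negative blank-corrected A410 clipped to 0")
    deltaA410 <- pmax(deltaA410, 0)
  }
  molar <- deltaA410 / (constants$epsilonNitrophenol * constants$pathlengthCm)
  nmolPerMl <- molar * 1e6  # mol/L -> nmol/ml
  nmolPerMl / minutes / od600
}

#' Inverse of absorbanceToActivity (forward assay model)
#'
#' Converts a true activity back to the blank-corrected A410 delta a
#' plate reader would record; used by the synthetic-signal generator.
#'
#' @inheritParams absorbanceToActivity
#' @param activity nmol/ml/min/OD600.
#' @return delta A410.
#' @export
activityToAbsorbance <- function(activity, minutes, od600,
                                 constants = assayConstants()) {
  activity * minutes * od600 *
    constants$epsilonNitrophenol * constants$pathlengthCm / 1e6
}

#' Activity unit conversions
#'
#' The canonical internal unit is molar-based (nmol product/ml/min/OD600).
#' Mass-based views multiply by the nitrophenol molecular weight:
#' ng/ml/min/OD = nmol/ml/min/OD x MW; ug = ng / 1000.
#'
#' @param activity activity in nmol/ml/min/OD600.
#' @param unit target unit, one of "nmol_ml_min_od", "ng_ml_min_od",
#'   "ug_ml_min_od".
#' @param constants an \code{\link{assayConstants}} list.
#' @return Converted activity value.
#' @export
#' @examples
#' convertActivityUnits(1, "ng_ml_min_od") # 139.11
convertActivityUnits <- function(activity,
                                 unit = c("nmol_ml_min_od", "ng_ml_min_od",
                                          "ug_ml_min_od"),
                                 constants = assayConstants()) {
  unit <- match.arg(unit)
  switch(unit,
         nmol_ml_min_od = activity,
         ng_ml_min_od = activity * constants$nitrophenolMW,
         ug_ml_min_od = activity * constants$nitrophenolMW / 1000)
}

#' Protease activity from FITC-casein fluorescence
#'
#' Per-sample baseline autofluorescence (t = 0) is subtracted from the
#' endpoint reading and the difference normalized by incubation time and
#' OD600. Negative differences clip to 0 with a warning.
#'
#' @param fEnd endpoint fluorescence (RFU).
#' @param fBaseline t = 0 autofluorescence of the same sample mix (RFU).
#' @param hours incubation time (> 0; the assay uses 4 h).
#' @param od600 culture optical density (> 0).
#' @return Activity in RFU/h/OD600.
#' @export
#' @examples
#' proteaseActivity(4000, 400, hours = 4, od600 = 0.45) # 2000
proteaseActivity <- function(fEnd, fBaseline, hours = 4, od600 = 0.45) {
  if (any(hours <= 0)) stop("hours must be > 0")
  if (any(od600 <= 0)) stop("od600 must be > 0")
  d <- fEnd - fBaseline
  if (any(d < 0)) {
    warning("endpoint fluorescence below baseline; clipped to 0")
    d <- pmax(d, 0)
  }
  d / hours / od600
}

#' Percent liposome lysis
#'
#' Normalizes sample fluorescence between the heat-denatured-supernatant
#' negative control (0%) and the Triton X-100 positive control (100%).
#' Values outside [0, 100] are reported unclipped with an out_of_range
#' attribute.
#'
#' @param fSample sample fluorescence.
#' @param fNegative negative-control fluorescence.
#' @param fTriton Triton X-100 positive-control fluorescence
#'   (must differ from fNegative).
#' @return Percent lysis (may be < 0 or > 100), with attribute
#'   \code{out_of_range} flagging such values.
#' @export
#' @examples
#' percentLysis(1500, 1000, 2000) # 50
percentLysis <- function(fSample, fNegative, fTriton) {
  if (isTRUE(all(fTriton == fNegative)) || any(fTriton == fNegative))
    stop("uninformative controls: fTriton equals fNegative")
  pct <- 100 * (fSample - fNegative) / (fTriton - fNegative)
  attr(pct, "out_of_range") <- pct < 0 | pct > 100
  pct
}

#' Convert a raw signal table to activity records
#'
#' Applies the per-enzyme conversion (Beer-Lambert for NPB/NPP/NPPC,
#' baseline-subtracted fluorescence rate for protease) to a signal table
#' in the layout written by \code{\link{simulateAssayReadouts}}.
#'
#' @param signals data.frame with columns design_id, enzyme, replicate,
#'   signal_start, signal_end, minutes, od600.
#' @param constants an \code{\link{assayConstants}} list.
#' @return data.frame(design_id, enzyme, replicate, activity, units) in
#'   canonical units (nmol/ml/min/OD600; protease RFU/h/OD600).
#' @export
convertSignals <- function(signals, constants = assayConstants()) {
  need <- c("design_id", "enzyme", "replicate", "signal_start",
            "signal_end", "minutes", "od600")
  if (!all(need %in% names(signals)))
    stop("signals table is missing columns: ",
         paste(setdiff(need, names(signals)), collapse = ", "))
  act <- numeric(nrow(signals))
  isProt <- signals$enzyme == "protease"
  if (any(!isProt)) {
    s <- signals[!isProt, ]
    act[!isProt] <- absorbanceToActivity(s$signal_end - s$signal_start,
                                         s$minutes, s$od600, constants)
  }
  if (any(isProt)) {
    s <- signals[isProt, ]
    act[isProt] <- proteaseActivity(s$signal_end, s$signal_start,
                                    hours = s$minutes / 60, od600 = s$od600)
  }
  data.frame(design_id = signals$design_id, enzyme = signals$enzyme,
             replicate = signals$replicate, activity = act,
             units = ifelse(isProt, "RFU/h/OD600", "nmol/ml/min/OD600"),
             stringsAsFactors = FALSE)
}
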