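# Physiological formulas for drought phenotyping.
#
# All operations are pure, vectorized arithmetic on measured quantities:
# leaf relative water content from fresh/turgid/dry weights, maximum PSII
# quantum yield from dark-adapted fluorescence, water-use efficiency from gas
# exchange, gravimetric soil water content, and daily water consumption from
# pot-weighing series. Units are carried in the record schema and are never
# converted automatically.

#' Leaf relative water content (LRWC)
#'
#' `LRWC = 100 * (FW - DW) / (TW - DW)` — leaf hydration relative to full
#' turgor, in percent. FW slightly outside `[DW, TW]` (a common weighing
#' anomaly) warns but the raw value is still returned; reporting stages may
#' cap it at 100.
#'
#' @param FW fresh weight (g).
#' @param TW turgid weight (g), after rehydration.
#' @param DW dry weight (g).
#' @return LRWC in percent.
#' @export
lrwc <- function(FW, TW, DW) {
  if (any(FW <= 0) || any(TW <= 0) || any(DW <= 0)) stopf("weights must be positive")
  if (any(TW <= DW)) stopf("turgid weight must exceed dry weight")
  if (any(FW < DW | FW > TW)) {
    warnf("FW outside [DW, TW] for %d observation(s): measurement anomaly, raw LRWC returned",
          sum(FW < DW | FW > TW))
  }
  100 * (FW - DW) / (TW - DW)
}

#' Maximum photosystem II quantum yield (Fv/Fm)
#'
#' `Fv/Fm = (Fm - Fo) / Fm` from dark-adapted minimum (Fo) and maximum (Fm)
#' fluorescence yields.
#'
#' @param Fo minimum fluorescence yield (dark-adapted), >= 0.
#' @param Fm maximum fluorescence yield, > 0 and >= Fo.
#' @return the Fv/Fm ratio in `[0, 1)`.
#' @export
fv_fm <- function(Fo, Fm) {
  if (any(Fm <= 0)) stopf("Fm must be positive")
  if (any(Fo < 0)) stopf("Fo must be non-negative")
  if (any(Fo > Fm)) stopf("Fo > Fm is physically impossible")
  (Fm - Fo) / Fm
}

#' Instantaneous water-use efficiency (A/E)
#'
#' Ratio of net CO2 assimilation to transpiration. Note: this follows the
#' printed A/E definition used for the drought screening; much of the gas
#' exchange literature reserves "intrinsic" WUE for A/gs — see the methods
#' vignette.
#'
#' @param A net CO2 assimilation rate (umol CO2 m^-2 s^-1).
#' @param E transpiration rate (mmol H2O m^-2 s^-1), nonzero.
#' @return A/E in the units implied by the inputs.
#' @export
iwue <- function(A, E) {
  if (any(E == 0)) stopf("E = 0 (stomata closed): iWUE undefined")
  A / E
}

#' Gravimetric soil water content
#'
#' `(wet - dry) / dry` on a dry-mass basis, from the oven-drying method
#' (105 degC to constant weight).
#'
#' @param wet_g soil sample wet weight (g).
#' @param oven_dry_g soil sample weight after oven drying (g), > 0.
#' @return water content as a fraction of dry mass.
#' @export
swc_gravimetric <- function(wet_g, oven_dry_g) {
  if (any(oven_dry_g <= 0)) stopf("oven-dry weight must be positive")
  if (any(wet_g < oven_dry_g)) stopf("wet weight below dry weight")
  (wet_g - oven_dry_g) / oven_dry_g
}

#' Daily water consumption from pot-weighing series
#'
#' Pots are weighed before the daily refill and again after refilling;
#' evapotranspiration on day t is the mass lost since the previous refill:
#' `DWC(t) = after_refill(t-1) - before(t)`, in grams (= mL of water).
#'
#' @param pot_weight_before_g weights before refill, days 1..T (g).
#' @param pot_weight_after_refill_g weights after refill, days 1..T (g).
#' @return DWC for days 2..T (g).
#' @export
daily_water_consumption <- function(pot_weight_before_g, pot_weight_after_refill_g) {
  b <- pot_weight_before_g; a <- pot_weight_after_refill_g
  if (length(b) != length(a)) stopf("before and after-refill series must have equal length")
  if (length(b) < 2) stopf("need at least two days of weighings")
  dwc <- a[-length(a)] - b[-1]
  if (any(dwc < 0)) {
    stopf("negative water consumption on day %s: pot gained mass between refills",
          paste(which(dwc < 0) + 1, collapse = ", "))
  }
  dwc
}

#' Validate a table of plant records
#'
#' Checks the physical invariants of the record schema (DW <= FW <= TW,
#' 0 <= LRWC <= 100, 0 <= Fv/Fm < 1, Fo <= Fm, leaf counts, non-negative
#' masses) and flags unit-implausible magnitudes. Violations warn; the report
#' is returned for inspection.
#'
#' @param records a data.frame of plant records (see [generate_experiment()]).
#' @return data.frame with one row per violation (`row`, `check`, `value`);
#'   zero rows when the table is clean.
#' @export
validate_plant_records <- function(records) {
  bad <- list()
  flag <- function(rows, check, values) {
    if (any(rows)) bad[[length(bad) + 1]] <<- data.frame(
      row = which(rows), check = check, value = values[rows])
  }
  has <- function(v) v %in% names(records)
  if (all(has(c("FW", "TW", "DW")))) {
    flag(records$DW > records$FW | records$FW > records$TW,
         "DW <= FW <= TW", records$FW)
  }
  if (has("LRWC")) flag(records$LRWC < 0 | records$LRWC > 100 + 1e-9, "0 <= LRWC <= 100", records$LRWC)
  if (has("FvFm")) flag(records$FvFm < 0 | records$FvFm >= 1, "0 <= FvFm < 1", records$FvFm)
  if (all(has(c("Fo", "Fm")))) flag(records$Fo > records$Fm, "Fo <= Fm", records$Fo)
  if (all(has(c("leaves_total", "leaves_wilted", "leaves_dead")))) {
    flag(records$leaves_wilted + records$leaves_dead > records$leaves_total,
         "wilted + dead <= total leaves", records$leaves_total)
  }
  for (v in intersect(c("FW", "TW", "DW", "AGB", "GY", "gs", "E"), names(records))) {
    flag(records[[v]] < 0, paste0(v, " >= 0"), records[[v]])
  }
  out <- if (length(bad)) do.call(rbind, bad) else
    data.frame(row = integer(), check = character(), value = numeric())
  if (nrow(out)) warnf("%d plant-record invariant violation(s); see the returned report", nrow(out))
  out
}
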