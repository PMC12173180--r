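# Biomass and productivity arithmetic from harvest records.
#
# Every returned quantity carries a "unit" attribute so downstream reports
# (and the unit-audit tests) can verify dimensions without a units package.

with_unit <- function(x, unit) {
  attr(x, "unit") <- unit
  x
}

#' Unit tag of a cultivation quantity
#'
#' @param x A value returned by the cultivation functions.
#' @return Character unit string (e.g. `"g/L/day"`), or `NULL`.
#' @export
unit_of <- function(x) attr(x, "unit", exact = TRUE)

#' Describe a culture vessel
#'
#' @param total_volume_l Total culture volume, L.
#' @param vessel_area_m2 Footprint area of the vessel, m2.
#' @param duration_days Cultivation duration, days.
#' @return A `culture_setup` object.
#' @export
culture_setup <- function(total_volume_l, vessel_area_m2, duration_days) {
  if (total_volume_l <= 0 || vessel_area_m2 <= 0 || duration_days <= 0) {
    .fame_error("culture volume, area and duration must all be positive",
                "famefuel_value_error")
  }
  structure(list(total_volume_l = total_volume_l,
                 vessel_area_m2 = vessel_area_m2,
                 duration_days = duration_days),
            class = "culture_setup")
}

#' Dry biomass concentration from replicate harvests
#'
#' Per replicate, the concentration is the dried pellet weight (g) divided
#' by the sampled culture volume (L); the replicate mean and sample standard
#' deviation (n - 1 denominator) are reported alongside.
#'
#' @param weights_g Replicate dry weights, g.
#' @param volumes_l Replicate sample volumes, L (recycled if scalar).
#' @return List with `per_replicate` (g/L), `mean`, `sd` and `n`.
#'
#' @examples
#' dry_biomass_concentration(c(0.0046, 0.0050, 0.0045), 0.005)$mean  # 0.94
#' @export
dry_biomass_concentration <- function(weights_g, volumes_l) {
  if (length(volumes_l) == 1L) volumes_l <- rep(volumes_l, length(weights_g))
  if (length(weights_g) != length(volumes_l)) {
    .fame_error("replicate weight and volume counts differ",
                "famefuel_value_error")
  }
  if (any(weights_g < 0)) {
    .fame_error("dry weights must be non-negative", "famefuel_value_error")
  }
  if (any(volumes_l <= 0)) {
    .fame_error("sample volumes must be positive", "famefuel_value_error")
  }
  conc <- weights_g / volumes_l
  list(per_replicate = with_unit(conc, "g/L"),
       mean = with_unit(mean(conc), "g/L"),
       sd = with_unit(stats::sd(conc), "g/L"),
       n = length(conc))
}

#' Volumetric productivity
#'
#' V = (final - initial biomass concentration) / elapsed days.  A declining
#' culture yields a negative productivity and a warning rather than an
#' error.
#'
#' @param initial_g_l Initial dry biomass concentration, g/L.
#' @param final_g_l Final dry biomass concentration, g/L.
#' @param days Elapsed time, days (> 0).
#' @return Productivity in g/L/day (unit-tagged).
#'
#' @examples
#' volumetric_productivity(0.2, 0.95, 15)  # 0.05 g/L/day
#' @export
volumetric_productivity <- function(initial_g_l, final_g_l, days) {
  if (days <= 0) {
    .fame_error("elapsed time must be positive", "famefuel_value_error")
  }
  v <- (final_g_l - initial_g_l) / days
  if (v < 0) {
    warning("negative volumetric productivity: culture declined over the interval",
            call. = FALSE)
  }
  with_unit(v, "g/L/day")
}

#' Areal productivity
#'
#' A = V * total culture volume / vessel footprint area, converting a
#' per-liter rate into a per-ground-area rate.
#'
#' @param v Volumetric productivity, g/L/day.
#' @param setup A `culture_setup`, or the total volume in L when
#'   `vessel_area_m2` is given directly.
#' @param vessel_area_m2 Vessel area, m2 (when `setup` is a plain volume).
#' @return Areal productivity in g/m2/day (unit-tagged).
#'
#' @examples
#' areal_productivity(0.0506, 35, 0.172)  # 10.3 g/m2/day
#' @export
areal_productivity <- function(v, setup, vessel_area_m2 = NULL) {
  if (inherits(setup, "culture_setup")) {
    vol <- setup$total_volume_l
    area <- setup$vessel_area_m2
  } else {
    vol <- setup
    area <- vessel_area_m2
  }
  if (is.null(area) || area <= 0) {
    .fame_error("vessel area must be positive", "famefuel_value_error")
  }
  with_unit(as.numeric(v) * vol / area, "g/m2/day")
}

#' Lipid yield per culture volume
#'
#' yield (mg/L) = biomass concentration (g/L) x lipid content (% of dry
#' weight) / 100 x 1000.
#'
#' @param biomass_g_l Dry biomass concentration, g/L.
#' @param lipid_percent Lipid content, percent of dry weight (0-100).
#' @return Lipid yield in mg/L (unit-tagged).
#'
#' @examples
#' lipid_yield(0.915, 27)  # 247.05 mg/L, prints as 247
#' @export
lipid_yield <- function(biomass_g_l, lipid_percent) {
  if (any(lipid_percent < 0 | lipid_percent > 100)) {
    .fame_error("lipid content must be within [0, 100] percent",
                "famefuel_value_error")
  }
  if (any(biomass_g_l < 0)) {
    .fame_error("biomass concentration must be non-negative",
                "famefuel_value_error")
  }
  with_unit(biomass_g_l * lipid_percent / 100 * 1000, "mg/L")
}

#' Summarize a harvest-record series into productivity metrics
#'
#' Takes a data frame of replicate harvests over time (columns `time`,
#' `replicate`, `weight_g`, `volume_l`), computes the per-time-point biomass
#' concentration, and derives the volumetric and areal productivity between
#' the first and last time points.
#'
#' @param harvests Data frame with columns `time`, `replicate`, `weight_g`,
#'   `volume_l`.
#' @param setup A `culture_setup`.
#' @return List with `concentrations` (data frame: time, mean, sd, n),
#'   `volumetric` (g/L/day) and `areal` (g/m2/day).
#' @export
cultivation_summary <- function(harvests, setup) {
  stopifnot(inherits(setup, "culture_setup"))
  need <- c("time", "replicate", "weight_g", "volume_l")
  if (!all(need %in% names(harvests))) {
    .fame_error(sprintf("harvest table must have columns %s",
                        paste(need, collapse = ", ")),
                "famefuel_io_error")
  }
  times <- sort(unique(harvests$time))
  conc <- do.call(rbind, lapply(times, function(tt) {
    sub <- harvests[harvests$time == tt, ]
    d <- dry_biomass_concentration(sub$weight_g, sub$volume_l)
    data.frame(time = tt, mean = as.numeric(d$mean), sd = as.numeric(d$sd),
               n = d$n)
  }))
  dt <- max(times) - min(times)
  v <- volumetric_productivity(conc$mean[1], conc$mean[nrow(conc)], dt)
  list(concentrations = conc, volumetric = v,
       areal = areal_productivity(v, setup))
}
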