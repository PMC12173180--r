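# Empirical FAME-composition -> fuel-property correlations and standard
# compliance.  All engine functions return full-precision values; rounding to
# the precision fuel-property tables are usually printed at happens only in
# the report layer (round_for_report, run_table3_demo).

.wt_of <- function(profile, carbons, double_bonds) {
  sel <- profile$species$carbons == carbons &
    profile$species$double_bonds == double_bonds
  sum(profile$species$weight_percent[sel])
}

.check_nonempty <- function(profile, what) {
  stopifnot(inherits(profile, "fame_profile"))
  if (nrow(profile$species) == 0L) {
    .fame_error(sprintf("%s undefined for an empty FAME profile", what),
                "famefuel_value_error")
  }
}

#' Saponification value from a FAME profile
#'
#' SV = sum over species of 560 P_i / M_i, with P_i the weight percent and
#' M_i the methyl-ester molecular weight (g/mol).
#'
#' @param profile A `fame_profile`.
#' @return Saponification value in mg KOH per g.
#' @export
saponification_value <- function(profile) {
  .check_nonempty(profile, "saponification value")
  m <- fame_molecular_weight(profile$species$carbons,
                             profile$species$double_bonds)
  sum(560 * profile$species$weight_percent / m)
}

#' Iodine value from a FAME profile
#'
#' IV = sum over species of 254 D_i P_i / M_i; zero exactly when the profile
#' is fully saturated.
#'
#' @param profile A `fame_profile`.
#' @return Iodine value in g I2 per 100 g.
#' @export
iodine_value <- function(profile) {
  .check_nonempty(profile, "iodine value")
  m <- fame_molecular_weight(profile$species$carbons,
                             profile$species$double_bonds)
  sum(254 * profile$species$double_bonds * profile$species$weight_percent / m)
}

#' Cetane number from saponification and iodine values
#'
#' CN = 46.3 + 5458/SV - 0.225 IV.
#'
#' @param sv Saponification value, mg KOH/g (> 0).
#' @param iv Iodine value, g I2/100 g.
#' @return Dimensionless cetane number.
#'
#' @examples
#' cetane_number(179, 72)  # 60.6, rounds to 61
#' @export
cetane_number <- function(sv, iv) {
  if (any(sv <= 0)) {
    .fame_error("cetane number requires a positive saponification value",
                "famefuel_value_error")
  }
  46.3 + 5458 / sv - 0.225 * iv
}

#' Degree of unsaturation
#'
#' DU = MUFA% + 2 PUFA%, the weight-percent-weighted double-bond index.
#'
#' @param totals A `fame_class_totals` (from [class_totals()]) or a
#'   `fame_profile`.
#' @return Dimensionless DU.
#' @export
degree_of_unsaturation <- function(totals) {
  if (inherits(totals, "fame_profile")) totals <- class_totals(totals)
  stopifnot(inherits(totals, "fame_class_totals"))
  totals$mufa + 2 * totals$pufa
}

#' Long-chain saturation factor
#'
#' Weighted sum of long saturated-chain percentages driving cold-flow
#' behavior.  The default uses the C16:0/C18:0 subset
#' LCSF = 0.1 C16:0 + 0.5 C18:0; `full = TRUE` adds the heavier terms
#' 1.0 C20:0 + 1.5 C22:0 + 2.0 C24:0.  Absent species contribute zero.
#'
#' @param profile A `fame_profile`.
#' @param full Use the five-term long-chain definition.
#' @return Dimensionless LCSF.
#' @export
long_chain_saturation_factor <- function(profile, full = FALSE) {
  stopifnot(inherits(profile, "fame_profile"))
  lcsf <- 0.1 * .wt_of(profile, 16, 0) + 0.5 * .wt_of(profile, 18, 0)
  if (full) {
    lcsf <- lcsf + 1.0 * .wt_of(profile, 20, 0) +
      1.5 * .wt_of(profile, 22, 0) + 2.0 * .wt_of(profile, 24, 0)
  }
  lcsf
}

#' Cold filter plugging point from LCSF
#'
#' CFPP = 3.1417 LCSF - 16.477 (degrees Celsius).
#'
#' @param lcsf Long-chain saturation factor (>= 0).
#' @return CFPP in degrees C.
#' @export
cfpp <- function(lcsf) {
  stopifnot(all(lcsf >= 0))
  3.1417 * lcsf - 16.477
}

#' Cloud point from palmitate content
#'
#' CP = 0.526 (wt% C16:0) - 4.992 (degrees Celsius); a profile without
#' C16:0 returns the intercept.
#'
#' @param profile A `fame_profile`.
#' @return Cloud point in degrees C.
#' @export
cloud_point <- function(profile) {
  stopifnot(inherits(profile, "fame_profile"))
  0.526 * .wt_of(profile, 16, 0) - 4.992
}

#' Higher heating value from SV and IV
#'
#' HHV = 49.43 - 0.041 SV - 0.015 IV (MJ/kg).
#'
#' @param sv Saponification value, mg KOH/g (> 0).
#' @param iv Iodine value, g I2/100 g.
#' @return HHV in MJ/kg.
#' @export
hhv <- function(sv, iv) {
  if (any(sv <= 0)) {
    .fame_error("HHV requires a positive saponification value",
                "famefuel_value_error")
  }
  49.43 - 0.041 * sv - 0.015 * iv
}

#' Density of the FAME mixture
#'
#' Mass-weighted mean of the per-species correlation
#' rho_i = 0.8463 + 4.9/M_i + 0.0118 D_i with weights P_i / sum(P), so the
#' result is invariant to uniform rescaling of the composition.
#'
#' @param profile A `fame_profile`.
#' @return Density in g/cm3.
#' @export
fame_density <- function(profile) {
  .check_nonempty(profile, "density")
  m <- fame_molecular_weight(profile$species$carbons,
                             profile$species$double_bonds)
  rho <- 0.8463 + 4.9 / m + 0.0118 * profile$species$double_bonds
  w <- profile$species$weight_percent
  sum(rho * w) / sum(w)
}

#' Predict the full biodiesel property vector
#'
#' Composes the individual correlations: SV, IV, CN, DU, LCSF (both the
#' C16:0/C18:0 subset used for the default CFPP and the five-term long-chain
#' variant), CFPP, cloud point, HHV and density.  Values are full precision;
#' see [round_for_report()] for print-precision rounding.
#'
#' @param profile A `fame_profile`.
#' @return A `biodiesel_properties` object (list of named numerics plus
#'   `sample_id`/`medium`).
#'
#' @examples
#' pw <- read_fame_csv(table2_fame_path())[["PW"]]
#' predict_biodiesel(pw)
#' @export
predict_biodiesel <- function(profile) {
  .check_nonempty(profile, "biodiesel property prediction")
  sv <- saponification_value(profile)
  iv <- iodine_value(profile)
  lcsf_sub <- long_chain_saturation_factor(profile, full = FALSE)
  lcsf_full <- long_chain_saturation_factor(profile, full = TRUE)
  structure(
    list(sample_id = profile$sample_id, medium = profile$medium,
         sv = sv, iv = iv, cn = cetane_number(sv, iv),
         du = degree_of_unsaturation(class_totals(profile)),
         lcsf = lcsf_sub, cfpp = cfpp(lcsf_sub),
         lcsf_full = lcsf_full, cfpp_full = cfpp(lcsf_full),
         cp = cloud_point(profile), hhv = hhv(sv, iv),
         density = fame_density(profile)),
    class = "biodiesel_properties")
}

#' @export
print.biodiesel_properties <- function(x, ...) {
  r <- round_for_report(x)
  cat(sprintf("<biodiesel_properties> sample %s (medium %s)\n",
              x$sample_id, x$medium))
  cat(sprintf("  CN %s  SV %s mg KOH/g  IV %s g I2/100 g  DU %s\n",
              r$cn, r$sv, r$iv, r$du))
  cat(sprintf("  CP %s degC  CFPP %s degC (subset LCSF %.2f; full-chain CFPP %s)\n",
              r$cp, r$cfpp, x$lcsf, r$cfpp_full))
  cat(sprintf("  HHV %s MJ/kg  density %s g/cm3\n", r$hhv, r$density))
  invisible(x)
}

#' Round predicted properties to report precision
#'
#' Rounding conventions of fuel-property tables: CN, SV, IV, DU and HHV to
#' integers; CP, CFPP to one decimal; density to two decimals.  The engine
#' functions themselves never round.
#'
#' @param props A `biodiesel_properties` object.
#' @return Named list of rounded values.
#' @export
round_for_report <- function(props) {
  stopifnot(inherits(props, "biodiesel_properties"))
  list(cn = round(props$cn), sv = round(props$sv), iv = round(props$iv),
       du = round(props$du), cp = round(props$cp, 1),
       cfpp = round(props$cfpp, 1), cfpp_full = round(props$cfpp_full, 1),
       hhv = round(props$hhv), density = round(props$density, 2))
}

#' Built-in fuel standard specifications
#'
#' `"en14214"` carries the EN 14214 thresholds: CN strictly greater than 51,
#' IV at most 120 g I2/100 g, density within 0.86-0.90 g/cm3.  `"astm_d6751"`
#' carries the ASTM D6751 saponification-value ceiling of 370 mg KOH/g.
#'
#' @param name `"en14214"` or `"astm_d6751"`.
#' @return A `standard_spec` object: list with `name`, `cn_min` (strict),
#'   `iv_max`, `sv_max`, `density_range` (fields `NA` where the standard sets
#'   no limit).
#' @export
biodiesel_standard <- function(name = c("en14214", "astm_d6751")) {
  name <- match.arg(name)
  spec <- switch(name,
    en14214 = list(name = "EN 14214", cn_min = 51, iv_max = 120,
                   sv_max = NA_real_, density_range = c(0.86, 0.90)),
    astm_d6751 = list(name = "ASTM D6751", cn_min = NA_real_,
                      iv_max = NA_real_, sv_max = 370,
                      density_range = c(NA_real_, NA_real_)))
  structure(spec, class = "standard_spec")
}

#' Check predicted properties against a fuel standard
#'
#' CN passes on a strict `>` comparison (a CN of exactly 51 fails EN 14214's
#' ">51"); IV and SV ceilings are non-strict (`<=`); density must lie within
#' the closed range.  Properties the standard does not limit are reported as
#' `not_assessed`.  Margins are signed distances to the binding threshold
#' (positive = inside the limit).
#'
#' @param props A `biodiesel_properties` object.
#' @param standard A `standard_spec`, or a name accepted by
#'   [biodiesel_standard()].
#' @return A `compliance_report`: data frame with columns `property`,
#'   `value`, `requirement`, `verdict` (`pass`/`fail`/`not_assessed`) and
#'   `margin`, with the standard name attached as an attribute.
#' @export
check_standard <- function(props, standard = "en14214") {
  stopifnot(inherits(props, "biodiesel_properties"))
  if (is.character(standard)) standard <- biodiesel_standard(standard)
  stopifnot(inherits(standard, "standard_spec"))
  rows <- list()
  add <- function(property, value, requirement, verdict, margin) {
    rows[[length(rows) + 1L]] <<- data.frame(
      property = property, value = value, requirement = requirement,
      verdict = verdict, margin = margin, stringsAsFactors = FALSE)
  }
  if (!is.na(standard$cn_min)) {
    add("cn", props$cn, sprintf("> %g", standard$cn_min),
        if (props$cn > standard$cn_min) "pass" else "fail",
        props$cn - standard$cn_min)
  } else add("cn", props$cn, "", "not_assessed", NA_real_)
  if (!is.na(standard$iv_max)) {
    add("iv", props$iv, sprintf("<= %g", standard$iv_max),
        if (props$iv <= standard$iv_max) "pass" else "fail",
        standard$iv_max - props$iv)
  } else add("iv", props$iv, "", "not_assessed", NA_real_)
  if (!is.na(standard$sv_max)) {
    add("sv", props$sv, sprintf("<= %g", standard$sv_max),
        if (props$sv <= standard$sv_max) "pass" else "fail",
        standard$sv_max - props$sv)
  } else add("sv", props$sv, "", "not_assessed", NA_real_)
  if (!anyNA(standard$density_range)) {
    lo <- standard$density_range[1]; hi <- standard$density_range[2]
    add("density", props$density, sprintf("[%g, %g]", lo, hi),
        if (props$density >= lo && props$density <= hi) "pass" else "fail",
        min(props$density - lo, hi - props$density))
  } else add("density", props$density, "", "not_assessed", NA_real_)
  for (p in c("du", "cp", "cfpp", "hhv")) {
    add(p, props[[p]], "", "not_assessed", NA_real_)
  }
  report <- do.call(rbind, rows)
  attr(report, "standard") <- standard$name
  class(report) <- c("compliance_report", "data.frame")
  report
}
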