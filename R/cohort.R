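#' Organic acids measured in stool samples
#'
#' The seven fecal organic acids quantified by the capillary-electrophoresis
#' assay: four straight-chain SCFAs (acetic, propionic, butyric, valeric),
#' two branched-chain acids (isobutyric, isovaleric), and phosphoric acid.
#'
#' @return Character vector of acid names.
#' @export
acid_names <- function() {
  c("acetic", "propionic", "butyric", "isobutyric",
    "valeric", "isovaleric", "phosphoric")
}

#' Food-frequency product groups
#'
#' Product groups retained from the food frequency questionnaire (FFQ):
#' fresh vegetables and fruits, dried fruits, whole-grain products, legumes,
#' alcohol, and dairy.  Consumption is recorded on a four-point scale:
#' `daily` (several times a day), `weekly`, `monthly`, `none`.
#'
#' @return Character vector of product-group names.
#' @export
ffq_products <- function() {
  c("fresh_veg_fruit", "dried_fruits", "whole_grain",
    "legumes", "alcohol", "dairy")
}

ffq_levels <- function() c("daily", "weekly", "monthly", "none")

med_flags <- function() {
  c("steroids", "antibiotics", "immunosuppressants",
    "asa5", "anti_tnf", "other_meds")
}

diet_types <- function() {
  c("standard", "easily_digestible", "low_fiber", "high_fiber", "other")
}

#' Detection limits for the acid assay
#'
#' Limits of quantification (LOQ) and detection (LOD) in ug/g dry mass.
#' The LOD is defined as one third of the LOQ; `max_rsd` is the maximal
#' relative standard deviation of repeated measurements accepted by the
#' assay (precision bound).
#'
#' @param loq Limit of quantification in ug/g dry mass (default 26).
#' @param lod Limit of detection in ug/g; `NULL` (default) sets `loq / 3`.
#' @param max_rsd Maximal accepted RSD as a fraction (default 0.15).
#' @return An object of class `detection_limits`.
#' @examples
#' detection_limits()
#' @export
detection_limits <- function(loq = 26, lod = NULL, max_rsd = 0.15) {
  if (!is.numeric(loq) || length(loq) != 1L || loq <= 0)
    stop("`loq` must be a single positive number", call. = FALSE)
  if (is.null(lod)) lod <- loq / 3
  if (!is.numeric(lod) || length(lod) != 1L || lod <= 0)
    stop("`lod` must be a single positive number", call. = FALSE)
  if (abs(lod - loq / 3) > 1e-8 * loq)
    stop("`lod` must equal `loq` / 3", call. = FALSE)
  if (!is.numeric(max_rsd) || max_rsd <= 0 || max_rsd >= 1)
    stop("`max_rsd` must lie in (0, 1)", call. = FALSE)
  structure(list(loq = loq, lod = lod, max_rsd = max_rsd),
            class = "detection_limits")
}

#' Body-mass index from weight and height
#'
#' @param weight_kg Body weight in kilograms (positive).
#' @param height_m Height in metres (positive).
#' @return BMI in kg/m^2, `weight_kg / height_m^2`.  Vectorised.
#' @examples
#' compute_bmi(70, 1.80)  # 21.6 kg/m^2
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("`weight_kg` must be positive", call. = FALSE)
  if (any(!is.finite(height_m)) || any(height_m <= 0))
    stop("`height_m` must be positive", call. = FALSE)
  weight_kg / height_m^2
}

#' BMI category
#'
#' Classifies BMI into `underweight` (< 18.5 kg/m^2), `normal`
#' (18.5–24.99 kg/m^2, both bounds included) and `excessive`
#' (> 24.99 kg/m^2).
#'
#' @param bmi BMI in kg/m^2 (positive). Vectorised; `NA` passes through.
#' @return Factor with levels `underweight`, `normal`, `excessive`.
#' @examples
#' categorize_bmi(c(13.8, 18.5, 24.99, 37.1))
#' @export
categorize_bmi <- function(bmi) {
  bad <- !is.na(bmi) & (!is.finite(bmi) | bmi <= 0)
  if (any(bad)) stop("`bmi` must be positive", call. = FALSE)
  out <- ifelse(is.na(bmi), NA_character_,
                ifelse(bmi < 18.5, "underweight",
                       ifelse(bmi <= 24.99, "normal", "excessive")))
  factor(out, levels = c("underweight", "normal", "excessive"))
}

#' Weight-change category over the preceding six months
#'
#' More than 5% loss of current body weight is `loss`, more than 5% gain is
#' `gain`; changes of up to 5% in either direction (bounds included) are
#' `stable`.
#'
#' @param pct Signed percent change. Vectorised; `NA` passes through.
#' @return Factor with levels `loss`, `stable`, `gain`.
#' @examples
#' categorize_weight_change(c(-6, 0, 5, 5.1))
#' @export
categorize_weight_change <- function(pct) {
  out <- ifelse(is.na(pct), NA_character_,
                ifelse(pct < -5, "loss", ifelse(pct > 5, "gain", "stable")))
  factor(out, levels = c("loss", "stable", "gain"))
}

#' Fiber-consumption category
#'
#' Assigns subjects to low-, normal- or high-fiber consumption.  By default
#' the category follows the declared diet type: low-fiber and
#' easily-digestible diets map to `low`, a high-fiber diet maps to `high`,
#' a standard (and `other`) diet maps to `normal`.  A numeric daily fiber
#' intake, when available, overrides the diet-type rule: < 25 g/day is
#' `low`, > 30 g/day is `high`, otherwise `normal`.
#'
#' @param diet_type One of `r paste(diet_types(), collapse = ", ")`.
#'   Vectorised.
#' @param fiber_g_day Optional numeric intake in g/day (same length or
#'   `NULL`).
#' @return Factor with levels `low`, `normal`, `high`.
#' @examples
#' categorize_fiber(c("low_fiber", "standard", "high_fiber"))
#' categorize_fiber("standard", fiber_g_day = 24.9)  # low
#' @export
categorize_fiber <- function(diet_type, fiber_g_day = NULL) {
  ok <- is.na(diet_type) | diet_type %in% diet_types()
  if (!all(ok))
    stop("unknown diet type: ",
         paste(unique(diet_type[!ok]), collapse = ", "), call. = FALSE)
  out <- ifelse(is.na(diet_type), NA_character_,
         ifelse(diet_type %in% c("low_fiber", "easily_digestible"), "low",
         ifelse(diet_type == "high_fiber", "high", "normal")))
  if (!is.null(fiber_g_day)) {
    num <- !is.na(fiber_g_day)
    out[num] <- ifelse(fiber_g_day[num] < 25, "low",
                       ifelse(fiber_g_day[num] > 30, "high", "normal"))
  }
  factor(out, levels = c("low", "normal", "high"))
}

#' Apply detection-limit censoring to a measured concentration
#'
#' Concentrations at or above the LOQ are returned as-is.  Values between
#' the LOD and the LOQ are retained (they still inform a median split) but
#' flagged `below_loq`.  Values below the LOD are replaced by `lod / 2`
#' (a standard substitution in analytical chemistry) and flagged
#' `below_lod`.
#'
#' @param raw Measured concentration in ug/g dry mass (non-negative).
#'   Vectorised.
#' @param limits A [detection_limits()] object.
#' @return Numeric vector of working values with attribute `censoring`, a
#'   factor with levels `none`, `below_loq`, `below_lod`.
#' @examples
#' censor_concentration(c(100, 10, 5), detection_limits(loq = 26))
#' @export
censor_concentration <- function(raw, limits = detection_limits()) {
  stopifnot(inherits(limits, "detection_limits"))
  if (any(!is.na(raw) & raw < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  flag <- ifelse(is.na(raw), NA_character_,
          ifelse(raw >= limits$loq, "none",
          ifelse(raw >= limits$lod, "below_loq", "below_lod")))
  val <- ifelse(!is.na(flag) & flag == "below_lod", limits$lod / 2, raw)
  structure(val,
            censoring = factor(flag, levels = c("none", "below_loq",
                                                "below_lod")))
}

#' Convert an extract concentration to dry-mass units
#'
#' The assay calibrates in ug/mL of stool extract; reported values are per
#' gram of dried sample: `conc_extract * extract_volume / sample_mass`.
#' With the default 1.0 mL extract volume, the lowest calibration standard
#' (7.8 ug/mL) over a 0.3 g sample gives the 26 ug/g quantification limit.
#'
#' @param conc_extract Concentration in the extract, ug/mL (positive).
#' @param extract_volume Extract volume in mL (positive, default 1.0).
#' @param sample_mass Dried sample mass in g (positive, default 0.3).
#' @return Concentration in ug/g dry mass.  Vectorised.
#' @examples
#' extract_to_dry_mass(7.8, 1.0, 0.3)  # 26
#' @export
extract_to_dry_mass <- function(conc_extract, extract_volume = 1.0,
                                sample_mass = 0.3) {
  for (v in list(conc_extract, extract_volume, sample_mass))
    if (any(!is.finite(v)) || any(v <= 0))
      stop("all inputs must be positive", call. = FALSE)
  conc_extract * extract_volume / sample_mass
}

acid_cols <- function() paste0("acid_", acid_names(), "_ugg")
ffq_cols <- function() paste0("ffq_", ffq_products())

#' Validate a subject-level cohort table
#'
#' Checks that a data frame has the expected subject-level layout: one row
#' per participant with identifier, group, sex, age, BMI, optional
#' weight-change percent, medication flags, diet type, FFQ columns
#' (`ffq_<product>`) and acid columns (`acid_<name>_ugg`).  Adults are
#' expected; ages below 18 raise a warning, not an error.
#'
#' @param records A data frame of subjects.
#' @return The validated data frame, invisibly.
#' @export
validate_cohort <- function(records) {
  req <- c("id", "group", "sex", "age", "bmi", "diet_type",
           med_flags(), ffq_cols(), acid_cols())
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("cohort table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(records$group %in% c("UC", "CD", "control")))
    stop("`group` must be one of UC, CD, control", call. = FALSE)
  if (!all(records$sex %in% c("male", "female")))
    stop("`sex` must be male or female", call. = FALSE)
  if (any(!is.na(records$bmi) & records$bmi <= 0))
    stop("`bmi` must be positive", call. = FALSE)
  if (any(!is.na(records$age) & records$age < 18))
    warning("cohort contains subjects younger than 18 years",
            call. = FALSE)
  bad_diet <- !is.na(records$diet_type) &
    !records$diet_type %in% diet_types()
  if (any(bad_diet))
    stop("unknown diet type: ",
         paste(unique(records$diet_type[bad_diet]), collapse = ", "),
         call. = FALSE)
  for (cc in ffq_cols()) {
    bad <- !is.na(records[[cc]]) & !records[[cc]] %in% ffq_levels()
    if (any(bad))
      stop("column ", cc, " has values outside ",
           paste(ffq_levels(), collapse = "/"), call. = FALSE)
  }
  for (cc in acid_cols())
    if (any(!is.na(records[[cc]]) & records[[cc]] < 0))
      stop("column ", cc, " has negative concentrations", call. = FALSE)
  invisible(records)
}

#' Write a cohort table to CSV
#'
#' Numeric columns are serialised at full double precision so that a
#' write/read round trip reproduces the records exactly.
#'
#' @param records Subject data frame (see [validate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(records, path) {
  out <- records
  for (nm in names(out))
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA_character_,
                          sprintf("%.17g", out[[nm]]))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV produced by [write_cohort()] or following the same
#'   layout; empty cells are missing values.
#' @param validate Run [validate_cohort()] on the result (default `TRUE`).
#' @return Subject data frame.
#' @export
read_cohort <- function(path, validate = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (nrow(df)) {
    for (nm in intersect(c("age", "bmi", "weight_change_pct", acid_cols()),
                         names(df)))
      df[[nm]] <- as.numeric(df[[nm]])
    for (nm in intersect(med_flags(), names(df)))
      df[[nm]] <- as.logical(df[[nm]])
    df$id <- as.character(df$id)
  }
  if (validate && nrow(df)) validate_cohort(df)
  df
}
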