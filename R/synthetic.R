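#' Specification of a synthetic IBD cohort
#'
#' Describes the joint structure used by [generate_cohort()]: group sizes
#' (ulcerative colitis, Crohn disease, controls), per-group log-normal BMI
#' and age distributions (clipped to the observed cohort ranges),
#' log-normal fecal acid baselines whose medians default to the study's
#' reported cohort medians, categorical marginals for sex, diet type,
#' medications and FFQ consumption, and a list of planted multiplicative
#' BMI-category effects on acid concentrations.
#'
#' The default plant mirrors the reported BMI/acid association pattern:
#' underweight subjects draw butyric, propionic and isovaleric
#' concentrations multiplied by 0.5; excessive-weight subjects draw
#' isobutyric multiplied by 2.0.  With `calibrate_medians = TRUE`
#' (default) each acid's baseline median is adjusted analytically so that
#' the cohort-wide mixture median still equals the configured median
#' despite the plant (the analysis is median-split-based, so medians, not
#' means, are held fixed).
#'
#' @param n_uc,n_cd,n_control Group sizes (defaults 43, 18, 16).
#' @param bmi_median,bmi_sdlog Per-group BMI log-normal parameters
#'   (medians in kg/m^2), names UC/CD/control.
#' @param bmi_range BMI truncation range in kg/m^2.
#' @param age_median,age_sdlog,age_range Per-group age distribution
#'   (years).
#' @param acid_medians Named vector of configured acid medians in ug/g dry
#'   mass.
#' @param acid_sdlog Log-scale SD shared by all acids (default 0.6).
#' @param effects Data frame with columns `category` (a BMI category),
#'   `acid`, `factor` (positive multiplier); `NULL` disables all plants.
#' @param null_effects Convenience flag: `TRUE` replaces all effect
#'   factors by 1 (the no-association null).
#' @param prob_male,diet_probs,med_probs,ffq_probs Categorical marginals;
#'   see defaults in the function body.
#' @param weight_change_sd SD of the 6-month weight-change percent.
#' @param dependencies Optional data frame (`category`, `field`, `prob`)
#'   overriding a medication-flag probability within a BMI category,
#'   e.g. a higher steroid probability among underweight subjects.
#' @param calibrate_medians Keep cohort acid medians at their configured
#'   values under planted effects (default `TRUE`).
#' @return An object of class `cohort_spec`.
#' @examples
#' sp <- cohort_spec()
#' sp$n
#' @export
cohort_spec <- function(n_uc = 43L, n_cd = 18L, n_control = 16L,
                        bmi_median = c(UC = 21.6, CD = 20.2,
                                       control = 21.6),
                        bmi_sdlog = c(UC = 0.18, CD = 0.16,
                                      control = 0.15),
                        bmi_range = c(13.8, 37.1),
                        age_median = c(UC = 32, CD = 30, control = 23.5),
                        age_sdlog = c(UC = 0.30, CD = 0.20,
                                      control = 0.35),
                        age_range = c(18, 77),
                        acid_medians = c(acetic = 1135.3,
                                         propionic = 381.2,
                                         butyric = 215.0,
                                         isobutyric = 43.0,
                                         valeric = 5.52,
                                         isovaleric = 46.3,
                                         phosphoric = 837.6),
                        acid_sdlog = 0.6,
                        effects = default_effects(),
                        null_effects = FALSE,
                        prob_male = c(UC = 29 / 43, CD = 10 / 18,
                                      control = 3 / 16),
                        diet_probs = NULL, med_probs = NULL,
                        ffq_probs = NULL,
                        weight_change_sd = 4,
                        dependencies = NULL,
                        calibrate_medians = TRUE) {
  if (any(c(n_uc, n_cd, n_control) < 1L))
    stop("group sizes must be at least 1", call. = FALSE)
  if (is.null(diet_probs)) {
    diet_probs <- rbind(
      UC      = c(0.372, 0.260, 0.280, 0.020, 0.068),
      CD      = c(0.440, 0.220, 0.220, 0.060, 0.060),
      control = c(0.6875, 0.000, 0.0625, 0.125, 0.125))
    colnames(diet_probs) <- diet_types()
  }
  if (is.null(med_probs)) {
    med_probs <- rbind(
      UC      = c(28, 19, 20, 56, 12, 21) / 61,
      CD      = c(28, 19, 20, 56, 12, 21) / 61,
      control = c(0.02, 0.10, 0.01, 0.02, 0.01, 0.30))
    colnames(med_probs) <- med_flags()
  }
  if (is.null(ffq_probs)) {
    ffq_probs <- rbind(
      fresh_veg_fruit = c(0.45, 0.40, 0.10, 0.05),
      dried_fruits    = c(0.05, 0.20, 0.40, 0.35),
      whole_grain     = c(0.30, 0.35, 0.20, 0.15),
      legumes         = c(0.03, 0.25, 0.45, 0.27),
      alcohol         = c(0.02, 0.18, 0.35, 0.45),
      dairy           = c(0.50, 0.30, 0.12, 0.08))
    colnames(ffq_probs) <- ffq_levels()
  }
  if (is.null(effects))
    effects <- data.frame(category = character(), acid = character(),
                          factor = numeric())
  if (null_effects && nrow(effects)) effects$factor <- 1
  if (nrow(effects) && any(effects$factor <= 0))
    stop("effect factors must be positive", call. = FALSE)
  if (nrow(effects) && !all(effects$acid %in% acid_names()))
    stop("unknown acid in `effects`", call. = FALSE)
  structure(list(n = c(UC = as.integer(n_uc), CD = as.integer(n_cd),
                       control = as.integer(n_control)),
                 bmi_median = bmi_median, bmi_sdlog = bmi_sdlog,
                 bmi_range = bmi_range,
                 age_median = age_median, age_sdlog = age_sdlog,
                 age_range = age_range,
                 acid_medians = acid_medians, acid_sdlog = acid_sdlog,
                 effects = effects, prob_male = prob_male,
                 diet_probs = diet_probs, med_probs = med_probs,
                 ffq_probs = ffq_probs,
                 weight_change_sd = weight_change_sd,
                 dependencies = dependencies,
                 calibrate_medians = calibrate_medians),
            class = "cohort_spec")
}

#' Default planted effects
#'
#' Underweight subjects: butyric, propionic and isovaleric acid multiplied
#' by 0.5.  Excessive-weight subjects: isobutyric acid multiplied by 2.0.
#'
#' @return Data frame with columns `category`, `acid`, `factor`.
#' @export
default_effects <- function() {
  data.frame(
    category = c("underweight", "underweight", "underweight",
                 "excessive"),
    acid = c("butyric", "propionic", "isovaleric", "isobutyric"),
    factor = c(0.5, 0.5, 0.5, 2.0),
    stringsAsFactors = FALSE)
}

# analytic BMI-category probabilities per group under the (untruncated)
# log-normal BMI model; truncation at the cohort range is negligible here
bmi_category_probs <- function(spec) {
  out <- sapply(names(spec$n), function(g) {
    mu <- log(spec$bmi_median[[g]]); s <- spec$bmi_sdlog[[g]]
    p_u <- pnorm((log(18.5) - mu) / s)
    p_e <- 1 - pnorm((log(24.99) - mu) / s)
    c(underweight = p_u, normal = 1 - p_u - p_e, excessive = p_e)
  })
  t(out)  # groups x categories
}

# baseline median m0 such that the cohort-wide mixture median equals the
# configured median M under the planted multiplicative effects
calibrated_baseline <- function(spec, acid) {
  M <- spec$acid_medians[[acid]]
  eff <- spec$effects[spec$effects$acid == acid, , drop = FALSE]
  if (!spec$calibrate_medians || nrow(eff) == 0 ||
      all(eff$factor == 1)) return(M)
  pg <- bmi_category_probs(spec)
  w <- colSums(pg * (spec$n / sum(spec$n)))  # category weights
  fac <- setNames(rep(1, 3), colnames(pg))
  fac[eff$category] <- eff$factor
  s <- spec$acid_sdlog
  g <- function(logm0)
    sum(w * pnorm((log(M) - logm0 - log(fac)) / s)) - 0.5
  exp(uniroot(g, interval = log(c(M / 8, M * 8)), tol = 1e-10)$root)
}

rtrunc_lnorm <- function(n, median, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, meanlog = log(median), sdlog = sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

sample_levels <- function(n, levels, probs) {
  levels[1L + findInterval(runif(n), cumsum(probs) / sum(probs))]
}

#' Generate a synthetic subject-level cohort
#'
#' Draws `sum(spec$n)` subject records with the structure described by a
#' [cohort_spec()]: per-group BMI and age (truncated log-normal), sex,
#' weight-change percent, medication flags, diet type, FFQ consumption
#' categories, and the seven fecal acid concentrations with planted
#' BMI-category effects.  Output is deterministic for a fixed `seed`.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed for the random generator (`NULL` leaves the
#'   RNG state untouched).
#' @return Subject data frame passing [validate_cohort()].
#' @examples
#' rec <- generate_cohort(cohort_spec(), seed = 1)
#' nrow(rec)       # 77
#' table(rec$group)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  groups <- rep(names(spec$n), times = spec$n)
  n <- length(groups)

  bmi <- numeric(n); age <- numeric(n); sex <- character(n)
  for (g in names(spec$n)) {
    idx <- groups == g
    bmi[idx] <- rtrunc_lnorm(sum(idx), spec$bmi_median[[g]],
                             spec$bmi_sdlog[[g]], spec$bmi_range)
    age[idx] <- round(rtrunc_lnorm(sum(idx), spec$age_median[[g]],
                                   spec$age_sdlog[[g]], spec$age_range),
                      1)
    sex[idx] <- ifelse(runif(sum(idx)) < spec$prob_male[[g]],
                       "male", "female")
  }
  bmi_cat <- as.character(categorize_bmi(bmi))
  weight_change <- round(rnorm(n, 0, spec$weight_change_sd), 2)

  meds <- matrix(NA, n, length(med_flags()),
                 dimnames = list(NULL, med_flags()))
  for (flag in med_flags()) {
    p <- spec$med_probs[groups, flag]
    if (!is.null(spec$dependencies)) {
      dep <- spec$dependencies
      dep <- dep[dep$field == flag, , drop = FALSE]
      for (i in seq_len(nrow(dep)))
        p[bmi_cat == dep$category[i]] <- dep$prob[i]
    }
    meds[, flag] <- runif(n) < p
  }

  diet <- character(n)
  for (g in names(spec$n)) {
    idx <- groups == g
    diet[idx] <- sample_levels(sum(idx), colnames(spec$diet_probs),
                               spec$diet_probs[g, ])
  }

  ffq <- matrix(NA_character_, n, length(ffq_products()),
                dimnames = list(NULL, ffq_cols()))
  for (pr in ffq_products())
    ffq[, paste0("ffq_", pr)] <-
      sample_levels(n, ffq_levels(), spec$ffq_probs[pr, ])

  acids <- matrix(NA_real_, n, length(acid_names()),
                  dimnames = list(NULL, acid_cols()))
  for (ac in acid_names()) {
    m0 <- calibrated_baseline(spec, ac)
    fac <- rep(1, n)
    eff <- spec$effects[spec$effects$acid == ac, , drop = FALSE]
    for (i in seq_len(nrow(eff)))
      fac[bmi_cat == eff$category[i]] <- eff$factor[i]
    acids[, paste0("acid_", ac, "_ugg")] <-
      round(rlnorm(n, meanlog = log(m0) + log(fac),
                   sdlog = spec$acid_sdlog), 4)
  }

  df <- data.frame(id = sprintf("S%03d", seq_len(n)),
                   group = groups, sex = sex,
                   age = age, bmi = round(bmi, 2),
                   weight_change_pct = weight_change,
                   diet_type = diet,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(meds), as.data.frame(ffq),
              as.data.frame(acids))
  validate_cohort(df)
  df
}
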