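#' Default parameter set for encoding
#'
#' The variable set entered into the correspondence analysis: subject age,
#' BMI category, weight-change category, diet type, three medication flags
#' (steroids, antibiotics, other medications), three FFQ product groups
#' (alcohol, whole-grain products, legumes), and the seven fecal acids.
#' Continuous parameters (age, acids) are median-split; the rest are
#' categorical.
#'
#' @return Character vector of parameter names understood by
#'   [encode_cohort()].
#' @export
default_parameters <- function() {
  c("age", "bmi_category", "weight_change_category", "diet_type",
    "steroids", "antibiotics", "other_meds",
    "ffq_alcohol", "ffq_whole_grain", "ffq_legumes",
    paste0("acid_", acid_names()))
}

#' Median dichotomization of a continuous parameter
#'
#' Splits values at the sample median (mean of the two middle order
#' statistics for even n).  A value is `above` iff it exceeds the median;
#' values equal to the median go to `under` (default tie rule), so the
#' `above` group is strictly above the median.
#'
#' @param values Numeric vector with at least two non-missing entries.
#' @param tie_rule `"under"` (default) sends ties at the median to `under`;
#'   `"above"` sends them to `above`.
#' @return List with `median` (numeric) and `labels` (factor with levels
#'   `under`, `above`; `NA` where the input is missing).
#' @examples
#' median_split(c(1, 2, 3, 4))
#' @export
median_split <- function(values, tie_rule = c("under", "above")) {
  tie_rule <- match.arg(tie_rule)
  obs <- values[!is.na(values)]
  if (length(obs) < 2L)
    stop("median split needs at least two non-missing values",
         call. = FALSE)
  m <- median(obs)
  lab <- if (tie_rule == "under") {
    ifelse(values > m, "above", "under")
  } else {
    ifelse(values >= m, "above", "under")
  }
  lab[is.na(values)] <- NA
  list(median = m,
       labels = factor(lab, levels = c("under", "above")))
}

# Resolve a parameter name to its per-subject values: a numeric vector
# (median-split parameter) or a factor (categorical parameter).
parameter_values <- function(records, name) {
  if (name == "age") return(records$age)
  if (grepl("^acid_", name)) {
    col <- paste0(name, "_ugg")
    if (!col %in% names(records))
      stop("parameter `", name, "` not found in records", call. = FALSE)
    return(records[[col]])
  }
  switch(name,
    bmi_category = categorize_bmi(records$bmi),
    weight_change_category = {
      if (!"weight_change_pct" %in% names(records))
        stop("parameter `weight_change_category` needs weight_change_pct",
             call. = FALSE)
      categorize_weight_change(records$weight_change_pct)
    },
    fiber_category = categorize_fiber(records$diet_type),
    diet_type = factor(records$diet_type, levels = diet_types()),
    group = factor(records$group, levels = c("UC", "CD", "control")),
    sex = factor(records$sex, levels = c("male", "female")),
    {
      if (name %in% med_flags()) {
        factor(ifelse(records[[name]], "yes", "no"),
               levels = c("no", "yes"))
      } else if (name %in% ffq_cols()) {
        factor(records[[name]], levels = ffq_levels())
      } else if (name %in% names(records)) {
        v <- records[[name]]
        if (is.numeric(v)) v else factor(v)
      } else {
        stop("parameter `", name, "` not found in records", call. = FALSE)
      }
    })
}

#' Encode a cohort into a subjects-by-levels indicator table
#'
#' Transforms subject records into the binary/categorical parameter space
#' consumed by the correspondence analysis: continuous parameters are
#' dichotomized at their cohort medians ([median_split()]); categorical
#' parameters are expanded into one 0/1 column per level.  Levels observed
#' in no subject are dropped (recorded in the scheme and reported via
#' `message()`).  A subject missing a parameter gets all-zero cells for
#' that parameter.
#'
#' @param records Subject data frame (see [validate_cohort()]).
#' @param parameters Character vector of parameter names
#'   (default [default_parameters()]).
#' @param tie_rule Tie rule for median splits, see [median_split()].
#' @param quiet Suppress messages about dropped levels and missing values.
#' @return An object of class `indicator_table`: list with `X` (0/1 matrix,
#'   subjects x levels, column names `parameter=level`), `param` and
#'   `level` (character vectors mapping columns), and `scheme` (a
#'   `category_scheme` holding per-parameter kind, levels and realized
#'   medians).
#' @examples
#' rec <- generate_cohort(cohort_spec(), seed = 1)
#' tab <- encode_cohort(rec)
#' dim(tab$X)
#' @export
encode_cohort <- function(records, parameters = default_parameters(),
                          tie_rule = c("under", "above"), quiet = FALSE) {
  tie_rule <- match.arg(tie_rule)
  if (nrow(records) < 2L)
    stop("need at least two records to encode", call. = FALSE)
  note <- if (quiet) function(...) invisible() else message

  cols <- list(); par_of <- character(); lev_of <- character()
  scheme <- list()
  for (p in parameters) {
    v <- parameter_values(records, p)
    if (is.numeric(v)) {
      sp <- median_split(v, tie_rule)
      f <- sp$labels
      entry <- list(name = p, kind = "median_split",
                    levels = levels(f), median = sp$median)
    } else {
      f <- v
      entry <- list(name = p, kind = "categorical",
                    levels = levels(f), median = NULL)
    }
    counts <- table(f)
    empty <- names(counts)[counts == 0L]
    if (length(empty)) {
      note("parameter `", p, "`: dropping empty level(s) ",
           paste(empty, collapse = ", "))
      f <- factor(f, levels = setdiff(levels(f), empty))
      entry$levels <- levels(f)
    }
    entry$dropped_levels <- empty
    entry$n_missing <- sum(is.na(f))
    if (entry$n_missing > 0)
      note("parameter `", p, "`: ", entry$n_missing,
           " missing value(s) encoded as all-zero cells")
    if (length(levels(f)) < 2L)
      stop("parameter `", p, "` has fewer than two observed levels",
           call. = FALSE)
    for (lv in levels(f)) {
      cols[[length(cols) + 1L]] <- as.integer(!is.na(f) & f == lv)
      par_of <- c(par_of, p)
      lev_of <- c(lev_of, lv)
    }
    scheme[[p]] <- entry
  }
  X <- do.call(cbind, cols)
  rownames(X) <- if ("id" %in% names(records))
    as.character(records$id) else as.character(seq_len(nrow(records)))
  colnames(X) <- paste0(par_of, "=", lev_of)
  structure(list(X = X, param = par_of, level = lev_of,
                 scheme = structure(list(parameters = scheme,
                                         tie_rule = tie_rule),
                                    class = "category_scheme")),
            class = "indicator_table")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("Category scheme:", length(x$parameters), "parameters\n")
  for (e in x$parameters) {
    if (e$kind == "median_split") {
      cat(sprintf("  %-24s median split at %.4g (under/above)\n",
                  e$name, e$median))
    } else {
      cat(sprintf("  %-24s categorical: %s\n", e$name,
                  paste(e$levels, collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
print.indicator_table <- function(x, ...) {
  cat("Indicator table:", nrow(x$X), "subjects x", ncol(x$X),
      "levels (", length(unique(x$param)), "parameters )\n")
  invisible(x)
}

#' Burt table of an indicator table
#'
#' The symmetric levels-by-levels cross-tabulation `t(X) %*% X`.
#' Correspondence analysis of the Burt table yields the same standard
#' column coordinates as the indicator table, with singular values equal
#' to the squares of the indicator-table singular values.
#'
#' @param tab An `indicator_table`.
#' @return An object of class `burt_table` (list with `B`, `param`,
#'   `level`, `scheme`).
#' @export
burt_table <- function(tab) {
  stopifnot(inherits(tab, "indicator_table"))
  B <- crossprod(tab$X)
  structure(list(B = B, param = tab$param, level = tab$level,
                 scheme = tab$scheme), class = "burt_table")
}

#' Remove parameters from an indicator table
#'
#' @param tab An `indicator_table`.
#' @param drop Character vector of parameter names to remove.
#' @return The reduced `indicator_table`.
#' @export
drop_parameters <- function(tab, drop) {
  stopifnot(inherits(tab, "indicator_table"))
  keep <- !(tab$param %in% drop)
  if (!any(keep)) stop("cannot drop all parameters", call. = FALSE)
  sc <- tab$scheme
  sc$parameters <- sc$parameters[setdiff(names(sc$parameters), drop)]
  structure(list(X = tab$X[, keep, drop = FALSE],
                 param = tab$param[keep], level = tab$level[keep],
                 scheme = sc),
            class = "indicator_table")
}

#' Write an encoded table to TSV with a JSON scheme side-car
#'
#' @param tab An `indicator_table`.
#' @param path Output TSV path; the scheme is written to
#'   `paste0(path, ".scheme.json")`.
#' @return `path`, invisibly.
#' @export
write_indicator <- function(tab, path) {
  stopifnot(inherits(tab, "indicator_table"))
  df <- data.frame(id = rownames(tab$X), tab$X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(scheme_to_list(tab$scheme),
                       paste0(path, ".scheme.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

scheme_to_list <- function(scheme) {
  list(tie_rule = scheme$tie_rule,
       parameters = lapply(unname(scheme$parameters), function(e) {
         out <- list(name = e$name, kind = e$kind, levels = e$levels)
         if (!is.null(e$median)) out$median <- e$median
         out$dropped_levels <- e$dropped_levels
         out
       }))
}
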