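#' Default group-contrast list for contingency statistics
#'
#' Contrasts compare two subject groupings (study group versus the rest,
#' or group versus group) on a binary split of a parameter level: the
#' standard-diet contrast of UC versus controls, and the above-median
#' valeric acid contrast of controls versus IBD.
#'
#' @return List of contrast descriptions consumed by
#'   [contingency_contrasts()].
#' @export
default_contrasts <- function() {
  list(
    list(name = "standard_diet_UC_vs_control",
         groups = c("UC", "control"),
         parameter = "diet_type", level = "standard"),
    list(name = "valeric_above_control_vs_IBD",
         groups = list("control", c("UC", "CD")),
         parameter = "acid_valeric", level = "above"),
    list(name = "legumes_weekly_control_vs_IBD",
         groups = list("control", c("UC", "CD")),
         parameter = "ffq_legumes", level = "weekly"),
    list(name = "alcohol_any_control_vs_IBD",
         groups = list("control", c("UC", "CD")),
         parameter = "ffq_alcohol", level = "any"))
}

contrast_indicator <- function(records, parameter, level,
                               tie_rule = "under") {
  v <- parameter_values(records, parameter)
  if (is.numeric(v)) {
    sp <- median_split(v, tie_rule)
    sp$labels == level
  } else if (identical(level, "any")) {
    !is.na(v) & v != "none"
  } else {
    !is.na(v) & v == level
  }
}

#' Contingency statistics for configured group contrasts
#'
#' For each contrast, builds the 2x2 table of group membership against
#' a binary parameter split (a categorical level versus the rest, `"any"`
#' versus `none` for FFQ items, or above/under the cohort median for a
#' continuous parameter) and computes odds ratio, Woolf interval and
#' Fisher exact p via [ct_stats()].
#'
#' @param records Subject data frame.
#' @param contrasts List of contrasts (default [default_contrasts()]);
#'   each a list with `name`, `groups` (two group labels, or a list of
#'   two label vectors), `parameter`, `level`.
#' @return Data frame with one row per contrast: counts, OR, CI bounds,
#'   exact and Woolf p-values.
#' @export
contingency_contrasts <- function(records,
                                  contrasts = default_contrasts()) {
  rows <- lapply(contrasts, function(ct) {
    g <- ct$groups
    g1 <- if (is.list(g)) g[[1]] else g[1]
    g2 <- if (is.list(g)) g[[2]] else g[2]
    in1 <- records$group %in% g1
    in2 <- records$group %in% g2
    pos <- contrast_indicator(records, ct$parameter, ct$level)
    a <- sum(in1 & pos); b <- sum(in1 & !pos)
    cc <- sum(in2 & pos); d <- sum(in2 & !pos)
    st <- ct_stats(a, b, cc, d)
    data.frame(contrast = ct$name,
               groups = paste(paste(g1, collapse = "+"), "vs",
                              paste(g2, collapse = "+")),
               parameter = ct$parameter, level = ct$level,
               a = a, b = b, c = cc, d = d,
               or = st$or, ci_low = st$ci_low, ci_high = st$ci_high,
               p_exact = st$p, p_woolf = st$p_woolf,
               corrected = st$corrected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates encode, select, associate and contingency stages from a
#' configuration, writing six artifacts to `out_dir`: the realized
#' category scheme (`scheme.json`), the final CA model
#' (`ca_model.json`), the selection trace (`selection_trace.json`), the
#' association report (`associations.tsv`), the contingency table
#' (`contingency.tsv`), and a run log (`run_log.txt`).  Outputs are
#' deterministic for a fixed input and configuration.
#'
#' @param input Subject data frame or CSV path.
#' @param config Named list (or YAML path) with optional entries
#'   `parameters`, `threshold`, `min_params`, `cutoff`, `tie_rule`,
#'   `aggregate`, `contrasts`, `seed`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the fitted `scfa_ca` object, the
#'   contingency data frame and the output paths.
#' @export
run_pipeline <- function(input, config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(parameters = default_parameters(), threshold = 0.5,
                   min_params = 4L, cutoff = 0.3, tie_rule = "under",
                   aggregate = "mass_mean", scaling = "benzecri",
                   contrasts = default_contrasts(), seed = NULL)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (!(is.numeric(cfg$threshold) && cfg$threshold > 0 &&
        cfg$threshold <= 1))
    stop("config field `threshold` must lie in (0, 1]", call. = FALSE)
  if (!(is.numeric(cfg$cutoff) && cfg$cutoff > 0))
    stop("config field `cutoff` must be positive", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))

  if (is.character(input) && length(input) == 1L)
    input <- read_cohort(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fit <- scfa_ca(input, parameters = cfg$parameters,
                 threshold = cfg$threshold, min_params = cfg$min_params,
                 cutoff = cfg$cutoff, tie_rule = cfg$tie_rule,
                 aggregate = cfg$aggregate, scaling = cfg$scaling)
  ct <- contingency_contrasts(input, cfg$contrasts)

  paths <- list(
    scheme = file.path(out_dir, "scheme.json"),
    ca_model = file.path(out_dir, "ca_model.json"),
    trace = file.path(out_dir, "selection_trace.json"),
    associations = file.path(out_dir, "associations.tsv"),
    contingency = file.path(out_dir, "contingency.tsv"),
    log = file.path(out_dir, "run_log.txt"))

  jsonlite::write_json(scheme_to_list(fit$scheme), paths$scheme,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_ca_model(fit$model, paths$ca_model)
  jsonlite::write_json(list(threshold = fit$threshold,
                            threshold_met = fit$threshold_met,
                            trace = fit$trace),
                       paths$trace, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_report(fit$associations, paths$associations)
  utils::write.table(ct, paths$contingency, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(c(
    paste("ibdscfa", as.character(utils::packageVersion("ibdscfa"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("subjects:", nrow(input)),
    paste("seed:", if (is.null(cfg$seed)) "none" else cfg$seed),
    paste("threshold:", cfg$threshold, "cutoff:", cfg$cutoff),
    paste("threshold_met:", fit$threshold_met)), paths$log)

  invisible(list(fit = fit, contingency = ct, paths = paths))
}
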