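#' Per-parameter quality of representation
#'
#' Aggregates level-wise cos^2 in the first two dimensions into one score
#' per parameter.  The default aggregate is the column-mass-weighted mean
#' of the parameter's levels (mass weighting matches the CA geometry,
#' where each point contributes mass times squared distance to the
#' inertia); `"max"` takes the best-represented level instead.
#'
#' @param model A `ca_model` fitted to an encoded table (must carry the
#'   `param` column map).
#' @param aggregate `"mass_mean"` (default) or `"max"`.
#' @return Named numeric vector, one score per parameter, in the encoding
#'   order.
#' @export
parameter_quality <- function(model, aggregate = c("mass_mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(model, "ca_model"))
  if (is.null(model$param))
    stop("model does not carry a parameter map; fit it on an encoded table",
         call. = FALSE)
  q <- vapply(seq_along(model$param), function(j)
    as.numeric(quality2(model, j)), numeric(1))
  params <- unique(model$param)
  out <- vapply(params, function(p) {
    idx <- which(model$param == p)
    if (aggregate == "max") max(q[idx])
    else weighted.mean(q[idx], w = model$col_mass[idx])
  }, numeric(1))
  names(out) <- params
  out
}

#' Iterative parameter-discard loop for the CA model
#'
#' Repeatedly fits the correspondence analysis and discards the
#' worst-represented parameter until the first two dimensions explain at
#' least `threshold` of the total inertia.  At each step every parameter's
#' quality is the aggregate of its levels' cos^2 in dimensions 1–2
#' ([parameter_quality()]); the parameter with the lowest quality is
#' removed (ties broken by discarding the later parameter in encoding
#' order) and the model refitted on the reduced table.  The loop also
#' stops, flagged, when only `min_params` parameters remain.
#'
#' @param tab An `indicator_table` from [encode_cohort()].
#' @param threshold Required inertia fraction in the first two dimensions,
#'   in `(0, 1]` (default 0.5).
#' @param min_params Minimal number of parameters to retain (default 4;
#'   below that the two-dimensional map is degenerate).
#' @param aggregate Parameter-quality aggregate, see [parameter_quality()].
#' @param scaling Convention for the inertia share tested against the
#'   threshold, see [inertia_explained()].  The default `"benzecri"` uses
#'   adjusted MCA percentages: the raw indicator shares never approach
#'   50% for more than a handful of parameters, whereas a full
#'   several-parameter model can legitimately satisfy the criterion in
#'   the adjusted convention (the one classic MCA software prints).
#' @param drop `"parameter"` (default) removes whole parameters;
#'   `"level"` removes single levels (a parameter losing all but one level
#'   is then removed entirely).
#' @return List with `model` (the final `ca_model`), `table` (the final
#'   `indicator_table`), `trace` (a data frame with one row per iteration:
#'   parameter count, 2-d inertia fraction, discarded item and its
#'   quality), `threshold_met` (logical), `threshold` and `min_params`.
#'   Class `selection_trace`.
#' @examples
#' rec <- generate_cohort(cohort_spec(), seed = 1)
#' sel <- select_model(encode_cohort(rec, quiet = TRUE))
#' sel$trace
#' @export
select_model <- function(tab, threshold = 0.5, min_params = 4L,
                         aggregate = c("mass_mean", "max"),
                         scaling = c("benzecri", "burt", "indicator"),
                         drop = c("parameter", "level")) {
  aggregate <- match.arg(aggregate)
  scaling <- match.arg(scaling)
  drop <- match.arg(drop)
  stopifnot(inherits(tab, "indicator_table"))
  if (!(threshold > 0 && threshold <= 1))
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  n_params0 <- length(unique(tab$param))
  if (n_params0 < min_params)
    stop("table has fewer than `min_params` parameters", call. = FALSE)

  order0 <- unique(tab$param)
  trace <- list()
  repeat {
    model <- fit_ca(tab)
    n_par <- length(unique(tab$param))
    frac <- inertia_explained(model, 2L, scaling = scaling,
                              n_params = n_par)
    row <- data.frame(n_params = n_par, inertia_2d = frac,
                      discarded = NA_character_, quality = NA_real_,
                      stringsAsFactors = FALSE)
    if (frac >= threshold || n_par <= min_params) {
      trace[[length(trace) + 1L]] <- row
      met <- frac >= threshold
      break
    }
    if (drop == "parameter") {
      q <- parameter_quality(model, aggregate)
      # ties: discard the later parameter in encoding order
      worst <- max(which(q <= min(q) + 0))
      row$discarded <- names(q)[worst]
      row$quality <- q[worst]
      tab <- drop_parameters(tab, names(q)[worst])
    } else {
      q <- vapply(seq_along(model$param), function(j)
        as.numeric(quality2(model, j)), numeric(1))
      worst <- max(which(q <= min(q)))
      row$discarded <- rownames(model$col_coord)[worst]
      row$quality <- q[worst]
      keep <- seq_along(tab$param) != worst
      tab$X <- tab$X[, keep, drop = FALSE]
      tab$param <- tab$param[keep]
      tab$level <- tab$level[keep]
      # a parameter reduced to a single level is uninformative: remove it
      single <- names(which(table(tab$param) < 2L))
      if (length(single)) tab <- drop_parameters(tab, single)
    }
    trace[[length(trace) + 1L]] <- row
  }
  trace <- do.call(rbind, trace)
  trace$iteration <- seq_len(nrow(trace))
  trace <- trace[, c("iteration", "n_params", "inertia_2d",
                     "discarded", "quality")]
  rownames(trace) <- NULL
  structure(list(model = model, table = tab, trace = trace,
                 threshold_met = met, threshold = threshold,
                 min_params = min_params, scaling = scaling,
                 initial_parameters = order0),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  n0 <- length(x$initial_parameters)
  nf <- length(unique(x$table$param))
  cat("Parameter selection:", n0, "->", nf, "parameters in",
      nrow(x$trace), "iteration(s)\n")
  cat(sprintf("Final 2-d inertia fraction: %.3f (threshold %.2f%s)\n",
              x$trace$inertia_2d[nrow(x$trace)], x$threshold,
              if (x$threshold_met) ", met" else ", NOT met"))
  invisible(x)
}
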