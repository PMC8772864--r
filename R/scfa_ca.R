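#' Fit the CA association model to a cohort
#'
#' End-to-end fit: encodes the subject table into a binary/categorical
#' indicator table ([encode_cohort()]), runs the iterative
#' parameter-discard correspondence analysis ([select_model()]) until the
#' first two dimensions explain at least `threshold` of the total
#' inertia, and scores all qualifying level pairs with signed association
#' weights ([build_report()]).
#'
#' @param data Subject data frame (see [validate_cohort()]) or a CSV path
#'   readable by [read_cohort()].
#' @param parameters Parameters to encode (default
#'   [default_parameters()]).
#' @param threshold Inertia fraction required of the first two dimensions
#'   (default 0.5).
#' @param min_params Minimal parameter count retained by the discard loop
#'   (default 4).
#' @param cutoff Coordinate-magnitude cutoff for association
#'   qualification (default 0.3).
#' @param tie_rule Median-split tie rule, see [median_split()].
#' @param aggregate Parameter-quality aggregate, see
#'   [parameter_quality()].
#' @param scaling Inertia-share convention for the stopping rule, see
#'   [select_model()].
#' @param quiet Suppress encoding messages (default `TRUE`).
#' @return An object of class `scfa_ca`: list with `scheme` (realized
#'   category scheme), `table` (final indicator table), `model` (final
#'   `ca_model`), `trace` (selection trace data frame), `threshold_met`,
#'   `associations` (the `association_report`), and `call`.
#' @examples
#' rec <- generate_cohort(cohort_spec(), seed = 1)
#' fit <- scfa_ca(rec)
#' fit
#' head(coef(fit))
#' @export
scfa_ca <- function(data, parameters = default_parameters(),
                    threshold = 0.5, min_params = 4L, cutoff = 0.3,
                    tie_rule = c("under", "above"),
                    aggregate = c("mass_mean", "max"),
                    scaling = c("benzecri", "burt", "indicator"),
                    quiet = TRUE) {
  tie_rule <- match.arg(tie_rule)
  aggregate <- match.arg(aggregate)
  scaling <- match.arg(scaling)
  if (is.character(data) && length(data) == 1L)
    data <- read_cohort(data)
  validate_cohort(data)
  tab <- encode_cohort(data, parameters, tie_rule = tie_rule,
                       quiet = quiet)
  sel <- select_model(tab, threshold = threshold,
                      min_params = min_params, aggregate = aggregate,
                      scaling = scaling)
  rep <- build_report(sel$model, cutoff = cutoff)
  structure(list(scheme = sel$table$scheme, table = sel$table,
                 model = sel$model, trace = sel$trace,
                 threshold_met = sel$threshold_met,
                 threshold = threshold, cutoff = cutoff,
                 scaling = scaling,
                 associations = rep, call = match.call()),
            class = "scfa_ca")
}

#' @export
print.scfa_ca <- function(x, ...) {
  cat("CA association model\n")
  cat("Call: "); print(x$call)
  n0 <- x$trace$n_params[1]; nf <- x$trace$n_params[nrow(x$trace)]
  cat(sprintf("Parameters: %d encoded, %d retained (%d discard iterations)\n",
              n0, nf, nrow(x$trace) - 1L))
  cat(sprintf("First two dimensions: %.1f%% of total inertia (threshold %.0f%%%s)\n",
              100 * x$trace$inertia_2d[nrow(x$trace)],
              100 * x$threshold,
              if (x$threshold_met) "" else ", NOT met"))
  cat(sprintf("Qualifying associations (|coordinate| > %.2g): %d pairs\n",
              x$cutoff, nrow(x$associations)))
  invisible(x)
}

#' @export
summary.scfa_ca <- function(object, n_pairs = 10L, ...) {
  structure(list(fit = object, n_pairs = n_pairs),
            class = "summary.scfa_ca")
}

#' @export
print.summary.scfa_ca <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nRealized medians of split parameters:\n")
  for (e in fit$scheme$parameters)
    if (e$kind == "median_split")
      cat(sprintf("  %-22s %.4g\n", e$name, e$median))
  cat("\nSelection trace:\n")
  print(fit$trace, row.names = FALSE)
  cat("\nStrongest associations:\n")
  a <- utils::head(as.data.frame(fit$associations), x$n_pairs)
  if (nrow(a)) {
    print(data.frame(pair = paste0(a$param_a, "=", a$level_a, " ~ ",
                                   a$param_b, "=", a$level_b),
                     weight = round(a$weight, 2),
                     cosine = round(a$cosine, 2)),
          row.names = FALSE)
  } else cat("  (none)\n")
  invisible(x)
}

#' @export
coef.scfa_ca <- function(object, dims = 2L, ...) {
  co <- object$model$col_coord
  co[, seq_len(min(dims, ncol(co))), drop = FALSE]
}

#' @export
residuals.scfa_ca <- function(object, ...) {
  N <- object$table$X
  P <- N / sum(N)
  r <- rowSums(P); cm <- colSums(P)
  (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
}

#' Plot the CA association plane
#'
#' Draws the column (level) points of the final model in the plane of the
#' first two dimensions, numbered in encoding order with a legend mapping
#' numbers to `parameter=level`, and marks the qualification cutoff.
#'
#' @param x A fitted `scfa_ca` object.
#' @param cutoff Cutoff drawn as dashed lines (defaults to the fit's).
#' @param legend Print the number-to-level legend (default `TRUE`).
#' @param ... Passed to [graphics::points()].
#' @return `x`, invisibly.
#' @export
plot.scfa_ca <- function(x, cutoff = x$cutoff, legend = TRUE, ...) {
  m <- x$model
  if (m$nd < 1L) stop("model has no usable dimensions", call. = FALSE)
  co <- plane_coords(m)
  pct <- 100 * m$inertia[1:2] / m$total_inertia
  lim <- range(co, -cutoff, cutoff) * 1.15
  plot.new(); plot.window(xlim = lim, ylim = lim, asp = 1)
  axis(1); axis(2); box()
  abline(h = 0, v = 0, col = "grey60")
  abline(h = c(-cutoff, cutoff), v = c(-cutoff, cutoff),
         lty = 3, col = "grey70")
  qual <- rownames(co) %in% qualifying_levels(m, cutoff)
  points(co[, 1], co[, 2], pch = 21,
         bg = ifelse(qual, "tomato", "grey85"), ...)
  text(co[, 1], co[, 2], labels = seq_len(nrow(co)), pos = 3,
       cex = 0.7)
  title(xlab = sprintf("Dimension 1 (%.1f%%)", pct[1]),
        ylab = sprintf("Dimension 2 (%.1f%%)", pct[2]),
        main = "Correspondence analysis association plane")
  if (legend)
    message(paste(sprintf("%d: %s", seq_len(nrow(co)), rownames(co)),
                  collapse = "; "))
  invisible(x)
}
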