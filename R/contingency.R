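check_counts <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (length(x) != 4L || any(!is.finite(x)) || any(x < 0) ||
      any(abs(x - round(x)) > 1e-8))
    stop("counts must be four non-negative integers", call. = FALSE)
  round(x)
}

#' Odds ratio of a 2x2 table
#'
#' For the table with cells `a, b` (first row) and `c, d` (second row) the
#' odds ratio is `(a*d) / (b*c)`.  When a zero cell makes the ratio
#' degenerate, the Haldane–Anscombe correction (adding 0.5 to every cell)
#' is applied under `correction = "auto"` (the default) and the result
#' carries attribute `corrected = TRUE`.
#'
#' @param a,b,c,d Cell counts (non-negative integers).
#' @param correction `"auto"` (correct only when a zero cell is present),
#'   `"none"` (error on degenerate tables), or `"haldane"` (always add
#'   0.5).
#' @return Positive odds ratio.
#' @examples
#' odds_ratio(16, 27, 11, 5)  # 0.269
#' @export
odds_ratio <- function(a, b, c, d,
                       correction = c("auto", "none", "haldane")) {
  correction <- match.arg(correction)
  x <- check_counts(a, b, c, d)
  if (all(x == 0)) stop("odds ratio undefined for an all-zero table",
                        call. = FALSE)
  corrected <- FALSE
  if (correction == "haldane" ||
      (correction == "auto" && any(x == 0))) {
    x <- x + 0.5; corrected <- TRUE
  }
  if (x[2] * x[3] == 0)
    stop("odds ratio undefined: zero cell without correction",
         call. = FALSE)
  structure((x[1] * x[4]) / (x[2] * x[3]), corrected = corrected)
}

#' Woolf confidence interval for an odds ratio
#'
#' The log-normal approximation: `exp(log(OR) +/- z * sqrt(1/a + 1/b +
#' 1/c + 1/d))` with `z` the standard-normal quantile for the requested
#' coverage (1.959964 at 95%).
#'
#' @inheritParams odds_ratio
#' @param level Coverage, default 0.95.
#' @return Named numeric vector `c(low, high)`; attribute `corrected` is
#'   set when the Haldane–Anscombe correction was applied.
#' @examples
#' woolf_ci(16, 27, 11, 5)  # 0.079 - 0.917
#' @export
woolf_ci <- function(a, b, c, d, level = 0.95,
                     correction = c("auto", "none", "haldane")) {
  correction <- match.arg(correction)
  x <- check_counts(a, b, c, d)
  corrected <- FALSE
  if (correction == "haldane" ||
      (correction == "auto" && any(x == 0))) {
    x <- x + 0.5; corrected <- TRUE
  }
  if (any(x == 0))
    stop("Woolf interval undefined: zero cell without correction",
         call. = FALSE)
  lor <- log((x[1] * x[4]) / (x[2] * x[3]))
  se <- sqrt(sum(1 / x))
  z <- qnorm(1 - (1 - level) / 2)
  structure(c(low = exp(lor - z * se), high = exp(lor + z * se)),
            corrected = corrected)
}

#' Woolf z-test p-value for a 2x2 table
#'
#' Two-sided normal-approximation p for the log odds ratio (the test
#' whose interval [woolf_ci()] inverts); reported alongside the exact p
#' for transparency.  Zero cells get the Haldane correction.
#'
#' @inheritParams odds_ratio
#' @return p-value in `(0, 1]`.
#' @export
woolf_p <- function(a, b, c, d) {
  x <- check_counts(a, b, c, d)
  if (any(x == 0)) x <- x + 0.5
  z <- log((x[1] * x[4]) / (x[2] * x[3])) / sqrt(sum(1 / x))
  2 * pnorm(-abs(z))
}

#' Fisher exact two-sided p-value for a 2x2 table
#'
#' Enumerates all tables with the observed margins under the
#' hypergeometric null.  With the default minimum-likelihood rule the
#' two-sided p is the sum of the probabilities of all tables whose point
#' probability does not exceed that of the observed table (up to a
#' relative tolerance of 1e-7); `method = "doubling"` doubles the smaller
#' one-sided tail instead (capped at 1).
#'
#' @inheritParams odds_ratio
#' @param method `"minlike"` (default) or `"doubling"`.
#' @return p-value in `(0, 1]`.
#' @examples
#' exact_p(16, 27, 11, 5)
#' @export
exact_p <- function(a, b, c, d, method = c("minlike", "doubling")) {
  method <- match.arg(method)
  x <- check_counts(a, b, c, d)
  m <- x[1] + x[2]          # first row total
  n2 <- x[3] + x[4]         # second row total
  k <- x[1] + x[3]          # first column total
  if (m + n2 == 0) return(1)
  lo <- max(0, k - n2); hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(x[1], m, n2, k)
  if (method == "minlike") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= x[1]])
    upper <- sum(probs[support >= x[1]])
    p <- 2 * min(lower, upper)
  }
  min(1, max(p, .Machine$double.xmin))
}

#' Full statistics for a 2x2 contingency table
#'
#' Bundles counts, odds ratio, Woolf 95% interval, Fisher exact p
#' (minimum-likelihood rule), and the Woolf z-test p.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level for the interval.
#' @return An object of class `contingency_result`.
#' @examples
#' ct_stats(13, 3, 20, 41)
#' @export
ct_stats <- function(a, b, c, d, level = 0.95) {
  x <- check_counts(a, b, c, d)
  or <- odds_ratio(x[1], x[2], x[3], x[4])
  ci <- woolf_ci(x[1], x[2], x[3], x[4], level = level)
  structure(list(counts = setNames(x, c("a", "b", "c", "d")),
                 or = as.numeric(or),
                 ci_low = as.numeric(ci["low"]),
                 ci_high = as.numeric(ci["high"]),
                 level = level,
                 p = exact_p(x[1], x[2], x[3], x[4]),
                 p_woolf = woolf_p(x[1], x[2], x[3], x[4]),
                 corrected = isTRUE(attr(or, "corrected")),
                 method = c(or = "cross-product", ci = "Woolf",
                            p = "Fisher exact (minlike)")),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 table: [%d %d; %d %d]%s\n",
              x$counts[1], x$counts[2], x$counts[3], x$counts[4],
              if (x$corrected) " (Haldane-corrected)" else ""))
  cat(sprintf("OR = %.3f  (%d%% CI %.3f-%.3f, Woolf)\n", x$or,
              round(100 * x$level), x$ci_low, x$ci_high))
  cat(sprintf("p = %.4g (Fisher exact), %.4g (Woolf z)\n",
              x$p, x$p_woolf))
  invisible(x)
}

#' Reconstruct 2x2 tables from printed margins and statistics
#'
#' Published reports often print only the row margins, the odds ratio and
#' its confidence interval.  This routine scans every integer 2x2 table
#' with the given row margins and returns those whose odds ratio and
#' Woolf 95% interval, rounded to three decimals, match the targets
#' within `tol`.  Tables with a zero cell are skipped (their Woolf
#' interval is not comparable to a printed finite interval).
#'
#' @param row_margins Integer pair: totals of the two rows.
#' @param target_or Printed odds ratio.
#' @param target_ci Printed interval, length-2 `(low, high)`.
#' @param tol Tolerance applied after rounding to 3 decimals
#'   (default 5e-4, i.e. agreement at the printed precision).
#' @return A list of matching tables, each an integer vector
#'   `c(a, b, c, d)`; empty when no table matches.
#' @examples
#' recover_table(c(43, 16), 0.269, c(0.079, 0.917))
#' @export
recover_table <- function(row_margins, target_or, target_ci,
                          tol = 5e-4) {
  stopifnot(length(row_margins) == 2L, all(row_margins > 0), tol > 0,
            length(target_ci) == 2L)
  r1 <- as.integer(row_margins[1]); r2 <- as.integer(row_margins[2])
  hits <- list()
  for (a in 0:r1) for (cc in 0:r2) {
    b <- r1 - a; dd <- r2 - cc
    if (a == 0 || b == 0 || cc == 0 || dd == 0) next
    or <- (a * dd) / (b * cc)
    if (abs(round(or, 3) - target_or) > tol) next
    ci <- woolf_ci(a, b, cc, dd, correction = "none")
    if (abs(round(ci[1], 3) - target_ci[1]) > tol) next
    if (abs(round(ci[2], 3) - target_ci[2]) > tol) next
    hits[[length(hits) + 1L]] <- c(a = a, b = b, c = cc, d = dd)
  }
  hits
}
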