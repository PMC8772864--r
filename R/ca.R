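#' Correspondence analysis of a non-negative table
#'
#' Fits a correspondence analysis by singular value decomposition of the
#' matrix of standardized residuals.  Writing `P` for the table divided by
#' its grand total, `r` and `c` for the row and column mass vectors, the
#' residuals are `S_ij = (P_ij - r_i c_j) / sqrt(r_i c_j)`; the SVD
#' `S = U D V'` yields principal inertias `lambda_k = sigma_k^2` (whose sum
#' is the table's chi-square statistic divided by the grand total), row and
#' column principal coordinates (`diag(1/sqrt(r)) U D` and
#' `diag(1/sqrt(c)) V D`), and per-level qualities of representation
#' (cos^2): the share of a column's squared chi-distance to the centroid
#' captured by each dimension.
#'
#' Applied to a subjects-by-levels indicator table this is the
#' indicator-matrix variant of multiple correspondence analysis.  No
#' inertia correction (Benzecri/Greenacre) is applied.  The sign of each
#' singular vector pair is fixed by making the largest-magnitude column
#' loading positive, so results are reproducible across platforms.
#'
#' @param x An `indicator_table`, a `burt_table`, or a non-negative numeric
#'   matrix/table of counts with at least 2 rows and 2 columns.
#' @return An object of class `ca_model`: list with `sv` (singular values,
#'   descending), `inertia` (their squares), `total_inertia`, `row_coord`
#'   and `col_coord` (principal coordinates, all retained dimensions),
#'   `col_std` (standard column coordinates), `col_cos2` (levels x
#'   dimensions), `col_dist2` (squared chi-distance of each level to the
#'   centroid), `row_mass`, `col_mass`, `nd` (number of retained
#'   dimensions), and — for encoded input — `param`/`level` column maps.
#' @examples
#' m <- fit_ca(matrix(c(2, 0, 0, 2), 2))
#' m$total_inertia  # 1: chi-square 4 over grand total 4
#' @export
fit_ca <- function(x) {
  param <- level <- NULL
  if (inherits(x, "indicator_table")) {
    N <- x$X; param <- x$param; level <- x$level
  } else if (inherits(x, "burt_table")) {
    N <- x$B; param <- x$param; level <- x$level
  } else if (is.matrix(x) || is.table(x) || is.data.frame(x)) {
    N <- as.matrix(x)
  } else {
    stop("unsupported input type for fit_ca()", call. = FALSE)
  }
  storage.mode(N) <- "double"
  if (nrow(N) < 2L || ncol(N) < 2L)
    stop("table must have at least 2 rows and 2 columns", call. = FALSE)
  if (any(!is.finite(N)) || any(N < 0))
    stop("table entries must be finite and non-negative", call. = FALSE)
  n <- sum(N)
  if (n <= 0) stop("table must have a positive grand total", call. = FALSE)

  P <- N / n
  r <- rowSums(P); cm <- colSums(P)
  if (any(r == 0) || any(cm == 0))
    stop("zero-mass rows/columns must be dropped before fitting",
         call. = FALSE)

  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  sv <- svd(S)
  tol <- max(dim(S)) * .Machine$double.eps * max(sv$d, 0)
  nd <- sum(sv$d > max(tol, 1e-12))
  nd <- min(nd, min(dim(S)) - 1L)

  if (nd == 0L) {
    model <- list(sv = numeric(0), inertia = numeric(0),
                  total_inertia = 0,
                  row_coord = matrix(0, nrow(N), 0,
                                     dimnames = list(rownames(N), NULL)),
                  col_coord = matrix(0, ncol(N), 0,
                                     dimnames = list(colnames(N), NULL)),
                  col_std = matrix(0, ncol(N), 0),
                  col_cos2 = matrix(0, ncol(N), 0),
                  col_dist2 = rep(0, ncol(N)),
                  row_mass = r, col_mass = cm, nd = 0L,
                  param = param, level = level)
    class(model) <- "ca_model"
    return(model)
  }

  d <- sv$d[seq_len(nd)]
  U <- sv$u[, seq_len(nd), drop = FALSE]
  V <- sv$v[, seq_len(nd), drop = FALSE]
  # deterministic sign: largest-magnitude column loading positive
  for (k in seq_len(nd)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  col_std <- V / sqrt(cm)
  col_coord <- sweep(col_std, 2, d, `*`)
  row_coord <- sweep(U / sqrt(r), 2, d, `*`)
  dist2 <- rowSums(col_coord^2)
  cos2 <- col_coord^2 / ifelse(dist2 > 0, dist2, 1)
  cos2[dist2 <= .Machine$double.eps, ] <- 0
  dimnames(row_coord) <- list(rownames(N), paste0("dim", seq_len(nd)))
  dimnames(col_coord) <- list(colnames(N), paste0("dim", seq_len(nd)))
  dimnames(cos2) <- dimnames(col_coord)
  names(dist2) <- colnames(N)

  model <- list(sv = d, inertia = d^2, total_inertia = sum(d^2),
                row_coord = row_coord, col_coord = col_coord,
                col_std = col_std, col_cos2 = cos2, col_dist2 = dist2,
                row_mass = r, col_mass = cm, nd = nd,
                param = param, level = level)
  class(model) <- "ca_model"
  model
}

#' @export
print.ca_model <- function(x, ...) {
  cat("Correspondence analysis:", length(x$row_mass), "rows x",
      length(x$col_mass), "columns,", x$nd, "dimensions\n")
  cat(sprintf("Total inertia: %.6g\n", x$total_inertia))
  if (x$nd > 0) {
    k <- min(x$nd, 5L)
    cat("Principal inertias:",
        paste(sprintf("%.4f", x$inertia[seq_len(k)]), collapse = ", "),
        if (x$nd > k) "..." else "", "\n")
    cat(sprintf("First two dimensions explain %.1f%% of total inertia\n",
                100 * inertia_explained(x, 2)))
  }
  invisible(x)
}

#' Share of total inertia explained by the leading dimensions
#'
#' With the default `scaling = "indicator"` this is the plain cumulative
#' share of the principal inertias, `sum(lambda_1..lambda_dims) /
#' sum(lambda)`.  Indicator-matrix MCA is known to understate the
#' structure captured by the leading dimensions, so two rescaled
#' conventions are provided for the encoded-table case: `"burt"` uses the
#' Burt-table spectrum (shares of `lambda_k^2`, what a CA of
#' `t(X) %*% X` reports), and `"benzecri"` uses the Benzecri-adjusted
#' inertias `((Q/(Q-1)) * (lambda_k - 1/Q))^2` over the dimensions with
#' `lambda_k > 1/Q`, `Q` being the number of encoded parameters — the
#' convention in which classic MCA software reports its percentages.
#'
#' @param model A `ca_model`.
#' @param dims Number of leading dimensions (positive integer).
#' @param scaling `"indicator"` (default), `"burt"`, or `"benzecri"`.
#' @param n_params Number of encoded parameters `Q`, required by
#'   `"benzecri"`; taken from the model's parameter map when present.
#' @return Fraction in `[0, 1]`; by convention 1 for a table with zero
#'   total inertia (exact independence) or when no dimension exceeds the
#'   `1/Q` floor under `"benzecri"`.
#' @export
inertia_explained <- function(model, dims = 2L,
                              scaling = c("indicator", "burt",
                                          "benzecri"),
                              n_params = NULL) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(model, "ca_model"), dims >= 1L)
  if (model$total_inertia <= 0 || model$nd == 0L) return(1)
  lam <- model$inertia
  if (scaling == "indicator") {
    k <- min(dims, model$nd)
    return(sum(lam[seq_len(k)]) / sum(lam))
  }
  if (scaling == "burt") {
    k <- min(dims, model$nd)
    return(sum(lam[seq_len(k)]^2) / sum(lam^2))
  }
  if (is.null(n_params)) {
    if (is.null(model$param))
      stop("`benzecri` scaling needs `n_params` (or an encoded-table model)",
           call. = FALSE)
    n_params <- length(unique(model$param))
  }
  Q <- n_params
  adj <- lam[lam > 1 / Q]
  if (!length(adj)) return(1)
  adj <- ((Q / (Q - 1)) * (adj - 1 / Q))^2
  sum(adj[seq_len(min(dims, length(adj)))]) / sum(adj)
}

#' Quality of representation of a level in the first two dimensions
#'
#' The cos^2 of a column point summed over dimensions 1 and 2: the share
#' of its squared chi-distance to the centroid that the association plane
#' captures.
#'
#' @param model A `ca_model`.
#' @param level Column name (for encoded tables, `"parameter=level"`) or
#'   column index.
#' @return Numeric in `[0, 1]`.  A level coinciding with the centroid has
#'   undefined quality; it is returned as 0 with attribute
#'   `at_centroid = TRUE`.
#' @export
quality2 <- function(model, level) {
  stopifnot(inherits(model, "ca_model"))
  j <- if (is.character(level)) match(level, rownames(model$col_cos2))
       else as.integer(level)
  if (is.na(j) || j < 1L || j > length(model$col_dist2))
    stop("level `", level, "` not found in model", call. = FALSE)
  if (model$nd == 0L || model$col_dist2[j] <= .Machine$double.eps)
    return(structure(0, at_centroid = TRUE))
  sum(model$col_cos2[j, seq_len(min(2L, model$nd))])
}

#' Serialize a CA model to JSON
#'
#' @param model A `ca_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_model <- function(model, path) {
  stopifnot(inherits(model, "ca_model"))
  obj <- list(n_dimensions = model$nd,
              singular_values = model$sv,
              principal_inertias = model$inertia,
              total_inertia = model$total_inertia,
              inertia_explained_2d = inertia_explained(model, 2),
              column_coordinates = as.data.frame(model$col_coord),
              column_cos2 = as.data.frame(model$col_cos2),
              column_mass = as.list(model$col_mass))
  if (!is.null(model$param)) {
    obj$column_coordinates <- cbind(parameter = model$param,
                                    level = model$level,
                                    obj$column_coordinates)
    obj$column_cos2 <- cbind(parameter = model$param,
                             level = model$level, obj$column_cos2)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
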