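#' Levels qualifying for association scoring
#'
#' A level qualifies when at least one of its first two principal
#' coordinates exceeds the cutoff in absolute value (strictly):
#' `max(|dim1|, |dim2|) > cutoff`.  Points near the centroid of the
#' association plane are excluded.
#'
#' @param model A `ca_model`.
#' @param cutoff Coordinate-magnitude cutoff (default 0.3).
#' @return Character vector of qualifying column names.
#' @export
qualifying_levels <- function(model, cutoff = 0.3) {
  stopifnot(inherits(model, "ca_model"))
  if (model$nd == 0L) return(character(0))
  co <- plane_coords(model)
  rownames(co)[pmax(abs(co[, 1]), abs(co[, 2])) > cutoff]
}

# first-two-dimension coordinates, zero-padded for a rank-1 model
plane_coords <- function(model) {
  if (model$nd >= 2L) return(model$col_coord[, 1:2, drop = FALSE])
  if (model$nd == 1L) {
    co <- cbind(dim1 = model$col_coord[, 1], dim2 = 0)
    rownames(co) <- rownames(model$col_coord)
    return(co)
  }
  stop("model has no usable dimensions", call. = FALSE)
}

#' Cosine of the angle between two level points
#'
#' The angle is determined by the two rays connecting the origin of the
#' CA plane with the two points.
#'
#' @param pA,pB Numeric length-2 coordinates on the plane (nonzero).
#' @return Cosine in `[-1, 1]`.
#' @examples
#' angle_cosine(c(1, 0), c(0, 1))  # 0
#' @export
angle_cosine <- function(pA, pB) {
  pA <- as.numeric(pA); pB <- as.numeric(pB)
  stopifnot(length(pA) == 2L, length(pB) == 2L)
  nA <- sqrt(sum(pA^2)); nB <- sqrt(sum(pB^2))
  if (nA == 0 || nB == 0)
    stop("angle undefined for a point at the origin", call. = FALSE)
  max(-1, min(1, sum(pA * pB) / (nA * nB)))
}

#' Signed association weight of two level points
#'
#' The product of the two coordinate magnitudes with the cosine of the
#' angle between their origin rays: `w = |pA| * |pB| * cos(theta)`, which
#' equals the planar dot product `xA*xB + yA*yB`.  The sign of `w` equals
#' the sign of the cosine, so inversely related levels (obtuse angle) get
#' negative weights.  The variant `method = "per_dimension"` returns the
#' two per-dimension coordinate products each multiplied by the cosine.
#'
#' @param pA,pB Numeric length-2 coordinates (nonzero).
#' @param method `"dot"` (default) or `"per_dimension"`.
#' @return A single signed weight, or a length-2 vector for the
#'   per-dimension variant.
#' @examples
#' association_weight(c(0.9, 0.5), c(0.8, -0.3))  # 0.57
#' @export
association_weight <- function(pA, pB, method = c("dot", "per_dimension")) {
  method <- match.arg(method)
  pA <- as.numeric(pA); pB <- as.numeric(pB)
  stopifnot(length(pA) == 2L, length(pB) == 2L)
  if (all(pA == 0) || all(pB == 0))
    stop("association weight undefined for a point at the origin",
         call. = FALSE)
  if (method == "dot") return(sum(pA * pB))
  cth <- angle_cosine(pA, pB)
  c(dim1 = pA[1] * pB[1] * cth, dim2 = pA[2] * pB[2] * cth)
}

#' Association report for a fitted CA model
#'
#' Lists every unordered pair of qualifying levels
#' ([qualifying_levels()]) that belong to different parameters, with the
#' plane coordinates of both levels, the cosine of their angle, and the
#' signed association weight.  Pairs of levels of the same parameter are
#' excluded: complementary levels of one encoded parameter oppose each
#' other by construction.
#'
#' @param model A `ca_model` fitted to an encoded table.
#' @param cutoff Coordinate cutoff passed to [qualifying_levels()].
#' @return A data frame of class `association_report` with columns
#'   `param_a`, `level_a`, `param_b`, `level_b`, `x1_a`, `x2_a`, `x1_b`,
#'   `x2_b`, `cosine`, `weight`, sorted by decreasing `|weight|`.
#' @export
build_report <- function(model, cutoff = 0.3) {
  stopifnot(inherits(model, "ca_model"))
  if (is.null(model$param))
    stop("model does not carry a parameter map", call. = FALSE)
  qual <- qualifying_levels(model, cutoff)
  empty <- data.frame(param_a = character(), level_a = character(),
                      param_b = character(), level_b = character(),
                      x1_a = numeric(), x2_a = numeric(),
                      x1_b = numeric(), x2_b = numeric(),
                      cosine = numeric(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (length(qual) < 2L)
    return(structure(empty, class = c("association_report",
                                      "data.frame")))
  co <- plane_coords(model)
  idx <- match(qual, rownames(co))
  pairs <- utils::combn(seq_along(qual), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- idx[pairs[1, k]]; j <- idx[pairs[2, k]]
    if (model$param[i] == model$param[j]) return(NULL)
    pA <- co[i, ]; pB <- co[j, ]
    data.frame(param_a = model$param[i], level_a = model$level[i],
               param_b = model$param[j], level_b = model$level[j],
               x1_a = pA[1], x2_a = pA[2], x1_b = pB[1], x2_b = pB[2],
               cosine = angle_cosine(pA, pB),
               weight = association_weight(pA, pB),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(-abs(out$weight)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("association_report", "data.frame"))
}

#' @export
print.association_report <- function(x, digits = 2, ...) {
  cat("Association report:", nrow(x), "qualifying pair(s)\n")
  if (nrow(x)) {
    df <- data.frame(
      pair = paste0(x$param_a, "=", x$level_a, "  ~  ",
                    x$param_b, "=", x$level_b),
      weight = round(x$weight, digits),
      cosine = round(x$cosine, digits))
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' Write an association report to TSV
#'
#' @param report An `association_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
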