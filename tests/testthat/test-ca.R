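test_that("degenerate tables give zero inertia; a perfect diagonal gives one", {
  m0 <- fit_ca(matrix(c(1, 1, 1, 1), 2))
  expect_equal(m0$total_inertia, 0)
  expect_equal(m0$nd, 0L)
  expect_equal(inertia_explained(m0, 1), 1)  # convention at zero inertia

  m1 <- fit_ca(matrix(c(2, 0, 0, 2), 2))
  expect_equal(m1$total_inertia, 1)          # chi-square 4 over n = 4
  expect_equal(m1$nd, 1L)
  expect_equal(m1$inertia, 1)
})

test_that("total inertia equals chi-square over n on random tables", {
  set.seed(101)
  for (i in 1:50) {
    N <- random_count_table(sample(3:6, 1), sample(3:6, 1))
    m <- fit_ca(N)
    chi <- suppressWarnings(chisq.test(N)$statistic)
    expect_equal(m$total_inertia, unname(chi) / sum(N),
                 tolerance = 1e-10)
    expect_equal(sum(m$inertia), m$total_inertia, tolerance = 1e-10)
  }
})

test_that("cos2 sums to one, transitions and reconstruction hold", {
  set.seed(102)
  for (i in 1:20) {
    N <- random_count_table(sample(4:8, 1), sample(4:8, 1))
    m <- fit_ca(N)
    # cos2 over all dimensions exhausts each off-centroid level
    pos <- m$col_dist2 > 1e-12
    expect_equal(unname(rowSums(m$col_cos2)[pos]),
                 rep(1, sum(pos)), tolerance = 1e-8)
    # transition: row principal coords are row profiles times column
    # standard coordinates
    P <- N / sum(N)
    expect_equal(unname((P / rowSums(P)) %*% m$col_std),
                 unname(m$row_coord), tolerance = 1e-8)
    # reconstruction of P from masses plus the full decomposition
    r <- rowSums(P); cm <- colSums(P)
    S_hat <- (sqrt(r) * m$row_coord) %*% t(sqrt(cm) * m$col_std)
    P_hat <- sqrt(tcrossprod(r, cm)) * S_hat + tcrossprod(r, cm)
    expect_equal(unname(P_hat), unname(P), tolerance = 1e-10)
  }
})

test_that("coordinates agree with an independent CA implementation", {
  skip_if_not_installed("MASS")
  set.seed(103)
  N <- random_count_table(6, 5)
  m <- fit_ca(N)
  ref <- MASS::corresp(N, nf = min(m$nd, 4))
  expect_equal(m$sv[seq_along(ref$cor)], unname(ref$cor),
               tolerance = 1e-8)
  for (j in seq_len(ncol(ref$cscore))) {
    ours <- m$col_coord[, j] / m$sv[j]  # standard coordinates
    diff <- min(max(abs(ours - ref$cscore[, j])),
                max(abs(ours + ref$cscore[, j])))
    expect_lt(diff, 1e-6)
  }
})

test_that("singular-vector signs are fixed deterministically", {
  set.seed(104)
  N <- random_count_table(5, 5)
  m1 <- fit_ca(N); m2 <- fit_ca(N)
  expect_identical(m1$col_coord, m2$col_coord)
  V <- sqrt(m1$col_mass) * m1$col_std
  for (k in seq_len(m1$nd))
    expect_gt(V[which.max(abs(V[, k])), k], 0)
})

test_that("inertia shares match an SVD oracle and rescaled conventions behave", {
  set.seed(105)
  N <- random_count_table(5, 6)
  m <- fit_ca(N)
  # independent oracle: cumulative squared singular values of the
  # standardized residual matrix
  P <- N / sum(N); r <- rowSums(P); cm <- colSums(P)
  d2 <- svd((P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm)))$d^2
  expect_equal(inertia_explained(m, 2), sum(d2[1:2]) / sum(d2),
               tolerance = 1e-10)
  expect_equal(inertia_explained(m, m$nd), 1)
  expect_equal(inertia_explained(m, 2, scaling = "burt"),
               sum(d2[1:2]^2) / sum(d2^2), tolerance = 1e-10)
  # rank-1 model: one dimension explains everything
  m1 <- fit_ca(matrix(c(3, 0, 0, 5), 2))
  expect_equal(inertia_explained(m1, 1), 1)
})

test_that("benzecri scaling counts only dimensions above the 1/Q floor", {
  rec <- generate_cohort(cohort_spec(), seed = 7)
  tab <- encode_cohort(rec, quiet = TRUE)
  m <- fit_ca(tab)
  Q <- length(unique(tab$param))
  adj <- m$inertia[m$inertia > 1 / Q]
  adj <- ((Q / (Q - 1)) * (adj - 1 / Q))^2
  expect_equal(inertia_explained(m, 2, scaling = "benzecri"),
               sum(adj[1:2]) / sum(adj), tolerance = 1e-12)
  expect_gt(inertia_explained(m, 2, scaling = "benzecri"),
            inertia_explained(m, 2))
})

test_that("quality2 matches brute force and flags centroid-coincident levels", {
  set.seed(106)
  N <- random_count_table(6, 5)
  m <- fit_ca(N)
  for (j in seq_len(ncol(N))) {
    brute <- sum(m$col_coord[j, 1:2]^2) / sum(m$col_coord[j, ]^2)
    expect_equal(as.numeric(quality2(m, j)), brute, tolerance = 1e-10)
  }
  # rank-2 table: the plane is exhaustive for every level
  N2 <- random_count_table(3, 5)
  m2 <- fit_ca(N2)
  expect_lte(m2$nd, 2L)
  for (j in seq_len(ncol(N2)))
    expect_equal(as.numeric(quality2(m2, j)), 1, tolerance = 1e-8)
  # a column proportional to the average profile sits at the centroid
  N3 <- cbind(c(1, 1), c(2, 1), c(1, 2))
  m3 <- fit_ca(N3)
  q <- quality2(m3, 1)
  expect_equal(as.numeric(q), 0)
  expect_true(attr(q, "at_centroid"))
})

test_that("invalid tables are rejected", {
  expect_error(fit_ca(matrix(c(1, 1, 0, 0), 2)), "zero-mass")
  expect_error(fit_ca(matrix(-1:2, 2)), "non-negative")
  expect_error(fit_ca(matrix(1, 1, 2)), "at least 2 rows")
})
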