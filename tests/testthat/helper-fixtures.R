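# Shared fixture builders (all data generated in code).

# Cohort of binary parameters: pA and pB strongly associated (pB is pA
# with labels flipped w.p. `flip`), plus independent Bernoulli(0.5) noise.
make_binary_cohort <- function(n = 77, flip = 0.1, n_noise = 10) {
  A <- runif(n) < 0.5
  B <- xor(A, runif(n) < flip)
  df <- data.frame(pA = ifelse(A, "yes", "no"),
                   pB = ifelse(B, "yes", "no"),
                   stringsAsFactors = FALSE)
  for (j in seq_len(n_noise))
    df[[paste0("noise", j)]] <- ifelse(runif(n) < 0.5, "yes", "no")
  df
}

# Minimal ca_model stand-in carrying fixed plane coordinates, for testing
# the qualification/pairing rules in isolation.
make_fake_model <- function(coords, params) {
  co <- as.matrix(coords)
  colnames(co) <- c("dim1", "dim2")
  rownames(co) <- paste0(params, "=", seq_len(nrow(co)))
  structure(list(col_coord = co, nd = 2L, param = params,
                 level = as.character(seq_len(nrow(co))),
                 col_mass = rep(1 / nrow(co), nrow(co)),
                 col_dist2 = rowSums(co^2),
                 col_cos2 = co^2 / pmax(rowSums(co^2), 1e-300),
                 sv = c(1, 0.5), inertia = c(1, 0.25),
                 total_inertia = 1.25,
                 row_mass = c(0.5, 0.5)),
            class = "ca_model")
}

# Small random count table without zero rows/columns.
random_count_table <- function(nr, nc, lambda = 5) {
  matrix(rpois(nr * nc, lambda) + 1, nr, nc)
}

expect_pair_present <- function(report, pa, la, pb, lb, positive = TRUE) {
  sel <- (report$param_a == pa & report$level_a == la &
          report$param_b == pb & report$level_b == lb) |
         (report$param_b == pa & report$level_b == la &
          report$param_a == pb & report$level_a == lb)
  hit <- if (positive) any(sel & report$weight > 0) else any(sel)
  hit
}
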