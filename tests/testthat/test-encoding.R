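test_that("median split uses the sample median and sends ties under", {
  sp <- median_split(c(1, 2, 3, 4))
  expect_equal(sp$median, 2.5)
  expect_equal(as.character(sp$labels),
               c("under", "under", "above", "above"))
  tied <- median_split(c(5, 5, 5))
  expect_equal(tied$median, 5)
  expect_true(all(tied$labels == "under"))
  tied2 <- median_split(c(5, 5, 5), tie_rule = "above")
  expect_true(all(tied2$labels == "above"))
  expect_error(median_split(c(NA, NA, 3)), "two non-missing")
})

test_that("encoding yields one active level per parameter and unit total mass", {
  rec <- generate_cohort(cohort_spec(), seed = 3)
  tab <- encode_cohort(rec, quiet = TRUE)
  n_par <- length(unique(tab$param))
  expect_equal(unname(rowSums(tab$X)), rep(n_par, nrow(rec)))
  expect_equal(sum(tab$X / sum(tab$X)), 1)
  # column count equals the total number of retained levels
  expect_equal(ncol(tab$X),
               sum(lengths(lapply(tab$scheme$parameters,
                                  function(e) e$levels))))
  # realized medians recorded for every split parameter
  expect_equal(tab$scheme$parameters$acid_butyric$median,
               median(rec$acid_butyric_ugg))
})

test_that("encoding is deterministic and stable under subject removal", {
  rec <- generate_cohort(cohort_spec(), seed = 4)
  t1 <- encode_cohort(rec, quiet = TRUE)
  t2 <- encode_cohort(rec, quiet = TRUE)
  expect_identical(t1, t2)
  t3 <- encode_cohort(rec[-5, ], quiet = TRUE)
  expect_true(all(colnames(t3$X) %in% colnames(t1$X)))
})

test_that("even-n tieless splits put exactly half the subjects under", {
  set.seed(9)
  df <- data.frame(v = sample(seq_len(40)))  # distinct values, even n
  tab <- encode_cohort(df, parameters = "v", quiet = TRUE)
  expect_equal(unname(colSums(tab$X)), c(20, 20))
})

test_that("empty levels are dropped with a message and missing values zero the row", {
  df <- data.frame(grp = c("UC", "UC", "CD", "CD"),
                   flag = c("yes", "no", "yes", NA),
                   stringsAsFactors = FALSE)
  expect_message(
    tab <- encode_cohort(df, parameters = c("grp", "flag")),
    "missing")
  # subject 4: all-zero cells for flag
  expect_equal(unname(rowSums(tab$X[, tab$param == "flag"])),
               c(1, 1, 1, 0))
  expect_error(encode_cohort(df, parameters = "absent"), "not found")
})

test_that("a single binary parameter over four subjects encodes as a 4x2 indicator", {
  df <- data.frame(p = c("yes", "yes", "no", "no"))
  tab <- encode_cohort(df, parameters = "p", quiet = TRUE)
  expect_equal(dim(tab$X), c(4L, 2L))
  expect_equal(unname(rowSums(tab$X)), rep(1, 4))
})

test_that("Burt-table CA matches indicator CA up to singular-value scaling", {
  rec <- generate_cohort(cohort_spec(), seed = 5)
  tab <- encode_cohort(rec, quiet = TRUE)
  mi <- fit_ca(tab)
  mb <- fit_ca(burt_table(tab))
  k <- min(mi$nd, mb$nd, 6L)
  expect_equal(mb$sv[seq_len(k)], mi$sv[seq_len(k)]^2, tolerance = 1e-8)
  for (j in seq_len(k)) {
    diff <- min(max(abs(mb$col_std[, j] - mi$col_std[, j])),
                max(abs(mb$col_std[, j] + mi$col_std[, j])))
    expect_lt(diff, 1e-6)
  }
})

test_that("indicator tables round-trip through TSV with a scheme side-car", {
  rec <- generate_cohort(cohort_spec(), seed = 6)
  tab <- encode_cohort(rec, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_indicator(tab, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), tab$X, ignore_attr = "dimnames")
  scheme <- jsonlite::read_json(paste0(path, ".scheme.json"))
  expect_equal(length(scheme$parameters),
               length(unique(tab$param)))
})
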