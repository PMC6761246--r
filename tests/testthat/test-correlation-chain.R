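test_that("pearson_table reproduces hand-computed coefficients", {
  X <- cbind(a = c(1, 2, 3, 4))
  expect_equal(unname(pearson_table(X, X, min_pairs = 3)[1, 1]), 1)
  Y <- cbind(up = c(2, 4, 6, 8), down = c(8, 6, 4, 2))
  r <- pearson_table(X, Y, min_pairs = 3)
  expect_equal(unname(r["a", ]), c(1, -1))
  X5 <- cbind(x = c(1, 2, 3, 4, 5))
  Y5 <- cbind(y = c(2, 1, 4, 3, 5))
  expect_equal(unname(pearson_table(X5, Y5, min_pairs = 3)[1, 1]), 0.8)
})

test_that("pearson_table is symmetric and affine-invariant", {
  set.seed(4)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("P", 1:12), paste0("x", 1:5)))
  Y <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("P", 1:12), paste0("y", 1:3)))
  expect_equal(pearson_table(X, Y, 3), t(pearson_table(Y, X, 3)), tolerance = 1e-12)
  expect_equal(pearson_table(2.5 * X + 3, Y, 3), pearson_table(X, Y, 3),
               tolerance = 1e-12)
  # zero-variance and short pairs report NA
  X[, 1] <- 1
  expect_true(all(is.na(pearson_table(X, Y, 3)[1, ])))
  Xna <- X; Xna[1:5, 2] <- NA
  expect_true(all(is.na(pearson_table(Xna, Y, min_pairs = 10)[2, ])))
})

test_that("misaligned pair identifiers are rejected", {
  X <- matrix(1:9, 3, 3, dimnames = list(c("P1", "P2", "P3"), NULL))
  Y <- matrix(1:9, 3, 3, dimnames = list(c("P1", "P2", "P9"), NULL))
  expect_error(pearson_table(X, Y), "aligned")
})

test_that("build_chain selects a planted milk variable and respects bounds", {
  spec <- slim_chain_spec(n_pairs = 30, r = 0.9)
  g <- generate_cohort(spec, seed = 2)
  ams <- preprocess_peaks(g$peaks, spec$library)
  I <- compartment_matrix(ams$positive, "infant_plasma")
  K <- compartment_matrix(ams$positive, "milk")
  M <- compartment_matrix(ams$positive, "maternal_plasma")
  res <- build_chain(I, K, M)
  expect_s3_class(res, "chain_result")
  expect_true("TG(49:4)" %in% res$selected_milk)
  expect_true(all(abs(res$stage1) <= 1, na.rm = TRUE))
  expect_true(all(rownames(res$stage2) %in% res$selected_milk))
  # impossible threshold empties the selection
  res2 <- build_chain(I, K, M, threshold = 1.01)
  expect_length(res2$selected_milk, 0)
  expect_equal(nrow(res2$stage2), 0)
  expect_error(build_chain(I[, setdiff(colnames(I), "PC(34:1)")], K, M),
               "PC\\(34:1\\)")
})

test_that("raising the threshold never adds selected milk variables", {
  set.seed(30)
  n <- 30
  I <- matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("P%02d", 1:n),
                                                  unlist(cbm_default())))
  K <- matrix(rnorm(n * 20), n, 20, dimnames = list(sprintf("P%02d", 1:n),
                                                    paste0("TG", 1:20)))
  M <- K
  prev <- NULL
  for (thr in c(0.2, 0.35, 0.5, 0.7, 0.9)) {
    sel <- build_chain(I, K, M, threshold = thr)$selected_milk
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
})

test_that("null false-selection matches the Fisher-z tail within binomial error", {
  set.seed(99)
  n <- 30; n_milk <- 100; reps <- 100
  cbms <- unlist(cbm_default())
  hits <- 0
  for (rep in seq_len(reps)) {
    I <- matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("P%02d", 1:n), cbms))
    K <- matrix(rnorm(n * n_milk), n, n_milk,
                dimnames = list(sprintf("P%02d", 1:n), paste0("m", 1:n_milk)))
    hits <- hits + length(build_chain(I, K, K, min_pairs = 5)$selected_milk)
  }
  q <- fisher_z_tail(0, 0.5, n)             # per (CBM, milk) pair
  p_var <- 1 - (1 - q)^5                     # any of the 5 CBMs
  expected <- reps * n_milk * p_var
  sd_bin <- sqrt(reps * n_milk * p_var * (1 - p_var))
  expect_lt(abs(hits - expected), 4 * sd_bin)
})

test_that("chain tables are written in the documented layout", {
  set.seed(1)
  n <- 12
  I <- matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("P%02d", 1:n),
                                                  unlist(cbm_default())))
  K <- matrix(rnorm(n * 4), n, 4, dimnames = list(sprintf("P%02d", 1:n),
                                                  paste0("TG", 1:4)))
  res <- build_chain(I, K, K, threshold = 0.3, min_pairs = 5)
  stem <- file.path(withr::local_tempdir(), "chain")
  write_chain(res, stem)
  s1 <- read.delim(paste0(stem, "_stage1.tsv"), check.names = FALSE)
  expect_equal(s1$variable, unlist(cbm_default(), use.names = FALSE))
  expect_equal(ncol(s1), 5)
})
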