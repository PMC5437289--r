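test_that("no heavy isotopes and perfect purity give the identity matrix", {
  fr <- fragment_spec("toy", "C", 1)
  cm <- build_correction_matrix(fr, toy_carbon_table(0), purity = 1.0)
  expect_equal(cm$matrix, diag(2))
})

test_that("column 0 is the fragment's natural distribution; purity shapes labeled columns", {
  fr <- fragment_spec("toy", "C2", 2)
  cm <- build_correction_matrix(fr, toy_carbon_table(0.0107))
  expect_equal(cm$matrix[, 1], c(0.9893^2, 2 * 0.9893 * 0.0107, 0.0107^2),
               tolerance = 1e-12)

  # j=1 on a carbon-only fragment with no natural 13C: the column is the
  # binomial purity factor itself
  fr1 <- fragment_spec("toy", "C", 1)
  cmp <- build_correction_matrix(fr1, toy_carbon_table(0), purity = 0.99)
  expect_equal(cmp$matrix[, 2], c(0.01, 0.99), tolerance = 1e-12)
})

test_that("correction matrices have valid column sums and purity is validated", {
  cm <- build_correction_matrix(tbdms_fragment(5))
  cs <- colSums(cm$matrix)
  expect_true(all(cs <= 1 + 1e-12 & cs >= 0.5))
  expect_error(build_correction_matrix(tbdms_fragment(5), purity = 0.4),
               "purity")
})

test_that("exact matrix columns invert to unit vectors", {
  cm <- build_correction_matrix(tbdms_fragment(5))
  n <- 5
  for (j in c(0, n)) {
    res <- correct_mid(cm$matrix[, j + 1], cm)
    want <- numeric(n + 1); want[j + 1] <- 1
    expect_equal(res$fractions, want, tolerance = 1e-9)
  }
})

test_that("forward model then correction recovers a known MID exactly", {
  fr <- fragment_spec("toy", "C8H18OSi", 2)
  cm <- build_correction_matrix(fr)
  truth <- c(0.2, 0.3, 0.5)
  meas <- as.numeric(cm$matrix %*% truth)
  res <- correct_mid(meas, cm)
  expect_equal(res$fractions, truth, tolerance = 1e-9)
  expect_lt(res$residual_norm, 1e-9)
})

test_that("round-trip identity holds for random MIDs on large fragments, both solvers", {
  set.seed(21)
  fr <- fragment_spec("big", "C20H40O6Si2", 6)
  cm <- build_correction_matrix(fr)
  for (i in 1:10) {
    truth <- random_mid(6)
    meas <- as.numeric(cm$matrix %*% truth)
    for (m in c("nnls", "solve")) {
      res <- correct_mid(meas, cm, method = m)
      expect_equal(res$fractions, truth, tolerance = 1e-9)
    }
  }
})

test_that("constrained solve agrees with an exhaustive simplex grid search", {
  set.seed(5)
  fr <- fragment_spec("toy", "C6H14O2Si", 2)
  cm <- build_correction_matrix(fr)
  for (i in 1:3) {
    truth <- random_mid(2)
    meas <- as.numeric(cm$matrix %*% truth)
    meas <- meas * exp(rnorm(3, 0, 0.02))  # noise so the optimum is interior
    res <- correct_mid(meas, cm)
    oracle <- grid_search_mid(cm$matrix, meas / sum(meas), step = 0.01)
    expect_lt(max(abs(res$fractions - oracle)), 0.011)  # grid resolution
  }
})

test_that("recovery error grows monotonically with multiplicative noise", {
  fr <- tbdms_fragment(5)
  cm <- build_correction_matrix(fr)
  sigmas <- c(0, 0.005, 0.01, 0.02)
  mae <- sapply(sigmas, function(s) {
    errs <- c()
    for (seed in 1:3) {
      set.seed(100 + seed)
      for (i in 1:30) {
        truth <- random_mid(5)
        raw <- forward_measure(truth, fr, noise = noise_model(sigma = s, seed = 1))
        res <- correct_mid(raw, cm)
        errs <- c(errs, mean(abs(res$fractions - truth)))
      }
    }
    mean(errs)
  })
  expect_true(all(diff(mae) > 0))
})

test_that("degenerate and mismatched inputs error clearly", {
  cm <- build_correction_matrix(tbdms_fragment(3))
  expect_error(correct_mid(rep(0, 4), cm), "all-zero")
  expect_error(correct_mid(rep(1, 3), cm), "does not match")
})
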