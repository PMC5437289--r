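test_that("delta-delta-Ct fold changes follow 2^-ddCt", {
  expect_equal(as.numeric(ddct_fold_change(
    make_ct(list(trt = 4, ctl = 4)), "G", "trt", "ctl")), 1)
  expect_equal(as.numeric(ddct_fold_change(
    make_ct(list(trt = 3, ctl = 5)), "G", "trt", "ctl")), 4)
  expect_equal(as.numeric(ddct_fold_change(
    make_ct(list(trt = 5, ctl = 3)), "G", "trt", "ctl")), 0.25)
})

test_that("fold changes are invariant to a global per-sample Ct shift", {
  ct <- make_ct(list(trt = 3, ctl = 5))
  shifted <- ct
  one_sample <- shifted$sample == "trt_r1"
  shifted$ct[one_sample] <- shifted$ct[one_sample] + 1.7  # efficiency drift
  expect_equal(as.numeric(ddct_fold_change(ct, "G", "trt", "ctl")),
               as.numeric(ddct_fold_change(shifted, "G", "trt", "ctl")),
               tolerance = 1e-12)
})

test_that("missing reference Ct is reported by sample", {
  ct <- make_ct(list(trt = 3, ctl = 5))
  ct <- ct[!(ct$sample == "trt_r2" & ct$gene == "RPL19"), ]
  expect_error(ddct_fold_change(ct, "G", "trt", "ctl"), "trt_r2")
})

test_that("the F-test gate routes to Student or Welch as variances dictate", {
  same <- variance_gated_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_equal(same$test_used, "student")

  shifted <- variance_gated_ttest(c(1, 2, 3), c(101, 102, 103))
  expect_equal(shifted$test_used, "student")
  expect_lt(shifted$p_value, 1e-6)
  # pooled-t closed form: t = d / (sp * sqrt(2/n))
  sp <- 1  # both groups have sd 1
  expect_equal(abs(shifted$statistic), 100 / (sp * sqrt(2 / 3)),
               tolerance = 1e-9)

  het <- variance_gated_ttest(c(10, 10.01, 9.99, 10, 10.02),
                              c(5, 25, 40, 1, 60))
  expect_equal(het$test_used, "welch")
  expect_lt(het$f_test_p, 0.05)
})

test_that("zero-variance groups hit the documented conventions", {
  eq <- variance_gated_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(eq$p_value, 1)
  expect_false(eq$degenerate)
  ne <- variance_gated_ttest(c(2, 2, 2), c(3, 3, 3))
  expect_equal(ne$p_value, 0)
  expect_true(ne$degenerate)
  expect_error(variance_gated_ttest(1, c(1, 2)), ">= 2")
})

test_that("Grubbs flags a gross outlier, not regular scatter, at most one per call", {
  expect_null(grubbs_outlier(c(1, 1, 1, 1)))
  expect_equal(grubbs_outlier(c(10, 11, 9, 10, 11, 50)), 6)
  expect_null(grubbs_outlier(c(10, 11, 9, 10, 11, 12)))
  expect_error(grubbs_outlier(c(1, 2)), ">= 3")
})

test_that("differential filter gates on both magnitude and significance", {
  mk <- function(a, b) data.frame(
    metabolite = "m", group = rep(c("A", "B"), c(length(a), length(b))),
    value = c(a, b))
  thr <- filter_thresholds()

  # 30% change, tight replicates: significant and large enough
  big <- differential_filter(mk(c(1.00, 1.01, 0.99), c(1.30, 1.31, 1.29)),
                             "A", "B", "contribution", thr)
  expect_true(big$retained)
  expect_equal(big$direction, 1)

  # 30% change but noisy: fails the p gate
  noisy <- differential_filter(mk(c(0.7, 1.0, 1.3), c(0.9, 1.3, 1.7)),
                               "A", "B", "contribution", thr)
  expect_gt(noisy$p_value, 0.05)
  expect_false(noisy$retained)

  # 10% change, tiny variance: fails the magnitude gate
  small <- differential_filter(mk(c(1.000, 1.001, 0.999), c(1.10, 1.101, 1.099)),
                               "A", "B", "contribution", thr)
  expect_lt(small$p_value, 0.001)
  expect_false(small$retained)

  # level kind uses the 27% threshold: a 26% change is out
  lvl <- differential_filter(mk(c(1.000, 1.001, 0.999), c(1.26, 1.261, 1.259)),
                             "A", "B", "level", thr)
  expect_false(lvl$retained)
})

test_that("filter threshold construction rejects out-of-range values", {
  expect_error(filter_thresholds(alpha = 0), "\\(0, 1\\)")
  expect_error(filter_thresholds(contribution_change = 1.2), "\\(0, 1\\)")
})
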