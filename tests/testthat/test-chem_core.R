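test_that("formula parsing handles implicit counts, multi-letter symbols, round-trips", {
  expect_equal(unclass(parse_formula("C2")), c(C = 2L), ignore_attr = TRUE)
  expect_equal(unclass(parse_formula("CO2")), c(C = 1L, O = 2L), ignore_attr = TRUE)
  f <- parse_formula("C11H26NO2Si")
  expect_equal(unclass(f)[c("C", "H", "N", "O", "Si")],
               c(C = 11L, H = 26L, N = 1L, O = 2L, Si = 1L))
  expect_equal(format(parse_formula(format(f))), format(f))
})

test_that("formula parsing rejects unknown elements and malformed input", {
  expect_error(parse_formula("C2Xx3"), "unknown element")
  expect_error(parse_formula("2C"), "cannot parse")
  expect_error(elemental_formula(c(C = -1)), "non-negative")
})

test_that("formula addition sums counts element-wise", {
  s <- parse_formula("C2H4") + parse_formula("CH2O")
  expect_equal(format(s), "C3H6O")
})

test_that("isotope tables are validated", {
  bad <- data.frame(element = "C", mass_shift = c(0L, 1L), abundance = c(0.9, 0.2))
  expect_error(isotope_table(bad), "sum to")
  expect_error(suppressWarnings(read_isotope_table(tempfile())),
               "cannot open|No such file")
  expect_silent(default_isotopes())
})

test_that("natural distribution matches hand binomial expansion for C2", {
  # (0.9893 + 0.0107 x)^2
  d <- natural_distribution(parse_formula("C2"), toy_carbon_table(0.0107),
                            max_shift = 2)
  expect_equal(as.numeric(d), c(0.9893^2, 2 * 0.9893 * 0.0107, 0.0107^2),
               tolerance = 1e-12)
})

test_that("degenerate pure-12C table gives a point mass at shift 0", {
  d <- natural_distribution(elemental_formula(c(C = 3)), toy_carbon_table(0),
                            max_shift = 3)
  expect_equal(as.numeric(d), c(1, 0, 0, 0))
})

test_that("entry 0 is the product of lightest-isotope abundances and mass is conserved", {
  iso <- default_isotopes()
  f <- parse_formula("C3H5NO2")
  d <- natural_distribution(f, iso, max_shift = 20, tail_warn = Inf)
  light <- c(C = 0.9893, H = 0.999885, N = 0.99636, O = 0.99757)
  expect_equal(d[1], prod(light[names(f)]^as.integer(f)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(d) + attr(d, "tail_mass"), 1, tolerance = 1e-9)
})

test_that("distribution of a sum of formulas equals the convolution of the parts", {
  set.seed(11)
  iso <- default_isotopes()
  for (i in 1:5) {
    a <- elemental_formula(c(C = sample(1:3, 1), H = sample(1:4, 1)))
    b <- elemental_formula(c(O = sample(1:2, 1), Si = sample(1:2, 1)))
    da <- natural_distribution(a, iso, max_shift = 6, tail_warn = Inf)
    db <- natural_distribution(b, iso, max_shift = 6, tail_warn = Inf)
    dab <- natural_distribution(a + b, iso, max_shift = 6, tail_warn = Inf)
    conv_full <- sapply(0:6, function(s) {
      sum(da[seq_len(s + 1)] * db[s + 1 - seq_len(s + 1) + 1])
    })
    expect_equal(as.numeric(dab), conv_full, tolerance = 1e-12)
  }
})

test_that("convolution engine agrees with exhaustive per-atom enumeration", {
  iso <- default_isotopes()
  for (txt in c("C2H3O", "CHNO2", "C3Si", "H4O2S")) {
    f <- parse_formula(txt)
    d <- natural_distribution(f, iso, max_shift = 4, tail_warn = Inf)
    expect_equal(as.numeric(d), enumerate_distribution(f, iso, 4),
                 tolerance = 1e-12, label = txt)
  }
})

test_that("fragment specs enforce the carbon-count invariant", {
  expect_error(fragment_spec("x", "C2H4", 3), "n_carbons")
  expect_error(fragment_spec("x", "H2O", 1), "n_carbons")
  fr <- fragment_spec("pyruvate", "C6H12O2Si", 3, base_mz = 174)
  expect_s3_class(fr, "fragment_spec")
  expect_equal(fr$n_carbons, 3L)
})

test_that("fragment library round-trips through TSV", {
  path <- system.file("extdata", "fragment_library_example.tsv", package = "tracemet")
  lib <- read_fragment_library(path)
  expect_true("proline" %in% names(lib))
  expect_equal(lib$proline$n_carbons, 5L)
  expect_equal(format(lib$lactate$fragment_formula), "C12H27O3Si2")
})
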