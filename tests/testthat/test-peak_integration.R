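make_trace <- function(t, y, met = "m", shift = 0L) ion_trace(met, shift, t, y)

test_that("two-point linear baseline removes constants and ramps but keeps peaks", {
  t <- 0:60
  b <- integration_bounds("m", 10, 50)

  flat <- baseline_correct(make_trace(t, rep(100, length(t))), b)
  inside <- t >= 10 & t <= 50
  expect_true(all(flat$intensity[inside] == 0))
  expect_true(all(flat$intensity[!inside] == 100))

  peak <- ifelse(abs(t - 30) <= 10, 5 * (10 - abs(t - 30)), 0)  # triangle
  tri <- baseline_correct(make_trace(t, peak), b)
  expect_equal(tri$intensity, peak)

  ramp <- 2 * t + 7
  both <- baseline_correct(make_trace(t, peak + ramp), b)
  expect_equal(both$intensity[inside], peak[inside], tolerance = 1e-9)
})

test_that("baseline correction rejects bounds outside the trace span", {
  tr <- make_trace(10:20, rep(1, 11))
  expect_error(baseline_correct(tr, integration_bounds("m", 5, 15)), "outside")
})

test_that("trapezoidal integration matches known areas", {
  t <- seq(0, 60, by = 0.05)
  b <- integration_bounds("m", 10, 50)
  rect <- as.numeric(t >= 20 & t <= 30)
  a <- integrate_ion(make_trace(t, rect), b)
  expect_equal(a, 10, tolerance = 0.02)  # sampling error at the edges

  expect_equal(integrate_ion(make_trace(t, rep(0, length(t))), b), 0)

  # Gaussian peak vs closed form at 1 Hz sampling
  t1 <- 0:60
  g <- 1000 * dnorm(t1, mean = 30, sd = 3)
  got <- integrate_ion(make_trace(t1, g), integration_bounds("m", 10, 50))
  want <- 1000 * (pnorm(50, 30, 3) - pnorm(10, 30, 3))
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("negative net areas clip to zero with a warning", {
  t <- 0:20
  tr <- make_trace(t, -abs(10 - t))
  expect_warning(a <- integrate_ion(tr, integration_bounds("m", 2, 18)),
                 "clipped")
  expect_equal(a, 0)
})

test_that("extract_mid assembles shift-ordered areas and checks completeness", {
  t <- seq(0, 60, by = 0.1)
  b <- integration_bounds("m", 10, 50)
  mk <- function(shift, scale) {
    make_trace(t, scale * as.numeric(t >= 25 & t <= 35), shift = shift)
  }
  mid <- extract_mid(list(mk(1L, 1), mk(0L, 3)), b)  # deliberately unordered
  expect_equal(mid$areas[1] / mid$areas[2], 3, tolerance = 1e-6)
  expect_length(mid$areas, 2)
  expect_error(extract_mid(list(mk(0L, 1), mk(2L, 1)), b), "M\\+1")
})

test_that("areas are scale-equivariant in intensity", {
  t <- seq(0, 60, by = 0.2)
  y <- dnorm(t, 30, 4) + 0.01 * t
  b <- integration_bounds("m", 10, 50)
  a1 <- integrate_ion(baseline_correct(make_trace(t, y), b), b)
  a5 <- integrate_ion(baseline_correct(make_trace(t, 5 * y), b), b)
  expect_equal(a5, 5 * a1, tolerance = 1e-12)
})

test_that("synthetic chromatograms round-trip the generating MID ratios", {
  td <- tempfile()
  res <- simulate_study(default_study_design(),
                        noise_model(sigma = 0, seed = 3), dir = td,
                        chromatograms = TRUE)
  chroms <- read_chromatograms(file.path(td, "chromatograms.tsv"))
  bounds <- read_bounds(file.path(td, "bounds.tsv"))
  areas <- read.delim(file.path(td, "ion_areas.tsv"))
  smp <- names(chroms)[1]
  for (met in c("proline", "lactate")) {
    got <- extract_mid(chroms[[smp]][[met]], bounds[[met]])$areas
    want <- areas$area[areas$sample == smp & areas$metabolite == met][
      order(areas$mass_shift[areas$sample == smp & areas$metabolite == met])]
    expect_equal(got / sum(got), want / sum(want), tolerance = 5e-3)
  }
})
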