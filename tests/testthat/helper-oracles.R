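# Shared fixtures and independent oracles used across the test files.

# toy isotope tables ---------------------------------------------------------

# carbon-only table with configurable 13C abundance (0 = pure 12C)
toy_carbon_table <- function(p13 = 0.0107) {
  if (p13 == 0) {
    tab <- data.frame(element = "C", mass_shift = 0L, abundance = 1)
  } else {
    tab <- data.frame(element = c("C", "C"), mass_shift = c(0L, 1L),
                      abundance = c(1 - p13, p13))
  }
  isotope_table(tab)
}

# exhaustive per-atom enumeration oracle for isotopologue distributions:
# iterates over every assignment of an isotope to every atom, summing
# probabilities by total mass shift. Independent of the convolution code.
enumerate_distribution <- function(formula, isotopes, max_shift) {
  atoms <- unlist(mapply(function(el, n) rep(el, n), names(formula),
                         as.integer(formula), SIMPLIFY = FALSE))
  choices <- lapply(atoms, function(el) {
    sub <- isotopes[isotopes$element == el, ]
    seq_len(nrow(sub))
  })
  out <- numeric(max_shift + 1L)
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    p <- 1; shift <- 0L
    for (a in seq_along(atoms)) {
      sub <- isotopes[isotopes$element == atoms[a], ]
      k <- grid[r, a]
      p <- p * sub$abundance[k]
      shift <- shift + sub$mass_shift[k]
    }
    if (shift <= max_shift) out[shift + 1L] <- out[shift + 1L] + p
  }
  out
}

# brute-force grid search oracle for the constrained MID solve: enumerate
# simplex directions at the given step, fit the overall scale analytically
# (the solve has a free total-signal scale), keep the best direction
grid_search_mid <- function(M, meas, step = 0.01) {
  best <- NULL; best_err <- Inf
  fs <- seq(0, 1, by = step)
  for (a in fs) for (b in fs) {
    if (a + b > 1 + 1e-12) next
    u <- c(a, b, 1 - a - b)
    mu <- as.numeric(M %*% u)
    t <- sum(mu * meas) / sum(mu * mu)
    err <- sqrt(sum((t * mu - meas)^2))
    if (err < best_err) { best_err <- err; best <- u }
  }
  best
}

# a realistic TBDMS-sized fragment for round-trip tests
tbdms_fragment <- function(n = 5L) {
  fragment_spec("testmet", "C16H34NO2Si2", n_carbons = n)
}

# random probability vector on the simplex
random_mid <- function(n) {
  x <- stats::rexp(n + 1L)
  x / sum(x)
}

# minimal qPCR Ct table with one target gene and fixed per-condition dCt
make_ct <- function(dct_by_cond, reps = 2, ref_ct = 16, gene = "G",
                    reference = "RPL19") {
  rows <- list()
  for (cond in names(dct_by_cond)) {
    for (r in seq_len(reps)) {
      smp <- paste0(cond, "_r", r)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, condition = cond, gene = reference, ct = ref_ct)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, condition = cond, gene = gene,
        ct = ref_ct + dct_by_cond[[cond]])
    }
  }
  do.call(rbind, rows)
}
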