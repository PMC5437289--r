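# Elemental formulas, isotope abundance tables and exact nominal-mass
# isotopologue distributions for derivatized metabolite fragments.

KNOWN_ELEMENTS <- c("C", "H", "N", "O", "P", "S", "Si", "F", "Cl", "Br", "B", "Se")

#' Parse an elemental formula string
#'
#' Parses Hill-style formula strings such as \code{"C11H26NO2Si"} into an
#' \code{elemental_formula} object (a named integer vector of atom counts).
#' Counts default to 1; repeated element tokens are summed.
#'
#' @param text Formula string, e.g. \code{"C6H12O6"} or \code{"C2"}.
#' @return An object of class \code{elemental_formula}: named integer vector
#'   of atom counts.
#' @examples
#' parse_formula("C11H26NO2Si")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  # tokenize: element symbol (capital + optional lowercase) + optional count
  pat <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  toks <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  if (sum(nchar(toks)) != nchar(text)) {
    # find the offending span: first char not covered by tokens
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(m)) {
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
    }
    bad <- which(!covered)[1]
    stop(sprintf("malformed formula '%s': cannot parse at position %d ('%s')",
                 text, bad, substr(text, bad, bad)))
  }
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% KNOWN_ELEMENTS) {
      stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text))
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  elemental_formula(counts)
}

#' Construct an elemental formula from atom counts
#'
#' @param counts Named integer vector or list, element symbol -> atom count.
#' @return An \code{elemental_formula} object.
#' @export
elemental_formula <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by element symbol")
  }
  bad <- setdiff(names(counts), KNOWN_ELEMENTS)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("atom counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  structure(counts, class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  ord <- names(x)
  # Hill order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), ord), sort(setdiff(ord, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    n <- x[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format(x), "\n")
  invisible(x)
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  all_el <- union(names(e1), names(e2))
  counts <- vapply(all_el, function(e) {
    (if (e %in% names(e1)) e1[[e]] else 0L) + (if (e %in% names(e2)) e2[[e]] else 0L)
  }, integer(1))
  elemental_formula(counts)
}

#' Default natural isotope abundance table
#'
#' Representative terrestrial isotopic abundances for the elements occurring
#' in MOX/TBDMS-derivatized metabolite fragments (C, H, N, O, S, Si),
#' indexed by nominal mass shift relative to the lightest isotope.
#'
#' @return A data.frame with columns \code{element}, \code{mass_shift},
#'   \code{abundance} of class \code{isotope_table}.
#' @export
default_isotopes <- function() {
  tab <- data.frame(
    element = c("C", "C",
                "H", "H",
                "N", "N",
                "O", "O", "O",
                "S", "S", "S", "S",
                "Si", "Si", "Si"),
    mass_shift = c(0L, 1L,
                   0L, 1L,
                   0L, 1L,
                   0L, 1L, 2L,
                   0L, 1L, 2L, 4L,
                   0L, 1L, 2L),
    abundance = c(0.9893, 0.0107,
                  0.999885, 0.000115,
                  0.99636, 0.00364,
                  0.99757, 0.00038, 0.00205,
                  0.9499, 0.0075, 0.0425, 0.0001,
                  0.92223, 0.04685, 0.03092),
    stringsAsFactors = FALSE
  )
  validate_isotope_table(tab)
}

#' Read an isotope abundance table from TSV
#'
#' Expects columns \code{element}, \code{mass_shift}, \code{abundance}.
#'
#' @param path Path to a tab-separated file.
#' @return A validated \code{isotope_table} data.frame.
#' @export
read_isotope_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element", "mass_shift", "abundance")
  if (!all(need %in% names(tab))) {
    stop("isotope table must have columns: ", paste(need, collapse = ", "))
  }
  validate_isotope_table(tab[need])
}

#' Validate and classify an isotope abundance data frame
#'
#' Checks that per-element abundances sum to 1, mass shifts start at 0 and
#' are unique, and no abundance is negative.
#'
#' @param tab Data frame with columns \code{element}, \code{mass_shift},
#'   \code{abundance}.
#' @return The table with class \code{isotope_table}.
#' @export
isotope_table <- function(tab) validate_isotope_table(tab)

validate_isotope_table <- function(tab) {
  for (el in unique(tab$element)) {
    sub <- tab[tab$element == el, ]
    sub <- sub[order(sub$mass_shift), ]
    if (sub$mass_shift[1] != 0L) stop("element ", el, ": mass shifts must start at 0")
    if (any(duplicated(sub$mass_shift))) stop("element ", el, ": duplicated mass shift")
    if (abs(sum(sub$abundance) - 1) > 1e-9) {
      stop(sprintf("element %s: abundances sum to %.10f, expected 1", el, sum(sub$abundance)))
    }
    if (any(sub$abundance < 0)) stop("element ", el, ": negative abundance")
  }
  class(tab) <- c("isotope_table", "data.frame")
  tab
}

# per-element single-atom shift distribution as a dense numeric vector
.atom_dist <- function(isotopes, element) {
  sub <- isotopes[isotopes$element == element, ]
  if (!nrow(sub)) {
    stop("element '", element, "' present in formula but absent from isotope table")
  }
  d <- numeric(max(sub$mass_shift) + 1L)
  d[sub$mass_shift + 1L] <- sub$abundance
  d
}

# discrete (linear) convolution of two probability vectors; direct O(n*m)
# rather than FFT so results are exact to machine precision on small vectors
conv <- function(a, b) {
  if (length(a) == 1L) return(a * b)
  if (length(b) == 1L) return(b * a)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# distribution of the sum of `count` iid copies of single-atom dist `d`,
# by binary exponentiation on convolution
.pow_dist <- function(d, count) {
  out <- 1
  base <- d
  while (count > 0L) {
    if (count %% 2L == 1L) out <- conv(out, base)
    base <- conv(base, base)
    count <- count %/% 2L
  }
  if (length(out) == 1L && identical(out, 1)) out <- c(1)
  out
}

#' Natural isotopologue distribution of a fragment
#'
#' Exact nominal-mass distribution of mass shifts for a molecular fragment
#' under natural isotope abundances, computed by per-element multinomial
#' expansion (repeated-squaring convolution of single-atom distributions)
#' combined across elements by discrete convolution, then truncated.
#'
#' @param formula An \code{elemental_formula} (or formula string).
#' @param isotopes An \code{isotope_table}; defaults to
#'   \code{\link{default_isotopes}}.
#' @param max_shift Largest mass shift retained (integer >= 0). The
#'   probability mass beyond it is returned as attribute \code{"tail_mass"}.
#' @param tail_warn Log a message when the truncated tail mass exceeds this
#'   (default 1e-6); set \code{Inf} where truncation is deliberate.
#' @return Numeric vector of probabilities over shifts \code{0..max_shift},
#'   with attribute \code{tail_mass}.
#' @examples
#' natural_distribution(parse_formula("C2"), max_shift = 2)
#' @export
natural_distribution <- function(formula, isotopes = default_isotopes(),
                                 max_shift = 4L, tail_warn = 1e-6) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "elemental_formula"))
  if (max_shift < 0) stop("max_shift must be >= 0")
  d <- 1
  for (el in names(formula)) {
    d <- conv(d, .pow_dist(.atom_dist(isotopes, el), formula[[el]]))
  }
  if (length(d) == 1L) d <- c(1)
  full <- d
  keep <- seq_len(min(length(full), max_shift + 1L))
  out <- numeric(max_shift + 1L)
  out[keep] <- full[keep]
  tail_mass <- max(0, sum(full) - sum(out))
  if (tail_mass > tail_warn) {
    message(sprintf("natural_distribution: truncation tail mass %.3g beyond shift %d",
                    tail_mass, max_shift))
  }
  attr(out, "tail_mass") <- tail_mass
  out
}

#' Define a measured fragment
#'
#' A fragment specification ties a metabolite to the elemental formula of its
#' measured (derivatized) fragment, the number of tracer-relevant parent
#' carbons \code{n}, and the nominal m/z of M+0.
#'
#' @param metabolite Metabolite name.
#' @param fragment_formula \code{elemental_formula} or formula string of the
#'   full derivatized fragment.
#' @param n_carbons Number of parent-metabolite carbons in the fragment.
#' @param base_mz Nominal m/z of the unlabeled fragment (integer; optional).
#' @return A \code{fragment_spec} object.
#' @export
fragment_spec <- function(metabolite, fragment_formula, n_carbons, base_mz = NA_integer_) {
  if (is.character(fragment_formula)) fragment_formula <- parse_formula(fragment_formula)
  n_carbons <- as.integer(n_carbons)
  total_c <- if ("C" %in% names(fragment_formula)) fragment_formula[["C"]] else 0L
  if (n_carbons < 1L || n_carbons > total_c) {
    stop(sprintf("n_carbons (%d) must be in [1, %d] for fragment %s",
                 n_carbons, total_c, format(fragment_formula)))
  }
  structure(list(metabolite = metabolite, fragment_formula = fragment_formula,
                 n_carbons = n_carbons, base_mz = as.integer(base_mz)),
            class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("<fragment_spec> %s  %s  n=%d  m/z %s\n", x$metabolite,
              format(x$fragment_formula), x$n_carbons,
              ifelse(is.na(x$base_mz), "?", x$base_mz)))
  invisible(x)
}

#' Read a fragment library from TSV
#'
#' Expects columns \code{metabolite}, \code{fragment_formula},
#' \code{n_carbons} and optionally \code{base_mz}.
#'
#' @param path Path to a tab-separated fragment library.
#' @return Named list of \code{fragment_spec}, keyed by metabolite.
#' @export
read_fragment_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "fragment_formula", "n_carbons")
  if (!all(need %in% names(tab))) {
    stop("fragment library must have columns: ", paste(need, collapse = ", "))
  }
  if (!"base_mz" %in% names(tab)) tab$base_mz <- NA_integer_
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    fragment_spec(tab$metabolite[i], tab$fragment_formula[i],
                  tab$n_carbons[i], tab$base_mz[i])
  })
  names(specs) <- tab$metabolite
  specs
}
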