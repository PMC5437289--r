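# Natural-abundance (and tracer-purity) correction matrices and the
# constrained inversion that recovers tracer-only MIDs from measured areas.

#' Build the natural-abundance correction matrix for a fragment
#'
#' Column j (j = 0..n) is the predicted measured isotopologue distribution
#' when exactly j of the fragment's tracer-relevant carbons carry the label:
#' the convolution of (a) the natural isotopologue distribution of the
#' fragment with those j carbons removed from the natural pool, and (b) the
#' binomial distribution of label incorporation for j tracer atoms at the
#' stated isotopic enrichment (a point mass at shift j when \code{purity} is
#' \code{NULL}), truncated to n+1 measured masses.
#'
#' @param fragment A \code{\link{fragment_spec}}.
#' @param isotopes An isotope abundance table (default
#'   \code{\link{default_isotopes}}).
#' @param purity Tracer isotopic enrichment per atom, in (0.5, 1], or
#'   \code{NULL} to skip purity correction (the default behaviour of the
#'   pipeline).
#' @return A \code{correction_matrix} object: (n+1) x (n+1) matrix with the
#'   fragment attached.
#' @examples
#' fr <- fragment_spec("pyruvate", "C6H12O2Si", n_carbons = 3)
#' cm <- build_correction_matrix(fr)
#' colSums(cm$matrix)
#' @export
build_correction_matrix <- function(fragment, isotopes = default_isotopes(),
                                    purity = NULL) {
  stopifnot(inherits(fragment, "fragment_spec"))
  n <- fragment$n_carbons
  if (!is.null(purity)) {
    if (!(purity > 0.5 && purity <= 1)) {
      stop("tracer purity must be in (0.5, 1], got ", purity)
    }
  }
  M <- matrix(0, nrow = n + 1L, ncol = n + 1L)
  for (j in 0:n) {
    counts <- unclass(fragment$fragment_formula)
    counts[["C"]] <- counts[["C"]] - j
    rest <- if (counts[["C"]] == 0L && length(counts) == 1L) {
      c(1)  # carbon-only fragment fully labeled: nothing left in natural pool
    } else {
      # truncation to the measured window is deliberate here; the column
      # sums report how much tail is cut
      natural_distribution(elemental_formula(counts[counts > 0]),
                           isotopes, max_shift = n, tail_warn = Inf)
    }
    lab <- if (is.null(purity)) {
      c(rep(0, j), 1)                      # all j tracer atoms heavy
    } else {
      stats::dbinom(0:j, size = j, prob = purity)
    }
    col <- conv(as.numeric(rest), lab)
    M[, j + 1L] <- col[seq_len(n + 1L)]
  }
  cs <- colSums(M)
  if (any(cs < 0.5)) {
    stop("correction-matrix column sums below 0.5; fragment formula or isotope table implausible")
  }
  structure(list(fragment = fragment, matrix = M, purity = purity),
            class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf("<correction_matrix> %s (%s), n=%d, purity=%s\n",
              x$fragment$metabolite, format(x$fragment$fragment_formula),
              x$fragment$n_carbons,
              if (is.null(x$purity)) "none" else format(x$purity)))
  print(round(x$matrix, 5))
  invisible(x)
}

#' Correct a measured MID for natural isotope abundance
#'
#' Normalizes raw areas to fractions and solves
#' \code{matrix \%*\% x = measured} for the tracer-only mass distribution
#' vector, by non-negative least squares (default) or plain inversion.
#' The solution is renormalized to sum to 1; the residual norm and the mass
#' removed by the non-negativity clip are recorded for QC.
#'
#' @param raw A \code{raw_mid} (list with \code{metabolite}, \code{areas}) or
#'   a bare numeric vector of areas.
#' @param cm A \code{\link{correction_matrix}} of matching dimension.
#' @param method \code{"nnls"} (default) or \code{"solve"} (unconstrained
#'   inversion, negative entries clipped afterwards).
#' @param residual_threshold Residual norm above which the result is flagged
#'   in QC output (not fatal).
#' @return A \code{corrected_mid}: list with \code{metabolite},
#'   \code{fractions} (sums to 1), \code{residual_norm}, \code{clipped_mass},
#'   \code{flagged}.
#' @export
correct_mid <- function(raw, cm, method = c("nnls", "solve"),
                        residual_threshold = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(cm, "correction_matrix"))
  if (is.numeric(raw)) raw <- list(metabolite = cm$fragment$metabolite, areas = raw)
  areas <- raw$areas
  if (length(areas) != ncol(cm$matrix)) {
    stop(sprintf("raw MID length %d does not match matrix dimension %d",
                 length(areas), ncol(cm$matrix)))
  }
  tot <- sum(areas)
  if (tot <= 0) stop("all-zero raw MID for ", raw$metabolite, ": undefined")
  meas <- areas / tot
  if (method == "nnls") {
    fit <- pracma::lsqnonneg(cm$matrix, meas)
    x <- fit$x
    resid_norm <- sqrt(sum((cm$matrix %*% x - meas)^2))
    clipped <- 0
  } else {
    x <- solve(cm$matrix, meas)
    resid_norm <- 0
    clipped <- -sum(x[x < 0])
    x[x < 0] <- 0
  }
  if (sum(x) <= 0) stop("degenerate correction for ", raw$metabolite)
  fractions <- x / sum(x)
  structure(list(metabolite = raw$metabolite, fractions = as.numeric(fractions),
                 residual_norm = resid_norm, clipped_mass = clipped,
                 flagged = resid_norm > residual_threshold),
            class = "corrected_mid")
}

#' @export
print.corrected_mid <- function(x, ...) {
  cat(sprintf("<corrected_mid> %s  [%s]  resid=%.3g%s\n", x$metabolite,
              paste(sprintf("%.4f", x$fractions), collapse = ", "),
              x$residual_norm, if (x$flagged) "  FLAGGED" else ""))
  invisible(x)
}
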