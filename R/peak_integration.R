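# Raw ion chromatograms -> uncorrected mass distribution vectors:
# shared integration bounds, two-point linear baseline, trapezoidal areas.

#' Construct an ion trace
#'
#' One extracted-ion chromatogram for a single metabolite fragment mass.
#'
#' @param metabolite Metabolite name.
#' @param mass_shift Integer isotopologue shift (0..n).
#' @param time_s Numeric vector of retention times (seconds), strictly
#'   increasing.
#' @param intensity Numeric vector of detector counts, same length.
#' @return An \code{ion_trace} object.
#' @export
ion_trace <- function(metabolite, mass_shift, time_s, intensity) {
  stopifnot(length(time_s) == length(intensity))
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  structure(list(metabolite = metabolite, mass_shift = as.integer(mass_shift),
                 time_s = as.numeric(time_s), intensity = as.numeric(intensity)),
            class = "ion_trace")
}

#' Integration bounds for a metabolite peak
#'
#' One bounds record per metabolite, shared across all samples and all
#' isotopologue masses, so that every ion of a peak is integrated over the
#' identical retention-time window.
#'
#' @param metabolite Metabolite name.
#' @param t_start,t_end Window in seconds, \code{t_start < t_end}.
#' @return An \code{integration_bounds} object.
#' @export
integration_bounds <- function(metabolite, t_start, t_end) {
  if (!(t_start < t_end)) stop("t_start must be < t_end")
  structure(list(metabolite = metabolite, t_start = t_start, t_end = t_end),
            class = "integration_bounds")
}

.check_bounds <- function(trace, bounds) {
  if (bounds$t_start < min(trace$time_s) || bounds$t_end > max(trace$time_s)) {
    stop(sprintf("bounds [%g, %g] outside trace span [%g, %g] for %s",
                 bounds$t_start, bounds$t_end, min(trace$time_s),
                 max(trace$time_s), trace$metabolite))
  }
}

# linear interpolation of trace intensity at time t
.interp <- function(trace, t) {
  stats::approx(trace$time_s, trace$intensity, xout = t, rule = 1)$y
}

#' Subtract a two-point linear baseline
#'
#' Draws the straight line through the trace values at \code{t_start} and
#' \code{t_end} and subtracts it from every point inside the window; points
#' outside the window are untouched.
#'
#' @param trace An \code{ion_trace}.
#' @param bounds An \code{integration_bounds} lying within the trace span.
#' @return The baseline-corrected \code{ion_trace}.
#' @export
baseline_correct <- function(trace, bounds) {
  .check_bounds(trace, bounds)
  y0 <- .interp(trace, bounds$t_start)
  y1 <- .interp(trace, bounds$t_end)
  slope <- (y1 - y0) / (bounds$t_end - bounds$t_start)
  inside <- trace$time_s >= bounds$t_start & trace$time_s <= bounds$t_end
  base <- y0 + slope * (trace$time_s[inside] - bounds$t_start)
  trace$intensity[inside] <- trace$intensity[inside] - base
  trace
}

#' Trapezoidal peak area within bounds
#'
#' Integrates a (baseline-corrected) ion trace over the integration window by
#' the trapezoidal rule, interpolating the endpoints. Negative net areas are
#' clipped to zero with a warning (signal below baseline is noise).
#'
#' @param trace An \code{ion_trace}, typically after
#'   \code{\link{baseline_correct}}.
#' @param bounds An \code{integration_bounds}.
#' @return Peak area (arbitrary units, >= 0).
#' @export
integrate_ion <- function(trace, bounds) {
  .check_bounds(trace, bounds)
  inside <- trace$time_s > bounds$t_start & trace$time_s < bounds$t_end
  t <- c(bounds$t_start, trace$time_s[inside], bounds$t_end)
  y <- c(.interp(trace, bounds$t_start), trace$intensity[inside],
         .interp(trace, bounds$t_end))
  if (length(t) < 2L) stop("fewer than 2 samples inside integration bounds")
  area <- sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  if (area < 0) {
    warning(sprintf("negative area (%.4g) clipped to 0 for %s M+%d",
                    area, trace$metabolite, trace$mass_shift))
    area <- 0
  }
  area
}

#' Extract a raw mass distribution vector
#'
#' Applies baseline correction and integration with the metabolite's shared
#' bounds to one trace per isotopologue mass, assembling the areas in shift
#' order M+0..M+n.
#'
#' @param traces List of \code{ion_trace}, one per mass shift 0..n, all for
#'   the same metabolite.
#' @param bounds The metabolite's \code{integration_bounds}.
#' @return A \code{raw_mid}: list with \code{metabolite} and \code{areas}
#'   (length n+1).
#' @export
extract_mid <- function(traces, bounds) {
  mets <- unique(vapply(traces, `[[`, character(1), "metabolite"))
  if (length(mets) != 1L) stop("traces span multiple metabolites: ",
                               paste(mets, collapse = ", "))
  shifts <- vapply(traces, `[[`, integer(1), "mass_shift")
  n <- max(shifts)
  missing <- setdiff(0:n, shifts)
  if (length(missing) || any(duplicated(shifts))) {
    stop("need exactly one trace per mass shift 0..", n,
         if (length(missing)) paste0("; missing M+", paste(missing, collapse = ", M+")))
  }
  ord <- order(shifts)
  areas <- unname(vapply(traces[ord], function(tr) {
    integrate_ion(baseline_correct(tr, bounds), bounds)
  }, numeric(1)))
  structure(list(metabolite = mets, areas = areas), class = "raw_mid")
}

#' Read long-format chromatograms from TSV
#'
#' Columns: \code{sample}, \code{metabolite}, \code{mass_shift},
#' \code{time_s}, \code{intensity}.
#'
#' @param path Path to the TSV file.
#' @return Nested list: \code{[[sample]][[metabolite]]} -> list of
#'   \code{ion_trace} per mass shift.
#' @export
read_chromatograms <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "metabolite", "mass_shift", "time_s", "intensity")
  if (!all(need %in% names(tab))) {
    stop("chromatogram file must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (smp in unique(tab$sample)) {
    st <- tab[tab$sample == smp, ]
    out[[smp]] <- lapply(split(st, st$metabolite), function(mt) {
      lapply(split(mt, mt$mass_shift), function(ms) {
        ms <- ms[order(ms$time_s), ]
        ion_trace(ms$metabolite[1], ms$mass_shift[1], ms$time_s, ms$intensity)
      })
    })
  }
  out
}

#' Read integration bounds from TSV
#'
#' Columns: \code{metabolite}, \code{t_start_s}, \code{t_end_s}.
#'
#' @param path Path to the TSV file.
#' @return Named list of \code{integration_bounds} keyed by metabolite.
#' @export
read_bounds <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "t_start_s", "t_end_s")
  if (!all(need %in% names(tab))) {
    stop("bounds file must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    integration_bounds(tab$metabolite[i], tab$t_start_s[i], tab$t_end_s[i])
  })
  names(out) <- tab$metabolite
  out
}
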