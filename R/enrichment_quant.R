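# Per-metabolite headline quantities: total carbon contribution, normalized
# levels, ratios, fold-to-control, media exchange rates, enrichment QC.

#' Total contribution of labeled carbon
#'
#' The weighted-average fraction of a metabolite's carbons derived from the
#' tracer: sum(i * m_i) / (n * sum(m_i)) over isotopologues M+0..M+n, where
#' n is the number of carbon atoms of the metabolite and m the abundance of
#' each mass.
#'
#' @param mid A \code{corrected_mid} or numeric MID vector of length n+1.
#' @param n Number of metabolite carbons; defaults to \code{length(mid) - 1}.
#' @return Total contribution, a fraction in [0, 1].
#' @examples
#' total_contribution(c(0.25, 0.5, 0.25))  # 0.5
#' @export
total_contribution <- function(mid, n = NULL) {
  if (inherits(mid, "corrected_mid")) mid <- mid$fractions
  if (is.null(n)) n <- length(mid) - 1L
  if (n < 1L) stop("total contribution undefined for n = 0")
  if (length(mid) != n + 1L) {
    stop(sprintf("MID length %d does not match n+1 = %d", length(mid), n + 1L))
  }
  s <- sum(mid)
  if (s <= 0) stop("MID sums to zero")
  sum((0:n) * mid) / (n * s)
}

#' Metabolite level normalized to internal standard and biomass
#'
#' @param area Integrated ion area of the metabolite (arbitrary units).
#' @param istd_area Internal-standard area in the same sample (> 0).
#' @param biomass mg protein (in vitro) or mg tissue (in vivo), > 0.
#' @param biomass_kind Provenance of the denominator, \code{"protein"} or
#'   \code{"tissue"}; recorded, never mixed within a comparison.
#' @return A \code{normalized_level}: numeric value with attribute
#'   \code{biomass_kind}.
#' @export
normalized_level <- function(area, istd_area, biomass,
                             biomass_kind = c("protein", "tissue")) {
  biomass_kind <- match.arg(biomass_kind)
  if (any(istd_area <= 0)) stop("internal-standard area must be > 0")
  if (any(biomass <= 0)) stop("biomass must be > 0")
  if (any(area < 0)) stop("area must be >= 0")
  structure(area / istd_area / biomass, biomass_kind = biomass_kind,
            class = "normalized_level")
}

#' Ratio of two normalized levels
#'
#' For paired readouts such as NADPH/NADP+; internal-standard and biomass
#' terms cancel when both levels share denominators.
#'
#' @param level_a,level_b Normalized levels (or bare numerics); \code{level_b
#'   > 0}.
#' @return Dimensionless ratio a/b.
#' @export
ratio_metric <- function(level_a, level_b) {
  a <- as.numeric(level_a); b <- as.numeric(level_b)
  ka <- attr(level_a, "biomass_kind"); kb <- attr(level_b, "biomass_kind")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb)) {
    stop("ratio across different biomass denominators (", ka, " vs ", kb, ")")
  }
  if (any(b == 0)) stop("zero denominator in ratio")
  a / b
}

#' Fold change relative to a control group
#'
#' Divides every sample's level by the mean of the control group, so the
#' control-group mean of the output is 1.
#'
#' @param levels Numeric vector of (normalized) levels.
#' @param group Group label per sample, same length.
#' @param control_group Label of the control group.
#' @return Numeric vector of folds, named as \code{levels}.
#' @export
relative_to_control <- function(levels, group, control_group) {
  stopifnot(length(levels) == length(group))
  ctrl <- as.numeric(levels)[group == control_group]
  if (!length(ctrl)) stop("control group '", control_group, "' is empty")
  m <- mean(ctrl)
  if (m == 0) stop("control-group mean is zero")
  as.numeric(levels) / m
}

#' Media-based uptake/secretion rate
#'
#' Net exchange rate inferred from fresh-vs-spent media concentrations,
#' normalized to biomass and culture time. Sign convention: positive =
#' uptake (consumption), negative = secretion.
#'
#' @param conc_fresh,conc_spent Metabolite concentration in fresh and spent
#'   medium (micromolar).
#' @param volume_ml Culture volume (ml).
#' @param span_h Culture duration (h), > 0.
#' @param biomass_mg End-point protein mass (mg), > 0.
#' @return Exchange rate in nmol per mg protein per hour.
#' @examples
#' exchange_rate(150, 100, volume_ml = 2, span_h = 120, biomass_mg = 1)
#' @export
exchange_rate <- function(conc_fresh, conc_spent, volume_ml, span_h, biomass_mg) {
  if (any(c(conc_fresh, conc_spent, volume_ml) < 0)) {
    stop("concentrations and volume must be >= 0")
  }
  if (any(span_h <= 0) || any(biomass_mg <= 0)) {
    stop("culture span and biomass must be > 0")
  }
  # uM * ml = nmol
  (conc_fresh - conc_spent) * volume_ml / (biomass_mg * span_h)
}

#' Reference-compartment enrichment QC
#'
#' For in vivo infusions: checks that tracer enrichment in a reference
#' compartment (e.g. blood glucose) is consistent across subjects, via the
#' coefficient of variation of the per-subject total contributions.
#'
#' @param contributions Numeric vector of per-subject total contributions
#'   (>= 2 subjects).
#' @param cv_threshold Maximum acceptable coefficient of variation (fraction;
#'   default 0.10).
#' @return List with \code{cv}, \code{mean}, \code{sd}, \code{n},
#'   \code{pass}.
#' @export
enrichment_qc <- function(contributions, cv_threshold = 0.10) {
  if (length(contributions) < 2L) stop("need >= 2 subjects for enrichment QC")
  m <- mean(contributions)
  s <- stats::sd(contributions)
  cv <- if (m == 0) Inf else s / m
  list(cv = cv, mean = m, sd = s, n = length(contributions),
       pass = cv <= cv_threshold)
}
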