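# qPCR fold change and the statistical decision procedure: F-test-gated
# Student/Welch t-tests, Grubbs single-outlier detection, and the
# change-plus-significance differential filters.

#' Delta-delta-Ct relative expression fold change
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); the fold change of
#' treated vs control is efficiency^-(mean dCt_treated - mean dCt_control),
#' with perfect amplification efficiency 2 by default.
#'
#' @param ct Data frame with columns \code{sample}, \code{condition},
#'   \code{gene}, \code{ct}.
#' @param target Target gene name.
#' @param treated,control Condition labels to compare.
#' @param reference Reference (housekeeping) gene; default \code{"RPL19"}.
#' @param efficiency Amplification efficiency (default 2: perfect doubling
#'   per cycle).
#' @return Fold change (dimensionless) with attribute \code{dct}: the
#'   per-condition mean delta-Ct values.
#' @export
ddct_fold_change <- function(ct, target, treated, control,
                             reference = "RPL19", efficiency = 2) {
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(ct$ct <= 0 | ct$ct >= 45)) stop("Ct values must lie in (0, 45)")
  dct_for <- function(cond) {
    sub <- ct[ct$condition == cond, ]
    tgt <- sub[sub$gene == target, ]
    if (!nrow(tgt)) stop("no Ct rows for gene '", target, "' in condition '", cond, "'")
    vapply(seq_len(nrow(tgt)), function(i) {
      ref <- sub$ct[sub$sample == tgt$sample[i] & sub$gene == reference]
      if (!length(ref)) {
        stop("sample '", tgt$sample[i], "' has no reference-gene (", reference, ") Ct")
      }
      tgt$ct[i] - ref[1]
    }, numeric(1))
  }
  d_treat <- dct_for(treated)
  d_ctrl <- dct_for(control)
  fold <- efficiency^-(mean(d_treat) - mean(d_ctrl))
  attr(fold, "dct") <- c(treated = mean(d_treat), control = mean(d_ctrl))
  fold
}

#' F-test-gated Student/Welch t-test
#'
#' Two-sided F-test on the variance ratio decides the routing: if its p-value
#' falls below \code{gate_alpha} the groups are compared by a two-tailed
#' Welch t-test, otherwise by a two-tailed pooled-variance Student t-test.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param gate_alpha Significance level of the variance gate (default 0.05).
#' @return A \code{gated_ttest} list: \code{statistic}, \code{p_value},
#'   \code{test_used} ("student" or "welch"), \code{f_test_p},
#'   \code{degenerate} flag for zero-variance inputs.
#' @export
variance_gated_ttest <- function(group_a, group_b, gate_alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 values")
  }
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    res <- list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                test_used = "student", f_test_p = 1, degenerate = !same)
    class(res) <- "gated_ttest"
    return(res)
  }
  f <- stats::var.test(group_a, group_b)
  welch <- f$p.value < gate_alpha
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
              test_used = if (welch) "welch" else "student",
              f_test_p = f$p.value, degenerate = FALSE)
  class(res) <- "gated_ttest"
  res
}

#' @export
print.gated_ttest <- function(x, ...) {
  cat(sprintf("<gated_ttest> t=%.4g, p=%.4g (%s; F-test p=%.4g)%s\n",
              x$statistic, x$p_value, x$test_used, x$f_test_p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Grubbs single-outlier test
#'
#' Two-sided single-outlier Grubbs test: G = max |x - mean| / sd, compared to
#' the t-distribution-based critical value at level \code{alpha}. At most one
#' outlier is flagged per call.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @return Index of the outlier, or \code{NULL} if none (including the
#'   zero-variance case).
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) stop("Grubbs test needs >= 3 values")
  s <- stats::sd(values)
  if (s == 0) return(NULL)
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  Gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  if (G > Gcrit) which.max(dev) else NULL
}

#' Filter thresholds for differential depiction
#'
#' Defaults follow the analysis conventions used throughout the package:
#' total-contribution changes > 25% and metabolite-level changes > 27%, each
#' additionally requiring p <= 0.05.
#'
#' @param contribution_change Minimum relative change for contribution-kind
#'   effects (default 0.25).
#' @param level_change Minimum relative change for level-kind effects
#'   (default 0.27).
#' @param alpha Significance threshold (default 0.05).
#' @return A \code{filter_thresholds} list.
#' @export
filter_thresholds <- function(contribution_change = 0.25, level_change = 0.27,
                              alpha = 0.05) {
  for (v in c(contribution_change, level_change, alpha)) {
    if (!(v > 0 && v < 1)) stop("thresholds must lie in (0, 1)")
  }
  structure(list(contribution_change = contribution_change,
                 level_change = level_change, alpha = alpha),
            class = "filter_thresholds")
}

#' Change-plus-significance differential filter
#'
#' For each metabolite, computes the relative change of the group-b mean vs
#' the group-a mean and the variance-gated t-test p-value, and retains the
#' metabolite iff |change| exceeds the kind-specific threshold AND p <= alpha.
#' Direction is the sign of (mean_b - mean_a).
#'
#' @param values Data frame with columns \code{metabolite}, \code{group},
#'   \code{value} (replicate-level measurements).
#' @param group_a,group_b Labels of the baseline and comparison groups.
#' @param kind \code{"contribution"} (threshold 25%) or \code{"level"}
#'   (threshold 27%).
#' @param thresholds A \code{\link{filter_thresholds}} object.
#' @param gate_alpha Variance-gate level passed to
#'   \code{\link{variance_gated_ttest}}.
#' @return Data frame per metabolite: means, \code{rel_change},
#'   \code{f_test_p}, \code{test_used}, \code{p_value}, \code{p_adj_bh}
#'   (supplementary Benjamini-Hochberg column, not used by the filter),
#'   \code{retained}, \code{direction}.
#' @export
differential_filter <- function(values, group_a, group_b,
                                kind = c("contribution", "level"),
                                thresholds = filter_thresholds(),
                                gate_alpha = 0.05) {
  kind <- match.arg(kind)
  need <- c("metabolite", "group", "value")
  if (!all(need %in% names(values))) {
    stop("values must have columns: ", paste(need, collapse = ", "))
  }
  thr <- if (kind == "contribution") thresholds$contribution_change else thresholds$level_change
  rows <- lapply(unique(values$metabolite), function(met) {
    a <- values$value[values$metabolite == met & values$group == group_a]
    b <- values$value[values$metabolite == met & values$group == group_b]
    if (length(a) < 2L || length(b) < 2L) {
      stop("metabolite '", met, "': need >= 2 replicates per condition")
    }
    if (mean(a) == 0) {
      warning("metabolite '", met, "': zero baseline mean, skipped")
      return(NULL)
    }
    tt <- variance_gated_ttest(a, b, gate_alpha = gate_alpha)
    change <- (mean(b) - mean(a)) / mean(a)
    data.frame(metabolite = met, mean_a = mean(a), mean_b = mean(b),
               rel_change = change, f_test_p = tt$f_test_p,
               test_used = tt$test_used, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$retained <- abs(out$rel_change) > thr & out$p_value <= thresholds$alpha
  out$direction <- sign(out$mean_b - out$mean_a)
  rownames(out) <- NULL
  out
}
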