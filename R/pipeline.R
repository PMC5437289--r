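# End-to-end orchestration: validated run configuration, correction stage,
# analysis stage, simulation stage. All tabular I/O is headered TSV.

#' Build and validate a run configuration
#'
#' Fail-fast: every referenced input file must exist (and the thresholds be
#' valid) before any computation starts.
#'
#' @param dir Study directory holding the standard file names written by
#'   \code{\link{simulate_study}}; individual paths below override it.
#' @param fragment_library,isotope_table,areas,sample_sheet,media,ct Paths to
#'   the input tables (TSV).
#' @param chromatograms,bounds Optional chromatogram input (used instead of
#'   \code{areas} when both are given).
#' @param out_dir Directory for output tables (default \code{dir}).
#' @param thresholds A \code{\link{filter_thresholds}}.
#' @param purity_correction \code{"auto"} (use the sample sheet's declared
#'   purity when present), \code{"off"}, or a numeric purity forced on.
#' @param control_condition,treated_condition Condition labels for the
#'   contrasts (defaults "2D" vs "3D").
#' @param reference_gene qPCR reference gene (default "RPL19").
#' @param seed Seed for the simulate stage.
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(dir = NULL, fragment_library = NULL,
                       isotope_table = NULL, areas = NULL,
                       sample_sheet = NULL, media = NULL, ct = NULL,
                       chromatograms = NULL, bounds = NULL, out_dir = NULL,
                       thresholds = filter_thresholds(),
                       purity_correction = "auto",
                       control_condition = "2D", treated_condition = "3D",
                       reference_gene = "RPL19", seed = 1L) {
  std <- function(given, fname) {
    if (!is.null(given)) return(given)
    if (is.null(dir)) return(NULL)
    f <- file.path(dir, fname)
    if (file.exists(f)) f else NULL
  }
  cfg <- list(
    fragment_library = std(fragment_library, "fragment_library.tsv"),
    isotope_table = std(isotope_table, "isotopes.tsv"),
    areas = std(areas, "ion_areas.tsv"),
    sample_sheet = std(sample_sheet, "sample_sheet.tsv"),
    media = std(media, "media.tsv"),
    ct = std(ct, "ct.tsv"),
    chromatograms = std(chromatograms, "chromatograms.tsv"),
    bounds = std(bounds, "bounds.tsv"),
    out_dir = if (!is.null(out_dir)) out_dir else dir,
    thresholds = thresholds,
    purity_correction = purity_correction,
    control_condition = control_condition,
    treated_condition = treated_condition,
    reference_gene = reference_gene,
    seed = as.integer(seed))
  stopifnot(inherits(thresholds, "filter_thresholds"))
  for (key in c("fragment_library", "isotope_table", "sample_sheet",
                "areas", "media", "ct", "chromatograms", "bounds")) {
    f <- cfg[[key]]
    if (!is.null(f) && !file.exists(f)) {
      stop("config validation failed: ", key, " file not found: ", f)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   \code{\link{run_config}}; threshold values may be given under
#'   \code{thresholds: \{contribution_change, level_change, alpha\}}.
#' @return A validated \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- do.call(filter_thresholds, if (is.null(y$thresholds)) list() else y$thresholds)
  y$thresholds <- thr
  do.call(run_config, y)
}

.write_out <- function(df, cfg, fname) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(cfg$out_dir, fname)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

.sheet_purity <- function(cfg, sheet) {
  pc <- cfg$purity_correction
  if (is.numeric(pc)) return(pc)
  if (identical(pc, "off")) return(NULL)
  if ("purity" %in% names(sheet) && all(is.finite(sheet$purity))) {
    pu <- unique(sheet$purity)
    if (length(pu) > 1L) stop("multiple tracer purities in one run not supported")
    return(pu)
  }
  NULL
}

#' Correction stage: raw areas to corrected MIDs
#'
#' Reads the fragment library, isotope table and ion-area table (or
#' chromatograms, integrating them first), builds one correction matrix per
#' fragment, and solves for the tracer-only MID of every sample x metabolite.
#' Writes \code{corrected_mids.tsv} and \code{qc_report.tsv}.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisible list with data frames \code{corrected} (long format:
#'   sample, metabolite, mass_shift, fraction) and \code{qc}.
#' @export
run_correct <- function(config) {
  stopifnot(inherits(config, "run_config"))
  frags <- read_fragment_library(config$fragment_library)
  iso <- if (is.null(config$isotope_table)) default_isotopes() else
    read_isotope_table(config$isotope_table)
  sheet <- utils::read.delim(config$sample_sheet, stringsAsFactors = FALSE)
  purity <- .sheet_purity(config, sheet)

  if (!is.null(config$chromatograms) && !is.null(config$bounds)) {
    chroms <- read_chromatograms(config$chromatograms)
    bounds <- read_bounds(config$bounds)
    rows <- list()
    for (smp in names(chroms)) {
      for (met in names(chroms[[smp]])) {
        rm <- extract_mid(chroms[[smp]][[met]], bounds[[met]])
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, metabolite = met,
          mass_shift = seq_along(rm$areas) - 1L, area = rm$areas,
          stringsAsFactors = FALSE)
      }
    }
    areas <- do.call(rbind, rows)
  } else {
    if (is.null(config$areas)) stop("no ion-area or chromatogram input configured")
    areas <- utils::read.delim(config$areas, stringsAsFactors = FALSE)
  }
  if (!nrow(areas)) stop("empty input area table")

  cms <- lapply(frags, build_correction_matrix, isotopes = iso, purity = purity)
  cor_rows <- list(); qc_rows <- list()
  for (smp in unique(areas$sample)) {
    for (met in unique(areas$metabolite[areas$sample == smp])) {
      if (!met %in% names(cms)) stop("metabolite '", met, "' missing from fragment library")
      sub <- areas[areas$sample == smp & areas$metabolite == met, ]
      sub <- sub[order(sub$mass_shift), ]
      res <- correct_mid(list(metabolite = met, areas = sub$area), cms[[met]])
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        sample = smp, metabolite = met,
        mass_shift = seq_along(res$fractions) - 1L,
        fraction = res$fractions, stringsAsFactors = FALSE)
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        sample = smp, metabolite = met, residual_norm = res$residual_norm,
        clipped_mass = res$clipped_mass, flagged = res$flagged,
        stringsAsFactors = FALSE)
    }
  }
  corrected <- do.call(rbind, cor_rows)
  qc <- do.call(rbind, qc_rows)
  .write_out(corrected, config, "corrected_mids.tsv")
  .write_out(qc, config, "qc_report.tsv")
  message(sprintf("run_correct: %d sample x metabolite MIDs corrected; median residual %.3g; %d flagged",
                  nrow(qc), stats::median(qc$residual_norm), sum(qc$flagged)))
  invisible(list(corrected = corrected, qc = qc))
}

#' Analysis stage: corrected MIDs to study-level results
#'
#' Computes per-sample total contributions, normalized metabolite levels and
#' folds vs the control condition, media exchange rates, qPCR fold changes,
#' and the variance-gated differential filters for both contribution-kind and
#' level-kind effects. Writes one TSV per result table.
#'
#' @param config A \code{\link{run_config}}.
#' @param corrected Optional corrected-MID data frame from
#'   \code{\link{run_correct}}; read from \code{corrected_mids.tsv} in
#'   \code{out_dir} when omitted.
#' @return Invisible list of data frames: \code{contributions},
#'   \code{levels}, \code{exchange}, \code{qpcr},
#'   \code{filter_contribution}, \code{filter_level}.
#' @export
run_analyze <- function(config, corrected = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(corrected)) {
    f <- file.path(config$out_dir, "corrected_mids.tsv")
    if (!file.exists(f)) stop("no corrected MID table; run run_correct first")
    corrected <- utils::read.delim(f, stringsAsFactors = FALSE)
  }
  frags <- read_fragment_library(config$fragment_library)
  sheet <- utils::read.delim(config$sample_sheet, stringsAsFactors = FALSE)
  miss <- sheet$sample[sheet$istd_area <= 0 | sheet$biomass_mg <= 0]
  if (length(miss)) stop("non-positive normalization denominators for sample(s): ",
                         paste(miss, collapse = ", "))
  cond_of <- stats::setNames(sheet$condition, sheet$sample)

  # total contributions ------------------------------------------------------
  tc_rows <- list()
  for (smp in unique(corrected$sample)) {
    for (met in unique(corrected$metabolite[corrected$sample == smp])) {
      sub <- corrected[corrected$sample == smp & corrected$metabolite == met, ]
      sub <- sub[order(sub$mass_shift), ]
      tc_rows[[length(tc_rows) + 1L]] <- data.frame(
        sample = smp, condition = unname(cond_of[smp]), metabolite = met,
        total_contribution = total_contribution(sub$fraction,
                                                frags[[met]]$n_carbons),
        stringsAsFactors = FALSE)
    }
  }
  contributions <- do.call(rbind, tc_rows)

  # normalized levels and folds ----------------------------------------------
  areas <- utils::read.delim(config$areas, stringsAsFactors = FALSE)
  tot <- stats::aggregate(area ~ sample + metabolite, data = areas, FUN = sum)
  tot <- merge(tot, sheet[c("sample", "condition", "istd_area", "biomass_mg",
                            "biomass_kind")], by = "sample")
  tot$level <- as.numeric(normalized_level(tot$area, tot$istd_area,
                                           tot$biomass_mg,
                                           tot$biomass_kind[1]))
  tot$fold_vs_control <- NA_real_
  for (met in unique(tot$metabolite)) {
    idx <- tot$metabolite == met
    tot$fold_vs_control[idx] <- relative_to_control(
      tot$level[idx], tot$condition[idx], config$control_condition)
  }
  levels_tab <- tot[c("sample", "condition", "metabolite", "level",
                      "fold_vs_control", "biomass_kind")]

  # media exchange rates ------------------------------------------------------
  exchange <- NULL
  if (!is.null(config$media)) {
    med <- utils::read.delim(config$media, stringsAsFactors = FALSE)
    med <- merge(med, sheet[c("sample", "biomass_mg")], by = "sample")
    med$rate_nmol_per_mg_h <- exchange_rate(
      med$conc_fresh_uM, med$conc_spent_uM, med$volume_ml, med$span_h,
      med$biomass_mg)
    exchange <- med[c("sample", "condition", "metabolite",
                      "rate_nmol_per_mg_h")]
  }

  # qPCR fold changes ---------------------------------------------------------
  qpcr <- NULL
  if (!is.null(config$ct)) {
    ct <- utils::read.delim(config$ct, stringsAsFactors = FALSE)
    genes <- setdiff(unique(ct$gene), config$reference_gene)
    qpcr <- do.call(rbind, lapply(genes, function(g) {
      fc <- ddct_fold_change(ct, g, treated = config$treated_condition,
                             control = config$control_condition,
                             reference = config$reference_gene)
      data.frame(gene = g, fold_change = as.numeric(fc),
                 stringsAsFactors = FALSE)
    }))
  }

  # differential filters -------------------------------------------------------
  fc_in <- data.frame(metabolite = contributions$metabolite,
                      group = contributions$condition,
                      value = contributions$total_contribution,
                      stringsAsFactors = FALSE)
  filter_contribution <- differential_filter(
    fc_in, config$control_condition, config$treated_condition,
    kind = "contribution", thresholds = config$thresholds)
  lv_in <- data.frame(metabolite = levels_tab$metabolite,
                      group = levels_tab$condition,
                      value = levels_tab$level, stringsAsFactors = FALSE)
  filter_level <- differential_filter(
    lv_in, config$control_condition, config$treated_condition,
    kind = "level", thresholds = config$thresholds)

  .write_out(contributions, config, "total_contributions.tsv")
  .write_out(levels_tab, config, "normalized_levels.tsv")
  if (!is.null(exchange)) .write_out(exchange, config, "exchange_rates.tsv")
  if (!is.null(qpcr)) .write_out(qpcr, config, "qpcr_folds.tsv")
  .write_out(filter_contribution, config, "filter_contribution.tsv")
  .write_out(filter_level, config, "filter_level.tsv")
  message(sprintf("run_analyze: %d contributions, %d retained (contribution), %d retained (level)",
                  nrow(contributions), sum(filter_contribution$retained),
                  sum(filter_level$retained)))
  invisible(list(contributions = contributions, levels = levels_tab,
                 exchange = exchange, qpcr = qpcr,
                 filter_contribution = filter_contribution,
                 filter_level = filter_level))
}

#' Simulation stage
#'
#' Delegates to \code{\link{simulate_study}} under the config's seed and
#' writes a manifest (file name, md5 checksum) alongside the bundle.
#'
#' @param config A \code{\link{run_config}} (its \code{out_dir} receives the
#'   bundle; its \code{seed} drives generation).
#' @param design,noise_sigma Study design and noise level; defaults are the
#'   standard 2D-vs-3D design at 1 percent multiplicative noise.
#' @param ... Passed to \code{\link{simulate_study}}.
#' @return Invisible result of \code{\link{simulate_study}} plus
#'   \code{manifest}.
#' @export
run_simulate <- function(config, design = default_study_design(),
                         noise_sigma = 0.01, ...) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$out_dir)) stop("out_dir must be set for simulation")
  res <- simulate_study(design,
                        noise_model(sigma = noise_sigma, seed = config$seed),
                        dir = config$out_dir, ...)
  files <- unlist(res$paths)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(res, list(manifest = manifest)))
}

#' Run simulate, correct and analyze end-to-end
#'
#' @param config A \code{\link{run_config}}.
#' @param ... Passed to \code{\link{run_simulate}}.
#' @return Invisible list with the results of all three stages.
#' @export
run_all <- function(config, ...) {
  sim <- run_simulate(config, ...)
  cfg <- run_config(dir = config$out_dir, out_dir = config$out_dir,
                    thresholds = config$thresholds,
                    purity_correction = config$purity_correction,
                    control_condition = config$control_condition,
                    treated_condition = config$treated_condition,
                    reference_gene = config$reference_gene,
                    seed = config$seed)
  corr <- run_correct(cfg)
  ana <- run_analyze(cfg, corrected = corr$corrected)
  invisible(list(sim = sim, correct = corr, analyze = ana, config = cfg))
}
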