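# Synthetic study generator: ground-truth labeling states forward-convolved
# through the natural-abundance model with multiplicative noise, plus level
# tables, media time courses and qPCR Ct tables with planted effects.

#' Noise model for simulated measurements
#'
#' @param sigma Multiplicative log-normal sigma on ion areas (0 = noise-free).
#' @param additive_sd Additive Gaussian noise s.d. on areas (for robustness
#'   testing; default 0).
#' @param seed Integer seed; identical seed implies identical dataset.
#' @return A \code{noise_model} list.
#' @export
noise_model <- function(sigma = 0.01, additive_sd = 0, seed = 1L) {
  if (sigma < 0 || additive_sd < 0) stop("noise magnitudes must be >= 0")
  structure(list(sigma = sigma, additive_sd = additive_sd,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Ground-truth MID for a given labeled fraction
#'
#' Two labeling models that both have total contribution exactly f:
#' \code{"binomial-mixture"} places Binomial(n, f) mass on M+0..M+n (each
#' carbon independently labeled with probability f); \code{"two-pool"} mixes
#' a fraction f of fully labeled molecules with (1-f) unlabeled ones.
#'
#' @param f Labeled fraction in [0, 1].
#' @param n Number of metabolite carbons.
#' @param model \code{"binomial-mixture"} (default) or \code{"two-pool"}.
#' @return Numeric probability vector of length n+1.
#' @export
simulate_mid <- function(f, n, model = c("binomial-mixture", "two-pool")) {
  model <- match.arg(model)
  if (f < 0 || f > 1) stop("labeled fraction must be in [0, 1]")
  if (model == "binomial-mixture") {
    stats::dbinom(0:n, size = n, prob = f)
  } else {
    c(1 - f, rep(0, n - 1L), f)
  }
}

#' Forward-simulate measured raw areas from a true MID
#'
#' Applies the natural-abundance (and optional tracer-purity) forward model
#' to a ground-truth MID, scales by a total-signal factor, and perturbs with
#' multiplicative log-normal (and optional additive Gaussian) noise.
#' Reproducible for a fixed RNG state; callers seed via the noise model.
#'
#' @param true_mid Probability vector of length n+1.
#' @param fragment A \code{\link{fragment_spec}} with matching n.
#' @param isotopes Isotope abundance table.
#' @param purity Tracer purity in (0.5, 1] or NULL.
#' @param noise A \code{\link{noise_model}} (its seed is NOT set here).
#' @param total_area Expected total ion area (signal scale).
#' @return A \code{raw_mid} with noisy areas.
#' @export
forward_measure <- function(true_mid, fragment, isotopes = default_isotopes(),
                            purity = NULL, noise = noise_model(sigma = 0),
                            total_area = 1e6) {
  cm <- build_correction_matrix(fragment, isotopes, purity)
  expected <- as.numeric(cm$matrix %*% true_mid)
  # renormalize so the truncation tail does not leak total signal
  areas <- total_area * expected / sum(expected)
  if (noise$sigma > 0) {
    areas <- areas * exp(stats::rnorm(length(areas), 0, noise$sigma))
  }
  if (noise$additive_sd > 0) {
    areas <- areas + stats::rnorm(length(areas), 0, noise$additive_sd)
    areas[areas < 0] <- 0
  }
  structure(list(metabolite = fragment$metabolite, areas = areas),
            class = "raw_mid")
}

#' Default study design: 2D monolayer vs 3D spheroid contrast
#'
#' A six-metabolite GC-MS panel with a proline-like metabolite whose labeled
#' fraction and level both drop by half in the 3D condition, the remaining
#' metabolites unchanged (nulls), plus qPCR transcripts with a 4-fold higher
#' proline-dehydrogenase-like signal in 3D, and a media time course in which
#' proline is secreted in 2D and consumed in 3D.
#'
#' @param n_replicates Biological replicates per condition (>= 2; default 3).
#' @param purity Tracer isotopic enrichment (default 0.99, a 99 percent
#'   enriched glucose tracer).
#' @return A \code{study_design} list.
#' @export
default_study_design <- function(n_replicates = 3L, purity = 0.99) {
  metabolites <- data.frame(
    metabolite = c("proline", "glutamate", "lactate", "alanine", "serine", "citrate"),
    fragment_formula = c("C16H34NO2Si2", "C19H42NO4Si3", "C12H27O3Si2",
                         "C14H32NO2Si2", "C20H46NO3Si3", "C26H55O7Si4"),
    n_carbons = c(5L, 5L, 3L, 3L, 3L, 6L),
    base_mz = c(258L, 432L, 261L, 260L, 390L, 591L),
    f_2D = c(0.60, 0.55, 0.70, 0.65, 0.50, 0.45),
    f_3D = c(0.30, 0.55, 0.70, 0.65, 0.50, 0.45),
    level_2D = c(1.00, 0.80, 2.50, 1.20, 0.60, 0.90),
    level_3D = c(0.50, 0.80, 2.50, 1.20, 0.60, 0.90),
    stringsAsFactors = FALSE
  )
  transcripts <- data.frame(
    gene = c("PRODH", "P5CDH", "PYCR1"),
    fold_3D = c(4.0, 2.0, 1.0),  # expression fold in 3D vs 2D
    dct_2D = c(10, 9, 6),        # mean dCt vs reference gene in 2D
    stringsAsFactors = FALSE
  )
  media <- data.frame(
    metabolite = "proline",
    conc_fresh_uM = 300,
    conc_spent_2D_uM = 320,  # net secretion in monolayer culture
    conc_spent_3D_uM = 250,  # net consumption in spheroids
    volume_ml = 2, span_h = 120,
    stringsAsFactors = FALSE
  )
  structure(list(conditions = c("2D", "3D"), control_condition = "2D",
                 n_replicates = as.integer(n_replicates),
                 tracer = "13C6-glucose", purity = purity,
                 metabolites = metabolites, transcripts = transcripts,
                 media = media, reference_gene = "RPL19",
                 istd_area = 1e5, biomass_mg = 1.0,
                 biomass_kind = "protein"),
            class = "study_design")
}

.validate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  if (design$n_replicates < 2L) {
    stop("design error: need >= 2 replicates per condition for tested contrasts")
  }
  invisible(design)
}

# deterministic per-stream sub-seed fan-out (kept below 2^31; arithmetic in
# doubles to avoid 32-bit integer overflow)
.sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483629)
}

#' Simulate a complete tracer study with known ground truth
#'
#' Writes every file the pipeline ingests — fragment library, isotope table,
#' ion-area table (optionally also synthetic chromatograms), sample sheet,
#' media table, Ct table — plus a ground-truth table for recovery scoring.
#'
#' @param design A \code{study_design} (default
#'   \code{\link{default_study_design}}).
#' @param noise A \code{\link{noise_model}}; its seed drives every random
#'   stream deterministically.
#' @param dir Output directory (created if needed).
#' @param labeling_model Passed to \code{\link{simulate_mid}}.
#' @param chromatograms If TRUE, also write Gaussian-peak chromatograms and
#'   an integration-bounds file.
#' @return Invisible list: \code{paths} of the written files,
#'   \code{ground_truth} data frame, and the \code{design}.
#' @export
simulate_study <- function(design = default_study_design(),
                           noise = noise_model(), dir,
                           labeling_model = "binomial-mixture",
                           chromatograms = FALSE) {
  .validate_design(design)
  if (missing(dir)) stop("output directory must be given")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mets <- design$metabolites
  reps <- seq_len(design$n_replicates)
  p <- function(f) file.path(dir, f)

  write_tsv <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
    p(f)
  }

  paths <- list()
  paths$fragment_library <- write_tsv(
    mets[c("metabolite", "fragment_formula", "n_carbons", "base_mz")],
    "fragment_library.tsv")
  iso <- default_isotopes()
  paths$isotope_table <- write_tsv(as.data.frame(iso), "isotopes.tsv")

  # sample sheet -------------------------------------------------------------
  set.seed(.sub_seed(noise$seed, 1L))
  sheet <- expand.grid(replicate = reps, condition = design$conditions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet$sample <- paste0(sheet$condition, "_r", sheet$replicate)
  sheet$tracer <- design$tracer
  sheet$purity <- design$purity
  sheet$istd_area <- design$istd_area *
    exp(stats::rnorm(nrow(sheet), 0, noise$sigma))
  sheet$biomass_mg <- design$biomass_mg *
    exp(stats::rnorm(nrow(sheet), 0, noise$sigma))
  sheet$biomass_kind <- design$biomass_kind
  sheet <- sheet[c("sample", "condition", "replicate", "tracer", "purity",
                   "istd_area", "biomass_mg", "biomass_kind")]
  paths$sample_sheet <- write_tsv(sheet, "sample_sheet.tsv")

  # ion areas (and ground truth) ---------------------------------------------
  set.seed(.sub_seed(noise$seed, 2L))
  area_rows <- list(); gt_rows <- list()
  for (si in seq_len(nrow(sheet))) {
    cond <- sheet$condition[si]
    for (mi in seq_len(nrow(mets))) {
      f <- mets[[paste0("f_", cond)]][mi]
      lev <- mets[[paste0("level_", cond)]][mi]
      n <- mets$n_carbons[mi]
      frag <- fragment_spec(mets$metabolite[mi], mets$fragment_formula[mi],
                            n, mets$base_mz[mi])
      true_mid <- simulate_mid(f, n, model = labeling_model)
      total <- lev * sheet$istd_area[si] * sheet$biomass_mg[si]
      raw <- forward_measure(true_mid, frag, purity = design$purity,
                             noise = noise, total_area = total)
      area_rows[[length(area_rows) + 1L]] <- data.frame(
        sample = sheet$sample[si], metabolite = mets$metabolite[mi],
        mass_shift = 0:n, area = raw$areas, stringsAsFactors = FALSE)
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        sample = sheet$sample[si], condition = cond,
        metabolite = mets$metabolite[mi], true_f = f,
        true_level = lev,
        true_fold = lev / mets[[paste0("level_", design$control_condition)]][mi],
        stringsAsFactors = FALSE)
    }
  }
  areas <- do.call(rbind, area_rows)
  paths$areas <- write_tsv(areas, "ion_areas.tsv")
  ground_truth <- do.call(rbind, gt_rows)
  paths$ground_truth <- write_tsv(ground_truth, "ground_truth.tsv")

  # optional chromatograms ---------------------------------------------------
  if (chromatograms) {
    set.seed(.sub_seed(noise$seed, 3L))
    chrom_rows <- list(); bounds_rows <- list()
    tgrid <- seq(0, 60, by = 1)  # 1 Hz sampling, 60 s window
    for (mi in seq_len(nrow(mets))) {
      bounds_rows[[mi]] <- data.frame(metabolite = mets$metabolite[mi],
                                      t_start_s = 10, t_end_s = 50,
                                      stringsAsFactors = FALSE)
    }
    sigma_peak <- 3  # chromatographic peak width (s)
    for (si in seq_len(nrow(sheet))) {
      sa <- areas[areas$sample == sheet$sample[si], ]
      for (r in seq_len(nrow(sa))) {
        peak <- sa$area[r] * stats::dnorm(tgrid, mean = 30, sd = sigma_peak)
        chrom_rows[[length(chrom_rows) + 1L]] <- data.frame(
          sample = sa$sample[r], metabolite = sa$metabolite[r],
          mass_shift = sa$mass_shift[r], time_s = tgrid,
          intensity = peak, stringsAsFactors = FALSE)
      }
    }
    paths$chromatograms <- write_tsv(do.call(rbind, chrom_rows),
                                     "chromatograms.tsv")
    paths$bounds <- write_tsv(do.call(rbind, bounds_rows), "bounds.tsv")
  }

  # media table ---------------------------------------------------------------
  set.seed(.sub_seed(noise$seed, 4L))
  media_rows <- list()
  for (mi in seq_len(nrow(design$media))) {
    md <- design$media[mi, ]
    for (si in seq_len(nrow(sheet))) {
      spent <- md[[paste0("conc_spent_", sheet$condition[si], "_uM")]] *
        exp(stats::rnorm(1, 0, noise$sigma))
      media_rows[[length(media_rows) + 1L]] <- data.frame(
        sample = sheet$sample[si], condition = sheet$condition[si],
        metabolite = md$metabolite, conc_fresh_uM = md$conc_fresh_uM,
        conc_spent_uM = spent, volume_ml = md$volume_ml, span_h = md$span_h,
        stringsAsFactors = FALSE)
    }
  }
  paths$media <- write_tsv(do.call(rbind, media_rows), "media.tsv")

  # Ct table ------------------------------------------------------------------
  set.seed(.sub_seed(noise$seed, 5L))
  ct_sd <- 0.10  # technical Ct scatter (cycles)
  ct_rows <- list()
  for (si in seq_len(nrow(sheet))) {
    ref_ct <- 16 + stats::rnorm(1, 0, ct_sd)
    ct_rows[[length(ct_rows) + 1L]] <- data.frame(
      sample = sheet$sample[si], condition = sheet$condition[si],
      gene = design$reference_gene, ct = ref_ct, stringsAsFactors = FALSE)
    for (gi in seq_len(nrow(design$transcripts))) {
      tr <- design$transcripts[gi, ]
      dct <- tr$dct_2D -
        (if (sheet$condition[si] == "3D") log2(tr$fold_3D) else 0)
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        sample = sheet$sample[si], condition = sheet$condition[si],
        gene = tr$gene, ct = ref_ct + dct + stats::rnorm(1, 0, ct_sd),
        stringsAsFactors = FALSE)
    }
  }
  paths$ct <- write_tsv(do.call(rbind, ct_rows), "ct.tsv")

  invisible(list(paths = paths, ground_truth = ground_truth, design = design))
}
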