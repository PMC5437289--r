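# tracemet

Analysis of stable-isotope (¹³C) tracer metabolomics measured by
nominal-mass GC-MS, built for studies that compare labeling and metabolite
levels between biological conditions — for example monolayer (2D) versus
spheroid (3D) cell culture, or primary tumours versus metastases, with
proline catabolism as the motivating readout.

## What it computes

Starting from extracted-ion chromatograms (or pre-integrated ion areas), the
package:

1. **Extracts mass distribution vectors (MIDs).** Each metabolite's
   isotopologue ions M+0..M+n are integrated over one shared retention-time
   window after two-point linear baseline correction, giving raw areas
   a₀..aₙ.
2. **Corrects for naturally occurring isotopes.** For a derivatized fragment
   with elemental formula F and n tracer-relevant carbons, the correction
   matrix **M** has as its j-th column the predicted measured distribution
   when exactly j carbons carry the label: the natural isotopologue
   distribution of F with j carbons removed from the natural pool, convolved
   with the binomial tracer-purity distribution of the j labeled positions.
   The tracer-only MID **m** solves **M m ≈ a** by non-negative least
   squares and is renormalized to sum to 1.
3. **Quantifies enrichment and levels.** Total carbon contribution
   TC = Σᵢ i·mᵢ / (n · Σᵢ mᵢ), the fraction of the metabolite's carbons
   derived from the tracer; metabolite levels as
   area / internal-standard area / mg protein (or mg tissue); folds relative
   to a control condition; media-based uptake/secretion rates
   (uptake positive, in nmol·mg⁻¹·h⁻¹); and blood-enrichment QC for in vivo
   infusions.
4. **Tests differences.** qPCR fold changes by ΔΔCt against a reference
   gene (default RPL19); group comparisons by a two-tailed Student t-test
   whose variance assumption is gated by a two-sided F-test (Welch's
   correction when variances differ); Grubbs single-outlier detection; and
   a differential filter that retains a metabolite only when the relative
   change of the group mean exceeds 25% (total contribution) or 27%
   (levels) *and* p ≤ 0.05.
5. **Simulates ground-truth studies.** A synthetic-data generator plants
   known labeled fractions, levels, folds and transcript effects, forward-
   convolves them through the same natural-abundance model with
   multiplicative log-normal noise, and writes every table the pipeline
   reads — so recovery can be scored exactly.

## Worked example

Correct a measured proline MID (TBDMS fragment C16H34NO2Si2, n = 5 carbons,
99%-enriched tracer) and compute its total contribution:

```r
library(tracemet)
fr  <- fragment_spec("proline", "C16H34NO2Si2", n_carbons = 5)
cm  <- build_correction_matrix(fr, purity = 0.99)
raw <- c(31500, 26400, 14800, 10700, 9300, 7300)  # areas M+0..M+5
res <- correct_mid(raw, cm)
res
#> <corrected_mid> proline  [0.4318, 0.2391, 0.0889, 0.0860, 0.0868, 0.0673]  resid=6.94e-17
total_contribution(res$fractions)
#> [1] 0.2718
```

The corrected fractions are the tracer-only isotopologue abundances; the
residual near machine precision says the measured vector is fully explained
by the natural-abundance model. About 27% of this proline's carbon came
from the tracer.

Run a full synthetic 2D-vs-3D study end-to-end:

```r
td  <- tempfile()
out <- run_all(run_config(out_dir = td, seed = 42))
out$analyze$filter_contribution[, c("metabolite", "rel_change", "p_value", "retained", "direction")]
#>   metabolite    rel_change      p_value retained direction
#> 1    proline -4.991409e-01 1.407696e-10     TRUE        -1
#> 2  glutamate -1.848723e-03 4.642871e-01    FALSE        -1
#> ...
out$analyze$qpcr
#>    gene fold_change
#> 1 PRODH   4.1470759
#> 2 P5CDH   2.0163476
#> 3 PYCR1   0.9545423
```

The planted proline effect (a 50% drop of labeled fraction in 3D) is the
only metabolite retained by the >25%-and-p≤0.05 filter, with negative
direction; the planted 4-fold PRODH induction is recovered by ΔΔCt.

A thin command-line wrapper with `simulate` / `correct` / `analyze` / `all`
subcommands lives at `inst/cli/tracemet.R` and takes a YAML config
(see `?run_config`).

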