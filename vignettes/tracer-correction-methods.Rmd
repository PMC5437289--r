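---
title: "Isotope correction and variance-gated differential analysis in tracemet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope correction and variance-gated differential analysis in tracemet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracemet)
```

## The measurement model

A metabolite measured by nominal-mass GC-MS after MOX/TBDMS derivatization
appears as a cluster of isotopologue ions M+0..M+n, where n is the number of
carbons of the parent metabolite contained in the fragment. Two processes
shape the observed mass distribution: incorporation of the ¹³C tracer into
those n carbons (the biological signal) and the natural heavy-isotope
content of *every* atom of the derivatized fragment — ¹³C in the
derivatization carbons, ²H, ¹⁵N, ¹⁷O/¹⁸O, and, importantly for TBDMS
chemistry, ²⁹Si/³⁰Si. The natural part is a nuisance that must be removed
before any labeling fraction is interpretable.

We model the measured fractional distribution $a$ as a linear image of the
tracer-only mass distribution vector $m$:

$$ a \;=\; \mathbf{M}\, m, $$

where column $j$ of $\mathbf{M}$ is the predicted measured distribution when
exactly $j$ tracer carbons are labeled. Each column is an exact discrete
convolution of two pieces:

* the natural isotopologue distribution of the fragment with $j$ carbons
  removed from the natural pool, computed per element by multinomial
  expansion (repeated-squaring convolution of the single-atom distribution)
  and combined across elements by convolution;
* the label distribution of the $j$ tracer positions — a point mass at
  shift $j$, or Binomial($j$, purity) when a tracer purity below 1 is
  declared.

Working at unit (nominal) mass resolution collapses fine isotope structure;
that matches quadrupole GC-MS data scanned over a 100–650 a.m.u. range and
is the standard dialect for this kind of correction.

### Inversion

Given raw areas (normalized to fractions), the tracer-only MID solves
$\mathbf{M} m \approx a$ by **non-negative least squares**
(`pracma::lsqnonneg`, an exact active-set solution of the constrained
normal equations), followed by renormalization to sum 1. Plain matrix
inversion is available (`method = "solve"`) and is used in tests as a
cross-check; it is not the default because measurement noise routinely
produces small negative fractions that then corrupt downstream means. The
residual norm and any mass removed by clipping are reported per
sample × metabolite in a QC table; residuals above 0.05 flag the row
(non-fatally).

The matrix is square by default — n+1 measured masses for n+1 unknowns.
Truncation of natural-abundance tails beyond M+n is deliberate and shows up
as column sums slightly below 1; a column-sum sanity floor of 0.5 guards
against implausible fragment formulas.

### Isotope abundances

The default table holds representative terrestrial abundances for C, H, N,
O, S and Si — the elements of TBDMS/MOX-derivatized fragments. It ships as
`inst/extdata/isotopes.tsv`, is overridable per run, and is validated
(per-element abundances sum to 1 within 1e-9, shifts strictly increasing
from 0). Tracer purity correction is **off** unless a purity is declared in
the sample sheet or forced in the configuration: whether a given historical
dataset was purity-corrected is often unknowable, so both behaviours are
first-class and tested. Declared purities must lie in (0.5, 1].

## Peak integration

Raw ion chromatograms are reduced to areas with one shared integration
window per metabolite, applied identically to every isotopologue ion of
every sample — consistency of the window across ions matters more for MID
accuracy than the window's exact placement, because MIDs are ratios of
areas integrated the same way. The baseline is the straight line through
the trace values at the window endpoints; the minimal, auditable choice.
Areas are trapezoidal; negative net areas (noise below baseline) clip to
zero with a warning. Pre-integrated area tables bypass this stage entirely,
since many instrument exports provide areas only.

## Derived quantities

* **Total contribution** $TC = \sum_i i\,m_i / (n \sum_i m_i)$ — the
  average fraction of the metabolite's carbons that came from the tracer.
  It is linear in mixtures: a fraction $f$ of fully labeled molecules gives
  $TC = f$ exactly, which the synthetic generator exploits as ground truth.
* **Levels**: area / internal-standard area / biomass. Biomass is mg
  protein in vitro and mg wet tissue in vivo; the provenance is recorded per
  sample and ratios across different denominators are refused.
* **Exchange rates**: (fresh − spent concentration) × volume /
  (biomass × time), uptake positive. The denominator uses end-point
  biomass — a documented simplification; time-averaged biomass would need a
  growth model the input tables do not carry.
* **ΔΔCt fold changes** with amplification efficiency fixed at 2
  (configurable); folds are invariant to global per-sample Ct shifts
  because the reference gene absorbs them.

## The statistical decision procedure

Group comparisons run a two-sided F-test on the variance ratio first; if
its p-value falls below the gate (α = 0.05) the t-test is Welch's,
otherwise a pooled-variance Student t-test. Both the routing and the F-test
p-value are reported. Degenerate zero-variance inputs use conventions
(p = 1 for identical groups, p → 0 flagged otherwise) rather than NaNs.
Grubbs single-outlier detection uses the two-sided t-quantile critical
value and flags at most one point per call; removal is logged, never
silent.

The differential filter retains a metabolite when the **relative change of
the group mean** exceeds 25% (total contribution) or 27% (levels) *and*
p ≤ 0.05. "Change > 25%" is interpreted as relative change, not
percentage-point difference — for a bounded quantity like a contribution
the two readings differ, and relative change is what "changes in total
contribution" most naturally means; the thresholds are plain parameters,
so the alternative reading is one argument away. No multiple-testing
correction is applied in the decision; a Benjamini–Hochberg column is
emitted as clearly-supplementary output.

```{r filter-example}
vals <- data.frame(metabolite = "m",
                   group = rep(c("A", "B"), each = 3),
                   value = c(1.00, 1.01, 0.99, 1.30, 1.31, 1.29))
differential_filter(vals, "A", "B", kind = "contribution")
```

## What the synthetic generator emulates — and what it does not

`simulate_study()` plants a known labeling state per metabolite × condition
(labeled fraction $f$ under a binomial-mixture or two-pool model, both with
$TC = f$ exactly), forward-convolves it through the *same* correction
matrix used for analysis, scales totals by planted levels, internal
standard and biomass, and perturbs with multiplicative log-normal noise —
the standard model for MS intensity scatter. The default design mirrors a
2D-vs-3D contrast: three biological replicates per condition, a 99%-pure
glucose tracer, a proline-like metabolite whose labeled fraction and level
both halve in 3D, null metabolites, a 4-fold induced PRODH-like transcript,
and a medium in which proline is secreted in 2D but consumed in 3D.
Replicate counts below 2 are refused at generation time. A single seed fans
out deterministically per output file, so regeneration is stable.

It does **not** simulate chromatographic co-elution, retention-time drift,
detector saturation, or fragment-formula misassignment. Passing recovery
tests therefore demonstrates correctness of the mathematics and the
plumbing, not robustness to every artefact of real chromatography — the QC
residuals exist precisely because real data violate the forward model in
ways synthetic data do not.

Because the generator and the correction share the convolution code, the
test suite anchors the chemistry independently: exhaustive per-atom isotope
enumeration reproduces every matrix column to 1e-12 on small fragments,
and a simplex grid search reproduces the constrained solve on toy cases.

## Numerical choices and problem sizes

* Distribution truncation: natural distributions are evaluated to the
  measured window; tail mass is tracked and logged above 1e-6 (suppressed
  where truncation is deliberate, i.e. inside matrix assembly).
* Convolutions are direct (quadratic) rather than FFT: vectors are short
  and exactness to machine precision is worth more than speed.
* Noise-free round-trips are asserted to 1e-9; identities of the
  contribution formula to 1e-12.
* Simulation sizes used by the validation suite: 100 random MIDs for
  round-trips, 1,000 samples per noise level for recovery error, 10,000
  null replicates (n = 5 per group) for t-test calibration, 500 simulated
  studies for filter sensitivity/specificity, 1,000 clean samples for the
  Grubbs flag rate. These sizes put Monte-Carlo error well below the
  asserted margins while keeping the default run fast on a laptop.

## Known limitations

* Single-tracer carbon correction only; resolved multi-element corrections
  (e.g. simultaneous ¹³C + ¹⁵N) and high-resolution fine structure are out
  of scope.
* The shipped fragment library is an editable example set; users must
  supply the fragment formulas their method actually measures, including
  all derivatization atoms — the correction is only as good as the formula.
* Exchange rates assume end-point biomass and a configurable but unverified
  medium volume/duration; absolute quantitation would need calibration
  curves.
* The acceptance of a metabolite by the differential filter inherits the
  usual fragility of small-n t-tests; the filter is a depiction rule, not
  an error-controlled discovery procedure.
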