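---
title: "Rank equivalence of fasting insulin sensitivity indices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank equivalence of fasting insulin sensitivity indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulindex)
```

## The model

Insulin sensitivity has a gold-standard measurement — the hyperinsulinemic
euglycemic clamp, summarized as the steady-state glucose infusion rate per
kg lean body mass, M_LBM in mg/(kg·min), higher meaning more sensitive —
and a family of cheap surrogates computed from blood samples. The three
most common fasting surrogates,

$$\mathrm{HOMA\text{-}IR} = \frac{G_0 I_0}{22.5}, \qquad
  \mathrm{QUICKI} = \frac{1}{\log_{10} G_0 + \log_{10} I_0}, \qquad
  \mathrm{FIRI} = \frac{G_0 I_0}{25},$$

are all functions of the single quantity $P = G_0 I_0$: HOMA-IR and FIRI are
proportional to $P$, and QUICKI is $1/\log_{10} P$, strictly decreasing in
$P$ wherever $P > 1$ (fasting physiology puts $P$ far above 1; with glucose
in mmol/L and insulin in µU/mL, typical values are 20–100). Each index is
therefore a strictly monotone function of the other two, with closed-form
transformations implemented in `transform_index()`:

$$\mathrm{HOMA\text{-}IR} = \mathrm{FIRI}\cdot\frac{25}{22.5}, \qquad
  \mathrm{HOMA\text{-}IR} = \frac{10^{1/\mathrm{QUICKI}}}{22.5}, \qquad
  \mathrm{QUICKI} = \frac{1}{\log_{10}\mathrm{HOMA\text{-}IR} + \log_{10} 22.5}.$$

The statistical consequence is the package's central claim: any analysis
that depends on the data only through ranks must give identical results for
the three indices (with order reversed for QUICKI). That covers Spearman
correlation with the clamp, ROC curves and AUC against a clamp-defined
binary label, and rank-sum tests between groups. Analyses that see the
scale — Pearson correlation, t-tests — genuinely differ across the indices
even though they are computed from the same glucose and insulin values.
Comparing the three indices by rank-based criteria is therefore
uninformative, and a study should simply pick one.

## Logarithm convention

The QUICKI literature does not always say which logarithm it means. This
package fixes base 10 throughout (`quicki()`, `revised_quicki()`, and the
matching $10^{1/\mathrm{QUICKI}}$ in `transform_index()`), the convention of
the index's originating literature. The choice is consequential only for
the *value* of QUICKI, not for any of the equivalence results: a change of
base rescales $1/\mathrm{QUICKI}$ by a constant, which preserves ranks,
ROC curves, and every transformation identity so long as the same base is
used on both sides. The test suite checks the internal consistency
(`transform_index(quicki(s), "quicki", "homa_ir")` equals `homa_ir(s)` to
1e-12 relative) that any coherent convention must satisfy.

## Units and missing data

The 22.5 and 25 denominators presume glucose in mmol/L and insulin in
µU/mL; Matsuda is documented for mg/dL glucose, and Stumvoll for pmol/L
insulin at 120 min and mmol/L glucose at 90 min. The package performs no
unit conversion, silent or otherwise — unit mix-ups are the dominant error
source for these indices, and a conversion layer would hide them. For the
same reason indices never impute: an OGTT-based index requested on a
fasting-only record is reported as an explicit per-kind failure by
`compute_indices()`, since an imputed Matsuda would not be the Matsuda
index.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a method-comparison study:

- fasting glucose and insulin are independent lognormals. Defaults:
  glucose median 5.4 mmol/L with log-scale SD 0.11, insulin median 8 µU/mL
  with log-scale SD 0.5 — plausible for a mixed adult cohort spanning
  normal to impaired glucose regulation, with insulin's characteristic
  right skew. These are configuration values (`lognormal_params`), not
  constants.
- M_LBM is lognormal (default median 6.5 mg/(kg·min), log-scale SD 0.45),
  coupled to the fasting pair so that the Pearson correlation between
  QUICKI and M_LBM on the raw scales hits a configured target, 0.75 by
  default — the order of agreement reported between fasting surrogates and
  the clamp.
- insulin resistance is labelled by the strict cutoff
  M_LBM < 4.7 mg/(kg·min); a subject exactly at the cutoff is not
  resistant. Under the defaults roughly a quarter of subjects are labelled
  resistant, a realistic prevalence for such cohorts.

### Latent-correlation calibration

Both fasting variables and M_LBM are normal on the log scale, so the
natural coupling is a Gaussian latent correlation: the log-scale normal
behind M_LBM is written as $r^\ast Z + \sqrt{1-r^{\ast 2}}\,\varepsilon$,
where $Z$ is the standardized *negated* score $\ln G_0 + \ln I_0$ — the
normal driver pointing in QUICKI's direction, so that $r^\ast$ increases
with the target — and $\varepsilon$ is independent noise. The Pearson
correlation this induces between QUICKI ($= \ln 10 / (\text{the score})$)
and M_LBM (an exponential of the latent) has no convenient closed form, so
`calibrate_latent_correlation()` solves for $r^\ast$ numerically: one
fixed-seed Monte Carlo sample (default size 100,000) is drawn, the induced
correlation becomes a smooth strictly increasing function of $r^\ast$ on
that sample, and bisection finds the target within `calibration_tolerance`
(default 0.01). An unattainable target raises a calibration error reporting
the closest achievable value. The calibration RNG stream is derived from,
but distinct from, the cohort seed, so the calibrated $r^\ast$ does not
depend on the cohort draw it is applied to.

The target is interpreted as Pearson(QUICKI, M_LBM) on the *raw* scales.
Correlations against log M_LBM are additionally reported by the pipeline
(the Spearman entries are identical by rank invariance; the Pearson entries
are not), but are not used for calibration.

### What the generator does and does not emulate

The generator reproduces the marginal shapes (lognormal), the
surrogate-clamp association strength, and the resistance labelling of a
clamp study. It deliberately omits measurement error and replicates (so
repeatability questions are out of scope), OGTT time courses, and any
fitting of marginals to a real cohort. Passing tests on simulated cohorts
therefore establish the *mathematical* equivalence claims — which hold for
any tie-free data — and the calibration accuracy of the generator itself;
they do not validate the default marginals against any particular
population. The equivalence properties are additionally exercised across
100 randomized configurations (varying marginals, targets, sizes and
seeds) in the test suite.

## The evaluation toolkit

The statistical layer is implemented from first principles because the
package's subject matter *is* how these statistics respond to monotone
transformations; each implementation is cross-checked in the tests against
an independent route (`stats::cor`, `wilcox.test`, `t.test`, `pROC`, and a
brute-force pairwise AUC oracle).

- **Correlation.** Pearson by the usual product-moment sample formula;
  Spearman as Pearson applied to mid-ranks (average ranks on ties —
  continuous simulations are tie-free, but loaded data may not be).
  Correlation on a constant series is an error, not an `NA` silently
  propagated (the pipeline catches it and *reports* the entry as
  undefined). No confidence intervals are produced: the standard forms
  assume bivariate normality, which skewed index distributions violate.
- **ρ→r conversion.** $r = 2\sin(\rho\pi/6)$, the meta-analytic conversion;
  it also assumes bivariate normality, and its documentation says so.
- **ROC.** All distinct score values are swept after orientation
  (sensitivity-type indices such as QUICKI are negated via
  `lower_is_positive`); tied scores move as a block, one curve vertex per
  distinct value, AUC by the trapezoidal rule. With these tie conventions
  the trapezoidal AUC equals exactly the probability that a random
  resistant subject outranks a random healthy one, ties counting a half —
  the identity is asserted to 1e-12 in the tests.
- **Group tests.** Mann-Whitney with the normal approximation, tie-corrected
  null variance and 0.5 continuity correction, two-sided; exact enumeration
  is unnecessary for the identity property (identical ranks give identical
  U under any p-value convention) and the approximation scales. The
  parametric companion is the Welch t-test, the safer default when group
  variances differ; the non-identity of t-results across indices holds for
  either t variant.

## The study pipeline

`run_study()` simulates a cohort, computes both correlation matrices, the
per-index clamp correlations (raw and log M_LBM), the three oriented ROC
curves, and Mann-Whitney/Welch results for a median split of M_LBM. The
median split stands in for a treatment/control grouping, which a
single-arm simulation does not have; any deterministic split suffices for
the identity demonstration. Verdicts are booleans, each accompanied by the
achieved numerical discrepancy (maximum deviation of Spearman entries from
±1, maximum ROC point discrepancy, AUC range, U and p ranges), so a
failing verdict is diagnosable. `write_report()` serializes numbers at full
double precision (`%.17g`), making reports byte-identical across reruns of
the same configuration.

Degenerate inputs are reported, not repaired: a two-subject or constant
cohort yields undefined correlation entries flagged as `NA`, group tests
are omitted when a split side has fewer than two subjects, and ROC is
omitted when only one class is present.

## Problem sizes

The shipped tests use cohorts of 50–1,000 subjects (50,000 for the
marginal goodness-of-fit check) with calibration Monte Carlo sizes of
10,000–20,000, and the acceptance computation uses n = 10,000 with the
full 100,000-point calibration — sizes at which every equivalence property
is already exact and the calibrated correlation is stable to well under
±0.03. The whole suite runs in seconds.

## Known limitations

- The equivalence argument is about *rank-based* analyses; nothing here
  says the three indices agree with the clamp, only that they agree with
  each other in rank.
- Exactly reproducing any previously distributed simulated dataset
  requires loading it via `load_cohort()` (CSV, or XLSX through `readxl`);
  its exact generating parameters are not recoverable from the package's
  defaults.
- QUICKI is undefined when $G_0 I_0 = 1$ and wildly unstable near it; the
  calculators refuse the degenerate point but values near it are the
  user's responsibility. Physiological fasting values are far away.
- Multiple-testing machinery, AUC inference (DeLong, bootstrap), and
  repeatability/ICC estimation are out of scope.

## A two-line check

```{r example}
rep <- run_study(study_config(simulation_config(n_subjects = 500, seed = 7,
                                                calibration_mc_size = 20000)))
rep$verdicts$roc_identity
```
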