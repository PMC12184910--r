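---
title: "Quantifying genetic buffering: models, scales, and the residual pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genetic buffering: models, scales, and the residual pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibuffer)
```

## The buffering description of an allele

Every operation in this package rests on one picture: the phenotypic
effect of an allele is a partitioning of a measurable trait between a
*transfer* compartment (what an observer sees in the mutant) and a
*buffer* compartment (the part of the reference genotype's output the
mutation diverts out of view). Writing the reference trajectory as
$\sigma(t)$ and the mutant trajectory as $\tau(t)$, the buffer function is
$\beta(t) = \sigma(t) - \tau(t)$, and conservation
$\sigma = \tau + \beta$ holds pointwise by construction
(`schmitt_triple()`).

The state of the partition at any time is captured by any one of five
interconvertible parameters:

| parameter | definition | range | undefined at |
|---|---|---|---|
| ŧ (`t_bar`) | transfer / total | any real | — |
| $b$ | buffer / total, $1-$ŧ | any real | — |
| $T$ | ŧ$/b$ | ratio scale | $b = 0$ |
| $B$ | $b/$ŧ | ratio scale | ŧ $= 0$ |
| $\alpha$ | angle of $($ŧ$, b)$ from the ŧ-axis | $(-45^\circ, 135^\circ]$ | — |

$T$ and $B$ are the ratio-scale measures (the analogue of odds against
probabilities); they support addition and hence the parallel combination
rule below, but each has a division-by-zero state. Those states are
*meaningful* — perfect transfer, perfect buffering — so the package
represents them with an explicit `undefined_value()` sentinel; arithmetic
on the sentinel raises a typed error instead of silently propagating a
`NaN`.

The buffering angle removes the discontinuities altogether. It is computed
as the angle between the ŧ-axis and the ray to $($ŧ$, b)$, equivalent to
`atan2(b, t_bar)` on the constraint line ŧ $+ b = 1$, and the package
verifies the two published branch formulas (an arccosine with a sign flip
at ŧ $> 1$) against that two-argument arctangent on a dense grid. The
regimes read directly off the angle: moderation on $(0^\circ, 90^\circ)$,
amplification on $(-45^\circ, 0^\circ)$ (a mutant fitter than the
reference), inversion on $(90^\circ, 116.57^\circ]$ (negative growth), and
inverted amplification beyond. $\alpha = 135^\circ$ and
$\alpha = -45^\circ$ are limit points requiring an infinite transfer
fraction; `state_from_angle()` rejects exactly 135 (the
$\cos\alpha + \sin\alpha = 0$ pole) and the range is open at $-45$.

One branch choice deserves a note. The published inverse-tangent
conversion adds $180^\circ$ only on $-2 \le B \le -1$, but the inversion
regime with ŧ $\in (-1, 0)$ has $B < -2$ and needs the same correction for
consistency with the arccosine branches. `angle_from_B()` therefore adds
$180^\circ$ for all $B < -1$; the equivalence with `angle_from_state()` is
property-tested across the full grid.

## Growth models and fitness

Three trajectory families are supported — linear $x_0 r t$, quadratic
$x_0 r t^2$, exponential $x_0 e^{rt}$ — because they span the cases where
the familiar product rule is and is not adequate. For polynomial growth
the transfer fraction of a mutant is constant in time
($r_\text{mut}/r_\text{ref}$); for exponential growth it is
$e^{(r_\text{mut}-r_\text{ref})t}$ and the *serial* expectation collapses
to the rate rule $r_{cd} = r_c + r_d - r_\text{ref}$ rather than the
product $r_c r_d$. The gap between the two is
$-(1-r_c)(1-r_d) \le 0$: the product rule systematically understates
exponential double-mutant fitness.

The parallel expectation under exponential growth is genuinely
time-varying, so `expected_exponential_parallel_trajectory()` returns a
trajectory object rather than a scalar rate; a scalar is extracted only at
a caller-chosen evaluation time. The same applies to epsilon scores on
exponential-parallel expectations: an explicit time is required, and no
canonical default is assumed.

The cumulative phenotype (`cumulative_phenotype()`) is the definite
integral of the trajectory, in trait-units × hours (cell·hours for
growth). The indefinite integral is not represented as an object: its
constant of integration is unobservable, so only definite values — which
quadrature can check — are exposed, with the integration origin chosen by
the caller. Exponential integration at $r = 0$ degenerates to
$x_0 \,\Delta t$ in code rather than dividing by zero. `time_dilation()`
gives the equivalent view along the time axis,
$t_\text{mut} = (t_\text{wt}^n / \text{ŧ})^{1/n}$ for degree-$n$
trajectories; it requires ŧ $> 0$ since inverted phenotypes have no real
dilation.

Negative rates (mortality exceeding proliferation) are deliberately legal
throughout; they produce ŧ $< 0$ and land in the inversion regime of the
angle.

## Neutrality models and interaction scales

`expected_serial()` folds transfer fractions by multiplication,
`expected_parallel()` folds $B$ by addition; both accept any number of
states and are order-invariant, which the suite checks by permutation.
"Fitness" in the SGA context is identified with ŧ relative to wild type —
for colony area, which scales linearly with time and with fitness, the
serial and product rules coincide, which is what makes the published data
reusable here. Parallel combination is permitted for states with
ŧ $> 1$ ($B < 0$) even though the worked material never exercises that
corner; the result is mathematically well defined (a divergence is raised
only if the summed $B$ hits $-1$) and is simply outside the validated
range.

The epsilon scales are relative errors on each model's native parameter,
with the serial scale negated so aggravating interactions are positive on
both. Landmarks `epsilon_weak`/`epsilon_strong` mark where the double
mutant matches the weaker or stronger single; epsilon between the
landmarks is equivalent to $B_{cd}$ between the single-mutant $B$s, and
that equivalence is property-tested. A lethal double mutant has unbounded
$B_{cd}$ and maps to $\varepsilon_\text{parallel} = +\infty$.

Classification (`classify_interaction()`) delegates significance to a
caller-supplied q-value with default threshold 0.05 — the framework
itself prescribes no threshold — and uses a configurable *lethality
floor* (default ŧ $\le 0.01$ of wild-type fitness) to separate synthetic
lethal from synthetic sick, since "not observably greater than zero" has
no universal measurement cutoff. Suppression is reported when an
ameliorating double mutant exceeds the fitter single, which requires the
single-mutant fitnesses to be supplied.

`quantify_buffering()` expresses Hartwellian buffering as the angular gap
between the observed double-mutant state and the neutral expectation,
clamped at zero from below: an observation milder than expected buffers
nothing.

## The residual pipeline

`sga_run()` chains the stages a cross-table analysis needs, each also
available separately:

1. **Load** (`load_crosses()`): delimited text with a header row and a
   user-supplied column map; rows with any missing or unparseable mapped
   field are dropped and counted. Nothing is positional.
2. **Expectations** (`compute_expectations()`): serial product and
   parallel harmonic form per cross. Nonpositive single-mutant fitness
   makes the parallel expectation undefined; such rows are flagged, not
   dropped.
3. **Significance** (`compute_qvalues()`): the per-cross statistic is
   (observed − expected) / sd. The reference null defaults to the
   standard normal because the reference reanalysis this pipeline mirrors
   specifies a two-tailed t-test without degrees of freedom or replicate
   counts; a
   `df` argument exposes the t-distribution for users who know their
   replication. p-values are Benjamini–Hochberg adjusted within each
   model family independently, since the hybrid step compares the two
   q-values per cross.
4. **Filter** (`apply_filters()`): single-mutant fitnesses in the closed
   interval $[0.1, 0.9]$ (model predictions converge at the ends of the
   fitness range, so the interval concentrates resolution) and q
   strictly above 0.5. The q rule defaults to *any*: a cross is kept when
   at least one neutrality model finds it unsurprising, because a truly
   epistatic pair deviates from every neutrality expectation. This
   produces one shared filtered set for all downstream models, matching
   the single retained set the full-scale reanalysis reports. `q_rule = "all"` and
   `q_cols` are available for stricter or single-model filtering; note
   that on noise-free single-model data the "all" rule rejects
   everything (the wrong model is always confidently rejected), which is
   why it is not the default.
5. **Hybrid** (`hybrid_expectation()`): per cross, adopt the expectation
   with the larger q — the model least likely to conclude a true
   deviation. Ties resolve to serial, the incumbent rule.
6. **Residuals** (`standardized_residuals()`): one scale
   $s = \sqrt{\sum r_i^2 / (n-2)}$ per model over the shared filtered
   set. If every cross sits exactly on the model ($s = 0$) the residuals
   are returned as exact zeros rather than dividing by zero.
7. **Comparison** (`cvm_2sample_test()`): two-sample Cramér–von Mises,
   implemented in-package (statistic with midranks for ties, exact
   finite-sample mean/variance normalization, limiting-distribution CDF
   via the Bessel-$K_{1/4}$ series summed adaptively). Frozen
   cross-checks against an independent implementation of the same test
   pin the p-values to six decimals.

## What the generator emulates — and what it does not

`simulate_crosses()` produces tables with the statistical structure the
pipeline assumes: single-mutant fitnesses uniform on $[0.1, 0.9]$ (so the
default filter passes everything and every cross is informative), a true
relationship class per cross (serial, parallel, or epistatic), the double
mutant placed by the class's rule, additive Gaussian measurement noise
(default sd 0.05) truncated at zero fitness, and a reported per-cross sd
dispersed around the true noise level. Everything is a deterministic
function of the seed.

Defaults are the study conditions used throughout the tests: 20,000
crosses, an even serial/parallel split, no epistatic contamination unless
requested. The epsilon distribution for epistatic pairs
(Normal(0.5, 0.25) on the model's native scale) is a placeholder — the
real data's interaction-strength distribution is not characterized — and
should be treated as such.

The generator does *not* model colony-plate spatial effects, batch
structure, linkage between query and array loci, or non-Gaussian error;
passing tests therefore demonstrate that the pipeline recovers the
direction and ordering of model bias under clean sampling assumptions,
not that real SGA noise is Gaussian. The full-scale reference landmarks
(medians 0.282 serial / −0.492 parallel / −0.082 hybrid over 77,401
retained crosses) require the external ~6.6M-row supplement;
`inst/scripts/costanzo-reanalysis.R` documents that optional job, and the
desk-scale suite exercises the identical code path on synthetic data at
$n = 20{,}000$ (seconds on one core; the problem sizes in the tests were
chosen to keep the whole suite under a minute while leaving the CLT
bounds sharp).

## Numerical choices and degenerate inputs

* Angles are exposed in degrees (the field's unit here); trigonometry is
  internal radians. Exact axis angles (0°, 90°) snap to exact states so
  that `state_from_angle(90)` has ŧ identically 0.
* Comparisons against three-decimal published values use tolerances of a
  few parts in $10^3$, because those references are themselves rounded
  (the same quantity appears as 0.429 and 0.428 in different places).
* Invariant checks (ŧ $+ b = 1$, level sums in diagrams, $T\cdot B = 1$)
  use absolute tolerance $10^{-9}$.
* Division-by-zero states: explicit sentinel for $T$/$B$; typed
  divergence errors for $B = -1$, $\alpha = 135^\circ$, zero partitions,
  zero expected values in epsilon denominators.
* BH adjustment is `stats::p.adjust(method = "BH")`; medians and means
  are base R.

## Gene-interaction diagrams

`build_tree()` stacks serial layers (single alleles or parallel pairs)
into a genotype tree; the combined transfer fraction of a pair comes from
`expected_parallel()`, so the diagram evaluator and the neutrality module
are mutually consistent by construction (and tested against each other on
random trees). Two conservation rules are enforced: values across every
horizontal level sum to 1, and the vertical product of edge fractions
equals the tree's expected transfer fraction. Observed (epistatic) values
attach to compartments as bracketed annotations and are reported as
discrepancies by `validate_tree()`, never as violations — the neutral
expectation stays auditable beside the observation, and the expected
edges are never rewritten. Serial placement of a neutral layer commutes
(upstream versus downstream gives the same expectation); an epistatic
overlay can break that symmetry, which is precisely the information the
bracketed values carry. Export is DOT (circles for genes, filled when
functional; squares for compartments; green/grey edge colors as style
defaults) or JSON, with a JSON round-trip that is exactly idempotent.

## Known limitations

* The per-cross test's degrees of freedom are a modeling choice, not a
  recovered fact; q-values shift slightly under small `df`.
* No uncertainty propagation on buffering parameters: states are point
  values.
* No aggregation of epsilon scores into network-level statistics, and no
  inference of pathway order from data — diagrams encode hypotheses, not
  fits.
* The parallel model with fitter-than-wild-type singles is computed but
  outside the validated range, as noted above.
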