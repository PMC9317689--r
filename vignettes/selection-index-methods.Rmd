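---
title: "Methods: multi-trait selection indices for multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait selection indices for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsel)
```

## The model

A genotype's *net genetic merit* is $H = \mathbf{w}'\mathbf{g}$, where
$\mathbf{g}$ is its vector of true genotypic values for $t$ traits
(multivariate normal with covariance $\mathbf{C}$) and $\mathbf{w}$ a vector
of fixed economic weights, each expressing the value of one unit of a trait
in merit units. $H$ is unobservable; what a trial delivers per genotype is a
phenotype vector $\mathbf{y}$ (here: the BLUEs across environments) with
covariance $\mathbf{P}$.

The Smith linear phenotypic selection index is the linear score
$I = \mathbf{b}'\mathbf{y}$ maximizing $\rho_{HI} = \mathrm{cor}(H, I)$; its
coefficients solve $\mathbf{P}\mathbf{b} = \mathbf{C}\mathbf{w}$
(`lpsi_coefficients()`). For truncation selection of the top fraction $p$
with standardized intensity $k$:

- response to selection $R = k\,\sigma_H\,\rho_{HI}$, with
  $\sigma_H^2 = \mathbf{w}'\mathbf{C}\mathbf{w}$;
- expected genetic gain per trait
  $\mathbf{E} = k\,\mathbf{C}\mathbf{b} / \sigma_I$, with
  $\sigma_I^2 = \mathbf{b}'\mathbf{P}\mathbf{b}$;
- $\rho_{HI} = \mathbf{w}'\mathbf{C}\mathbf{b} / (\sigma_H \sigma_I)$.

These are the standard Smith forms; for the unrestricted index the identity
$\mathbf{w}'\mathbf{C}\boldsymbol\beta =
\boldsymbol\beta'\mathbf{P}\boldsymbol\beta$ makes $R = k\sigma_I$, which
the tests exploit.

The constrained index projects the Smith solution onto a constraint set.
With $\mathbf{U}'$ an $r \times t$ 0/1 indicator of restricted traits,
$\boldsymbol\Psi' = \mathbf{U}'\mathbf{C}$, and
$\mathbf{M}' = \mathbf{D}'\boldsymbol\Psi'$ where $\mathbf{D}'$ is the
$(r-1)\times r$ Mallard contrast matrix of predetermined proportional gains
($\mathbf{D} = \mathbf{U}$, i.e. $\mathbf{M}' = \mathbf{U}'\mathbf{C}$, in
the null-restricted case), the coefficients are
$\mathbf{b} = \mathbf{K}\boldsymbol\beta$ with
$\mathbf{K} = \mathbf{I} - \mathbf{Q}$,
$\mathbf{Q} = \mathbf{P}^{-1}\mathbf{M}
(\mathbf{M}'\mathbf{P}^{-1}\mathbf{M})^{-1}\mathbf{M}'$
(`restricted_coefficients()`). $\mathbf{Q}$ is an oblique projector
($\mathbf{Q}^2 = \mathbf{Q}$), and
$\mathbf{U}'\mathbf{C}\mathbf{b} = 0$ follows algebraically in null mode, so
the restricted traits' expected gains are zero to machine precision — not
approximately, and independently of how $\mathbf{C}$ and $\mathbf{P}$ were
estimated. With an empty restriction $\mathbf{b} = \boldsymbol\beta$
exactly. A single *proportional* restriction ($r = 1$ with a desired gain
$d$) yields an empty contrast and also returns $\boldsymbol\beta$: one
desired-gain direction on one trait constrains nothing beyond scale.

### Assumptions

Joint multivariate normality of $(\mathbf{g}, \mathbf{y})$; known (in
practice, well-estimated) $\mathbf{C}$ and $\mathbf{P}$; selection by
truncation on the index; discrete generations. Because the index is applied
to genotype means across environments, $\mathbf{P}$ must be the covariance
*of those means* — see "the entry-mean basis" below.

## Estimation from trial records

`compute_blues()` fits the two-way genotype + environment fixed-effects
model per trait and reports each genotype's adjusted mean; on complete
balanced data this collapses to the arithmetic genotype mean and is computed
that way. `variance_components()` uses balanced-ANOVA method of moments:
$\hat\sigma^2_\varepsilon = MS_{error}$,
$\hat\sigma^2_{ge} = (MS_{GE} - MS_{error})/r$,
$\hat\sigma^2_g = (MS_G - MS_{GE})/(re)$, with negative estimates truncated
at zero and flagged. `covariance_matrices()` is the multivariate analogue
via mean cross-product matrices:
$\hat{\mathbf{C}} = (MCP_G - MCP_{GE})/(re)$ and
$\hat{\mathbf{P}} = MCP_G/(re)$.

We chose the moment estimator over a REML mixed model deliberately: it is
closed-form, so every estimate in the test suite can be checked against
hand-computed sums of squares, and on balanced data the two coincide. The
cost is that unbalanced data are rejected rather than absorbed — callers
must either impute via the two-way least-squares fit (`compute_blues()`
handles missing plots) or drop incomplete genotypes before variance
estimation. `mask_plots()` is the sanctioned way to create unbalanced data
in simulations.

**The entry-mean basis.** $\hat{\mathbf{P}} = MCP_G/(re)$ estimates
$\mathbf{C} + \mathbf{C}_{ge}/e + \mathbf{C}_\varepsilon/(re)$ — the
covariance of genotype BLUEs, not of single plots. Since the indices score
BLUEs, this is the basis on which $\sigma_I$, $\rho_{HI}$ and $\mathbf{E}$
are meaningful; the per-trait ratio
$\mathrm{diag}(\mathbf{C})/\mathrm{diag}(\mathbf{P})$ is then exactly the
entry-mean broad-sense heritability
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/e +
\sigma^2_\varepsilon/(re))$ (`broad_sense_heritability()`). Plot-basis
$\mathbf{P}$ would understate $\rho_{HI}$ and distort every gain prediction.

**Conditioning.** Estimated $\hat{\mathbf{C}}$ can be indefinite in small
samples; `ensure_psd()` floors eigenvalues (at 0 for $\mathbf{C}$; at
$10^{-8}\times\overline{\mathrm{diag}}$ for $\mathbf{P}$, which must be
invertible) and leaves the remaining eigenpairs untouched. All inversions
are linear solves; a residual condition number above $10^{12}$ aborts with a
diagnostic rather than silently pseudo-inverting.

## The synthetic wheat panel

`default_wheat_spec()` emulates the study system the package is built
around: 196 spring-wheat genotypes, four traits — days to maturity (d),
plant height (cm), grain yield (t/ha), grain protein content (%) — in 5
conventionally and 4 organically managed environments with 2 replicates
(3528 plots). Choices, in order of how strongly the field pins them down:

- **Genetic correlations** yield–GPC $-0.56$, yield–height $-0.47$,
  yield–maturity $+0.50$: the observed values in this germplasm.
- **Trait means and genetic SDs** (89 d / 2.7, 89 cm / 6.0, 4.8 t/ha /
  0.65, 14.2% / 1.2): means sit mid-range of the observed BLUE ranges
  (81–97 d, 71–107 cm, 2.8–6.7 t/ha, 10.6–17.7%) and SDs are roughly
  one-sixth of those ranges.
- **Noise magnitudes** are *choices, not reconstructions*: the field data
  report that G×E is significant but not its magnitude. We set per-trait
  G×E and residual variances as multiples of the genetic variance (2×/4×
  for maturity and height, 3×/5× for yield, 0.8×/1.6× for GPC) so that
  entry-mean heritabilities land inside the observed 0.32–0.80 band per
  management, with GPC the most and yield the least heritable — the
  qualitative pattern wheat breeders expect. The remaining genetic
  correlations (maturity–height 0.15, maturity–GPC −0.15, height–GPC 0.10)
  are weak placeholders consistent with positive-definiteness.
- **Structure**: the generator produces a complete balanced layout even
  though real trials used incomplete blocks, because every downstream
  moment estimator assumes balance and balanced closed forms are
  verifiable. G×E deviations are independent across environments
  (compound symmetry) and share the genetic correlation structure;
  environment main effects are drawn once per environment and cancel from
  all genotype contrasts, so their spread is a free parameter.

What passing tests on this generator do **not** show: robustness to spatial
field trend, to year/weather structure in G×E, to non-normal trait
distributions, or to the selection bias present in real germplasm panels.

## Selection intensity

`selection_intensity(p)` returns the infinite-population normal truncation
value $k = \phi(z_p)/p$ (1.755 at $p = 0.10$). For a panel of $n = 196$,
the exact expectation of the mean of the top $m = 20$ of $n$ standard
normal order statistics is about 1.733; `selection_intensity(p, n)`
computes it by numerical integration of the order-statistic densities. The
finite-$n$ value is what the Monte-Carlo validation uses, since there the
predicted and realized differentials must agree in expectation, not just
asymptotically. Default reporting uses the asymptotic $k$, the convention
in breeding tables.

## The weight sweep

`default_grid()` fixes the levels as $\{-1,-5,-10,-15\}$ for maturity and
height, $\{1, 10, \ldots, 80\}$ for GPC (9 levels) and
$\{1, 10, \ldots, 150\}$ for yield (16 levels). "1 to 80 at an interval of
10" is arithmetically ambiguous; only this reading yields the canonical
grid size $4 \cdot 4 \cdot 9 \cdot 16 = 2304$, which is why it is fixed
prominently here. Because $\mathbf{b}$ is linear in $\mathbf{w}$ per
scenario, `evaluate_grid()` evaluates all 2304 weights with a handful of
matrix products rather than 2304 solves.

Weight comparison follows the per-factor convention: a one-way ANOVA of a
selection parameter over one trait's weight levels
(`compare_weight_levels()`), with Tukey HSD as an optional addendum and a
factorial model behind `factorial = TRUE` for users who prefer adjusted
comparisons. Two degenerate cases are resolved by convention: identical
rows across levels report $F = 0$; between-level variation with zero
within-level variance reports $F$ as undefined.

`select_best_weights()` filters by thresholds (max gain for maturity and
height, min gain for yield/GPC, min response, min $\rho_{HI}$) and ranks by
the target-trait gain; ties break by $\rho_{HI}$, then response, then
lexicographic weight order — a deterministic chain chosen so shortlists are
invariant to row order.

## Truncation selection and consistency

`select_top_fraction()` selects $m = \lfloor pn + 0.5 \rfloor$ genotypes
(round-half-up reproduces $196 \times 0.10 \rightarrow 20$); genotypes tied
exactly at the cut are all included and the expansion is logged, since
silently dropping one of two equal genotypes would make results depend on
sort order. Consistency analysis counts, per scenario, how many distinct
weight vectors selected each genotype (membership in any management counts)
and reports the consensus at configurable thresholds, defaulting to "all
shortlisted weights in at least 2 of 3 scenarios"; consensus sets are
nested as thresholds tighten.

Per-management selection uses management-specific $\mathbf{C}/\mathbf{P}$
with management-specific BLUEs by default; the alternative path (combined
matrices, management BLUEs) is exposed via `use_combined_cov` because trial
reports are often ambiguous about which was done, and the choice visibly
changes the selected sets.

## Validation design and problem sizes

The suite validates each layer against an independent oracle: BLUEs against
explicit normal equations; variance components against hand-computed
expected-mean-square arithmetic on a 2×2×2 table; `net_merit_variance`
against brute-force double sums; LPSI optimality against $10^4$ random
candidate indices per instance (analytic correlations); the projector
against direct idempotency checks; selection intensity against numerical
integration and a 2000-draw order-statistic simulation; and the full chain
against Monte-Carlo truth: over 200 simulated panels, the realized genetic
gain of the selected top 10% matches $\mathbf{E} = k\mathbf{C}\mathbf{b} /
\sigma_I$ per trait within three Monte-Carlo standard errors, for both LPSI
and the yield-restricted RLPSI (whose realized yield gain is statistically
zero). Covariance recovery uses 30 replicates of the full 196×9×2 panel.
These sizes were chosen to put Monte-Carlo standard errors well below the
effect sizes being verified while keeping the suite comfortably fast.

## Known limitations

- No REML path: unbalanced data beyond BLUE computation are out of scope.
- $\mathbf{C}$ and $\mathbf{P}$ are treated as known once estimated; the
  sampling error of the index coefficients themselves is not propagated
  into $R$ or $\mathbf{E}$.
- Single-stage, single-cycle theory: no accounting for the Bulmer effect,
  overlapping generations, or genomic information.
- Economic weights are inputs; the package searches a user-supplied grid
  but does not elicit weights or construct Pareto-optimal sets.
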