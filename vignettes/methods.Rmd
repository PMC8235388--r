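---
title: "Methods: a stochastic world-trade CGE for wheat Nutrition at Risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stochastic world-trade CGE for wheat Nutrition at Risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements: the
economic structure, the statistical machinery around it, the parameters that
matter, what the synthetic world does and does not emulate, and the numerical
and design choices made where the design was genuinely open. It states no
empirical result that the test suite or the acceptance script does not itself
compute.

## 1. The question and the pipeline

Wheat supplies a large fraction of protein, energy, iron, zinc, folate and
magnesium in many import-dependent countries. Two kinds of shock threaten
those flows in the short run: weather-driven yield fluctuations, and export
restrictions imposed by large exporters during bad years. The pipeline
quantifies the joint risk as **Nutrition at Risk (NAR)**: the worst-tail
(1-in-20-year, or 1-in-100-year) loss in household wheat consumption, expressed
as a percentage of the population's annual requirement for each nutrient.

Stages: (1) estimate per-region productivity volatility σ_r from yearly yield
series; (2) calibrate a static multi-region trade CGE to a benchmark SAM;
(3) draw i.i.d. N(1, σ_r) wheat-productivity multipliers, re-solve the
equilibrium per draw, with and without export quotas; (4) convert worst-tail
consumption losses into NAR via nutrient contribution shares.

## 2. Model structure and assumptions

Production in each sector is Leontief over intermediate composites and a CES
value-added aggregate of mobile labor and a sector-specific capital/land
composite. Factors are fully employed; only unskilled labor reallocates
across sectors (never across regions) — the short-run assumption that farming
cannot quickly adjust its specific factors. The wheat productivity shock
enters as a Hicks-neutral multiplier on output per unit of the Leontief
bundle, because yearly productivity measured as production over harvested
area absorbs *all* inputs' contributions, not land alone.

Trade is the standard two-nest structure on both sides: CET between domestic
sales and aggregate exports, then CET across bilateral destinations; CES
(Armington) between domestic goods and aggregate imports, then CES across
bilateral sources. Households first aggregate food items in a CES nest with
elasticity 0.1 (food items are poor substitutes for one another), then choose
between the food composite and non-food goods with Cobb–Douglas preferences.
The closure is savings-driven: households save a fixed income share,
investment spends savings plus a fixed net-foreign-savings inflow at
benchmark expenditure shares (the allocation across sectors is not pinned
down by theory; fixed benchmark value shares are the documented choice).

There is no government or tax block: the household owns all factors and the
world capital account closes trade imbalances. This is the smallest closed
structure consistent with the stated closures; whether the original data base
carried taxes is unknowable from the published description, so the tax-free
world is a deliberate, flagged simplification rather than a claimed
equivalence.

### Numeraire, exchange rates and Walras' law

A genuinely open design point. The published description fixes one region's
exchange rate and drops one balance-of-payments equation "by Walras' law".
Working through the accounting of this closure shows something stronger: with
households, investment and quota rents exhausting their budgets *by
construction*, **each region's balance of payments is an identity** implied by
its own zero-profit, factor-market and goods-market equations (a regional
Walras law). BoP equations therefore cannot pin exchange rates, and a
formulation that includes them must drop one equation *per region* and anchor
one nominal level per region.

The equivalent, numerically cleaner formulation used here prices everything
in a common world currency: unknowns are factor prices, domestic prices and
bilateral world prices; one global numeraire equation fixes a
benchmark-weighted world consumer-price index at 1; net foreign savings are
indexed to that numeraire (so they are real, and re-normalizing the numeraire
rescales all nominal variables without touching real quantities — the
homogeneity property the tests check). One labor-market equation (region 1's)
is dropped as the single redundant equation; its residual, and every region's
BoP residual, are exposed through `excess_demand()` as solver-correctness
oracles and are required to vanish at every converged solution. Real exchange
rates (relative national price levels) remain fully endogenous; nominal
exchange rates are a reporting convention in this formulation.

### Calibration in calibrated share form

All quantities are stored in benchmark-value units (benchmark prices 1), so
every CES/CET share parameter is a benchmark value share and scale parameters
are absorbed into units. The aggregator primitives (`ces_price`,
`ces_demand`, `cet_price`, `cet_supply`) satisfy adding-up exactly, which is
what makes the budget identities — and hence the Walras oracles — hold to
machine precision. The tests cross-check this parameterization against the
conventional share/scale form derived independently from first-order
conditions. Elasticities within 1e-6 of 1 switch to the Cobb–Douglas
limiting form.

### Quotas

Export quotas are sized at a fraction (default 0.5) of each baseline
bilateral wheat flow; reading the published "half the original import level
from these exporters" as a statement about bilateral imports. An
aggregate-per-exporter variant sits behind a flag. Enforcement is
solve-and-check: solve unconstrained, clamp violated flows to their ceilings
with a producer-price wedge (the quota rent, accruing to the exporting
household — the paper is silent; this keeps budgets closed), re-solve,
and iterate on the active set until complementarity holds: every quota either
binds with nonnegative rent or is slack with zero rent.

## 3. Parameters that matter

| parameter | default | units / rationale |
|---|---|---|
| wheat Armington elasticity | 4.45 | the one trade elasticity the source states |
| other Armington elasticities | 2.0 | mid-range placeholder, configurable |
| bilateral import-nest elasticity | 2 × Armington | the usual two-nest "rule of two" |
| CET elasticities | 2.0 | not published; neutral placeholder, flagged |
| value-added CES elasticity | 1.2 | not published; placeholder, configurable |
| food-nest CES elasticity | 0.1 | stated estimate for food commodities |
| shock distribution | N(1, σ_r), i.i.d. | mean 1: shocks multiply productivity standardized to reference-year = 1 |
| shock floor | 0.3 | computational floor; applied by *clamping*, because the published per-region count of out-of-range draws matches the untruncated normal tail mass, implying draws below the floor occur and are limited, not redrawn |
| draws | 1000 | 1 draw = 1 year, so the 5% tail is a 1-in-20-year event |
| quota fraction | 0.5 | half of baseline exports |
| VaR tail probabilities | 0.05, 0.01 | reported tails |
| savings rate | 0.25 | feasibility of the default world: the dominant exporter's trade surplus must be funded out of savings; 0.25 is a realistic world-scale rate |

## 4. Volatility estimation

Series are standardized by division by the reference-year value (idempotent;
the reference-year entry becomes exactly 1). `fit_arima()` fixes d = 1 — the
model is written on first differences — and selects (p, q) ≤ (3, 3) by AIC,
ties toward smaller p + q then smaller p; exact ML with a logged
conditional-sum-of-squares fallback. σ_r is the *sample* (n − 1) standard
deviation of the residuals; with n = 25 the convention matters and must
simply be fixed and documented. Non-producing regions carry a null fit with
σ_r = 0, so their shock multiplier is always 1.

Two caveats the tests encode deliberately:

* **AIC order selection is not consistent.** On pure white noise AIC picks a
  spuriously larger model with material probability, so the tests assert what
  the estimator is actually used for — recovery of the innovation SD, and the
  invariant that the selected AIC never exceeds the (0,0) model's — rather
  than exact order identification.
* **Boundary MA fits.** First-differencing a near-trend-stationary series
  manufactures a unit MA root; fits with |θ| ≥ 0.999 are accepted (they are
  ubiquitous in the published volatility table) but flagged in the output.

## 5. What the synthetic world emulates — and what it does not

The generator reproduces the *mechanisms*: a configurable miniature (default
3 regions × 4 sectors: wheat, other-food, food-processing, non-food; one
dominant wheat exporter and one import-dependent, high-volatility region),
balanced SAMs built from a constructed unit-price equilibrium so calibration
has an exact round-trip oracle; yield series with known ARMA structure and
innovation SD; nutrition tables whose contribution shares can be set exactly
(they are back-solved into the nutrient profile), so high-dependence regions
are emulated with known ground truth.

It does **not** emulate: the scale (25 regions, 8 sectors, 4 factors) or any
real country's magnitudes; taxes/tariffs; cross-region correlation of yield
shocks (the method assumes i.i.d. draws); within-country income
heterogeneity; non-price food choice. A green test therefore establishes
that the *method* is implemented correctly and behaves as the theory
predicts on worlds with known truth — not that any real-world headline number
is reproduced. The published country tables rest on a proprietary database
and are out of reach by construction; the one in-source quantitative target
(the Monte Carlo truncation count at the largest published σ) is recomputed
by `scripts/acceptance.R`.

The default yield-series generator is stationary around the reference level
(level = 1 + ARMA); an integrated variant (d = 1 differences, anchored at
the reference year) exists for parameter-recovery oracles. Paths that cross
zero are rejected — productivity is positive by definition — so heavy-σ
simulations condition on admissible paths.

## 6. Numerical choices

* **Solver.** Damped Newton on the logs of the strictly positive unknowns
  (~50 unknowns at default scale), forward-difference Jacobian, benchmark
  warm start, step-halving line search; on failure, homotopy in the shock
  (walking α from 1 toward the target). Convergence at an infinity-norm
  residual below 1e-11 × max benchmark output — residuals are in value units,
  so this is far inside the 1e-7 market-clearing contract.
* **Tolerances.** SAM balance 1e-8 relative; benchmark replication residual
  1e-8; Walras/BoP oracles 1e-6; quota complementarity 1e-7.
* **Degenerate inputs.** Autarkic sectors (no trade) drop their bilateral
  unknowns and equations; zero-share CES/CET branches are inert; constant
  yield series produce the null fit; zero population is rejected.
* **Determinism.** Every generator takes one integer seed through a single
  RNG contract (`with_seed`), solves are deterministic given inputs, and the
  pipeline writes a manifest of md5 checksums; identical configs produce
  byte-identical numeric outputs.
* **VaR.** A pure order statistic (⌈p·n⌉-th smallest), no interpolation:
  "the worst 5% outcome of 1000 draws" reads most naturally as the 50th
  smallest draw, and the choice is isolated behind one function.

## 7. Known limitations

* The within-region factor structure supports one mobile factor; additional
  specific factors add explicit clearing equations but the default world uses
  a single capital/land composite.
* Failed equilibrium solves are excluded from consumption distributions and
  counted; a batch with more than 5% failures aborts loudly rather than
  reporting a biased tail.
* The return-period mapping (1 draw = 1 year) inherits the i.i.d. assumption;
  serially correlated climate regimes would change the interpretation.
* NAR assumes proportional nutrient loss within wheat consumption (no
  substitution inside the wheat basket), consistent with the single-commodity
  focus of the method.
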