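# wheatnar

Stochastic world-trade CGE simulation of wheat-based **Nutrition at Risk
(NAR)** — a desk-scale, fully synthetic re-implementation of a published
analysis pipeline that asks: *if regional wheat yields fluctuate the way
history says they do, and major exporters restrict trade, how much of a
population's nutrient requirement is at risk in a bad year?*

The original analysis runs on proprietary global social-accounting data and
public yield/nutrition statistics. This package replaces every external input
with a seeded synthetic generator with known ground truth, so the entire
method — volatility estimation, general-equilibrium calibration, Monte Carlo
simulation, worst-tail nutrition accounting — is testable end to end on any
machine.

## Who it is for

Researchers and students in food-security economics and nutrition
epidemiology who want a transparent, fully reproducible implementation of the
stochastic-CGE / value-at-risk methodology, and a miniature world economy on
which its mechanics can be interrogated.

## The method

1. **Yield volatility.** Regional wheat productivity series (production per
   harvested area) are standardized to a reference year and fitted with
   ARIMA(p, 1, q) models, orders selected by AIC over p, q ≤ 3. The residual
   standard deviation σ_r measures each region's productivity risk.

2. **Synthetic world & calibration.** A balanced social accounting matrix
   (SAM) for R regions × S sectors × 2 factors is generated from a
   constructed benchmark equilibrium at unit prices. A nested
   CES/CET Armington trade model is calibrated to it: Leontief gross output
   over intermediates and CES value added; CET allocation between domestic
   sales and bilateral export destinations; CES Armington aggregation of
   domestic goods and bilateral imports (wheat elasticity 4.45); two-stage
   household demand (CES food nest, elasticity 0.1, under a Cobb–Douglas top
   level); savings-driven closure with fixed net foreign savings; mobile
   unskilled labor, sector-specific capital.

3. **Monte Carlo shocks.** Wheat total-factor-productivity multipliers are
   drawn i.i.d. N(1, σ_r) per region (1000 draws by default), clamped at a
   floor of 0.3. The equilibrium is re-solved for every draw (damped Newton
   on log prices, benchmark warm start). Scenarios: `Reference` (no shock),
   `Y` (yield shocks), `YQ` (yield shocks + export quotas at 50% of baseline
   exports for designated exporters, enforced with quota-rent
   complementarity).

4. **Nutrition at Risk.** The worst-tail household wheat-consumption change
   (value at risk: the ⌈p·n⌉-th smallest of n draws; p = 0.05 is a 1-in-20
   -year event) is multiplied by the wheat *contribution share* — annual
   wheat-based nutrient supply over the age/sex-adjusted population
   requirement — giving NAR per nutrient (protein, energy, iron, zinc,
   folate, magnesium):

   `NAR% = VaR_p(consumption change %) × (wheat nutrient supply / population requirement)`

   Comparing paired Y and YQ distributions yields the return-period
   amplification: how much more frequent a given-severity nutrition shock
   becomes once exporters restrict trade.

## Worked example

```r
library(wheatnar)

spec   <- world_spec(seed = 42)              # 3 regions x 4 sectors, REG1 dominant wheat exporter
params <- calibrate(generate_sam(spec))

# regional volatilities (here: given; fit_arima() estimates them from series)
sig    <- c(REG1 = 0.159, REG2 = 0.098, REG3 = 0.368)
shocks <- draw_shocks(sig, n_draws = 200, seed = 909)

y  <- run_batch(params, shocks, scenario = "Y")
yq <- run_batch(params, shocks, scenario = "YQ",
                quotas = quota_baseline(params, "REG1", 0.5))

value_at_risk(y[, "REG3"], 0.05)    # -> -29.16937  (worst 5% consumption change, %)
value_at_risk(yq[, "REG3"], 0.05)   # -> -41.55981  (deeper tail under the quota)

return_period_amplification(y[, "REG3"], yq[, "REG3"], p_ref = 0.01)
# -> $probability 0.04: Y's 1-in-100-year loss becomes a 1-in-25-year event under YQ

tabs <- generate_nutrition_tables(params$regions, seed = 42)
print(nar_table(yq, contribution_share(tabs), p = 0.05), digits = 3)
#   region var_consumption_change protein energy   iron   zinc folate magnesium flagged
# 1   REG1                   -9.0   -5.88  -5.12  -4.89  -1.83  -4.55     -1.97    TRUE
# 2   REG2                  -14.4   -6.12  -8.75  -2.92  -4.39  -5.63     -9.92    TRUE
# 3   REG3                  -41.6  -25.68 -16.38 -25.62 -27.15 -17.37    -17.28    TRUE
```

Each NAR cell is the worst-5% consumption loss expressed as a percentage of
that nutrient's annual population requirement; `flagged` marks regions with
any loss beyond 5% of requirements.

(The numbers above are what this exact script prints under seed 909/42; your
seeds will vary. REG3 is the import-dependent region with the most volatile
yields, so it carries the largest Nutrition at Risk, and the exporter's quota
amplifies its tail risk several-fold — the central qualitative finding of the
methodology.)

A full run from one config file:

```sh
Rscript inst/scripts/wheatnar run --config inst/extdata/example_config.txt
```

## Package layout

| module | contents |
|---|---|
| `R/world_spec.R`, `R/synthetic_sam.R` | miniature world spec; balanced SAM generator |
| `R/yield_volatility.R` | yield series generator, standardization, AIC-selected ARIMA fits |
| `R/calibration.R` | benchmark calibration, share parameters, quota sizing |
| `R/cge_core.R` | equilibrium system, Newton solver, quota active set, Walras oracle |
| `R/shock_engine.R` | seeded shock matrices, scenario batch runner |
| `R/nutrition_risk.R` | nutrient supplies, population requirements, VaR, NAR, return periods |
| `R/scenario_cli.R` | flat-file config, pipeline, manifest, CLI |

See `vignettes/methods.Rmd` for the model's assumptions, numerical choices
and known limitations.
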