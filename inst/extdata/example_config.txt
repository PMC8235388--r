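# wheatnar example run configuration.
# Every method constant is stated here explicitly; there are no hidden
# defaults for these values.

regions = REG1,REG2,REG3
seed = 20260909
out_dir = wheatnar_out

# Monte Carlo design: 1000 i.i.d. normal productivity draws per region,
# mean 1, clamped at the 0.3 minimum yield multiplier.
n_draws = 1000
floor = 0.3

# Per-region residual standard deviations of standardized productivity
# (replace with yield_csv = <file> to fit them from a yield series instead).
sigmas = 0.159, 0.098, 0.368

# Trade elasticities: wheat Armington substitution 4.45; household food-nest
# CES elasticity 0.1.
armington_wheat = 4.45
food_elasticity = 0.1

# Scenarios: Reference (no shock), Y (yield shocks), YQ (yield shocks plus
# export quotas at half the baseline export level of the designated
# exporters).
scenarios = Reference,Y,YQ
quota_exporters = REG1
quota_fraction = 0.5

# Worst-tail probabilities for value at risk: 5% (1-in-20 years) and
# 1% (1-in-100 years).
var_probabilities = 0.05, 0.01
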