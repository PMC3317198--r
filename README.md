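# cuptox

Acute copper toxicity analysis for hard, sediment-laden dryland river
waters.

`cuptox` implements the complete computational chain of a 96-h acute
copper bioassay and its supporting hydrochemistry analysis, of the kind
used to test whether a biotic-ligand-model (BLM) prediction for one fish
species can be extrapolated to another:

1. **Probit LC50 estimation.** At each observation time the cumulative
   mortality counts are fit by maximum likelihood to
   P(death) = Φ(α + β·log₁₀ C), and the median lethal concentration is
   LC50 = 10^((Φ⁻¹(0.5) − α)/β), with 95% confidence limits by the delta
   method (default) or Fieller's theorem on the log-dose scale.
   Abbott's correction (p − c)/(1 − c) handles control mortality.
2. **LC50–time decay.** The LC50s at 24–96 h are fit to
   LC50(t) = a·e^(−kt) by ordinary least squares of ln LC50 on t.
3. **Hardness normalization.** Hardness = 2.497·Ca + 4.118·Mg
   (mg CaCO₃/L); LC50s from waters of different hardness are made
   comparable with the US EPA conversion
   LC50₅₀ = LC50·(50/H)^0.9422.
4. **Copper partitioning.** Particulate copper P·Cu = (T·Cu − D·Cu)/TSS,
   the partition coefficient Kd = P·Cu/D·Cu, and the empirical
   BLM-MONTE relation Kd = 1.04×10⁶·TSS^−0.7436.
5. **Seasonal comparison.** Monitoring records are split into dry
   (May–October) and wet (November–April) seasons and each variable's
   means are compared with the dm statistic,
   dm = (x̄ − ȳ)/√(ESx² + ESy²), whose standard errors come from
   bootstrap resampling; |dm| > 2 flags a seasonal difference.

A synthetic-data generator (`simulate_trial()`,
`simulate_seasonal_series()`) reproduces the statistical structure of the
survival trials (binomial mortality under a probit dose–response with
time-decaying LC50, pathwise-monotone cumulative counts) and the
two-season lognormal monitoring series, so every stage is testable
without external data.

## Worked example

```r
library(cuptox)
rep <- run_pipeline(seed = 1, B = 200)   # synthetic trial + monitoring series
print(rep)
```

```
Acute copper toxicity pipeline report
seed: 1 | CI method: delta | B: 200

Lethal concentrations (mg/L):
   24 h: LC50 = 1.133 (0.851-1.508)
   48 h: LC50 = 1.030 (0.809-1.311)
   72 h: LC50 = 0.859 (0.680-1.084)
   96 h: LC50 = 0.671 (0.531-0.847)

LC50 decay: LC50(t) = 1.4040 * exp(-0.0073 t), R^2 = 0.9638

Test-water hardness: 308.7 mg CaCO3/L (Ca:Mg molar ratio 1.46)
Final-time LC50 normalized to 50 mg CaCO3/L: 0.121 mg/L
```

The trial was simulated with a true 96-h LC50 of 0.655 mg/L decaying at
0.0061/h; the fitted 96-h LC50 of 0.671 (0.531–0.847) mg/L recovers it
within its confidence interval. The test water (Ca 73.33, Mg 30.5 mg/L)
is very hard — 308.7 mg CaCO₃/L — so the normalized LC50 of ~0.12 mg/L
at the 50 mg CaCO₃/L reference is what should be compared against
soft-water studies. The seasonal block of the report then flags which
monitoring variables (discharge, Ca, Mg, Na, SO₄, Cl, TSS, TDS, T·Cu,
temperature) differ between the dry and wet seasons at |dm| > 2.

The bundled demo tables (`demo_lc50_series()`,
`demo_seasonal_summary()`, `demo_dm_values()`,
`demo_sampling_chemistry()`) carry the observed LC50 series, seasonal
summary statistics, and sampling-date chemistry of the study system, and
can be substituted for the synthetic inputs anywhere.

A thin command-line wrapper with subcommands
(`simulate | lc50 | decay | waterchem | seasonal | pipeline`) is in
`inst/cli/cuptox.R`:

```sh
Rscript inst/cli/cuptox.R pipeline --seed 1 --B 2000 --out results/run1
```

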