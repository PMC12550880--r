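# thermotraits

Infers thermal-tolerance and resource-competition traits of phytoplankton
populations from crossed temperature × resource growth experiments, and
analyses how those traits covary across populations.

Plate-reader growth experiments of this design — populations grown at every
combination of a temperature gradient (15–35 °C) and a resource gradient
(light, nitrogen or phosphorus at 8 levels), replicated — produce thousands
of exponential growth-rate estimates. Two classical models turn them into
ecology:

* the **Monod model** per population × temperature,
  μ(R) = μ_max·R/(K_s + R) − m, from which the competitive traits derive:
  affinity α = μ_max/K_s, the minimum resource requirement
  **R\*** = m_tot·K_s/(μ_max − m_tot) with m_tot = m + m_ext (lower R\* wins
  equilibrium competition; m_ext = 0.1 d⁻¹ is the system's external loss
  rate), and the net maximum growth rate μ_max − m;
* the **double-exponential thermal performance curve** per
  population × resource level,
  μ(T) = b₁·e^(b₂T)·g(R) − [d₀ + (b₁b₂/d₂)·e^((b₂−d₂)T_opt)·e^(d₂T)],
  whose zero crossings and 80%-performance interval give the thermal limits
  T_max, T_min and the thermal breadth T_br around the optimum T_opt.

Both are fitted by MCMC (4 chains, half burn-in, truncated-normal priors,
split-R̂ diagnostics), derived traits are computed per posterior draw by
closed form or root finding, and two higher-level analyses follow: a
posterior-bootstrap GAM/LM procedure that classifies each trait–gradient
relationship as U-shaped / hump-shaped / increasing / decreasing /
uncertain, and a cross-population association stage (trait summaries, PCA,
ANOSIM, Welch ANOVA + Games-Howell, Kendall correlations, and a
constrained-resampling null for correlations with T_max). A synthetic-data
module generates the full 19-population × 3-resource × 6-temperature × 4-replicate
design (10,944 wells) with known ground-truth traits, so every stage is
testable end-to-end without laboratory data.

The package is aimed at experimental ecologists running factorial
growth-rate assays and at methodologists who want a fully seeded, tested
reference implementation of this trait-inference workflow.

## Worked example

The `analysis/` directory holds the six pipeline stages as numbered
scripts (simulate → growth rates → Monod → TPC → shapes → associations),
each writing its tables under `results/`. Running them in order on the
default synthetic study prints, among other things:

```
$ Rscript analysis/01_simulate.R
simulated 10944 wells across 3 resource experiments (19 populations)
wrote 7488 fluorescence readings (576 wells x 13 time points)

$ Rscript analysis/02_growth_rates.R
estimated 576 growth rates (0 failed)
median |error| 0.0214 /d; model usage: lag=165, lag+saturating=154, linear=82, saturating=175

$ Rscript analysis/03_monod.R
108 Monod fits; 78 retained (growth above m_ext at >= 3 levels); 71 converged
R* spans 0.00364 to 221 across resources

$ Rscript analysis/04_tpc.R
144 TPC units; 108 fitted (>= 3 temperatures above m_ext), 36 skipped
exclusion flags: Topt 0, Tmax 0, Tmin 55, Tbr 0 of 108 fitted
Topt medians span 17.8-32.7 C across populations and levels

$ Rscript analysis/05_shapes.R
53 trait-gradient relationships classified
             decreasing hump-shaped increasing U-shaped uncertain
  alpha               1           1         12        0         4
  net_mu_max          2          12          4        0         0
  rstar               0           0          5       12        0

$ Rscript analysis/06_associations.R
PCA: PC1+PC2 explain 67.4% of trait variance (0 rows dropped for missing traits)
ANOSIM by phylum: R = -0.0350, p = 0.617
TRstar_min ~ Tmax_max: observed tau 0.511 sits at percentile 0.95 of the
constrained null (null mean 0.239)
```

Reading these numbers: the growth-rate estimator recovers per-well rates to
~0.02 d⁻¹; minimum resource requirements span five orders of magnitude
across the three resources; most lower thermal limits (T_min) extrapolate
below 0 °C and are excluded, as expected from a 15–35 °C design; R\* mostly
responds to temperature in a U shape while net-μ_max is hump-shaped —
exactly what the generative growth surface encodes; and the positive null
mean (0.24) for the TRstar_min–Tmax_max correlation shows how much apparent
trait covariation the thermal-range constraint alone produces (phylum
labels are assigned arbitrarily in the simulation, so ANOSIM finds no
phylum signal — on real data this tests phylogenetic structure).

The same pipeline runs as one call:

```r
library(thermotraits)
res <- run_pipeline(default_config(seed = 1, reduced = TRUE), outdir = "results/run1")
```

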