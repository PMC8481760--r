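# smartsim

Monte Carlo microsimulation comparing two trial designs for learning the best
*sequence* of two telemedicine interventions — a self-titration smartphone app
(**App**) and a nurse-led telephone titration service (**Nurse**) — for
patients with type 2 diabetes starting insulin, with glycated hemoglobin
(HbA1c, %) at week 12 as the outcome:

* a two-stage **SMART** (Sequential Multiple Assignment Randomized Trial):
  randomize 1:1 between Nurse and App, classify response at week 6
  (HbA1c reduction ≥ δ, default 0.5), re-randomize non-responders 1:1 between
  switching and the App + Nurse combination;
* a comparable **four-arm RCT** in which the four adaptive interventions (AIs)
  are separate arms fixed at baseline, with the same interim response rule.

Both designs compare the same four adaptive interventions
(N = Nurse, A = App):

| AI | rule |
|----|------|
| 1 | (N, Nᴿ A¹⁻ᴿ) — Nurse, switch to App if non-responder |
| 2 | (N, Nᴿ (A+N)¹⁻ᴿ) — Nurse, combination if non-responder |
| 3 | (A, Aᴿ N¹⁻ᴿ) — App, switch to Nurse if non-responder |
| 4 | (A, Aᴿ (A+N)¹⁻ᴿ) — App, combination if non-responder |

Synthetic subjects follow a fully specified generative model: baseline
HbA1c ~ N(9.73, 1.37) truncated at the 7.5 eligibility floor; independent
latent receptiveness Bernoulli(0.51) to App and Bernoulli(0.69) to Nurse
(combination receptiveness averaging 0.75 among the initially
non-receptive); stage-wise HbA1c reductions N(1.53, 0.71) then N(0.94, 0.77)
for receptive subjects and mean-zero otherwise. In the SMART the embedded
AI means E(Y)\_AIj are estimated by inverse probability weighting (weight 2
for once-randomized responders, 4 for twice-randomized non-responders,
self-normalized); the RCT uses arm means. Across B replicate trials the
package reports the Monte Carlo mean ỹ = Σ ȳ\_b / B and SD
s = √(Σ(ȳ\_b − ỹ)² / (B−1)) of each estimate, the probability of selecting
the truly best AI (argmin of E(Y)), and per-subject trial cost accumulated
from configurable stage/monitoring/re-randomization components.

The methods vignette (`vignettes/smart-vs-rct-microsimulation.Rmd`) explains
the model, the estimators, and every design choice in detail. This package is
intended for trial statisticians and health-services researchers exploring
when a SMART buys efficiency over a conventional multi-arm design.

## Worked example

```r
library(smartsim)

gp <- generative_params()   # base-case population
mc <- run_monte_carlo("SMART", n = 100, B = 2000, master_seed = 42)
mc
#> Monte Carlo summary: SMART design, n = 100, B = 2000, delta = 0.50
#>   overall Y : 8.21 (0.19)
#>   cost (USD): 343.33 (1.59)
#>   AI1: Y = 8.07 (0.32), p_opt = 33.25%
#>   AI2: Y = 8.01 (0.31), p_opt = 45.35%
#>   AI3: Y = 8.39 (0.32), p_opt =  9.85%
#>   AI4: Y = 8.34 (0.30), p_opt = 11.55%

round(analytic_expectations(gp), 3)   # exact model expectations, no simulation
#>   AI1   AI2   AI3   AI4
#> 8.089 8.025 8.393 8.342
```

Reading the output: starting from a mean baseline of 9.88, the cohort ends
near 8.2 under either design; AI2 (Nurse first, combination for
non-responders) is the truly optimal rule and a SMART of n = 100 identifies
it in ~45% of replicate trials — more often than the comparable RCT, whose
per-AI estimates are noisier (arm of 25 vs. ~50 weighted subjects per
embedded AI). Per-subject cost is ~343 USD in both designs.

Single trials with full subject records, experiment runners
(`run_base_case()`, `run_sweep_n()`, `run_sweep_threshold()`) and a YAML
config loader are exported too. A thin CLI wraps them:

```sh
Rscript inst/cli/smartsim.R base-case --n 100 --b 10000 --seed 1 --out results/
Rscript inst/cli/smartsim.R sweep-threshold --design both --b 1000 --seed 1 --out results/
```

Outputs are plain CSVs with a `#`-commented reproducibility header; identical
configuration and seed give byte-identical files.

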