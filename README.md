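# mnemosharp

Analysis tools for recognition-memory experiments in which a subject views
a stream of images and judges each as *novel* or *repeated*, in the
presence of *lure* images — never-seen images visually similar to an
earlier one at a graded dissimilarity `d`. The package asks a specific
quantitative question: is the memory read-out a *linear* function of visual
dissimilarity, or is it **sharpened** (lures rejected more readily than
their visual similarity warrants) or **broadened**?

## What it implements

With `x` a population spike-count vector, both decoders are linear
discriminants

```
f(x) = w·x − b,   b = ½ w·(μN + μR)
```

with `w = (1,…,1)` (spike-count classifier, a pure repetition-suppression
read-out) or `w = μN − μR` (prototype / weighted classifier). A trial is
"novel" iff `f(x) ≥ 0`. Cross-validated decoder predictions yield a
percent-chose-repeat (PCR) curve over `d`, anchored at the repeat (`d = 0`)
and novel (`d = 1`) conditions. After anchor rescaling

```
C_rescaled = (C − C_R) / (C_N − C_R)
```

the **sharpening metric** is twice the signed trapezoidal area between the
rescaled curve and the diagonal benchmark, weighted by
`((acc − 0.5)/(peak − 0.5))²` clipped to [0, 1]. It ranges from −1
(maximally broadened) through 0 (linear) to +1 (maximally sharpened).

The full chain is implemented and tested:

* `representational_dissimilarity()` (1 − Pearson r), greedy lure-pair
  selection, and the 18-statistic low-level image confound classifier;
* session screening (trial count, visual responsiveness, ≥2% repetition
  modulation), unit d′, and rank-aligned pseudopopulation assembly across
  sessions;
* cross-validated decoding with within-condition shuffling, ranked lure
  bins, anchor rescaling, and ranked-unit (High/Low/Rand) curves;
* the sharpening metric, 21-window sliding dynamics, latency of the 0.1
  threshold crossing, and Welch latency comparisons;
* a Poisson spiking simulator (`sim_config()`, `simulate_study()`) with a
  known ground-truth memory-transfer function `m(d)` (linear, power,
  logistic), so recovery of the metric can be validated against ground
  truth.

## Worked example

```r
library(mnemosharp)

cfg <- sim_config(n_sessions = 6, units_per_session = 24,
                  transfer = transfer_profile("power", 3),  # sharpened truth
                  seed = 2026)
study <- simulate_study(cfg)
kept  <- Filter(function(s) session_inclusion(s)$included, study$sessions)
pop   <- build_pseudopopulation(kept, target_nbacks = 23:26, seed = 1)
cv    <- crossval_run(pop, kind = "spike_count", n_iterations = 100, seed = 17)
sharpening_from_crossval(cv)[c("mean", "se")]
```

```
$mean
[1] 0.4335

$se
[1] 0.01
```

The decoder (overall accuracy 0.832 in the 300–500 ms window) predicts a
PCR curve bowed below the linear benchmark, and the metric reads +0.43:
strongly sharpened, matching the generative `γ = 3` transfer whose
ground-truth score is +0.50 (count noise attenuates the estimate toward
the benchmark, never away from it). The same study under a linear transfer
reads −0.014 ± 0.010, and under `γ = 1/3` it reads −0.41 — the metric
recovers the sign of the generative regime in each case.

The numbered drivers under `analysis/` run the chain stage by stage
(simulate → screen → pseudopopulation → decode → sharpening → dynamics),
print what each stage found, and write tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R
...
Rscript analysis/06_dynamics.R
```

`run_pipeline(config, out_dir)` runs the same chain from one (YAML or
list) configuration with a content-hashed manifest; re-running a config
reproduces byte-identical outputs.

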