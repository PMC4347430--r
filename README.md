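# fragilenet

Closed-loop control of a fragile neuronal network: simulate an epileptic
circuit that randomly slips from a stable (non-seizure) into an unstable
(seizure) mode, detect the transition from single-node firing rates, and
stabilize the network with state feedback.

## The problem and who this is for

One influential view of epilepsy is that the cortical network is
*fragile*: it operates close to instability, and a small change in the
synaptic connections of one node tips the whole network into seizure
dynamics. For computational neuroscientists and control engineers
studying closed-loop neurostimulation, this package provides a complete,
reproducible in-silico test bed for that hypothesis:

* a stochastic binary-neuron network (event-driven Gillespie simulation)
  with transition rates `tr_i = α·x_i + f(s_i)·(1 − x_i)` and synaptic
  input `s_i = Σ_j W_ij·x_j + u_i`, where `f` is a clamped hyperbolic
  tangent and `α = 0.1 ms⁻¹` (100 Hz) caps firing rates;
* mean-field analysis: fixed point `r*` of
  `ṙ_i = −α·r_i + f(s̄_i)(1 − r_i)`, functional connectivity
  `A = ∂ṙ/∂r`, input matrix `B = ∂ṙ/∂u` (diagonal);
* **nodal fragility**: the minimum-energy single-row perturbation `Δ`
  placing an eigenvalue of `A + Δ` at a target real part, in closed form
  `δ = −c/‖c‖²`, `c = (A − λI)⁻¹ e_k`; the fragile node is the row of
  minimum energy;
* a two-mode HMM **instability detector** on the fragile node's
  normalized, window-averaged firing rate (250 ms windows, 25-window
  average, 1 ms grid): Gaussian emissions fit by MLE, likelihood ratio
  `LR_k = q₂(p_k)/q₁(p_k)`, detection when the cumulative-LR derivative
  crosses a calibrated threshold, and stable-mode re-detection after
  500 ms inside the ±2 SD stable band;
* **state-feedback controllers** applied to the fragile node while the
  detector's switch σ is closed: a linear-model gain `K = −B⁻¹Δ`
  (restores the stable spectrum, `A + Δ + BK = A`) and a nonlinear-model
  gain `K = −Δ` (cancels the perturbation exactly inside the synaptic
  input);
* a **synthetic network generator** for paper-like fixtures (6 nodes, 14
  directed connections, Dale's rule, an inhibitory most-fragile node,
  leading eigenvalue just below zero) verified in simulation to show the
  seizure mechanism: *disinhibition* — the fragile inhibitory node's rate
  collapses while the network speeds up;
* a closed-loop benchmark reporting detection delay, stable-mode delay
  and time to first stable firing rate per seizure episode.

See `vignettes/fragilenet-methods.Rmd` for the model, calibration
procedure, numerical choices, and limitations.

## Worked example

```r
library(fragilenet)

# 1. a reproducible fragile network fixture
gen <- generate_network(seed = 42)
gen
#> <generated_network> N = 6 | connections = 14 | inhibitory: 4, 5 |
#>   fragile node: 4 | Re(lambda_1(A)) = -0.04 ms^-1
gen$fragility
#> <fragility_report> target Re(lambda_1) = 0 ms^-1 |
#>   energies: 0.09044 0.1458 0.17 0.06264 0.09685 0.136 | fragile node: 4
```

The network is stable but on the brink (`Re λ₁(A) = −0.04 ms⁻¹`), and
node 4 — inhibitory — needs the least perturbation energy (0.063) to
destabilize the whole network: it is the fragile node.

```r
# 2. calibrate the detector (100 s stable + unstable simulations)
calib <- calibrate_detector(gen$cfg, gen$modes, seed = 1042)
calib
#> <detector_calibration> node 4 | max_count = 17 | threshold = 740 per ms
#>   <emission_model> q1: N( 0.4631 , 0.01653 ) | q2: N( 0.04128 , 0.002599 )
```

In the stable mode node 4 fires at ~46% of its calibrated maximum; in the
seizure mode its rate collapses to ~4% (disinhibition), so the two
emission densities are well separated.

```r
# 3. run the closed loop: random onsets, detection, feedback, recovery
res <- closed_loop_run(gen$cfg, gen$modes, calib, variant = "nonlinear",
                       n_episodes = 5, seed = 7)
res$episodes[, c("target", "onset_time", "detection_delay",
                 "stable_mode_delay", "first_stable_fr")]
#>       target onset_time detection_delay stable_mode_delay first_stable_fr
#> 1   target_0        505             259               661             161
#> 2 target_0.2       2178             399               622             122
#> 3   target_0      16295             472               631             131
#> 4 target_0.2      20017             254               653             153
#> 5   target_0      25516             415              1539             139
```

Each seizure is detected a few hundred ms after onset and suppressed
within ~1–2 s (all times in ms).

```r
# 4. benchmark both controllers (25 detections per seizure matrix each)
rep <- run_benchmark(gen$cfg, gen$modes, calib, detections_per_matrix = 25,
                     variants = c("linear", "nonlinear"), seed = 5)
rep$summary
#>     variant            metric  n mean_ms      sd_ms
#> 1    linear   detection_delay 50  332.78  182.26604
#> 2    linear stable_mode_delay 50 2309.30 1645.86484
#> 3    linear   first_stable_fr 50   89.88   29.52456
#> 4    linear   onset_to_stable 50 2642.08 1701.65302
#> 5 nonlinear   detection_delay 50  339.42  141.32682
#> 6 nonlinear stable_mode_delay 50  731.10  251.58536
#> 7 nonlinear   first_stable_fr 50  137.54   53.74323
#> 8 nonlinear   onset_to_stable 50 1070.52  301.91114
```

The nonlinear-model gain returns the network to its stable mode faster
(mean stable-mode delay 0.73 s vs 2.31 s) because it cancels the
perturbation exactly, while the linear-model gain brings the firing rate
back into the stable band sooner for the first time (90 ms vs 138 ms) —
its transient is less abrupt. Every detection in both runs was a true
positive.

## Command line

```sh
fragilenet generate --seed 42 --out out/            # network + fragility
fragilenet calibrate --network out/network.json --seed 1 --out out/
fragilenet simulate --network out/network.json --matrix target_0.2 \
    --duration-s 10 --seed 3 --out out/
fragilenet run-closed-loop --network out/network.json \
    --calibration out/calibration.json --variant nonlinear --out out/
fragilenet benchmark --network out/network.json \
    --calibration out/calibration.json --detections 100 --out out/
```

(The entry point installs to `<library>/fragilenet/exec/fragilenet`; every
run writes a `manifest.json` with version, seed and input hashes.)

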