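# picovir

Quantitative analysis of batch-culture infection experiments with lytic
viruses of picophytoplankton (e.g. *Ostreococcus* and its
prasinoviruses). The package turns the raw flow-cytometric outputs of
such an experiment — host and free-virion concentration time series,
per-cell SYBR (DNA) fluorescence event tables, and serial-dilution
endpoint-assay well outcomes — into the standard infection-biology
quantities, and ships a ground-truth-bearing simulator of the whole
experiment so every estimator is testable end to end.

## What it computes

* **MPN titration** — maximum-likelihood Most Probable Number estimation
  of infectious titre under the Poisson single-hit model
  (`estimateMPN()`): a well at dilution *d* with inoculum volume *v* is
  positive with probability 1 − e^(−c·v·d); the MLE maximizes
  Σ [pᵢ ln(1 − e^(−c·vᵢ·dᵢ)) − (nᵢ−pᵢ)·c·vᵢ·dᵢ] over all levels, with a
  Wald 95% CI on log c. Infectivity = MPN / total virions, and
  MOI = virus:host ratio × infectivity (`infectivity()`,
  `computeMOI()`).
* **Cell-cycle gating** (`gateG1()`) — gain-invariant G1-peak detection
  on the log-fluorescence KDE (the G1 peak sits at half the fluorescence
  of the G2/M peak) and the **infected-fraction correction**
  (`infectedFraction()`): F_I = F^>G1 − F^D with F^D = F^D_C · s,
  s = clamp(n_I/n_C, 0, 1).
* **Kinetics** — log2 fold change n_t = (ln N_t − ln N_i)/ln 2, growth
  rate μ = ln(N_t/N_i)/Δt, the latent-period interval (first timepoint
  whose virion log2FC tests significantly > 0), burst size
  ΔV/(−ΔH) over a late-lysis window, viral production VP = N_t/N_i and
  the limited-light/standard-light sensitivity ratio, plus the
  per-timepoint Type II ANOVA + Tukey + Welch testing protocol
  (`latentPeriod()`, `burstSize()`, `viralProduction()`,
  `sensitivityRatio()`, `testProtocol()`).
* **Replication energetics** — direct cost of dsDNA genome replication,
  E ≈ 2·L_g·(e_d + e_p) ATP-equivalents with e_d = 11, e_p = 2
  (`replicationCost()`, `costDifference()`).
* **Simulation** — a stochastic discrete-time model of the experiment
  (diel-pulsed host division, adsorption, latency, burst, reinfection,
  DNA-content observation model, lognormal count noise, MPN wells) with
  exact mass balance and bit-reproducible output (`SimConfig()`,
  `runExperiment()`, `simulateMPNAssay()`).
* **Pipeline** — `runPipeline()` ties simulate → MPN → cell cycle →
  kinetics into one reproducible run, writing tidy CSVs, JSON summaries
  and (in synthetic mode) a parameter-recovery report.

See `vignettes/picovir-methods.Rmd` for the models, assumptions,
parameter defaults and design decisions.

## Worked example

A full synthetic experiment at the default study conditions (hosts at
3.2×10⁶ cells/mL growing at 0.76/d, target MOI 3 at 32% infectivity,
latent period 7 h, mean burst 500):

```r
library(picovir)

cfg <- SimConfig(seed = 21)
res <- runPipeline(list(simulate = cfg, seed = 21,
                        analysis = list(burst_window = c(10.5, 14.5))),
                   outDir = "run21")

res$summary$moi
#> $value  2.4      $ci  1.5 4.1
res$summary$latent_interval_h
#> [1] 6.5 8.5
res$summary$burst_size$mean
#> [1] 545.2926
res$recovery$burst_size$relative_error
#> [1] 0.09058527
```

The recovery report compares every estimate with the generative truth:
the latent interval (6.5, 8.5] h contains the true 7 h latency, the burst
estimate 545 sits within 10% of the true 500, and the MPN-derived
infectivity 0.26 (CI 0.16–0.43) covers the true 0.32. Estimating MPN
directly from a well table:

```r
est <- estimateMPN(DilutionAssay(10^-(4:8), c(24, 24, 18, 4, 0),
                                 total = 24, volume = 0.05))
est
#> MPN estimate: 28652906 /mL  (95% CI 18321318-44810586)

computeMOI(4.8, 0.32, ci = c(0.20, 0.52))
#> Infectivity: 32% (20%-52%)
#> MOI: 1.5 (0.96-2.5) at virus:host = 4.8
```

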