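# beetlecue

Circular-statistics tools for analysing how an insect compass combines two
directional cues of unequal reliability. The package was built around the
cue-conflict paradigm used with ball-rolling dung beetles: an animal sets a
heading using an artificial sun (a green LED at a controlled elevation) and a
wind current, the wind azimuth is shifted by 60 or 120 degrees between two
consecutive arena exits, and the *change in heading* reveals how the two cues
were weighted. `beetlecue` provides the full chain:

1. **Cue noise model.** Each cue's perceptual noise is a von Mises
   distribution `f(x; mu, kappa) = exp(kappa cos(x - mu)) / (2 pi I0(kappa))`.
   Reliability (the concentration `kappa`) is predicted from the physical
   condition by linear fits of the mean vector length,
   `R_wind = 0.11 s + 0.43 + c_wind` (s in m/s) and
   `R_light = -0.07 phi + 0.80 + c_light` for elevations `phi` (radians) up
   to 75 degrees, `-1.26 phi + 2.31 + c_light` above, then inverted to
   `kappa` with Fisher's three-branch approximation.
2. **Five integration models**, all mapping two sampled cue directions to one
   heading: winner-take-all (**WTA**), the linear weighted arithmetic mean
   (**WAM**, included because it is classical and wrong for angles), the
   optimal weighted vector sum (**WVS**, weights proportional to kappas), a
   sigmoid-adjusted non-optimal vector sum (**NVS**, steepness `a = 53`) and
   its biased variant (**BVS**) with a per-individual weight bias
   `b ~ N(0, sigma)` with `sigma^2 = 0.000303`.
3. **Monte-Carlo simulator** of the conflict paradigm (default 10^6
   individuals per condition, 5-degree binned PMFs over the 21-condition
   grid) and **binned-likelihood model comparison** (log-likelihood ratios,
   AIC and BIC ratios relative to the maximally likely model).
4. **Empirical pipeline** for exit-angle tables: cue normalisation, Rayleigh
   exclusion screens, menotaxis classification, precision medians, and
   change-in-heading statistics.
5. **Synthetic-data generator** with known-truth manifests, so the entire
   pipeline is testable end-to-end (model recovery) without any downloads.

## Worked example

Synthesise a conflict experiment generated by the biased vector-sum model,
run the screening/analysis pipeline, and ask which of the five models best
explains the resulting changes in heading:

```r
library(beetlecue)

condition_kappas(cue_condition(60, 2.5))
#>  kappa_wind kappa_light
#>    3.419141    3.924119        # the near-parity condition

ds  <- generate_conflict_dataset(model = "BVS", n_beetles = 30, seed = 7)
res <- reproduce_comparison(ds$exits, n_sim = 1e5, seed = 8)
print(res$comparison)
#> Cross-model comparison (best first):
#>  model n_params log_likelihood_ratio AIC_ratio BIC_ratio
#>    BVS        2              0.00000   1.00000   1.00000
#>    NVS        1             -4.58054   1.00162   1.00062
#>    WTA        0            -31.09805   1.01319   1.01116
#>    WVS        0            -38.73839   1.01665   1.01462
#>    WAM        0            -88.50323   1.03920   1.03713
#> n = 612 data points; lnP in nats
```

The generating model (BVS) is top-ranked: its log-likelihood ratio is 0 by
definition and every rival is less likely (more negative LR, AIC/BIC ratios
above 1). 204 of the 210 simulated beetles passed the bearing-recovery
screen, leaving 612 changes in heading (3 per session). Per-condition
behavioural statistics come from the same result object:

```r
summarize_condition(res$analysis$changes_by_condition[["e60_s2.5_c60"]])
#> $n 30; $mean_deg 20.2; $circ_sd_deg 37.3; $R 0.809; $rayleigh_p 3.7e-09
```

## Command line

```sh
Rscript inst/exec/beetlecue synth    --out exits.csv --seed 1
Rscript inst/exec/beetlecue reproduce --data exits.csv --out table1.csv --nsim 100000
```

`reproduce` chains screening, simulation and evaluation with the published
defaults (`a = 53`, `sigma_bias^2 = 0.000303`, 5-degree bins) and writes the
comparison table as CSV and JSON. All subcommands accept `--seed` and are
bit-reproducible given it.

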