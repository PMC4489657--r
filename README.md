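# proturn

Kinetic analysis of unstable regulatory proteins whose abundance is set by
the balance between synthesis and constitutive proteolysis.  The motivating
system is the bacterial replication initiator DnaA in *Caulobacter
crescentus*, which the Lon protease degrades with a ~20-min half-life: when
a culture runs out of nutrients and translation of the initiator slows,
ongoing degradation eliminates the protein within a couple of hours and DNA
replication arrests.  `proturn` packages the modelling and inference used to
dissect such behaviour from standard wet-lab readouts — immunoblot band
densitometry across a growth curve, chloramphenicol-chase decay assays, and
comparative-Ct qPCR.

## The model

Relative protein abundance P(t) follows first-order turnover with a
time-varying degradation rate,

    dP/dt = ks − kd(t) · P(t),        kd(t) = a·t + kd0,

where ks is the synthesis rate (constant unless inferred point-wise), kd0 =
ln2 / t½(0) is the degradation rate in exponential phase, and the
acceleration a captures any change in proteolysis along the growth curve.
Half-life and rate interconvert as t½ = ln2 / kd.  Dilution by growth is
neglected because the half-life is much shorter than the doubling time.
Time is measured in minutes from the exponential-phase reference (OD600
0.4); the anchors OD 0.4 / 1.0 / 1.5 correspond to t = 0 / 160 / 400 min.

On top of the forward model the package provides:

* **Half-life estimation** from synthesis shut-off (chase) time courses by
  pooled semi-log least squares, with censored reporting ("> chase
  duration") for proteins stable over the chase.
* **Degradation-acceleration fitting**: bounded multi-start minimization of
  the relative least-squares objective
  Σᵢ ((P_model(tᵢ) − P_obs(tᵢ)) / P_obs(tᵢ))² over (ks, a), with kd0
  anchored at the measured exponential-phase half-life.
* **Point-wise synthesis inference** ks(tᵢ) = dP/dt + kd(tᵢ)·P(tᵢ), with
  dP/dt from a global linear fit, and **translation-rate estimation** by
  dividing through the relative mRNA abundance from ΔΔCt qPCR.
* **Synthetic data generators** (logistic growth curves, abundance courses
  forward-solved from any synthesis/degradation schedule, chase assays, Ct
  tables) with seeded multiplicative lognormal noise, so the entire
  inference chain is testable by simulation.

## Worked example

How much protein can a measured 23 → 20 min half-life change eliminate?

```r
library(proturn)
sched <- build_linear_schedule(23, 20, t1 = 160, window_end = 400)
m <- turnover_model(sched, ks = "steady_state", p0 = 1)
solve_abundance(m, c(0, 160, 400))
#>   time_min abundance
#> 1        0 1.0000000
#> 2      160 0.8914745
#> 3      400 0.7398851
```

Only a ~26% decrease by 400 min — nowhere near the ~90% drop such proteins
show on entry to stationary phase, so the decline must come from synthesis,
not proteolysis.  The rest of the chain runs on synthetic data emulating
the assays (seeded, CV 10% densitometry noise):

```r
g <- generate_scenario(default_scenario(), seed = 1)
synth <- infer_synthesis_pointwise(g$abundance, halflives = c(23, 23, 20, 20))
synth
#>   time_min od600     ks_raw    ks_norm
#> 1   0.0000   0.4 0.02709501 1.00000000
#> 2 107.4770   0.8 0.01852064 0.68354433
#> 3 225.0557   1.2 0.01172136 0.43260211
#> 4 342.6344   1.4 0.00194853 0.07191472

expr <- delta_delta_ct(g$ct, target = "dnaA", reference = "16S",
                       calibrator = "od0.4")
translation_rates(synth, expr)
#>   time_min od600      mrna  rate_raw rate_norm
#> 1   0.0000   0.4 1.0000000 1.0000000 1.0000000
#> 2 107.4770   0.8 0.8577918 0.7968650 0.7968650
#> 3 225.0557   1.2 0.7378655 0.5862886 0.5862886
#> 4 342.6344   1.4 0.5844370 0.1230496 0.1230496
```

The inferred synthesis rate falls ~14-fold across the growth curve in this
noisy draw (the generating truth is 20-fold; the terminal estimate is the
small difference of two nearly cancelling terms, so single noisy draws
scatter around it), while mRNA only drops to ~58% — the gap is the
translation-rate decline in the last column.  `run_pipeline()` chains the
same stages (half-life → fit → synthesis → qPCR) from tidy CSVs and writes
per-stage tables plus a deterministic `summary.json`.

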