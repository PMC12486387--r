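# mckm

Kinetic characterization of individual CHO cell line culture runs during
cell line development (CLD).

Screening campaigns cultivate hundreds of clonal GS-CHO cell lines in
parallel 15 mL fed-batch minibioreactors, sampling each culture about seven
times over ~15 days for seven quantities: viable cell concentration (VCC),
mAb titre, glucose, glutamate, glutamine, ammonium, and lactate. `mckm`
turns each such run — 49 data points — into a 13-parameter kinetic
fingerprint that makes clones, passages, and campaigns comparable on
interpretable metabolic axes.

The model couples eight states between bolus feeds:

- Monod growth on glucose, `mu = mu_max * glc / (K_glc + glc)`, with
  ammonium-driven death `mu_d = k_d * amm / (KD_amm + amm)`;
- growth-associated (Luedeking–Piret) rates for product, glutamate,
  glutamine (with glutamine-synthetase conversion of glutamate), and
  ammonium;
- a glucose-gated lactate switch: overflow production
  `q_lac = +Y_lac_glc * q_glc` while `glc >= alpha_glc`, consumption
  `q_lac = -mu / Y_X_lac` below the threshold;
- an auxiliary growth-rate state `d(mu_est)/dt = mu_max * K_glc *
  (dglc/dt) / (K_glc + glc)^2` regressed against growth-rate estimates
  derived from the VCC series, constraining fits toward realistic growth
  dynamics.

Around the model sit the full workflow pieces: bolus fed-batch simulation
(7 sampling times, 6 batch iterations, feeds applied right after
sampling), bounded least-squares regression with automated parameter
balancing (refits with `K_glc` or `mu_max` fixed when the free fit misses
R² ≥ 0.90 on VCC or titre), a local sensitivity / collinearity-index
identifiability toolkit, a synthetic Ambr15™-style campaign generator, and
cohort summaries with Fisher LDA on the fitted parameters.

## Worked example

```r
library(mckm)

theta <- kinetic_parameters(mckm_population_defaults()$mean)
cons  <- model_constants()

sim <- simulate_fedbatch(theta, default_initial_state(), cons,
                         default_feed_schedule())
print(sim)
#> Fed-batch simulation: 7 sampling times, 6 batch iterations, 5 feeds
#>      time_h      Xv      P    glc    glu    gln    amm    lac  mu_est
#> [1,]      0  0.3000 0.0000 6.0000 4.0000 0.5000 1.0000 0.2000 0.0220
#> [2,]     72  1.2092 0.0494 5.4939 3.8851 0.4161 1.0934 0.3448 0.0217
#> [3,]    144  4.8925 0.2534 6.4368 4.8946 0.0534 1.4467 0.9358 0.0222
#> [4,]    192 11.6876 0.6496 5.2215 5.3644 0.0000 2.1652 2.0904 0.0215
#> [5,]    240 22.1610 1.3679 0.5341 5.0008 0.0000 3.4944 4.1891 0.0087
#> [6,]    312 17.7381 1.6653 0.0000 5.5391 0.0000 4.0298 4.5918 0.0000
#> [7,]    360 16.6100 1.8965 0.0008 6.1611 0.0000 4.4415 4.8146 0.0000
```

The culture grows to a peak VCC of ~22×10⁹ cells/L on day 10, glutamine is
exhausted by day 8, glucose crosses the 0.5 g/L lactate-switch threshold
during the day 10–13 interval (lactate then plateaus as cells start
consuming it), and titre climbs to ~1.9 g/L while rising ammonium drives
the death phase.

Regressing a synthetic noisy run back to its parameters:

```r
spec <- campaign_spec(noise_cv = 0.02, missing_rate = 0)
set.seed(7)
run <- generate_run(theta, spec)      # 7x7 noisy observations + mu_est
fit <- fit_run(run, cons)
fit$mode                              # "free" — no balancing needed
round(fit$r2, 3)
#>    Xv      P    glc    glu    gln    amm    lac mu_est
#> 0.976  0.999  0.993  0.991  0.999  0.998  0.997  0.989
round(fit$theta_hat[c("mu_max", "Y_P_X", "Y_X_glc")], 4)
#> mu_max  Y_P_X Y_X_glc
#> 0.0196 0.0644  1.8799
```

The generating values were `mu_max` 0.0258, `Y_P_X` 0.0481, and `Y_X_glc`
2.03: trajectories are reproduced almost exactly (R² ≥ 0.98 everywhere)
while individual growth parameters carry the partial-collinearity
uncertainty discussed in the methods vignette.

Identifiability of the fit (structurally collinear yield pairs are
flagged):

```r
rep <- identifiability_report(theta, default_initial_state(), cons)
rep$flagged
#>      param1    param2           CI
#> 1 Y_lac_glc   Y_X_lac          Inf
#> 2   Y_X_gln Y_gln_glu 3.088159e+05
#> 3    mu_max     K_glc 9.551971e+01
```

A shell entry point wraps the same functions:

```sh
exec/mckm synth --out data/ --clones 8 --seed 1
exec/mckm fit --run data/clone001_Ambr-1_rep1.csv --feeds data/feeds.csv --out fit.json
exec/mckm identifiability --params fit.json --run data/clone001_Ambr-1_rep1.csv --out ident
```

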