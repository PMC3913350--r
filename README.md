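# hnmbio

Grey-box modeling of two batch bioprocesses for second-generation biofuels,
for bioprocess engineers and modelers who want mechanistic structure where
the chemistry is known and a trained network where it is not.

**Enzymatic transesterification (biodiesel).** The lipase-catalyzed
alcoholysis of triolein with ethanol in hexane is modeled by a Ping-Pong
Bi-Bi rate law with ethanol inhibition,

```
-d[T]/dt = [e0] * (K1[T][Et] - K2[P][EO]) /
           (K3[T] + K4[Et] + K5[T][Et] + K6[P] + K7[EO] + K8[P][EO]
            + K9[T][P] + K10[Et][EO] + K11[Et]^2 + K12[Et][P])
```

integrated as a scalar batch ODE whose co-species closures are supplied
either by linear stoichiometric correlations (`[EO] = 2.25 ([T0]-[T])`,
baseline) or by a trained 6-10-3-1 perceptron that learns the actual,
sigmoid-like ester-versus-conversion relation — the **hybrid neural model**.
Gauged least-squares estimation of the twelve lumped constants is included,
with an honest identifiability analysis (two parameter pairs are only
determined in combination; see the methods vignette).

**Anaerobic codigestion (biogas).** Cumulative methane productivity of
manure/orange-juice-waste (OJW) batches is modeled by a 5-6-2-1 perceptron
in (OJW %, pH0, COD0, (C/N)0, day), trained with **Bayesian regularization**
(`F = beta*E_D + alpha*E_W` with evidence-approximation hyperparameter
updates inside a Levenberg-Marquardt loop, written from scratch and
gradient-checked). A grid optimizer scores all 64 piecewise
feed-composition scenarios (OJW in {0, 10, 15, 20}% over days 1-9, 10-19,
20-28) and returns the ranked feeding strategies.

Both experimental campaigns are emulated by seeded synthetic-data
generators (144-point transesterification design, 140-point digestion
design) that are themselves tested, documented code.

## Worked example

```r
library(hnmbio)

## transesterification: synthetic campaign -> hybrid model -> simulation
gen  <- gen_transester(transester_gen_config(seed = 42))
ds1  <- build_ann1_dataset(gen$trajectories, seed = 42)
ann1 <- train_ann1(ds1, seed = 42)
model <- hnm(default_true_params(), ann1)
sim <- simulate_hnm(model, gen$trajectories[[6]]$conditions, seq(0, 24, by = 6))
round(sim$states, 4)
#>    t      T     Et     EO      P
#> 1  0 0.5159 1.0317 0.0000 0.0000
#> 2  6 0.4597 0.9775 0.0542 0.0561
#> 3 12 0.4107 0.8830 0.1487 0.1051
#> 4 18 0.3692 0.7649 0.2669 0.1466
#> 5 24 0.3352 0.6403 0.3915 0.1806
ann1$evaluation$validation$rmse    # 0.0134 mol/L on held-out points
```

The simulated run (low enzyme load, 1:20) converts ~35% of the triolein in
24 h; the network-closed ester curve starts slower than the 2.25-slope
linear correlation would (the "initial delay" the hybrid model exists to
capture), and the pooled-product balance `P + T = T0` holds exactly.

```r
## codigestion: synthetic campaign -> methane network -> feed strategy
rec  <- gen_digestion(digestion_gen_config(seed = 42))
ds2  <- build_ann2_dataset(rec, holdout_run = 3, seed = 42)
ann2 <- train_ann2(ds2, seed = 42)
mlp_evaluate(ann2, ds2, "validation")$rmse   # 2.65 L on the held-out run
best_scenario(gompertz_truth_model())$table[1:3, ]
#>   p1 p2 p3 increment_p1 increment_p2 increment_p3 cumulative_L rank
#> 1  0 20 20     55.54096     71.27653     29.19201     156.0095    1
#> 2 10 20 20     53.60683     71.27653     29.19201     154.0754    2
#> 3  0 20 15     55.54096     71.27653     27.16159     153.9791    3
```

The held-out 10%-OJW run is predicted with an RMSE of ~2.7 L on a ~150 L
scale, and the best feeding strategy starts the digester on manure only
(its active inoculum wins the lag-dominated first period) and switches to
20% OJW after day 9 — moderate OJW raises the methane potential, while 50%
OJW would acidify the batch.

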