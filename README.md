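# narxgrip

Decoding continuous, dynamic grip force from multi-channel surface
electromyography (sEMG) with NARX networks.

Myoelectric interfaces usually classify *which* movement a user intends;
controlling a prosthetic hand well also requires knowing *how hard* the
user is gripping, moment by moment. `narxgrip` implements that decoding
problem end to end for a lightweight rig — three forearm EMG channels at
1000 Hz plus a 10 Hz load-cell force channel recorded over repeated
squeeze/hold/release cycles — and, because no public recordings exist for
this design, ships a seeded simulator of the whole acquisition so every
stage is testable from a clean checkout.

The decoder is a nonlinear autoregressive model with exogenous inputs
(NARX):

    y(t) = f( u(t), u(t−1), …, u(t−D),  y(t−1), …, y(t−D) )

with `u(t)` the 3-channel preprocessed EMG envelope, `y(t)` grip force in
newtons, `D` a shared delay order, and `f` a feed-forward network (tanh
hidden layers, linear output) trained teacher-forced on the one-step
mean squared error. Three trainers are implemented behind one interface:
nonlinear conjugate gradient (Polak–Ribière+ with a strong-Wolfe line
search), Levenberg–Marquardt, and Bayesian-regularized stochastic
gradient descent with evidence re-estimation of the data/penalty weights.

The package provides:

* `simulate_grip()` — seeded sEMG/force session generator (trapezoidal
  activation, 20–150 Hz amplitude-modulated carrier, baseline drift,
  50 Hz mains, white noise, impulsive artifacts);
* `preprocess_pipeline()` — robust outlier interpolation, zero-phase
  Butterworth 10–200 Hz band-pass, 50 Hz notch, db4 wavelet-threshold
  denoising, polynomial baseline removal, block-RMS downsampling to
  10 Hz, aligned against the force channel;
* `narx()` — the model-fitting function, returning a classed object with
  `print`, `summary`, `coef`, `predict` (open- and closed-loop),
  `fitted`, `residuals`, `simulate` and `plot` methods;
* `split_dataset()`, `compute_metrics()`, `run_sweep()`,
  `compare_trainers()`, `error_distribution()` — temporal splits, fit
  metrics (MSE/RMSE/MAE and the regression value R), hidden-size × delay
  sweeps with per-size averages, and phase-resolved residual box-plot
  summaries;
* `run_experiment()` — the full chain under one seed, writing
  byte-reproducible artifacts (signals, model file, metrics, manifest).

## Worked example

```r
library(narxgrip)

sim <- simulate_grip(seed = 1)        # 5 s hold / 5 s rest × 3, 33 s session
ds  <- preprocess_pipeline(sim$emg, sim$force, phase = sim$activation$phase)
sp  <- split_dataset(ds, test_fraction = 0.3)

fit <- narx(sp$train, delay = 5, hidden = 10, method = "cg",
            control = narx_control(max_epochs = 300))
fit
#> NARX grip-force model
#>   delay 5, hidden [10], 251 parameters, trained by CG
#>   300 epoch(s) (max_epochs); training MSE 5.738, R 0.9999

compute_metrics(predict(fit, newdata = sp$test), sp$test$force[-(1:5)])
#> MSE 11.072 N^2 | RMSE 3.32747 N | MAE 2.26572 N | R 0.9997 | n = 94
```

Read: on the held-out final 30% of the session the decoder tracks the
measured grip force to within ~3.3 N RMS on a 300 N-peak signal, with a
prediction/measurement correlation (regression value R) of 0.9997.
Residuals concentrate at grip onset and release, which
`error_distribution(pred, target, phase)` quantifies per grip phase.

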