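# fusemix

Fusion mixture feature extraction and hybrid swarm classification for
biosignals.

fusemix is for researchers who need a fully seeded, auditable pipeline for
two-class biosignal classification — the motivating case is EEG segments
(e.g. ictal vs. background activity, patient vs. control). It implements
four stages as plain R functions plus an end-to-end cross-validated driver:

1. **Descriptors** (`build_feature_matrix`): each window is summarised by
   mean, unbiased variance, skewness, excess kurtosis, sample entropy
   (`-ln(A/B)`, Chebyshev templates, m = 2, r = 0.2 sd) and order-3
   natural-log permutation entropy.
2. **Fusion mixture modelling** (`select_model`): the normalised
   observations z are fitted by three mixture families
   `f(z) = (1 - π) f0(z) + π f1(z)` — a uniform-plus-normal model (NUDGE),
   its Q-component-bulk extension (eNUDGE), and an exponential-tails model
   (GNG) whose f1 is `ρ Exp(-z - ξ1; β1)` on `z < -ξ1` plus
   `(1 - ρ) Exp(z - ξ2; β2)` on `z > ξ2` — by EM on the weighted likelihood
   `Σ w_k log f(z_k)`. SVD-derived intensity weights
   `w(v) = 1 if v > -g, g/|v| otherwise` (g = 1.5) down-weight dim
   observations. Q is chosen by BIC within a family, the family by AIC.
   Components with `|μ_q| + 2σ_q > 1.5 IQR` are flagged differential, and
   observations are retained when `FDR(z_k)/w_k ≤ y0` with
   `FDR(z_k) = f_nondiff(z_k) / f(z_k)`.
3. **Feature selection** (`select_features_hdpab`): a hybrid optimizer
   cycling differential-evolution mutation/crossover/greedy-selection, a
   particle-swarm velocity update, and artificial-bee-colony scout
   re-seeding, with elitism; candidate masks are scored by nearest-centroid
   balanced accuracy under internal 5-fold CV plus a sparsity penalty.
4. **Classifiers**: a zero-inflated Poisson mixture regression model
   (`fit_zipmrm`) — `ψ 1{u=0} + (1-ψ) Σ_q π_q(v2) Poisson(u; exp(β0q +
   v1'βq))` with concomitant softmax weights, fitted by EM — and a
   bidirectional LSTM (`train_bilstm`) with hand-verified
   backpropagation-through-time and Adam (lr 0.01, batch 40, 80 hidden
   units, L2 1e-4).

Seeded generators (`gen_two_class_signals`, `gen_mixture_sample`,
`gen_zip_counts`, `benchmark_function`) produce every input the pipeline
needs, so the whole package is testable offline; `run_pipeline` wires the
stages into stratified 10-fold cross-validation with an inner 80/10/10
split and strict training-rows-only derivation of every learned artifact.

## Worked example

```r
library(fusemix)

spec <- synthetic_spec(n_per_class = 30, signal_length = 256, seed = 21)
cfg  <- pipeline_config(k = 4, hdpab_NP = 8, hdpab_iter = 8,
                        hidden_size = 20, epochs = 30, batch_size = 16,
                        classifier = "both", seed = 11)
report <- run_pipeline(spec, cfg)
print(report)
#> <evaluation_report> 60 observations, 4-fold CV (seed 11)
#>   bilstm   mean accuracy 1.000
#>   zipmrm   mean accuracy 0.967

report$confusion$bilstm
#>              background spiking
#>   background         30       0
#>   spiking             0      30

which(report$masks[[1]])   # features selected in fold 1
#> [1] 4 5 6
```

Sixty synthetic segments (spiking class = AR(2)+sinusoid background plus
high-amplitude transients) are classified by the full
descriptors → fusion mixture → HDPAB → classifier chain under 4-fold CV.
The Bi-LSTM separates the classes perfectly and the ZIPMRM misses two
windows; fold 1 selects kurtosis, sample entropy and permutation entropy —
the descriptors the spike bursts actually move.

Mixture-level parameter recovery from a known generator:

```r
truth <- fhm_params("eNUDGE", pi = 0.2, mu = c(-1.5, 1.5), sigma = c(1, 1),
                    uniform = c(-8, 8))
z   <- gen_mixture_sample(truth, 5000, seed = 42)
fit <- em_fit(z, 1, "eNUDGE", Q = 2)
round(c(pi = fit$params$pi, mu = sort(fit$params$mu)), 3)
#>     pi    mu1    mu2
#>  0.208 -1.540  1.453
```

The mixing weight and both bulk means land within sampling error of the
generator (π = 0.2, μ = ±1.5).

## Documentation

The methods vignette (`vignettes/fusemix-methods.Rmd`) describes the
models, their assumptions, all tunable parameters with defaults, what the
synthetic generator does and does not emulate, the numerical safeguards,
and the design choices made where the underlying method descriptions were
open.
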