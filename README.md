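# gxeyield

Genotype-by-environment soybean yield prediction from daily growing-season
weather, maturity group and pedigree-derived genotype clusters, with
recurrent sequence models and temporal attention — implemented end to end
in R, including the networks themselves.

## The problem

Multi-environment soybean trials record *genotype × location × year →
seed yield (bu/acre)*, with each variety's maturity group (MG 0–8) and
parentage. Yield depends not only on how much weather happens but on
*when* it happens during the 214-day growing season (April 1 – October
31). `gxeyield` provides:

* **Pedigree clustering** — Wright's numerator relationship matrix A by
  the tabular method (`relationship_matrix()`), diagonal-normalized to a
  correlation matrix (`to_correlation()`), and K-means on the correlation
  profiles (`cluster_genotypes()`, K = 20 recommended at real scale) so a
  single cluster ID summarizes relatedness for each genotype.
* **Weather preparation** — `downsample_weather()` maps the first 210
  days to weekly/biweekly/monthly steps (Tx = 30/15/7; daily keeps all
  214), aggregating each of the 7 variables by its own sense (mean for
  ADNI/ARH/AvgSur and AP, max for MDNI/MaxSur, min for MinSur);
  min-max scaling to (−1, 1) fitted on the training split only.
* **Two many-to-one sequence regressors** — a two-layer **stacked LSTM**
  (hidden 128, dropout 0.2, 2-unit context bottleneck) that predicts from
  the final annotation a^⟨Tx⟩, and a **temporal attention** variant that
  scores every annotation with a shared linear scorer, softmax-normalizes
  over time, α^⟨t⟩ = exp(e^⟨t⟩)/Σ exp(e^⟨s⟩), and predicts from the
  context c = Σ α^⟨t⟩ a^⟨t⟩. With 9-dimensional steps (7 weather + MG +
  cluster) and Tx = 30 these hold exactly 202,503 and 202,632 trainable
  parameters. Forward passes, backpropagation through time and the Adam
  optimizer are implemented in vectorized base R and verified against
  finite-difference gradients.
* **Experiment protocol** — 80/10/10 record split, Adam (lr 0.001), MSE,
  100 epochs, batch 512, repeated runs with mean ± SD; greedy forward
  selection over weather variables; SVR-RBF (ε = 0.1, C = 1) and LASSO
  (α = 1e-6) baselines on the flattened features.
* **Interpretability** — per-record attention profiles, stratified
  mean-profile summaries by MG × yield range, and a localization score
  comparing attention density inside vs outside a time-step window.
* **Synthetic trial generator** — `sim_trial()` builds pedigree, daily
  weather and yields with a planted mechanism (family effects, quadratic
  MG–latitude adaptation penalty, time-windowed weather effects, Gaussian
  noise), so the whole pipeline is testable against known ground truth.

## Worked example

```r
library(gxeyield)

# a synthetic multi-environment trial with known ground truth
tb <- sim_trial(sim_config(seed = 11))
tb
#> <trial_bundle>
#>  3723 records | 260 genotypes | 12 locations x 6 years

# pedigree -> relationship -> correlation -> clusters
C  <- to_correlation(relationship_matrix(tb$pedigree))
cl <- cluster_genotypes(C, k = 5, seed = 1)
glance(cl)
#> # A tibble: 1 × 3
#>       n     k inertia
#>   <int> <int>   <dbl>
#> 1   260     5    409.

# weekly weather steps, scaler fitted on the training split only
wds <- downsample_weather(tb$weather, "weekly")
sp  <- split_records(nrow(tb$records), seed = 5)
sc  <- fit_input_scaler(tb$records[sp$train, ], wds, cl)
tri <- assemble_inputs(tb$records[sp$train, ], wds, sc, cl,
                       include_mg_cluster = TRUE)
tei <- assemble_inputs(tb$records[sp$test, ], wds, sc, cl,
                       include_mg_cluster = TRUE)

# temporal attention model (small hidden size for a quick run)
spec <- model_spec("attention", tx = 30, input_dim = 9, hidden = 16,
                   context_dim = 2)
fit <- train_model(spec, tri,
                   cfg = train_config(epochs = 60, batch_size = 512,
                                      seed = 1))
evaluate_model(fit, tei)
#> # A tibble: 1 × 4
#>    rmse   mae    r2     n
#>   <dbl> <dbl> <dbl> <int>
#> 1  3.27  2.58 0.780   372

# where in the season does the model look? The generator planted its
# weather effect on days 120-168 (weekly steps 18-24):
localization_score(extract_profiles(fit, tei), c(18, 24))
#> # A tibble: 1 × 7
#>   mass_in density_in density_out density_ratio window_start window_end    tx
#>     <dbl>      <dbl>       <dbl>         <dbl>        <int>      <int> <int>
#> 1   0.244     0.0348      0.0329          1.06           18         24    30
```

An RMSE of 3.27 bu/acre against a plot-noise SD of 3 bu/acre and test
R² = 0.78 against a generative-oracle ceiling of ≈ 0.8 means the model
recovers most of the learnable structure; a localization density ratio
above 1 means the attention profile puts above-background weight on the
planted effect window. The reference-scale architectures are available for
accounting even though training them is out of desk scope:

```r
count_params(model_spec("stacked",   tx = 30, input_dim = 9))  # 202503
count_params(model_spec("attention", tx = 30, input_dim = 9))  # 202632
```

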