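# Shared fixtures (built once per test run) and independent oracles.

fixture_env <- new.env(parent = emptyenv())

# small but fully structured trial: 3 families, 2 generations
small_trial <- function() {
  if (is.null(fixture_env$small_trial)) {
    fixture_env$small_trial <- sim_trial(sim_config(
      n_founders = 9, n_generations = 2, crosses_per_generation = 9,
      n_families = 3, location_latitudes = seq(31, 47, length.out = 6),
      years = 2003:2004, seed = 42))
  }
  fixture_env$small_trial
}

# default-condition trial used by the recovery experiments
default_trial <- function() {
  if (is.null(fixture_env$default_trial)) {
    fixture_env$default_trial <- sim_trial(sim_config(seed = 11))
  }
  fixture_env$default_trial
}

# exhaustive minimum-inertia partition oracle (all assignments of n points
# into exactly k non-empty clusters); rows of X are feature vectors
oracle_min_inertia <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 9)
  inertia_of <- function(assign) {
    sum(vapply(unique(assign), function(c) {
      xs <- X[assign == c, , drop = FALSE]
      ctr <- colMeans(xs)
      sum(sweep(xs, 2, ctr)^2)
    }, numeric(1)))
  }
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf; best_assign <- NULL
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    if (length(unique(a)) != k) next
    val <- inertia_of(a)
    if (val < best - 1e-12) {
      best <- val
      best_assign <- a
    }
  }
  list(inertia = best, assignment = best_assign)
}

# closed-form trainable-parameter accounting, independent of the builder
oracle_param_count <- function(input_dim, hidden, context_dim,
                               include_mg_cluster, attention) {
  lstm <- function(d, h) 4 * h * (d + h + 1)
  head_dim <- context_dim + if (include_mg_cluster) 2 else 0
  total <- lstm(input_dim, hidden) + lstm(hidden, hidden) +
    (hidden * context_dim + context_dim) + (head_dim * 1 + 1)
  if (attention) total <- total + hidden + 1
  total
}

# adjusted Rand index between two hard partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# A tiny assembled training problem, built once: monthly steps, weather-only.
tiny_problem <- function() {
  if (is.null(fixture_env$tiny_problem)) {
    tb <- small_trial()
    wds <- downsample_weather(tb$weather, "monthly")
    sp <- split_records(nrow(tb$records), seed = 2)
    sc <- fit_input_scaler(tb$records[sp$train, ], wds)
    fixture_env$tiny_problem <- list(
      train = assemble_inputs(tb$records[sp$train, ], wds, sc),
      val = assemble_inputs(tb$records[sp$validation, ], wds, sc),
      test = assemble_inputs(tb$records[sp$test, ], wds, sc),
      split = sp, bundle = tb)
  }
  fixture_env$tiny_problem
}

tiny_spec <- function(hidden = 4)
  model_spec("stacked", tx = 7, input_dim = 7, hidden = hidden,
             context_dim = 2, include_mg_cluster = FALSE)

# greedy selection exercised on a three-variable fixture where only ARH
# carries planted signal; the candidates AP, ARH, ADNI are generated through
# mutually independent channels, so the signal is attributable, and the 72
# location-years make environment memorization harder than learning the
# real response
greedy_fixture <- function() {
  if (is.null(fixture_env$greedy_fixture)) {
    tb <- sim_trial(sim_config(
      n_founders = 10, n_generations = 2, crosses_per_generation = 20,
      n_families = 2, location_latitudes = seq(30, 48, length.out = 12),
      years = 2003:2008, cluster_effect_sd = 0, mg_adapt_penalty = 0,
      effect_sizes = c(ARH = 4), noise_sd = 2, seed = 21))
    fixture_env$greedy_fixture <- list(
      tb = tb, wds = downsample_weather(tb$weather, "monthly"))
  }
  fixture_env$greedy_fixture
}

greedy_cfg <- function(seed)
  train_config(epochs = 12, batch_size = 256, seed = seed)

greedy_spec <- model_spec("stacked", tx = 7, input_dim = 1, hidden = 8,
                          context_dim = 2, include_mg_cluster = FALSE)
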