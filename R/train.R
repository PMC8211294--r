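#' Training protocol configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 0.001, mean
#' squared error loss, 100 epochs, batch size 512, an 80/10/10
#' train/validation/test record split, and three repeated runs for
#' mean +/- SD reporting.
#'
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param split Fractions for train/validation/test; must sum to 1.
#' @param n_repeats Number of repeated runs (fresh initialization seeds,
#'   fixed split).
#' @param seed Base integer seed.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 100,
                         batch_size = 512, split = c(0.8, 0.1, 0.1),
                         n_repeats = 3, seed = 1L) {
  if (abs(sum(split) - 1) > 1e-8 || length(split) != 3)
    stop("`split` must be three fractions summing to 1", call. = FALSE)
  if (epochs <= 0 || batch_size <= 0)
    stop("`epochs` and `batch_size` must be positive", call. = FALSE)
  if (n_repeats < 1) stop("`n_repeats` must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "train_config")
}

#' Random record-level train/validation/test split
#'
#' Disjoint, exhaustive partition of record indices; sizes are the floored
#' fractional counts with any remainder assigned to the training set, so
#' 1000 records at (0.8, 0.1, 0.1) give exactly 800/100/100. Deterministic
#' for a given seed.
#'
#' @param n Number of records (or a data frame, whose rows are counted).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
split_records <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must sum to 1", call. = FALSE)
  if (n < 3) stop("need at least 3 records to split", call. = FALSE)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Train a sequence-regression model with Adam on MSE
#'
#' Mini-batch gradient training with the Adam optimizer and fresh dropout
#' masks per batch. The loss history records full-pass (dropout-off)
#' training and validation MSE per epoch on the scaled target. Training is
#' deterministic for a given seed in a single-threaded run.
#'
#' @param model A [build_model()] result (or a [model_spec()], instantiated
#'   with `cfg$seed`).
#' @param train_inputs [assemble_inputs()] result for the training split
#'   (its scaler must have been fitted on this split).
#' @param val_inputs Optional validation-split inputs for the history.
#' @param cfg A [train_config()].
#' @return Object of class `gxe_fit`: list with `spec`, `params`, `history`
#'   (tibble epoch/train_loss/val_loss), `cfg`, `scaler`.
#' @export
train_model <- function(model, train_inputs, val_inputs = NULL,
                        cfg = train_config()) {
  if (inherits(model, "model_spec")) model <- build_model(model, cfg$seed)
  stopifnot(inherits(model, "gxe_model"), inherits(train_inputs, "model_input"))
  spec <- model$spec
  params <- model$params
  n <- dim(train_inputs$x)[1]
  y <- train_inputs$y
  state <- adam_init(params)
  history <- vector("list", cfg$epochs)
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      s <- starts[bi]
      idx <- perm[s:min(s + cfg$batch_size - 1, n)]
      xb <- train_inputs$x[idx, , , drop = FALSE]
      sb <- if (!is.null(train_inputs$side))
        train_inputs$side[idx, , drop = FALSE]
      fwd <- nn_forward(params, spec, xb, sb, training = TRUE)
      batch_losses[bi] <- mse_loss(fwd$yhat, y[idx])
      dyhat <- 2 * (fwd$yhat - y[idx]) / length(idx)
      grads <- nn_backward(params, spec, fwd$cache, dyhat)
      upd <- adam_step(params, grads, state, lr = cfg$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    tr_loss <- mean(batch_losses)  # running training loss over mini-batches
    if (!is.finite(tr_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    va_loss <- if (!is.null(val_inputs))
      mse_loss(nn_forward(params, spec, val_inputs$x,
                          val_inputs$side)$yhat, val_inputs$y)
    else NA_real_
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tr_loss,
                                       val_loss = va_loss)
  }
  structure(list(spec = spec, params = params,
                 history = dplyr::bind_rows(history), cfg = cfg,
                 scaler = train_inputs$scaler, seed = cfg$seed),
            class = c("gxe_fit", "gxe_model"))
}

#' @export
print.gxe_fit <- function(x, ...) {
  print(x$spec)
  last <- x$history[nrow(x$history), ]
  cat("  trained", nrow(x$history), "epochs | final train MSE",
      format(last$train_loss, digits = 5),
      if (!is.na(last$val_loss))
        paste("| val MSE", format(last$val_loss, digits = 5)), "\n")
  invisible(x)
}

#' Regression metrics on the original yield scale
#'
#' RMSE \eqn{= \sqrt{\overline{(y-\hat y)^2}}}, MAE
#' \eqn{= \overline{|y-\hat y|}} and \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Tibble with columns `rmse`, `mae`, `r2`.
#' @export
#' @examples
#' eval_metrics(c(1, 2, 3), c(1, 2, 4))  # mae 1/3, rmse sqrt(1/3), r2 0.5
eval_metrics <- function(y, yhat) {
  if (length(y) == 0) stop("cannot evaluate an empty set", call. = FALSE)
  res <- y - yhat
  tibble::tibble(
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res)),
    r2 = 1 - sum(res^2) / sum((y - mean(y))^2)
  )
}

#' Evaluate a fitted model on a data split, in bu/acre
#'
#' Predicts on the scaled target scale, inverts the training-fitted min-max
#' scaling, and computes RMSE, MAE and R-squared in original yield units.
#'
#' @param fit A fitted `gxe_fit` (or any `gxe_model`).
#' @param inputs [assemble_inputs()] result for the evaluation split.
#' @return Tibble with columns `rmse`, `mae`, `r2`, `n`.
#' @export
evaluate_model <- function(fit, inputs) {
  yhat_scaled <- predict(fit, inputs)
  scaler <- if (!is.null(fit$scaler)) fit$scaler else inputs$scaler
  yhat <- unscale_feature(yhat_scaled, scaler, "yield")
  dplyr::mutate(eval_metrics(inputs$y_raw, yhat), n = length(yhat))
}

#' Repeated training runs with fresh initialization seeds
#'
#' Trains `cfg$n_repeats` models on a fixed split, varying only the
#' initialization/shuffling seed (`cfg$seed + repeat - 1`), and reports
#' per-repeat test metrics plus their mean and population standard
#' deviation (the reported SD convention, recorded in the result).
#'
#' @param spec A [model_spec()].
#' @param train_inputs,val_inputs,test_inputs Assembled split inputs.
#' @param cfg A [train_config()].
#' @return Object of class `repeat_runs`: list with `runs` (per-repeat
#'   metric tibble), `summary` (metric, mean, sd), `sd_convention`, `fits`.
#' @export
repeated_runs <- function(spec, train_inputs, val_inputs = NULL,
                          test_inputs, cfg = train_config()) {
  runs <- vector("list", cfg$n_repeats)
  fits <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    rcfg <- cfg
    rcfg$seed <- cfg$seed + r - 1L
    fit <- train_model(spec, train_inputs, val_inputs, rcfg)
    fits[[r]] <- fit
    runs[[r]] <- dplyr::mutate(evaluate_model(fit, test_inputs),
                               repeat_id = r, .before = 1)
  }
  runs <- dplyr::bind_rows(runs)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summary <- runs |>
    tidyr::pivot_longer(c("rmse", "mae", "r2"), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = pop_sd(.data$value),
                     .groups = "drop")
  structure(list(runs = runs, summary = summary,
                 sd_convention = "population", fits = fits),
            class = "repeat_runs")
}

#' @export
print.repeat_runs <- function(x, ...) {
  cat("<repeat_runs>", nrow(x$runs), "repeats (SD:", x$sd_convention, ")\n")
  print(x$summary)
  invisible(x)
}

#' Express an MAE as a percentage of a reference level
#'
#' E.g. an MAE of 5.441 bu/acre is 10.72% of a 50.745 bu/acre test-set mean
#' and 33.96% of a 16.019 bu/acre test-set SD.
#'
#' @param mae Mean absolute error (bu/acre).
#' @param reference Positive reference level (bu/acre), e.g. the test-set
#'   mean or standard deviation.
#' @return Percentage, `100 * mae / reference`.
#' @export
mae_percent <- function(mae, reference) {
  if (reference <= 0) stop("`reference` must be positive", call. = FALSE)
  100 * mae / reference
}
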