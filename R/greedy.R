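#' Greedy forward selection over weather variables
#'
#' Stage 1 trains one model per candidate weather variable and keeps the
#' variable with the least RMSE; each later stage re-trains with every
#' remaining variable added to the kept set and again keeps the best, until
#' all variables are ranked (7 candidates cost 7 + 6 + ... + 1 = 28
#' trainings). The default criterion is validation-set RMSE, which keeps
#' the test set untouched during selection; `criterion = "test_rmse"`
#' matches the protocol that reports test RMSE instead.
#'
#' @param records Full records tibble (with `yield`).
#' @param weather_ds Downsampled weather from [downsample_weather()].
#' @param split Index list from [split_records()].
#' @param variables Candidate weather variables.
#' @param spec A [model_spec()] template; its `input_dim` is overridden per
#'   stage to the current variable count (plus 2 when MG/cluster included).
#' @param cfg A [train_config()].
#' @param clusters Optional cluster assignment when `include_mg_cluster`.
#' @param include_mg_cluster Include MG and cluster inputs in every model.
#' @param criterion "val_rmse" (default) or "test_rmse".
#' @param max_stages Optional cap on the number of selection stages (default
#'   all variables); stage-1-only runs are useful for replicate studies of
#'   the first pick.
#' @return Object of class `greedy_trace`: tibble of all evaluated
#'   candidates (`stage`, `variable`, `rmse`, `selected`) with the final
#'   `ranking` attribute.
#' @export
greedy_search <- function(records, weather_ds, split,
                          variables = weather_variables(),
                          spec = model_spec("stacked", tx = 7, input_dim = 1,
                                            hidden = 16,
                                            include_mg_cluster = FALSE),
                          cfg = train_config(),
                          clusters = NULL, include_mg_cluster = FALSE,
                          criterion = c("val_rmse", "test_rmse"),
                          max_stages = length(variables)) {
  criterion <- match.arg(criterion)
  if (length(variables) < 1)
    stop("need at least one candidate variable", call. = FALSE)
  train_rec <- records[split$train, ]
  eval_idx <- if (criterion == "val_rmse") split$validation else split$test
  eval_rec <- records[eval_idx, ]
  scaler <- fit_input_scaler(train_rec, weather_ds, clusters)
  selected <- character(0)
  rows <- list()
  for (stage in seq_len(min(max_stages, length(variables)))) {
    remaining <- setdiff(variables, selected)
    stage_rmse <- vapply(remaining, function(v) {
      vars <- c(selected, v)
      sp <- spec
      sp$input_dim <- length(vars) + if (include_mg_cluster) 2L else 0L
      sp$include_mg_cluster <- include_mg_cluster
      tr_in <- assemble_inputs(train_rec, weather_ds, scaler, clusters,
                               variables = vars,
                               include_mg_cluster = include_mg_cluster)
      ev_in <- assemble_inputs(eval_rec, weather_ds, scaler, clusters,
                               variables = vars,
                               include_mg_cluster = include_mg_cluster)
      fit <- train_model(sp, tr_in, cfg = cfg)
      evaluate_model(fit, ev_in)$rmse
    }, numeric(1))
    best <- remaining[which.min(stage_rmse)]
    rows[[stage]] <- tibble::tibble(stage = stage, variable = remaining,
                                    rmse = unname(stage_rmse),
                                    selected = remaining == best)
    selected <- c(selected, best)
  }
  trace <- dplyr::bind_rows(rows)
  structure(trace, ranking = selected, criterion = criterion,
            class = c("greedy_trace", class(trace)))
}

#' Variable ranking from a greedy trace
#'
#' @param trace A [greedy_search()] result.
#' @return Character vector: variables in order of selection.
#' @export
greedy_ranking <- function(trace) attr(trace, "ranking")
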