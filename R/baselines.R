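#' Hyperparameters for the SVR-RBF and LASSO baselines
#'
#' Defaults are the tuned reference values: epsilon-insensitive support
#' vector regression with a radial-basis kernel (epsilon 0.1, cost C = 1)
#' and an L1-penalized linear model (alpha 1e-6, at most 1000 iterations).
#'
#' @param svr_epsilon,svr_cost SVR epsilon tube and regularization C.
#' @param lasso_alpha L1 penalty weight (the scikit-learn `alpha`
#'   parameterization, equal to glmnet's lambda for a Gaussian model
#'   without standardization).
#' @param lasso_max_iter Iteration cap for the LASSO solver.
#' @return Object of class `baseline_spec`.
#' @export
baseline_spec <- function(svr_epsilon = 0.1, svr_cost = 1,
                          lasso_alpha = 1e-6, lasso_max_iter = 1000) {
  if (svr_epsilon <= 0 || svr_cost <= 0 || lasso_alpha <= 0)
    stop("baseline hyperparameters must be positive", call. = FALSE)
  structure(list(svr_epsilon = svr_epsilon, svr_cost = svr_cost,
                 lasso_alpha = lasso_alpha,
                 lasso_max_iter = as.integer(lasso_max_iter)),
            class = "baseline_spec")
}

flatten_inputs <- function(inputs) {
  n <- dim(inputs$x)[1]
  X <- matrix(inputs$x, n, inputs$tx * inputs$dim)
  if (!is.null(inputs$side)) X <- cbind(X, inputs$side)
  X
}

#' Fit the SVR-RBF and LASSO baselines on flattened sequence inputs
#'
#' The Tx-step sequences are flattened to fixed-length feature vectors
#' (Tx x step-dim, plus the MG/cluster side features when present), exactly
#' the scaled features the sequence models receive, and fitted with
#' epsilon-SVR (radial-basis kernel) and LASSO. Metrics are computed on the
#' original bu/acre scale like [evaluate_model()].
#'
#' @param train_inputs,test_inputs Assembled split inputs.
#' @param spec A [baseline_spec()].
#' @param which Baselines to fit, subset of `c("svr", "lasso")`.
#' @return Object of class `baseline_results`: list with `metrics` (tibble
#'   `model`, `rmse`, `mae`, `r2`, `n`) and `spec` (echoed
#'   hyperparameters).
#' @export
fit_baselines <- function(train_inputs, test_inputs,
                          spec = baseline_spec(),
                          which = c("svr", "lasso")) {
  which <- match.arg(which, several.ok = TRUE)
  Xtr <- flatten_inputs(train_inputs)
  Xte <- flatten_inputs(test_inputs)
  if (any(apply(Xtr, 2, stats::sd) == 0) && ncol(Xtr) < 2)
    stop("degenerate (constant) feature matrix", call. = FALSE)
  scaler <- train_inputs$scaler
  y <- train_inputs$y
  out <- list()
  if ("svr" %in% which) {
    svr <- e1071::svm(x = Xtr, y = y, type = "eps-regression",
                      kernel = "radial", epsilon = spec$svr_epsilon,
                      cost = spec$svr_cost, scale = FALSE)
    yhat <- unscale_feature(stats::predict(svr, Xte), scaler, "yield")
    out$svr <- dplyr::mutate(eval_metrics(test_inputs$y_raw, yhat),
                             model = "svr_rbf", .before = 1)
  }
  if ("lasso" %in% which) {
    las <- glmnet::glmnet(Xtr, y, alpha = 1, lambda = spec$lasso_alpha,
                          standardize = FALSE, maxit = spec$lasso_max_iter)
    yhat_s <- drop(stats::predict(las, Xte, s = spec$lasso_alpha))
    yhat <- unscale_feature(yhat_s, scaler, "yield")
    out$lasso <- dplyr::mutate(eval_metrics(test_inputs$y_raw, yhat),
                               model = "lasso", .before = 1)
  }
  metrics <- dplyr::mutate(dplyr::bind_rows(out),
                           n = length(test_inputs$y_raw))
  structure(list(metrics = metrics, spec = spec),
            class = "baseline_results")
}

#' @export
print.baseline_results <- function(x, ...) {
  cat("<baseline_results> (epsilon =", x$spec$svr_epsilon,
      ", C =", x$spec$svr_cost, ", alpha =", x$spec$lasso_alpha, ")\n")
  print(x$metrics)
  invisible(x)
}
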