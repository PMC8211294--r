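#' Specify a sequence-regression architecture
#'
#' Both architectures share a two-layer LSTM encoder (equal hidden sizes,
#' dropout after each layer), a linear bottleneck compressing the sequence
#' encoding to `context_dim` units, optional concatenation of the maturity
#' group and genotype-cluster scalars, and a linear single-unit output. The
#' `stacked` variant summarizes the sequence by the final annotation
#' \eqn{a^{<T_x>}}; the `attention` variant scores every annotation with a
#' shared linear scorer, softmax-normalizes the scores over time and uses
#' the attention-weighted sum of annotations (the context) instead.
#'
#' @param variant "stacked" or "attention".
#' @param tx Number of input time-steps (7, 15, 30 or 214 for
#'   monthly/biweekly/weekly/daily weather).
#' @param input_dim Per-step input dimension: 7 for weather only, 9 with MG
#'   and cluster appended.
#' @param hidden LSTM hidden-state size for both layers (default 128).
#' @param context_dim Units of the sequence-encoding bottleneck (default 2).
#' @param dropout Dropout rate after each LSTM layer (default 0.2; disabled
#'   at inference).
#' @param include_mg_cluster Whether MG and cluster also enter the head just
#'   before prediction.
#' @return Object of class `model_spec`.
#' @export
#' @examples
#' model_spec("attention", tx = 30, input_dim = 9)
model_spec <- function(variant = c("stacked", "attention"),
                       tx = 30, input_dim = 9, hidden = 128,
                       context_dim = 2, dropout = 0.2,
                       include_mg_cluster = input_dim > 7) {
  variant <- match.arg(variant)
  if (hidden <= 0 || context_dim <= 0)
    stop("`hidden` and `context_dim` must be positive", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  if (tx < 1) stop("`tx` must be >= 1", call. = FALSE)
  structure(list(variant = variant, tx = as.integer(tx),
                 input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 context_dim = as.integer(context_dim),
                 dropout = dropout,
                 include_mg_cluster = isTRUE(include_mg_cluster)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$variant, "| Tx =", x$tx, "| input dim =",
      x$input_dim, "| hidden =", x$hidden, "| context =", x$context_dim,
      "| dropout =", x$dropout,
      if (x$include_mg_cluster) "| +MG/cluster head" else "", "\n")
  invisible(x)
}

#' Build (initialize) a sequence-regression model
#'
#' Allocates and initializes all trainable parameters for the given spec:
#' Glorot-uniform input and dense kernels, orthogonal recurrent kernels,
#' zero biases except a forget-gate bias of 1.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initialization draws.
#' @return Object of class `gxe_model`: list with `spec`, `params`, `seed`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  structure(list(spec = spec, params = init_params(spec, seed = seed),
                 seed = as.integer(seed)),
            class = "gxe_model")
}

#' @export
print.gxe_model <- function(x, ...) {
  print(x$spec)
  cat("  trainable parameters:", count_params(x), "\n")
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' Sums the scalar elements of every allocated parameter array. Under the
#' single-bias LSTM convention each LSTM layer contributes
#' \eqn{4h(d + h + 1)} parameters, a dense layer \eqn{d u + u}, and the
#' attention scorer \eqn{h + 1}. The reference configurations (Tx = 30,
#' 9-dimensional steps, hidden 128, context 2, MG + cluster head) hold
#' 202,503 (stacked) and 202,632 (attention) parameters.
#'
#' @param model A [build_model()] result, a fitted model, or a
#'   [model_spec()] (which is then instantiated).
#' @return Integer parameter count.
#' @export
#' @examples
#' count_params(model_spec("stacked", tx = 30, input_dim = 9))
count_params <- function(model) {
  if (inherits(model, "model_spec")) model <- build_model(model)
  stopifnot(!is.null(model$params))
  sum(vapply(model$params, length, integer(1)))
}

#' Per-layer parameter table of a model
#'
#' @param model A model or spec as in [count_params()].
#' @return Tibble with columns `layer` and `parameters`.
#' @export
describe_params <- function(model) {
  if (inherits(model, "model_spec")) model <- build_model(model)
  p <- model$params
  grp <- list(lstm_1 = c("W1", "U1", "b1"), lstm_2 = c("W2", "U2", "b2"),
              context_dense = c("Wc", "bc"), output_dense = c("Wo", "bo"))
  if (!is.null(p$wa)) grp$attention_scorer <- c("wa", "ba")
  tibble::tibble(
    layer = names(grp),
    parameters = vapply(grp, function(nms)
      sum(vapply(p[nms], length, integer(1))), integer(1))
  )
}

#' Softmax attention weights from annotation scores
#'
#' Applies the shared linear scorer \eqn{e^{<t>} = w^\top a^{<t>} + b} to
#' each time-step annotation and normalizes the scores with a numerically
#' stabilized (max-subtracted) softmax over time. Weights are non-negative
#' and sum to one; adding a constant to all scores leaves them unchanged.
#'
#' @param annotations Tx x hidden matrix of encoder annotations, or a
#'   numeric vector of precomputed scores (then `scorer` is ignored).
#' @param scorer List with `w` (hidden-length weights) and `b` (scalar).
#' @return Numeric vector of Tx attention weights summing to 1.
#' @export
#' @examples
#' attention_weights(c(0, log(3)))  # 0.25, 0.75
attention_weights <- function(annotations, scorer = NULL) {
  if (is.matrix(annotations)) {
    if (is.null(scorer))
      stop("`scorer` is required when annotations are supplied",
           call. = FALSE)
    e <- drop(annotations %*% matrix(scorer$w, ncol = 1)) + scorer$b
  } else {
    e <- as.numeric(annotations)
  }
  e <- e - max(e)
  w <- exp(e)
  w / sum(w)
}

#' Context vector: attention-weighted sum of annotations
#'
#' @param annotations Tx x hidden matrix.
#' @param alpha Attention profile of length Tx.
#' @return Hidden-length numeric context vector
#'   \eqn{c = \sum_t \alpha^{<t>} a^{<t>}}.
#' @export
context_vector <- function(annotations, alpha) {
  if (nrow(annotations) != length(alpha))
    stop("annotations and attention profile lengths differ", call. = FALSE)
  drop(crossprod(annotations, alpha))
}

#' Predict scaled yield for assembled inputs
#'
#' Runs the forward pass with dropout disabled; two calls on identical
#' inputs are bit-identical.
#'
#' @param object A `gxe_model` or fitted `gxe_fit`.
#' @param inputs A [assemble_inputs()] result.
#' @param ... Unused.
#' @return Numeric vector of predictions on the scaled (-1, 1) target scale.
#' @export
predict.gxe_model <- function(object, inputs, ...) {
  stopifnot(inherits(inputs, "model_input"))
  if (inputs$dim != object$spec$input_dim)
    stop("input step dimension ", inputs$dim, " does not match spec ",
         object$spec$input_dim, call. = FALSE)
  nn_forward(object$params, object$spec, inputs$x, inputs$side,
             training = FALSE)$yhat
}
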