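#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn train_model Tidy the per-epoch loss history of a fit.
#' @param x A fitted model.
#' @param ... Unused.
#' @method tidy gxe_fit
#' @export
tidy.gxe_fit <- function(x, ...) x$history

#' @describeIn train_model One-row model summary (architecture, parameter
#'   count, final losses).
#' @method glance gxe_fit
#' @export
glance.gxe_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    variant = x$spec$variant, tx = x$spec$tx, hidden = x$spec$hidden,
    context_dim = x$spec$context_dim, n_params = count_params(x),
    epochs = nrow(x$history), train_loss = last$train_loss,
    val_loss = last$val_loss
  )
}

#' @describeIn cluster_genotypes Tidy per-genotype cluster assignments.
#' @param x A `genotype_clusters` object.
#' @param ... Unused.
#' @method tidy genotype_clusters
#' @export
tidy.genotype_clusters <- function(x, ...) x$assignments

#' @describeIn cluster_genotypes One-row clustering summary.
#' @method glance genotype_clusters
#' @export
glance.genotype_clusters <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, inertia = x$inertia)
}

#' @describeIn repeated_runs Tidy per-repeat test metrics.
#' @param x A `repeat_runs` object.
#' @param ... Unused.
#' @method tidy repeat_runs
#' @export
tidy.repeat_runs <- function(x, ...) x$runs

#' @describeIn repeated_runs Metric means and SDs in one wide row.
#' @method glance repeat_runs
#' @export
glance.repeat_runs <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' @describeIn fit_baselines Tidy per-baseline test metrics.
#' @param x A `baseline_results` object.
#' @param ... Unused.
#' @method tidy baseline_results
#' @export
tidy.baseline_results <- function(x, ...) x$metrics
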