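#' Extract per-record attention profiles from a fitted attention model
#'
#' Runs the forward pass with dropout disabled and returns each record's
#' softmax-normalized attention weights over the Tx time-steps; every
#' profile is non-negative and sums to one.
#'
#' @param fit A fitted `gxe_fit` (or `gxe_model`) of the attention variant.
#' @param inputs [assemble_inputs()] result.
#' @return Object of class `attention_profiles`: long tibble with columns
#'   `record_id`, `step`, `alpha`.
#' @export
extract_profiles <- function(fit, inputs) {
  if (fit$spec$variant != "attention")
    stop("attention profiles require the attention variant, got '",
         fit$spec$variant, "'", call. = FALSE)
  stopifnot(inherits(inputs, "model_input"))
  fwd <- nn_forward(fit$params, fit$spec, inputs$x, inputs$side,
                    training = FALSE)
  alpha <- fwd$alpha
  rid <- inputs$records$record_id
  if (is.null(rid)) rid <- seq_len(nrow(alpha))
  out <- tibble::tibble(
    record_id = rep(rid, times = ncol(alpha)),
    step = rep(seq_len(ncol(alpha)), each = nrow(alpha)),
    alpha = as.vector(alpha)
  )
  structure(dplyr::arrange(out, .data$record_id, .data$step),
            tx = ncol(alpha), class = c("attention_profiles", class(out)))
}

#' Stratified attention summaries by yield range and maturity group
#'
#' Buckets records by maturity group and actual-yield range and summarises
#' each bucket's attention profile: per-step mean weight (each mean curve
#' still sums to one) and an inter-quartile dispersion band. Default yield
#' breaks are the within-MG quartiles; buckets with fewer than `min_n`
#' records are dropped with a message.
#'
#' @param profiles [extract_profiles()] result.
#' @param records Records tibble with `record_id`, `mg`, `yield`.
#' @param yield_breaks Optional strictly increasing break points (bu/acre);
#'   default: within-MG quartiles.
#' @param mg_values Maturity groups to summarise (default: MG 1 and 7 where
#'   present, else all observed groups).
#' @param min_n Minimum records per reported bucket (default 20).
#' @return Object of class `attention_summary`: tibble `mg`, `yield_range`,
#'   `n`, `step`, `mean_alpha`, `q25`, `q75`.
#' @export
stratify_profiles <- function(profiles, records, yield_breaks = NULL,
                              mg_values = NULL, min_n = 20) {
  if (!is.null(yield_breaks) && is.unsorted(yield_breaks, strictly = TRUE))
    stop("`yield_breaks` must be strictly increasing", call. = FALSE)
  if (is.null(mg_values)) {
    mg_values <- intersect(c(1, 7), unique(records$mg))
    if (length(mg_values) == 0) mg_values <- sort(unique(records$mg))
  }
  pieces <- list()
  for (mg in mg_values) {
    rec_mg <- records[records$mg == mg, ]
    if (nrow(rec_mg) == 0) next
    brk <- yield_breaks
    if (is.null(brk))
      brk <- unique(stats::quantile(rec_mg$yield, 0:4 / 4))
    rng <- cut(rec_mg$yield, breaks = brk, include.lowest = TRUE)
    dat <- dplyr::inner_join(
      profiles,
      tibble::tibble(record_id = rec_mg$record_id, yield_range = rng),
      by = "record_id")
    if (nrow(dat) == 0) next
    sm <- dat |>
      dplyr::group_by(.data$yield_range, .data$step) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$record_id),
                       mean_alpha = mean(.data$alpha),
                       q25 = stats::quantile(.data$alpha, 0.25),
                       q75 = stats::quantile(.data$alpha, 0.75),
                       .groups = "drop") |>
      dplyr::mutate(mg = mg, .before = 1)
    small <- unique(sm$yield_range[sm$n < min_n])
    if (length(small) > 0) {
      message("dropping ", length(small), " bucket(s) with n < ", min_n,
              " for MG ", mg)
      sm <- sm[!(sm$yield_range %in% small), ]
    }
    pieces[[length(pieces) + 1]] <- sm
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0)
    stop("no stratum contains any records", call. = FALSE)
  structure(out, class = c("attention_summary", class(out)))
}

#' Attention mass localization against a time-step window
#'
#' Quantifies how much attention mass falls inside a window of time-steps:
#' `mass_in` is the mean over records of the summed in-window weights, and
#' the per-step densities (mass divided by the number of steps inside /
#' outside) make windows of different lengths comparable. A density ratio
#' above 1 means the model attends preferentially to the window.
#'
#' @param profiles [extract_profiles()] result.
#' @param window Integer `c(first, last)` time-step range within 1..Tx.
#' @return Tibble with `mass_in`, `density_in`, `density_out`,
#'   `density_ratio`, `window_start`, `window_end`, `tx`.
#' @export
localization_score <- function(profiles, window) {
  tx <- attr(profiles, "tx")
  if (is.null(tx)) tx <- max(profiles$step)
  window <- as.integer(window)
  if (length(window) != 2 || window[1] > window[2] ||
      window[1] < 1 || window[2] > tx)
    stop("`window` must be c(first, last) within 1..", tx, call. = FALSE)
  len_in <- window[2] - window[1] + 1L
  len_out <- tx - len_in
  per_rec <- profiles |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(m = sum(.data$alpha[.data$step >= window[1] &
                                           .data$step <= window[2]]),
                     .groups = "drop")
  mass_in <- mean(per_rec$m)
  density_in <- mass_in / len_in
  density_out <- if (len_out > 0) (1 - mass_in) / len_out else NA_real_
  tibble::tibble(mass_in = mass_in, density_in = density_in,
                 density_out = density_out,
                 density_ratio = density_in / density_out,
                 window_start = window[1], window_end = window[2], tx = tx)
}
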