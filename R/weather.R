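#' Model time-step count for a downsampling granularity
#'
#' Weekly, biweekly and monthly granularities partition the first 210 days
#' of the 214-day growing season into 30, 15 and 7 windows; daily keeps all
#' 214 days.
#'
#' @param granularity One of "daily", "weekly", "biweekly", "monthly".
#' @return Integer number of time-steps (214, 30, 15 or 7).
#' @export
granularity_steps <- function(granularity) {
  switch(match.arg(granularity, c("daily", "weekly", "biweekly", "monthly")),
         daily = 214L, weekly = 30L, biweekly = 15L, monthly = 7L)
}

granularity_window <- function(granularity) {
  switch(granularity, weekly = 7L, biweekly = 14L, monthly = 30L)
}

#' Downsample daily weather to model time-steps
#'
#' For weekly/biweekly/monthly granularity the first 210 days of each
#' location-year are split into consecutive equal windows (7/14/30 days) and
#' aggregated so each variable keeps its sense: window mean for ADNI, ARH,
#' AvgSur, window maximum for MDNI and MaxSur, window minimum for MinSur.
#' Precipitation (AP) is averaged by default; window totals are available
#' via `ap = "total"`. Daily granularity passes all 214 rows through
#' unchanged.
#'
#' @param weather Tibble of daily weather: `location_id`, `year`, `day`
#'   (1..214) and the seven variable columns of [weather_variables()]. Every
#'   location-year must have exactly 214 days.
#' @param granularity One of "daily", "weekly", "biweekly", "monthly".
#' @param ap Precipitation aggregation, "mean" (default) or "total".
#' @return Tibble `location_id`, `year`, `step` (1..Tx) and the seven
#'   variables.
#' @export
#' @examples
#' tb <- sim_trial(sim_config(n_founders = 4, n_generations = 0,
#'                            location_latitudes = 40, years = 2003))
#' nrow(downsample_weather(tb$weather, "monthly"))  # 7 steps
downsample_weather <- function(weather, granularity = "weekly",
                               ap = c("mean", "total")) {
  granularity <- match.arg(granularity,
                           c("daily", "weekly", "biweekly", "monthly"))
  ap <- match.arg(ap)
  counts <- dplyr::count(weather, .data$location_id, .data$year)
  if (any(counts$n != 214))
    stop("every location-year series must have exactly 214 days; offending: ",
         paste(utils::head(paste0(counts$location_id[counts$n != 214], "/",
                                  counts$year[counts$n != 214]), 5),
               collapse = ", "), call. = FALSE)
  if (granularity == "daily") {
    out <- weather |>
      dplyr::arrange(.data$location_id, .data$year, .data$day) |>
      dplyr::mutate(step = .data$day)
    return(out[, c("location_id", "year", "step", weather_variables())])
  }
  w <- granularity_window(granularity)
  ap_fun <- if (ap == "mean") mean else sum
  weather |>
    dplyr::filter(.data$day <= 210) |>
    dplyr::mutate(step = ((.data$day - 1L) %/% w) + 1L) |>
    dplyr::group_by(.data$location_id, .data$year, .data$step) |>
    dplyr::summarise(
      ADNI = mean(.data$ADNI),
      AP = ap_fun(.data$AP),
      ARH = mean(.data$ARH),
      MDNI = max(.data$MDNI),
      MaxSur = max(.data$MaxSur),
      MinSur = min(.data$MinSur),
      AvgSur = mean(.data$AvgSur),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$location_id, .data$year, .data$step)
}

#' Fit a (-1, 1) min-max scaler on training-set features
#'
#' Stores the observed per-feature minimum and maximum; the transform is
#' \eqn{x \mapsto 2 (x - min)/(max - min) - 1}, so training-set values map
#' into [-1, 1] (test values outside the training range legitimately map
#' outside; no clipping). A constant feature maps to 0 by convention.
#'
#' @param data Data frame of training features (one column per feature).
#' @param features Character vector of column names to fit; defaults to all
#'   numeric columns.
#' @return Object of class `minmax_scaler`: tibble `feature`, `min`, `max`.
#' @export
fit_scaler <- function(data, features = NULL) {
  if (is.null(features))
    features <- names(data)[vapply(data, is.numeric, logical(1))]
  if (nrow(data) == 0 || length(features) == 0)
    stop("cannot fit a scaler on an empty training set", call. = FALSE)
  sc <- tibble::tibble(
    feature = features,
    min = vapply(features, function(f) min(data[[f]]), numeric(1)),
    max = vapply(features, function(f) max(data[[f]]), numeric(1))
  )
  structure(sc, class = c("minmax_scaler", class(sc)))
}

#' Apply a fitted min-max scaler to one feature
#'
#' @param x Numeric vector in original units.
#' @param scaler A [fit_scaler()] result.
#' @param feature Feature name within the scaler.
#' @return Scaled values (training range maps to [-1, 1]).
#' @export
scale_feature <- function(x, scaler, feature) {
  i <- match(feature, scaler$feature)
  if (is.na(i)) stop("feature not in scaler: ", feature, call. = FALSE)
  rng <- scaler$max[i] - scaler$min[i]
  if (rng == 0) return(rep(0, length(x)))
  2 * (x - scaler$min[i]) / rng - 1
}

#' Invert a min-max scaling back to original units
#'
#' @inheritParams scale_feature
#' @param x Scaled values.
#' @return Values in original feature units.
#' @export
unscale_feature <- function(x, scaler, feature) {
  i <- match(feature, scaler$feature)
  if (is.na(i)) stop("feature not in scaler: ", feature, call. = FALSE)
  rng <- scaler$max[i] - scaler$min[i]
  if (rng == 0) return(rep(scaler$min[i], length(x)))
  (x + 1) / 2 * rng + scaler$min[i]
}

#' Fit the input scaler for a set of training records
#'
#' Pools each weather variable over all time-steps of the training records'
#' location-years and records min/max, together with the maturity group,
#' cluster ID and yield ranges — every model input (and the target) is
#' scaled to (-1, 1) with statistics from the training split only.
#'
#' @param records Training-split records (tibble with `location_id`, `year`,
#'   `mg`, `yield`, `genotype_id`).
#' @param weather_ds Downsampled weather from [downsample_weather()].
#' @param clusters Optional [cluster_genotypes()] result (or its
#'   `assignments` tibble) when cluster IDs are model inputs.
#' @param variables Weather variables to include (default all seven).
#' @return A `minmax_scaler` covering `variables`, `mg`, `cluster` (if
#'   given) and `yield`.
#' @export
fit_input_scaler <- function(records, weather_ds, clusters = NULL,
                             variables = weather_variables()) {
  wtrain <- dplyr::semi_join(weather_ds, records,
                             by = c("location_id", "year"))
  feats <- as.data.frame(wtrain[, variables, drop = FALSE])
  sc <- fit_scaler(feats, variables)
  extra <- tibble::tibble(feature = "mg",
                          min = min(records$mg), max = max(records$mg))
  if (!is.null(clusters)) {
    asg <- if (inherits(clusters, "genotype_clusters")) clusters$assignments
           else clusters
    cl <- asg$cluster[match(records$genotype_id, asg$genotype_id)]
    extra <- dplyr::bind_rows(extra,
      tibble::tibble(feature = "cluster",
                     min = min(cl, na.rm = TRUE), max = max(cl, na.rm = TRUE)))
  }
  extra <- dplyr::bind_rows(extra,
    tibble::tibble(feature = "yield",
                   min = min(records$yield), max = max(records$yield)))
  out <- dplyr::bind_rows(tibble::as_tibble(sc), extra)
  structure(out, class = c("minmax_scaler", class(tibble::tibble())))
}

#' Assemble per-record model input sequences
#'
#' Builds, for each performance record, the Tx-step input sequence the
#' sequence regressors consume: the scaled weather variables of its
#' location-year in fixed column order, optionally with the scaled maturity
#' group and cluster ID appended at every time-step (9-dimensional steps)
#' and kept as a side vector that re-enters the head just before
#' prediction. The target yield is scaled with the same training-fitted
#' scaler.
#'
#' @param records Records to assemble (any split).
#' @param weather_ds Downsampled weather from [downsample_weather()].
#' @param scaler Training-fitted scaler from [fit_input_scaler()].
#' @param clusters Cluster assignment (required when
#'   `include_mg_cluster = TRUE`).
#' @param variables Weather variables to include, in order.
#' @param include_mg_cluster Append MG and cluster ID to every step and to
#'   the head (per-step dimension becomes `length(variables) + 2`).
#' @return Object of class `model_input`: list with `x` (array n x Tx x d),
#'   `side` (n x 2 matrix or NULL), `y` (scaled), `y_raw` (bu/acre),
#'   `records`, `tx`, `dim`, `variables`, `scaler`.
#' @export
assemble_inputs <- function(records, weather_ds, scaler, clusters = NULL,
                            variables = weather_variables(),
                            include_mg_cluster = FALSE) {
  if (include_mg_cluster && is.null(clusters))
    stop("`clusters` is required when include_mg_cluster = TRUE",
         call. = FALSE)
  key <- paste(weather_ds$location_id, weather_ds$year)
  tx <- max(weather_ds$step)
  rec_key <- paste(records$location_id, records$year)
  miss <- !(rec_key %in% key)
  if (any(miss))
    stop("no weather for records: ",
         paste(utils::head(unique(rec_key[miss]), 5), collapse = ", "),
         call. = FALSE)

  # scaled weather matrix per location-year, in fixed variable order
  wmat <- as.matrix(weather_ds[, variables, drop = FALSE])
  for (j in seq_along(variables))
    wmat[, j] <- scale_feature(wmat[, j], scaler, variables[j])
  ord <- order(key, weather_ds$step)
  wmat <- wmat[ord, , drop = FALSE]
  ukeys <- unique(key[ord])
  series <- lapply(seq_along(ukeys), function(i)
    wmat[((i - 1) * tx + 1):(i * tx), , drop = FALSE])
  names(series) <- ukeys

  n <- nrow(records)
  d <- length(variables) + if (include_mg_cluster) 2L else 0L
  x <- array(0, dim = c(n, tx, d))
  side <- NULL
  mg_s <- scale_feature(records$mg, scaler, "mg")
  cl_s <- NULL
  if (include_mg_cluster) {
    asg <- if (inherits(clusters, "genotype_clusters")) clusters$assignments
           else clusters
    cl <- asg$cluster[match(records$genotype_id, asg$genotype_id)]
    if (anyNA(cl))
      stop("no cluster for genotypes: ",
           paste(utils::head(unique(records$genotype_id[is.na(cl)]), 5),
                 collapse = ", "), call. = FALSE)
    cl_s <- scale_feature(cl, scaler, "cluster")
    side <- cbind(mg = mg_s, cluster = cl_s)
  }
  for (r in seq_len(n)) {
    m <- series[[rec_key[r]]]
    if (include_mg_cluster)
      m <- cbind(m, mg_s[r], cl_s[r])
    x[r, , ] <- m
  }
  y_raw <- records$yield
  structure(list(
    x = x, side = side,
    y = scale_feature(y_raw, scaler, "yield"), y_raw = y_raw,
    records = records, tx = as.integer(tx), dim = as.integer(d),
    variables = variables, include_mg_cluster = include_mg_cluster,
    scaler = scaler
  ), class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  cat("<model_input>", dim(x$x)[1], "records | Tx =", x$tx,
      "| step dim =", x$dim,
      if (x$include_mg_cluster) "(weather + MG + cluster)" else "(weather)",
      "\n")
  invisible(x)
}

subset_input <- function(inputs, idx) {
  structure(list(
    x = inputs$x[idx, , , drop = FALSE],
    side = if (!is.null(inputs$side)) inputs$side[idx, , drop = FALSE],
    y = inputs$y[idx], y_raw = inputs$y_raw[idx],
    records = inputs$records[idx, ], tx = inputs$tx, dim = inputs$dim,
    variables = inputs$variables,
    include_mg_cluster = inputs$include_mg_cluster, scaler = inputs$scaler
  ), class = "model_input")
}
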