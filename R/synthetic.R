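#' Configuration for the synthetic multi-environment trial generator
#'
#' Bundles every knob of the synthetic uniform-trial simulator: pedigree
#' shape, trial geography, the planted yield-generating mechanism and the
#' noise level. The defaults describe a small but fully structured trial
#' system: five founder families crossed within family for four generations,
#' twelve locations spanning 30-48 degrees N, six trial years, and a yield
#' surface with additive family (cluster) effects, a quadratic maturity-group
#' adaptation penalty, and time-windowed weather effects.
#'
#' @param n_founders Number of founder lines (>= 2), split evenly across
#'   `n_families`.
#' @param n_generations Number of crossing generations after the founders.
#' @param crosses_per_generation New lines created per generation.
#' @param n_families Number of founder families; crossing stays within
#'   family, so families are the ground-truth relatedness clusters.
#' @param location_latitudes Numeric vector of trial-site latitudes in
#'   degrees N (all within 25-55).
#' @param years Integer vector of trial years.
#' @param base_yield Intercept yield in bu/acre.
#' @param cluster_effect_sd SD (bu/acre) of the per-family yield effect.
#' @param mg_adapt_penalty Yield penalty in bu/acre per squared maturity-group
#'   unit of mismatch between a line's MG and the local optimum.
#' @param mg_opt_slope Change in locally optimal MG per degree of latitude
#'   (negative: northern sites favour earlier groups).
#' @param effect_window Integer day range `c(d1, d2)` within 1..214 over
#'   which weather affects yield.
#' @param effect_sizes Named numeric vector, bu/acre per standardized unit of
#'   the window mean of each named weather variable.
#' @param noise_sd Residual plot-level SD in bu/acre.
#' @param plant_prob Probability that a line is planted in any given
#'   adaptation-eligible location-year.
#' @param seed Integer seed; identical configurations generate identical
#'   trials.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_founders = 4, n_generations = 1,
#'                   crosses_per_generation = 2, years = 2003, seed = 7)
#' cfg$n_founders
sim_config <- function(n_founders = 20,
                       n_generations = 4,
                       crosses_per_generation = 60,
                       n_families = min(5L, n_founders),
                       location_latitudes = seq(30, 48, length.out = 12),
                       years = 2003:2008,
                       base_yield = 50,
                       cluster_effect_sd = 4,
                       mg_adapt_penalty = 2,
                       mg_opt_slope = -0.4,
                       effect_window = c(120L, 168L),
                       effect_sizes = c(MinSur = 4, ADNI = 2),
                       noise_sd = 3,
                       plant_prob = 0.85,
                       seed = 1L) {
  stopifnot(is.numeric(n_founders), length(n_founders) == 1)
  if (n_founders < 2) stop("`n_founders` must be >= 2", call. = FALSE)
  if (n_generations < 0 || crosses_per_generation < 0)
    stop("generation and cross counts must be non-negative", call. = FALSE)
  if (n_families < 1 || n_families > n_founders)
    stop("`n_families` must be in 1..n_founders", call. = FALSE)
  if (any(location_latitudes < 25 | location_latitudes > 55))
    stop("latitudes must lie within [25, 55] degrees N", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  ew <- as.integer(effect_window)
  if (length(ew) != 2 || ew[1] < 1 || ew[2] > 214 || ew[1] > ew[2])
    stop("`effect_window` must satisfy 1 <= d1 <= d2 <= 214", call. = FALSE)
  if (length(effect_sizes) &&
      !all(names(effect_sizes) %in% weather_variables()))
    stop("`effect_sizes` names must be weather variables: ",
         paste(weather_variables(), collapse = ", "), call. = FALSE)
  if (plant_prob <= 0 || plant_prob > 1)
    stop("`plant_prob` must be in (0, 1]", call. = FALSE)
  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    crosses_per_generation = as.integer(crosses_per_generation),
    n_families = as.integer(n_families),
    location_latitudes = as.numeric(location_latitudes),
    years = as.integer(years),
    base_yield = base_yield,
    cluster_effect_sd = cluster_effect_sd,
    mg_adapt_penalty = mg_adapt_penalty,
    mg_opt_slope = mg_opt_slope,
    effect_window = ew,
    effect_sizes = effect_sizes,
    noise_sd = noise_sd,
    plant_prob = plant_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' The seven daily weather variables, in canonical column order
#'
#' ADNI and MDNI are average and maximum direct normal irradiance (W m^-2),
#' AP is average precipitation (inches), ARH average relative humidity (%),
#' and MaxSur/MinSur/AvgSur are daily maximum/minimum/average surface
#' temperature (degrees C).
#'
#' @return Character vector of length 7.
#' @export
weather_variables <- function() {
  c("ADNI", "AP", "ARH", "MDNI", "MaxSur", "MinSur", "AvgSur")
}

#' Locally optimal maturity group for a latitude
#'
#' Linear adaptation map: MG 8 at 30 degrees N falling by `slope` per degree,
#' clamped to the 0-8 maturity-group scale, so northern sites favour early
#' (low) groups.
#'
#' @param latitude Latitude in degrees N.
#' @param slope MG units per degree latitude (default -0.4 reaches MG 0 by
#'   50 degrees N).
#' @return Numeric optimal MG, same length as `latitude`.
#' @export
mg_optimum <- function(latitude, slope = -0.4) {
  pmin(8, pmax(0, 8 + slope * (latitude - 30)))
}

#' Simulate a founder-family pedigree
#'
#' Founders (unknown parents) are split into families; each later generation
#' adds lines by crossing two distinct, earlier individuals of the same
#' family, so ancestry always terminates in founders and between-family
#' relatedness is exactly zero. Each line carries a maturity group: founders
#' draw MG uniformly from 0-8 and offspring take the rounded mid-parent MG
#' with small jitter.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `id`, `parent1`, `parent2` (NA for
#'   founders), `generation`, `family`, `mg`.
#' @export
sim_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  founders <- tibble::tibble(
    id = sprintf("F%03d", seq_len(cfg$n_founders)),
    parent1 = NA_character_,
    parent2 = NA_character_,
    generation = 0L,
    family = rep_len(seq_len(cfg$n_families), cfg$n_founders),
    mg = sample(0:8, cfg$n_founders, replace = TRUE)
  )
  ped <- founders
  if (cfg$n_generations > 0 && cfg$crosses_per_generation > 0) {
    for (g in seq_len(cfg$n_generations)) {
      rows <- purrr::map(seq_len(cfg$crosses_per_generation), function(k) {
        # restrict to families with at least two members so parents differ
        tab <- table(ped$family)
        fams <- as.integer(names(tab)[tab >= 2])
        fam <- if (length(fams) == 1) fams else sample(fams, 1)
        pool <- ped[ped$family == fam, ]
        pick <- sample(nrow(pool), 2)
        p <- pool[pick, ]
        mg_off <- round(mean(p$mg) + stats::rnorm(1, 0, 0.6))
        tibble::tibble(
          id = sprintf("G%d_%03d", g, k),
          parent1 = p$id[1], parent2 = p$id[2],
          generation = g, family = fam,
          mg = as.integer(pmin(8, pmax(0, mg_off)))
        )
      })
      ped <- dplyr::bind_rows(ped, rows)
    }
  }
  ped
}

#' Simulate daily growing-season weather for every location-year
#'
#' Each of the 214 days (April 1 - October 31) of every location-year gets
#' the seven weather variables. Average surface temperature follows a
#' latitude-shifted seasonal sinusoid (peak near mid-July) plus AR(1) noise;
#' daily minima and maxima are the average offset by strictly positive random
#' gaps, so MinSur <= AvgSur <= MaxSur holds by construction, as does
#' ADNI <= MDNI. Precipitation is a zero-inflated gamma (>= 0) and relative
#' humidity is clamped to [0, 100].
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `location_id`, `latitude`, `year`, `day`
#'   (1-214) and the seven weather variables.
#' @export
sim_weather <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  lats <- cfg$location_latitudes
  locs <- sprintf("L%02d", seq_along(lats))
  grid <- tidyr::expand_grid(loc_i = seq_along(lats), year = cfg$years)
  days <- 1:214
  season <- cos(2 * pi * (days - 107) / 365)  # peaks mid-July (day ~107)
  out <- purrr::pmap(grid, function(loc_i, year) {
    lat <- lats[loc_i]
    ar1 <- as.numeric(stats::filter(stats::rnorm(214, 0, 1.5),
                                    filter = 0.6, method = "recursive"))
    avg_sur <- 12 + 12 * season - 0.35 * (lat - 30) + ar1
    gap_lo <- 2 + stats::rexp(214, 1 / 3)
    gap_hi <- 2 + stats::rexp(214, 1 / 3)
    adni <- pmax(0, 150 + 120 * season - 2 * (lat - 30) +
                   stats::rnorm(214, 0, 30))
    tibble::tibble(
      location_id = locs[loc_i], latitude = lat, year = year, day = days,
      ADNI = adni,
      AP = stats::rbinom(214, 1, 0.45) *
        stats::rgamma(214, shape = 0.8, scale = 0.15),
      ARH = pmin(100, pmax(0, stats::rnorm(214, 70, 12))),
      MDNI = adni + 50 + stats::rexp(214, 1 / 100),
      MaxSur = avg_sur + gap_hi,
      MinSur = avg_sur - gap_lo,
      AvgSur = avg_sur
    )
  })
  dplyr::bind_rows(out)
}

#' Simulate the planting design (which line is trialled where and when)
#'
#' Mirrors uniform-trial practice: a line is entered only at locations whose
#' locally optimal maturity group lies within one MG unit of its own, and
#' each eligible location-year is planted independently with probability
#' `plant_prob`. Lines whose MG matches no site (or that lose every draw)
#' are planted at the nearest-adaptation site in the first year, so every
#' genotype yields at least one record.
#'
#' @param cfg A [sim_config()].
#' @param pedigree Output of [sim_pedigree()].
#' @return A tibble with columns `genotype_id`, `location_id`, `latitude`,
#'   `year`, `mg`.
#' @export
sim_records <- function(cfg, pedigree) {
  set.seed(cfg$seed + 2L)
  lats <- cfg$location_latitudes
  locs <- sprintf("L%02d", seq_along(lats))
  mg_opt <- mg_optimum(lats, cfg$mg_opt_slope)
  rows <- purrr::pmap(list(pedigree$id, pedigree$mg), function(gid, mg) {
    elig <- which(abs(mg - mg_opt) <= 1)
    if (length(elig) == 0) elig <- which.min(abs(mg - mg_opt))
    cells <- tidyr::expand_grid(loc_i = elig, year = cfg$years)
    keep <- stats::runif(nrow(cells)) < cfg$plant_prob
    if (!any(keep)) keep[1] <- TRUE
    cells <- cells[keep, ]
    tibble::tibble(genotype_id = gid, location_id = locs[cells$loc_i],
                   latitude = lats[cells$loc_i], year = cells$year, mg = mg)
  })
  dplyr::bind_rows(rows)
}

#' Simulate yields and assemble a complete trial bundle
#'
#' Generates pedigree, weather and planting design, then computes each
#' record's yield from the planted mechanism:
#' \deqn{y = \mu + c_{fam} - p\,(MG - MG_{opt}(lat))^2 +
#'       \sum_v \beta_v z_v + \epsilon}
#' where \eqn{c_{fam}} is a family effect drawn once per family from
#' N(0, `cluster_effect_sd`), the quadratic term penalises maturity-group
#' mismatch, \eqn{z_v} is the location-year mean of variable v over
#' `effect_window`, standardized across location-years, and
#' \eqn{\epsilon \sim N(0, noise\_sd)}. The full decomposition is stored per
#' record in `truth`, so with `noise_sd = 0` the stated formula reproduces
#' every yield exactly.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `trial_bundle`: a list with `records`
#'   (tibble incl. `yield`), `pedigree`, `weather`, `truth` (per-record
#'   effect decomposition) and `config`.
#' @export
#' @examples
#' tb <- sim_trial(sim_config(n_founders = 6, n_generations = 1,
#'                            crosses_per_generation = 4,
#'                            location_latitudes = c(32, 44),
#'                            years = 2003, seed = 3))
#' nrow(tb$records)
sim_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pedigree <- sim_pedigree(cfg)
  weather <- sim_weather(cfg)
  records <- sim_records(cfg, pedigree)

  set.seed(cfg$seed + 3L)
  fam_eff <- stats::rnorm(cfg$n_families, 0, cfg$cluster_effect_sd)

  # standardized window means of the effect-carrying weather variables
  ew <- cfg$effect_window
  wmeans <- weather |>
    dplyr::filter(.data$day >= ew[1], .data$day <= ew[2]) |>
    dplyr::group_by(.data$location_id, .data$year) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(weather_variables()), mean),
                     .groups = "drop")
  for (v in weather_variables()) {
    x <- wmeans[[v]]
    s <- stats::sd(x)
    wmeans[[paste0("z_", v)]] <-
      if (!is.na(s) && s > 0) (x - mean(x)) / s else x * 0
  }

  miss <- dplyr::anti_join(records, wmeans, by = c("location_id", "year"))
  if (nrow(miss) > 0)
    stop("missing weather for location-years: ",
         paste(unique(paste0(miss$location_id, "/", miss$year)),
               collapse = ", "), call. = FALSE)

  truth <- records |>
    dplyr::left_join(pedigree[, c("id", "family")],
                     by = c(genotype_id = "id")) |>
    dplyr::left_join(wmeans, by = c("location_id", "year"))
  truth$cluster_true <- truth$family
  truth$cluster_effect <- fam_eff[truth$family]
  truth$mg_penalty <- -cfg$mg_adapt_penalty *
    (truth$mg - mg_optimum(truth$latitude, cfg$mg_opt_slope))^2
  we <- rep(0, nrow(truth))
  for (v in names(cfg$effect_sizes)) {
    we <- we + cfg$effect_sizes[[v]] * truth[[paste0("z_", v)]]
  }
  truth$weather_effect <- we
  truth$noise <- stats::rnorm(nrow(truth), 0, cfg$noise_sd)
  truth$base_yield <- cfg$base_yield
  truth$yield <- truth$base_yield + truth$cluster_effect + truth$mg_penalty +
    truth$weather_effect + truth$noise

  records$yield <- truth$yield
  records$record_id <- seq_len(nrow(records))
  truth$record_id <- records$record_id
  truth <- truth[, c("record_id", "genotype_id", "location_id", "year", "mg",
                     "cluster_true", "base_yield", "cluster_effect",
                     "mg_penalty", "weather_effect", "noise", "yield")]
  structure(list(records = records, pedigree = pedigree, weather = weather,
                 truth = truth, config = cfg),
            class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat("<trial_bundle>\n",
      nrow(x$records), "records |",
      nrow(x$pedigree), "genotypes |",
      dplyr::n_distinct(x$weather$location_id), "locations x",
      dplyr::n_distinct(x$weather$year), "years\n")
  invisible(x)
}

#' Write a trial bundle to plain-text CSV files
#'
#' Writes `records.csv`, `pedigree.csv` (unknown parents as NA),
#' `weather.csv` (long format: location_id, year, day, variable, value) and
#' `truth.csv` into `dir`.
#'
#' @param bundle A [sim_trial()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(bundle, dir) {
  stopifnot(inherits(bundle, "trial_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- bundle$records[, c("genotype_id", "location_id", "year", "mg",
                            "yield")]
  names(rec)[5] <- "yield_bu_ac"
  utils::write.csv(rec, file.path(dir, "records.csv"), row.names = FALSE)
  ped <- bundle$pedigree[, c("id", "parent1", "parent2")]
  utils::write.csv(ped, file.path(dir, "pedigree.csv"), row.names = FALSE)
  wl <- tidyr::pivot_longer(
    bundle$weather[, c("location_id", "year", "day", weather_variables())],
    dplyr::all_of(weather_variables()),
    names_to = "variable", values_to = "value")
  utils::write.csv(wl, file.path(dir, "weather.csv"), row.names = FALSE)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read trial CSV files written by [write_trial()]
#'
#' @param dir Directory containing `records.csv`, `pedigree.csv`,
#'   `weather.csv`.
#' @return A list with tibbles `records`, `pedigree`, `weather` (wide, one
#'   column per weather variable).
#' @export
read_trial <- function(dir) {
  rec <- tibble::as_tibble(utils::read.csv(file.path(dir, "records.csv")))
  names(rec)[names(rec) == "yield_bu_ac"] <- "yield"
  ped <- tibble::as_tibble(utils::read.csv(file.path(dir, "pedigree.csv")))
  wl <- tibble::as_tibble(utils::read.csv(file.path(dir, "weather.csv")))
  weather <- tidyr::pivot_wider(wl, names_from = "variable",
                                values_from = "value")
  list(records = rec, pedigree = ped, weather = weather)
}
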