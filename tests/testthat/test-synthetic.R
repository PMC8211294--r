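test_that("pedigree generation counts and base cases are exact", {
  cfg0 <- sim_config(n_founders = 5, n_generations = 0,
                     location_latitudes = 40, years = 2003, seed = 1)
  ped0 <- sim_pedigree(cfg0)
  expect_equal(nrow(ped0), 5)
  expect_true(all(is.na(ped0$parent1)) && all(is.na(ped0$parent2)))

  cfg <- sim_config(n_founders = 4, n_generations = 2,
                    crosses_per_generation = 3, n_families = 2,
                    location_latitudes = 40, years = 2003, seed = 1)
  ped <- sim_pedigree(cfg)
  expect_equal(nrow(ped), 4 + 2 * 3)
  nonf <- ped[ped$generation > 0, ]
  expect_false(anyNA(nonf$parent1))
  expect_false(anyNA(nonf$parent2))
  # every ancestry terminates in founders: relationship matrix must build
  expect_silent(relationship_matrix(ped))
})

test_that("generators are deterministic given an identical configuration", {
  cfg <- sim_config(n_founders = 6, n_generations = 1,
                    crosses_per_generation = 4,
                    location_latitudes = c(32, 44), years = 2003:2004,
                    seed = 99)
  expect_identical(sim_pedigree(cfg), sim_pedigree(cfg))
  expect_identical(sim_weather(cfg), sim_weather(cfg))
  b1 <- sim_trial(cfg)
  b2 <- sim_trial(cfg)
  expect_identical(b1$records, b2$records)
  expect_identical(b1$truth, b2$truth)
})

test_that("weather series have 214 x 7 shape and physical ordering", {
  tb <- small_trial()
  w <- tb$weather
  counts <- dplyr::count(w, location_id, year)
  expect_true(all(counts$n == 214))
  expect_equal(length(weather_variables()), 7)
  expect_true(all(weather_variables() %in% names(w)))
  expect_true(all(w$MinSur <= w$AvgSur))
  expect_true(all(w$AvgSur <= w$MaxSur))
  expect_true(all(w$ADNI <= w$MDNI))
  expect_true(all(w$AP >= 0))
  expect_true(all(w$ARH >= 0 & w$ARH <= 100))
})

test_that("seasonal curve makes July warmer at southern latitudes", {
  cfg <- sim_config(n_founders = 2, location_latitudes = c(30, 48),
                    years = 2003, seed = 7)
  w <- sim_weather(cfg)
  july <- w[w$day >= 92 & w$day <= 122, ]  # July within Apr 1 indexing
  m <- tapply(july$AvgSur, july$latitude, mean)
  expect_gt(m[["30"]], m[["48"]])
})

test_that("yield decomposition is exact when noise is zero", {
  cfg <- sim_config(n_founders = 6, n_generations = 1,
                    crosses_per_generation = 4, n_families = 2,
                    location_latitudes = c(32, 40, 46), years = 2003:2004,
                    noise_sd = 0, seed = 5)
  tb <- sim_trial(cfg)
  with(tb$truth, {
    expect_equal(yield,
                 base_yield + cluster_effect + mg_penalty + weather_effect,
                 tolerance = 1e-12)
    expect_true(all(noise == 0))
  })
  expect_equal(tb$records$yield, tb$truth$yield)
})

test_that("degenerate config (no effects, no noise) yields base_yield", {
  cfg <- sim_config(n_founders = 4, n_generations = 0, n_families = 1,
                    location_latitudes = 40, years = 2003,
                    cluster_effect_sd = 0, mg_adapt_penalty = 0,
                    effect_sizes = numeric(0), noise_sd = 0,
                    base_yield = 47.5, seed = 2)
  tb <- sim_trial(cfg)
  expect_true(all(tb$records$yield == 47.5))
})

test_that("a planted MinSur effect shows up as a positive yield correlation", {
  cfg <- sim_config(n_founders = 20, n_generations = 3,
                    crosses_per_generation = 40,
                    cluster_effect_sd = 0, mg_adapt_penalty = 0,
                    effect_sizes = c(MinSur = 4), noise_sd = 1, seed = 13)
  tb <- sim_trial(cfg)
  expect_gte(nrow(tb$records), 1000)
  ew <- cfg$effect_window
  wm <- tb$weather |>
    dplyr::filter(day >= ew[1], day <= ew[2]) |>
    dplyr::group_by(location_id, year) |>
    dplyr::summarise(minsur = mean(MinSur), .groups = "drop")
  rec <- dplyr::left_join(tb$records, wm, by = c("location_id", "year"))
  expect_gt(cor(rec$minsur, rec$yield), 0.5)
})

test_that("record count equals the sum of planted location-years", {
  tb <- small_trial()
  per_cell <- dplyr::count(tb$records, location_id, year)
  expect_equal(sum(per_cell$n), nrow(tb$records))
  # every record resolves to weather and pedigree
  expect_true(all(paste(tb$records$location_id, tb$records$year) %in%
                    paste(tb$weather$location_id, tb$weather$year)))
  expect_true(all(tb$records$genotype_id %in% tb$pedigree$id))
  expect_true(all(is.finite(tb$records$yield)))
})

test_that("trial CSV round-trip preserves records, pedigree and weather", {
  tb <- small_trial()
  dir <- withr::local_tempdir()
  write_trial(tb, dir)
  expect_true(all(file.exists(file.path(dir,
    c("records.csv", "pedigree.csv", "weather.csv", "truth.csv")))))
  back <- read_trial(dir)
  expect_equal(nrow(back$records), nrow(tb$records))
  expect_equal(back$records$yield, tb$records$yield)
  expect_equal(back$pedigree$id, tb$pedigree$id)
  w <- dplyr::arrange(back$weather, location_id, year, day)
  w0 <- dplyr::arrange(tb$weather[, names(w)[names(w) != "latitude"]],
                       location_id, year, day)
  expect_equal(as.data.frame(w[weather_variables()]),
               as.data.frame(w0[weather_variables()]))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_founders = 1), "n_founders")
  expect_error(sim_config(effect_window = c(0, 10)), "effect_window")
  expect_error(sim_config(effect_window = c(50, 220)), "effect_window")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(location_latitudes = c(40, 60)), "latitudes")
  expect_error(sim_config(effect_sizes = c(NotAVar = 1)), "weather variables")
})
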