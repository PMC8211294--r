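# an untrained attention model is enough for the structural contracts
attn_setup <- function() {
  if (is.null(fixture_env$attn_setup)) {
    pb <- tiny_problem()
    m <- build_model(model_spec("attention", tx = 7, input_dim = 7,
                                hidden = 6, context_dim = 2,
                                include_mg_cluster = FALSE), seed = 3)
    fixture_env$attn_setup <- list(pb = pb, m = m,
                                   pr = extract_profiles(m, pb$test))
  }
  fixture_env$attn_setup
}

test_that("extracted profiles are normalized, typed and deterministic", {
  s <- attn_setup()
  pr <- s$pr
  sums <- tapply(pr$alpha, pr$record_id, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(pr$alpha >= 0))
  expect_equal(max(pr$step), 7)
  expect_identical(pr, extract_profiles(s$m, s$pb$test))
  # identical records get identical profiles
  inp2 <- s$pb$test
  inp2$x[2, , ] <- inp2$x[1, , ]
  pr2 <- extract_profiles(s$m, inp2)
  expect_equal(pr2$alpha[pr2$record_id == pr2$record_id[1]],
               pr2$alpha[pr2$record_id == unique(pr2$record_id)[2]])
  # stacked models are rejected
  ms <- build_model(tiny_spec(), seed = 1)
  expect_error(extract_profiles(ms, s$pb$test), "attention")
})

test_that("weekly attention profiles have length 30", {
  tb <- small_trial()
  wds <- downsample_weather(tb$weather, "weekly")
  sc <- fit_input_scaler(tb$records, wds)
  inp <- assemble_inputs(tb$records[1:5, ], wds, sc)
  m <- build_model(model_spec("attention", tx = 30, input_dim = 7,
                              hidden = 4, include_mg_cluster = FALSE))
  pr <- extract_profiles(m, inp)
  expect_equal(sort(unique(pr$step)), 1:30)
  expect_equal(nrow(pr), 5 * 30)
})

test_that("stratified mean curves are exact convex summaries", {
  # hand toy: two records in one bucket
  pr <- structure(tibble::tibble(
    record_id = c(1L, 1L, 2L, 2L),
    step = c(1L, 2L, 1L, 2L),
    alpha = c(0.2, 0.8, 0.4, 0.6)), tx = 2L,
    class = c("attention_profiles", class(tibble::tibble())))
  rec <- tibble::tibble(record_id = 1:2, mg = c(1, 1), yield = c(40, 60))
  sm <- stratify_profiles(pr, rec, yield_breaks = c(0, 100),
                          mg_values = 1, min_n = 1)
  expect_equal(sm$mean_alpha, c(0.3, 0.7))
  expect_equal(sm$n, c(2, 2))
  # mean curve sums to 1 and lies within member min/max per step
  expect_equal(sum(sm$mean_alpha), 1)
  expect_true(all(sm$mean_alpha >= c(0.2, 0.6) - 1e-12))
  expect_true(all(sm$mean_alpha <= c(0.4, 0.8) + 1e-12))
})

test_that("a single all-encompassing stratum equals the global mean profile", {
  s <- attn_setup()
  rec <- s$pb$test$records
  sm <- stratify_profiles(s$pr, rec,
                          yield_breaks = range(rec$yield) + c(-1, 1),
                          mg_values = sort(unique(rec$mg))[1], min_n = 1)
  sub <- rec$record_id[rec$mg == sort(unique(rec$mg))[1]]
  glob <- s$pr[s$pr$record_id %in% sub, ]
  expect_equal(sm$mean_alpha,
               as.numeric(tapply(glob$alpha, glob$step, mean)))
  # every reported mean curve sums to 1
  expect_equal(sum(sm$mean_alpha), 1, tolerance = 1e-6)
})

test_that("stratification drops small buckets and rejects empty panels", {
  # 30 records in one MG: 25 low-yield, 5 high-yield; uniform profiles
  n <- 30
  pr <- structure(tibble::tibble(
    record_id = rep(seq_len(n), each = 2),
    step = rep(1:2, n),
    alpha = rep(0.5, 2 * n)), tx = 2L,
    class = c("attention_profiles", class(tibble::tibble())))
  rec <- tibble::tibble(record_id = seq_len(n), mg = 1,
                        yield = c(rep(40, 25), rep(80, 5)))
  # min_n = 10 keeps the 25-record bucket, drops the 5-record one
  expect_message(
    sm <- stratify_profiles(pr, rec, yield_breaks = c(0, 60, 100),
                            mg_values = 1, min_n = 10),
    "dropping")
  expect_equal(unique(sm$n), 25)
  expect_equal(nrow(sm), 2)  # one surviving bucket x two steps
  # min_n above every bucket size leaves nothing to report
  expect_error(
    suppressMessages(stratify_profiles(pr, rec,
                                       yield_breaks = c(0, 60, 100),
                                       mg_values = 1, min_n = 26)),
    "no stratum")
  expect_error(stratify_profiles(pr, rec, yield_breaks = c(3, 2)),
               "increasing")
})

test_that("localization scores are exact for uniform and one-hot profiles", {
  mk <- function(alpha_mat) {
    tx <- ncol(alpha_mat)
    structure(tibble::tibble(
      record_id = rep(seq_len(nrow(alpha_mat)), each = tx),
      step = rep(seq_len(tx), nrow(alpha_mat)),
      alpha = as.vector(t(alpha_mat))), tx = tx,
      class = c("attention_profiles", class(tibble::tibble())))
  }
  unif <- mk(matrix(1 / 10, 4, 10))
  ls <- localization_score(unif, c(1, 5))
  expect_equal(ls$mass_in, 0.5)
  expect_equal(ls$density_ratio, 1)
  onehot <- matrix(0, 3, 10); onehot[, 4] <- 1
  ls2 <- localization_score(mk(onehot), c(3, 5))
  expect_equal(ls2$mass_in, 1)
  expect_equal(ls2$density_out, 0)
  expect_error(localization_score(unif, c(0, 5)), "within")
  expect_error(localization_score(unif, c(7, 6)), "within")
})

test_that("interpretability plots build without error", {
  s <- attn_setup()
  rec <- s$pb$test$records
  sm <- suppressMessages(stratify_profiles(s$pr, rec,
                                           mg_values = unique(rec$mg),
                                           min_n = 1))
  p <- autoplot(sm)
  expect_s3_class(p, "ggplot")
  fit <- train_model(tiny_spec(), s$pb$train,
                     s$pb$val, train_config(epochs = 2, batch_size = 256,
                                            seed = 1))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_inertia(tibble::tibble(k = 1:3,
                                              inertia = c(3, 2, 1))),
                  "ggplot")
})
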