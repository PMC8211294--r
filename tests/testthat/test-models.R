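test_that("parameter counts reproduce the reference architectures", {
  expect_equal(count_params(model_spec("stacked", tx = 30, input_dim = 9)),
               202503)
  expect_equal(count_params(model_spec("attention", tx = 30, input_dim = 9)),
               202632)
  expect_equal(count_params(model_spec("stacked", tx = 30, input_dim = 7,
                                       include_mg_cluster = FALSE)),
               201477)
  # attention adds exactly the linear scorer: hidden + 1
  expect_equal(202632 - 202503, 128 + 1)
  # toy hand count: d=2, h=1, ctx=1, no side inputs, stacked
  expect_equal(count_params(model_spec("stacked", tx = 3, input_dim = 2,
                                       hidden = 1, context_dim = 1,
                                       include_mg_cluster = FALSE)),
               32)
})

test_that("parameter counts match the closed-form accounting oracle", {
  set.seed(17)
  for (i in 1:20) {
    d <- sample(c(1, 3, 7, 9), 1)
    h <- sample(c(2, 5, 16, 64), 1)
    ctx <- sample(1:4, 1)
    inc <- sample(c(TRUE, FALSE), 1)
    att <- sample(c(TRUE, FALSE), 1)
    spec <- model_spec(if (att) "attention" else "stacked",
                       tx = sample(c(7, 15, 30), 1), input_dim = d,
                       hidden = h, context_dim = ctx,
                       include_mg_cluster = inc)
    expect_equal(count_params(spec),
                 oracle_param_count(d, h, ctx, inc, att))
  }
  tab <- describe_params(model_spec("attention", tx = 30, input_dim = 9))
  expect_equal(sum(tab$parameters), 202632)
  expect_equal(unname(tab$parameters[tab$layer == "attention_scorer"]), 129)
})

test_that("attention weights are a stabilized softmax", {
  expect_equal(attention_weights(1), 1)
  expect_equal(attention_weights(c(0, log(3))), c(0.25, 0.75))
  # shift invariance
  e <- c(2, -1, 0.5, 3)
  expect_equal(attention_weights(e), attention_weights(e + 1000))
  # scorer form on annotations
  a <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  w <- attention_weights(a, scorer = list(w = c(0, log(3)), b = 2))
  expect_equal(w, c(0.25, 0.75))
  # extreme scores stay finite
  expect_equal(sum(attention_weights(c(1e4, 0, -1e4))), 1)
})

test_that("context vector is the exact weighted sum of annotations", {
  a <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(context_vector(a, c(0.25, 0.75)), c(0.25, 0.75))
  expect_equal(context_vector(a, c(1, 0)), a[1, ])
  a3 <- matrix(rnorm(12), 4)
  expect_equal(context_vector(a3, rep(0.25, 4)), colMeans(a3))
  expect_error(context_vector(a3, c(0.5, 0.5)), "lengths differ")
})

test_that("attention profiles normalize for random weights and inputs", {
  set.seed(5)
  spec <- model_spec("attention", tx = 6, input_dim = 4, hidden = 5,
                     context_dim = 2, include_mg_cluster = FALSE)
  for (i in 1:10) {
    m <- build_model(spec, seed = i)
    x <- array(rnorm(10 * 6 * 4, sd = 2), c(10, 6, 4))
    fwd <- gxeyield:::nn_forward(m$params, spec, x)
    expect_equal(rowSums(fwd$alpha), rep(1, 10), tolerance = 1e-6)
    expect_true(all(fwd$alpha >= 0))
    expect_true(all(is.finite(fwd$yhat)))
  }
})

test_that("a one-hot final-step attention profile reproduces the stacked model", {
  set.seed(6)
  spec_s <- model_spec("stacked", tx = 5, input_dim = 3, hidden = 4,
                       context_dim = 2, dropout = 0,
                       include_mg_cluster = FALSE)
  m <- build_model(spec_s, seed = 9)
  x <- array(rnorm(8 * 5 * 3), c(8, 5, 3))
  fwd_s <- gxeyield:::nn_forward(m$params, spec_s, x)
  # shared encoder + head, attention forced one-hot on the final step
  ann <- fwd_s$cache$a
  yhat_att <- vapply(1:8, function(r) {
    A <- do.call(rbind, lapply(ann, function(h) h[r, ]))
    ctx <- context_vector(A, c(0, 0, 0, 0, 1))
    drop(ctx %*% m$params$Wc) + m$params$bc
  }, numeric(2))
  ctx_att <- t(yhat_att)
  yhat <- drop(ctx_att %*% m$params$Wo) + m$params$bo
  expect_equal(yhat, fwd_s$yhat, tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  for (variant in c("stacked", "attention")) {
    spec <- model_spec(variant, tx = 4, input_dim = 3, hidden = 3,
                       context_dim = 2, dropout = 0,
                       include_mg_cluster = TRUE)
    m <- build_model(spec, seed = 2)
    set.seed(30)
    n <- 5
    x <- array(rnorm(n * 4 * 3), c(n, 4, 3))
    side <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    loss_fn <- function(params)
      gxeyield:::mse_loss(
        gxeyield:::nn_forward(params, spec, x, side)$yhat, y)
    fwd <- gxeyield:::nn_forward(m$params, spec, x, side)
    grads <- gxeyield:::nn_backward(m$params, spec, fwd$cache,
                                    2 * (fwd$yhat - y) / n)
    eps <- 1e-6
    for (nm in names(m$params)) {
      idx <- seq_len(min(length(m$params[[nm]]), 6))
      for (i in idx) {
        pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-5,
                     info = paste(variant, nm, i))
      }
    }
  }
})

test_that("inference is deterministic (dropout disabled)", {
  tb <- small_trial()
  wds <- downsample_weather(tb$weather, "monthly")
  sc <- fit_input_scaler(tb$records, wds)
  inp <- assemble_inputs(tb$records, wds, sc)
  m <- build_model(model_spec("attention", tx = 7, input_dim = 7,
                              hidden = 6, context_dim = 2,
                              include_mg_cluster = FALSE), seed = 1)
  p1 <- predict(m, inp)
  p2 <- predict(m, inp)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  # zero inputs give a finite scalar per record
  z <- inp
  z$x[] <- 0
  expect_true(all(is.finite(predict(m, z))))
})

test_that("model specification invariants are enforced", {
  expect_error(model_spec("stacked", hidden = 0), "positive")
  expect_error(model_spec("stacked", dropout = 1), "dropout")
  expect_error(model_spec("nonsense"), "arg")
  m <- build_model(model_spec("stacked", tx = 7, input_dim = 9,
                              include_mg_cluster = TRUE))
  tb <- small_trial()
  wds <- downsample_weather(tb$weather, "monthly")
  sc <- fit_input_scaler(tb$records, wds)
  inp <- assemble_inputs(tb$records, wds, sc)
  expect_error(predict(m, inp), "does not match")
})
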