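tiny_cfg <- function(kind = "lstm", blocks = 2, fc_layers = 2, hist = 12,
                     scenario = "carbs_pm_b") {
  model_config(kind, scenario, "inertial", state_size = 4, fc_width = 8,
               fc_layers = fc_layers, dropout = 0, blocks = blocks,
               history_steps = hist)
}

test_that("all-zero weights reduce the chain to its output bias", {
  cfg <- tiny_cfg()
  p <- zero_params(init_params(cfg, 1))
  p$out$b <- 0.37
  inp <- tiny_input(n = 4, hist_steps = 12)
  fw <- lstm_chain_forward(inp, p)
  expect_equal(fw$estimate, rep(0.37, 4))
})

test_that("inference is deterministic and sensitive to the horizon", {
  cfg <- tiny_cfg()
  p <- init_params(cfg, 2)
  inp <- tiny_input(n = 2, hist_steps = 12, win_steps = 8)
  expect_identical(lstm_chain_forward(inp, p)$estimate,
                   lstm_chain_forward(inp, p)$estimate)
  # an inertial example has all-zero window channels, yet the estimate moves
  # with tau through the unroll length and the tau feature
  inert <- tiny_input(n = 1, hist_steps = 12, win_steps = 8)
  inert$win[] <- 0
  longer <- inert
  longer$win <- array(0, c(1, 14, 3))
  longer$extras[1, 2] <- inert$extras[1, 2] + 0.4   # tau feature
  expect_false(isTRUE(all.equal(lstm_chain_forward(inert, p)$estimate,
                                lstm_chain_forward(longer, p)$estimate)))
})

test_that("a one-block stack equals the chain restricted to its forecast output", {
  cfg <- tiny_cfg("residual", blocks = 1)
  p <- init_params(cfg, 3)
  inp <- tiny_input(n = 3, hist_steps = 12)
  st <- residual_stack_forward(inp, p)
  ch <- lstm_chain_forward(inp, p[[1]])   # last output coordinate = forecast
  expect_equal(st$estimate, ch$estimate, tolerance = 1e-12)
  expect_equal(st$estimate, st$blocks[[1]]$forecast)
})

test_that("zeroed later blocks contribute only their forecast bias", {
  cfg <- tiny_cfg("residual", blocks = 3)
  p <- init_params(cfg, 4)
  for (b in 2:3) {
    p[[b]] <- zero_params(p[[b]])
    p[[b]]$out$b[13] <- 0.05   # forecast coordinate bias (12 backcast + 1)
  }
  inp <- tiny_input(n = 2, hist_steps = 12)
  st <- residual_stack_forward(inp, p)
  expect_equal(st$estimate, st$blocks[[1]]$forecast + 2 * 0.05, tolerance = 1e-12)
})

test_that("residual algebra: subtraction chain and telescoping identity", {
  cfg <- tiny_cfg("residual", blocks = 3)
  p <- init_params(cfg, 5)
  inp <- tiny_input(n = 3, hist_steps = 12)
  st <- residual_stack_forward(inp, p)
  for (b in 1:2)
    expect_equal(st$blocks[[b + 1]]$bg_input + st$blocks[[b]]$backcast,
                 st$blocks[[b]]$bg_input, tolerance = 1e-12)
  bsum <- Reduce(`+`, lapply(st$blocks, function(b) b$backcast))
  expect_equal(bsum + st$residual, matrix(inp$hist[, , 1], 3), tolerance = 1e-12)
})

test_that("training loss matches scalar arithmetic on a one-block case", {
  cfg <- tiny_cfg("residual", blocks = 1, hist = 2)
  fw <- list(estimate = 1.5,
             blocks = list(list(forecast = 1.5,
                                backcast = matrix(c(0.2, 0.4), 1),
                                bg_input = matrix(c(0.1, 0.1), 1))))
  y <- 1.0
  # MSE(1.5, 1) + 1/1 * MSE(1.5, 1) + 1/1 * mean((0.2-0.1)^2, (0.4-0.1)^2)
  expect_equal(training_loss(fw, y, cfg), 0.25 + 0.25 + mean(c(0.01, 0.09)))
  cfg0 <- cfg; cfg0$alpha <- 0; cfg0$beta <- 0
  expect_equal(training_loss(fw, y, cfg0), 0.25)
  # perfect fit gives zero loss
  fw2 <- list(estimate = y, blocks = list(list(forecast = y,
                                               backcast = matrix(0, 1, 2),
                                               bg_input = matrix(0, 1, 2))))
  expect_equal(training_loss(fw2, y, cfg), 0)
})

test_that("parameter counts match the enumeration over parameter arrays", {
  for (cfg in list(tiny_cfg(), tiny_cfg("residual", blocks = 3),
                   model_config("lstm", "bolus_p_c"),
                   model_config("residual", "bolus_pm_c"),
                   model_config("lstm", "carbs_m_b"))) {
    p <- init_params(cfg, 1)
    expect_equal(count_parameters(cfg), length(flatten_params(p)))
  }
  # a 64->64 ReLU layer alone holds 64*64 + 64 = 4160 parameters
  a <- model_config("lstm", "carbs_pm_b", fc_layers = 2)
  b <- model_config("lstm", "carbs_pm_b", fc_layers = 3)
  expect_equal(count_parameters(b) - count_parameters(a), 4160)
  # doubling the head width more than doubles the count of head parameters
  w1 <- model_config("lstm", "carbs_pm_b", fc_width = 32)
  w2 <- model_config("lstm", "carbs_pm_b", fc_width = 64)
  base <- count_parameters(model_config("lstm", "carbs_pm_b", fc_layers = 0,
                                        fc_width = 1))
  expect_gt(count_parameters(w2) - base, 2 * (count_parameters(w1) - base))
})

test_that("carbs-without-bolus configs use the halved widths", {
  cfg <- model_config("residual", "carbs_m_b")
  expect_equal(cfg$state_size, 16L)
  expect_equal(cfg$fc_width, 32L)
  expect_equal(model_config("lstm", "carbs_pm_b")$state_size, 32L)
})

test_that("analytic gradients match central differences on both architectures", {
  set.seed(9)
  for (cfg in list(tiny_cfg("lstm"), tiny_cfg("residual", blocks = 2))) {
    p <- init_params(cfg, 6)
    inp <- tiny_input(n = 3, hist_steps = 12, seed = 10)
    y <- rnorm(3)
    lg <- model_loss_grad(p, inp, y, cfg)
    flat <- flatten_params(p)
    g <- flatten_params(lg$grads)
    f <- function(v) {
      pp <- unflatten_params(v, p)
      fw <- if (cfg$kind == "lstm") lstm_chain_forward(inp, pp)
            else residual_stack_forward(inp, pp)
      training_loss(fw, y, cfg)
    }
    idx <- sample(length(flat), 40)
    num <- vapply(idx, function(i) {
      e <- 1e-5
      v1 <- flat; v1[i] <- v1[i] + e
      v2 <- flat; v2[i] <- v2[i] - e
      (f(v1) - f(v2)) / (2 * e)
    }, 0)
    rel <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("dropout masks perturb training forward passes but not inference", {
  cfg <- tiny_cfg()
  cfg$dropout <- 0.5
  p <- init_params(cfg, 7)
  inp <- tiny_input(n = 4, hist_steps = 12)
  set.seed(1); m1 <- make_dropout_masks(cfg, 4)
  set.seed(2); m2 <- make_dropout_masks(cfg, 4)
  est1 <- lstm_chain_forward(inp, p, m1)$estimate
  est2 <- lstm_chain_forward(inp, p, m2)$estimate
  expect_false(isTRUE(all.equal(est1, est2)))
  expect_identical(lstm_chain_forward(inp, p)$estimate,
                   lstm_chain_forward(inp, p)$estimate)
})

test_that("an identity label scaler makes scaled and physical estimates agree", {
  sc <- structure(list(min = c(bg = 40, carbs = 0, bolus = 0, basal = 0, label = 0),
                       max = c(bg = 400, carbs = 100, bolus = 10, basal = 1, label = 1)),
                  class = "rec_scaler")
  # label channel spans [0,1]: scale/unscale are the identity there
  x <- runif(10)
  expect_equal(scale_channel(x, sc, "label"), x)
  expect_equal(unscale_channel(x, sc, "label"), x)
})
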