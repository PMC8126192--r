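#' Model configuration for the LSTM chain and the residual stack
#'
#' The recommendation network chains two recurrent encoders: encoder 1 reads
#' the 72-step (6 h) history of glucose/carbs/bolus/basal up to the present
#' time `t`; its final state, passed through a linear projection, initialises
#' encoder 2, which reads the sparse event channels (carbs, bolus, basal - no
#' glucose, which is unobservable there) over the prediction window
#' `(t, t+10+tau]`. Both final states are concatenated with the extra features
#' (glucose target, horizon, time-of-day average, and - for bolus-given-carbs -
#' the planned carbs) and fed to a fully connected ReLU head with a linear
#' output.
#'
#' `kind = "lstm"` uses one such chain with a scalar output. `kind =
#' "residual"` stacks `blocks` chains: each block's head emits jointly a
#' 72-step glucose backcast and a scalar forecast; the backcast is subtracted
#' from the block's glucose input to form the next block's glucose channel,
#' and the forecasts of all blocks are summed into the final estimate.
#'
#' Defaults follow the tuned settings per scenario and example class: LSTM
#' models use 2-3 FC layers; residual models 3-5 blocks and 2-5 FC layers;
#' the carbs-without-bolus scenario halves the state and FC widths (16/32)
#' because of its much smaller example population.
#'
#' @param kind `"lstm"` or `"residual"`.
#' @param scenario one of [SCENARIOS].
#' @param example_class `"inertial"` or `"unrestricted"`.
#' @param state_size LSTM state width (default 32; 16 for carbs_m_b).
#' @param fc_layers,fc_width,dropout fully connected head shape and dropout
#'   rate (applied after each hidden layer during training only).
#' @param blocks number of residual blocks (residual kind only).
#' @param alpha,beta weights of the per-block forecast and backcast auxiliary
#'   losses (residual kind; default 1 each).
#' @param history_steps lookback length (default 72).
#' @return a `model_config` list.
#' @export
model_config <- function(kind = c("lstm", "residual"), scenario, example_class = "inertial",
                         state_size = NULL, fc_layers = NULL, fc_width = NULL,
                         dropout = NULL, blocks = NULL, alpha = 1, beta = 1,
                         history_steps = 72) {
  kind <- match.arg(kind)
  scenario <- match.arg(scenario, SCENARIOS)
  example_class <- match.arg(example_class, c("inertial", "unrestricted"))
  key <- if (scenario == "carbs_m_b") "carbs_pm_b" else scenario
  tuned_lstm <- list(  # fc_layers, dropout
    carbs_pm_b = list(inertial = c(3, 0.1), unrestricted = c(3, 0.1)),
    bolus_pm_c = list(inertial = c(3, 0.0), unrestricted = c(2, 0.3)),
    bolus_p_c = list(inertial = c(2, 0.2), unrestricted = c(2, 0.5)))
  tuned_res <- list(   # blocks, fc_layers, dropout
    carbs_pm_b = list(inertial = c(5, 2, 0.3), unrestricted = c(3, 3, 0.3)),
    bolus_pm_c = list(inertial = c(5, 4, 0.2), unrestricted = c(4, 4, 0.2)),
    bolus_p_c = list(inertial = c(5, 4, 0.5), unrestricted = c(3, 5, 0.2)))
  if (kind == "lstm") {
    tv <- tuned_lstm[[key]][[example_class]]
    if (is.null(fc_layers)) fc_layers <- tv[1]
    if (is.null(dropout)) dropout <- tv[2]
    if (is.null(blocks)) blocks <- 1L
  } else {
    tv <- tuned_res[[key]][[example_class]]
    if (is.null(blocks)) blocks <- tv[1]
    if (is.null(fc_layers)) fc_layers <- tv[2]
    if (is.null(dropout)) dropout <- tv[3]
  }
  half <- scenario == "carbs_m_b"
  if (is.null(state_size)) state_size <- if (half) 16L else 32L
  if (is.null(fc_width)) fc_width <- if (half) 32L else 64L
  stopifnot(state_size > 0, fc_width > 0, dropout >= 0, dropout < 1, blocks >= 1)
  structure(list(kind = kind, scenario = scenario, example_class = example_class,
                 state_size = as.integer(state_size), fc_layers = as.integer(fc_layers),
                 fc_width = as.integer(fc_width), dropout = dropout,
                 blocks = as.integer(blocks), alpha = alpha, beta = beta,
                 history_steps = as.integer(history_steps),
                 hist_channels = 4L, win_channels = 3L,
                 n_extra = if (scenario == "bolus_p_c") 4L else 3L),
            class = "model_config")
}

# output width of one chain: scalar for the plain model, joint
# [backcast, forecast] for a residual block
chain_out_width <- function(config) {
  if (config$kind == "lstm") 1L else config$history_steps + 1L
}

# parameters of one chain (encoder 1, projection, encoder 2, FC head)
init_chain_params <- function(config) {
  s <- config$state_size
  fc_in <- 2 * s + config$n_extra
  fc <- list()
  w <- fc_in
  for (l in seq_len(config$fc_layers)) {
    fc[[l]] <- init_linear(w, config$fc_width)
    w <- config$fc_width
  }
  list(lstm1 = init_lstm(config$hist_channels, s),
       proj = init_linear(s, s),
       lstm2 = init_lstm(config$win_channels, s),
       fc = fc,
       out = init_linear(w, chain_out_width(config)))
}

#' Initialise model parameters
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the random initialisation.
#' @return for `kind = "lstm"` a single chain parameter list; for
#'   `kind = "residual"` a list with one chain parameter set per block
#'   (no weight sharing).
#' @export
init_params <- function(config, seed = 1) {
  set.seed(seed)
  if (config$kind == "lstm") init_chain_params(config)
  else lapply(seq_len(config$blocks), function(b) init_chain_params(config))
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars for a configuration, from the layer
#' dimensions.
#'
#' @param config a [model_config()].
#' @return integer.
#' @export
count_parameters <- function(config) {
  s <- config$state_size
  lstm_n <- function(d) d * 4 * s + s * 4 * s + 4 * s
  fc_in <- 2 * s + config$n_extra
  n <- lstm_n(config$hist_channels) + (s * s + s) + lstm_n(config$win_channels)
  w <- fc_in
  for (l in seq_len(config$fc_layers)) {
    n <- n + w * config$fc_width + config$fc_width
    w <- config$fc_width
  }
  n <- n + w * chain_out_width(config) + chain_out_width(config)
  n_blocks <- if (config$kind == "lstm") 1L else config$blocks
  as.integer(n * n_blocks)
}

# ---- forward / backward of a single chain -----------------------------------

# input: list(hist = n x T x 4, win = n x W x 3, extras = n x n_extra)
chain_forward_full <- function(input, p, masks = NULL) {
  l1 <- lstm_forward(input$hist, p$lstm1)
  h20 <- l1$H %*% p$proj$W + matrix(p$proj$b, nrow(l1$H), ncol(p$proj$W), byrow = TRUE)
  l2 <- lstm_forward(input$win, p$lstm2, H0 = h20)
  feat <- cbind(l1$H, l2$H, input$extras)
  fco <- fc_forward(feat, p$fc, p$out, masks)
  list(y = fco$y, s1 = l1$H, s2 = l2$H,
       cache = list(l1 = l1$cache, l2 = l2$cache, fc = fco$cache, s1 = l1$H))
}

# dy: gradient at the chain output (n x out_width)
chain_backward_full <- function(dy, cache, p) {
  s <- ncol(cache$s1)
  fb <- fc_backward(dy, cache$fc, p$fc, p$out)
  ds1 <- fb$dfeat[, 1:s, drop = FALSE]
  ds2 <- fb$dfeat[, s + 1:s, drop = FALSE]
  l2b <- lstm_backward(ds2, cache$l2, p$lstm2)
  dproj <- list(W = crossprod(cache$s1, l2b$dH0), b = colSums(l2b$dH0))
  ds1 <- ds1 + l2b$dH0 %*% t(p$proj$W)
  l1b <- lstm_backward(ds1, cache$l1, p$lstm1)
  list(grads = list(lstm1 = list(Wx = l1b$Wx, Wh = l1b$Wh, b = l1b$b),
                    proj = dproj,
                    lstm2 = list(Wx = l2b$Wx, Wh = l2b$Wh, b = l2b$b),
                    fc = fb$fc, out = fb$out),
       dhist = l1b$dX)
}

# ---- public forward surfaces ------------------------------------------------

#' Forward pass of the two-LSTM-chain model
#'
#' Deterministic given parameters and input (dropout is off unless masks are
#' supplied by the training loop).
#'
#' @param input list with `hist` (n x history_steps x 4 array, scaled),
#'   `win` (n x W x 3 array over the prediction window, scaled) and `extras`
#'   (n x n_extra matrix: scaled glucose target, horizon mapped to `[0,1]`,
#'   time-of-day average, optionally planned carbs).
#' @param params chain parameters from [init_params()].
#' @param masks optional dropout masks (training only).
#' @return list with `estimate` (length-n vector, scaled label units) and the
#'   internal `cache` used by the backward pass.
#' @export
lstm_chain_forward <- function(input, params, masks = NULL) {
  cf <- chain_forward_full(input, params, masks)
  list(estimate = as.numeric(cf$y[, ncol(cf$y)]), cache = cf$cache, y = cf$y)
}

#' Forward pass of the deep residual stack
#'
#' Block 1 receives the scaled glucose history; each subsequent block receives
#' the previous block's glucose input minus its backcast; the sparse event
#' channels and extra features are passed unchanged to every block. The final
#' estimate is the sum of the per-block forecasts.
#'
#' @inheritParams lstm_chain_forward
#' @param params list of per-block chain parameters.
#' @param masks optional list of per-block dropout masks.
#' @return list with `estimate`, `blocks` (per block: `backcast`, `forecast`,
#'   `bg_input`), and `cache`.
#' @export
residual_stack_forward <- function(input, params, masks = NULL) {
  B <- length(params)
  if (B == 0) stop("residual stack needs at least one block")
  n <- dim(input$hist)[1]
  Tn <- dim(input$hist)[2]
  bg <- matrix(input$hist[, , 1], n)
  est <- rep(0, n)
  blocks <- vector("list", B)
  caches <- vector("list", B)
  hist_b <- input$hist
  for (b in seq_len(B)) {
    hist_b[, , 1] <- bg
    cf <- chain_forward_full(list(hist = hist_b, win = input$win, extras = input$extras),
                             params[[b]], if (is.null(masks)) NULL else masks[[b]])
    backcast <- cf$y[, 1:Tn, drop = FALSE]
    forecast <- as.numeric(cf$y[, Tn + 1])
    blocks[[b]] <- list(backcast = backcast, forecast = forecast, bg_input = bg,
                        s1 = cf$s1, s2 = cf$s2)
    caches[[b]] <- cf$cache
    est <- est + forecast
    bg <- bg - backcast
  }
  list(estimate = est, blocks = blocks, residual = bg, cache = caches)
}

#' Training loss
#'
#' Mean squared error between the estimate and the label, in scaled units.
#' For the residual stack, per-block auxiliary terms add supervision: the
#' cumulative forecast through each block is pulled toward the label (weight
#' `alpha/B`) and each block's backcast toward its own glucose input (weight
#' `beta/B`). With `alpha = beta = 0` the loss reduces to the plain MSE.
#'
#' @param forward output of [lstm_chain_forward()] or [residual_stack_forward()].
#' @param labels scaled label vector.
#' @param config the [model_config()].
#' @return scalar loss.
#' @export
training_loss <- function(forward, labels, config) {
  n <- length(labels)
  loss <- mean((forward$estimate - labels)^2)
  if (!is.null(forward$blocks) && config$kind == "residual") {
    B <- length(forward$blocks)
    cum <- rep(0, n)
    for (b in seq_len(B)) {
      blk <- forward$blocks[[b]]
      cum <- cum + blk$forecast
      loss <- loss + config$alpha / B * mean((cum - labels)^2)
      loss <- loss + config$beta / B * mean((blk$backcast - blk$bg_input)^2)
    }
  }
  loss
}

#' Training loss and analytic parameter gradients
#'
#' Computes [training_loss()] and its exact gradient with respect to every
#' trainable parameter by reverse-mode differentiation through the FC head,
#' both recurrent encoders, the state projection, and - for the residual
#' stack - the backcast subtraction chain (gradients flow into earlier blocks
#' both through their backcasts and through the auxiliary-loss targets).
#'
#' @param params model parameters.
#' @param input batched scaled input (see [lstm_chain_forward()]).
#' @param labels scaled labels.
#' @param config the [model_config()].
#' @param masks optional dropout masks.
#' @return list with `loss`, `grads` (same structure as `params`), `estimate`.
#' @export
model_loss_grad <- function(params, input, labels, config, masks = NULL) {
  n <- length(labels)
  if (config$kind == "lstm") {
    fw <- lstm_chain_forward(input, params, masks)
    loss <- mean((fw$estimate - labels)^2)
    dy <- matrix(2 * (fw$estimate - labels) / n, n, 1)
    bk <- chain_backward_full(dy, fw$cache, params)
    return(list(loss = loss, grads = bk$grads, estimate = fw$estimate))
  }
  fw <- residual_stack_forward(input, params, masks)
  B <- length(params)
  Tn <- config$history_steps
  loss <- training_loss(fw, labels, config)
  # suffix sums of cumulative-forecast gradients
  cum <- rep(0, n)
  dcum <- matrix(0, n, B)
  for (b in seq_len(B)) {
    cum <- cum + fw$blocks[[b]]$forecast
    dcum[, b] <- config$alpha / B * 2 * (cum - labels) / n
  }
  d_est <- 2 * (fw$estimate - labels) / n
  suffix <- matrix(0, n, B)   # suffix[, b] = sum_{j >= b} dcum[, j]
  acc <- rep(0, n)
  for (b in rev(seq_len(B))) {
    acc <- acc + dcum[, b]
    suffix[, b] <- acc
  }
  grads <- vector("list", B)
  Dnext <- matrix(0, n, Tn)   # dLoss / d bg_input_{b+1}
  for (b in rev(seq_len(B))) {
    blk <- fw$blocks[[b]]
    direct <- config$beta / B * 2 * (blk$backcast - blk$bg_input) / (n * Tn)
    d_backcast <- direct - Dnext
    d_forecast <- d_est + suffix[, b]
    dy <- cbind(d_backcast, matrix(d_forecast, n, 1))
    bk <- chain_backward_full(dy, fw$cache[[b]], params[[b]])
    grads[[b]] <- bk$grads
    Dnext <- Dnext - direct + matrix(bk$dhist[, , 1], n)
  }
  list(loss = loss, grads = grads, estimate = fw$estimate)
}

# dropout masks for one batch (inverted dropout); NULL when rate is 0
make_dropout_masks <- function(config, n) {
  if (config$dropout <= 0) return(NULL)
  keep <- 1 - config$dropout
  one_chain <- function() lapply(seq_len(config$fc_layers), function(l)
    matrix(stats::rbinom(n * config$fc_width, 1, keep) / keep, n, config$fc_width))
  if (config$kind == "lstm") one_chain()
  else lapply(seq_len(config$blocks), function(b) one_chain())
}

#' Predict scaled estimates for a prepared dataset
#'
#' Handles mixed prediction-window lengths by evaluating one horizon group at
#' a time. Dropout is off: inference is deterministic given parameters.
#'
#' @param params model parameters.
#' @param config the [model_config()].
#' @param data a prepared model dataset from [prepare_model_data()].
#' @return numeric vector of scaled estimates, in `data` row order.
#' @export
model_predict <- function(params, config, data) {
  out <- numeric(length(data$labels))
  for (grp in split(seq_along(data$labels), data$tau)) {
    input <- gather_input(data, grp)
    fw <- if (config$kind == "lstm") lstm_chain_forward(input, params)
          else residual_stack_forward(input, params)
    out[grp] <- fw$estimate
  }
  out
}

# assemble the batched arrays for a set of example indices (equal tau)
gather_input <- function(data, idx) {
  n <- length(idx)
  Tn <- dim(data$hist)[2]
  hist <- data$hist[idx, , , drop = FALSE]
  W <- nrow(data$win[[idx[1]]])
  win <- array(0, c(n, W, 3))
  for (j in seq_len(n)) win[j, , ] <- data$win[[idx[j]]]
  list(hist = hist, win = win, extras = data$extras[idx, , drop = FALSE])
}

#' Scale examples into model-ready arrays
#'
#' Applies the training-range min-max scaler channel-wise: glucose history and
#' target with the `bg` channel, event channels with `carbs`/`bolus`/`basal`,
#' labels and the time-of-day average with the `label` channel, planned carbs
#' with the `carbs` channel, and the horizon mapped linearly from
#' `[30, 90]` min to `[0, 1]`.
#'
#' @param examples a `rec_examples` object (physical units).
#' @param scaler a `rec_scaler` fitted on the subject's training split.
#' @return a list: `hist` (n x steps x 4 array), `win` (list of W x 3
#'   matrices), `extras`, `labels`, `tau`, `meta`, `scaler`.
#' @export
prepare_model_data <- function(examples, scaler) {
  n <- nrow(examples$meta)
  Tn <- examples$history_steps
  hist <- array(0, c(n, Tn, 4))
  win <- vector("list", n)
  for (j in seq_len(n)) {
    H <- examples$history[[j]]
    hist[j, , 1] <- scale_channel(H[, "bg"], scaler, "bg")
    hist[j, , 2] <- scale_channel(H[, "carbs"], scaler, "carbs")
    hist[j, , 3] <- scale_channel(H[, "bolus"], scaler, "bolus")
    hist[j, , 4] <- scale_channel(H[, "basal"], scaler, "basal")
    Wm <- examples$window[[j]]
    win[[j]] <- cbind(scale_channel(Wm[, "carbs"], scaler, "carbs"),
                      scale_channel(Wm[, "bolus"], scaler, "bolus"),
                      scale_channel(Wm[, "basal"], scaler, "basal"))
  }
  m <- examples$meta
  extras <- cbind(target_bg = scale_channel(m$target_bg, scaler, "bg"),
                  tau = (m$tau - 30) / 60,
                  tod_avg = scale_channel(m$tod_avg, scaler, "label"))
  if (examples$scenario == "bolus_p_c")
    extras <- cbind(extras, planned_carbs = scale_channel(m$planned_carbs, scaler, "carbs"))
  list(hist = hist, win = win, extras = extras,
       labels = scale_channel(m$label, scaler, "label"),
       tau = m$tau, meta = m, scaler = scaler)
}

# subset of a prepared dataset
data_subset <- function(data, idx) {
  if (is.logical(idx)) idx <- which(idx)
  list(hist = data$hist[idx, , , drop = FALSE], win = data$win[idx],
       extras = data$extras[idx, , drop = FALSE], labels = data$labels[idx],
       tau = data$tau[idx], meta = data$meta[idx, , drop = FALSE],
       scaler = data$scaler)
}

# pool prepared datasets (e.g. across subjects); scalers stay per-subject,
# values are already in scaled units so pooling is safe
data_pool <- function(datasets) {
  list(hist = do.call(abind1, lapply(datasets, `[[`, "hist")),
       win = do.call(c, lapply(datasets, `[[`, "win")),
       extras = do.call(rbind, lapply(datasets, `[[`, "extras")),
       labels = do.call(c, lapply(datasets, `[[`, "labels")),
       tau = do.call(c, lapply(datasets, `[[`, "tau")),
       meta = do.call(rbind, lapply(datasets, `[[`, "meta")),
       scaler = NULL)
}

# bind 3D arrays along the first dimension
abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], 0))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0
  for (x in xs) {
    k <- dim(x)[1]
    if (k) out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}
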