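#' Training protocol settings
#'
#' Adam with a fixed learning rate, mini-batches grouped by horizon (examples
#' in one batch share the prediction-window length), dropout during training,
#' and early stopping with an inertia of `patience` epochs on the validation
#' loss. The paper-style protocol trains 10 models per subject under different
#' seeds and reports mean and best-by-validation-MAE aggregates.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size mini-batch size (default 64; tunable per subject).
#' @param patience early-stopping inertia in epochs (default 10).
#' @param max_epochs hard cap on epochs (default 500).
#' @param seeds integer seeds for the ensemble (default `1:10`).
#' @return a `train_protocol` list.
#' @export
train_protocol <- function(learning_rate = 0.001, batch_size = 64, patience = 10,
                           max_epochs = 500, seeds = 1:10) {
  stopifnot(patience >= 1, max_epochs >= 1, learning_rate >= 0)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 patience = patience, max_epochs = max_epochs, seeds = seeds),
            class = "train_protocol")
}

#' Early-stopping rule
#'
#' Given a sequence of per-epoch validation losses, returns the epoch training
#' halts at: exactly `patience` epochs after the last strict improvement of
#' the running best (or the last epoch if the patience budget is never
#' exhausted), together with the best epoch itself.
#'
#' @param val_losses numeric vector of validation losses by epoch.
#' @param patience inertia in epochs.
#' @return list with `best_epoch` and `stop_epoch`.
#' @export
early_stop_epoch <- function(val_losses, patience = 10) {
  best <- Inf; best_epoch <- 0
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
    } else if (e - best_epoch >= patience) {
      return(list(best_epoch = best_epoch, stop_epoch = e))
    }
  }
  list(best_epoch = best_epoch, stop_epoch = length(val_losses))
}

# shuffled mini-batches; examples are grouped by horizon so a batch's
# prediction windows have equal length
make_batches <- function(tau, batch_size) {
  idx <- sample(seq_along(tau))
  groups <- split(idx, tau[idx])
  batches <- list()
  for (g in groups) {
    k <- ceiling(length(g) / batch_size)
    batches <- c(batches, split(g, rep(seq_len(k), each = batch_size)[seq_along(g)]))
  }
  batches[sample(length(batches))]
}

#' Fit a recommendation model with Adam and early stopping
#'
#' Optimises [training_loss()] on the training examples, monitoring plain MSE
#' on the validation examples after each epoch; training halts `patience`
#' epochs after the last validation improvement and the best-validation-epoch
#' weights are returned.
#'
#' @param params initial parameters ([init_params()] or a pretrained set).
#' @param config a [model_config()].
#' @param train_data,val_data prepared datasets ([prepare_model_data()]).
#' @param protocol a [train_protocol()].
#' @param seed RNG seed for shuffling and dropout.
#' @return list: `params` (best epoch), `history` (per-epoch train/val loss),
#'   `best_epoch`, `epochs_run`.
#' @export
fit_recommender <- function(params, config, train_data, val_data, protocol, seed = 1) {
  if (!length(train_data$labels)) stop("empty training split")
  if (!length(val_data$labels)) stop("empty validation split")
  set.seed(seed)
  flat <- flatten_params(params)
  m <- v <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  best <- Inf; best_epoch <- 0; best_flat <- flat
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  for (epoch in seq_len(protocol$max_epochs)) {
    batches <- make_batches(train_data$tau, protocol$batch_size)
    ep_loss <- 0
    for (idx in batches) {
      input <- gather_input(train_data, idx)
      masks <- make_dropout_masks(config, length(idx))
      p_now <- unflatten_params(flat, params)
      lg <- model_loss_grad(p_now, input, train_data$labels[idx], config, masks)
      g <- flatten_params(lg$grads)
      step <- step + 1
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^step)
      vh <- v / (1 - b2^step)
      flat <- flat - protocol$learning_rate * mh / (sqrt(vh) + eps)
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    p_now <- unflatten_params(flat, params)
    val_pred <- model_predict(p_now, config, val_data)
    val_loss <- mean((val_pred - val_data$labels)^2)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / length(train_data$labels),
                                   val_loss = val_loss))
    if (val_loss < best) {
      best <- val_loss; best_epoch <- epoch; best_flat <- flat
    } else if (epoch - best_epoch >= protocol$patience) break
  }
  list(params = unflatten_params(best_flat, params), history = hist,
       best_epoch = best_epoch, epochs_run = nrow(hist))
}

#' Pre-train a generic model on pooled subjects
#'
#' Trains one parameter set from scratch on the union of all subjects'
#' training examples (each subject scaled with its own training-range scaler),
#' early-stopping on the pooled validation examples. Deterministic for a
#' given seed.
#'
#' @param subjects list of prepared subject pipelines ([prepare_subject()]).
#' @param config a [model_config()].
#' @param protocol a [train_protocol()].
#' @param seed RNG seed (initialisation, shuffling, dropout).
#' @return as [fit_recommender()].
#' @export
pretrain_global <- function(subjects, config, protocol, seed = 1) {
  train <- data_pool(lapply(subjects, function(s) s$data$train))
  val <- data_pool(lapply(subjects, function(s) s$data$validation))
  if (!length(train$labels)) stop("no pooled training examples")
  params <- init_params(config, seed)
  fit_recommender(params, config, train, val, protocol, seed = seed)
}

#' Personalise a pretrained model for one subject
#'
#' Continues optimisation from the given parameters on the subject's training
#' examples only, early-stopping on the subject's validation examples.
#'
#' @param params pretrained parameters.
#' @param subject one prepared subject ([prepare_subject()]).
#' @inheritParams pretrain_global
#' @return as [fit_recommender()].
#' @export
finetune_subject <- function(params, subject, config, protocol, seed = 1) {
  fit_recommender(params, config, subject$data$train, subject$data$validation,
                  protocol, seed = seed)
}

#' RMSE and MAE in physical units
#' @param pred,obs numeric vectors (g or u).
#' @return named vector `c(rmse, mae)`.
#' @export
score_predictions <- function(pred, obs) {
  c(rmse = sqrt(mean((pred - obs)^2)), mae = mean(abs(pred - obs)))
}

#' Pick the ensemble member by validation MAE
#'
#' Selection deliberately sees validation metrics only - test scores are not
#' an argument - so the reported best score can never be test-selected.
#'
#' @param val_mae numeric vector of per-seed validation MAE.
#' @return index of the selected seed.
#' @export
select_best_seed <- function(val_mae) which.min(val_mae)

#' Aggregate per-subject, per-seed scores into mean and best scores
#'
#' The mean score averages test RMSE/MAE over seeds within a subject, then
#' over subjects. The best score picks, per subject, the seed with the lowest
#' validation MAE ([select_best_seed()]) and averages that seed's test scores
#' over subjects.
#'
#' @param cells data.frame with columns `subject_id, seed, val_mae, rmse, mae`
#'   (test scores in physical units); empty test cells are dropped from
#'   aggregation.
#' @return an `eval_report`: `cells`, `mean_score`, `best_score`.
#' @export
evaluate_report <- function(cells) {
  cells <- cells[!is.na(cells$mae), , drop = FALSE]
  if (!nrow(cells)) stop("no scored cells")
  per_subj <- lapply(split(cells, cells$subject_id), function(d) {
    best <- select_best_seed(d$val_mae)
    data.frame(subject_id = d$subject_id[1],
               mean_rmse = mean(d$rmse), mean_mae = mean(d$mae),
               best_rmse = d$rmse[best], best_mae = d$mae[best],
               best_seed = d$seed[best])
  })
  ps <- do.call(rbind, per_subj)
  structure(list(cells = cells, per_subject = ps,
                 mean_score = c(rmse = mean(ps$mean_rmse), mae = mean(ps$mean_mae)),
                 best_score = c(rmse = mean(ps$best_rmse), mae = mean(ps$best_mae))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report over", nrow(x$per_subject), "subjects,",
      length(unique(x$cells$seed)), "seeds\n")
  cat(sprintf("  mean score: RMSE %.3f  MAE %.3f\n", x$mean_score["rmse"], x$mean_score["mae"]))
  cat(sprintf("  best score: RMSE %.3f  MAE %.3f\n", x$best_score["rmse"], x$best_score["mae"]))
  invisible(x)
}

#' Full pretrain-then-personalize protocol on prepared subjects
#'
#' For each seed: pretrain a generic model on all subjects' pooled training
#' examples, fine-tune it per subject, and score the personalised model on
#' the subject's test examples in physical units. Aggregates with
#' [evaluate_report()]. Subjects with empty test or validation splits are
#' excluded from aggregation.
#'
#' @param subjects list of prepared subjects ([prepare_subject()]).
#' @param config a [model_config()].
#' @param protocol a [train_protocol()]; its `seeds` drive the ensemble.
#' @param finetune fine-tune per subject (default TRUE; FALSE scores the
#'   generic model directly).
#' @return an `eval_report` with an extra `pretrained` field (per-seed
#'   pretraining fits).
#' @export
run_protocol <- function(subjects, config, protocol, finetune = TRUE) {
  cells <- list(); pres <- list()
  for (seed in protocol$seeds) {
    pre <- pretrain_global(subjects, config, protocol, seed = seed)
    pres[[as.character(seed)]] <- pre
    for (s in subjects) {
      if (!length(s$data$test$labels) || !length(s$data$validation$labels)) {
        cells[[length(cells) + 1]] <- data.frame(
          subject_id = s$subject_id, seed = seed, val_mae = NA, rmse = NA, mae = NA)
        next
      }
      fit <- if (finetune) finetune_subject(pre$params, s, config, protocol, seed = seed)
             else pre
      val_pred <- unscale_channel(model_predict(fit$params, config, s$data$validation),
                                  s$scaler, "label")
      val_obs <- unscale_channel(s$data$validation$labels, s$scaler, "label")
      test_pred <- unscale_channel(model_predict(fit$params, config, s$data$test),
                                   s$scaler, "label")
      test_obs <- unscale_channel(s$data$test$labels, s$scaler, "label")
      sc <- score_predictions(test_pred, test_obs)
      cells[[length(cells) + 1]] <- data.frame(
        subject_id = s$subject_id, seed = seed,
        val_mae = mean(abs(val_pred - val_obs)),
        rmse = sc["rmse"], mae = sc["mae"])
    }
  }
  rep <- evaluate_report(do.call(rbind, cells))
  rep$pretrained <- pres
  rep
}

#' Baseline scores under the same evaluation protocol
#'
#' Fits the global-average and time-of-day-average baselines on each subject's
#' training events and scores them on the test examples, averaging over
#' subjects.
#'
#' @param subjects list of prepared subjects.
#' @return data.frame with one row per baseline: mean RMSE and MAE.
#' @export
baseline_scores <- function(subjects) {
  rows <- lapply(c("global", "tod"), function(kind) {
    sc <- vapply(subjects, function(s) {
      if (!length(s$data$test$labels)) return(c(NA, NA))
      tr <- s$examples$train$meta
      ev <- tr[!duplicated(tr$event_time), ]
      te <- s$examples$test
      pred <- if (kind == "global") predict(fit_global(ev$label), te)
              else predict(fit_tod(ev$label, ev$wall_min), te)
      score_predictions(pred, te$meta$label)
    }, c(rmse = 0, mae = 0))
    data.frame(model = paste0(kind, "_average"),
               rmse = mean(sc[1, ], na.rm = TRUE), mae = mean(sc[2, ], na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' One-tailed two-sample t-test for model comparison
#'
#' Tests whether `mean(a) < mean(b)` (e.g. a model's per-subject errors
#' against a baseline's). Welch's unequal-variance variant by default.
#'
#' @param a,b numeric score vectors (length >= 2).
#' @param welch use the Welch variant (default TRUE).
#' @return the one-tailed p-value.
#' @export
compare_models <- function(a, b, welch = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("need at least two scores per model")
  stats::t.test(a, b, alternative = "less", var.equal = !welch)$p.value
}

#' Per-horizon transfer experiment
#'
#' For each horizon in `tau_list`, trains a model only on that horizon's
#' examples and compares it, on that horizon's test examples, with a model
#' trained on all horizons - quantifying transfer learning across horizons.
#' Both models are trained on the pooled subjects (pretraining stage only) for
#' each seed, and scored in physical units per subject and averaged.
#'
#' @param subjects list of prepared subjects (inertial examples, typically).
#' @param config a [model_config()] (residual kind, typically).
#' @param protocol a [train_protocol()].
#' @param tau_list horizons to probe (default `c(30, 45, 60, 75, 90)`).
#' @return data.frame with rows (trained_on = one_tau / all_tau) x tau and an
#'   `average` row per metric; horizons with no test examples are NA.
#' @export
horizon_transfer_experiment <- function(subjects, config, protocol,
                                        tau_list = c(30, 45, 60, 75, 90)) {
  score_on <- function(params, tau) {
    sc <- vapply(subjects, function(s) {
      keep <- s$data$test$tau == tau
      if (!sum(keep)) return(c(NA_real_, NA_real_))
      d <- data_subset(s$data$test, keep)
      pred <- unscale_channel(model_predict(params, config, d), s$scaler, "label")
      obs <- unscale_channel(d$labels, s$scaler, "label")
      score_predictions(pred, obs)
    }, c(rmse = 0, mae = 0))
    c(rmse = mean(sc[1, ], na.rm = TRUE), mae = mean(sc[2, ], na.rm = TRUE))
  }
  subset_subjects <- function(tau) lapply(subjects, function(s) {
    s$data$train <- data_subset(s$data$train, s$data$train$tau == tau)
    s$data$validation <- data_subset(s$data$validation, s$data$validation$tau == tau)
    s
  })
  rows <- list()
  for (seed in protocol$seeds) {
    all_fit <- pretrain_global(subjects, config, protocol, seed = seed)
    for (tau in tau_list) {
      subs <- subset_subjects(tau)
      n_tr <- sum(vapply(subs, function(s) length(s$data$train$labels), 0))
      n_va <- sum(vapply(subs, function(s) length(s$data$validation$labels), 0))
      one <- if (n_tr && n_va) {
        fit <- pretrain_global(subs, config, protocol, seed = seed)
        score_on(fit$params, tau)
      } else c(rmse = NA_real_, mae = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(seed = seed, tau = tau,
                                             trained_on = "one_tau",
                                             rmse = one["rmse"], mae = one["mae"])
      allsc <- score_on(all_fit$params, tau)
      rows[[length(rows) + 1]] <- data.frame(seed = seed, tau = tau,
                                             trained_on = "all_tau",
                                             rmse = allsc["rmse"], mae = allsc["mae"])
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  agg <- stats::aggregate(cbind(rmse, mae) ~ tau + trained_on, tab, mean)
  avg <- stats::aggregate(cbind(rmse, mae) ~ trained_on, agg, mean)
  avg$tau <- NA
  out <- rbind(agg, avg[, c("tau", "trained_on", "rmse", "mae")])
  attr(out, "by_seed") <- tab
  out
}

#' End-to-end per-subject example pipeline
#'
#' Runs the pre-processing and example-construction pipeline for one raw
#' record: meal anchoring (optional, for the raw-data ablation), glucose gap
#' interpolation, chronological splitting, example construction on the full
#' record, partition of examples by event time into train/validation/test,
#' scaler fitting on the training split, and scaling into model-ready arrays.
#'
#' @param record a raw `subject_record`.
#' @param scenario one of [SCENARIOS].
#' @param example_class `"inertial"` or `"unrestricted"`.
#' @param anchor apply [anchor_meals()] (FALSE reproduces the raw-meal
#'   ablation).
#' @param match_window meal--bolus matching window, minutes.
#' @param taus horizon grid.
#' @param history_steps lookback length.
#' @return a prepared subject: `subject_id`, `record`, `scaler`, `examples`
#'   (train/validation/test `rec_examples`), `data` (prepared arrays).
#' @export
prepare_subject <- function(record, scenario, example_class = "inertial",
                            anchor = TRUE, match_window = 60,
                            taus = seq(30, 90, 5), history_steps = 72) {
  rec <- if (anchor) anchor_meals(record, match_window) else record
  rec <- interpolate_glucose(rec)
  sp <- split_record(rec)
  rec$split <- unname(sp$boundaries)
  ex <- build_examples(rec, scenario, example_class, taus = taus,
                       history_steps = history_steps, allow_raw = !anchor)
  b <- rec$split
  part <- function(keep) examples_subset(ex, keep)
  exs <- list(train = part(ex$meta$event_time < b[1]),
              validation = part(ex$meta$event_time >= b[1] & ex$meta$event_time < b[2]),
              test = part(ex$meta$event_time >= b[2]))
  if (!nrow(exs$train$meta)) stop("no training examples for subject ", rec$subject_id)
  train_grid <- to_grid(subset_record(rec, 0, b[1]))
  scaler <- fit_scaler(train_grid, exs$train$meta$label)
  list(subject_id = rec$subject_id, record = rec, scaler = scaler, examples = exs,
       data = lapply(exs, prepare_model_data, scaler = scaler))
}
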