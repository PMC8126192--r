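#' Global-average baseline
#'
#' Predicts the same value - the arithmetic mean of the training labels (carb
#' grams or bolus units) - for every test example of a subject, irrespective
#' of context.
#'
#' @param labels numeric vector of training event magnitudes.
#' @return object of class `global_avg_model` with field `mu`.
#' @export
fit_global <- function(labels) {
  if (!length(labels)) stop("no training events")
  structure(list(mu = mean(labels)), class = "global_avg_model")
}

#' Time-of-day-average baseline
#'
#' Computes one mean label per time-of-day window (see [tod_interval()]); at
#' prediction time the window overlapping the event time `t+10` selects the
#' average. Windows without training events fall back to the global mean.
#'
#' @param labels numeric vector of training event magnitudes.
#' @param wall_min minute-of-day of each training event (`t+10`).
#' @return object of class `tod_avg_model` with fields `mu_k` (length 5),
#'   `n_k` (counts) and `mu` (global fallback).
#' @export
fit_tod <- function(labels, wall_min) {
  if (!length(labels)) stop("no training events")
  stopifnot(length(labels) == length(wall_min))
  k <- tod_interval(wall_min)
  mu <- mean(labels)
  n_k <- vapply(1:5, function(j) sum(k == j), 0L)
  mu_k <- vapply(1:5, function(j) if (n_k[j]) mean(labels[k == j]) else mu, 0)
  structure(list(mu_k = mu_k, n_k = n_k, mu = mu), class = "tod_avg_model")
}

#' @export
predict.global_avg_model <- function(object, newdata = NULL, ...) {
  n <- if (is.null(newdata)) 1L else if (inherits(newdata, "rec_examples")) nrow(newdata$meta) else length(newdata)
  rep(object$mu, n)
}

#' Predict from a time-of-day baseline
#'
#' @param object a `tod_avg_model`.
#' @param newdata a `rec_examples` object, or a numeric vector of
#'   minute-of-day values for the event times.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.tod_avg_model <- function(object, newdata, ...) {
  wall <- if (inherits(newdata, "rec_examples")) newdata$meta$wall_min else newdata
  object$mu_k[tod_interval(wall)]
}
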