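# Fixture builders used across the suite. All fixtures are constructed in
# code; nothing is read from disk.

# A flat record: constant glucose on the 5-min grid, one basal rate, no events
# unless supplied. `minutes` is the time of the last glucose sample.
flat_record <- function(minutes = 2875, bg = 120, boluses = NULL, meals = NULL,
                        basal_rate = 1.0, split = NULL) {
  times <- seq(0, minutes, by = 5)
  rec <- subject_record(
    "fix1",
    glucose = data.frame(time = times, value = rep(bg, length(times)),
                         interpolated = FALSE),
    boluses = boluses, meals = meals,
    basal = data.frame(start = 0, end = minutes + 5, rate = basal_rate),
    split = split)
  rec$anchored <- TRUE
  rec$interpolated <- TRUE
  rec
}

# small noisy simulated subject for property tests
sim_fixture <- function(seed = 11, days = 25, ...) {
  simulate_subject(sim_config(seed = seed, days = days, ...))
}

# tiny model input batch with given shapes
tiny_input <- function(n = 3, hist_steps = 12, win_steps = 8, n_extra = 3, seed = 1) {
  set.seed(seed)
  list(hist = array(stats::rnorm(n * hist_steps * 4), c(n, hist_steps, 4)),
       win = array(stats::rnorm(n * win_steps * 3), c(n, win_steps, 3)),
       extras = matrix(stats::rnorm(n * n_extra), n, n_extra))
}

# set every parameter in a nested list to a constant
zero_params <- function(p, value = 0) {
  if (is.list(p)) return(lapply(p, zero_params, value = value))
  p[] <- value
  p
}
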