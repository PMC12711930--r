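# shared fixtures: small layouts/trial tables built in code

balanced_layout <- function(grid = c(15, 15), seed = 7, ...) {
  quadrat_layout(grid_shape = grid,
                 base_props = c("pause" = 0.25, "burst-pause" = 0.25,
                                "pause-burst" = 0.25, "increase" = 0.25),
                 seed = seed, ...)
}

compact_trials <- function(n = 6, outcome = "R", spacing_s = 4,
                           first_s = 4) {
  data.frame(outcome = rep(outcome, length.out = n),
             outcome_time_s = first_s + spacing_s * (seq_len(n) - 1))
}

# times grid fine enough to hit template extrema exactly
fine_times <- function(step = 0.01, window = c(-1, 1)) {
  seq(window[1], window[2] - step, by = step)
}
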