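# Fixture builders used across the test files; everything is generated in
# code under fixed seeds.

# small random progressive six-state dataset from the frailty simulator
random_prog6 <- function(n, seed, cens_rate = 0.00095, censoring = TRUE) {
  simulate_prog6(sim_config(n = n, cens_rate = cens_rate,
                            censoring = censoring), seed = seed)
}

# pure-survival reduction: only 0 -> 5 transitions, exponential censoring
pure_survival_dataset <- function(n, seed, rate = 0.01, cens_rate = 0.008) {
  set.seed(seed)
  tt <- rexp(n, rate)
  cc <- rexp(n, cens_rate)
  obs <- pmin(tt, cc)
  d <- tt <= cc
  msm_dataset(data.frame(id = seq_len(n), from = 0L,
                         to = ifelse(d, 5L, NA_integer_), time = obs),
              model_prog6())
}

# empirical proportion of individuals occupying `states` at time t, read
# directly off the observed paths (only meaningful for uncensored data)
occupancy_proportion <- function(dataset, states, t) {
  ev <- dataset$events
  ids <- unique(ev$id)
  inset <- vapply(ids, function(i) {
    e <- ev[ev$id == i, , drop = FALSE]
    past <- e[e$time <= t, , drop = FALSE]
    st <- if (nrow(past) == 0L) 0L else past$to[nrow(past)]
    st %in% states
  }, logical(1))
  mean(inset)
}

# off-diagonal cumulative entry A_gh(t) of an msm_cumhaz
cumhaz_entry <- function(ch, g, h, t) {
  k <- findInterval(t, ch$times)
  if (k == 0L) 0 else ch$A[g + 1L, h + 1L, k]
}
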