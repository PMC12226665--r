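# Independent brute-force recount of every session readout, written as plain
# per-trial loops with no code shared with the package internals. Takes only
# the raw observable sequences (action, rewarded, latency) and re-derives the
# lever roles from scratch.

oracle_summary <- function(log, censoring = "strict") {
  tr <- log$trials
  n <- nrow(tr)
  criterion <- log$config$reversal_criterion

  # re-derive the correct lever trajectory from the actions alone
  correct <- NA_character_
  streak <- 0L
  n_rev <- 0L
  role <- rep(NA_character_, n)  # lever role of each press at press time
  for (t in seq_len(n)) {
    a <- tr$action[t]
    if (a == "omission") next
    if (is.na(correct)) correct <- a
    if (a == correct) {
      role[t] <- "correct"
      streak <- streak + 1L
      if (streak == criterion) {
        n_rev <- n_rev + 1L
        correct <- if (correct == "left") "right" else "left"
        streak <- 0L
      }
    } else {
      role[t] <- "incorrect"
      streak <- 0L
    }
  }

  press_t <- which(tr$action != "omission")
  # stay/shift against the next press under the requested censoring rule
  relation <- function(t) {
    if (censoring == "strict") {
      if (t == n || tr$action[t + 1] == "omission") return(NA_character_)
      if (tr$action[t + 1] == tr$action[t]) "stay" else "shift"
    } else {
      later <- press_t[press_t > t]
      if (!length(later)) return(NA_character_)
      if (tr$action[later[1]] == tr$action[t]) "stay" else "shift"
    }
  }

  mis_nf_den <- 0L; mis_nf_shift <- 0L
  act_nf_den <- 0L; act_nf_shift <- 0L
  win_den <- 0L; win_stay <- 0L
  for (t in press_t) {
    rel <- relation(t)
    if (is.na(rel)) next
    if (tr$rewarded[t]) {
      win_den <- win_den + 1L
      if (rel == "stay") win_stay <- win_stay + 1L
    } else if (role[t] == "correct") {
      mis_nf_den <- mis_nf_den + 1L
      if (rel == "shift") mis_nf_shift <- mis_nf_shift + 1L
    } else {
      act_nf_den <- act_nf_den + 1L
      if (rel == "shift") act_nf_shift <- act_nf_shift + 1L
    }
  }

  lat <- tr$latency[press_t]
  list(
    prob_ls_ratio = if (mis_nf_den) mis_nf_shift / mis_nf_den else NA_real_,
    actual_ls_ratio = if (act_nf_den) act_nf_shift / act_nf_den else NA_real_,
    ws_ratio = if (win_den) win_stay / win_den else NA_real_,
    n_reversals = n_rev,
    median_latency = if (length(lat)) median(lat) else NA_real_,
    n_omissions = sum(tr$action == "omission")
  )
}

# a random session from a randomly drawn agent, for property-style tests
random_session <- function(seed) {
  set.seed(seed)
  p <- agent_params(
    p_stay_after_win = runif(1),
    p_shift_after_loss = runif(1),
    p_omit = runif(1, 0, 0.5),
    p_persev = runif(1, 0, 0.7),
    latency_location = runif(1, 0.5, 6),
    latency_scale = runif(1, 0.1, 0.9),
    side_bias = runif(1),
    drowsy_persistence = runif(1, 0, 0.95)
  )
  run_session(wsls_agent(p, nearest = sample(c("left", "right"), 1)),
              prl_config(), seed = seed + 1L)
}

# hand-built session log from parallel vectors (for worked scoring examples)
make_log <- function(action, correct, rewarded,
                     latency = ifelse(action == "omission", NA_real_, 1),
                     reversal = rep(FALSE, length(action))) {
  structure(list(
    config = prl_config(n_trials = length(action)),
    seed = NA_integer_, subject_id = "S", dose_label = "vehicle",
    session_id = "S_T1",
    first_press_side = {
      pr <- action[action != "omission"]
      if (length(pr)) pr[1] else NA_character_
    },
    trials = data.frame(
      trial_index = seq_along(action) - 1L,
      correct_lever = correct, action = action, rewarded = rewarded,
      latency = latency, consecutive_correct_after = NA_integer_,
      reversal_occurred_after = reversal, stringsAsFactors = FALSE)
  ), class = "prl_session")
}
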