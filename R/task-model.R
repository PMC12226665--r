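#' @keywords internal
other_side <- function(side) ifelse(side == "left", "right", "left")

SIDES <- c("left", "right")
OMISSION <- "omission"

#' Start a PRL session
#'
#' Creates the session state machine. The correct lever starts UNASSIGNED: the
#' first lever actually pressed becomes the correct lever (endogenous
#' assignment), after which the 80/20 contingencies and the reversal counter
#' apply. Use [step_trial()] to advance one trial at a time, or [run_session()]
#' to play a whole session with an agent.
#'
#' @param config A [prl_config()].
#' @param seed Integer seed recorded in the state (used by [run_session()] to
#'   derive the reward and agent random streams).
#' @return An object of class `prl_state`.
#' @export
start_session <- function(config = prl_config(), seed = NA_integer_) {
  validate_prl_config(config)
  structure(list(
    config = config,
    seed = as.integer(seed),
    trial = 0L,                  # 0-based index of the NEXT trial
    correct_lever = NA_character_,
    consecutive_correct = 0L,
    n_reversals = 0L,
    first_press_side = NA_character_,
    finished = FALSE
  ), class = "prl_state")
}

#' Advance the session by one trial
#'
#' Applies one action (a side press or an omission) to the session state.
#' A press on the current correct lever is rewarded with probability
#' `p_reward_correct`, on the incorrect lever with `p_reward_incorrect`; an
#' omission is never rewarded. The consecutive-correct counter increments on a
#' correct press regardless of the reward outcome, resets on an incorrect
#' press, and is left unchanged by omissions (an omission is not a press).
#' When the counter reaches the reversal criterion the lever identities swap
#' effective from the next trial and the counter resets.
#'
#' @param state A `prl_state` from [start_session()] or a previous call.
#' @param action `"left"`, `"right"` or `"omission"`.
#' @param latency Press latency in seconds (ignored for omissions). Latencies
#'   exceeding the response window are recorded as omissions.
#' @param u Uniform(0,1) draw used for the reward decision; defaults to
#'   consuming R's RNG. Supplying it makes the step fully deterministic.
#' @return A list with elements `state` (updated `prl_state`) and `record`
#'   (one-row data frame: `trial_index` (0-based), `correct_lever`, `action`,
#'   `rewarded`, `latency`, `consecutive_correct_after`,
#'   `reversal_occurred_after`).
#' @export
step_trial <- function(state, action, latency = NA_real_, u = stats::runif(1)) {
  stopifnot(inherits(state, "prl_state"))
  if (state$finished || state$trial >= state$config$n_trials)
    stop("step_trial: session already finished", call. = FALSE)
  if (!(action %in% c(SIDES, OMISSION)))
    stop("protocol error: invalid action '", action, "'", call. = FALSE)
  if (action != OMISSION && is.finite(latency) &&
      latency > state$config$response_window) {
    action <- OMISSION
    latency <- NA_real_
  }

  cfg <- state$config
  rewarded <- FALSE
  reversal <- FALSE
  if (action == OMISSION) {
    latency <- NA_real_
  } else {
    if (is.na(state$correct_lever)) {
      state$correct_lever <- action
      state$first_press_side <- action
    }
    on_correct <- action == state$correct_lever
    rewarded <- u < (if (on_correct) cfg$p_reward_correct else cfg$p_reward_incorrect)
    if (on_correct) {
      state$consecutive_correct <- state$consecutive_correct + 1L
      if (state$consecutive_correct >= cfg$reversal_criterion) {
        reversal <- TRUE
        state$n_reversals <- state$n_reversals + 1L
        state$consecutive_correct <- 0L
      }
    } else {
      state$consecutive_correct <- 0L
    }
  }

  record <- data.frame(
    trial_index = state$trial,
    correct_lever = if (is.na(state$correct_lever)) "none" else state$correct_lever,
    action = action,
    rewarded = rewarded,
    latency = if (action == OMISSION) NA_real_ else latency,
    consecutive_correct_after = if (reversal) cfg$reversal_criterion else state$consecutive_correct,
    reversal_occurred_after = reversal,
    stringsAsFactors = FALSE
  )

  # reversal takes effect at the start of the next trial
  if (reversal) state$correct_lever <- other_side(state$correct_lever)
  state$trial <- state$trial + 1L
  if (state$trial >= cfg$n_trials) state$finished <- TRUE
  list(state = state, record = record)
}

#' Run a complete PRL session with an agent
#'
#' Plays `config$n_trials` trials of the task with a behavioral agent and
#' returns the trial-by-trial log. The session RNG is seeded once and split
#' into two streams drawn up front — reward draws first, then agent draws — so
#' agent stochasticity never perturbs the reward contingency stream.
#'
#' Agents never see the hidden correct lever: a WSLS agent
#' ([wsls_agent()]) observes only its own most recent press and that press's
#' outcome; a plain function agent receives `history` (either `NULL` or
#' `list(side=, rewarded=)`) and must return `"left"`, `"right"` or
#' `"omission"`.
#'
#' @param agent A [wsls_agent()] or a function of `history`.
#' @param config A [prl_config()].
#' @param seed Integer seed; identical (agent, config, seed) gives an
#'   identical log.
#' @param subject_id,dose_label,session_id Optional labels stored in the log.
#' @return An object of class `prl_session`: a list with `config`, `seed`,
#'   `subject_id`, `dose_label`, `session_id`, `first_press_side` and
#'   `trials` (data frame, one row per trial, 0-based `trial_index`).
#' @examples
#' log <- run_session(function(history) "left", prl_config(), seed = 1)
#' sum(log$trials$reversal_occurred_after) # exactly 1 for an always-left agent
#' @export
run_session <- function(agent, config = prl_config(), seed,
                        subject_id = NA_character_,
                        dose_label = NA_character_,
                        session_id = NA_character_) {
  validate_prl_config(config)
  if (missing(seed) || !is.finite(seed))
    stop("run_session: an integer seed is required", call. = FALSE)
  n <- config$n_trials

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  u_reward <- stats::runif(n)          # contingency stream, drawn first
  u_gate  <- stats::runif(n)           # agent: drowsiness-gate transitions
  u_split <- stats::runif(n)           # agent: omission-vs-perseveration split
  u_act   <- stats::runif(n)           # agent: WSLS / first-choice draws
  z_lat   <- stats::rnorm(n)           # agent: latency model

  is_wsls <- inherits(agent, "prl_agent")
  if (!is_wsls && !is.function(agent))
    stop("run_session: agent must be a prl_agent or a function(history)",
         call. = FALSE)
  p <- if (is_wsls) agent$params else NULL

  # drowsiness gate: marginal rate of drowsy acts (omission or perseveration),
  # matching the sequential p_omit / p_persev gates exactly when persistence = 0
  if (is_wsls) {
    pi_d <- p$p_omit + (1 - p$p_omit) * p$p_persev
    rho <- p$drowsy_persistence
    p_omit_given_d <- if (pi_d > 0) p$p_omit / pi_d else 0
    drowsy <- stats::runif(1) < pi_d   # stationary start
    nearest <- agent$nearest
  }

  trial_index <- integer(n); correct_col <- character(n)
  action_col <- character(n); rewarded_col <- logical(n)
  latency_col <- rep(NA_real_, n); consec_col <- integer(n)
  reversal_col <- logical(n)

  cur_correct <- NA_character_; cc <- 0L; first_press <- NA_character_
  prev_side <- NA_character_; prev_rewarded <- NA

  for (t in seq_len(n)) {
    history <- if (is.na(prev_side)) NULL else list(side = prev_side, rewarded = prev_rewarded)
    latency <- NA_real_
    if (is_wsls) {
      # update latent drowsiness state (two-state Markov; rho = 0 -> i.i.d.)
      p_d <- if (rho > 0) {
        if (drowsy) rho + (1 - rho) * pi_d else (1 - rho) * pi_d
      } else pi_d
      drowsy <- u_gate[t] < p_d
      if (drowsy) {
        if (u_split[t] < p_omit_given_d) {
          action <- OMISSION
        } else {
          # perseverative press: previous side, or the nearest-lever rule
          action <- if (!is.na(prev_side)) prev_side else {
            first_choice(nearest, p$side_bias, u_act[t])
          }
        }
      } else {
        if (is.na(prev_side)) {
          action <- first_choice(nearest, p$side_bias, u_act[t])
        } else if (isTRUE(prev_rewarded)) {
          action <- if (u_act[t] < p$p_stay_after_win) prev_side else other_side(prev_side)
        } else {
          action <- if (u_act[t] < p$p_shift_after_loss) other_side(prev_side) else prev_side
        }
      }
      if (action != OMISSION)
        latency <- exp(log(p$latency_location) + p$latency_scale * z_lat[t])
    } else {
      out <- agent(history)
      if (is.list(out)) { action <- out$action; latency <- out$latency %||% 1 }
      else { action <- out; latency <- 1 }
      if (!is.character(action) || length(action) != 1L ||
          !(action %in% c(SIDES, OMISSION)))
        stop("protocol error: agent returned an invalid action", call. = FALSE)
    }

    # inlined step_trial update (kept in lockstep with step_trial; the test
    # suite replays sessions through step_trial to assert equivalence)
    if (action != OMISSION && is.finite(latency) &&
        latency > config$response_window) {
      action <- OMISSION
      latency <- NA_real_
    }
    rewarded <- FALSE
    reversal <- FALSE
    if (action == OMISSION) {
      latency <- NA_real_
    } else {
      if (is.na(cur_correct)) {
        cur_correct <- action
        first_press <- action
      }
      if (action == cur_correct) {
        rewarded <- u_reward[t] < config$p_reward_correct
        cc <- cc + 1L
        if (cc >= config$reversal_criterion) {
          reversal <- TRUE
          cc <- 0L
        }
      } else {
        rewarded <- u_reward[t] < config$p_reward_incorrect
        cc <- 0L
      }
    }
    trial_index[t] <- t - 1L
    correct_col[t] <- if (is.na(cur_correct)) "none" else cur_correct
    action_col[t] <- action
    rewarded_col[t] <- rewarded
    latency_col[t] <- latency
    consec_col[t] <- if (reversal) config$reversal_criterion else cc
    reversal_col[t] <- reversal
    if (reversal) cur_correct <- if (cur_correct == "left") "right" else "left"
    if (action != OMISSION) {
      prev_side <- action
      prev_rewarded <- rewarded
    }
  }

  structure(list(
    config = config,
    seed = as.integer(seed),
    subject_id = subject_id,
    dose_label = dose_label,
    session_id = session_id,
    first_press_side = first_press,
    trials = data.frame(
      trial_index = trial_index,
      correct_lever = correct_col,
      action = action_col,
      rewarded = rewarded_col,
      latency = latency_col,
      consecutive_correct_after = consec_col,
      reversal_occurred_after = reversal_col,
      stringsAsFactors = FALSE
    )
  ), class = "prl_session")
}

first_choice <- function(nearest, side_bias, u) {
  # nearest lever with probability side_bias, otherwise uniform
  if (u < side_bias) nearest
  else if (u < side_bias + (1 - side_bias) / 2) "left"
  else "right"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prl_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("PRL session (%d trials, seed %s)\n", nrow(tr), x$seed))
  if (!is.na(x$subject_id)) cat(sprintf("  subject %s, dose %s\n", x$subject_id, x$dose_label))
  cat(sprintf("  first press: %s | reversals: %d | omissions: %d\n",
              ifelse(is.na(x$first_press_side), "none", x$first_press_side),
              sum(tr$reversal_occurred_after),
              sum(tr$action == OMISSION)))
  invisible(x)
}
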