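#' Task configuration for one PRL session
#'
#' Bundles every timing, probability and criterion parameter of a single
#' probabilistic reversal learning (PRL) session. Defaults reproduce the
#' standard rodent protocol: 200 trials, reward with 80% probability on the
#' correct lever and 20% on the incorrect one, contingency reversal after 8
#' consecutive correct presses (regardless of outcome), a 2 s lever-extension
#' delay, a 10 s response window (no press is an omission), a 5 s outcome
#' period and a 5 s inter-trial interval, so a trial lasts at most 22 s.
#'
#' @param n_trials Number of trials in the session.
#' @param p_reward_correct Reward probability for a press on the correct lever.
#' @param p_reward_incorrect Reward probability for a press on the incorrect
#'   lever. Must be strictly smaller than `p_reward_correct`.
#' @param reversal_criterion Consecutive correct presses (outcome-independent)
#'   that trigger a reversal of the lever contingencies.
#' @param lever_extend_delay Seconds from trial start to lever extension.
#' @param response_window Seconds allowed for a press; longer latencies are
#'   recorded as omissions.
#' @param outcome_period Seconds of outcome/feedback presentation.
#' @param iti Seconds of inter-trial interval.
#' @return An object of class `prl_config` (a validated list).
#' @examples
#' cfg <- prl_config()
#' max_trial_duration(cfg) # 22 seconds under the default protocol
#' @export
prl_config <- function(n_trials = 200L,
                       p_reward_correct = 0.8,
                       p_reward_incorrect = 0.2,
                       reversal_criterion = 8L,
                       lever_extend_delay = 2,
                       response_window = 10,
                       outcome_period = 5,
                       iti = 5) {
  cfg <- list(
    n_trials = as.integer(n_trials),
    p_reward_correct = p_reward_correct,
    p_reward_incorrect = p_reward_incorrect,
    reversal_criterion = as.integer(reversal_criterion),
    lever_extend_delay = lever_extend_delay,
    response_window = response_window,
    outcome_period = outcome_period,
    iti = iti
  )
  class(cfg) <- "prl_config"
  validate_prl_config(cfg)
  cfg
}

validate_prl_config <- function(cfg) {
  stopifnot(inherits(cfg, "prl_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("p_reward_correct", "p_reward_incorrect", "lever_extend_delay",
              "response_window", "outcome_period", "iti")) {
    if (!num1(cfg[[f]])) stop("prl_config: field '", f, "' must be a finite number", call. = FALSE)
  }
  if (!num1(cfg$n_trials) || cfg$n_trials < 1L)
    stop("prl_config: n_trials must be >= 1", call. = FALSE)
  if (!num1(cfg$reversal_criterion) || cfg$reversal_criterion < 1L)
    stop("prl_config: reversal_criterion must be >= 1", call. = FALSE)
  if (cfg$p_reward_incorrect < 0 || cfg$p_reward_correct > 1 ||
      cfg$p_reward_incorrect >= cfg$p_reward_correct)
    stop("prl_config: need 0 <= p_reward_incorrect < p_reward_correct <= 1",
         call. = FALSE)
  if (cfg$response_window <= 0)
    stop("prl_config: response_window must be positive", call. = FALSE)
  invisible(cfg)
}

#' Maximum duration of one trial, in seconds
#'
#' @param config A [prl_config()].
#' @return Lever-extension delay + response window + outcome period + ITI.
#' @export
max_trial_duration <- function(config) {
  validate_prl_config(config)
  config$lever_extend_delay + config$response_window +
    config$outcome_period + config$iti
}

#' @export
print.prl_config <- function(x, ...) {
  cat("PRL session configuration\n")
  cat(sprintf("  trials: %d, reward p (correct/incorrect): %.2f/%.2f\n",
              x$n_trials, x$p_reward_correct, x$p_reward_incorrect))
  cat(sprintf("  reversal after %d consecutive correct presses\n",
              x$reversal_criterion))
  cat(sprintf("  timing (s): extend %.3g, window %.3g, outcome %.3g, ITI %.3g (max trial %.3g)\n",
              x$lever_extend_delay, x$response_window, x$outcome_period,
              x$iti, max_trial_duration(x)))
  invisible(x)
}
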