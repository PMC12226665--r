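#' Behavioral policy parameters for a WSLS agent
#'
#' The agent family is a probabilistic win-stay/lose-shift (WSLS) policy with
#' a drowsiness gate layered on top. Per trial the agent is either *drowsy* —
#' in which case it omits or perseverates on the previously pressed (nearest)
#' lever, irrespective of feedback — or *awake*, in which case it applies the
#' WSLS rule to its most recent press: stay with probability
#' `p_stay_after_win` after a rewarded press, shift with probability
#' `p_shift_after_loss` after an unrewarded one. With no press history the
#' agent chooses its nearest lever with probability `side_bias`, otherwise a
#' uniformly random side.
#'
#' `p_omit` and `p_persev` are the marginal per-trial rates of the two drowsy
#' acts, applied as sequential gates (omission first). `drowsy_persistence`
#' clusters drowsy trials into bouts via a two-state Markov chain on the gate
#' (0 = independent trials, reproducing the plain sequential gates exactly);
#' it is a structural property of the agent family, shared across doses.
#'
#' Press latencies are drawn from a log-normal distribution with median
#' `latency_location` (seconds) and log-scale `latency_scale`; draws beyond
#' the response window are recorded as omissions, coupling slowness to
#' omissions.
#'
#' @param p_stay_after_win Probability of repeating the side after a reward.
#' @param p_shift_after_loss Probability of switching sides after a
#'   non-reward.
#' @param p_omit Marginal per-trial omission probability.
#' @param p_persev Probability of a perseverative press (repeat previous side,
#'   pre-empting the WSLS rule) given no omission.
#' @param latency_location Median press latency, seconds.
#' @param latency_scale Log-scale (sd of log latency).
#' @param side_bias Probability of choosing the fixed nearest lever when no
#'   history exists.
#' @param drowsy_persistence Markov persistence of the drowsiness gate in
#'   `[0, 1)`; 0 gives independent trials.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(p_stay_after_win = 0.9,
                         p_shift_after_loss = 0.6,
                         p_omit = 0.02,
                         p_persev = 0.05,
                         latency_location = 1.2,
                         latency_scale = 0.4,
                         side_bias = 0.7,
                         drowsy_persistence = 0) {
  p <- list(p_stay_after_win = p_stay_after_win,
            p_shift_after_loss = p_shift_after_loss,
            p_omit = p_omit,
            p_persev = p_persev,
            latency_location = latency_location,
            latency_scale = latency_scale,
            side_bias = side_bias,
            drowsy_persistence = drowsy_persistence)
  probs <- c("p_stay_after_win", "p_shift_after_loss", "p_omit", "p_persev",
             "side_bias")
  for (f in probs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("agent_params: '", f, "' must be a probability in [0, 1]",
           call. = FALSE)
  }
  if (!is.numeric(p$latency_location) || p$latency_location <= 0)
    stop("agent_params: latency_location must be > 0", call. = FALSE)
  if (!is.numeric(p$latency_scale) || p$latency_scale < 0)
    stop("agent_params: latency_scale must be >= 0", call. = FALSE)
  if (p$drowsy_persistence < 0 || p$drowsy_persistence >= 1)
    stop("agent_params: drowsy_persistence must be in [0, 1)", call. = FALSE)
  class(p) <- "agent_params"
  p
}

#' Create a WSLS agent
#'
#' @param params An [agent_params()] object.
#' @param nearest Which lever is the agent's "nearest" lever (`"left"` or
#'   `"right"`); the target of the side bias and of perseveration before any
#'   press has occurred.
#' @return An object of class `prl_agent` usable with [run_session()].
#' @export
wsls_agent <- function(params = agent_params(), nearest = "left") {
  stopifnot(inherits(params, "agent_params"), nearest %in% SIDES)
  structure(list(params = params, nearest = nearest), class = "prl_agent")
}

#' @export
print.prl_agent <- function(x, ...) {
  p <- x$params
  cat("WSLS agent\n")
  cat(sprintf("  stay|win %.2f, shift|loss %.2f, omit %.2f, persev %.2f (persistence %.2f)\n",
              p$p_stay_after_win, p$p_shift_after_loss, p$p_omit, p$p_persev,
              p$drowsy_persistence))
  cat(sprintf("  latency ~ lognormal(median %.2f s, scale %.2f); nearest lever: %s (bias %.2f)\n",
              p$latency_location, p$latency_scale, x$nearest, p$side_bias))
  invisible(x)
}

#' One WSLS action draw (stateless form)
#'
#' Applies the awake part of the WSLS policy plus the independent-trials
#' drowsiness gates to a single decision. This is the per-trial decision rule
#' used by [run_session()] when `drowsy_persistence = 0`, exposed for direct
#' testing; within a session the gate may instead be bout-persistent.
#'
#' @param params An [agent_params()].
#' @param history `NULL` (no press yet) or `list(side=, rewarded=)` describing
#'   the agent's most recent press.
#' @param nearest Nearest lever for the no-history and perseveration rules.
#' @param u Optional vector of 3 uniforms (omission gate, perseveration gate,
#'   action draw); defaults to consuming R's RNG.
#' @return `"left"`, `"right"` or `"omission"`.
#' @export
wsls_action <- function(params, history = NULL, nearest = "left",
                        u = stats::runif(3)) {
  stopifnot(inherits(params, "agent_params"), length(u) == 3L)
  if (u[1] < params$p_omit) return(OMISSION)
  if (u[2] < params$p_persev) {
    if (!is.null(history)) return(history$side)
    return(first_choice(nearest, params$side_bias, u[3]))
  }
  if (is.null(history)) return(first_choice(nearest, params$side_bias, u[3]))
  if (isTRUE(history$rewarded)) {
    if (u[3] < params$p_stay_after_win) history$side else other_side(history$side)
  } else {
    if (u[3] < params$p_shift_after_loss) other_side(history$side) else history$side
  }
}
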