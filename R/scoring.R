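#' Classify every press of a session by its feedback
#'
#' Walks the trial log and emits one feedback event per lever press (omissions
#' generate no event). Each press is classified by the role of the pressed
#' lever at that trial and the outcome:
#'
#' * `true-PF` — correct lever, rewarded;
#' * `misleading-PF` — incorrect lever, rewarded;
#' * `misleading-NF` — correct lever, unrewarded (the 20% probabilistic
#'   non-rewards that sensitivity to misleading negative feedback is scored
#'   against);
#' * `actual-NF` — incorrect lever, unrewarded.
#'
#' The stay/shift relation compares the press with the animal's next press.
#' Under the default `"strict"` censoring rule an event is censored when the
#' immediately following trial is an omission or when no subsequent press
#' exists (the last press of a session); censored events are excluded from
#' both numerator and denominator of every ratio. The `"lookahead"` variant
#' instead relates the press to the next press anywhere later in the session,
#' censoring only presses with no successor.
#'
#' @param log A `prl_session` from [run_session()] or [read_trial_log()].
#' @param censoring `"strict"` (default) or `"lookahead"`.
#' @return Data frame with one row per press: `trial_index`, `side`,
#'   `lever_role` (`"correct"`/`"incorrect"`), `rewarded`, `feedback_class`,
#'   `next_press_relation` (`"stay"`/`"shift"`/`"censored"`).
#' @export
classify_feedback <- function(log, censoring = c("strict", "lookahead")) {
  censoring <- match.arg(censoring)
  tr <- log$trials
  check_log_integrity(tr)
  press <- which(tr$action != OMISSION)
  if (!length(press)) {
    return(data.frame(trial_index = integer(0), side = character(0),
                      lever_role = character(0), rewarded = logical(0),
                      feedback_class = character(0),
                      next_press_relation = character(0),
                      stringsAsFactors = FALSE))
  }
  side <- tr$action[press]
  role <- ifelse(side == tr$correct_lever[press], "correct", "incorrect")
  rewarded <- tr$rewarded[press]
  feedback_class <- ifelse(rewarded,
                           ifelse(role == "correct", "true-PF", "misleading-PF"),
                           ifelse(role == "correct", "misleading-NF", "actual-NF"))

  n <- nrow(tr)
  m <- length(press)
  relation <- character(m)
  if (censoring == "strict") {
    nxt <- press + 1L
    ok <- nxt <= n & tr$action[pmin(nxt, n)] != OMISSION
    relation[!ok] <- "censored"
    relation[ok] <- ifelse(tr$action[nxt[ok]] == side[ok], "stay", "shift")
  } else {
    # next press anywhere later in the session
    nxt_side <- c(side[-1], NA_character_)
    relation <- ifelse(is.na(nxt_side), "censored",
                       ifelse(nxt_side == side, "stay", "shift"))
  }
  data.frame(trial_index = tr$trial_index[press], side = side,
             lever_role = role, rewarded = rewarded,
             feedback_class = feedback_class,
             next_press_relation = relation, stringsAsFactors = FALSE)
}

check_log_integrity <- function(tr) {
  required <- c("trial_index", "correct_lever", "action", "rewarded",
                "latency", "reversal_occurred_after")
  miss <- setdiff(required, names(tr))
  if (length(miss))
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  press <- tr$action != OMISSION
  if (any(press & tr$correct_lever == "none"))
    stop("integrity error: press recorded while correct lever unassigned",
         call. = FALSE)
  # the correct lever must be constant between consecutive reversal events
  assigned <- which(tr$correct_lever != "none")
  if (length(assigned) > 1L) {
    cl <- tr$correct_lever[assigned]
    rev_after <- tr$reversal_occurred_after[assigned]
    changes <- cl[-1] != cl[-length(cl)]
    if (any(changes & !rev_after[-length(rev_after)]))
      stop("integrity error: correct lever changed without a reversal",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Lose-shift ratios of a session
#'
#' The probabilistic lose-shift ratio is the fraction of non-censored
#' misleading-NF events (unrewarded presses on the correct lever) followed by
#' a switch of levers; the actual lose-shift ratio is computed likewise over
#' actual-NF events (unrewarded presses on the incorrect lever). A ratio is
#' `NA` exactly when its denominator is zero.
#'
#' @param events Output of [classify_feedback()].
#' @return List with `prob_ls_ratio` and `actual_ls_ratio`.
#' @export
ls_ratios <- function(events) {
  one <- function(class) {
    e <- events[events$feedback_class == class &
                events$next_press_relation != "censored", , drop = FALSE]
    if (!nrow(e)) return(NA_real_)
    mean(e$next_press_relation == "shift")
  }
  list(prob_ls_ratio = one("misleading-NF"),
       actual_ls_ratio = one("actual-NF"))
}

#' Win-stay ratio of a session
#'
#' Stays after any rewarded press, pooled over the correct and incorrect
#' levers, divided by the number of non-censored rewarded presses. `NA` when
#' no rewarded press is scorable.
#'
#' @param events Output of [classify_feedback()].
#' @return A single number in `[0, 1]`, or `NA`.
#' @export
ws_ratio <- function(events) {
  e <- events[events$rewarded & events$next_press_relation != "censored", ,
              drop = FALSE]
  if (!nrow(e)) return(NA_real_)
  mean(e$next_press_relation == "stay")
}

#' Number of completed reversals in a session
#'
#' @param log A `prl_session`.
#' @return Count of trials on which the consecutive-correct counter reached
#'   the reversal criterion.
#' @export
count_reversals <- function(log) {
  sum(log$trials$reversal_occurred_after)
}

#' The six per-session readouts
#'
#' Computes the session summary analyzed throughout: probabilistic and actual
#' lose-shift ratios, pooled win-stay ratio, number of reversals, median press
#' latency (over press trials only; `NA` if the session has no press), and
#' number of omissions.
#'
#' @param log A `prl_session`.
#' @param censoring Censoring rule, see [classify_feedback()].
#' @return An object of class `session_summary` (list with fields
#'   `prob_ls_ratio`, `actual_ls_ratio`, `ws_ratio`, `n_reversals`,
#'   `median_latency`, `n_omissions`, `n_trials`).
#' @export
summarize_session <- function(log, censoring = c("strict", "lookahead")) {
  censoring <- match.arg(censoring)
  events <- classify_feedback(log, censoring = censoring)
  ls <- ls_ratios(events)
  lat <- log$trials$latency[log$trials$action != OMISSION]
  out <- list(
    prob_ls_ratio = ls$prob_ls_ratio,
    actual_ls_ratio = ls$actual_ls_ratio,
    ws_ratio = ws_ratio(events),
    n_reversals = count_reversals(log),
    median_latency = if (length(lat)) stats::median(lat) else NA_real_,
    n_omissions = sum(log$trials$action == OMISSION),
    n_trials = nrow(log$trials)
  )
  class(out) <- "session_summary"
  out
}

#' @export
print.session_summary <- function(x, ...) {
  cat("PRL session summary\n")
  cat(sprintf("  prob LS %.3f | actual LS %.3f | WS %.3f\n",
              x$prob_ls_ratio, x$actual_ls_ratio, x$ws_ratio))
  cat(sprintf("  reversals %d | median latency %.2f s | omissions %d/%d\n",
              x$n_reversals, x$median_latency, x$n_omissions, x$n_trials))
  invisible(x)
}

#' Training-phase advancement criterion
#'
#' An animal qualifies for drug testing when each of its last 3 consecutive
#' training sessions shows at least 3 completed reversals and strictly fewer
#' than 15% omissions.
#'
#' @param summaries List of 3 `session_summary` objects (consecutive
#'   sessions), or a data frame with columns `reversals` and `omissions`.
#' @param n_trials Trials per session (denominator of the omission rate).
#' @return `TRUE` or `FALSE`.
#' @examples
#' s <- data.frame(reversals = c(3, 4, 3), omissions = c(10, 29, 0))
#' check_training_criteria(s, n_trials = 200) # 29/200 = 14.5% < 15% -> TRUE
#' @export
check_training_criteria <- function(summaries, n_trials = 200L) {
  if (is.data.frame(summaries)) {
    reversals <- summaries$reversals
    omissions <- summaries$omissions
  } else {
    reversals <- vapply(summaries, function(s) s$n_reversals, numeric(1))
    omissions <- vapply(summaries, function(s) s$n_omissions, numeric(1))
  }
  if (length(reversals) != 3L)
    stop("check_training_criteria: exactly 3 consecutive sessions required",
         call. = FALSE)
  all(reversals >= 3) && all(omissions / n_trials < 0.15)
}
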