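#' Write a trial-by-trial session log as CSV
#'
#' One row per trial with header
#' `session_id,subject_id,dose_label,trial_index,correct_lever,action,rewarded,latency_s,reversal_after`.
#' Trial indices are 1-based in exports (0-based internally); missing latency
#' is written as an empty field; logical columns are written as 0/1. UTF-8,
#' "." decimal separator.
#'
#' @param log A `prl_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  tr <- log$trials
  out <- data.frame(
    session_id = log$session_id,
    subject_id = log$subject_id,
    dose_label = log$dose_label,
    trial_index = tr$trial_index + 1L,
    correct_lever = tr$correct_lever,
    action = tr$action,
    rewarded = as.integer(tr$rewarded),
    latency_s = tr$latency,
    reversal_after = as.integer(tr$reversal_occurred_after),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial-log CSV back into a session object
#'
#' @param path File written by [write_trial_log()].
#' @param config The [prl_config()] the log was recorded under (defaults to
#'   the standard protocol).
#' @return A `prl_session`.
#' @export
read_trial_log <- function(path, config = prl_config(n_trials = 1L)) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(latency_s = "numeric"),
                         fileEncoding = "UTF-8")
  required <- c("session_id", "subject_id", "dose_label", "trial_index",
                "correct_lever", "action", "rewarded", "latency_s",
                "reversal_after")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("trial-log CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cfg <- config
  cfg$n_trials <- nrow(raw)
  first_press <- raw$action[raw$action != OMISSION]
  structure(list(
    config = cfg,
    seed = NA_integer_,
    subject_id = as.character(raw$subject_id[1]),
    dose_label = as.character(raw$dose_label[1]),
    session_id = as.character(raw$session_id[1]),
    first_press_side = if (length(first_press)) first_press[1] else NA_character_,
    trials = data.frame(
      trial_index = raw$trial_index - 1L,
      correct_lever = raw$correct_lever,
      action = raw$action,
      rewarded = as.logical(raw$rewarded),
      latency = raw$latency_s,
      consecutive_correct_after = NA_integer_,
      reversal_occurred_after = as.logical(raw$reversal_after),
      stringsAsFactors = FALSE
    )
  ), class = "prl_session")
}

#' Write the session-summary table as TSV
#'
#' One row per (subject, dose):
#' `subject_id dose_label prob_ls actual_ls ws reversals median_latency_s omissions`.
#' Undefined ratios are written as `NA`.
#'
#' @param summaries Data frame from [summarize_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summaries, path) {
  cols <- c("subject_id", "dose_label", "prob_ls", "actual_ls", "ws",
            "reversals", "median_latency_s", "omissions")
  miss <- setdiff(cols, names(summaries))
  if (length(miss))
    stop("summary table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.table(summaries[cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a session-summary TSV
#'
#' @param path File written by [write_summary_tsv()].
#' @return Data frame in the summary dialect.
#' @export
read_summary_tsv <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  cols <- c("subject_id", "dose_label", "prob_ls", "actual_ls", "ws",
            "reversals", "median_latency_s", "omissions")
  miss <- setdiff(cols, names(s))
  if (length(miss))
    stop("summary TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  s$subject_id <- as.character(s$subject_id)
  s
}

#' Read a run configuration from YAML
#'
#' All sections are optional; omitted values fall back to the pinned
#' [fig1_pattern()] scenario. Recognized sections: `seed`, `task` (any
#' [prl_config()] field), `design` (`n_subjects`, `randomize`, `seed`),
#' `effects` (dose label -> [agent_params()] fields), `jitter`
#' (`subject_sigma`, `session_sigma`), `scoring` (`censoring`), `stats`
#' (`posthoc_error`, `dunn_adjust`).
#'
#' @param path YAML file.
#' @return A run-config list shaped like [fig1_pattern()] plus `scoring` and
#'   `stats` flag lists.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- fig1_pattern()
  cfg <- base$config
  if (!is.null(y$task)) {
    bad <- setdiff(names(y$task), names(unclass(cfg)))
    if (length(bad))
      stop("config: unknown task field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg <- do.call(prl_config, utils::modifyList(unclass(cfg), y$task))
  }
  effects <- base$effects
  if (!is.null(y$effects)) {
    eff <- lapply(names(y$effects), function(nm) {
      fields <- y$effects[[nm]]
      bad <- setdiff(names(fields), names(unclass(agent_params())))
      if (length(bad))
        stop("config: unknown agent field(s) for '", nm, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      do.call(agent_params, fields)
    })
    names(eff) <- names(y$effects)
    effects <- dose_effects(eff)
  }
  n_subjects <- y$design$n_subjects %||% base$design$n_subjects
  design <- latin_square(n = n_subjects, k = length(names(effects)),
                         labels = names(effects),
                         randomize = isTRUE(y$design$randomize),
                         seed = y$design$seed %||% 1L)
  list(
    design = design,
    effects = effects,
    config = cfg,
    seed = y$seed %||% base$seed,
    subject_sigma = y$jitter$subject_sigma %||% base$subject_sigma,
    session_sigma = y$jitter$session_sigma %||% base$session_sigma,
    scoring = list(censoring = y$scoring$censoring %||% "strict"),
    stats = list(posthoc_error = y$stats$posthoc_error %||% "pooled",
                 dunn_adjust = y$stats$dunn_adjust %||% "bonferroni")
  )
}

#' Ingest an externally deposited summary dataset
#'
#' Maps a locally downloaded data deposit (a directory of delimited text
#' tables) onto the package's session-summary dialect. The function never
#' touches the network. Column names are matched case-insensitively against a
#' set of synonyms per field (e.g. `subject`/`animal`/`rat_id`;
#' `dose`/`treatment`/`condition`; `prob_ls`/`probabilistic_ls`/
#' `lose_shift_misleading` ...). If no table in the directory carries all the
#' required fields, the error lists the columns that were found.
#'
#' @param deposit_dir Local directory containing the deposit's tables.
#' @return Data frame in the summary dialect (see [read_summary_tsv()]).
#' @export
ingest_external <- function(deposit_dir) {
  if (!dir.exists(deposit_dir))
    stop("ingest_external: directory not found: ", deposit_dir, call. = FALSE)
  files <- list.files(deposit_dir, pattern = "\\.(csv|tsv|txt)$",
                      full.names = TRUE, ignore.case = TRUE)
  if (!length(files))
    stop("ingest_external: no delimited text tables in ", deposit_dir,
         call. = FALSE)
  synonyms <- list(
    subject_id = c("subject_id", "subject", "animal", "animal_id", "rat",
                   "rat_id", "id"),
    dose_label = c("dose_label", "dose", "treatment", "condition", "group"),
    prob_ls = c("prob_ls", "probabilistic_ls", "prob_lose_shift",
                "ls_misleading", "lose_shift_misleading"),
    actual_ls = c("actual_ls", "actual_lose_shift", "ls_actual",
                  "lose_shift_actual"),
    ws = c("ws", "win_stay", "ws_ratio"),
    reversals = c("reversals", "n_reversals", "reversal_count"),
    median_latency_s = c("median_latency_s", "median_latency", "latency",
                         "latency_s", "press_latency"),
    omissions = c("omissions", "n_omissions", "omission_count")
  )
  found_cols <- character(0)
  for (f in files) {
    sep <- if (grepl("\\.csv$", f, ignore.case = TRUE)) "," else "\t"
    tab <- tryCatch(utils::read.delim(f, sep = sep, stringsAsFactors = FALSE),
                    error = function(e) NULL)
    if (is.null(tab) || !ncol(tab)) next
    found_cols <- union(found_cols, names(tab))
    lc <- tolower(names(tab))
    map <- vapply(synonyms, function(syn) {
      hit <- match(syn, lc)
      hit <- hit[!is.na(hit)]
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    if (!anyNA(map)) {
      out <- tab[, map]
      names(out) <- names(synonyms)
      out$subject_id <- as.character(out$subject_id)
      out$dose_label <- as.character(out$dose_label)
      for (col in names(synonyms)[-(1:2)]) out[[col]] <- as.numeric(out[[col]])
      return(out)
    }
  }
  stop("ingest_external: no table maps onto the summary dialect; ",
       "columns found: ", paste(found_cols, collapse = ", "), call. = FALSE)
}
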