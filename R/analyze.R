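RATIO_OUTCOMES <- c("prob_ls", "actual_ls", "ws")
COUNT_OUTCOMES <- c("reversals", "median_latency_s", "omissions")

#' Run the full per-outcome statistical battery
#'
#' For each of the six session readouts, routes the subjects-by-conditions
#' matrix to the parametric branch (Lilliefors normality check, then
#' repeated-measures ANOVA with Sidak-corrected pairwise comparisons) or the
#' nonparametric branch (Friedman test with Dunn post hocs). The default
#' `routing = "fixed"` sends the three ratio outcomes to the parametric branch
#' and reversals, latency and omissions to the nonparametric branch (the
#' conventional assignment for these measures); `routing = "auto"` lets the
#' normality check decide per outcome at alpha = 0.05 (normality is checked
#' on the within-subject residuals, i.e. after removing subject and condition
#' means).
#'
#' Subjects with undefined (missing) values for an outcome are dropped from
#' that outcome only, with a message reporting the n used.
#'
#' @param summaries Summary data frame ([summarize_cohort()] /
#'   [read_summary_tsv()]).
#' @param routing `"fixed"` or `"auto"`.
#' @param comparisons `"all"` (all condition pairs) or a list of pairs.
#' @param posthoc_error Error term for [sidak_pairwise()].
#' @param dunn_adjust Adjustment for [dunn_posthoc()].
#' @param reference Condition used for effect-direction badges.
#' @param ks_B Monte-Carlo replicates for the normality check.
#' @param ks_seed Seed for the normality check's Monte-Carlo p.
#' @return Object of class `prl_report`: per-outcome list with `branch`,
#'   `ks`, `test` (an [rm_anova()] or [friedman_rm()]), `posthoc` and
#'   `badge`, plus a `meta` element (package version, n, flags).
#' @export
analyze_outcomes <- function(summaries,
                             routing = c("fixed", "auto"),
                             comparisons = "all",
                             posthoc_error = c("pooled", "perpair"),
                             dunn_adjust = c("bonferroni", "sidak"),
                             reference = "vehicle",
                             ks_B = 400L, ks_seed = 1L) {
  routing <- match.arg(routing)
  posthoc_error <- match.arg(posthoc_error)
  dunn_adjust <- match.arg(dunn_adjust)
  conditions <- unique(summaries$dose_label)
  if (length(conditions) < 2L)
    stop("analyze_outcomes: need at least 2 conditions", call. = FALSE)

  outcomes <- c(RATIO_OUTCOMES, COUNT_OUTCOMES)
  sections <- list()
  for (oc in outcomes) {
    m <- outcome_matrix(summaries, oc)
    mc <- suppressMessages(complete_cases_matrix(m))
    resid <- mc - rowMeans(mc) -
      matrix(colMeans(mc), nrow(mc), ncol(mc), byrow = TRUE) + mean(mc)
    ks <- tryCatch(ks_normality(as.vector(resid), B = ks_B, seed = ks_seed),
                   error = function(e) list(D = NA_real_, p = NA_real_))
    branch <- if (routing == "fixed") {
      if (oc %in% RATIO_OUTCOMES) "parametric" else "nonparametric"
    } else {
      if (!is.na(ks$p) && ks$p > 0.05) "parametric" else "nonparametric"
    }
    if (branch == "parametric") {
      test <- rm_anova(m)
      posthoc <- sidak_pairwise(m, comparisons = comparisons,
                                error = posthoc_error, anova = test)
      omnibus_p <- test$p
    } else {
      test <- friedman_rm(m)
      posthoc <- dunn_posthoc(m, comparisons = comparisons,
                              adjust = dunn_adjust)
      omnibus_p <- test$p
    }
    badge <- effect_badge(mc, posthoc, branch, reference)
    sections[[oc]] <- list(outcome = oc, branch = branch, ks = ks,
                           test = test, posthoc = posthoc,
                           omnibus_p = omnibus_p, badge = badge,
                           n = nrow(mc))
  }
  structure(list(outcomes = sections,
                 meta = list(package_version = as.character(utils::packageVersion("prlsim")),
                             routing = routing,
                             posthoc_error = posthoc_error,
                             dunn_adjust = dunn_adjust,
                             reference = reference,
                             assumptions = paste(
                               "post hoc error term and comparison family are",
                               "package defaults (pooled within-subject error;",
                               "all pairwise comparisons)"))),
            class = "prl_report")
}

# machine-readable effect-direction badge per outcome: direction and
# adjusted significance of each non-reference condition vs the reference
effect_badge <- function(m, posthoc, branch, reference) {
  labels <- colnames(m)
  if (!(reference %in% labels)) return(NULL)
  center <- if (branch == "parametric") colMeans(m)
            else apply(m, 2L, stats::median)
  out <- lapply(setdiff(labels, reference), function(cond) {
    pair1 <- paste(cond, "vs", reference)
    pair2 <- paste(reference, "vs", cond)
    row <- posthoc[posthoc$pair %in% c(pair1, pair2), , drop = FALSE]
    padj <- if (nrow(row)) row$p_adj[1] else NA_real_
    delta <- center[[cond]] - center[[reference]]
    data.frame(condition = cond,
               direction = if (delta > 0) "up" else if (delta < 0) "down" else "flat",
               delta = delta, p_adj = padj,
               significant = !is.na(padj) && padj < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.prl_report <- function(x, ...) {
  cat("PRL statistical report (prlsim", x$meta$package_version, ")\n", sep = "")
  cat("  routing:", x$meta$routing,
      "| post hoc:", x$meta$posthoc_error, "/", x$meta$dunn_adjust, "\n")
  for (sec in x$outcomes) {
    cat(sprintf("\n== %s [%s branch] (n = %d) ==\n",
                sec$outcome, sec$branch, sec$n))
    if (!is.na(sec$ks$D))
      cat(sprintf("  normality: Lilliefors D = %.3f, p = %.3g\n",
                  sec$ks$D, sec$ks$p))
    print(sec$test)
    ph <- sec$posthoc
    for (r in seq_len(nrow(ph))) {
      stat <- if ("t" %in% names(ph)) sprintf("t = %.2f", ph$t[r])
              else sprintf("Z = %.2f", ph$Z[r])
      cat(sprintf("    %-22s %s, p_adj = %.4g\n", ph$pair[r], stat,
                  ph$p_adj[r]))
    }
    if (!is.null(sec$badge)) {
      for (r in seq_len(nrow(sec$badge)))
        cat(sprintf("    [%s] %s vs %s: %s%s\n", sec$outcome,
                    sec$badge$condition[r], x$meta$reference,
                    sec$badge$direction[r],
                    if (sec$badge$significant[r]) " *" else ""))
    }
  }
  invisible(x)
}

#' Serialize a statistical report to JSON
#'
#' Writes the structured report (statistics, dfs, p-values, post hoc tables,
#' effect badges, metadata) as JSON. Timestamps are deliberately excluded so
#' re-analysis under the same seed is byte-stable.
#'
#' @param report A `prl_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(sec) {
    test <- unclass(sec$test)
    test$means <- as.list(test$means)
    if (!is.null(test$mean_ranks)) test$mean_ranks <- as.list(test$mean_ranks)
    list(outcome = sec$outcome, branch = sec$branch,
         ks = sec$ks[c("D", "p")], test = test,
         posthoc = sec$posthoc, badge = sec$badge, n = sec$n)
  }
  out <- list(meta = report$meta, outcomes = lapply(report$outcomes, strip))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
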