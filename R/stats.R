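#' Subjects-by-conditions outcome matrix
#'
#' Reshapes a cohort summary table into the wide matrix consumed by the
#' statistical battery. Rows are subjects, columns conditions.
#'
#' @param summaries Data frame from [summarize_cohort()] (or
#'   [read_summary_tsv()]).
#' @param outcome Column to extract (e.g. `"prob_ls"`, `"ws"`, `"reversals"`).
#' @param conditions Condition labels in display order; defaults to the dose
#'   labels present, vehicle first if available.
#' @return Numeric matrix with subject row names and condition column names.
#' @export
outcome_matrix <- function(summaries, outcome,
                           conditions = NULL) {
  stopifnot(outcome %in% names(summaries))
  if (is.null(conditions)) {
    present <- unique(summaries$dose_label)
    conditions <- c(intersect(DOSE_LABELS, present),
                    setdiff(present, DOSE_LABELS))
  }
  subjects <- unique(summaries$subject_id)
  m <- matrix(NA_real_, nrow = length(subjects), ncol = length(conditions),
              dimnames = list(subjects, conditions))
  for (r in seq_len(nrow(summaries))) {
    m[summaries$subject_id[r], summaries$dose_label[r]] <-
      summaries[[outcome]][r]
  }
  m
}

complete_cases_matrix <- function(m, context = "outcome") {
  keep <- stats::complete.cases(m)
  if (!all(keep))
    message(sprintf("%s: dropping %d incomplete subject(s); n = %d used",
                    context, sum(!keep), sum(keep)))
  m[keep, , drop = FALSE]
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA with subject as the blocking factor, computed from the
#' classical sums-of-squares decomposition: the dose effect is tested against
#' the subject-by-condition interaction with df (k - 1, (k - 1)(n - 1)).
#' Mauchly's test of sphericity is computed from the covariance of the
#' orthonormal within-subject contrasts, and the Greenhouse-Geisser corrected
#' p-value is reported alongside the uncorrected one for use when sphericity
#' is rejected.
#'
#' Subjects with any missing condition are dropped (complete-case handling;
#' undefined ratios propagate as missing values).
#'
#' @param m Subjects x conditions matrix from [outcome_matrix()].
#' @return Object of class `rm_anova` (list): `F`, `df_effect`, `df_error`,
#'   `p`, `gg_epsilon`, `p_gg`, `mauchly_W`, `mauchly_p`, `ms_error`,
#'   `means`, `n`, `k`.
#' @export
rm_anova <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("rm_anova: need at least 2 conditions", call. = FALSE)
  m <- complete_cases_matrix(m, "rm_anova")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) stop("rm_anova: need at least 2 complete subjects", call. = FALSE)

  grand <- mean(m)
  col_means <- colMeans(m)
  row_means <- rowMeans(m)
  ss_cond <- n * sum((col_means - grand)^2)
  ss_subj <- k * sum((row_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_effect <- k - 1L
  df_error <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df_effect
  ms_err <- ss_err / df_error
  F <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond == 0) 0 else Inf
  p <- if (ms_err > 0) stats::pf(F, df_effect, df_error, lower.tail = FALSE)
       else if (ms_cond == 0) 1 else 0

  # sphericity: Mauchly's W on orthonormal contrasts, GG epsilon
  sph <- sphericity_stats(m)

  structure(list(F = F, df_effect = df_effect, df_error = df_error, p = p,
                 gg_epsilon = sph$epsilon,
                 p_gg = if (is.finite(F) && ms_err > 0)
                   stats::pf(F, df_effect * sph$epsilon,
                             df_error * sph$epsilon, lower.tail = FALSE)
                 else p,
                 mauchly_W = sph$W, mauchly_p = sph$p,
                 ms_error = ms_err, means = col_means, n = n, k = k),
            class = "rm_anova")
}

sphericity_stats <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (k == 2L) return(list(W = 1, p = 1, epsilon = 1))
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))                      # orthonormal contrast basis, k x (k-1)
  Y <- m %*% C
  S <- stats::cov(Y)
  d <- k - 1L
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  epsilon <- sum(ev)^2 / (d * sum(ev^2))
  if (any(ev <= 0) || n <= d) return(list(W = NA_real_, p = NA_real_,
                                          epsilon = epsilon))
  W <- prod(ev) / (sum(ev) / d)^d
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
  chisq <- -(n - 1) * f * log(W)
  df <- d * (d + 1) / 2 - 1
  list(W = W, p = stats::pchisq(chisq, df, lower.tail = FALSE),
       epsilon = epsilon)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.2f, p = %.4g\n",
              x$df_effect, x$df_error, x$F, x$p))
  cat(sprintf("  Mauchly W = %.3f (p = %.3g); GG epsilon = %.3f, GG p = %.4g\n",
              x$mauchly_W, x$mauchly_p, x$gg_epsilon, x$p_gg))
  invisible(x)
}

all_pairs <- function(labels) {
  idx <- utils::combn(length(labels), 2L)
  lapply(seq_len(ncol(idx)), function(j) labels[idx[, j]])
}

#' Sidak-corrected pairwise comparisons after a repeated-measures ANOVA
#'
#' Paired contrasts using the pooled within-subject ANOVA error term:
#' `t = (mean_i - mean_j) / sqrt(2 * MS_error / n)` on `df_error` degrees of
#' freedom, with Sidak multiplicity adjustment `p_adj = 1 - (1 - p)^m` over
#' the `m` requested comparisons. A per-pair paired-t variant (each pair's own
#' error and df) is available via `error = "perpair"`.
#'
#' @param m Subjects x conditions matrix.
#' @param comparisons `"all"` (default: all condition pairs) or a list of
#'   2-element label vectors.
#' @param error `"pooled"` (ANOVA error term) or `"perpair"`.
#' @param anova Optional precomputed [rm_anova()] result for the pooled error.
#' @return Data frame: `pair`, `estimate`, `t`, `df`, `p`, `p_adj`.
#' @export
sidak_pairwise <- function(m, comparisons = "all",
                           error = c("pooled", "perpair"), anova = NULL) {
  error <- match.arg(error)
  m <- complete_cases_matrix(as.matrix(m), "sidak_pairwise")
  labels <- colnames(m)
  if (identical(comparisons, "all")) comparisons <- all_pairs(labels)
  nc <- length(comparisons)
  if (error == "pooled" && is.null(anova)) anova <- rm_anova(m)

  rows <- lapply(comparisons, function(pr) {
    stopifnot(length(pr) == 2L, all(pr %in% labels))
    d <- m[, pr[1]] - m[, pr[2]]
    est <- mean(d)
    if (error == "pooled") {
      se <- sqrt(2 * anova$ms_error / nrow(m))
      df <- anova$df_error
    } else {
      se <- stats::sd(d) / sqrt(length(d))
      df <- length(d) - 1L
    }
    tval <- if (se > 0) est / se else 0
    p <- if (se > 0) 2 * stats::pt(abs(tval), df, lower.tail = FALSE) else 1
    data.frame(pair = paste(pr, collapse = " vs "), estimate = est,
               t = tval, df = df, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- sidak_adjust(out$p, nc)
  out
}

#' Sidak adjustment of a p-value
#'
#' @param p Raw p-value(s).
#' @param m Number of comparisons in the family.
#' @return `1 - (1 - p)^m`.
#' @export
sidak_adjust <- function(p, m) 1 - (1 - p)^m

#' Friedman rank test for a within-subject design
#'
#' Ranks the conditions within each subject (mid-ranks for ties) and tests the
#' equality of mean ranks with the chi-square approximation on k - 1 df,
#' using the standard tie-correction denominator. When every subject's values
#' are completely tied the statistic is 0 (with a warning).
#'
#' @param m Subjects x conditions matrix.
#' @return Object of class `friedman_rm` (list): `chisq`, `df`, `p`,
#'   `mean_ranks`, `n`, `k`.
#' @export
friedman_rm <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("friedman_rm: need at least 2 conditions", call. = FALSE)
  m <- complete_cases_matrix(m, "friedman_rm")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) stop("friedman_rm: need at least 2 complete subjects", call. = FALSE)
  R <- t(apply(m, 1L, rank))
  Rj <- colSums(R)
  raw <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  # tie correction: 1 - sum over subjects of (t^3 - t) / (n k (k^2 - 1))
  ties <- sum(apply(m, 1L, function(x) {
    t <- table(x); sum(t^3 - t)
  }))
  denom <- 1 - ties / (n * k * (k^2 - 1))
  if (denom <= 0) {
    warning("friedman_rm: all values tied within every subject; chi-square = 0")
    chisq <- 0
  } else {
    chisq <- raw / denom
  }
  structure(list(chisq = chisq, df = k - 1L,
                 p = stats::pchisq(chisq, k - 1L, lower.tail = FALSE),
                 mean_ranks = Rj / n, n = n, k = k),
            class = "friedman_rm")
}

#' @export
print.friedman_rm <- function(x, ...) {
  cat(sprintf("Friedman test: chi-square(%d) = %.2f, p = %.4g (n = %d)\n",
              x$df, x$chisq, x$p, x$n))
  invisible(x)
}

#' Dunn's post hoc comparisons after a Friedman test
#'
#' Z statistics from the difference of mean within-subject ranks,
#' `Z = (Rbar_i - Rbar_j) / sqrt(k (k + 1) / (6 n))`, with Bonferroni
#' adjustment over the requested comparisons (the classical Dunn procedure);
#' a Sidak variant is available.
#'
#' @param m Subjects x conditions matrix.
#' @param comparisons `"all"` or a list of 2-element label vectors.
#' @param adjust `"bonferroni"` (default) or `"sidak"`.
#' @return Data frame: `pair`, `Z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(m, comparisons = "all",
                         adjust = c("bonferroni", "sidak")) {
  adjust <- match.arg(adjust)
  m <- complete_cases_matrix(as.matrix(m), "dunn_posthoc")
  n <- nrow(m); k <- ncol(m)
  labels <- colnames(m)
  R <- t(apply(m, 1L, rank))
  rbar <- colMeans(R)
  names(rbar) <- labels
  if (identical(comparisons, "all")) comparisons <- all_pairs(labels)
  se <- sqrt(k * (k + 1) / (6 * n))
  nc <- length(comparisons)
  rows <- lapply(comparisons, function(pr) {
    stopifnot(length(pr) == 2L, all(pr %in% labels))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    data.frame(pair = paste(pr, collapse = " vs "), Z = z, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "bonferroni") pmin(1, out$p * nc)
               else sidak_adjust(out$p, nc)
  out
}

#' Lilliefors-type Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic against a normal distribution with mean and sd
#' estimated from the data, with the p-value obtained by Monte-Carlo
#' simulation of the null (estimation makes the textbook KS null distribution
#' invalid; the Lilliefors form accounts for it).
#'
#' @param x Numeric sample (n >= 4, non-constant).
#' @param B Number of Monte-Carlo null replicates.
#' @param seed Optional seed for the Monte-Carlo draw (reproducible p).
#' @return List with `D`, `p`, `n`, `B`.
#' @export
ks_normality <- function(x, B = 1000L, seed = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("ks_normality: need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("ks_normality: degenerate (constant) sample", call. = FALSE)
  D <- lilliefors_D(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  D0 <- replicate(B, lilliefors_D(stats::rnorm(n)))
  list(D = D, p = (sum(D0 >= D) + 1) / (B + 1), n = n, B = B)
}

lilliefors_D <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  Fz <- stats::pnorm(z)
  max(seq_len(n) / n - Fz, Fz - (seq_len(n) - 1) / n)
}
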