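test_that("rm_anova matches independent sums-of-squares and mlm oracles", {
  set.seed(5)
  n <- 12; k <- 4
  Y <- matrix(rnorm(n * k), n, k) + rnorm(n)
  colnames(Y) <- paste0("c", 1:k)
  r <- rm_anova(Y)
  expect_identical(r$df_effect, 3L)
  expect_identical(r$df_error, 33L)

  # oracle 1: univariate aov with subject error stratum
  df <- data.frame(y = as.vector(Y), cond = factor(rep(1:k, each = n)),
                   subj = factor(rep(1:n, k)))
  a <- summary(stats::aov(y ~ cond + Error(subj / cond), df))
  tab <- a[["Error: subj:cond"]][[1]]
  expect_equal(r$F, tab[["F value"]][1])
  expect_equal(r$p, tab[["Pr(>F)"]][1])

  # oracle 2: multivariate lm route for sphericity and GG correction
  fit <- stats::lm(Y ~ 1)
  idata <- data.frame(cond = factor(1:k))
  mt <- stats::mauchly.test(fit, M = ~cond, X = ~1, idata = idata)
  expect_equal(r$mauchly_W, unname(mt$statistic))
  expect_equal(r$mauchly_p, mt$p.value, tolerance = 0.01)
  am <- stats::anova(fit, M = ~cond, X = ~1, idata = idata,
                     test = "Spherical")
  expect_equal(r$p_gg, am$`G-G Pr`[1], tolerance = 1e-8)
})

test_that("rm_anova handles degenerate and incomplete inputs", {
  m <- matrix(rep(rnorm(6), 3), ncol = 3)   # identical condition columns
  colnames(m) <- c("a", "b", "c")
  r <- rm_anova(m)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  m2 <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  m2[2, 3] <- NA
  expect_message(r2 <- rm_anova(m2), "dropping 1 incomplete")
  expect_identical(r2$n, 4L)
  expect_error(rm_anova(m2[, 1, drop = FALSE]), "at least 2 conditions")
})

test_that("Sidak pairwise comparisons use the pooled error term", {
  set.seed(21)
  m <- matrix(rnorm(40, sd = 0.3), 10, 4) + rnorm(10) +
    matrix(rep(c(0, 0, 0, 1), each = 10), 10, 4)
  colnames(m) <- c("vehicle", "5 mg/kg", "10 mg/kg", "40 mg/kg")
  a <- rm_anova(m)
  ph <- sidak_pairwise(m, anova = a)
  expect_identical(nrow(ph), 6L)
  expect_true(all(ph$df == a$df_error))
  # closed form: t from pooled MS_error, p_adj = 1 - (1 - p)^6
  d <- colMeans(m)[["vehicle"]] - colMeans(m)[["40 mg/kg"]]
  tref <- d / sqrt(2 * a$ms_error / 10)
  row <- ph[ph$pair == "vehicle vs 40 mg/kg", ]
  expect_equal(row$t, tref)
  expect_equal(row$p_adj, 1 - (1 - row$p)^6)
  expect_true(all(ph$p_adj >= ph$p))

  # identical pair of columns -> t = 0, p_adj = 1
  m2 <- cbind(a1 = m[, 1], a2 = m[, 1], b = m[, 4])
  ph2 <- sidak_pairwise(m2, comparisons = list(c("a1", "a2")))
  expect_equal(ph2$t, 0)
  expect_equal(ph2$p_adj, 1)

  # per-pair variant reduces to the paired t test
  php <- sidak_pairwise(m, comparisons = list(c("vehicle", "40 mg/kg")),
                        error = "perpair")
  tt <- stats::t.test(m[, "vehicle"], m[, "40 mg/kg"], paired = TRUE)
  expect_equal(php$t, unname(tt$statistic))
  expect_equal(php$p, tt$p.value)
})

test_that("the Sidak adjustment is monotone and exact in closed form", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.05, 6), 1 - 0.95^6)
  expect_equal(sidak_adjust(0.05, 6), 0.2649, tolerance = 1e-4)
  p <- seq(0.001, 0.5, by = 0.013)
  for (m in 1:8) {
    expect_true(all(diff(sidak_adjust(p, m)) > 0))           # monotone in p
    expect_true(all(sidak_adjust(p, m + 1) >= sidak_adjust(p, m))) # and in m
  }
})

test_that("friedman_rm matches closed forms and the tie-free base oracle", {
  # perfect concordance, k = 4, n = 10: chi-square = n (k - 1) = 30
  m <- matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4) +
    matrix(rep(seq(0, 0.09, 0.01), 4), 10, 4)
  colnames(m) <- letters[1:4]
  f <- friedman_rm(m)
  expect_equal(f$chisq, 30)
  expect_identical(f$df, 3L)

  # identical columns: statistic 0 under the tie convention, with a warning
  m2 <- matrix(rep(rnorm(8), 3), ncol = 3, dimnames = list(NULL, letters[1:3]))
  expect_warning(f2 <- friedman_rm(m2), "tied")
  expect_equal(f2$chisq, 0)

  # tie-free data: agrees exactly with stats::friedman.test
  set.seed(31)
  m3 <- matrix(rnorm(60), 15, 4, dimnames = list(NULL, letters[1:4]))
  f3 <- friedman_rm(m3)
  ref <- stats::friedman.test(m3)
  expect_equal(f3$chisq, unname(ref$statistic))
  expect_equal(f3$p, ref$p.value)
})

test_that("friedman p agrees with an exhaustive permutation oracle", {
  # n = 6 subjects, k = 3: enumerate all 6^6 within-subject orderings
  set.seed(7)
  m <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[, 3] <- m[, 3] + 1.2
  f <- friedman_rm(m)

  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  chisq_of <- function(R) {
    Rj <- colSums(R)
    12 / (6 * 3 * 4) * sum(Rj^2) - 3 * 6 * 4
  }
  grid <- expand.grid(rep(list(1:6), 6))
  null_stats <- apply(grid, 1, function(ix) chisq_of(perms[unlist(ix), ]))
  p_perm <- mean(null_stats >= f$chisq - 1e-9)
  # absolute agreement within the discreteness of the permutation null
  expect_lt(abs(f$p - p_perm), 0.02)
})

test_that("Dunn post hoc Z follows the rank-sum closed form", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4) +
    matrix(rep(seq(0, 0.09, 0.01), 4), 10, 4)
  colnames(m) <- c("vehicle", "5 mg/kg", "10 mg/kg", "40 mg/kg")
  d <- dunn_posthoc(m)
  # extreme pair under perfect concordance: mean-rank difference 3,
  # SE = sqrt(k (k+1) / (6 n)) = sqrt(20/60)
  row <- d[d$pair == "vehicle vs 40 mg/kg", ]
  expect_equal(row$Z, -3 / sqrt(20 / 60))
  expect_true(all(d$p_adj >= d$p))
  expect_true(all(d$p_adj <= 1))

  # identical columns -> Z = 0, p_adj = 1
  m2 <- matrix(rep(rnorm(8), 3), ncol = 3, dimnames = list(NULL, letters[1:3]))
  d2 <- dunn_posthoc(m2, comparisons = list(c("a", "b")))
  expect_equal(d2$Z, 0)
  expect_equal(d2$p_adj, 1)

  # Sidak variant never exceeds Bonferroni
  set.seed(4)
  m3 <- matrix(rnorm(48), 12, 4, dimnames = list(NULL, letters[1:4]))
  db <- dunn_posthoc(m3, adjust = "bonferroni")
  ds <- dunn_posthoc(m3, adjust = "sidak")
  expect_true(all(ds$p_adj <= db$p_adj + 1e-12))
})

test_that("the Lilliefors check is calibrated and detects non-normality", {
  expect_error(ks_normality(rep(1, 20)), "degenerate")
  expect_error(ks_normality(c(1, 2)), "at least 4")

  # size: standard-normal samples keep p > 0.05 about 95% of the time
  set.seed(12)
  keep <- mean(replicate(300, ks_normality(rnorm(80), B = 300)$p > 0.05))
  expect_gte(keep, 0.92)

  # power: uniform samples of n = 500 are rejected essentially always
  rej <- mean(replicate(40, ks_normality(runif(500), B = 300)$p < 0.05))
  expect_gte(rej, 0.95)

  # agreement with the nortest reference implementation
  x <- rnorm(100, mean = 3, sd = 2)
  mine <- ks_normality(x, B = 4000, seed = 1)
  ref <- nortest::lillie.test(x)
  expect_equal(mine$D, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 0.05)
})

test_that("rank-transformed anova and friedman agree in rejection direction", {
  set.seed(17)
  agree <- 0; total <- 40
  for (b in 1:total) {
    m <- matrix(rnorm(160), 40, 4) + rnorm(40) +
      matrix(rep(c(0, 0, 0.2, 0.35), each = 40), 40, 4)
    colnames(m) <- letters[1:4]
    fr <- friedman_rm(m)$p < 0.05
    ranked <- t(apply(m, 1, rank))
    colnames(ranked) <- letters[1:4]
    ra <- rm_anova(ranked)$p < 0.05
    agree <- agree + (fr == ra)
  }
  expect_gte(agree / total, 0.95)
})
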