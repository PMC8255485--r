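test_that("t tests reproduce closed-form values with Cohen's d", {
  r1 <- usv_t_test("one_sample", c(49, 50, 51), mu = 50)
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p, 1)

  r2 <- usv_t_test("one_sample", c(52, 54, 56), mu = 50)
  expect_equal(r2$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(r2$df, 2)
  expect_equal(r2$effect_size, 4 / 2)  # mean diff 4, sd 2

  r3 <- usv_t_test("paired", c(3, 3, 5), c(1, 2, 3))
  expect_equal(r3$statistic, 5)
  expect_equal(r3$df, 2)

  r4 <- usv_t_test("one_sample", c(50, 50, 50), mu = 50)
  expect_true(r4$degenerate)
  expect_true(is.na(r4$statistic))
})

test_that("within-subject ANOVA F equals the squared paired t for 2 levels", {
  d <- data.frame(subject = rep(1:3, each = 2),
                  cond = rep(c("a", "b"), 3),
                  y = c(10, 13, 20, 22, 30, 35))
  an <- rm_anova_within(d, "y", "cond", "subject")
  expect_equal(an$F, 14.2857, tolerance = 1e-4)
  expect_equal(c(an$df1, an$df2), c(1, 2))
  tt <- usv_t_test("paired", d$y[d$cond == "b"], d$y[d$cond == "a"])
  expect_equal(an$F, tt$statistic^2, tolerance = 1e-8)

  flat <- d; flat$y <- rep(c(5, 5), 3) + rep(1:3, each = 2)
  expect_equal(rm_anova_within(flat, "y", "cond", "subject")$F, 0)
})

test_that("two-factor within ANOVA matches the sums-of-squares oracle", {
  set.seed(41)
  for (rep in 1:5) {
    d <- expand.grid(subject = 1:8, A = c("c1", "c2"),
                     B = c("z1", "z2", "z3"))
    d$y <- rnorm(nrow(d))
    an <- rm_anova_within(d, "y", c("A", "B"), "subject")
    oracle <- rm_anova_oracle(d, "y", c("A", "B"), "subject")
    expect_equal(an$F[an$effect == "A"], unname(oracle["A"]),
                 tolerance = 1e-10)
    expect_equal(an$F[an$effect == "B"], unname(oracle["B"]),
                 tolerance = 1e-10)
    expect_equal(an$F[an$effect == "A:B"], unname(oracle["AB"]),
                 tolerance = 1e-10)
  }
  d2 <- expand.grid(subject = 1:4, A = c("c1", "c2"))
  d2$y <- rnorm(nrow(d2))
  expect_error(rm_anova_within(d2[-1, ], "y", "A", "subject"),
               "complete and balanced")
})

test_that("partial eta squared comes from the effect's own stratum", {
  d <- data.frame(subject = rep(1:3, each = 2),
                  cond = rep(c("a", "b"), 3),
                  y = c(10, 13, 20, 22, 30, 35))
  an <- rm_anova_within(d, "y", "cond", "subject")
  # SS_cond = 3 * (mean_b - mean_a)^2 / 2 parts; check via oracle pieces
  ya <- d$y[d$cond == "a"]; yb <- d$y[d$cond == "b"]
  diffs <- yb - ya
  ss_e <- 3 * (mean(diffs) / 2)^2 * 2
  ss_r <- sum((diffs - mean(diffs))^2) / 2
  expect_equal(an$pes, ss_e / (ss_e + ss_r), tolerance = 1e-8)
})

test_that("Bonferroni multiplies and caps at 1", {
  expect_equal(bonferroni(c(0.01, 0.02, 0.03)), c(0.03, 0.06, 0.09))
  expect_equal(bonferroni(0.04, m = 1), 0.04)
  expect_equal(bonferroni(c(0.5, 0.6), m = 3), c(1, 1))

  d <- data.frame(subject = rep(1:4, 3),
                  cond = rep(c("a", "b", "c"), each = 4),
                  y = c(1, 2, 3, 4, 2, 3, 5, 6, 4, 6, 7, 9))
  ph <- posthoc_pairwise(d, "y", "cond", "subject")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, ph$p * 3))
})

test_that("rank statistics match closed forms", {
  kw <- rank_test("kruskal_wallis", c(1, 2, 3, 4, 5, 6),
                  rep(c("g1", "g2"), each = 3))
  expect_equal(kw$statistic, 3.8571, tolerance = 1e-4)

  mw <- rank_test("mann_whitney", c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)

  fr <- rank_test("friedman", rbind(c(1, 2, 3), c(2, 4, 6),
                                    c(1, 5, 9)))
  expect_equal(fr$statistic, 6)

  ws <- rank_test("wilcoxon_signed_rank", c(2, 4, 6), c(1, 2, 3))
  expect_equal(ws$statistic, 0)  # all diffs positive: min rank sum 0

  degen <- rank_test("wilcoxon_signed_rank", c(1, 2), c(1, 2))
  expect_true(degen$degenerate)
})

test_that("U statistics of the two orderings sum to nA * nB", {
  set.seed(42)
  for (i in 1:20) {
    x <- sample(1:10, 5, replace = TRUE)
    y <- sample(1:10, 7, replace = TRUE)
    u1 <- rank_test("mann_whitney", x, y)$statistic
    u2 <- rank_test("mann_whitney", y, x)$statistic
    expect_equal(u1 + u2, length(x) * length(y))
  }
})

test_that("Kruskal-Wallis on two groups agrees with Mann-Whitney", {
  set.seed(43)
  x <- rnorm(12); g <- rep(c("a", "b"), 6)
  kw <- rank_test("kruskal_wallis", x, g)
  mw <- rank_test("mann_whitney", x[g == "a"], x[g == "b"],
                  continuity = FALSE)
  expect_equal(kw$p, mw$p, tolerance = 1e-6)
  # and the statistic agrees with base R exactly
  expect_equal(kw$statistic,
               unname(kruskal.test(x, factor(g))$statistic),
               tolerance = 1e-10)
})

test_that("exact rank-test p-values match full enumeration for small n", {
  # Mann-Whitney / Wilcoxon rank sum: oracle is the exact distribution
  x <- c(1.2, 3.4, 2.2); y <- c(4.1, 5.0, 6.3, 0.5)
  mine <- rank_test("mann_whitney", x, y, exact = TRUE)
  oracle <- wilcox.test(x, y, exact = TRUE)
  expect_equal(mine$p, oracle$p.value, tolerance = 1e-12)

  # signed rank: oracle is wilcox.test's exact two-sided p
  d <- c(1.0, -2.0, 3.0, 4.0, 5.5)
  mine2 <- rank_test("wilcoxon_signed_rank", d, rep(0, 5), exact = TRUE)
  oracle2 <- wilcox.test(d, exact = TRUE)
  expect_equal(mine2$p, oracle2$p.value, tolerance = 1e-12)

  # Kruskal-Wallis: oracle enumerates all label permutations with the
  # base R statistic
  xk <- c(0.3, 1.9, 1.1, 2.8, 0.1, 2.2)
  gk <- factor(rep(c("a", "b", "c"), each = 2))
  mine3 <- rank_test("kruskal_wallis", xk, gk, exact = TRUE)
  perms <- usvscore:::perm_all(6)
  h_obs <- unname(kruskal.test(xk, gk)$statistic)
  h_all <- apply(perms, 1, function(ix)
    unname(kruskal.test(xk[ix], gk)$statistic))
  expect_equal(mine3$p, mean(h_all >= h_obs - 1e-12), tolerance = 1e-12)

  # Friedman: oracle enumerates within-row permutations with base R
  mat <- rbind(c(0.1, 0.9, 0.5), c(1.2, 0.3, 0.8), c(0.2, 0.6, 0.4))
  mine4 <- rank_test("friedman", mat, exact = TRUE)
  p3 <- usvscore:::perm_all(3)
  grid <- expand.grid(1:6, 1:6, 1:6)
  chi_obs <- unname(friedman.test(mat)$statistic)
  chi_all <- apply(grid, 1, function(gi) {
    m2 <- mat
    for (r in 1:3) m2[r, ] <- mat[r, p3[gi[r], ]]
    unname(friedman.test(m2)$statistic)
  })
  expect_equal(mine4$p, mean(chi_all >= chi_obs - 1e-12),
               tolerance = 1e-12)
})

test_that("mixed model recovers a noiseless planted slope exactly", {
  d <- expand.grid(animal = 1:6, sucrose = c(2, 5, 10))
  shifts <- c(-0.2, -0.1, 0, 0.1, 0.2, 0.3)
  d$dcvs <- 0.1 + 0.034 * d$sucrose + shifts[d$animal]
  # noiseless data: the optimizer grumbles about machine precision but
  # the balanced-design slope is exact
  fit <- suppressWarnings(fit_mixed_model(d, "dcvs",
                                          ci_method = "model"))
  expect_equal(fit$slope, 0.034, tolerance = 1e-5)
  expect_true(fit$ci[1] <= fit$slope && fit$slope <= fit$ci[2])
  expect_equal(fit$df, nrow(d) - 6 - 1)
  # robust interval on noiseless data degenerates to the model CI
  fitr <- suppressWarnings(fit_mixed_model(d, "dcvs"))
  expect_equal(fitr$slope, fit$slope, tolerance = 1e-8)
  # with noise, the robust interval uses animal-level df
  set.seed(46)
  d$dcvs <- d$dcvs + rnorm(nrow(d), 0, 0.05)
  fitn <- suppressWarnings(fit_mixed_model(d, "dcvs"))
  expect_equal(fitn$df, 5)
})

test_that("mixed model falls back to pooled regression when singular", {
  # residuals sum to zero within every animal: the between-animal
  # variance component is estimated at exactly zero
  d <- expand.grid(animal = 1:6, sucrose = c(2, 5, 10))
  eps <- c(0.1, -0.1, 0)
  d <- d[order(d$animal), ]
  d$dcvs <- 0.02 * d$sucrose + rep(c(eps, eps[c(2, 3, 1)]), 3)
  expect_warning(fit <- fit_mixed_model(d, "dcvs"), "singular")
  expect_equal(fit$method, "pooled_lm")
  expect_equal(fit$ranef_var, 0)
})

test_that("mixed-model CI covers a zero slope at the nominal rate", {
  set.seed(45)
  n_rep <- 200
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- expand.grid(animal = 1:8, sucrose = c(2, 5, 10))
    d$dcvs <- rnorm(8, 0, 0.08)[d$animal] + rnorm(nrow(d), 0, 0.15)
    fit <- withCallingHandlers(
      fit_mixed_model(d, "dcvs"),
      warning = function(w) invokeRestart("muffleWarning"))
    covered[r] <- fit$ci[1] <= 0 && 0 <= fit$ci[2]
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("Cohen's kappa matches its closed form", {
  expect_equal(cohen_kappa(c("A", "B", "A"), c("A", "B", "A")), 1)
  expect_equal(cohen_kappa(c("A", "A", "B", "B"),
                           c("A", "B", "A", "B")), 0)
  a <- c(rep("A", 50), rep("B", 50))
  b <- c(rep("A", 45), rep("B", 5), rep("A", 5), rep("B", 45))
  expect_equal(cohen_kappa(a, b), 0.8)
  expect_error(cohen_kappa(c("A", "B"), c("A")), "equal length")
  expect_error(cohen_kappa(rep("A", 4), rep("A", 4)), "undefined")
})
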