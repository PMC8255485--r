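#' Student t tests with effect size
#'
#' Thin contract over [stats::t.test()] that also reports Cohen's d
#' (mean difference over the relevant SD) and flags degenerate inputs
#' (zero variance of the tested quantity) instead of returning an
#' infinite statistic.
#'
#' @param mode `"one_sample"`, `"paired"` or `"independent"`.
#' @param x Numeric sample.
#' @param y Second sample (paired/independent modes).
#' @param mu Null value for the one-sample mode (e.g. 50 for an
#'   indifference test on a percentage).
#' @param alternative Passed to [stats::t.test()].
#' @return Tibble: `test`, `statistic`, `df`, `p`, `effect_size`
#'   (Cohen's d), `degenerate`.
#' @export
usv_t_test <- function(mode = c("one_sample", "paired", "independent"),
                       x, y = NULL, mu = 0, alternative = "two.sided") {
  mode <- match.arg(mode)
  if (mode != "one_sample" && is.null(y)) stop("y required for ", mode)
  if (mode == "paired" && length(x) != length(y))
    stop("paired samples must have equal length")
  if (length(x) < 2) stop("need n >= 2")

  dvals <- switch(mode,
    one_sample = x - mu,
    paired = x - y,
    independent = NULL)
  degenerate <- if (mode == "independent") {
    stats::sd(x) == 0 && stats::sd(y) == 0
  } else stats::sd(dvals) == 0

  if (degenerate) {
    return(tibble::tibble(test = paste0(mode, "_t"),
                          statistic = NA_real_, df = NA_real_,
                          p = NA_real_, effect_size = NA_real_,
                          degenerate = TRUE))
  }
  ht <- switch(mode,
    one_sample = stats::t.test(x, mu = mu, alternative = alternative),
    paired = stats::t.test(x, y, paired = TRUE,
                           alternative = alternative),
    independent = stats::t.test(x, y, var.equal = TRUE,
                                alternative = alternative))
  d <- switch(mode,
    one_sample = mean(dvals) / stats::sd(x),
    paired = mean(dvals) / stats::sd(dvals),
    independent = {
      sp <- sqrt(((length(x) - 1) * stats::var(x) +
                    (length(y) - 1) * stats::var(y)) /
                   (length(x) + length(y) - 2))
      (mean(x) - mean(y)) / sp
    })
  tibble::tibble(test = paste0(mode, "_t"),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 effect_size = d, degenerate = FALSE)
}

#' Repeated-measures ANOVA (within-subject factors)
#'
#' Fully within-subject design with one or two factors, fit with
#' [stats::aov()] using the classical `Error(subject/(A*B))` strata; no
#' sphericity correction is applied. Partial eta squared is computed per
#' effect from its stratum sums of squares,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of 1 or 2 within-subject factor
#'   columns.
#' @param subject Name of the subject id column.
#' @return Tibble: one row per effect (`effect`, `df1`, `df2`, `F`, `p`,
#'   `pes` = partial eta squared).
#' @export
rm_anova_within <- function(data, dv, within, subject) {
  stopifnot(length(within) %in% 1:2)
  df <- data.frame(
    y = data[[dv]],
    subject = factor(data[[subject]])
  )
  for (i in seq_along(within)) df[[within[i]]] <- factor(data[[within[i]]])
  if (any(is.na(df$y))) stop("missing DV values: design incomplete")
  cells <- do.call(table, c(list(df$subject), df[within]))
  if (any(cells != 1))
    stop("design must be complete and balanced: every subject x cell ",
         "exactly once")

  rhs <- paste(within, collapse = "*")
  form <- stats::as.formula(
    paste0("y ~ ", rhs, " + Error(subject/(", rhs, "))"))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)

  ss_tot <- sum((df$y - mean(df$y))^2)
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    err <- which(rn == "Residuals")
    if (!length(err)) next
    for (i in setdiff(seq_along(rn), err)) {
      ss_e <- tab[i, "Sum Sq"]; ss_r <- tab[err, "Sum Sq"]
      fv <- tab[i, "F value"]; pv <- tab[i, "Pr(>F)"]
      pes <- ss_e / (ss_e + ss_r)
      if (ss_e <= 1e-12 * max(ss_tot, 1)) {
        # effect sums of squares numerically zero: a constant DV within
        # the factor, not evidence either way
        fv <- 0; pv <- 1; pes <- 0
      }
      out[[rn[i]]] <- tibble::tibble(
        effect = rn[i],
        df1 = tab[i, "Df"], df2 = tab[err, "Df"],
        F = fv, p = pv, pes = pes)
    }
  }
  do.call(rbind, out)
}

#' Pairwise post hoc paired t tests with Bonferroni correction
#'
#' All level pairs of a within-subject factor, each a paired t test
#' across subjects, with `p_adj = min(1, p * m)` where `m` is the number
#' of pairs.
#'
#' @inheritParams rm_anova_within
#' @param factor_col Name of the factor column.
#' @return Tibble: `level_a`, `level_b`, `statistic`, `df`, `p`, `p_adj`,
#'   `effect_size`.
#' @export
posthoc_pairwise <- function(data, dv, factor_col, subject) {
  f <- factor(data[[factor_col]])
  levs <- levels(f)
  if (length(levs) < 2) stop("need >= 2 levels")
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  rows <- list()
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    da <- data[f == a, ]; db <- data[f == b, ]
    ord_a <- order(da[[subject]]); ord_b <- order(db[[subject]])
    tt <- usv_t_test("paired", da[[dv]][ord_a], db[[dv]][ord_b])
    rows[[j]] <- tibble::tibble(level_a = a, level_b = b,
                                statistic = tt$statistic, df = tt$df,
                                p = tt$p, p_adj = pmin(1, tt$p * m),
                                effect_size = tt$effect_size)
  }
  do.call(rbind, rows)
}

#' Bonferroni correction
#'
#' @param p Vector of raw p-values.
#' @param m Number of comparisons (defaults to `length(p)`).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

# ---- rank tests -----------------------------------------------------------

midranks <- function(x) rank(x, ties.method = "average")

kw_statistic <- function(values, groups) {
  r <- midranks(values)
  n <- length(values)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  # tie correction
  ties <- table(values)
  ct <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (ct > 0) h <- h / ct
  h
}

mw_statistic <- function(x, y) {
  # U of x over y with midrank ties
  r <- midranks(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

wsr_statistic <- function(d) {
  # smaller of the signed-rank sums over nonzero differences
  d <- d[d != 0]
  r <- midranks(abs(d))
  min(sum(r[d > 0]), sum(r[d < 0]))
}

friedman_statistic <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  r <- t(apply(mat, 1, midranks))
  rs <- colSums(r)
  12 / (n * k * (k + 1)) * sum(rs^2) - 3 * n * (k + 1)
}

# enumerate all distinct assignments of n items into groups of given
# sizes; returns a matrix with one group-label vector per row
multinom_groupings <- function(n, sizes) {
  res <- list()
  rec <- function(avail, si, labels) {
    if (si == length(sizes)) {
      labels[avail] <- si
      res[[length(res) + 1]] <<- labels
      return(invisible(NULL))
    }
    picks <- utils::combn(length(avail), sizes[si])
    for (j in seq_len(ncol(picks))) {
      lab2 <- labels
      chosen <- avail[picks[, j]]
      lab2[chosen] <- si
      rec(setdiff(avail, chosen), si + 1, lab2)
    }
  }
  rec(seq_len(n), 1, integer(n))
  do.call(rbind, res)
}

#' Rank-based tests with exact small-sample option
#'
#' One entry point for the nonparametric battery: Kruskal-Wallis (between
#' groups), Mann-Whitney U, Wilcoxon signed rank (paired), Friedman
#' (subjects x conditions). Ties take midranks. Below `exact_cutoff`
#' observations the null distribution is enumerated exhaustively
#' (group-label permutations, sign flips, or within-row rank
#' permutations); above it the usual asymptotic approximation is used
#' (the default, with continuity correction where standard).
#'
#' @param kind `"kruskal_wallis"`, `"mann_whitney"`,
#'   `"wilcoxon_signed_rank"` or `"friedman"`.
#' @param x First sample; for `kruskal_wallis` the value vector; for
#'   `friedman` a subjects x conditions matrix.
#' @param y Second sample (`mann_whitney`, `wilcoxon_signed_rank`), or
#'   the group factor (`kruskal_wallis`).
#' @param exact `TRUE`, `FALSE`, or `NULL` to decide by `exact_cutoff`.
#' @param exact_cutoff Maximum total n for automatic exact mode when
#'   `exact = NULL`; the asymptotic path stays the default (`FALSE`).
#' @param continuity Apply the continuity correction in the asymptotic
#'   Mann-Whitney and signed-rank approximations (default `TRUE`;
#'   without it a two-group Kruskal-Wallis and Mann-Whitney give the
#'   same asymptotic p).
#' @return Tibble: `test`, `statistic`, `df` (where defined), `p`,
#'   `method`, `degenerate`.
#' @export
rank_test <- function(kind = c("kruskal_wallis", "mann_whitney",
                               "wilcoxon_signed_rank", "friedman"),
                      x, y = NULL, exact = FALSE, exact_cutoff = 10,
                      continuity = TRUE) {
  kind <- match.arg(kind)
  res <- switch(kind,
    kruskal_wallis = {
      groups <- factor(y)
      n <- length(x)
      h <- kw_statistic(x, groups)
      df <- nlevels(groups) - 1
      use_exact <- isTRUE(exact) ||
        (is.null(exact) && n <= exact_cutoff)
      p <- if (use_exact) {
        sizes <- as.integer(table(groups))
        gr <- multinom_groupings(n, sizes)
        all_h <- apply(gr, 1, function(g) kw_statistic(x, factor(g)))
        mean(all_h >= h - 1e-12)
      } else stats::pchisq(h, df, lower.tail = FALSE)
      list(stat = h, df = df, p = p,
           method = if (use_exact) "exact" else "asymptotic",
           degenerate = FALSE)
    },
    mann_whitney = {
      u <- mw_statistic(x, y)
      n <- length(x) + length(y)
      use_exact <- isTRUE(exact) ||
        (is.null(exact) && n <= exact_cutoff)
      if (use_exact) {
        all_u <- {
          pool <- c(x, y)
          sel <- utils::combn(n, length(x))
          apply(sel, 2, function(ix)
            mw_statistic(pool[ix], pool[-ix]))
        }
        p <- min(1, 2 * min(mean(all_u >= u - 1e-12),
                            mean(all_u <= u + 1e-12)))
        list(stat = u, df = NA_real_, p = p, method = "exact",
             degenerate = FALSE)
      } else {
        ht <- suppressWarnings(
          stats::wilcox.test(x, y, exact = FALSE, correct = continuity))
        list(stat = u, df = NA_real_, p = ht$p.value,
             method = "asymptotic", degenerate = FALSE)
      }
    },
    wilcoxon_signed_rank = {
      if (is.null(y)) y <- rep(0, length(x))
      d <- x - y
      if (all(d == 0)) {
        list(stat = NA_real_, df = NA_real_, p = NA_real_,
             method = "degenerate", degenerate = TRUE)
      } else {
        w <- wsr_statistic(d)
        nz <- sum(d != 0)
        use_exact <- isTRUE(exact) ||
          (is.null(exact) && nz <= exact_cutoff)
        if (use_exact) {
          dnz <- d[d != 0]
          r <- midranks(abs(dnz))
          signs <- as.matrix(expand.grid(
            rep(list(c(-1, 1)), length(dnz))))
          all_w <- apply(signs, 1, function(s)
            min(sum(r[s > 0]), sum(r[s < 0])))
          p <- mean(all_w <= w + 1e-12)
          list(stat = w, df = NA_real_, p = p, method = "exact",
               degenerate = FALSE)
        } else {
          ht <- suppressWarnings(
            stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                               correct = continuity))
          list(stat = w, df = NA_real_, p = ht$p.value,
               method = "asymptotic", degenerate = FALSE)
        }
      }
    },
    friedman = {
      mat <- as.matrix(x)
      chi <- friedman_statistic(mat)
      k <- ncol(mat)
      use_exact <- isTRUE(exact) ||
        (is.null(exact) && nrow(mat) * k <= exact_cutoff)
      p <- if (use_exact) {
        rows_perms <- perm_all(k)
        grid_idx <- as.matrix(expand.grid(
          rep(list(seq_len(nrow(rows_perms))), nrow(mat))))
        all_chi <- apply(grid_idx, 1, function(gi) {
          m2 <- mat
          for (r in seq_len(nrow(mat)))
            m2[r, ] <- mat[r, rows_perms[gi[r], ]]
          friedman_statistic(m2)
        })
        mean(all_chi >= chi - 1e-12)
      } else stats::pchisq(chi, k - 1, lower.tail = FALSE)
      list(stat = chi, df = k - 1, p = p,
           method = if (use_exact) "exact" else "asymptotic",
           degenerate = FALSE)
    })
  tibble::tibble(test = kind, statistic = res$stat, df = res$df,
                 p = res$p, method = res$method,
                 degenerate = res$degenerate)
}

# all permutations of 1..n as a matrix (n! rows); n kept small by callers
perm_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_all(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Random-intercept mixed linear model of delta scores on sucrose level
#'
#' Gaussian linear mixed model fit by REML with [lme4::lmer()]: the delta
#' score (dCVS or per-subtype dSVS) as DV, sucrose concentration (numeric
#' %) as the fixed effect, animal as random intercept. Two Wald-type
#' intervals for the slope are available: `"robust"` (the default) uses a
#' cluster-robust sandwich covariance over animals with t quantiles on
#' `n_animals - 1` df — occupancy-driven heteroscedasticity across
#' conditions makes the model-based interval slightly anticonservative —
#' while `"model"` uses the model covariance with t quantiles on
#' `N - n_animals - 1` df (the within-animal residual df of the balanced
#' design). Marginal R-squared follows Nakagawa: variance of the
#' fixed-effect predictions over the total (fixed + random-intercept +
#' residual) variance. If the random-intercept variance collapses to
#' zero (singular fit), the model falls back to a pooled ordinary
#' regression with a warning.
#'
#' @param data Data frame with one row per animal x condition.
#' @param dv Name of the DV column.
#' @param fixed Name of the numeric predictor column (sucrose %).
#' @param group Name of the animal id column.
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"robust"` (cluster-robust sandwich over animals) or
#'   `"model"` (model-based covariance).
#' @return A `mixed_fit` list: `intercept`, `slope`, `se`, `ci` (length
#'   2), `t`, `df`, `p`, `ranef_var`, `resid_var`, `r2_marginal`,
#'   `singular`, `method`, `ci_method`.
#' @export
fit_mixed_model <- function(data, dv, fixed = "sucrose",
                            group = "animal", conf_level = 0.95,
                            ci_method = c("robust", "model")) {
  ci_method <- match.arg(ci_method)
  df <- data.frame(y = data[[dv]], x = data[[fixed]],
                   g = factor(data[[group]]))
  df <- df[stats::complete.cases(df), ]
  n_per <- tapply(df$x, df$g, function(v) length(unique(v)))
  if (any(n_per < 2)) stop("need >= 2 conditions per animal")
  n <- nrow(df); k <- nlevels(df$g)
  ddf <- n - k - 1

  fit <- suppressMessages(
    lme4::lmer(y ~ x + (1 | g), data = df, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("random-intercept variance is singular; ",
            "falling back to pooled regression")
    lmfit <- stats::lm(y ~ x, data = df)
    co <- summary(lmfit)$coefficients
    beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    intercept <- co["(Intercept)", "Estimate"]
    ranef_var <- 0
    resid_var <- summary(lmfit)$sigma^2
    fixed_pred <- stats::fitted(lmfit)
    method <- "pooled_lm"
  } else {
    fe <- lme4::fixef(fit)
    vc <- lme4::VarCorr(fit)
    ranef_var <- as.numeric(vc$g)
    resid_var <- attr(vc, "sc")^2
    # fixed-effect covariance: prefer lme4's, else the closed-form GLS
    # (X' Sigma^-1 X)^-1 at the estimated variance components, which for
    # a random intercept is computable group by group
    vc_f <- tryCatch(as.matrix(stats::vcov(fit)), error = function(e) {
      xtsx <- matrix(0, 2, 2)
      for (gl in levels(df$g)) {
        xg <- cbind(1, df$x[df$g == gl])
        ng <- nrow(xg)
        cst <- ranef_var / (resid_var + ng * ranef_var)
        xtsx <- xtsx +
          (crossprod(xg) - cst * tcrossprod(colSums(xg))) / resid_var
      }
      v <- solve(xtsx)
      dimnames(v) <- list(c("(Intercept)", "x"), c("(Intercept)", "x"))
      v
    })
    beta <- fe[["x"]]; se <- sqrt(vc_f["x", "x"])
    intercept <- fe[["(Intercept)"]]
    fixed_pred <- stats::model.matrix(fit) %*% lme4::fixef(fit)
    method <- "lmer_reml"
  }

  if (ci_method == "robust") {
    # cluster-robust sandwich around the GLS estimate: per-animal score
    # outer products with the GLS weights implied by the fitted variance
    # components (identity weights when the fit fell back to OLS)
    bread <- matrix(0, 2, 2); meat <- matrix(0, 2, 2)
    res_all <- df$y - cbind(1, df$x) %*% c(intercept, beta)
    for (gl in levels(df$g)) {
      i <- df$g == gl
      xg <- cbind(1, df$x[i]); ng <- nrow(xg)
      cst <- ranef_var / (resid_var + ng * ranef_var)
      wg <- (diag(ng) - matrix(cst, ng, ng)) / resid_var  # Sigma_g^-1
      bread <- bread + t(xg) %*% wg %*% xg
      sg <- t(xg) %*% wg %*% res_all[i]
      meat <- meat + tcrossprod(sg)
    }
    se_cr <- tryCatch({
      bi <- solve(bread)
      v_cr <- bi %*% meat %*% bi * k / (k - 1)
      sqrt(v_cr[2, 2])
    }, error = function(e) NA_real_)
    if (is.finite(se_cr) && se_cr > 0) {
      se_use <- se_cr
      ddf_use <- k - 1
    } else {
      # degenerate weights (e.g. zero residual variance): model-based CI
      se_use <- se
      ddf_use <- ddf
    }
  } else {
    se_use <- se
    ddf_use <- ddf
  }
  tval <- beta / se_use
  p <- 2 * stats::pt(-abs(tval), ddf_use)
  tq <- stats::qt(1 - (1 - conf_level) / 2, ddf_use)
  var_f <- stats::var(as.numeric(fixed_pred))
  r2m <- var_f / (var_f + ranef_var + resid_var)
  structure(list(intercept = intercept, slope = beta, se = se_use,
                 se_model = se,
                 ci = c(beta - tq * se_use, beta + tq * se_use),
                 t = tval, df = ddf_use, p = p,
                 ranef_var = ranef_var, resid_var = resid_var,
                 r2_marginal = r2m, singular = singular,
                 method = method, ci_method = ci_method,
                 n = n, n_groups = k),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept model (%s): slope = %.4f, 95%% CI [%.4f, %.4f]\n",
    x$method, x$slope, x$ci[1], x$ci[2]))
  cat(sprintf("  t(%d) = %.2f, p = %.4g, marginal R2 = %.3f\n",
              x$df, x$t, x$p, x$r2_marginal))
  invisible(x)
}

#' Cohen's kappa for inter-rater agreement
#'
#' `(p_o - p_e) / (1 - p_e)` over two equal-length categorical label
#' sequences, with chance agreement from the raters' marginal label
#' frequencies.
#'
#' @param labels_a,labels_b Categorical vectors of equal length.
#' @return Kappa in `[-1, 1]`; error when chance agreement is 1.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label sequences must have equal length")
  n <- length(labels_a)
  if (n == 0) stop("empty label sequences")
  levs <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = levs)
  b <- factor(labels_b, levels = levs)
  po <- mean(a == b)
  pe <- sum(table(a) / n * table(b) / n)
  if (abs(1 - pe) < 1e-12) stop("chance agreement is 1: kappa undefined")
  (po - pe) / (1 - pe)
}
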