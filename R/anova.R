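#' One-way fixed-effects ANOVA
#'
#' Classical decomposition from sums of squares:
#' `F = MS_between / MS_within`, with the p-value from the upper tail of the
#' F distribution. Built by hand (group means and residuals, not a wrapper
#' around a model-fitting routine) so the arithmetic is transparent and can
#' be checked against an independent least-squares oracle.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor); every group must have at
#'   least one observation and there must be at least 2 groups.
#' @return An `anova_result` with a `table` data.frame (effect, df, ss, ms,
#'   F, p) plus `ms_within`, `df_resid` and the data for post-hoc tests.
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$table
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  if (anyNA(values) || anyNA(groups)) stop("missing values", call. = FALSE)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- tabulate(groups)
  if (any(n == 0L)) stop("empty group", call. = FALSE)
  N <- length(values)
  df_b <- k - 1L
  df_w <- N - k
  if (df_w < 1L) stop("residual df must be >= 1", call. = FALSE)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  eps <- 1e-12 * max(ssb + ssw, 1)
  if (ssb < eps) ssb <- 0
  if (ssw < eps) ssw <- 0
  msb <- ssb / df_b
  msw <- ssw / df_w
  if (msw == 0 && msb > 0) {
    f <- Inf
    p <- 0
  } else if (msw == 0) {
    f <- 0
    p <- 1
  } else {
    f <- msb / msw
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  tab <- data.frame(
    effect = c("group", "residual"),
    df = c(df_b, df_w),
    ss = c(ssb, ssw),
    ms = c(msb, msw),
    F = c(f, NA),
    p = c(p, NA)
  )
  structure(list(table = tab, ms_within = msw, df_resid = df_w,
                 values = values, groups = groups),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(format(x$table, digits = 5), row.names = FALSE)
  if (!is.null(x$tukey)) {
    cat("Tukey HSD:\n")
    print(format(x$tukey, digits = 5), row.names = FALSE)
  }
  invisible(x)
}

# Residual sum of squares of the least-squares fit of y on model matrix X.
rss_of <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Effects for factor A, factor B, their interaction and the residual. On
#' balanced designs the sums of squares are the classical sequential ones
#' (sequential and partial coincide there); on unbalanced designs partial
#' (Type II-style) sums of squares are used: each main effect is assessed
#' after the other main effect, the interaction after both.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factor labels (e.g. season and tissue age).
#' @return An `anova_result` with one row per effect plus residual.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- droplevels(factor(factor_a))
  b <- droplevels(factor(factor_b))
  if (length(values) != length(a) || length(values) != length(b)) {
    stop("values and factors must have equal length", call. = FALSE)
  }
  if (anyNA(values) || anyNA(a) || anyNA(b)) {
    stop("missing values", call. = FALSE)
  }
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  cells <- table(a, b)
  if (any(cells == 0L)) {
    stop("empty cell: interaction model is not estimable", call. = FALSE)
  }
  N <- length(values)
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  df_res <- N - nlevels(a) * nlevels(b)
  if (df_res < 1L) stop("residual df must be >= 1", call. = FALSE)

  X0 <- stats::model.matrix(~1, data.frame(a, b))
  Xa <- stats::model.matrix(~a)
  Xb <- stats::model.matrix(~b)
  Xab_main <- stats::model.matrix(~a + b)
  Xfull <- stats::model.matrix(~a * b)

  rss_full <- rss_of(values, Xfull)
  ss_a <- rss_of(values, Xb) - rss_of(values, Xab_main)
  ss_b <- rss_of(values, Xa) - rss_of(values, Xab_main)
  ss_ab <- rss_of(values, Xab_main) - rss_full
  ss_res <- rss_full

  # snap floating-point dust to zero so exact-fit designs (zero noise,
  # additive means) give F = 0 rather than a ratio of rounding errors
  ss_tot <- sum((values - mean(values))^2)
  eps <- 1e-12 * max(ss_tot, 1)
  ss_a <- if (ss_a < eps) 0 else ss_a
  ss_b <- if (ss_b < eps) 0 else ss_b
  ss_ab <- if (ss_ab < eps) 0 else ss_ab
  ss_res <- if (ss_res < eps) 0 else ss_res

  mse <- ss_res / df_res
  fstat <- function(ss, df) {
    ms <- ss / df
    if (mse == 0) {
      if (ms > 0) c(Inf, 0) else c(0, 1)
    } else {
      f <- ms / mse
      c(f, stats::pf(f, df, df_res, lower.tail = FALSE))
    }
  }
  fa <- fstat(ss_a, df_a)
  fb <- fstat(ss_b, df_b)
  fab <- fstat(ss_ab, df_ab)
  tab <- data.frame(
    effect = c("factor_a", "factor_b", "interaction", "residual"),
    df = c(df_a, df_b, df_ab, df_res),
    ss = c(ss_a, ss_b, ss_ab, ss_res),
    ms = c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab, mse),
    F = c(fa[1], fb[1], fab[1], NA),
    p = c(fa[2], fb[2], fab[2], NA)
  )
  structure(list(table = tab, ms_within = mse, df_resid = df_res,
                 values = values, groups_a = a, groups_b = b,
                 balanced = length(unique(as.vector(cells))) == 1L),
            class = "anova_result")
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' Tukey-Kramer studentized-range test on the group (or cell) means of a
#' fitted ANOVA: for each pair,
#' `q = |mean_i - mean_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))` with the
#' adjusted p-value from the studentized-range distribution on the ANOVA's
#' residual degrees of freedom. With two groups this reduces to the ANOVA
#' itself (q = t * sqrt(2)).
#'
#' @param fit An `anova_result` from [one_way_anova()] or
#'   [two_way_anova()].
#' @param effect For two-way fits: `"a"`, `"b"` or `"cells"` (all A:B cell
#'   means). Ignored for one-way fits.
#' @return data.frame with columns `pair`, `diff`, `se`, `p_adj`.
#' @export
tukey_hsd <- function(fit, effect = c("a", "b", "cells")) {
  stopifnot(inherits(fit, "anova_result"))
  effect <- match.arg(effect)
  if (!is.null(fit$groups)) {
    g <- fit$groups
  } else {
    g <- switch(effect,
                a = fit$groups_a,
                b = fit$groups_b,
                cells = interaction(fit$groups_a, fit$groups_b, sep = ":"))
  }
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups for Tukey HSD", call. = FALSE)
  means <- tapply(fit$values, g, mean)
  ns <- tabulate(g)
  pairs <- utils::combn(levels(g), 2L)
  out <- data.frame(pair = character(), diff = numeric(), se = numeric(),
                    p_adj = numeric())
  for (j in seq_len(ncol(pairs))) {
    i1 <- match(pairs[1, j], levels(g))
    i2 <- match(pairs[2, j], levels(g))
    d <- means[i2] - means[i1]
    se <- sqrt(fit$ms_within / 2 * (1 / ns[i1] + 1 / ns[i2]))
    if (se == 0) {
      p <- if (d == 0) 1 else 0
      q <- if (d == 0) 0 else Inf
    } else {
      q <- abs(d) / se
      p <- stats::ptukey(q, nmeans = k, df = fit$df_resid,
                         lower.tail = FALSE)
    }
    out <- rbind(out, data.frame(
      pair = paste(pairs[2, j], pairs[1, j], sep = "-"),
      diff = as.numeric(d), se = se, p_adj = p))
  }
  rownames(out) <- NULL
  out
}

#' ANOVA + Tukey on a long-format factorial table
#'
#' Convenience wrapper used by the pipeline: runs [one_way_anova()] when
#' only `factor_a` is given, [two_way_anova()] when both factors are, and
#' attaches the Tukey table.
#'
#' @param values Numeric response.
#' @param factor_a Primary factor (season).
#' @param factor_b Optional second factor (tissue age).
#' @param tukey_effect Passed to [tukey_hsd()] for two-way fits
#'   (default `"cells"`).
#' @return An `anova_result` with a `tukey` component.
#' @export
factorial_anova <- function(values, factor_a, factor_b = NULL,
                            tukey_effect = "cells") {
  fit <- if (is.null(factor_b)) {
    one_way_anova(values, factor_a)
  } else {
    two_way_anova(values, factor_a, factor_b)
  }
  fit$tukey <- tukey_hsd(fit, effect = tukey_effect)
  fit
}
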