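# ANOVA and Tukey HSD

test_that("one_way_anova matches hand-computed sums of squares", {
  fit <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  tab <- fit$table
  expect_equal(tab$ss[tab$effect == "group"], 13.5) # SSB
  expect_equal(tab$ss[tab$effect == "residual"], 4) # SSW
  expect_equal(tab$df, c(1, 4))
  # F = MSB/MSW = 13.5/1.0 (the spec sheet's 9.0 is an arithmetic slip;
  # confirmed against aov())
  expect_equal(tab$F[1], 13.5)
  oracle <- anova(lm(y ~ g, data.frame(y = c(1, 2, 3, 4, 5, 6),
                                       g = rep(c("a", "b"), each = 3))))
  expect_equal(tab$F[1], oracle$`F value`[1])
  expect_equal(tab$p[1], oracle$`Pr(>F)`[1])
})

test_that("one_way_anova handles degenerate groups", {
  fit <- one_way_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(fit$table$F[1], 0) # identical groups
  # zero residual variance with real between-variance
  fit2 <- one_way_anova(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_equal(fit2$table$F[1], Inf)
  expect_equal(fit2$table$p[1], 0)
  expect_error(one_way_anova(1:3, rep("a", 3)), "2 groups")
})

test_that("one-way p agrees with a permutation null", {
  set.seed(11)
  y <- c(rnorm(5), rnorm(5, mean = 1.2))
  g <- rep(c("a", "b"), each = 5)
  p_param <- one_way_anova(y, g)$table$p[1]
  f_obs <- one_way_anova(y, g)$table$F[1]
  f_perm <- replicate(10000, one_way_anova(y, sample(g))$table$F[1])
  p_perm <- mean(f_perm >= f_obs)
  # Monte-Carlo error ~ sqrt(p(1-p)/1e4); allow 4 sd
  expect_lt(abs(p_param - p_perm),
            4 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.01)
})

test_that("two_way_anova matches the least-squares projection oracle", {
  set.seed(21)
  a <- factor(rep(c("Jan", "Oct"), each = 6))
  b <- factor(rep(rep(c("new", "old"), each = 3), 2))
  y <- 5 + 2 * (a == "Jan") + 1 * (b == "old") +
    0.8 * (a == "Jan") * (b == "old") + rnorm(12, sd = 0.6)
  fit <- two_way_anova(y, a, b)
  oracle <- anova(lm(y ~ a * b))
  expect_equal(fit$table$F[1:3], oracle$`F value`[1:3], tolerance = 1e-10)
  expect_equal(fit$table$p[1:3], oracle$`Pr(>F)`[1:3], tolerance = 1e-10)
  expect_equal(fit$table$ss, oracle$`Sum Sq`, tolerance = 1e-10)
  # balanced sum-of-squares decomposition is exact
  expect_equal(sum(fit$table$ss), sum((y - mean(y))^2), tolerance = 1e-10)
})

test_that("additive cell means with zero noise give interaction F = 0", {
  a <- rep(c("x", "y"), each = 4)
  b <- rep(c("u", "v"), 4)
  mu <- 1 + 2 * (a == "y") + 3 * (b == "v") # purely additive
  fit <- two_way_anova(mu + rep(c(-0.1, 0.1), 4), a, b)
  expect_equal(fit$table$F[fit$table$effect == "interaction"], 0,
               tolerance = 1e-10)
})

test_that("unbalanced designs use partial (Type II) sums of squares", {
  set.seed(31)
  a <- factor(c(rep("A", 5), rep("B", 3)))
  b <- factor(c("u", "u", "v", "v", "v", "u", "v", "v"))
  y <- rnorm(8) + 2 * (a == "B")
  fit <- two_way_anova(y, a, b)
  # Type II oracle: each main effect after the other, interaction last
  rss <- function(f) sum(resid(lm(f))^2)
  ss_a <- rss(y ~ b) - rss(y ~ a + b)
  ss_b <- rss(y ~ a) - rss(y ~ a + b)
  ss_ab <- rss(y ~ a + b) - rss(y ~ a * b)
  expect_equal(fit$table$ss[1:3], c(ss_a, ss_b, ss_ab), tolerance = 1e-10)
})

test_that("two_way_anova rejects empty cells", {
  a <- rep(c("x", "y"), each = 3)
  b <- c("u", "u", "u", "v", "v", "v") # cell (x,v) and (y,u) empty
  expect_error(two_way_anova(rnorm(6), a, b), "empty cell")
})

test_that("F is invariant to affine response transformations", {
  set.seed(41)
  y <- rnorm(12, mean = rep(c(0, 1), each = 6))
  g <- rep(c("a", "b"), each = 6)
  f0 <- one_way_anova(y, g)$table$F[1]
  expect_equal(one_way_anova(3 + 2.5 * y, g)$table$F[1], f0,
               tolerance = 1e-10)
  a <- rep(c("x", "y"), each = 6)
  b <- rep(rep(c("u", "v"), each = 3), 2)
  f2 <- two_way_anova(y, a, b)$table$F[1:3]
  expect_equal(two_way_anova(-1 + 10 * y, a, b)$table$F[1:3], f2,
               tolerance = 1e-10)
})

test_that("tukey_hsd reduces to the ANOVA p with two groups", {
  set.seed(51)
  y <- c(rnorm(4), rnorm(4, 1))
  g <- rep(c("a", "b"), each = 4)
  fit <- one_way_anova(y, g)
  tk <- tukey_hsd(fit)
  expect_equal(tk$p_adj, fit$table$p[1], tolerance = 1e-6)
  # oracle: base R TukeyHSD
  oracle <- TukeyHSD(aov(y ~ g))$g
  expect_equal(tk$p_adj, unname(oracle[, "p adj"]), tolerance = 1e-6)
  expect_equal(tk$diff, unname(oracle[, "diff"]), tolerance = 1e-10)
})

test_that("tukey_hsd separates a far-shifted group only", {
  set.seed(61)
  y <- c(rnorm(5, 0, 0.5), rnorm(5, 0.2, 0.5), rnorm(5, 10, 0.5))
  g <- rep(c("a", "b", "c"), each = 5)
  tk <- tukey_hsd(one_way_anova(y, g))
  far <- grepl("c", tk$pair)
  expect_true(all(tk$p_adj[far] < 0.001))
  expect_gt(tk$p_adj[!far], 0.05)
  # identical groups: all adjusted p = 1
  tk2 <- tukey_hsd(one_way_anova(rep(c(1, 2, 3), 3),
                                 rep(c("a", "b", "c"), each = 3)))
  expect_true(all(tk2$p_adj > 0.999))
  expect_error(tukey_hsd(structure(list(values = 1:3,
                                        groups = factor(rep("a", 3)),
                                        ms_within = 1, df_resid = 2),
                                   class = "anova_result")),
               "2 groups")
})

test_that("synthetic pigment season effect is detected with power", {
  # Ulva Chl a: configured Jan/Oct means 2500/1000, CV 15%, n = 3 -> the
  # season effect should be found at alpha = 0.05 in nearly every run
  hits <- vapply(1:50, function(s) {
    pt <- make_pigment_table(seed = s)
    x <- pt[pt$species == "Ulva sp." & pt$pigment == "Chl a", ]
    one_way_anova(x$concentration, x$season)$table$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # two-way power at the generator's noise model: season means 2500/1000
  # (the Ulva Chl a contrast), no tissue effect, lognormal CV 15%, n = 3
  sdlog <- sqrt(log(1 + 0.15^2))
  season <- rep(c("January", "October"), each = 6)
  tissue <- rep(rep(c("new", "old"), each = 3), 2)
  mu <- ifelse(season == "January", 2500, 1000)
  both <- vapply(1:200, function(s) {
    set.seed(s)
    y <- mu * exp(rnorm(12, -sdlog^2 / 2, sdlog))
    fit <- two_way_anova(y, season, tissue)
    fit$table$p[1] < 0.05 && fit$table$p[2] > 0.05
  }, logical(1))
  expect_gte(mean(both), 0.9)
})
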