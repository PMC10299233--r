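test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(8)
  d <- data.frame(g = rep(c("a", "b"), each = 9), y = rnorm(18))
  d$y[d$g == "b"] <- d$y[d$g == "b"] + 0.8
  fit <- anova_factorial(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tidy(fit)$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(tidy(fit)$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("a shifted factor is detected with overwhelming evidence", {
  set.seed(3)
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:50)
  d$y <- rnorm(nrow(d)) + 2 * (d$a == "x")
  tab <- tidy(anova_factorial(d, "y", c("a", "b")))
  expect_lt(tab$p_value[tab$term == "a"], 0.001)
  expect_equal(tab$stars[tab$term == "a"], "***")
})

test_that("unbalanced designs report their sum-of-squares convention", {
  set.seed(10)
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:6)
  d <- d[-(1:5), ]  # unbalance the cells
  d$y <- rnorm(nrow(d))
  f2 <- anova_factorial(d, "y", c("a", "b"))
  expect_false(f2$balanced)
  expect_equal(f2$ss_type, "II")
  expect_equal(glance(f2)$ss_type, "II")
  f1 <- anova_factorial(d, "y", c("a", "b"), ss_type = "I")
  f3 <- anova_factorial(d, "y", c("a", "b"), ss_type = "III")
  # conventions genuinely differ on unbalanced data
  expect_false(isTRUE(all.equal(tidy(f1)$sumsq, tidy(f2)$sumsq)))
  expect_equal(nrow(tidy(f3)), 3)
})

test_that("degenerate designs are rejected", {
  d <- data.frame(g = rep("a", 10), y = rnorm(10))
  expect_error(anova_factorial(d, "y", "g"), "single observed level")
  d2 <- data.frame(g = c("a", "b"), y = rnorm(2))
  expect_error(anova_factorial(d2, "y", "g"), "residual degrees")
})

test_that("ANOVA p-values agree with a permutation oracle on small data", {
  set.seed(15)
  y <- rnorm(12)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  y[g == "c"] <- y[g == "c"] + 1.2
  p_perm <- perm_anova_p(y, g, B = 4000)
  p_aov <- tidy(anova_factorial(data.frame(y = y, g = g), "y", "g"))$p_value
  expect_lt(abs(p_perm - p_aov), 0.05)
})

test_that("Tukey on two equal groups reduces to the pooled t-test", {
  set.seed(21)
  d <- data.frame(g = rep(c("a", "b"), each = 10), y = rnorm(20))
  tk <- tukey_kramer(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tk$adj_p, tt$p.value, tolerance = 1e-9)
})

test_that("identical group means give zero differences and p = 1", {
  base <- data.frame(g = rep(c("a", "b", "c"), each = 4), y = rep(1:4, 3))
  tk <- tukey_kramer(base, "y", "g")
  expect_equal(tk$mean_diff, rep(0, 3), tolerance = 1e-12)
  expect_equal(tk$adj_p, rep(1, 3), tolerance = 1e-12)
  expect_true(all(tk$stars == "ns"))
})

test_that("a 5 SD shifted group is flagged *** against both others", {
  set.seed(33)
  d <- data.frame(
    g = rep(c("a", "b", "c"), each = 20),
    y = c(rnorm(20), rnorm(20), rnorm(20) + 5)
  )
  tk <- tukey_kramer(d, "y", "g")
  vs_c <- tk[tk$level_a == "c" | tk$level_b == "c", ]
  expect_true(all(vs_c$stars == "***"))
})

test_that("Tukey-Kramer adjustment never undercuts the unadjusted p", {
  set.seed(44)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    n <- sample(4:9, k, replace = TRUE)
    d <- data.frame(
      g = factor(rep(letters[1:k], times = n)),
      y = rnorm(sum(n), mean = rep(runif(k, 0, 2), times = n))
    )
    tk <- tukey_kramer(d, "y", "g")
    fit <- aov(y ~ g, data = d)
    mse <- summary(fit)[[1]]$`Mean Sq`[2]
    dfr <- fit$df.residual
    means <- tapply(d$y, d$g, mean)
    cnts <- tapply(d$y, d$g, length)
    pairs <- combn(levels(d$g), 2)
    p_unadj <- apply(pairs, 2, function(pr) {
      se <- sqrt(mse * (1 / cnts[pr[1]] + 1 / cnts[pr[2]]))
      2 * pt(-abs((means[pr[2]] - means[pr[1]]) / se), dfr)
    })
    expect_true(all(tk$adj_p >= p_unadj - 1e-12), info = paste("dataset", i))
  }
})

test_that("Tukey input validation matches the contract", {
  d <- data.frame(g = c("a", "a", "b"), y = 1:3)
  expect_error(tukey_kramer(d, "y", "g"), "at least 2 observations")
  d1 <- data.frame(g = rep("a", 4), y = 1:4)
  expect_error(tukey_kramer(d1, "y", "g"), "at least 2 levels")
})

test_that("star mapping follows the conventional legend exactly", {
  p <- c(0.2, 0.0501, 0.05, 0.049, 0.011, 0.01, 0.009, 0.001, 0.0009, NA)
  expect_equal(
    significance_stars(p),
    c("ns", "ns", "ns", "*", "*", "*", "**", "**", "***", NA)
  )
})

test_that("log-normal fits recover the generating parameters", {
  set.seed(55)
  v <- exp(rnorm(10000))
  s <- lognormal_summary(v)
  expect_lt(abs(s$log_mean - 0), 3 / sqrt(10000))
  expect_lt(abs(s$log_sd - 1), 3 / sqrt(2 * 10000))
  expect_gt(s$gof_p, 0.001)
  expect_false(s$degenerate)
})

test_that("degenerate and non-log-normal samples are flagged", {
  s <- lognormal_summary(rep(3.2, 50))
  expect_true(s$degenerate)
  expect_equal(s$log_sd, 0)
  expect_true(is.na(s$gof_p))

  set.seed(66)
  u <- runif(2000, 0.001, 1)   # log-uniform tail: decisively not log-normal
  expect_lt(lognormal_summary(u)$gof_p, 0.05)
  expect_error(lognormal_summary(c(1, -2, 3)), "positive")
})
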