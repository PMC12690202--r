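test_that("chi-square independence handles structure and degeneracy", {
  r <- chi_square_independence(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 1)
  expect_error(chi_square_independence(matrix(c(1, 2, 0, 0), 2, 2)),
               "margin")
  expect_error(chi_square_independence(matrix(c(1.5, 2, 3, 4), 2, 2)),
               "integer")
  expect_error(chi_square_independence(matrix(1:3, 3, 1)), "2 x 2")
})

test_that("Mann-Whitney U agrees with the pair-count definition", {
  # identical samples: U = n1 n2 / 2, p about 1
  x <- c(1, 2, 3, 4, 5)
  r <- continuous_group_test(c(x, x), rep(c("a", "b"), each = 5),
                             alpha_norm = 1)   # force nonparametric route
  expect_identical(r$routing, "nonparametric")
  expect_equal(r$statistic, 12.5)
  expect_gt(r$p_value, 0.95)

  # x entirely below y: U(x over y) = 0, complement 9, from brute force
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  u_brute <- sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  r2 <- continuous_group_test(c(x, y), rep(c("a", "b"), each = 3),
                              alpha_norm = 1)
  expect_equal(r2$statistic, u_brute)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$u_complement, 9)

  # random data: statistic equals the brute-force pair count
  set.seed(47)
  for (rep in 1:20) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1))
    u_brute <- sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
    r3 <- continuous_group_test(c(x, y),
                                rep(c("a", "b"), c(length(x), length(y))),
                                alpha_norm = 1)
    expect_equal(r3$statistic, u_brute)
  }
})

test_that("normality routing is recorded and type-I error is calibrated", {
  set.seed(53)
  n_rep <- 1000
  routes <- character(n_rep)
  pvals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    v <- rnorm(150, 10, 2)
    g <- rep(c("a", "b", "c"), each = 50)
    r <- continuous_group_test(v, g)
    routes[i] <- r$routing
    pvals[i] <- r$p_value
  }
  # normal data: parametric route in the large majority of replicates
  expect_gt(mean(routes == "parametric"), 0.7)
  # under the null the rejection rate is within the binomial 95% interval
  rej <- sum(pvals < 0.05)
  expect_gte(rej, qbinom(0.025, n_rep, 0.05))
  expect_lte(rej, qbinom(0.975, n_rep, 0.05))
})

# normal-equations + explicit-F oracle for the adjusted comparison
glm_oracle <- function(y, g, covs) {
  g <- droplevels(as.factor(g))
  X0 <- cbind(1, as.matrix(covs))
  X <- cbind(X0, sapply(levels(g)[-1], function(l) as.numeric(g == l)))
  bhat <- solve(crossprod(X), crossprod(X, y))
  b0 <- solve(crossprod(X0), crossprod(X0, y))
  rss1 <- sum((y - X %*% bhat)^2)
  rss0 <- sum((y - X0 %*% b0)^2)
  df1 <- ncol(X) - ncol(X0)
  df2 <- length(y) - ncol(X)
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(beta = drop(bhat), F = f, p = pf(f, df1, df2, lower.tail = FALSE),
       sigma2 = rss1 / df2, XtXinv = solve(crossprod(X)))
}

test_that("the adjusted GLM matches a normal-equations oracle", {
  set.seed(59)
  for (rep in 1:30) {
    n <- sample(30:80, 1)
    g <- factor(sample(c("HC", "P", "T"), n, replace = TRUE))
    while (nlevels(droplevels(g)) < 3) g <- factor(sample(c("HC", "P", "T"),
                                                          n, replace = TRUE))
    covs <- data.frame(age = rnorm(n, 65, 7), sex = rbinom(n, 1, 0.5))
    y <- rnorm(n, 50, 10) + 0.2 * covs$age + 3 * (g == "T")
    fit <- glm_adjusted_comparison(y, g, covs)
    orc <- glm_oracle(y, g, covs)
    expect_equal(fit$statistic, orc$F, tolerance = 1e-8)
    expect_equal(fit$p_value, orc$p, tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[, 1]), unname(orc$beta),
                 tolerance = 1e-8)
    # pairwise contrast P vs T from the oracle covariance
    cvec <- c(rep(0, 3), -1, 1)
    est <- sum(cvec * orc$beta)
    se <- sqrt(orc$sigma2 * drop(t(cvec) %*% orc$XtXinv %*% cvec))
    ct <- fit$contrasts
    row <- ct[ct$group1 == "P" & ct$group2 == "T", ]
    expect_equal(row$estimate, est, tolerance = 1e-8)
    expect_equal(row$se, se, tolerance = 1e-8)
    expect_equal(row$p_adjusted, min(1, row$p_raw * 3))
  }
})

test_that("the GLM reports no signal when there is none", {
  y <- rep(5, 20)
  g <- factor(rep(c("a", "b"), each = 10))
  covs <- data.frame(z = rep(0, 20))
  expect_error(glm_adjusted_comparison(y, g, covs), "aliased")
  # lm legitimately warns about the deliberately perfect fit
  fit <- suppressWarnings(glm_adjusted_comparison(y, g))
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p_value, 1)
})

test_that("rank deficiency and missing data are surfaced", {
  set.seed(61)
  n <- 30
  g <- factor(rep(c("a", "b"), each = 15))
  covs <- data.frame(x1 = rnorm(n))
  covs$x2 <- 2 * covs$x1          # aliased column
  expect_error(glm_adjusted_comparison(rnorm(n), g, covs), "x2")
  covs2 <- data.frame(x1 = c(NA, rnorm(n - 1)))
  fit <- glm_adjusted_comparison(rnorm(n), g, covs2)
  expect_identical(fit$n_dropped, 1L)
})

test_that("stage-offset recovery: estimated contrast is unbiased", {
  # two-stage design with an imposed offset of 1 SD, paper-like sizes
  set.seed(67)
  delta <- 1
  est <- replicate(200, {
    g <- factor(rep(c("HC", "E"), c(47, 11)), levels = c("HC", "E"))
    covs <- data.frame(age = rnorm(58, 65, 7))
    y <- rnorm(58) + delta * (g == "E") + 0.0 * covs$age
    fit <- glm_adjusted_comparison(y, g, covs)
    fit$contrasts$estimate[1]
  })
  expect_lt(abs(mean(est) - delta), 0.1)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(71)
  # constant covariate behaves like plain Pearson
  x <- rnorm(20); y <- rnorm(20)
  r <- partial_correlation(x, y, rep(1, 20))
  expect_equal(r$estimate, cor(x, y), tolerance = 1e-12)
  # y = x with a non-degenerate covariate: r = 1
  z <- rnorm(20)
  expect_equal(partial_correlation(x, x, z)$estimate, 1, tolerance = 1e-12)
  # confounder-driven 10-point dataset vs explicit two-pass least squares
  for (rep in 1:20) {
    z <- rnorm(10)
    x <- 2 * z + rnorm(10)
    y <- -1.5 * z + rnorm(10)
    got <- partial_correlation(x, y, z)
    Z <- cbind(1, z)
    rx <- x - Z %*% solve(crossprod(Z), crossprod(Z, x))
    ry <- y - Z %*% solve(crossprod(Z), crossprod(Z, y))
    r_orc <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(got$estimate, r_orc, tolerance = 1e-8)
    t_orc <- r_orc * sqrt((10 - 3) / (1 - r_orc^2))
    expect_equal(got$p_value, 2 * pt(-abs(t_orc), 7), tolerance = 1e-8)
  }
  expect_error(partial_correlation(rnorm(4), rnorm(4), cbind(rnorm(4),
                                                             rnorm(4))),
               "n > k")
})

# textbook BH step-up computed independently
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

test_that("p-value adjustment matches definitional oracles", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(adjust_pvalues(p, "benjamini-hochberg"), bh_oracle(p))
  expect_equal(adjust_pvalues(p, "bonferroni"), pmin(1, 5 * p))
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  set.seed(73)
  for (rep in 1:25) {
    p <- runif(sample(2:40, 1))
    bon <- adjust_pvalues(p, "bonferroni")
    bh <- adjust_pvalues(p, "BH")
    expect_equal(bh, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bon >= p))          # Bonferroni never below raw
    expect_true(all(bh <= bon + 1e-12)) # BH never above Bonferroni
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(adjust_pvalues(p[perm], "BH"), bh[perm])
    expect_equal(adjust_pvalues(p[perm], "bonferroni"), bon[perm])
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})
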