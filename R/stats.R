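.test_result <- function(test, statistic, df, p_value, ...) {
  structure(c(list(test = test, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value)),
              list(...)),
            class = "qsm_test_result")
}

#' @export
print.qsm_test_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 5),
      ", df = ", paste(format(x$df, digits = 5), collapse = "/"),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  if (!is.null(x$routing)) cat("  routing: ", x$routing, "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction) on an
#' r x c contingency table of counts, df = (r-1)(c-1).
#'
#' @param tab Matrix of non-negative integer counts, at least 2 x 2.
#' @return A `qsm_test_result`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8))
    stop("contingency table must contain non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an all-zero margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  .test_result("Pearson chi-square", res$statistic, res$parameter,
               res$p.value)
}

.ks_normal <- function(x, method) {
  if (method == "lilliefors") {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("the 'nortest' package is required for Lilliefors normality tests")
    nortest::lillie.test(x)$p.value
  } else {
    suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
}

# Mann-Whitney U for sample x against y: number of (x_i > y_j) pairs, ties
# counted half. Equals wilcox.test's W statistic.
.mann_whitney_u <- function(x, y) {
  unname(suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))$statistic)
}

#' Normality-routed comparison of a continuous variable across groups
#'
#' Assesses per-group normality (Kolmogorov-Smirnov against a normal with
#' estimated mean and SD by default; set `normality = "lilliefors"` for the
#' small-sample corrected variant). If every group passes at `alpha_norm`,
#' two groups are compared by a two-sample t-test and three or more by
#' one-way ANOVA with pairwise t post hocs; otherwise by the Mann-Whitney U
#' test (two groups; U reported for the first sample, with the complementary
#' U recorded) or Kruskal-Wallis with pairwise Mann-Whitney post hocs. The
#' route taken is always recorded, never silent.
#'
#' @param values Numeric vector.
#' @param groups Factor/character of the same length.
#' @param normality "ks" or "lilliefors".
#' @param alpha_norm Normality-test significance level (default 0.05).
#' @param p_adjust_method Post hoc adjustment (default "bonferroni").
#' @return A `qsm_test_result` with `routing`, `normal_p` per group, and for
#'   3+ groups a `pairwise` data frame.
#' @export
continuous_group_test <- function(values, groups,
                                  normality = c("ks", "lilliefors"),
                                  alpha_norm = 0.05,
                                  p_adjust_method = "bonferroni") {
  normality <- match.arg(normality)
  keep <- stats::complete.cases(values, groups)
  values <- values[keep]
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) stop("every group needs at least two observations")

  normal_p <- vapply(levels(groups),
                     function(g) .ks_normal(values[groups == g], normality),
                     numeric(1))
  parametric <- all(normal_p > alpha_norm)

  if (k == 2L) {
    x <- values[groups == levels(groups)[1]]
    y <- values[groups == levels(groups)[2]]
    if (parametric) {
      if (stats::sd(x) == 0 && stats::sd(y) == 0)
        stop("zero-variance groups cannot be compared parametrically")
      tt <- stats::t.test(x, y, var.equal = TRUE)
      res <- .test_result("two-sample t-test", tt$statistic, tt$parameter,
                          tt$p.value, routing = "parametric",
                          normal_p = normal_p, groups = levels(groups))
    } else {
      u <- .mann_whitney_u(x, y)
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      res <- .test_result("Mann-Whitney U", u, NA_real_, wt$p.value,
                          routing = "nonparametric", normal_p = normal_p,
                          u_complement = length(x) * length(y) - u,
                          groups = levels(groups))
    }
    return(res)
  }

  pairs <- utils::combn(levels(groups), 2)
  if (parametric) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    pw <- apply(pairs, 2, function(pr) {
      stats::t.test(values[groups == pr[1]], values[groups == pr[2]],
                    var.equal = TRUE)$p.value
    })
    routing <- "parametric"
    stat <- an[1, "F value"]; df <- c(an[1, "Df"], an[2, "Df"])
    p <- an[1, "Pr(>F)"]; name <- "one-way ANOVA"
  } else {
    kw <- stats::kruskal.test(values, groups)
    pw <- apply(pairs, 2, function(pr) {
      suppressWarnings(stats::wilcox.test(values[groups == pr[1]],
                                          values[groups == pr[2]],
                                          exact = FALSE))$p.value
    })
    routing <- "nonparametric"
    stat <- kw$statistic; df <- kw$parameter; p <- kw$p.value
    name <- "Kruskal-Wallis"
  }
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         p_raw = pw,
                         p_adjusted = stats::p.adjust(pw, p_adjust_method),
                         stringsAsFactors = FALSE)
  .test_result(name, stat, df, p, routing = routing, normal_p = normal_p,
               pairwise = pairwise, p_adjust_method = p_adjust_method,
               groups = levels(groups))
}

#' Covariate-adjusted group comparison by general linear model
#'
#' Least-squares fit of `response ~ covariates + group` with the group factor
#' treatment-coded against its first level. The overall group effect is the
#' nested-model F comparing the full model with the covariate-only model;
#' pairwise group contrasts are t-tests on coefficient differences,
#' Bonferroni-adjusted within the declared family. Rows with missing values
#' are dropped listwise and the count logged.
#'
#' @param response Numeric response vector.
#' @param group Factor (first level is the reference, e.g. HC or the
#'   earliest stage).
#' @param covariates Optional data frame / matrix of numeric covariates
#'   (e.g. age, sex coded 0/1, LEDD).
#' @param family_size Number of tests in the Bonferroni family; defaults to
#'   the number of pairwise contrasts. Recorded in the output so the family
#'   can be redefined.
#' @return A `qsm_test_result` with the nested F (`statistic`, `df` =
#'   c(df1, df2), `p_value`), `coefficients` table, `contrasts` data frame
#'   (raw and Bonferroni-adjusted p, family size), and `n_dropped`.
#' @export
glm_adjusted_comparison <- function(response, group, covariates = NULL,
                                    family_size = NULL) {
  group <- as.factor(group)
  df <- data.frame(.response = response, .group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!all(vapply(covariates, is.numeric, logical(1))))
      stop("covariates must be numeric (code sex as 0/1)")
    df <- cbind(df, covariates)
  }
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  df$.group <- droplevels(df$.group)
  if (nlevels(df$.group) < 2L) stop("group factor needs at least 2 levels")

  cov_names <- setdiff(names(df), c(".response", ".group"))
  rhs_cov <- if (length(cov_names))
    paste(paste0("`", cov_names, "`"), collapse = " + ") else "1"
  full_f <- stats::as.formula(paste(".response ~", rhs_cov, "+ .group"))
  red_f <- stats::as.formula(paste(".response ~", rhs_cov))

  X <- stats::model.matrix(full_f, df)
  if (nrow(X) <= ncol(X))
    stop("not enough observations for the number of parameters")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(bad, collapse = ", "))
  }

  fit <- stats::lm(full_f, data = df)
  fit0 <- stats::lm(red_f, data = df)
  an <- stats::anova(fit0, fit)
  fstat <- an$F[2]; df1 <- an$Df[2]; df2 <- an$Res.Df[2]
  pval <- an[["Pr(>F)"]][2]
  # a response the covariate-only model already fits exactly carries no
  # group signal: report F = 0, p = 1 (avoids 0/0 and rounding artefacts)
  scale <- sum(df$.response^2) + 1
  if (is.na(fstat) ||
      (an[["Sum of Sq"]][2] < 1e-10 * scale && an$RSS[2] < 1e-10 * scale)) {
    fstat <- 0; pval <- 1
  }

  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  lv <- levels(df$.group)
  cn <- paste0(".group", lv)
  pairs <- utils::combn(lv, 2)
  est <- se <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    cvec <- stats::setNames(numeric(length(beta)), names(beta))
    a <- cn[match(pairs[1, i], lv)]; b <- cn[match(pairs[2, i], lv)]
    if (a %in% names(cvec)) cvec[a] <- -1    # reference level has no column
    if (b %in% names(cvec)) cvec[b] <- 1
    est[i] <- sum(cvec * beta)
    se[i] <- sqrt(drop(t(cvec) %*% V %*% cvec))
  }
  tstat <- est / se
  tstat[se == 0 & est == 0] <- 0   # degenerate no-signal case
  df_res <- fit$df.residual
  praw <- 2 * stats::pt(-abs(tstat), df_res)
  m <- if (is.null(family_size)) ncol(pairs) else family_size
  contrasts <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          estimate = est, se = se, t = tstat, df = df_res,
                          p_raw = praw, p_adjusted = pmin(1, praw * m),
                          family_size = m, stringsAsFactors = FALSE)

  .test_result("GLM group effect (nested F)", fstat, c(df1, df2), pval,
               coefficients = summary(fit)$coefficients,
               contrasts = contrasts,
               covariates = cov_names, reference = lv[1],
               n_dropped = n_dropped, family_size = m)
}

#' Partial correlation by the residual method
#'
#' Pearson correlation of the residuals of x and y after each is regressed
#' (with intercept) on the covariates; the test statistic is
#' t = r * sqrt((n - 2 - k) / (1 - r^2)) on n - 2 - k degrees of freedom for
#' k covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric vector / matrix / data frame.
#' @return A `qsm_test_result` with `estimate` (r), `df` and `p_value`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    Z <- matrix(1, length(x), 1)
    k <- 0L
  } else {
    Z <- cbind(1, as.matrix(as.data.frame(covariates)))
    k <- ncol(Z) - 1L
  }
  keep <- stats::complete.cases(x, y, Z)
  x <- x[keep]; y <- y[keep]; Z <- Z[keep, , drop = FALSE]
  n <- length(x)
  if (n <= k + 2L) stop("need n > k + 2 observations for ", k, " covariate(s)")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("degenerate residuals: a variable is fully explained by covariates")
  r <- stats::cor(rx, ry)
  dfree <- n - 2L - k
  tstat <- r * sqrt(dfree / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), dfree)
  .test_result("partial correlation", tstat, dfree, p, estimate = r,
               n = n, n_covariates = k)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up with enforced
#' monotonicity; input order is preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method "bonferroni" or "benjamini-hochberg" (alias "BH").
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "benjamini-hochberg",
                                         "BH")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, if (method == "bonferroni") "bonferroni" else "BH")
}
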