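test_that("normality screening applies the log-transform rule", {
  set.seed(101)
  n <- 500
  coh <- data.frame(
    fried = rep(frailty_levels(), length.out = n),
    normal_var = rnorm(n),
    lognormal_var = rlnorm(n, meanlog = 1, sdlog = 0.9),
    constant_var = 5)
  scr <- normality_screen(coh, params = c("normal_var", "lognormal_var",
                                          "constant_var"))
  expect_equal(scr$transform_applied[scr$parameter == "normal_var"], "none")
  expect_equal(scr$transform_applied[scr$parameter == "lognormal_var"],
               "log")
  expect_true(scr$degenerate[scr$parameter == "constant_var"])
  # a non-normal variable with negative values cannot be log-transformed
  coh$neg_var <- c(rnorm(n - 1), -50)
  scr2 <- normality_screen(coh, params = "neg_var")
  expect_equal(scr2$transform_applied, "log_infeasible")
})

test_that("box-plot outliers are reported per group, never removed", {
  set.seed(5)
  coh <- data.frame(fried = rep(frailty_levels(), each = 50),
                    speed = rnorm(150, 500, 20))
  coh$speed[1] <- 900   # gross outlier in the non-frail group
  scr <- normality_screen(coh, params = "speed")
  out <- attr(scr, "outliers")$speed
  expect_true(1 %in% out[["non-frail"]])
  expect_equal(nrow(coh), 150)  # untouched
})

test_that("univariate screening separates signal from noise predictors", {
  set.seed(12)
  n <- 1000
  fried <- factor(rep(frailty_levels(), length.out = n),
                  levels = frailty_levels(), ordered = TRUE)
  coh <- data.frame(
    fried = fried,
    informative = -as.integer(fried) + rnorm(n),  # 1 sd between groups
    noise = rnorm(n))
  res <- univariate_screen(coh, params = c("informative", "noise"))
  expect_true(res$selected[res$parameter == "informative"])
  expect_false(res$selected[res$parameter == "noise"])
  # a failing parameter is reported, not fatal
  coh$broken <- 1
  res2 <- suppressWarnings(
    univariate_screen(coh, params = c("informative", "broken")))
  expect_equal(nrow(res2), 2)
})

test_that("variance inflation factors follow their regression definition", {
  set.seed(3)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  # orthonormalised design has VIF identically 1
  Q <- qr.Q(qr(cbind(x1 - mean(x1), x2 - mean(x2))))
  v0 <- vif(Q)
  expect_equal(as.numeric(v0), c(1, 1), tolerance = 1e-10)

  vdup <- vif(cbind(a = x1, b = x1))
  expect_true(all(is.infinite(vdup)))
  expect_true(all(attr(vdup, "flagged")))

  x3 <- x1 + x2 + rnorm(n, 0, 0.01)
  v3 <- vif(cbind(x1 = x1, x2 = x2, x3 = x3))
  expect_gt(v3[["x3"]], 10)
  expect_true(attr(v3, "flagged")[["x3"]])

  expect_error(vif(cbind(x1)), "2 columns")
  expect_error(vif(matrix(rnorm(4), 2, 2)), "more rows")
})

test_that("forward stepwise selection is AIC-greedy and deterministic", {
  set.seed(21)
  n <- 2000
  fried <- draw_ordinal(cbind(z <- rnorm(n)), c(-0.5, 1.5), 1.2, seed = 22)
  d <- data.frame(fried = fried, informative = z, noise = rnorm(n))

  sel0 <- stepwise_aic(d, candidates = character(0))
  expect_equal(sel0$selected, character(0))
  expect_equal(length(sel0$fit$coefficients), 0)

  sel <- stepwise_aic(d, candidates = c("noise", "informative"))
  expect_equal(sel$selected, "informative")
  expect_lte(sel$fit$aic, sel0$fit$aic)

  # duplicated candidates: the tie breaks by declaration order, the
  # second copy's singular fit is skipped, and exactly one of the pair
  # enters the model
  d$informative_dup <- d$informative
  expect_warning(
    sel2 <- stepwise_aic(d, candidates = c("informative",
                                           "informative_dup")),
    "skipping")
  expect_equal(sel2$selected, "informative")
  # forced_out removes a candidate up front
  sel3 <- stepwise_aic(d, candidates = c("informative", "noise"),
                       forced_out = "informative")
  expect_false("informative" %in% sel3$selected)
})

test_that("ROC AUC equals exhaustive pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 3), c(1, 1, 0)), 1)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(30)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))          # both classes present
    expect_equal(roc_auc(scores, labels), auc_bruteforce(scores, labels))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("stratified folds partition the sample with near-equal sizes", {
  for (spec in list(c(352, 10), c(100, 7), c(60, 10), c(47, 4))) {
    n <- spec[1]; k <- spec[2]
    y <- factor(rep(frailty_levels(), length.out = n),
                levels = frailty_levels(), ordered = TRUE)
    set.seed(n + k)
    f <- stratified_folds(y, k)
    expect_equal(sort(unique(f)), 1:k)
    expect_equal(length(f), n)                      # every index assigned
    expect_lte(diff(range(table(f))), 1)            # balanced
    for (j in 1:k) {                                # all categories per fold
      expect_equal(nlevels(droplevels(factor(y[f == j]))), 3)
    }
  }
})

test_that("cross-validation is reproducible and demands feasible k", {
  set.seed(40)
  n <- 240
  d <- data.frame(x = rnorm(n))
  d$fried <- draw_ordinal(cbind(d$x), c(-0.5, 1.2), 1.5, seed = 41)
  cv1 <- crossval(d, "x", k = 6, seed = 9)
  cv2 <- crossval(d, "x", k = 6, seed = 9)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$folds, cv2$folds)
  expect_true(all(cv1$per_fold$auc_prefrailty >= 0 &
                    cv1$per_fold$auc_prefrailty <= 1))
  nfrail <- sum(d$fried == "frail")
  expect_error(crossval(d, "x", k = nfrail + 1), "reduce `k`")
})

test_that("a nearly separable cohort cross-validates near perfectly", {
  set.seed(50)
  n <- 300
  g <- rep(1:3, each = n / 3)
  # strong group separation with a few overlapping subjects so the
  # training likelihood stays bounded
  x <- -g * 4 + rnorm(n, 0, 0.3)
  x[seq(1, n, by = 25)] <- x[seq(1, n, by = 25)] + 4
  d <- data.frame(fried = factor(frailty_levels()[g],
                                 levels = frailty_levels(), ordered = TRUE),
                  x = x)
  cv <- crossval(d, "x", k = 5, seed = 51)
  expect_gt(cv$mean[["auc_prefrailty"]], 0.9)
  expect_gt(cv$mean[["auc_frailty"]], 0.9)
  expect_gt(cv$mean[["accuracy"]], 0.8)
})

test_that("correlation utilities report Pearson and Spearman jointly", {
  x <- seq_len(50)
  r <- correlations(x, 2 * x + 1)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r$spearman_rho, 1, tolerance = 1e-12)

  x <- seq(-2, 2, length.out = 100)
  r2 <- correlations(x, x^3)
  expect_equal(r2$spearman_rho, 1, tolerance = 1e-12)
  expect_lt(r2$pearson_r, 1)

  set.seed(60)
  r3 <- correlations(rnorm(1000), rnorm(1000))
  expect_lt(abs(r3$pearson_r), 0.1)
  expect_error(correlations(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlations(1:2, 1:2), "n >= 3")
})

test_that("gamma fitting recovers known score distributions", {
  set.seed(70)
  x <- rgamma(2000, shape = 2, scale = 0.1)
  g <- gamma_fit(x)
  expect_equal(g$shape, 2, tolerance = 0.1)
  expect_equal(g$scale, 0.1, tolerance = 0.15)
  expect_gt(g$ks_p, 0.01)   # the fitted gamma is not rejected

  e <- gamma_fit(rexp(2000, rate = 3))
  expect_equal(e$shape, 1, tolerance = 0.15)

  expect_error(gamma_fit(rep(0.3, 100)), "constant")
  expect_error(gamma_fit(rgamma(5, 2)), ">= 10")
  # exact zeros are offset by half the minimum positive increment
  z <- c(0, 0, seq(0.1, 1, by = 0.1), rgamma(50, 2, 2))
  expect_silent(gamma_fit(z))
})
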