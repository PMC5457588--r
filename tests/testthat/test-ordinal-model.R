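test_that("intercept-only fit matches closed-form cumulative logits", {
  y <- factor(rep(frailty_levels(), c(132, 175, 45)),
              levels = frailty_levels(), ordered = TRUE)
  fit <- fit_proportional_odds(matrix(numeric(0), 352, 0), y)
  expect_equal(unname(fit$intercepts),
               c(qlogis(132 / 352), qlogis(307 / 352)), tolerance = 1e-7)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$logLik)
})

test_that("an uninformative constant predictor leaves the symmetric MLE", {
  y <- factor(rep(frailty_levels(), each = 60), levels = frailty_levels(),
              ordered = TRUE)
  d <- data.frame(fried = y, z = 0)
  expect_warning(fit <- propodds(fried ~ z, d), "constant")
  expect_equal(unname(fit$coefficients), 0)
  expect_equal(unname(fit$intercepts), c(qlogis(1 / 3), qlogis(2 / 3)),
               tolerance = 1e-7)
})

test_that("known parameters are recovered from simulated data", {
  set.seed(2024)
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n, 0, 2))
  alpha <- c(-0.8, 1.3)
  beta <- c(0.9, -0.45)
  y <- draw_ordinal(X, alpha, beta, seed = 11)
  fit <- fit_proportional_odds(X, y)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  truth <- c(alpha, beta)
  expect_true(all(abs(est - truth) < 3 * se))
  # the fitted optimum dominates the simulating parameters
  ll_at <- function(a, b) {
    eta <- drop(X %*% b)
    cum <- cbind(plogis(outer(eta, a, `+`)), 1)
    pr <- cum; pr[, -1] <- cum[, -1] - cum[, -ncol(cum)]
    sum(log(pr[cbind(seq_len(n), as.integer(y))]))
  }
  expect_gte(fit$logLik, ll_at(alpha, beta))
})

test_that("the fit agrees with an independent ordinal regression routine", {
  set.seed(7)
  n <- 600
  d <- data.frame(x1 = rnorm(n), x2 = runif(n))
  d$fried <- draw_ordinal(cbind(d$x1, d$x2), c(-1, 1), c(1.1, -0.8),
                          seed = 8)
  mine <- propodds(fried ~ x1 + x2, d)
  ref <- MASS::polr(fried ~ x1 + x2, d, Hess = TRUE)
  # MASS parameterises P(Y<=k) = logistic(zeta_k - x'beta)
  expect_equal(unname(mine$intercepts), unname(ref$zeta), tolerance = 1e-4)
  expect_equal(unname(mine$coefficients), unname(-coef(ref)),
               tolerance = 1e-4)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(sqrt(diag(vcov(mine)))[3:4],
               sqrt(diag(vcov(ref)))[1:2], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("separation and singular designs are diagnosed by name", {
  n <- 90
  y <- factor(rep(frailty_levels(), each = n / 3),
              levels = frailty_levels(), ordered = TRUE)
  sep <- data.frame(fried = y, good = rnorm(n),
                    bad = as.integer(y) * 10)  # perfectly separating
  expect_error(propodds(fried ~ good + bad, sep), "bad")

  dup <- data.frame(fried = y, a = rnorm(n))
  dup$b <- dup$a
  expect_error(propodds(fried ~ a + b, dup), "collinear.*b")
})

test_that("rescaling a predictor rescales its coefficient inversely", {
  set.seed(5)
  d <- data.frame(x = rnorm(400))
  d$fried <- draw_ordinal(cbind(d$x), c(-0.5, 1), 0.8, seed = 6)
  f1 <- propodds(fried ~ x, d)
  d$x10 <- d$x / 10
  f2 <- propodds(fried ~ x10, d)
  expect_equal(unname(f2$coefficients), 10 * unname(f1$coefficients),
               tolerance = 1e-6)
  expect_equal(f2$logLik, f1$logLik, tolerance = 1e-8)
})

test_that("predicted probabilities obey the cumulative-logit closed forms", {
  co <- uef_coefs(intercepts = c(0, log(3)),
                  coefficients = c(x = 0))
  pr <- predict_probabilities(co, c(x = 1))
  expect_equal(unname(pr), c(0.5, 0.25, 0.25), tolerance = 1e-12)

  co2 <- uef_coefs(intercepts = c(-1, 1), coefficients = c(x = 1))
  pr_hi <- predict_probabilities(co2, c(x = 50))
  expect_equal(unname(pr_hi), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(sum(predict_probabilities(co2, c(x = 0.3))), 1,
               tolerance = 1e-10)
  expect_error(predict_probabilities(co2, c(y = 1)), "missing predictor")
  expect_error(predict_probabilities(co2, c(x = Inf)), "non-finite")
})

test_that("probabilities are monotone in the linear predictor", {
  co <- uef_coefs(intercepts = c(-0.7, 0.9), coefficients = c(x = 1))
  eta <- seq(-6, 6, length.out = 100)
  pr <- t(vapply(eta, function(e) predict_probabilities(co, c(x = e)),
                 numeric(3)))
  expect_true(all(rowSums(pr) - 1 < 1e-10))
  expect_true(all(diff(pr[, 1]) > 0))   # non-frail rises with eta
  expect_true(all(diff(pr[, 3]) < 0))   # frail falls with eta
})

test_that("published coefficients reproduce the worked probability example", {
  co <- uef_published_coefficients()
  x <- c(speed = 300, flexibility = 120, moment = 1, speed_variability = 20,
         speed_reduction = -10, flexion_number = 40, sex_female = 0,
         age = 75, bmi = 27)
  pr <- predict_probabilities(co, x)
  # frozen hand-computed linear predictor 2.0873 -> (0.3675, 0.6059, 0.0266)
  expect_equal(unname(pr), c(0.3675, 0.6059, 0.0266), tolerance = 1e-3)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("classification is arg-max with ties toward the frailer category", {
  expect_equal(as.character(classify_frailty(c(0.5, 0.25, 0.25))),
               "non-frail")
  expect_equal(as.character(classify_frailty(c(0.2, 0.3, 0.5))), "frail")
  expect_equal(as.character(classify_frailty(c(0.4, 0.4, 0.2))), "pre-frail")
  m <- rbind(c(0.6, 0.3, 0.1), c(1, 1, 1) / 3)
  expect_equal(as.character(classify_frailty(m)), c("non-frail", "frail"))
  expect_error(classify_frailty(c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("Wald statistics follow their chi-square closed forms", {
  stub <- structure(list(intercepts = c(`a|b` = 0),
                         coefficients = c(b1 = 2, b2 = 0, b3 = 1),
                         vcov = diag(c(4, 1, 1, -1))), class = "propodds")
  w <- wald_tests(stub)
  r <- w[w$term == "b1", ]
  expect_equal(r$chisq, 4)
  expect_equal(r$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(c(r$ci_lower, r$ci_upper), c(2 - 1.96, 2 + 1.96))
  expect_equal(w$chisq[w$term == "b2"], 0)
  expect_equal(w$p[w$term == "b2"], 1)
  expect_true(w$degenerate[w$term == "b3"])  # negative variance flagged
  # published speed row: estimate 0.0025, se 0.0010 -> CI (0.0005, 0.0045)
  expect_equal(round(0.0025 + c(-1, 1) * 1.96 * 0.0010, 4),
               c(0.0005, 0.0045))
})

test_that("simulate() draws categories with the fitted distribution", {
  set.seed(9)
  d <- data.frame(x = rnorm(800))
  d$fried <- draw_ordinal(cbind(d$x), c(-0.5, 1.2), 1, seed = 10)
  fit <- propodds(fried ~ x, d)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(800, 3))
  expect_identical(simulate(fit, nsim = 2, seed = 4),
                   simulate(fit, nsim = 2, seed = 4))
  # empirical category shares track the fitted marginal probabilities
  expect_equal(as.numeric(table(sims[[1]])) / 800,
               unname(colMeans(fitted(fit))), tolerance = 0.08)
})
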