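#' Names of the eight elbow-motion outcomes
#'
#' @return Character vector of the eight trial-level outcome names.
#' @export
uef_parameter_names <- function() {
  c("speed", "flexibility", "power", "rise_time", "moment",
    "speed_variability", "speed_reduction", "flexion_number")
}

#' Prepare a cohort table for modelling
#'
#' Adds the derived modelling columns: `log_moment` (natural logarithm of
#' the elbow moment), `sex_female` (indicator), `log_power`, and - when
#' `bmi_form = "categorical"` - a five-level BMI factor
#' (<20, 20-24.9, 25-29.9, 30-34.9, >= 35 kg/m^2).
#'
#' @param cohort Cohort table with extracted outcomes.
#' @param bmi_form `"continuous"` (default) or `"categorical"`.
#' @return The augmented data frame.
#' @export
prepare_model_data <- function(cohort, bmi_form = c("continuous",
                                                    "categorical")) {
  bmi_form <- match.arg(bmi_form)
  d <- cohort
  if ("moment" %in% names(d)) d$log_moment <- log(d$moment)
  if ("power" %in% names(d)) d$log_power <- log(d$power)
  if ("sex" %in% names(d)) d$sex_female <- as.numeric(d$sex == "female")
  if (bmi_form == "categorical" && "bmi" %in% names(d)) {
    d$bmi_cat <- cut(d$bmi, breaks = c(-Inf, 20, 25, 30, 35, Inf),
                     right = FALSE,
                     labels = c("<20", "20-24.9", "25-29.9", "30-34.9",
                                ">=35"))
  }
  d$fried <- as_frailty(d$fried)
  d
}

#' Normality screening of the elbow-motion outcomes
#'
#' For each outcome: a Shapiro-Wilk test on the raw values; when the raw
#' test rejects at 0.05 and all values are positive, the test is repeated
#' on the logarithm and a log transform is recorded if the transformed
#' values pass (p >= 0.05). Outliers are identified per frailty group as
#' points beyond the 1.5 x IQR box-plot whiskers; they are reported, never
#' removed. Constant (zero-variance) outcomes are flagged degenerate.
#'
#' @param cohort Cohort table containing the outcome columns and `fried`.
#' @param params Outcome columns to screen.
#' @return A `data.frame` of class `uef_screening` with columns `parameter`,
#'   `shapiro_w`, `shapiro_p`, `shapiro_p_log`, `transform_applied`
#'   (`"none"`/`"log"`), `degenerate`, `n_outliers`; the per-group outlier
#'   row indices are in `attr(x, "outliers")`.
#' @export
normality_screen <- function(cohort, params = intersect(uef_parameter_names(),
                                                        names(cohort))) {
  fried <- as_frailty(cohort$fried)
  if (min(table(fried)) < 3) stop("need >= 3 observations per frailty group",
                                  call. = FALSE)
  outliers <- list()
  rows <- lapply(params, function(pn) {
    x <- cohort[[pn]]
    ok <- is.finite(x)
    xs <- x[ok]
    degenerate <- length(unique(xs)) < 3 || sd(xs) == 0
    w <- p <- p_log <- NA_real_
    transform <- "none"
    if (!degenerate) {
      sw <- shapiro.test(xs)
      w <- unname(sw$statistic); p <- sw$p.value
      if (p < 0.05) {
        if (all(xs > 0)) {
          p_log <- shapiro.test(log(xs))$p.value
          if (p_log >= 0.05) transform <- "log"
        } else {
          transform <- "log_infeasible"
        }
      }
    }
    grp_out <- lapply(split(seq_along(x)[ok], fried[ok]), function(idx) {
      v <- x[idx]
      stats <- grDevices::boxplot.stats(v)
      idx[v %in% stats$out]
    })
    outliers[[pn]] <<- grp_out
    data.frame(parameter = pn, shapiro_w = w, shapiro_p = p,
               shapiro_p_log = p_log, transform_applied = transform,
               degenerate = degenerate,
               n_outliers = sum(lengths(grp_out)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "outliers") <- outliers
  class(out) <- c("uef_screening", "data.frame")
  out
}

#' Univariate ordinal association screen
#'
#' Fits a one-predictor proportional-odds model of the Fried category for
#' each outcome and flags outcomes whose Wald p-value falls below
#' `threshold`. Fit failures for individual outcomes are reported in the
#' table, not raised.
#'
#' @param cohort Cohort table with `fried` and the outcome columns.
#' @param params Outcome columns to screen.
#' @param threshold Selection p-value threshold (default 0.05).
#' @return A `data.frame` with columns `parameter`, `beta`, `se`, `p`,
#'   `selected`, `error`.
#' @export
univariate_screen <- function(cohort,
                              params = intersect(uef_parameter_names(),
                                                 names(cohort)),
                              threshold = 0.05) {
  d <- cohort
  d$fried <- as_frailty(d$fried)
  rows <- lapply(params, function(pn) {
    res <- tryCatch({
      fit <- propodds(stats::reformulate(pn, response = "fried"), d)
      wt <- wald_tests(fit)
      wt <- wt[wt$term == pn, ]
      data.frame(parameter = pn, beta = wt$estimate, se = wt$se, p = wt$p,
                 selected = is.finite(wt$p) && wt$p < threshold,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(parameter = pn, beta = NA_real_, se = NA_real_,
                 p = NA_real_, selected = FALSE,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column j
#' on all other columns (with intercept). Exactly collinear columns get
#' infinite VIF.
#'
#' @param X Numeric matrix or data frame of predictors (>= 2 columns,
#'   more rows than columns).
#' @param cutoff Flagging threshold (default 10).
#' @return Named numeric vector of VIFs with a logical `flagged` attribute.
#' @export
#' @examples
#' vif(cbind(a = rnorm(50), b = rnorm(50)))
vif <- function(X, cutoff = 10) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need >= 2 columns", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("need more rows than columns", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  attr(out, "flagged") <- out > cutoff
  out
}

#' Forward stepwise selection by AIC
#'
#' Starting from the intercept-only proportional-odds model, repeatedly
#' adds the candidate predictor that lowers AIC the most; stops when no
#' addition lowers AIC. Ties break by candidate declaration order.
#' Candidates whose fit fails are skipped with a warning.
#'
#' @param data Data frame containing `response` and all candidate columns.
#' @param candidates Character vector of candidate predictor columns.
#' @param response Response column name (ordered outcome).
#' @param forced_out Candidates to exclude up front.
#' @return A list of class `uef_stepwise` with `selected` (in order of
#'   entry), `fit` (the final [propodds()] model), and `path` (a data frame
#'   of the per-step AIC trace).
#' @export
stepwise_aic <- function(data, candidates, response = "fried",
                         forced_out = character()) {
  d <- data
  d[[response]] <- as_frailty(d[[response]])
  candidates <- setdiff(candidates, forced_out)
  fit0 <- propodds(stats::reformulate("1", response = response), d)
  selected <- character(0)
  current <- fit0
  path <- data.frame(step = 0L, added = "(intercept)", aic = fit0$aic,
                     stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    aics <- vapply(remaining, function(cn) {
      tryCatch(propodds(stats::reformulate(c(selected, cn),
                                           response = response), d)$aic,
               error = function(e) {
                 warning("skipping candidate ", cn, ": ",
                         conditionMessage(e), call. = FALSE)
                 Inf
               })
    }, numeric(1))
    best <- which.min(aics)   # first index wins ties: declaration order
    if (aics[best] >= current$aic) break
    step <- step + 1L
    selected <- c(selected, remaining[best])
    current <- propodds(stats::reformulate(selected, response = response), d)
    path <- rbind(path, data.frame(step = step, added = remaining[best],
                                   aic = current$aic))
  }
  structure(list(selected = selected, fit = current, path = path),
            class = "uef_stepwise")
}

#' @export
print.uef_stepwise <- function(x, ...) {
  cat("Forward stepwise selection by AIC\n")
  print(x$path, row.names = FALSE)
  cat("Selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive scores higher, counting ties as one half. Equivalent
#' to trapezoidal integration of the empirical ROC curve.
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param labels Binary labels (logical, 0/1 or two-level factor).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  if (any(is.na(scores)) || any(is.na(labels))) {
    stop("missing values in `scores` or `labels`", call. = FALSE)
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present",
                                 call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: within each category, members are dealt
# round-robin over folds ordered by current load, so overall fold sizes
# differ by <= 1 and every fold keeps every category.
stratified_folds <- function(y, k) {
  n <- length(y)
  folds <- integer(n)
  load <- integer(k)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    ord <- order(load, seq_len(k))       # least-loaded first, stable
    folds[idx] <- rep_len(ord, length(idx))
    load <- tabulate(folds[folds > 0L], k)
  }
  folds
}

#' Stratified k-fold cross-validation of a frailty model
#'
#' The sample is randomly divided into `k` near-equal parts, stratified by
#' Fried category; at each iteration the model is trained on k-1 parts and
#' evaluated on the held-out part. Reported per fold and as mean (sd):
#' ROC AUC for pre-frailty (non-frail vs pre-frail-or-frail, scored by
#' `p(pre-frail) + p(frail)`), ROC AUC for frailty (frail vs rest, scored
#' by `p(frail)`), the training-fit AIC, and classification accuracy
#' (three-class arg-max by default, or dichotomised non-frail vs rest).
#'
#' @param data Data frame with the response and predictor columns.
#' @param predictors Character vector of predictor column names.
#' @param response Response column (Fried category).
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param accuracy Accuracy definition: `"three-class"` (default) or
#'   `"dichotomous"`.
#' @return A list of class `uef_cv` with `folds` (assignment vector),
#'   `per_fold` (fold-level metrics), `mean`, `sd` and `seed`.
#' @export
crossval <- function(data, predictors, response = "fried", k = 10,
                     seed = NULL, accuracy = c("three-class",
                                               "dichotomous")) {
  accuracy <- match.arg(accuracy)
  d <- data
  d[[response]] <- as_frailty(d[[response]])
  y <- d[[response]]
  if (min(table(y)) < k) {
    stop("a frailty category has fewer members than folds; reduce `k`",
         call. = FALSE)
  }
  folds <- with_seed(seed, stratified_folds(y, k))
  fml <- stats::reformulate(if (length(predictors)) predictors else "1",
                            response = response)
  per <- lapply(seq_len(k), function(f) {
    train <- d[folds != f, , drop = FALSE]
    test <- d[folds == f, , drop = FALSE]
    if (nlevels(droplevels(factor(test[[response]]))) < 3L) {
      stop("fold ", f, " lacks a frailty category; reduce `k`",
           call. = FALSE)
    }
    fit <- propodds(fml, train)
    pr <- predict(fit, newdata = test, type = "probs")
    truth <- test[[response]]
    pred <- classify_frailty(pr)
    acc <- if (accuracy == "three-class") {
      mean(pred == truth)
    } else {
      mean((pred != "non-frail") == (truth != "non-frail"))
    }
    data.frame(
      fold = f, n = nrow(test),
      auc_prefrailty = roc_auc(pr[, "pre-frail"] + pr[, "frail"],
                               truth != "non-frail"),
      auc_frailty = roc_auc(pr[, "frail"], truth == "frail"),
      aic = fit$aic, accuracy = acc)
  })
  per <- do.call(rbind, per)
  metrics <- c("auc_prefrailty", "auc_frailty", "aic", "accuracy")
  structure(list(folds = folds, per_fold = per,
                 mean = colMeans(per[metrics]),
                 sd = vapply(per[metrics], sd, numeric(1)),
                 k = k, seed = seed, predictors = predictors,
                 accuracy = accuracy),
            class = "uef_cv")
}

#' @export
print.uef_cv <- function(x, digits = 3, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %s)\n", x$k,
              format(x$seed)))
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-15s %.*f (%.*f)\n", m, digits, x$mean[[m]], digits,
                x$sd[[m]]))
  }
  invisible(x)
}

#' Pearson and Spearman correlations
#'
#' @param x,y Numeric vectors (n >= 3, finite).
#' @return One-row `data.frame`: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`.
#' @export
correlations <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3 finite pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input", call. = FALSE)
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  data.frame(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
             spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
             n = length(x))
}

#' Gamma fit of a score distribution
#'
#' Maximum-likelihood gamma parameters for a positive score sample, with a
#' one-sample Kolmogorov-Smirnov statistic against the fitted gamma. Zero
#' scores are offset by half the minimum positive increment observed in
#' the sample (the score is discrete, so exact zeros occur).
#'
#' @param scores Non-negative scores (n >= 10).
#' @return A list of class `uef_gamma`: `shape`, `rate`, `scale`, `ks_stat`,
#'   `ks_p`, `n`.
#' @export
gamma_fit <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 10L) stop("need >= 10 observations", call. = FALSE)
  if (any(scores < 0)) stop("scores must be non-negative", call. = FALSE)
  if (sd(scores) == 0) stop("degenerate (constant) score sample",
                            call. = FALSE)
  if (any(scores == 0)) {
    inc <- diff(sort(unique(scores)))
    scores[scores == 0] <- min(inc[inc > 0]) / 2
  }
  est <- suppressWarnings(MASS::fitdistr(scores, "gamma"))
  shape <- unname(est$estimate["shape"])
  rate <- unname(est$estimate["rate"])
  ks <- suppressWarnings(ks.test(scores, "pgamma", shape = shape,
                                 rate = rate))
  structure(list(shape = shape, rate = rate, scale = 1 / rate,
                 ks_stat = unname(ks$statistic), ks_p = ks$p.value,
                 n = length(scores)),
            class = "uef_gamma")
}

#' @export
print.uef_gamma <- function(x, ...) {
  cat(sprintf(
    "Gamma fit: shape %.3f, scale %.4f (n = %d); KS D = %.3f, p = %.3g\n",
    x$shape, x$scale, x$n, x$ks_stat, x$ks_p))
  invisible(x)
}
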