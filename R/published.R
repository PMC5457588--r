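#' Published UEF categorical-index coefficients
#'
#' The published multivariable proportional-odds coefficients for the UEF
#' categorical index, shipped as a versioned plain-text asset. The model is
#' parameterised as `P(frailty <= k) = logistic(alpha_k + x' beta)` over
#' the ordering non-frail < pre-frail < frail; the elbow moment enters as
#' its natural logarithm (`log_moment`) and sex as a female indicator.
#'
#' @param version Asset version (currently only 1).
#' @return A `uef_coefs` object: list with `intercepts` (length 2, ordered)
#'   and `coefficients` (named vector over `speed`, `flexibility`,
#'   `log_moment`, `speed_variability`, `speed_reduction`,
#'   `flexion_number`, `sex_female`, `age`, `bmi`), plus the standard
#'   errors as attributes.
#' @export
#' @examples
#' uef_published_coefficients()
uef_published_coefficients <- function(version = 1) {
  path <- system.file("extdata",
                      sprintf("uef_index_coefficients_v%d.csv", version),
                      package = "uefrailty", mustWork = TRUE)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  ia <- grepl("^intercept_", tab$term)
  uef_coefs(intercepts = setNames(tab$estimate[ia],
                                  sub("^intercept_", "", tab$term[ia])),
            coefficients = setNames(tab$estimate[!ia], tab$term[!ia]),
            se = setNames(tab$se, tab$term))
}

#' Construct a coefficient set for cumulative-logit scoring
#'
#' @param intercepts Ordered cumulative intercepts (length K-1).
#' @param coefficients Named coefficient vector.
#' @param se Optional named standard errors.
#' @param levels Outcome category labels.
#' @return A list of class `uef_coefs`.
#' @export
uef_coefs <- function(intercepts, coefficients, se = NULL,
                      levels = frailty_levels()) {
  if (is.unsorted(intercepts, strictly = TRUE)) {
    stop("cumulative intercepts must be strictly increasing", call. = FALSE)
  }
  if (length(intercepts) != length(levels) - 1L) {
    stop("need one intercept per category boundary", call. = FALSE)
  }
  structure(list(intercepts = intercepts,
                 coefficients = coefficients, se = se, levels = levels),
            class = "uef_coefs")
}

#' @export
print.uef_coefs <- function(x, ...) {
  cat("Cumulative-logit coefficient set (",
      paste(x$levels, collapse = " < "), ")\n", sep = "")
  print(round(c(x$intercepts, x$coefficients), 4))
  invisible(x)
}

#' Frailty category probabilities from a model or coefficient set
#'
#' Evaluates `p(non-frail) = logistic(alpha_1 + x'beta)`,
#' `p(frail) = 1 - logistic(alpha_2 + x'beta)` and `p(pre-frail)` as the
#' remainder, for a fitted [propodds()] model or a [uef_coefs()] set (such
#' as the published index coefficients). When the coefficient set contains
#' a `log_moment` term and `x` supplies `moment`, the logarithm is taken
#' automatically.
#'
#' @param object A `propodds` fit or `uef_coefs` coefficient set.
#' @param x Named list/vector or data frame of predictor values covering
#'   the coefficient names.
#' @return For a single observation, a named probability vector (classes
#'   sum to 1); for a data frame, a probability matrix with one row per
#'   observation.
#' @export
#' @examples
#' co <- uef_published_coefficients()
#' predict_probabilities(co, c(speed = 300, flexibility = 120, moment = 1,
#'   speed_variability = 20, speed_reduction = -10, flexion_number = 40,
#'   sex_female = 0, age = 75, bmi = 27))
predict_probabilities <- function(object, x) {
  UseMethod("predict_probabilities")
}

#' @export
predict_probabilities.uef_coefs <- function(object, x) {
  X <- if (is.data.frame(x)) x else as.data.frame(as.list(x))
  if ("log_moment" %in% names(object$coefficients) &&
      !("log_moment" %in% names(X)) && "moment" %in% names(X)) {
    X$log_moment <- log(X$moment)
  }
  need <- names(object$coefficients)
  missing <- setdiff(need, names(X))
  if (length(missing)) {
    stop("missing predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  M <- as.matrix(X[, need, drop = FALSE])
  if (any(!is.finite(M))) stop("non-finite predictor values", call. = FALSE)
  eta <- drop(M %*% object$coefficients)
  pr <- cumlogit_probs(object$intercepts, eta, object$levels)
  if (nrow(pr) == 1L) setNames(drop(pr), object$levels) else pr
}

#' @export
predict_probabilities.propodds <- function(object, x) {
  pr <- predict(object, newdata = x, type = "probs")
  if (nrow(pr) == 1L) setNames(drop(pr), object$levels) else pr
}

#' Classify frailty from category probabilities
#'
#' Arg-max classification with ties broken toward the more frail category.
#'
#' @param p Probability vector (length 3) or matrix with one row per
#'   observation, columns ordered non-frail, pre-frail, frail.
#' @param levels Category labels.
#' @return An ordered factor of predicted categories.
#' @export
#' @examples
#' classify_frailty(c(0.4, 0.4, 0.2))  # tie goes to pre-frail
classify_frailty <- function(p, levels = frailty_levels()) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("rows of `p` must be probabilities summing to 1", call. = FALSE)
  }
  k <- apply(p, 1, which_max_frail)
  factor(levels[k], levels = levels, ordered = TRUE)
}
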