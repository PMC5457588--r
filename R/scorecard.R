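#' Category cutoffs from frailty-group means
#'
#' Splits a continuous variable into three risk categories using the three
#' frailty-group means as reference values (W): cutoffs are the midpoints
#' of adjacent group means, and the reference category is the non-frail
#' group (the low-risk end). The construction requires the group means to
#' be monotone across non-frail, pre-frail, frail.
#'
#' @param group_means Length-3 numeric vector of means for the non-frail,
#'   pre-frail and frail groups, in that order.
#' @param name Variable name used in error messages.
#' @return List with `cutoffs` (length 2, between adjacent means), `W`
#'   (the group means), `reference` (index of the reference category, 1)
#'   and `direction` (`+1` if the variable increases with frailty, `-1`
#'   if it decreases).
#' @export
#' @examples
#' derive_categories(c(100, 80, 60))
derive_categories <- function(group_means, name = "variable") {
  if (length(group_means) != 3L || any(!is.finite(group_means))) {
    stop("`group_means` must be three finite values", call. = FALSE)
  }
  d <- diff(group_means)
  if (all(d > 0)) {
    direction <- 1
  } else if (all(d < 0)) {
    direction <- -1
  } else if (all(d == 0)) {
    direction <- 0
  } else {
    stop("group means for `", name, "` are not monotone across frailty ",
         "groups; category midpoints are ill-defined", call. = FALSE)
  }
  list(cutoffs = (group_means[-3] + group_means[-1]) / 2,
       W = group_means, reference = 1L, direction = direction)
}

#' Base constant for the points score
#'
#' One point corresponds to the change in the linear predictor associated
#' with `increment_years` years of age: `B = |age_beta| * increment_years`.
#'
#' @param age_beta Fitted age coefficient (regression units per year).
#' @param increment_years Age increment per point (default 4 years, the
#'   typical age gap between adjacent frailty groups).
#' @return The base constant B (> 0).
#' @export
#' @examples
#' base_constant(-0.0206)  # 0.0824
base_constant <- function(age_beta, increment_years = 4) {
  stopifnot_scalar_num(age_beta, "age_beta")
  if (age_beta == 0) stop("`age_beta` must be non-zero", call. = FALSE)
  stopifnot_scalar_num(increment_years, "increment_years", positive = TRUE)
  abs(age_beta) * increment_years
}

#' Integer points for a risk category
#'
#' `points = round(beta_risk * (W - W_ref) / B)` with half-away-from-zero
#' rounding; `beta_risk` is the regression coefficient re-signed so larger
#' variable values mean greater frailty risk.
#'
#' @param beta_risk Risk-oriented coefficient.
#' @param W Category reference value(s).
#' @param W_ref Reference-category value.
#' @param B Base constant (> 0).
#' @return Integer points (vectorised over `W`).
#' @export
#' @examples
#' compute_points(0.30, 2, 0, 0.20)  # 3
compute_points <- function(beta_risk, W, W_ref, B) {
  if (!is.finite(beta_risk) || any(!is.finite(W)) || !is.finite(W_ref)) {
    stop("non-finite inputs", call. = FALSE)
  }
  stopifnot_scalar_num(B, "B", positive = TRUE)
  as.integer(round_half_away(beta_risk * (W - W_ref) / B))
}

#' Build a frailty score card
#'
#' Framingham-style conversion of a fitted categorical-index model into an
#' integer points system. For every scored variable (the model's
#' elbow-motion outcomes plus BMI; age and sex are never scored), the
#' three frailty-group means define the categories
#' ([derive_categories()]); each category's points are
#' `round(beta_risk (W - W_ref) / B)` where `beta_risk` is the coefficient
#' oriented so that points are non-negative (higher = frailer) and the
#' base constant `B` is the age-increment constant
#' ([base_constant()]). A variable enters on the scale it entered the
#' model (e.g. `log_moment` uses group means of the log moment). Variables
#' whose three group means coincide carry zero points and are excluded
#' from the maximum.
#'
#' @param fit A [propodds()] fit (or [uef_coefs()] set) containing an
#'   `age` coefficient and the scored variables.
#' @param group_means Named list: for each scored variable, its length-3
#'   vector of non-frail / pre-frail / frail group means.
#' @param increment_years Age increment per point (default 4).
#' @return An object of class `uef_scorecard`: per-variable list with
#'   `cutoffs`, `W`, `direction`, `points` (reference category = 0), plus
#'   `base_constant`, `age_increment`, `max_total_points`.
#' @export
build_scorecard <- function(fit, group_means, increment_years = 4) {
  beta <- if (inherits(fit, "propodds")) fit$coefficients else
    fit$coefficients
  if (!("age" %in% names(beta))) {
    stop("`fit` must contain an age coefficient for the base constant",
         call. = FALSE)
  }
  B <- base_constant(beta[["age"]], increment_years)
  scored <- setdiff(names(beta), c("age", "sex_female"))
  missing <- setdiff(scored, names(group_means))
  if (length(missing)) {
    stop("missing group means for scored variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vars <- lapply(scored, function(vn) {
    cats <- derive_categories(group_means[[vn]], name = vn)
    beta_risk <- -beta[[vn]]   # frailty-increasing orientation
    pts <- compute_points(beta_risk, cats$W, cats$W[cats$reference], B)
    if (any(pts < 0)) {
      # group means ordered against the coefficient's risk direction
      # (can happen in small samples); re-anchor at the lowest-risk end
      pts <- pts - min(pts)
    }
    c(cats, list(points = pts, beta = beta[[vn]]))
  })
  names(vars) <- scored
  maxpts <- vapply(vars, function(v) max(v$points), numeric(1))
  structure(list(variables = vars, base_constant = B,
                 age_increment = increment_years,
                 max_total_points = sum(maxpts)),
            class = "uef_scorecard")
}

#' @export
print.uef_scorecard <- function(x, ...) {
  cat(sprintf("UEF score card: %d variables, base constant %.4f, max %d points\n",
              length(x$variables), x$base_constant,
              as.integer(x$max_total_points)))
  for (vn in names(x$variables)) {
    v <- x$variables[[vn]]
    cat(sprintf("  %-18s W = %s; cutoffs = %s; points = %s\n", vn,
                paste(signif(v$W, 4), collapse = "/"),
                paste(signif(v$cutoffs, 4), collapse = "/"),
                paste(v$points, collapse = "/")))
  }
  invisible(x)
}

# category index (1..3) of a value given ordered cutoffs and direction;
# boundary values go to the higher-risk category
scorecard_category <- function(value, cutoffs, direction) {
  if (direction >= 0) {                 # risk increases with the value
    if (value < cutoffs[1]) 1L else if (value < cutoffs[2]) 2L else 3L
  } else {                              # risk decreases with the value
    if (value > cutoffs[1]) 1L else if (value > cutoffs[2]) 2L else 3L
  }
}

#' Apply a score card
#'
#' Assigns each scored variable its risk category (values exactly on a
#' cutoff go to the higher-risk category), sums the integer points and
#' normalises by the maximum attainable total, yielding a score in
#' `[0, 1]` with 0 = most resilient and 1 = most frail.
#'
#' @param card A [build_scorecard()] score card.
#' @param values Named list/vector or one-row data frame of variable
#'   values; a `log_moment` entry is derived from `moment` when absent.
#' @return The continuous frailty score in `[0, 1]`; `attr(,"points")`
#'   holds the per-variable points.
#' @export
apply_scorecard <- function(card, values) {
  stopifnot(inherits(card, "uef_scorecard"))
  vals <- if (is.data.frame(values)) as.list(values) else as.list(values)
  if (!("log_moment" %in% names(vals)) && "moment" %in% names(vals)) {
    vals$log_moment <- log(vals$moment)
  }
  need <- names(card$variables)
  missing <- setdiff(need, names(vals))
  if (length(missing)) {
    stop("missing scored variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pts <- vapply(need, function(vn) {
    v <- card$variables[[vn]]
    x <- vals[[vn]][[1]]
    if (!is.finite(x)) stop("non-finite value for `", vn, "`",
                            call. = FALSE)
    if (max(v$points) == 0L) return(0)
    v$points[scorecard_category(x, v$cutoffs, v$direction)]
  }, numeric(1))
  if (card$max_total_points <= 0) stop("score card has no scored points",
                                       call. = FALSE)
  structure(sum(pts) / card$max_total_points, points = pts)
}

#' Score a whole cohort
#'
#' Applies [apply_scorecard()] row-wise and appends a `uef_score` column.
#'
#' @param card A `uef_scorecard`.
#' @param cohort Cohort table containing the scored variables (or
#'   `moment`, from which `log_moment` is derived).
#' @return The cohort table with `uef_score` appended.
#' @export
score_cohort <- function(card, cohort) {
  d <- cohort
  if (!("log_moment" %in% names(d)) && "moment" %in% names(d)) {
    d$log_moment <- log(d$moment)
  }
  cohort$uef_score <- vapply(seq_len(nrow(d)), function(i) {
    as.numeric(apply_scorecard(card, d[i, , drop = FALSE]))
  }, numeric(1))
  cohort
}

#' Frailty-group means of the scored variables
#'
#' Convenience helper computing, for each requested column, the mean per
#' Fried group in group order - the `group_means` input of
#' [build_scorecard()].
#'
#' @param cohort Cohort table with `fried` and the variable columns.
#' @param vars Variable names.
#' @return Named list of length-3 mean vectors.
#' @export
group_means <- function(cohort, vars) {
  fried <- as_frailty(cohort$fried)
  out <- lapply(vars, function(vn) {
    as.numeric(tapply(cohort[[vn]], fried, mean, na.rm = TRUE))
  })
  names(out) <- vars
  out
}

#' Serialise / read a score card
#'
#' Score cards are stored as versioned YAML text files.
#'
#' @param card A `uef_scorecard`.
#' @param path File path.
#' @return `read_scorecard()` returns the `uef_scorecard`;
#'   `write_scorecard()` returns `path` invisibly.
#' @export
write_scorecard <- function(card, path) {
  stopifnot(inherits(card, "uef_scorecard"))
  out <- list(format = "uef_scorecard/1",
              base_constant = card$base_constant,
              age_increment = card$age_increment,
              max_total_points = card$max_total_points,
              variables = lapply(card$variables, function(v) {
                list(W = as.numeric(v$W), cutoffs = as.numeric(v$cutoffs),
                     direction = v$direction, reference = v$reference,
                     points = as.integer(v$points), beta = v$beta)
              }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scorecard
#' @export
read_scorecard <- function(path) {
  if (!file.exists(path)) stop("score card not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!identical(raw$format, "uef_scorecard/1")) {
    stop("not a recognised score-card file: ", path, call. = FALSE)
  }
  vars <- lapply(raw$variables, function(v) {
    list(cutoffs = as.numeric(v$cutoffs), W = as.numeric(v$W),
         reference = as.integer(v$reference), direction = v$direction,
         points = as.integer(v$points), beta = v$beta)
  })
  structure(list(variables = vars, base_constant = raw$base_constant,
                 age_increment = raw$age_increment,
                 max_total_points = raw$max_total_points),
            class = "uef_scorecard")
}
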