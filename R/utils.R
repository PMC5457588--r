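# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so library code never
# perturbs the user's RNG stream. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Mean of a normal(mu, sd) truncated to [a, b].
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  Z <- pnorm(be) - pnorm(al)
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / Z
}

# Inverse-CDF sampler for a normal truncated to [lower, upper]. With
# match_mean = TRUE the (pre-truncation) location is solved so that the
# truncated distribution's mean equals `mean` - without this, bounds close
# to the location (e.g. a cognitive score capped at its ceiling) would
# systematically bias group means away from their configured values.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                       match_mean = FALSE) {
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  mu <- mean
  if (match_mean && (is.finite(lower) || is.finite(upper))) {
    if (mean <= lower || mean >= upper) {
      stop("target mean must lie inside the truncation interval",
           call. = FALSE)
    }
    mu <- stats::uniroot(function(m) truncnorm_mean(m, sd, lower, upper) -
                           mean,
                         interval = mean + c(-6, 6) * sd, tol = 1e-10,
                         extendInt = "upX")$root
  }
  plo <- pnorm(lower, mu, sd)
  phi <- pnorm(upper, mu, sd)
  if (phi <= plo) stop("empty truncation interval", call. = FALSE)
  qnorm(runif(n, plo, phi), mu, sd)
}

# "Round to the nearest integer" with half-away-from-zero ties
# (base round() ties to even, which is not the convention used for
# points-score construction). A relative epsilon keeps exact .5 ratios
# (e.g. 0.3/0.2) from falling on the wrong side of the tie through
# floating-point representation.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) * (1 + 4 * .Machine$double.eps) + 0.5)
}

# Largest-remainder apportionment of n into length(p) groups with target
# proportions p (used for deterministic cohort group sizes).
apportion <- function(n, p) {
  quota <- n * p
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

#' Frailty category levels
#'
#' The ordered Fried phenotype categories used throughout the package.
#'
#' @return Character vector `c("non-frail", "pre-frail", "frail")`, ordered
#'   from least to most frail.
#' @export
frailty_levels <- function() c("non-frail", "pre-frail", "frail")

# Coerce a vector of category labels/integers to the ordered factor used
# internally; trims whitespace and is case-insensitive for file input.
as_frailty <- function(x) {
  lv <- frailty_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% 1:3)) stop("numeric frailty categories must be 1, 2 or 3",
                               call. = FALSE)
    return(factor(lv[x], levels = lv, ordered = TRUE))
  }
  xs <- tolower(trimws(x))
  xs[xs %in% c("nonfrail", "non frail")] <- "non-frail"
  xs[xs %in% c("prefrail", "pre frail")] <- "pre-frail"
  bad <- setdiff(unique(xs), c(lv, NA))
  if (length(bad)) {
    stop("unknown frailty category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(xs, levels = lv, ordered = TRUE)
}
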