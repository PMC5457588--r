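#' Proportional-odds ordinal logistic regression
#'
#' Fits the cumulative-logit (proportional-odds) model
#' \deqn{P(Y \le k \mid x) = \mathrm{logistic}(\alpha_k + x^\top \beta)}
#' for an ordered outcome by full maximum likelihood, using damped Newton
#' iterations with analytic gradient and Hessian. With the frailty ordering
#' non-frail < pre-frail < frail, a larger linear predictor shifts
#' probability mass toward the less frail categories, so positive
#' coefficients are protective.
#'
#' @param formula Model formula; the response must be (coercible to) an
#'   ordered factor.
#' @param data Data frame.
#' @param tol Convergence tolerance on the maximum absolute score
#'   component.
#' @param max_iter Maximum Newton iterations.
#' @param x,y For the default (matrix) method: numeric predictor matrix
#'   without an intercept column, and the ordered response.
#' @param ... Unused.
#'
#' @return An object of class `propodds`: a list with `intercepts` (the
#'   ordered cumulative intercepts \eqn{\alpha_k}, named by the category
#'   each cumulative probability is "at or below"), `coefficients`
#'   (\eqn{\beta}), `vcov` (inverse observed information over all
#'   parameters), `logLik`, `aic`, `n`, `levels`, `fitted` (n x K
#'   probability matrix) and bookkeeping for `predict()`.
#'
#' @seealso [predict_probabilities()], [classify_frailty()], [wald_tests()]
#' @export
#' @examples
#' coh <- sample_demographics(300, seed = 1)
#' coh$x <- as.numeric(coh$fried) + rnorm(300)
#' fit <- propodds(fried ~ x, coh)
#' summary(fit)
propodds <- function(formula, data, tol = 1e-8, max_iter = 100, ...) {
  UseMethod("propodds")
}

#' @rdname propodds
#' @export
propodds.formula <- function(formula, data, tol = 1e-8, max_iter = 100, ...) {
  mf <- model.frame(formula, data, na.action = na.omit)
  y <- model.response(mf)
  if (!is.ordered(y)) y <- factor(y, ordered = TRUE)
  tms <- terms(mf)
  X <- model.matrix(tms, mf)
  has_int <- "(Intercept)" %in% colnames(X)
  if (has_int) X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  fit <- fit_proportional_odds(X, y, tol = tol, max_iter = max_iter)
  fit$terms <- tms
  fit$call <- match.call()
  fit$xlevels <- stats::.getXlevels(tms, mf)
  fit
}

#' @rdname propodds
#' @export
propodds.default <- function(formula, data, tol = 1e-8, max_iter = 100,
                             x = formula, y = data, ...) {
  fit_proportional_odds(x, y, tol = tol, max_iter = max_iter)
}

#' @rdname propodds
#' @export
fit_proportional_odds <- function(x, y, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(x)
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.factor(y)) y <- factor(y, ordered = TRUE)
  y <- droplevels(y)
  lv <- levels(y)
  K <- length(lv)
  if (K < 2L) stop("response needs at least two observed categories",
                   call. = FALSE)
  if (any(table(y) == 0L)) stop("every category needs >= 1 observation",
                                call. = FALSE)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(x) must match length(y)", call. = FALSE)
  if (any(!is.finite(X))) stop("missing or non-finite predictor values",
                               call. = FALSE)
  p <- ncol(X)

  # constant columns carry no information beyond the intercepts: pin their
  # coefficient at 0 (flagged with NA variance) rather than failing
  const <- if (p) apply(X, 2, function(v) max(v) == min(v)) else logical(0)
  if (any(const)) {
    warning("constant predictor column(s) ",
            paste(colnames(X)[const], collapse = ", "),
            ": coefficient fixed at 0", call. = FALSE)
    keep <- colnames(X)[!const]
    sub <- fit_proportional_odds(X[, !const, drop = FALSE], y,
                                 tol = tol, max_iter = max_iter)
    beta <- setNames(rep(0, p), colnames(X))
    beta[keep] <- sub$coefficients
    npar <- K - 1L + p
    vc <- matrix(NA_real_, npar, npar)
    pnames <- c(names(sub$intercepts), colnames(X))
    dimnames(vc) <- list(pnames, pnames)
    live <- c(names(sub$intercepts), keep)
    vc[live, live] <- sub$vcov
    sub$coefficients <- beta
    sub$vcov <- vc
    sub$aic <- 2 * npar - 2 * sub$logLik
    sub$x <- X
    return(sub)
  }

  # singular design check
  if (p) {
    q <- qr(cbind(`(Intercept)` = 1, X))
    if (q$rank < p + 1L) {
      dep <- colnames(X)[setdiff(seq_len(p) + 1L,
                                 q$pivot[seq_len(q$rank)]) - 1L]
      stop("singular design; collinear column(s): ",
           paste(dep, collapse = ", "), call. = FALSE)
    }
  }

  yi <- as.integer(y)
  cum <- cumsum(tabulate(yi, K)) / n
  theta <- c(qlogis(cum[-K]), rep(0, p))
  npar <- K - 1L + p
  xsd <- if (p) apply(X, 2, sd) else numeric(0)
  xsd[xsd == 0] <- 1

  ll_parts <- function(th) {
    a <- th[seq_len(K - 1L)]
    b <- if (p) th[K:npar] else numeric(0)
    if (is.unsorted(a, strictly = TRUE)) return(NULL)
    xb <- if (p) drop(X %*% b) else rep(0, n)
    up <- ifelse(yi <= K - 1L, a[pmin(yi, K - 1L)] + xb, Inf)
    lo <- ifelse(yi >= 2L, a[pmax(yi - 1L, 1L)] + xb, -Inf)
    Fu <- plogis(up); Fl <- plogis(lo)
    L <- Fu - Fl
    if (any(L <= 0) || any(!is.finite(L))) return(NULL)
    list(a = a, b = b, xb = xb, Fu = Fu, Fl = Fl, L = L,
         ll = sum(log(L)))
  }

  score_hess <- function(parts) {
    Fu <- parts$Fu; Fl <- parts$Fl; L <- parts$L
    fu <- Fu * (1 - Fu); fl <- Fl * (1 - Fl)
    dfu <- fu * (1 - 2 * Fu); dfl <- fl * (1 - 2 * Fl)
    gu <- fu / L; gl <- -fl / L
    huu <- dfu / L - (fu / L)^2
    hll <- -dfl / L - (fl / L)^2
    hul <- fu * fl / L^2
    g <- numeric(npar)
    H <- matrix(0, npar, npar)
    for (j in seq_len(K)) {
      idx <- which(yi == j)
      if (!length(idx)) next
      Xg <- if (p) X[idx, , drop = FALSE] else matrix(0, length(idx), 0)
      au <- if (j <= K - 1L) j else NA_integer_
      al <- if (j >= 2L) j - 1L else NA_integer_
      wu <- huu[idx]; wl <- hll[idx]; wc <- hul[idx]
      if (!is.na(au)) {
        g[au] <- g[au] + sum(gu[idx])
        H[au, au] <- H[au, au] + sum(wu)
      }
      if (!is.na(al)) {
        g[al] <- g[al] + sum(gl[idx])
        H[al, al] <- H[al, al] + sum(wl)
      }
      if (!is.na(au) && !is.na(al)) {
        H[au, al] <- H[au, al] + sum(wc)
        H[al, au] <- H[al, au] + sum(wc)
      }
      if (p) {
        bi <- K:npar
        gb <- (gu[idx] + gl[idx])
        g[bi] <- g[bi] + drop(crossprod(Xg, gb))
        if (!is.na(au)) {
          v <- wu + (if (!is.na(al)) wc else 0)
          H[au, bi] <- H[au, bi] + drop(crossprod(Xg, v))
          H[bi, au] <- H[au, bi]
        }
        if (!is.na(al)) {
          v <- wl + (if (!is.na(au)) wc else 0)
          H[al, bi] <- H[al, bi] + drop(crossprod(Xg, v))
          H[bi, al] <- H[al, bi]
        }
        wbb <- wu + wl + 2 * (if (!is.na(au) && !is.na(al)) wc else 0)
        H[bi, bi] <- H[bi, bi] + crossprod(Xg * wbb, Xg)
      }
    }
    list(g = g, H = H)
  }

  parts <- ll_parts(theta)
  if (is.null(parts)) stop("invalid starting values", call. = FALSE)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    sh <- score_hess(parts)
    if (max(abs(sh$g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(sh$H, sh$g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      stop("information matrix is singular; model cannot be fitted",
           call. = FALSE)
    }
    lam <- 1
    repeat {
      cand <- theta - lam * step
      cparts <- ll_parts(cand)
      if (!is.null(cparts) && cparts$ll >= parts$ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cparts <- NULL; break }
    }
    if (is.null(cparts)) break
    theta <- cand
    parts <- cparts
    # runaway coefficients indicate separation
    if (p) {
      bstd <- abs(parts$b) * xsd
      if (any(bstd > 30)) {
        stop("complete or quasi-complete separation detected for predictor: ",
             colnames(X)[which.max(bstd)], call. = FALSE)
      }
    }
  }
  if (!converged) {
    sh <- score_hess(parts)
    if (max(abs(sh$g)) < sqrt(tol)) {
      converged <- TRUE
    } else {
      offender <- if (p) colnames(X)[which.max(abs(parts$b) * xsd)] else "intercepts"
      stop("proportional-odds fit did not converge (possible separation in ",
           offender, ")", call. = FALSE)
    }
  }

  sh <- score_hess(parts)
  vc <- tryCatch(solve(-sh$H), error = function(e)
    matrix(NA_real_, npar, npar))
  anames <- paste0(lv[-K], "|", lv[-1])
  pnames <- c(anames, colnames(X))
  dimnames(vc) <- list(pnames, pnames)
  intercepts <- setNames(parts$a, anames)
  beta <- setNames(parts$b, colnames(X))
  ll <- parts$ll
  fitted <- cumlogit_probs(parts$a, parts$xb, lv)
  structure(list(intercepts = intercepts, coefficients = beta, vcov = vc,
                 logLik = ll, aic = 2 * npar - 2 * ll, n = n,
                 levels = lv, fitted = fitted, iter = iter,
                 converged = converged, y = y, x = X),
            class = "propodds")
}

#' @export
coef.propodds <- function(object, ...) {
  c(object$intercepts, object$coefficients)
}

#' @export
vcov.propodds <- function(object, ...) object$vcov

#' @export
logLik.propodds <- function(object, ...) {
  structure(object$logLik,
            df = length(object$intercepts) + length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.propodds <- function(object, ...) object$n

#' @export
fitted.propodds <- function(object, ...) object$fitted

#' @export
print.propodds <- function(x, digits = 4, ...) {
  cat("Proportional-odds (cumulative-logit) model\n")
  cat(sprintf("  n = %d, categories: %s\n", x$n,
              paste(x$levels, collapse = " < ")))
  cat("  Intercepts:\n")
  print(round(x$intercepts, digits))
  if (length(x$coefficients)) {
    cat("  Coefficients:\n")
    print(round(x$coefficients, digits))
  }
  cat(sprintf("  logLik %.3f, AIC %.2f (%d Newton iterations)\n",
              x$logLik, x$aic, x$iter))
  invisible(x)
}

#' @export
summary.propodds <- function(object, ...) {
  tab <- wald_tests(object)
  structure(list(fit = object, wald = tab), class = "summary.propodds")
}

#' @export
print.summary.propodds <- function(x, ...) {
  print(x$fit)
  cat("\nWald tests:\n")
  print(x$wald, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
predict.propodds <- function(object, newdata = NULL,
                             type = c("probs", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    pr <- object$fitted
  } else {
    if (!is.null(object$terms)) {
      tms <- stats::delete.response(object$terms)
      mf <- model.frame(tms, newdata, xlev = object$xlevels,
                        na.action = na.omit)
      X <- model.matrix(tms, mf)
      X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
    } else {
      X <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
    }
    pr <- cumlogit_probs(object$intercepts,
                         drop(X %*% object$coefficients), object$levels)
  }
  if (type == "probs") return(pr)
  factor(object$levels[apply(pr, 1, which_max_frail)],
         levels = object$levels, ordered = TRUE)
}

#' @export
simulate.propodds <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                              ...) {
  pr <- predict(object, newdata = newdata, type = "probs")
  with_seed(seed, {
    out <- replicate(nsim, {
      k <- apply(pr, 1, function(p) sample.int(length(p), 1, prob = p))
      factor(object$levels[k], levels = object$levels, ordered = TRUE)
    }, simplify = FALSE)
    names(out) <- paste0("sim_", seq_len(nsim))
    as.data.frame(out)
  })
}

#' @export
plot.propodds <- function(x, n_grid = 200, ...) {
  xb <- if (length(x$coefficients)) drop(x$x %*% x$coefficients) else
    rep(0, x$n)
  grid <- seq(min(xb) - 1, max(xb) + 1, length.out = n_grid)
  pr <- cumlogit_probs(x$intercepts, grid, x$levels)
  graphics::matplot(grid, pr, type = "l", lty = 1, lwd = 2,
                    xlab = "linear predictor", ylab = "category probability",
                    ...)
  graphics::legend("right", legend = x$levels, col = seq_along(x$levels),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

# category probabilities from cumulative intercepts and linear predictor
cumlogit_probs <- function(alpha, eta, levels) {
  cum <- cbind(plogis(outer(eta, alpha, `+`)), 1)
  pr <- cum
  if (ncol(cum) > 1L) {
    pr[, -1] <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
  }
  colnames(pr) <- levels
  rownames(pr) <- NULL
  pr
}

# arg-max with ties broken toward the more frail (later) category
which_max_frail <- function(p) {
  m <- max(p)
  max(which(p >= m - 1e-12))
}

#' Wald statistics for a fitted proportional-odds model
#'
#' Per-parameter Wald chi-square (`(estimate/se)^2` on 1 df), p-value and
#' 95\% confidence interval, computed from the observed-information
#' covariance. Parameters with zero or negative estimated variance are
#' flagged `degenerate` and get `NA` statistics.
#'
#' @param fit A [propodds()] fit.
#' @return A `data.frame` with columns `term`, `estimate`, `se`, `chisq`,
#'   `p`, `ci_lower`, `ci_upper`, `degenerate`.
#' @export
wald_tests <- function(fit) {
  est <- coef(fit)
  v <- diag(vcov(fit))
  bad <- !is.finite(v) | v <= 0
  se <- ifelse(bad, NA_real_, sqrt(pmax(v, 0)))
  chisq <- (est / se)^2
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             chisq = unname(chisq),
             p = unname(pchisq(chisq, df = 1, lower.tail = FALSE)),
             ci_lower = unname(est - 1.96 * se),
             ci_upper = unname(est + 1.96 * se),
             degenerate = unname(bad), stringsAsFactors = FALSE)
}
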