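# Shared fixtures, built in code at test time.

# A noise-free pure-sinusoid angular-velocity series (A deg/s at f Hz).
sinusoid_series <- function(A = 200, f = 0.5, duration = 20, fs = 100) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  angular_velocity_series(A * sin(2 * pi * f * t), fs)
}

# A deterministic noise-free subject for trace round-trip checks.
clean_subject <- function(frequency = 0.5, amplitude = 200, rom = NULL,
                          decline = 0, jitter = 0) {
  if (is.null(rom)) rom <- amplitude / (pi * frequency)  # sinusoid-consistent
  data.frame(true_frequency = frequency, true_amplitude = amplitude,
             true_rom = rom, true_decline = decline, true_jitter = jitter)
}

# Full default synthetic cohort with extracted outcomes; memoised within a
# test file so the (few-second) generation cost is paid once.
uef_full_cohort <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache)) {
      sim <- generate_cohort(uef_config(), seed = seed)
      cache <<- prepare_model_data(extract_cohort(sim))
    }
    cache
  }
})

# Draw ordinal outcomes from known cumulative-logit parameters.
draw_ordinal <- function(X, alpha, beta, seed) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  eta <- drop(as.matrix(X) %*% beta)
  cum <- cbind(plogis(outer(eta, alpha, `+`)), 1)
  pr <- cum
  pr[, -1] <- cum[, -1] - cum[, -ncol(cum)]
  withr_seed({
    k <- apply(pr, 1, function(p) sample.int(3, 1, prob = p))
    factor(frailty_levels()[k], levels = frailty_levels(), ordered = TRUE)
  })
}

# Exhaustive pairwise-concordance AUC oracle (for small n).
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
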