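#' Sample cohort demographics
#'
#' Draws a synthetic cohort with the group structure of a three-category
#' Fried-phenotype study population. Group sizes are either the
#' largest-remainder apportionment of `n * group_proportions`
#' (`deterministic_counts = TRUE`) or multinomial. Within each group, age,
#' height, body-mass index and MMSE are drawn from truncated normal
#' distributions defined by the [group_profile()]; weight is derived as
#' `bmi * (height/100)^2` so the anthropometrics are internally consistent;
#' sex is Bernoulli with the group's female fraction. Each subject also
#' receives "true" elbow-motion parameters (cycle frequency, peak angular
#' velocity, range of motion, fatigue decline, amplitude jitter) drawn from
#' the group's motion profile; these drive [simulate_trace()].
#'
#' @param n Number of subjects (>= 3).
#' @param group_proportions Length-3 proportions (non-frail, pre-frail,
#'   frail) summing to 1.
#' @param profiles Named list of three [group_profile()] objects.
#' @param seed Integer seed for reproducibility (optional).
#' @param deterministic_counts Use exact apportioned group sizes (default).
#'
#' @return A `data.frame` (cohort table) with one row per subject: `id`,
#'   `fried` (ordered factor), `age`, `sex`, `height`, `weight`, `bmi`,
#'   `mmse`, and true motion parameters `true_frequency` (Hz),
#'   `true_amplitude` (deg/s), `true_rom` (deg), `true_decline`,
#'   `true_jitter`.
#' @export
#' @examples
#' coh <- sample_demographics(352, seed = 1)
#' table(coh$fried)
sample_demographics <- function(n,
                                group_proportions = c(132, 175, 45) / 352,
                                profiles = list(
                                  "non-frail" = group_profile("non-frail"),
                                  "pre-frail" = group_profile("pre-frail"),
                                  "frail"     = group_profile("frail")),
                                seed = NULL,
                                deterministic_counts = TRUE) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3 ||
      n != round(n)) {
    stop("`n` must be a whole number >= 3", call. = FALSE)
  }
  if (length(group_proportions) != 3L ||
      any(group_proportions < -1e-9) || any(group_proportions > 1 + 1e-9)) {
    stop("`group_proportions` must be three values in [0, 1]", call. = FALSE)
  }
  if (abs(sum(group_proportions) - 1) > 1e-6) {
    stop("`group_proportions` must sum to 1", call. = FALSE)
  }
  profiles <- lapply(profiles, validate_group_profile)
  lv <- frailty_levels()
  with_seed(seed, {
    sizes <- if (deterministic_counts) {
      apportion(n, group_proportions)
    } else {
      as.integer(stats::rmultinom(1, n, group_proportions))
    }
    rows <- lapply(seq_along(lv), function(g) {
      m <- sizes[g]
      if (m == 0L) return(NULL)
      p <- profiles[[lv[g]]]
      height <- rtruncnorm(m, p$height_mean, p$height_sd, 120, 210,
                           match_mean = TRUE)
      bmi <- rtruncnorm(m, p$bmi_mean, p$bmi_sd, 10, 60, match_mean = TRUE)
      data.frame(
        fried = factor(lv[g], levels = lv, ordered = TRUE),
        age = rtruncnorm(m, p$age_mean, p$age_sd, 60, 110,
                         match_mean = TRUE),
        sex = ifelse(runif(m) < p$female_fraction, "female", "male"),
        height = height,
        weight = bmi * (height / 100)^2,
        bmi = bmi,
        mmse = round(rtruncnorm(m, p$mmse_mean, p$mmse_sd, 0, 30,
                                match_mean = TRUE)),
        true_frequency = rtruncnorm(m, p$cycle_frequency_mean,
                                    p$cycle_frequency_sd, 0.2, 3,
                                    match_mean = TRUE),
        true_amplitude = rtruncnorm(m, p$velocity_amplitude_mean,
                                    p$velocity_amplitude_sd, 30, 1500,
                                    match_mean = TRUE),
        true_rom = rtruncnorm(m, p$rom_mean, p$rom_sd, 30, 180,
                              match_mean = TRUE),
        true_decline = rtruncnorm(m, p$fatigue_decline_mean,
                                  p$fatigue_decline_sd, 0, 0.9,
                                  match_mean = TRUE),
        true_jitter = rep(p$cycle_jitter_cv, m),
        stringsAsFactors = FALSE)
    })
    coh <- do.call(rbind, rows)
    coh <- cbind(id = sprintf("S%04d", seq_len(nrow(coh))), coh,
                 stringsAsFactors = FALSE)
    rownames(coh) <- NULL
    coh
  })
}

# Mean of |sin(pi u)|^p over u in [0, 1]; p = 1 gives 2/pi. Controls how
# "square" the velocity waveform is, decoupling range of motion from peak
# angular velocity at a given cycle frequency.
sine_power_mean <- function(p) {
  exp(lgamma((p + 1) / 2) - lgamma(p / 2 + 1)) / sqrt(pi)
}

# Waveform exponent matching a target angle range given amplitude and
# frequency: rom = amplitude / (2 f) * sine_power_mean(p).
solve_waveform_exponent <- function(frequency, amplitude, rom) {
  target <- 2 * frequency * rom / amplitude
  lo <- sine_power_mean(5); hi <- sine_power_mean(0.2)
  if (target >= hi) return(0.2)
  if (target <= lo) return(5)
  stats::uniroot(function(p) sine_power_mean(p) - target,
                 c(0.2, 5), tol = 1e-8)$root
}

#' Simulate an elbow-motion trace
#'
#' Generates a 20-second two-channel angular-velocity recording for one
#' subject. The elbow channel (forearm minus upper arm) is a train of
#' flexion/extension cycles at the subject's cycle frequency: each cycle is
#' a signed power-of-sine pulse whose exponent is chosen so the integrated
#' elbow angle spans the subject's range of motion. Per-cycle amplitude
#' declines linearly in time so that the mean amplitude of cycles in the
#' last 5 s is `(1 - decline)` times the mean over the first 5 s (the scale
#' on which fatigue-related speed reduction is measured), with
#' multiplicative cycle-to-cycle jitter. White sensor noise is added to the
#' forearm channel, and the upper-arm channel is low-amplitude noise
#' representing trunk/shoulder stabilisation.
#'
#' @param subject One row of a cohort table from [sample_demographics()]
#'   (or any list with `true_frequency`, `true_amplitude`, `true_rom`,
#'   `true_decline`, `true_jitter`).
#' @param sampling_rate Sampling rate in Hz (>= 50).
#' @param duration Trial duration in seconds (default 20).
#' @param noise_sd Forearm-channel white noise sd, deg/s.
#' @param upperarm_sd Upper-arm channel noise sd, deg/s.
#' @param seed Integer seed (optional).
#'
#' @return A `motion_trace`: list with `sampling_rate`, `time` (s),
#'   `forearm_velocity` and `upperarm_velocity` (deg/s).
#' @export
#' @examples
#' coh <- sample_demographics(3, seed = 1)
#' tr <- simulate_trace(coh[1, ], seed = 2)
#' str(tr)
simulate_trace <- function(subject, sampling_rate = 100, duration = 20,
                           noise_sd = 1.5, upperarm_sd = 1.0, seed = NULL) {
  stopifnot_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  if (sampling_rate < 50) stop("`sampling_rate` must be >= 50 Hz",
                               call. = FALSE)
  pars <- c(frequency = subject$true_frequency[[1]],
            amplitude = subject$true_amplitude[[1]],
            rom = subject$true_rom[[1]],
            decline = subject$true_decline[[1]],
            jitter = subject$true_jitter[[1]])
  if (any(!is.finite(pars))) {
    stop("non-finite motion parameters for subject", call. = FALSE)
  }
  f <- pars[["frequency"]]; A <- pars[["amplitude"]]
  with_seed(seed, {
    nsamp <- round(duration * sampling_rate)
    t <- seq(0, by = 1 / sampling_rate, length.out = nsamp)
    pexp <- solve_waveform_exponent(f, A, pars[["rom"]])
    period <- 1 / f
    n_cycles <- ceiling(duration / period) + 1L
    starts <- (seq_len(n_cycles) - 1L) * period
    mids <- starts + period / 2
    # linear fatigue ramp anchored at the first/last 5-s window midpoints
    ramp <- 1 - pars[["decline"]] * (mids - 2.5) / (duration - 5)
    ramp <- pmax(ramp, 0.05)
    jit <- 1 + rnorm(n_cycles, 0, pars[["jitter"]])
    amp <- pmax(A * ramp * jit, 0.05 * A)
    cyc_idx <- pmin(floor(t / period) + 1L, n_cycles)
    phase <- (t - starts[cyc_idx]) / period          # in [0, 1)
    s <- sin(2 * pi * phase)
    elbow <- amp[cyc_idx] * sign(s) * abs(s)^pexp
    upper <- rnorm(nsamp, 0, upperarm_sd)
    fore <- elbow + upper + rnorm(nsamp, 0, noise_sd)
    motion_trace(sampling_rate, t, fore, upper)
  })
}

#' Construct a motion trace object
#'
#' @param sampling_rate Sampling rate, Hz.
#' @param time Time stamps in seconds, strictly increasing, uniform.
#' @param forearm_velocity,upperarm_velocity Angular velocity, deg/s.
#' @return A list of class `motion_trace`.
#' @export
motion_trace <- function(sampling_rate, time, forearm_velocity,
                         upperarm_velocity) {
  if (length(time) != length(forearm_velocity) ||
      length(time) != length(upperarm_velocity)) {
    stop("trace channels and time must have equal length", call. = FALSE)
  }
  if (length(time) < 2L) stop("trace is empty or too short", call. = FALSE)
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing",
                                 call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 time = as.numeric(time),
                 forearm_velocity = as.numeric(forearm_velocity),
                 upperarm_velocity = as.numeric(upperarm_velocity)),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("Motion trace: %.1f s at %g Hz (%d samples)\n",
              diff(range(x$time)), x$sampling_rate, length(x$time)))
  invisible(x)
}

#' Generate a full synthetic cohort with motion traces
#'
#' Draws demographics with [sample_demographics()] and one motion trace per
#' subject with [simulate_trace()]. Per-subject trace seeds are derived
#' deterministically from `seed`, so identical `(config, seed)` pairs yield
#' bit-identical output.
#'
#' @param config A [uef_config()].
#' @param seed Integer seed.
#'
#' @return A list of class `uef_cohort` with elements `cohort` (the cohort
#'   table), `traces` (named list of `motion_trace`, one per subject id),
#'   `config` (the configuration echoed back) and `seed`.
#' @export
#' @examples
#' sim <- generate_cohort(uef_config(n = 12), seed = 1)
#' names(sim$traces)[1:3]
generate_cohort <- function(config = uef_config(), seed = 1L) {
  stopifnot(inherits(config, "uef_config"))
  cohort <- sample_demographics(
    n = config$n,
    group_proportions = config$group_proportions,
    profiles = config$profiles,
    seed = seed,
    deterministic_counts = config$deterministic_counts)
  trace_seeds <- with_seed(seed + 1L,
                           sample.int(.Machine$integer.max - 1L, nrow(cohort)))
  traces <- lapply(seq_len(nrow(cohort)), function(i) {
    simulate_trace(cohort[i, ],
                   sampling_rate = config$sampling_rate,
                   duration = config$trial_duration,
                   noise_sd = config$noise_sd,
                   seed = trace_seeds[i])
  })
  names(traces) <- cohort$id
  structure(list(cohort = cohort, traces = traces, config = config,
                 seed = seed),
            class = "uef_cohort")
}

#' @export
print.uef_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s)\n", nrow(x$cohort),
              paste(table(x$cohort$fried), collapse = "/")))
  cat(sprintf("  traces: %d at %g Hz, seed %s\n", length(x$traces),
              x$config$sampling_rate, format(x$seed)))
  invisible(x)
}
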