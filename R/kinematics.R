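#' Anthropometric inertia model for the forearm and hand
#'
#' Segment inertia about the elbow flexion axis is estimated from body mass
#' and stature using standard anthropometric fractions: segment mass as a
#' fraction of body mass, segment length as a fraction of height, and
#' radius of gyration as a fraction of segment length. Defaults are
#' Winter-style values for the combined forearm + hand segment.
#'
#' @param segment_mass_fraction Segment mass / body mass.
#' @param segment_length_fraction Segment length / height.
#' @param gyration_radius_fraction Radius of gyration / segment length.
#' @return A list of class `inertia_model`.
#' @export
inertia_model <- function(segment_mass_fraction = 0.022,
                          segment_length_fraction = 0.254,
                          gyration_radius_fraction = 0.827) {
  fr <- c(segment_mass_fraction, segment_length_fraction,
          gyration_radius_fraction)
  if (any(!is.finite(fr)) || any(fr <= 0) || any(fr >= 1)) {
    stop("inertia fractions must lie in (0, 1)", call. = FALSE)
  }
  structure(list(segment_mass_fraction = segment_mass_fraction,
                 segment_length_fraction = segment_length_fraction,
                 gyration_radius_fraction = gyration_radius_fraction),
            class = "inertia_model")
}

#' Forearm + hand moment of inertia about the elbow
#'
#' `I = (mass * m_frac) * (height/100 * l_frac * k_frac)^2`, in kg m^2.
#'
#' @param mass Body mass, kg.
#' @param height Stature, cm.
#' @param model An [inertia_model()].
#' @return Moment of inertia in kg m^2.
#' @export
#' @examples
#' estimate_inertia(74, 164)
estimate_inertia <- function(mass, height, model = inertia_model()) {
  if (any(!is.finite(mass)) || any(mass <= 0) ||
      any(!is.finite(height)) || any(height <= 0)) {
    stop("`mass` and `height` must be positive", call. = FALSE)
  }
  (mass * model$segment_mass_fraction) *
    (height / 100 * model$segment_length_fraction *
       model$gyration_radius_fraction)^2
}

#' Elbow angular velocity from a two-channel trace
#'
#' The elbow angular velocity is the forearm channel minus the upper-arm
#' channel (flexion positive). Each channel's constant gyroscope bias is
#' estimated as its mean over an initial rest window and removed;
#' `rest_window = 0` (the default) skips bias removal, appropriate when the
#' subject is already moving at the first sample.
#'
#' @param trace A [motion_trace()].
#' @param rest_window Length in seconds of the initial rest window used for
#'   bias estimation.
#' @return A list of class `angular_velocity_series` with `sampling_rate`
#'   and `values` (deg/s).
#' @export
elbow_velocity <- function(trace, rest_window = 0) {
  stopifnot(inherits(trace, "motion_trace"))
  if (length(trace$forearm_velocity) != length(trace$upperarm_velocity)) {
    stop("channel lengths differ", call. = FALSE)
  }
  if (length(trace$forearm_velocity) == 0L) stop("empty trace", call. = FALSE)
  fore <- trace$forearm_velocity
  upper <- trace$upperarm_velocity
  if (rest_window > 0) {
    nrest <- max(1L, min(length(fore),
                         round(rest_window * trace$sampling_rate)))
    fore <- fore - mean(fore[seq_len(nrest)])
    upper <- upper - mean(upper[seq_len(nrest)])
  }
  structure(list(sampling_rate = trace$sampling_rate, values = fore - upper),
            class = "angular_velocity_series")
}

#' @rdname elbow_velocity
#' @param sampling_rate Sampling rate in Hz.
#' @param values Elbow angular velocity samples, deg/s.
#' @export
angular_velocity_series <- function(values, sampling_rate) {
  if (!all(is.finite(values))) stop("velocity series must be finite",
                                    call. = FALSE)
  structure(list(sampling_rate = sampling_rate, values = as.numeric(values)),
            class = "angular_velocity_series")
}

# cumulative trapezoidal integral (same spacing dt)
cumtrapz <- function(x, dt) c(0, cumsum((x[-1] + x[-length(x)]) / 2 * dt))

#' Segment flexion/extension cycles
#'
#' Candidate cycle boundaries are positive-going zero crossings of a
#' low-pass-filtered copy of the series (4th-order zero-phase Butterworth).
#' Candidates closer together than `min_duration` are merged, segments
#' whose raw velocity range falls below `min_range_frac` times the median
#' candidate range are discarded, and a trailing segment from the last
#' onset to the end of the trace is kept when it passes both rules. All
#' per-cycle quantities are computed from the unfiltered series; the elbow
#' angle is obtained by trapezoidal integration with a per-cycle linear
#' detrend to suppress gyroscope drift.
#'
#' @param series An [angular_velocity_series()] (or [elbow_velocity()]
#'   output).
#' @param filter_cutoff Low-pass cutoff in Hz used only for boundary
#'   detection.
#' @param min_duration Minimum cycle duration, seconds.
#' @param min_range_frac Range floor as a fraction of the median candidate
#'   cycle range.
#' @param min_abs_range Absolute velocity-range floor in deg/s; candidate
#'   cycles below it are treated as sensor noise and discarded, so an
#'   all-noise series yields zero cycles rather than spurious ones.
#' @param inertia Optional moment of inertia (kg m^2); when supplied, a
#'   per-cycle peak elbow moment (Nm) is computed as inertia times peak
#'   unsigned angular acceleration (converted to rad/s^2).
#'
#' @return A `data.frame` with one row per cycle: `start`, `end` (half-open
#'   sample-index interval), `velocity_range` (deg/s), `angle_range` (deg),
#'   `acceleration_range` (deg/s^2), `peak_acceleration` (deg/s^2),
#'   `rise_time` (s), `midpoint_time` (s) and, when `inertia` is given,
#'   `peak_moment` (Nm). Zero rows (not an error) when no cycles are found.
#' @export
segment_cycles <- function(series, filter_cutoff = 3, min_duration = 0.25,
                           min_range_frac = 0.10, min_abs_range = 20,
                           inertia = NULL) {
  stopifnot(inherits(series, "angular_velocity_series"))
  v <- series$values
  fs <- series$sampling_rate
  n <- length(v)
  if (n < fs) stop("series shorter than 1 s", call. = FALSE)
  dt <- 1 / fs

  bf <- signal::butter(4, min(filter_cutoff / (fs / 2), 0.99), type = "low")
  vf <- as.numeric(signal::filtfilt(bf, v))

  empty <- data.frame(start = integer(), end = integer(),
                      velocity_range = numeric(), angle_range = numeric(),
                      acceleration_range = numeric(),
                      peak_acceleration = numeric(), rise_time = numeric(),
                      midpoint_time = numeric())
  pos <- vf > 0
  onsets <- which(pos & !c(FALSE, pos[-n]))   # first positive after <= 0
  if (length(onsets) == 0L) return(empty)

  # enforce minimum spacing between onsets
  min_gap <- round(min_duration * fs)
  keep <- onsets[1]
  for (o in onsets[-1]) if (o - keep[length(keep)] >= min_gap) keep <- c(keep, o)
  # leading and trailing partial segments are candidates too (subject to the
  # same duration/range rules), so edge cycles are treated symmetrically
  if (keep[1] > min_gap) keep <- c(1L, keep)
  bounds <- c(keep, n + 1L)                   # trailing segment to trace end
  if (length(bounds) < 2L) return(empty)

  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1] - 1L)
  segs <- segs[segs$end - segs$start + 1L >= min_gap, , drop = FALSE]
  if (nrow(segs) == 0L) return(empty)

  rng <- vapply(seq_len(nrow(segs)), function(i) {
    seg <- v[segs$start[i]:segs$end[i]]
    max(seg) - min(seg)
  }, numeric(1))
  floor_rng <- max(min_range_frac * median(rng), min_abs_range)
  segs <- segs[rng >= floor_rng & rng > 0, , drop = FALSE]
  if (nrow(segs) == 0L) return(empty)

  acc <- c(NA, (v[-(1:2)] - v[1:(n - 2)]) / (2 * dt), NA)  # central diff
  out <- lapply(seq_len(nrow(segs)), function(i) {
    idx <- segs$start[i]:segs$end[i]
    seg <- v[idx]
    a <- acc[idx]; a <- a[is.finite(a)]
    ang <- cumtrapz(seg, dt)
    tt <- seq_along(ang)
    ang <- ang - (ang[1] + (ang[length(ang)] - ang[1]) *
                    (tt - 1) / (length(tt) - 1))   # linear detrend of drift
    data.frame(start = segs$start[i], end = segs$end[i] + 1L,
               velocity_range = max(seg) - min(seg),
               angle_range = max(ang) - min(ang),
               acceleration_range = if (length(a)) max(a) - min(a) else NA_real_,
               peak_acceleration = if (length(a)) max(abs(a)) else NA_real_,
               rise_time = (which.max(seg) - 1L) * dt,
               midpoint_time = ((segs$start[i] + segs$end[i]) / 2 - 1) * dt)
  })
  cycles <- do.call(rbind, out)
  if (!is.null(inertia)) {
    cycles$peak_moment <- inertia * cycles$peak_acceleration * pi / 180
  }
  cycles
}

#' Compute the eight elbow-motion outcomes
#'
#' Aggregates per-cycle quantities into the eight trial-level outcomes:
#' \describe{
#'   \item{speed}{mean per-cycle angular-velocity range (max minus min),
#'     deg/s.}
#'   \item{flexibility}{mean per-cycle elbow flexion (angle) range, deg.}
#'   \item{power}{mean per-cycle product of angular-acceleration range and
#'     angular-velocity range, deg^2/s^3.}
#'   \item{rise_time}{mean time from cycle onset to peak angular velocity,
#'     s.}
#'   \item{moment}{mean per-cycle peak elbow moment, Nm: segment moment of
#'     inertia times peak unsigned angular acceleration.}
#'   \item{speed_variability}{coefficient of variation (percent) of the
#'     per-cycle velocity ranges.}
#'   \item{speed_reduction}{percent change in mean per-cycle velocity range
#'     from the first 5 s to the last 5 s of the trial (cycles assigned to
#'     windows by midpoint time); negative values indicate slowing.}
#'   \item{flexion_number}{number of flexion/extension cycles in the trial.}
#' }
#' With fewer than two cycles, `speed_variability` and `speed_reduction`
#' are `NA` and the remaining outcomes are computed where possible.
#'
#' @param series An [angular_velocity_series()].
#' @param cycles Cycle table from [segment_cycles()].
#' @param mass,height Subject body mass (kg) and stature (cm); required for
#'   the moment outcome.
#' @param model An [inertia_model()].
#' @param window Fatigue-window length in seconds (default 5).
#' @return A one-row `data.frame` of class `uef_parameters` with the eight
#'   outcomes.
#' @export
#' @examples
#' t <- seq(0, 20 - 0.01, by = 0.01)
#' s <- angular_velocity_series(200 * sin(2 * pi * 0.5 * t), 100)
#' compute_uef_parameters(s, segment_cycles(s), mass = 74, height = 164)
compute_uef_parameters <- function(series, cycles, mass = NULL, height = NULL,
                                   model = inertia_model(), window = 5) {
  stopifnot(inherits(series, "angular_velocity_series"))
  ncyc <- nrow(cycles)
  dur <- length(series$values) / series$sampling_rate
  out <- data.frame(speed = NA_real_, flexibility = NA_real_,
                    power = NA_real_, rise_time = NA_real_,
                    moment = NA_real_, speed_variability = NA_real_,
                    speed_reduction = NA_real_, flexion_number = ncyc)
  class(out) <- c("uef_parameters", "data.frame")
  if (ncyc == 0L) return(out)
  out$speed <- mean(cycles$velocity_range)
  out$flexibility <- mean(cycles$angle_range)
  out$power <- mean(cycles$acceleration_range * cycles$velocity_range)
  out$rise_time <- mean(cycles$rise_time)
  if (!is.null(mass) && !is.null(height)) {
    inert <- estimate_inertia(mass, height, model)
    out$moment <- mean(inert * cycles$peak_acceleration * pi / 180)
  }
  if (ncyc >= 2L) {
    out$speed_variability <- 100 * sd(cycles$velocity_range) /
      mean(cycles$velocity_range)
    first <- cycles$velocity_range[cycles$midpoint_time <= window]
    last <- cycles$velocity_range[cycles$midpoint_time >= dur - window]
    if (length(first) && length(last) && mean(first) > 0) {
      out$speed_reduction <- 100 * (mean(last) - mean(first)) / mean(first)
    }
  }
  out
}

#' Extract elbow-motion outcomes from a trace
#'
#' Convenience wrapper: [elbow_velocity()], [segment_cycles()] and
#' [compute_uef_parameters()] in one call.
#'
#' @param trace A [motion_trace()].
#' @param mass,height Body mass (kg) and stature (cm).
#' @param rest_window Initial rest window (s) for bias removal.
#' @param filter_cutoff,min_duration,min_range_frac,min_abs_range
#'   Segmentation settings, see [segment_cycles()].
#' @param model An [inertia_model()].
#' @return A one-row `uef_parameters` data frame.
#' @export
extract_uef <- function(trace, mass = NULL, height = NULL, rest_window = 0,
                        filter_cutoff = 3, min_duration = 0.25,
                        min_range_frac = 0.10, min_abs_range = 20,
                        model = inertia_model()) {
  series <- elbow_velocity(trace, rest_window = rest_window)
  cycles <- segment_cycles(series, filter_cutoff = filter_cutoff,
                           min_duration = min_duration,
                           min_range_frac = min_range_frac,
                           min_abs_range = min_abs_range)
  compute_uef_parameters(series, cycles, mass = mass, height = height,
                         model = model)
}

#' Extract outcomes for a whole cohort
#'
#' Runs [extract_uef()] on every trace of a simulated (or loaded) cohort
#' and appends the eight outcome columns to the cohort table.
#'
#' @param sim A `uef_cohort` from [generate_cohort()], or a list with
#'   elements `cohort` and `traces`.
#' @param ... Passed to [extract_uef()].
#' @return The cohort table with columns `speed`, `flexibility`, `power`,
#'   `rise_time`, `moment`, `speed_variability`, `speed_reduction`,
#'   `flexion_number` appended.
#' @export
extract_cohort <- function(sim, ...) {
  coh <- sim$cohort
  stopifnot(all(coh$id %in% names(sim$traces)))
  feats <- lapply(coh$id, function(id) {
    i <- match(id, coh$id)
    extract_uef(sim$traces[[id]], mass = coh$weight[i],
                height = coh$height[i], ...)
  })
  cbind(coh, do.call(rbind, lapply(feats, as.data.frame)))
}
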