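#' Read and write motion-trace files
#'
#' Traces are plain-text CSV, one file per trial, with columns `time_s`,
#' `forearm_velocity_dps`, `upperarm_velocity_dps` and the sampling rate
#' declared in a commented header line
#' (`# sampling_rate_hz: <value>`).
#'
#' @param path File path.
#' @param trace A [motion_trace()].
#' @param digits Significant digits written (default 6).
#' @return `read_trace()` returns a `motion_trace`; `write_trace()`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path,
                               call. = FALSE)
  header <- readLines(path, n = 5L)
  hl <- grep("^#\\s*sampling_rate_hz:", header, value = TRUE)
  if (!length(hl)) {
    stop("malformed trace header: missing '# sampling_rate_hz:' line",
         call. = FALSE)
  }
  fs <- suppressWarnings(as.numeric(sub("^#\\s*sampling_rate_hz:\\s*", "",
                                        hl[1])))
  if (!is.finite(fs) || fs <= 0) {
    stop("malformed trace header: unreadable sampling rate", call. = FALSE)
  }
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "forearm_velocity_dps", "upperarm_velocity_dps")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("trace file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dt <- diff(tab$time_s)
  if (any(dt <= 0)) stop("`time_s` must be strictly increasing",
                         call. = FALSE)
  if (max(abs(dt - 1 / fs)) > 0.01 / fs) {
    stop("non-uniform time steps beyond tolerance", call. = FALSE)
  }
  motion_trace(fs, tab$time_s, tab$forearm_velocity_dps,
               tab$upperarm_velocity_dps)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path, digits = 6) {
  stopifnot(inherits(trace, "motion_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.10g", trace$sampling_rate), con)
  writeLines("time_s,forearm_velocity_dps,upperarm_velocity_dps", con)
  writeLines(paste(signif(trace$time, digits + 4),
                   signif(trace$forearm_velocity, digits),
                   signif(trace$upperarm_velocity, digits), sep = ","), con)
  invisible(path)
}

#' Read and write cohort tables
#'
#' Cohort tables are CSV with one row per subject. Required columns: `id`
#' (unique) and `fried` (one of non-frail / pre-frail / frail, matched
#' after trimming and case-folding). Demographic columns (`age`, `sex`,
#' `height`, `weight`, `bmi`, `mmse`) and the eight extracted outcome
#' columns are optional - outcomes are typically absent before
#' [extract_cohort()] has run.
#'
#' @param path File path.
#' @param cohort Cohort data frame.
#' @return `read_cohort()` returns the cohort `data.frame` with `fried`
#'   parsed as an ordered factor; `write_cohort()` returns `path`
#'   invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path,
                               call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "fried")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("cohort file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup)) {
    stop("duplicated subject id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  tab$fried <- as_frailty(tab$fried)
  tab
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$fried <- as.character(out$fried)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
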