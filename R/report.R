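#' Descriptive cohort report by frailty group
#'
#' Produces the standard cohort description table: group counts with
#' percentages of the total, per-group mean (SD) of each numeric variable
#' with a between-group one-way ANOVA p-value, and the male fraction per
#' group with a chi-square test.
#'
#' @param cohort Cohort table with `fried`, `sex` and numeric variables.
#' @param vars Numeric columns to summarise (defaults to the demographics
#'   plus any extracted elbow-motion outcomes present).
#' @return A list of class `uef_report`: `counts` (n and percentage per
#'   group), `sex` (male n/percentage per group and chi-square p), and
#'   `table` (one row per variable: per-group `mean (sd)` and p-value).
#' @export
#' @examples
#' coh <- sample_demographics(60, seed = 1)
#' cohort_report(coh)
cohort_report <- function(cohort,
                          vars = intersect(c("age", "height", "weight",
                                             "bmi", "mmse",
                                             uef_parameter_names()),
                                           names(cohort))) {
  fried <- as_frailty(cohort$fried)
  lv <- frailty_levels()
  n <- as.integer(table(fried))
  counts <- data.frame(group = lv, n = n,
                       percent = 100 * n / length(fried))
  sex_tab <- NULL
  if ("sex" %in% names(cohort)) {
    male <- tapply(cohort$sex == "male", fried, sum)
    p_sex <- tryCatch(
      suppressWarnings(chisq.test(table(fried, cohort$sex))$p.value),
      error = function(e) NA_real_)
    sex_tab <- data.frame(group = lv, male_n = as.integer(male),
                          male_percent = 100 * as.numeric(male) / n,
                          p = p_sex)
  }
  rows <- lapply(vars, function(vn) {
    x <- cohort[[vn]]
    m <- tapply(x, fried, mean, na.rm = TRUE)
    s <- tapply(x, fried, sd, na.rm = TRUE)
    p <- tryCatch(summary(aov(x ~ fried))[[1]][["Pr(>F)"]][1],
                  error = function(e) NA_real_)
    out <- data.frame(variable = vn, t(as.numeric(m)), t(as.numeric(s)), p)
    names(out) <- c("variable", paste0("mean_", gsub("-", "", lv)),
                    paste0("sd_", gsub("-", "", lv)), "p")
    out
  })
  structure(list(counts = counts, sex = sex_tab,
                 table = do.call(rbind, rows)),
            class = "uef_report")
}

#' @export
print.uef_report <- function(x, digits = 2, ...) {
  cat("Cohort description by Fried frailty group\n\n")
  with(x$counts, cat(sprintf("  %-10s n = %3d (%4.1f%%)\n", group, n,
                             percent), sep = ""))
  if (!is.null(x$sex)) {
    cat(sprintf("\n  Male: %s (chi-square p = %.2f)\n",
                paste(sprintf("%d (%.0f%%)", x$sex$male_n,
                              x$sex$male_percent), collapse = ", "),
                x$sex$p[1]))
  }
  cat("\n  Variable means (SD) and between-group ANOVA p:\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-18s %s  p = %s\n", tab$variable[i],
                paste(sprintf("%.*f (%.*f)", digits, unlist(tab[i, 2:4]),
                              digits, unlist(tab[i, 5:7])),
                      collapse = "  "),
                format.pval(tab$p[i], digits = 2)))
  }
  invisible(x)
}
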