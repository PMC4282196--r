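# Demographic/clinical group comparison tables: per-variable means, SDs and
# two-sample tests, mirroring the standard participants-characteristics table.

.cohort_cols <- c("subject_id", "group", "sex", "age", "education_years",
                  "cias", "sas", "sds", "bis_attentional", "bis_motor",
                  "bis_nonplanning", "bis_total")

#' Packaged reference cohort scores
#'
#' The per-subject demographic and clinical scores of the emulated study's
#' 39 participants (18 internet-gaming-addiction subjects, 21 healthy
#' controls): sex, age, education years, Chen Internet Addiction Scale
#' (CIAS), Self-Rating Anxiety Scale (SAS), Self-rating Depression Scale
#' (SDS) and Barratt Impulsiveness Scale-11 subscales and total, exactly as
#' published. Scale cut-offs in the source study: CIAS 64, SAS 50, SDS 53.
#'
#' @return data.frame with the [cohort_table()] schema.
#' @export
iga_cohort <- function() {
  f <- system.file("extdata", "iga_cohort_scores.csv", package = "dkimaps",
                   mustWork = TRUE)
  cohort_table(read.csv(f, stringsAsFactors = FALSE))
}

#' Validate a cohort table
#'
#' Checks the per-subject schema used throughout the package: subject id,
#' group (`IGA` or `control`), sex (`M`/`F`), age, education years and the
#' CIAS/SAS/SDS/BIS-11 scores.
#'
#' @param df a data.frame.
#' @return the validated data.frame, classed `cohort_table`.
#' @export
cohort_table <- function(df) {
  miss <- setdiff(.cohort_cols, names(df))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "))
  stopifnot(all(df$group %in% c("IGA", "control")),
            all(df$sex %in% c("M", "F")))
  if (!all(table(df$group) >= 1)) stop("both groups must be nonempty")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Compare one variable between groups
#'
#' For a continuous variable: per-group sample mean and SD (n-1 denominator)
#' and an equal-variance (pooled) two-sample t-test (Welch available behind
#' `var_equal = FALSE`). For `sex`: a Pearson chi-square on the 2x2 table
#' (`yates = TRUE` adds the continuity correction). Two-tailed p throughout.
#' Rows with a missing value are excluded (count reported in the row).
#'
#' @param table a [cohort_table()].
#' @param variable column name, or `"sex"`.
#' @param var_equal pooled-variance t (default) vs Welch.
#' @param yates continuity correction for the chi-square.
#' @return one-row data.frame: `variable`, `mean_iga`, `sd_iga`,
#'   `mean_control`, `sd_control`, `test`, `statistic`, `p`, `n_excluded`.
#'   For `sex` the "means" are the male counts and SDs are `NA`.
#' @export
group_summary <- function(table, variable, var_equal = TRUE, yates = FALSE) {
  stopifnot(inherits(table, "cohort_table") || is.data.frame(table))
  if (!variable %in% names(table)) stop("unknown variable: ", variable)
  g <- table$group
  x <- table[[variable]]
  keep <- !is.na(x) & !is.na(g)
  n_excl <- sum(!keep)
  x <- x[keep]; g <- g[keep]
  if (variable == "sex") {
    tab <- base::table(factor(g, c("IGA", "control")), factor(x, c("M", "F")))
    ct <- suppressWarnings(chisq.test(tab, correct = yates))
    return(data.frame(variable = "sex", mean_iga = tab["IGA", "M"],
                      sd_iga = NA_real_, mean_control = tab["control", "M"],
                      sd_control = NA_real_, test = "chi-square",
                      statistic = unname(ct$statistic), p = ct$p.value,
                      n_excluded = n_excl))
  }
  xi <- x[g == "IGA"]; xc <- x[g == "control"]
  stopifnot(length(xi) >= 2L, length(xc) >= 2L)
  row <- data.frame(variable = variable, mean_iga = mean(xi), sd_iga = sd(xi),
                    mean_control = mean(xc), sd_control = sd(xc),
                    test = if (var_equal) "two-sample t" else "Welch t",
                    statistic = NA_real_, p = NA_real_, n_excluded = n_excl)
  if (sd(xi) == 0 && sd(xc) == 0) {
    row$test <- "degenerate (zero variance)"
    return(row)
  }
  tt <- t.test(xi, xc, var.equal = var_equal)
  row$statistic <- unname(tt$statistic)
  row$p <- tt$p.value
  row
}

#' Demographic and clinical comparison table
#'
#' Builds the standard participants table: age, sex, education, CIAS, SAS,
#' SDS and BIS-11 total, each compared between the IGA and control groups
#' (pooled t for continuous variables, chi-square for sex).
#'
#' @inheritParams group_summary
#' @return data.frame of class `clinical_table`, seven rows.
#' @examples
#' tab <- clinical_table(iga_cohort())
#' print(tab)
#' @export
clinical_table <- function(table, var_equal = TRUE, yates = FALSE) {
  vars <- c("age", "sex", "education_years", "cias", "sas", "sds", "bis_total")
  out <- do.call(rbind, lapply(vars, function(v)
    group_summary(table, v, var_equal = var_equal, yates = yates)))
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' @export
print.clinical_table <- function(x, ...) {
  lab <- c(age = "Age (years)", sex = "Gender (M count)",
           education_years = "Education (years)", cias = "CIAS", sas = "SAS",
           sds = "SDS", bis_total = "BIS-11 total")
  cat(sprintf("%-20s %-16s %-16s %s\n", "", "IGA", "Control", "p-value"))
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    fmt <- function(m, s) if (is.na(s)) sprintf("%g", m)
      else sprintf("%.2f ± %.2f", m, s)
    cat(sprintf("%-20s %-16s %-16s %s\n", lab[[r$variable]],
                fmt(r$mean_iga, r$sd_iga), fmt(r$mean_control, r$sd_control),
                ifelse(is.na(r$p), "-", format.pval(r$p, digits = 3))))
  }
  invisible(x)
}
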