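# Simulated clinical-score cohorts: Gaussian draws per scale and group,
# rounded to the integer instruments and clipped to each scale's range, with
# an optional linkage tying a patient's CIAS score to a regional kurtosis
# deviation (used for correlation-recovery studies).

# valid integer ranges of the instruments
.scale_ranges <- list(
  age = c(10, 80), education_years = c(0, 25),
  cias = c(26, 104), sas = c(20, 80), sds = c(20, 80),
  bis_attentional = c(8, 32), bis_motor = c(11, 44),
  bis_nonplanning = c(11, 44), bis_total = c(30, 120))

#' Clinical score model
#'
#' Per-group means/SDs for each scale plus the male/female ratio, and an
#' optional CIAS-kurtosis linkage coefficient. `default_score_model()`
#' carries the published group statistics of the emulated study (IGA group:
#' CIAS 74.44 +/- 8.33, SAS 53.66 +/- 9.71, SDS 54.72 +/- 10.44, BIS-11
#' 63.94 +/- 8.26, age 20.5 +/- 3.55, education 11.39 +/- 1.85, 15 M / 3 F;
#' controls: CIAS 38.43 +/- 9.10, SAS 40.95 +/- 8.44, SDS 38.57 +/- 6.67,
#' BIS-11 50.81 +/- 6.95, age 21.95 +/- 2.39, education 12.38 +/- 2.13,
#' 18 M / 3 F), with BIS-11 subscale parameters taken from the packaged
#' per-subject table.
#'
#' @param means,sds named lists with elements `IGA` and `control`, each a
#'   named numeric vector over the scales in `names(.scale_ranges)`.
#' @param male_fraction named numeric: probability of male sex per group.
#' @param linkage_r population correlation tying patient CIAS scores to a
#'   supplied regional kurtosis deviation (0 = none).
#' @return object of class `score_model`.
#' @export
score_model <- function(means, sds, male_fraction, linkage_r = 0) {
  for (g in c("IGA", "control")) {
    stopifnot(all(names(.scale_ranges) %in% names(means[[g]])),
              all(names(.scale_ranges) %in% names(sds[[g]])),
              all(sds[[g]] >= 0))
  }
  stopifnot(abs(linkage_r) <= 1)
  structure(list(means = means, sds = sds, male_fraction = male_fraction,
                 linkage_r = linkage_r), class = "score_model")
}

#' @rdname score_model
#' @export
default_score_model <- function(linkage_r = 0) {
  fx <- iga_cohort()
  sub <- c("bis_attentional", "bis_motor", "bis_nonplanning")
  m <- s <- list()
  for (g in c("IGA", "control")) {
    rows <- fx[fx$group == g, ]
    m[[g]] <- c(vapply(sub, function(v) mean(rows[[v]]), 0))
    s[[g]] <- c(vapply(sub, function(v) sd(rows[[v]]), 0))
  }
  m$IGA <- c(age = 20.5, education_years = 11.39, cias = 74.44, sas = 53.66,
             sds = 54.72, bis_total = 63.94, m$IGA)
  s$IGA <- c(age = 3.55, education_years = 1.85, cias = 8.33, sas = 9.71,
             sds = 10.44, bis_total = 8.26, s$IGA)
  m$control <- c(age = 21.95, education_years = 12.38, cias = 38.43,
                 sas = 40.95, sds = 38.57, bis_total = 50.81, m$control)
  s$control <- c(age = 2.39, education_years = 2.13, cias = 9.10, sas = 8.44,
                 sds = 6.67, bis_total = 6.95, s$control)
  score_model(m, s, male_fraction = c(IGA = 15 / 18, control = 18 / 21),
              linkage_r = linkage_r)
}

#' Simulate a clinical-score cohort
#'
#' Draws every scale from `Normal(group mean, group SD)`, rounds to integers
#' and clips to the instrument's valid range; sex is Bernoulli with the
#' group's male fraction. When the model's `linkage_r` is nonzero, patient
#' CIAS scores are generated as
#' `mean + sd * (r * z + sqrt(1 - r^2) * e)` where `z` is the standardized
#' `kurtosis_deviation` supplied per patient (so the population correlation
#' between CIAS and the regional metric is `r`).
#'
#' @param model a [score_model()].
#' @param n_per_group length-2 count `c(IGA, control)`, each >= 2.
#' @param seed RNG seed.
#' @param kurtosis_deviation per-patient regional kurtosis values (length
#'   `n_per_group[1]`); required when `linkage_r != 0`.
#' @return a [cohort_table()] data.frame.
#' @export
simulate_scores <- function(model, n_per_group = c(18L, 21L), seed = 1L,
                            kurtosis_deviation = NULL) {
  stopifnot(inherits(model, "score_model"))
  n_per_group <- as.integer(n_per_group)
  if (any(n_per_group < 0)) stop("negative group size")
  if (any(n_per_group < 2)) stop("each group needs at least 2 subjects")
  r <- model$linkage_r
  if (r != 0) {
    if (is.null(kurtosis_deviation) ||
        length(kurtosis_deviation) != n_per_group[1])
      stop("linkage_r != 0 needs one kurtosis_deviation value per patient")
    z <- as.numeric(scale(kurtosis_deviation))
  }
  with_seed(seed, {
    draw <- function(g, n) {
      df <- data.frame(
        subject_id = paste0(ifelse(g == "IGA", "SIM-IGA", "SIM-CON"), seq_len(n)),
        group = g,
        sex = ifelse(runif(n) < model$male_fraction[[g]], "M", "F"))
      for (v in names(.scale_ranges)) {
        raw <- rnorm(n, model$means[[g]][[v]], model$sds[[g]][[v]])
        if (g == "IGA" && v == "cias" && r != 0)
          raw <- model$means[[g]][[v]] + model$sds[[g]][[v]] *
            (r * z + sqrt(1 - r^2) * rnorm(n))
        rng <- .scale_ranges[[v]]
        df[[v]] <- pmin(pmax(round(raw), rng[1]), rng[2])
      }
      df
    }
    out <- rbind(draw("IGA", n_per_group[1]), draw("control", n_per_group[2]))
  })
  cohort_table(out[, .cohort_cols])
}
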