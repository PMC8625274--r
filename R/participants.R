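#' Participant anthropometrics of the reference cohort
#'
#' The eleven-subject cohort on which the estimation workflow was developed:
#' per-subject age, gender, height and body mass. Body mass is the value
#' used to normalize the ground-reaction-force targets (N to N/kg).
#'
#' @return A tibble with columns `subject_id`, `age_years`, `gender`,
#'   `height_cm`, `weight_kg`.
#' @export
participants <- function() {
  path <- system.file("extdata", "participants.csv", package = "vdjkinetics")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Cohort summary statistics
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' cohort's age, height and weight.
#'
#' @param cohort Participant table as returned by [participants()].
#' @return A tibble with columns `variable`, `mean`, `sd`.
#' @export
participant_summary <- function(cohort = participants()) {
  vars <- c(age_years = "age_years", height_cm = "height_cm",
            weight_kg = "weight_kg")
  dplyr::bind_rows(lapply(names(vars), function(v) {
    tibble::tibble(variable = v, mean = mean(cohort[[v]]),
                   sd = stats::sd(cohort[[v]]))
  }))
}
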