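# Eligibility screening mirroring the survey participant flow.

eligibility_reasons <- function() {
  c("age_under_30", "medical_exclusion", "incomplete_periodontal_status", "edentulous")
}

#' Screen charts for analysis eligibility
#'
#' A participant enters the analysis only if aged at least `min_age`, not
#' medically excluded from the periodontal exam, dentate (at least one
#' eligible tooth present) and with complete periodontal status. "Complete"
#' means every present tooth has all six sites measured for both PPD and CAL
#' (the full-mouth protocol measures every site); relax with
#' `require_complete = FALSE` for partially recorded sources.
#'
#' @param charts Chart tibble (see [validate_charts()]).
#' @param min_age Minimum age in years (default 30).
#' @param require_complete Enforce the complete-periodontal-status rule.
#' @return A tibble with one row per participant: logical columns for each
#'   exclusion reason, `eligible`, and a `reasons` list-column holding the
#'   applicable reason codes (empty iff eligible).
#' @examples
#' ch <- make_fixture_chart(participant_id = "A", age_years = 45)
#' check_eligibility(ch)$eligible
#' @export
check_eligibility <- function(charts, min_age = 30, require_complete = TRUE) {
  validate_charts(charts)
  per <- charts |>
    group_by(.data$participant_id) |>
    summarise(
      age_years = .data$age_years[1],
      medically_excluded = .data$medically_excluded[1],
      n_present = n_distinct(.data$tooth_fdi[.data$present]),
      complete = all(!.data$present | (!is.na(.data$ppd_mm) & !is.na(.data$cal_mm))),
      .groups = "drop"
    ) |>
    mutate(
      age_under_30 = .data$age_years < min_age,
      medical_exclusion = .data$medically_excluded,
      edentulous = .data$n_present == 0L,
      incomplete_periodontal_status =
        require_complete & !.data$complete & !.data$edentulous
    )
  per |>
    mutate(
      reasons = purrr::pmap(
        list(.data$age_under_30, .data$medical_exclusion,
             .data$incomplete_periodontal_status, .data$edentulous),
        function(a, m, i, e) eligibility_reasons()[c(a, m, i, e)]
      ),
      eligible = lengths(.data$reasons) == 0L
    ) |>
    select("participant_id", dplyr::all_of(eligibility_reasons()),
           "eligible", "reasons")
}

#' Summarise an eligibility screen as a participant-flow table
#'
#' Participants failing several criteria are attributed to the first
#' applicable reason in the fixed order age, medical exclusion, incomplete
#' periodontal status, edentulous; counts therefore conserve:
#' initial = analysed + sum of exclusions.
#'
#' @param reports Output of [check_eligibility()].
#' @return A tibble with rows `initial`, one per exclusion reason, and
#'   `analysed`, with participant counts.
#' @export
flow_report <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  first_reason <- purrr::map_chr(reports$reasons,
                                 \(r) if (length(r)) r[[1]] else NA_character_)
  counts <- vapply(eligibility_reasons(),
                   \(r) sum(first_reason == r, na.rm = TRUE), integer(1))
  tibble(
    step = c("initial", eligibility_reasons(), "analysed"),
    n = unname(c(nrow(reports), counts, sum(reports$eligible)))
  )
}
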