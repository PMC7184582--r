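# Long-format CSV chart interchange.

#' Read periodontal charts from long-format CSV
#'
#' The canonical interchange format is a long CSV with one row per measured
#' (participant, tooth, site): columns `participant_id`, `age_years`,
#' `medically_excluded` (0/1), `tooth_fdi`, `present` (0/1), `site`
#' (MB|B|DB|ML|L|DL), `ppd_mm`, `cal_mm`; an empty cell is a missing
#' measurement. The `nhanes_universal` dialect is identical except the tooth
#' column is `tooth_universal` (1-32, Universal numbering); third-molar rows
#' are dropped on input and the remaining codes converted to FDI.
#'
#' Teeth without any row for a participant are completed as present with all
#' sites missing, so a partially listed chart reads back as an incomplete
#' periodontal status (see [check_eligibility()]).
#'
#' @param path CSV file path.
#' @param dialect `"canonical"` (FDI codes) or `"nhanes_universal"`.
#' @param strict If `TRUE`, non-integer millimetre values are an error;
#'   otherwise they are rounded half-up.
#' @param max_mm Measurement ceiling in millimetres.
#' @return A validated chart tibble (28 teeth x 6 sites per participant).
#' @seealso [write_charts()]
#' @export
read_charts <- function(path, dialect = c("canonical", "nhanes_universal"),
                        strict = TRUE, max_mm = 19) {
  dialect <- match.arg(dialect)
  tooth_col <- if (dialect == "canonical") "tooth_fdi" else "tooth_universal"
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    site = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  needed <- c("participant_id", "age_years", "medically_excluded", tooth_col,
              "present", "site", "ppd_mm", "cal_mm")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("chart CSV is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "perioprp_parse_error")
  }

  if (dialect == "nhanes_universal") {
    u <- raw$tooth_universal
    if (any(is.na(u) | u < 1 | u > 32)) {
      bad <- which(is.na(u) | u < 1 | u > 32)[1]
      abort(sprintf("line %d: tooth_universal outside 1-32.", bad + 1L),
            class = "perioprp_parse_error")
    }
    raw$tooth_fdi <- universal_to_fdi(u)
    raw <- filter(raw, !is.na(.data$tooth_fdi))  # third molars dropped
  } else if (any(raw$tooth_fdi %in% third_molars(), na.rm = TRUE)) {
    bad <- which(raw$tooth_fdi %in% third_molars())[1]
    abort(sprintf("line %d: third molar (tooth %d) is not an eligible tooth.",
                  bad + 1L, raw$tooth_fdi[bad]),
          class = "perioprp_parse_error")
  }

  bad_site <- which(!raw$site %in% site_codes())
  if (length(bad_site)) {
    abort(sprintf("line %d: unknown site code '%s'.", bad_site[1] + 1L,
                  raw$site[bad_site[1]]),
          class = "perioprp_parse_error")
  }
  dup <- duplicated(raw[c("participant_id", "tooth_fdi", "site")])
  if (any(dup)) {
    abort(sprintf("line %d: duplicate (participant, tooth, site) measurement.",
                  which(dup)[1] + 1L),
          class = "perioprp_integrity_error")
  }

  for (col in c("ppd_mm", "cal_mm")) {
    v <- raw[[col]]
    frac <- !is.na(v) & v != round(v)
    if (any(frac)) {
      if (strict) {
        abort(sprintf("line %d: %s is not an integer millimetre value (strict mode).",
                      which(frac)[1] + 1L, col),
              class = "perioprp_parse_error")
      }
      v[frac] <- floor(v[frac] + 0.5)  # round half-up, lenient mode
    }
    neg <- !is.na(v) & v < 0
    if (any(neg)) {
      abort(sprintf("line %d: negative %s.", which(neg)[1] + 1L, col),
            class = "perioprp_parse_error")
    }
    raw[[col]] <- as.integer(v)
  }

  meta <- raw |>
    distinct(.data$participant_id, .data$age_years, .data$medically_excluded)
  if (anyDuplicated(meta$participant_id)) {
    abort("inconsistent age/medical-exclusion metadata within a participant.",
          class = "perioprp_integrity_error")
  }

  # Complete the 28 x 6 grid: unlisted sites are missing; a tooth with any
  # row present=0 is absent; unlisted teeth are present but unmeasured.
  tooth_presence <- raw |>
    summarise(present = all(.data$present > 0),
              .by = c("participant_id", "tooth_fdi"))
  grid <- tidyr::expand_grid(
    participant_id = meta$participant_id,
    tooth_fdi = fdi_teeth(),
    site = site_codes()
  )
  charts <- grid |>
    left_join(meta, by = "participant_id") |>
    left_join(tooth_presence, by = c("participant_id", "tooth_fdi")) |>
    left_join(select(raw, "participant_id", "tooth_fdi", "site", "ppd_mm", "cal_mm"),
              by = c("participant_id", "tooth_fdi", "site")) |>
    mutate(
      present = dplyr::coalesce(.data$present, TRUE),
      medically_excluded = .data$medically_excluded > 0,
      age_years = as.integer(.data$age_years),
      tooth_fdi = as.integer(.data$tooth_fdi),
      ppd_mm = ifelse(.data$present, .data$ppd_mm, NA_integer_),
      cal_mm = ifelse(.data$present, .data$cal_mm, NA_integer_)
    ) |>
    select(dplyr::all_of(chart_columns())) |>
    arrange(.data$participant_id, .data$tooth_fdi,
            match(.data$site, site_codes()))
  validate_charts(charts, max_mm = max_mm)
  charts
}

#' Write periodontal charts to long-format canonical CSV
#'
#' Emits the full 28 x 6 grid for every participant so that
#' `read_charts(write_charts(x))` round-trips exactly.
#'
#' @param charts Validated chart tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_charts <- function(charts, path) {
  validate_charts(charts)
  out <- charts |>
    mutate(medically_excluded = as.integer(.data$medically_excluded),
           present = as.integer(.data$present)) |>
    arrange(.data$participant_id, .data$tooth_fdi,
            match(.data$site, site_codes()))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
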