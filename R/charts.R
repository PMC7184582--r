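# Chart data model: coordinate conventions, validation, fixtures.

#' Tooth and site coordinate conventions
#'
#' The analysed dentition is the 28 permanent teeth excluding third molars,
#' identified by FDI two-digit codes (first digit = quadrant 1-4, second =
#' position 1-7 from the midline). Each tooth carries six probing sites:
#' mesio-buccal (MB), mid-buccal (B), disto-buccal (DB), mesio-lingual (ML),
#' mid-lingual (L) and disto-lingual (DL).
#'
#' @return `fdi_teeth()` returns the 28 eligible FDI codes as an integer
#'   vector; `site_codes()` the six site codes in canonical order.
#' @examples
#' length(fdi_teeth())
#' site_codes()
#' @export
fdi_teeth <- function() {
  as.integer(c(11:17, 21:27, 31:37, 41:47))
}

#' @rdname fdi_teeth
#' @export
site_codes <- function() {
  c("MB", "B", "DB", "ML", "L", "DL")
}

third_molars <- function() as.integer(c(18, 28, 38, 48))

# Universal code u (1-32) -> FDI code, third molars included.
.universal_fdi_map <- local({
  upper <- as.integer(c(18, 17, 16, 15, 14, 13, 12, 11, 21, 22, 23, 24, 25, 26, 27, 28))
  lower <- as.integer(c(38, 37, 36, 35, 34, 33, 32, 31, 41, 42, 43, 44, 45, 46, 47, 48))
  c(upper, lower)
})

#' Convert Universal tooth numbers to FDI codes
#'
#' NHANES oral-health files use the Universal (ADA) numbering system
#' (1-32, starting at the upper right third molar and ending at the lower
#' right third molar); analyses here are reported in FDI codes. Third molars
#' (Universal 1, 16, 17, 32) are excluded from the analysed dentition and
#' map to `NA`, which callers treat as an exclusion marker.
#'
#' @param universal Integer vector of Universal tooth numbers in 1-32.
#' @return Integer vector of FDI codes; `NA` for third molars.
#' @examples
#' universal_to_fdi(8)  # 11
#' universal_to_fdi(9)  # 21
#' universal_to_fdi(1)  # NA: third molar
#' @export
universal_to_fdi <- function(universal) {
  u <- suppressWarnings(as.integer(universal))
  if (any(is.na(u) | u < 1L | u > 32L)) {
    abort("`universal` must contain integers in 1-32.", class = "perioprp_coordinate_error")
  }
  fdi <- .universal_fdi_map[u]
  fdi[fdi %in% third_molars()] <- NA_integer_
  fdi
}

#' @rdname universal_to_fdi
#' @param fdi Integer vector of FDI codes from [fdi_teeth()].
#' @export
fdi_to_universal <- function(fdi) {
  f <- as.integer(fdi)
  if (any(!f %in% fdi_teeth())) {
    abort("`fdi` must contain eligible FDI codes (third molars excluded).",
          class = "perioprp_coordinate_error")
  }
  match(f, .universal_fdi_map)
}

chart_columns <- function() {
  c("participant_id", "age_years", "medically_excluded", "tooth_fdi",
    "present", "site", "ppd_mm", "cal_mm")
}

#' Validate a long-format chart table
#'
#' A chart collection is a long tibble with one row per (participant, tooth,
#' site): columns `participant_id`, `age_years`, `medically_excluded`,
#' `tooth_fdi`, `present`, `site`, `ppd_mm`, `cal_mm`. Every participant has
#' exactly the 28 eligible teeth x 6 sites; measurements are integer
#' millimetres in `[0, max_mm]` or `NA` (missing); absent teeth carry only
#' `NA` measurements.
#'
#' @param charts Chart tibble to validate.
#' @param max_mm Measurement ceiling in millimetres.
#' @return `charts`, invisibly, if valid; otherwise an error.
#' @export
validate_charts <- function(charts, max_mm = 19) {
  if (!is.data.frame(charts)) abort("`charts` must be a data frame.")
  missing_cols <- setdiff(chart_columns(), names(charts))
  if (length(missing_cols)) {
    abort(paste0("`charts` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(charts$participant_id) | charts$participant_id == "")) {
    abort("participant_id must be non-empty.")
  }
  if (any(charts$tooth_fdi %in% third_molars())) {
    abort("third molars (18, 28, 38, 48) must not be stored.",
          class = "perioprp_coordinate_error")
  }
  if (any(!charts$tooth_fdi %in% fdi_teeth())) {
    abort("tooth_fdi contains codes outside the eligible FDI set.",
          class = "perioprp_coordinate_error")
  }
  if (any(!charts$site %in% site_codes())) {
    abort("site contains codes outside {MB, B, DB, ML, L, DL}.")
  }
  grid_ok <- charts |>
    dplyr::count(.data$participant_id, .data$tooth_fdi, .data$site) |>
    dplyr::summarise(
      dup = any(.data$n > 1L),
      n_cells = dplyr::n(),
      .by = "participant_id"
    )
  if (any(grid_ok$dup)) {
    abort("duplicate (participant, tooth, site) measurements.",
          class = "perioprp_integrity_error")
  }
  if (any(grid_ok$n_cells != 28L * 6L)) {
    abort("every participant must have exactly 28 teeth x 6 sites.")
  }
  for (col in c("ppd_mm", "cal_mm")) {
    v <- charts[[col]]
    bad <- !is.na(v) & (v < 0 | v > max_mm | v != round(v))
    if (any(bad)) {
      abort(sprintf("%s must be integer millimetres in [0, %d] or NA.", col, max_mm))
    }
  }
  absent <- !charts$present
  if (any(absent & (!is.na(charts$ppd_mm) | !is.na(charts$cal_mm)))) {
    abort("absent teeth must have all-missing measurements.")
  }
  invisible(charts)
}

#' Build a chart from a short list of site measurements
#'
#' Constructs a single participant's full-mouth chart in which every
#' unspecified site on a present tooth reads 0 mm PPD and 0 mm CAL --
#' a periodontally healthy mouth apart from the lesions placed by `spec`.
#' Useful for worked examples and rule-engine fixtures.
#'
#' @param spec Data frame with columns `tooth_fdi`, `site`, `ppd_mm`,
#'   `cal_mm`, one row per lesion site. May be empty.
#' @param participant_id,age_years,medically_excluded Chart metadata.
#' @param absent_teeth FDI codes of missing teeth (all sites become `NA`).
#' @return A one-participant chart tibble (168 rows).
#' @examples
#' ch <- make_fixture_chart(data.frame(
#'   tooth_fdi = c(16, 26), site = "MB", ppd_mm = 5, cal_mm = 6
#' ))
#' nrow(ch)
#' @export
make_fixture_chart <- function(spec = NULL, participant_id = "FX1",
                               age_years = 45, medically_excluded = FALSE,
                               absent_teeth = integer()) {
  chart <- tidyr::expand_grid(tooth_fdi = fdi_teeth(), site = site_codes()) |>
    mutate(
      participant_id = participant_id,
      age_years = as.integer(age_years),
      medically_excluded = isTRUE(medically_excluded),
      present = !.data$tooth_fdi %in% as.integer(absent_teeth),
      ppd_mm = ifelse(.data$present, 0L, NA_integer_),
      cal_mm = ifelse(.data$present, 0L, NA_integer_)
    ) |>
    select(dplyr::all_of(chart_columns()))
  if (!is.null(spec) && nrow(as.data.frame(spec))) {
    spec <- as_tibble(spec)
    if (any(spec$tooth_fdi %in% third_molars()) || any(!spec$tooth_fdi %in% fdi_teeth())) {
      abort("fixture spec addresses an ineligible tooth position.",
            class = "perioprp_coordinate_error")
    }
    if (any(!spec$site %in% site_codes())) {
      abort("fixture spec addresses an unknown site code.")
    }
    key <- paste(chart$tooth_fdi, chart$site)
    skey <- paste(spec$tooth_fdi, spec$site)
    idx <- match(skey, key)
    chart$ppd_mm[idx] <- as.integer(spec$ppd_mm)
    chart$cal_mm[idx] <- as.integer(spec$cal_mm)
  }
  validate_charts(chart)
  chart
}
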