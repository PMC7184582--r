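# Rule engines for the 2012 CDC/AAP and 2018 EFP/AAP case definitions.

#' Site classes used by the case definitions
#'
#' The four mesial/distal probing sites per tooth are interproximal
#' (interdental); the two central faces are the mid sites (mid-buccal and
#' mid-lingual/oral). The 2012 definition consults interproximal sites only;
#' the 2018 definition adds a buccal/oral pathway over the mid sites.
#'
#' @return Character vector of site codes.
#' @examples
#' interproximal_sites()
#' mid_sites()
#' @export
interproximal_sites <- function() c("MB", "DB", "ML", "DL")

#' @rdname interproximal_sites
#' @export
mid_sites <- function() c("B", "L")

# Anatomical arch sequence: position 1..14 running right second molar ->
# left second molar within each arch; adjacency is consecutive positions in
# the same arch regardless of which teeth are clinically present.
tooth_arch <- function(fdi) ifelse(fdi %/% 10L <= 2L, "maxilla", "mandible")

tooth_arch_position <- function(fdi) {
  q <- fdi %/% 10L
  p <- fdi %% 10L
  ifelse(q %in% c(1L, 4L), 8L - p, 7L + p)
}

#' Are two teeth non-adjacent?
#'
#' Adjacency is anatomical: two teeth are adjacent iff they occupy
#' consecutive positions in the same arch's sequence (right second molar
#' through left second molar), irrespective of whether intervening teeth are
#' present. The central incisors 11 and 21 (and 31/41) are adjacent across
#' the midline; teeth in different arches are never adjacent.
#'
#' @param a,b FDI codes (vectorised; `a[i] != b[i]`).
#' @return Logical vector: `TRUE` where the pair is non-adjacent.
#' @examples
#' non_adjacent(11, 21)  # FALSE: adjacent across the midline
#' non_adjacent(16, 36)  # TRUE: different arches
#' non_adjacent(16, 14)  # TRUE even if 15 is missing
#' @export
non_adjacent <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (any(!a %in% fdi_teeth()) || any(!b %in% fdi_teeth())) {
    abort("FDI codes must be in the eligible 28-tooth set.",
          class = "perioprp_coordinate_error")
  }
  if (any(a == b)) abort("`a` and `b` must differ.")
  tooth_arch(a) != tooth_arch(b) |
    abs(tooth_arch_position(a) - tooth_arch_position(b)) >= 2L
}

# Does a set of teeth contain at least one non-adjacent pair?
has_nonadjacent_pair <- function(teeth) {
  teeth <- unique(teeth)
  if (length(teeth) < 2L) return(FALSE)
  if (length(unique(tooth_arch(teeth))) > 1L) return(TRUE)
  pos <- tooth_arch_position(teeth)
  max(pos) - min(pos) >= 2L
}

#' Site selectors
#'
#' A site selector is a tibble with columns `tooth_fdi` and `site` naming
#' the subset of the 28 x 6 examination grid an observer records.
#' `full_mouth_selector()` is the complete grid.
#'
#' @return A selector tibble.
#' @export
full_mouth_selector <- function() {
  tidyr::expand_grid(tooth_fdi = fdi_teeth(), site = site_codes())
}

check_selector <- function(selector) {
  if (is.null(selector)) return(full_mouth_selector())
  if (inherits(selector, "prp_protocol")) selector <- selector$selector
  selector <- as_tibble(selector)
  if (!all(c("tooth_fdi", "site") %in% names(selector))) {
    abort("a selector needs columns `tooth_fdi` and `site`.")
  }
  if (nrow(selector) == 0L) {
    abort("empty site selector.", class = "perioprp_config_error")
  }
  if (any(!selector$tooth_fdi %in% fdi_teeth()) || any(!selector$site %in% site_codes())) {
    abort("selector addresses positions outside the 28 x 6 grid.",
          class = "perioprp_coordinate_error")
  }
  distinct(selector, .data$tooth_fdi, .data$site)
}

# Observed measurements restricted to a selector: present teeth only;
# missing values never satisfy a criterion downstream.
observed_sites <- function(charts, selector) {
  charts |>
    semi_join(selector, by = c("tooth_fdi", "site")) |>
    filter(.data$present)
}

#' Greatest interdental attachment loss under a selector
#'
#' Maximum CAL over the measured interproximal sites the selector includes;
#' 0 when none is measured. This is the "site of greatest loss" quantity the
#' 2018 staging bands are read from.
#'
#' @param charts Chart tibble.
#' @param selector Site selector (default full mouth).
#' @return Tibble with `participant_id` and `max_interdental_cal` (integer mm).
#' @export
max_interdental_cal <- function(charts, selector = NULL) {
  selector <- check_selector(selector)
  obs <- observed_sites(charts, selector) |>
    filter(.data$site %in% interproximal_sites(), !is.na(.data$cal_mm)) |>
    summarise(max_interdental_cal = max(c(.data$cal_mm, 0L)),
              .by = "participant_id")
  distinct(charts, .data$participant_id) |>
    left_join(obs, by = "participant_id") |>
    mutate(max_interdental_cal =
             as.integer(dplyr::coalesce(.data$max_interdental_cal, 0L)))
}

diagnosis_tbl <- function(ids, definition, stage) {
  tibble(
    participant_id = ids,
    definition = definition,
    is_case = stage >= 1L,
    stage = as.integer(stage)
  )
}

#' Classify periodontitis under the 2012 CDC/AAP surveillance definition
#'
#' Only interproximal sites within the selector are consulted. Severity:
#' severe when >=2 interproximal sites with CAL >= 6 mm on >=2 distinct
#' teeth and >=1 interproximal site with PPD >= 5 mm; else moderate when
#' >=2 interproximal sites with CAL >= 4 mm on >=2 distinct teeth or >=2
#' interproximal sites with PPD >= 5 mm on >=2 distinct teeth; else mild
#' when >=2 interproximal sites with CAL >= 3 mm and (>=2 interproximal
#' sites with PPD >= 4 mm on >=2 distinct teeth or >=1 site with
#' PPD >= 5 mm); else none. Missing measurements never satisfy a criterion.
#'
#' @param charts Chart tibble.
#' @param selector Site selector (default full mouth); a [prp_protocol()] is
#'   accepted.
#' @return Tibble with `participant_id`, `definition`, `is_case`, `stage`
#'   (0 none, 1 mild, 2 moderate, 3 severe).
#' @export
classify_2012 <- function(charts, selector = NULL) {
  selector <- check_selector(selector)
  obs <- observed_sites(charts, selector) |>
    filter(.data$site %in% interproximal_sites())
  feat <- obs |>
    group_by(.data$participant_id) |>
    summarise(
      cal6_teeth = n_distinct(.data$tooth_fdi[!is.na(.data$cal_mm) & .data$cal_mm >= 6L]),
      cal4_teeth = n_distinct(.data$tooth_fdi[!is.na(.data$cal_mm) & .data$cal_mm >= 4L]),
      cal3_sites = sum(!is.na(.data$cal_mm) & .data$cal_mm >= 3L),
      ppd5_sites = sum(!is.na(.data$ppd_mm) & .data$ppd_mm >= 5L),
      ppd5_teeth = n_distinct(.data$tooth_fdi[!is.na(.data$ppd_mm) & .data$ppd_mm >= 5L]),
      ppd4_teeth = n_distinct(.data$tooth_fdi[!is.na(.data$ppd_mm) & .data$ppd_mm >= 4L]),
      .groups = "drop"
    )
  all_ids <- distinct(charts, .data$participant_id)
  feat <- left_join(all_ids, feat, by = "participant_id") |>
    mutate(across(-"participant_id", \(x) dplyr::coalesce(x, 0L)))
  stage <- with(feat, ifelse(
    cal6_teeth >= 2L & ppd5_sites >= 1L, 3L,
    ifelse(cal4_teeth >= 2L | ppd5_teeth >= 2L, 2L,
           ifelse(cal3_sites >= 2L & (ppd4_teeth >= 2L | ppd5_sites >= 1L), 1L, 0L))
  ))
  diagnosis_tbl(feat$participant_id, "CDC_AAP_2012", stage)
}

#' Classify periodontitis under the 2018 EFP/AAP case definition
#'
#' A participant is a case when (a) interdental CAL of at least
#' `detectable_cal_mm` is found at two or more non-adjacent teeth
#' (interproximal sites within the selector), or (b) at two or more teeth a
#' mid (buccal/oral) site shows CAL >= 3 mm together with PPD > 3 mm at
#' that same site. Staging reads interdental CAL at the site of greatest
#' loss: 1-2 mm mild (stage 1), 3-4 mm moderate (stage 2), >= 5 mm severe
#' (stages III/IV collapsed, stage 3). Cases detected only through pathway
#' (b) with no measurable interdental loss are staged mild.
#'
#' @inheritParams classify_2012
#' @param detectable_cal_mm Detection threshold (mm) for interdental CAL in
#'   pathway (a); default 1 mm, consistent with the stage-1 band.
#' @return Tibble as in [classify_2012()], `definition = "EFP_AAP_2018"`.
#' @export
classify_2018 <- function(charts, selector = NULL, detectable_cal_mm = 1) {
  selector <- check_selector(selector)
  if (detectable_cal_mm < 1) {
    abort("`detectable_cal_mm` must be >= 1 mm.", class = "perioprp_config_error")
  }
  obs <- observed_sites(charts, selector)
  inter <- filter(obs, .data$site %in% interproximal_sites())
  mid <- filter(obs, .data$site %in% mid_sites())
  feat_a <- inter |>
    group_by(.data$participant_id) |>
    summarise(
      pathway_a = has_nonadjacent_pair(
        .data$tooth_fdi[!is.na(.data$cal_mm) & .data$cal_mm >= detectable_cal_mm]),
      max_cal = max(c(.data$cal_mm[!is.na(.data$cal_mm)], 0L)),
      .groups = "drop"
    )
  feat_b <- mid |>
    group_by(.data$participant_id) |>
    summarise(
      pathway_b = n_distinct(.data$tooth_fdi[
        !is.na(.data$cal_mm) & .data$cal_mm >= 3L &
          !is.na(.data$ppd_mm) & .data$ppd_mm > 3L]) >= 2L,
      .groups = "drop"
    )
  feat <- distinct(charts, .data$participant_id) |>
    left_join(feat_a, by = "participant_id") |>
    left_join(feat_b, by = "participant_id") |>
    mutate(
      pathway_a = dplyr::coalesce(.data$pathway_a, FALSE),
      pathway_b = dplyr::coalesce(.data$pathway_b, FALSE),
      max_cal = dplyr::coalesce(.data$max_cal, 0L)
    )
  is_case <- feat$pathway_a | feat$pathway_b
  stage <- ifelse(!is_case, 0L,
                  ifelse(feat$max_cal >= 5L, 3L,
                         ifelse(feat$max_cal >= 3L, 2L, 1L)))
  diagnosis_tbl(feat$participant_id, "EFP_AAP_2018", stage)
}

definition_codes <- function() c("CDC_AAP_2012", "EFP_AAP_2018")

normalise_definition <- function(definition) {
  d <- toupper(gsub("[^0-9A-Za-z]", "_", definition))
  out <- dplyr::case_when(
    d %in% c("2012", "CDC", "CDC_AAP", "CDC_AAP_2012") ~ "CDC_AAP_2012",
    d %in% c("2018", "EFP", "EFP_AAP", "EFP_AAP_2018") ~ "EFP_AAP_2018",
    TRUE ~ NA_character_
  )
  if (any(is.na(out))) {
    abort(paste0("unknown case definition: ", definition[is.na(out)][1]),
          class = "perioprp_config_error")
  }
  out
}

#' Classify charts under either case definition
#'
#' Thin dispatcher over [classify_2012()] and [classify_2018()].
#'
#' @inheritParams classify_2018
#' @param definition `"CDC_AAP_2012"`/`"2012"` or `"EFP_AAP_2018"`/`"2018"`.
#' @return Diagnosis tibble.
#' @export
classify_charts <- function(charts, definition, selector = NULL,
                            detectable_cal_mm = 1) {
  definition <- normalise_definition(definition)
  if (definition == "CDC_AAP_2012") {
    classify_2012(charts, selector)
  } else {
    classify_2018(charts, selector, detectable_cal_mm = detectable_cal_mm)
  }
}
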