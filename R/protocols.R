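# Named full-mouth partial recording protocols.

ramfjord_teeth <- function() as.integer(c(16, 21, 24, 36, 41, 44))

cpitn_teeth <- function() as.integer(c(17, 16, 11, 26, 27, 36, 37, 31, 46, 47))

protocol_names <- function() {
  c("FULL_MOUTH", "RAMFJORD", "CPITN", "MB_B", "MB_B_DB", "MB_B_DL")
}

normalise_protocol_name <- function(name) {
  toupper(gsub("-", "_", trimws(name)))
}

#' Construct a partial recording protocol
#'
#' The five named full-mouth PRPs, plus the identity protocol and custom
#' selections:
#' * `RAMFJORD` -- the six Ramfjord index teeth (16, 21, 24, 36, 41, 44),
#'   six-site circumferential inspection (36 positions);
#' * `CPITN` -- the ten CPITN index teeth (17, 16, 11, 26, 27, 36, 37, 31,
#'   46, 47), six sites each (60 positions);
#' * `MB_B` -- mesio-buccal and mid-buccal sites on all 28 teeth;
#' * `MB_B_DB` -- MB, B and disto-buccal sites on all teeth;
#' * `MB_B_DL` -- MB, B and disto-lingual sites on all teeth;
#' * `FULL_MOUTH` -- the complete 28 x 6 grid;
#' * `CUSTOM` -- any subset, given via `teeth`/`sites` or `selector`.
#'
#' Missing index teeth contribute no evidence; there is no substitution by
#' neighbouring teeth.
#'
#' @param name Protocol name (case-insensitive; `-` and `_` equivalent).
#' @param teeth,sites For `CUSTOM`: FDI codes and site codes whose product
#'   forms the selector.
#' @param selector For `CUSTOM`: an explicit selector tibble
#'   (`tooth_fdi`, `site`), overriding `teeth`/`sites`.
#' @return A `prp_protocol` object: list with `name` and `selector`.
#' @examples
#' nrow(make_protocol("RAMFJORD")$selector)  # 36
#' nrow(make_protocol("mb-b-dl")$selector)   # 84
#' @export
make_protocol <- function(name, teeth = NULL, sites = NULL, selector = NULL) {
  key <- normalise_protocol_name(name)
  sel <- switch(
    key,
    FULL_MOUTH = full_mouth_selector(),
    RAMFJORD = tidyr::expand_grid(tooth_fdi = ramfjord_teeth(), site = site_codes()),
    CPITN = tidyr::expand_grid(tooth_fdi = cpitn_teeth(), site = site_codes()),
    MB_B = tidyr::expand_grid(tooth_fdi = fdi_teeth(), site = c("MB", "B")),
    MB_B_DB = tidyr::expand_grid(tooth_fdi = fdi_teeth(), site = c("MB", "B", "DB")),
    MB_B_DL = tidyr::expand_grid(tooth_fdi = fdi_teeth(), site = c("MB", "B", "DL")),
    CUSTOM = {
      if (is.null(selector)) {
        if (is.null(teeth) || is.null(sites)) {
          abort("CUSTOM protocols need `teeth` and `sites`, or `selector`.",
                class = "perioprp_config_error")
        }
        selector <- tidyr::expand_grid(tooth_fdi = as.integer(teeth), site = sites)
      }
      selector
    },
    abort(paste0("unknown protocol name: ", name), class = "perioprp_config_error")
  )
  structure(list(name = key, selector = check_selector(sel)),
            class = "prp_protocol")
}

#' @export
print.prp_protocol <- function(x, ...) {
  cat(sprintf("<prp_protocol %s: %d teeth, %d positions>\n",
              x$name, dplyr::n_distinct(x$selector$tooth_fdi), nrow(x$selector)))
  invisible(x)
}

#' Diagnose charts under a partial recording protocol
#'
#' Applies a case definition to the chart restricted to the protocol's
#' sites. With `FULL_MOUTH` this is the reference-standard diagnosis.
#'
#' @param charts Chart tibble.
#' @param protocol A `prp_protocol` or a protocol name for [make_protocol()].
#' @param definition Case definition (see [classify_charts()]).
#' @param detectable_cal_mm Passed to [classify_2018()].
#' @return Diagnosis tibble with a `protocol` column prepended.
#' @export
diagnose_under_protocol <- function(charts, protocol, definition,
                                    detectable_cal_mm = 1) {
  if (!inherits(protocol, "prp_protocol")) protocol <- make_protocol(protocol)
  classify_charts(charts, definition, selector = protocol$selector,
                  detectable_cal_mm = detectable_cal_mm) |>
    mutate(protocol = protocol$name, .before = 1L)
}

#' Export or import a protocol definition as JSON
#'
#' Audit-friendly interchange: `{"name": ..., "teeth": [...], "sites": [...],
#' "positions": [{"tooth_fdi":..., "site":...}, ...]}`. Import rebuilds the
#' selector from `positions` when given, else from the `teeth` x `sites`
#' product.
#'
#' @param protocol A `prp_protocol`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `protocol_to_json()`: the JSON string (invisibly if written to
#'   `path`); `protocol_from_json()`: a `prp_protocol`.
#' @export
protocol_to_json <- function(protocol, path = NULL) {
  stopifnot(inherits(protocol, "prp_protocol"))
  obj <- list(
    name = protocol$name,
    teeth = sort(unique(protocol$selector$tooth_fdi)),
    sites = intersect(site_codes(), unique(protocol$selector$site)),
    positions = protocol$selector
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname protocol_to_json
#' @param json JSON string or file path to read.
#' @export
protocol_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  sel <- if (!is.null(obj$positions)) {
    as_tibble(obj$positions)
  } else {
    tidyr::expand_grid(tooth_fdi = as.integer(obj$teeth), site = obj$sites)
  }
  key <- normalise_protocol_name(obj$name)
  if (key %in% protocol_names()) {
    proto <- make_protocol(key)
    rebuilt <- check_selector(sel)
    if (!identical(arrange(proto$selector, .data$tooth_fdi, .data$site),
                   arrange(rebuilt, .data$tooth_fdi, .data$site))) {
      abort(sprintf("JSON selector does not match the named protocol %s.", key),
            class = "perioprp_integrity_error")
    }
    return(proto)
  }
  structure(list(name = key, selector = check_selector(sel)),
            class = "prp_protocol")
}
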