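# End-to-end runner: ingest/simulate -> eligibility -> diagnoses -> tables.

#' Configure an end-to-end pipeline run
#'
#' @param input Path to a canonical chart CSV, or `NULL` to simulate.
#' @param dialect CSV dialect for `input` (see [read_charts()]).
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param protocols,definitions Which protocols and case definitions to
#'   evaluate.
#' @param ci_level Confidence level for intervals.
#' @param detectable_cal_mm Detection threshold for the 2018 interdental
#'   pathway (mm).
#' @param min_age Eligibility age threshold (years).
#' @param out_dir Output directory for the artifact bundle.
#' @param seed Seed for every stochastic step (simulation).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, dialect = "canonical",
                            synthetic = synthetic_config(),
                            protocols = c("RAMFJORD", "CPITN", "MB_B",
                                          "MB_B_DB", "MB_B_DL"),
                            definitions = c("CDC_AAP_2012", "EFP_AAP_2018"),
                            ci_level = 0.95, detectable_cal_mm = 1,
                            min_age = 30, out_dir = tempfile("perioprp_run_"),
                            seed = synthetic$seed) {
  if (length(protocols) < 1L || length(definitions) < 1L) {
    abort("need at least one protocol and one definition.",
          class = "perioprp_config_error")
  }
  if (detectable_cal_mm < 1) {
    abort("detectable_cal_mm must be >= 1.", class = "perioprp_config_error")
  }
  structure(
    list(input = input, dialect = dialect, synthetic = synthetic,
         protocols = protocols, definitions = normalise_definition(definitions),
         ci_level = ci_level, detectable_cal_mm = detectable_cal_mm,
         min_age = min_age, out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

fmt_pct <- function(x) round(100 * x, 1)

#' Run the full analysis pipeline
#'
#' Ingests (or simulates) charts, applies the eligibility screen, computes
#' full-mouth reference diagnoses under both case definitions, evaluates
#' every requested protocol, and writes the artifact bundle to
#' `config$out_dir`:
#' * `eligibility_flow.csv` -- participant flow counts;
#' * `presence_indicators.csv` -- tidy indicator table (definition,
#'   protocol, indicator, estimate, ci_lo, ci_hi), percentage-type rows on
#'   the 0-100 scale rounded to 1 decimal, DOR-scale rows to 2 decimals;
#' * `staging_performance.csv` -- multiclass AUC and per-stage precision;
#' * `reclassification_matrix.csv` / `reclassification_edges.csv` -- the
#'   full-mouth 2012 -> 2018 staging cross-tab and its edge list;
#' * `run_log.json` -- configuration, seed and library versions.
#'
#' Outputs are a deterministic function of (input, config, seed).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory artifacts (`charts`,
#'   `eligibility`, `flow`, `evaluation`, `reclassification`, `paths`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$input)) {
    charts <- read_charts(config$input, dialect = config$dialect)
  } else {
    charts <- generate_population(config$synthetic, seed = config$seed)$charts
  }

  elig <- check_eligibility(charts, min_age = config$min_age)
  flow <- flow_report(elig)
  kept <- filter(elig, .data$eligible)$participant_id
  if (length(kept) == 0L) abort("no eligible participants.")
  analysed <- filter(charts, .data$participant_id %in% kept)

  ev <- evaluate_protocols(analysed,
                           definitions = config$definitions,
                           protocols = config$protocols,
                           ci_level = config$ci_level,
                           detectable_cal_mm = config$detectable_cal_mm)

  recl <- NULL
  if (all(c("CDC_AAP_2012", "EFP_AAP_2018") %in% config$definitions)) {
    d12 <- classify_2012(analysed)
    d18 <- classify_2018(analysed,
                         detectable_cal_mm = config$detectable_cal_mm)
    stopifnot(identical(d12$participant_id, d18$participant_id))
    recl <- reclassification_table(d12$stage, d18$stage)
  }

  paths <- list(
    flow = file.path(config$out_dir, "eligibility_flow.csv"),
    presence = file.path(config$out_dir, "presence_indicators.csv"),
    staging = file.path(config$out_dir, "staging_performance.csv"),
    log = file.path(config$out_dir, "run_log.json")
  )
  readr::write_csv(flow, paths$flow, progress = FALSE)

  presence_out <- ev$presence |>
    mutate(across(c("estimate", "conf.low", "conf.high"),
                  \(x) ifelse(.data$indicator %in% c("dor", "log10_dor"),
                              round(x, 2), fmt_pct(x)))) |>
    rename(ci_lo = "conf.low", ci_hi = "conf.high")
  readr::write_csv(presence_out, paths$presence, progress = FALSE, na = "")

  staging_out <- ev$staging |>
    mutate(across(c("estimate", "conf.low", "conf.high"), fmt_pct)) |>
    rename(ci_lo = "conf.low", ci_hi = "conf.high")
  readr::write_csv(staging_out, paths$staging, progress = FALSE, na = "")

  if (!is.null(recl)) {
    paths$recl_matrix <- file.path(config$out_dir, "reclassification_matrix.csv")
    paths$recl_edges <- file.path(config$out_dir, "reclassification_edges.csv")
    m <- as.data.frame(unclass(recl))
    names(m) <- paste0("to_", 0:3)
    readr::write_csv(dplyr::bind_cols(tibble(from_stage = 0:3), m),
                     paths$recl_matrix, progress = FALSE)
    readr::write_csv(tidy(recl) |>
                       rename(source_stage = "from_stage",
                              target_stage = "to_stage"),
                     paths$recl_edges, progress = FALSE)
  }

  log <- list(
    seed = config$seed,
    input = config$input %||% "synthetic",
    definitions = config$definitions,
    protocols = config$protocols,
    ci_level = config$ci_level,
    detectable_cal_mm = config$detectable_cal_mm,
    min_age = config$min_age,
    synthetic = if (is.null(config$input)) unclass(config$synthetic),
    versions = list(
      r = paste(R.version$major, R.version$minor, sep = "."),
      perioprp = as.character(packageVersion("perioprp"))
    )
  )
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  invisible(list(charts = charts, eligibility = elig, flow = flow,
                 evaluation = ev, reclassification = recl, paths = paths))
}
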