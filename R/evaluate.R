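# Protocol x definition performance battery against the full-mouth reference.

per_stage_precision <- function(ref_stage, test_stage) {
  purrr::map_dfr(0:3, function(s) {
    tp <- sum(test_stage == s & ref_stage == s)
    denom <- sum(test_stage == s)
    ci <- wilson_ci(tp, denom)
    tibble(stage = s,
           estimate = if (denom > 0) tp / denom else NA_real_,
           conf.low = ci[1], conf.high = ci[2])
  })
}

#' Evaluate partial recording protocols against the full-mouth reference
#'
#' For each case definition the full-mouth diagnosis is the reference
#' standard. Every protocol is then scored against it: the presence-level
#' indicator battery of [indicators()] on the case/non-case labels, the
#' hard-label multiclass staging AUC of [multiclass_auc()], and one-vs-rest
#' per-stage precision (positive predictive value of each predicted stage).
#'
#' @param charts Chart tibble (already eligibility-filtered, if desired).
#' @param definitions Character vector of case definitions.
#' @param protocols Character vector of protocol names, or a list of
#'   `prp_protocol` objects.
#' @param ci_level Confidence level for intervals.
#' @param detectable_cal_mm Passed to [classify_2018()].
#' @return A `prp_evaluation` object with components
#'   `presence` (long tibble: definition, protocol, indicator, estimate,
#'   conf.low, conf.high), `staging` (multiclass AUC and per-stage
#'   precision), `diagnoses` (per-participant reference and protocol
#'   stages), and `prevalence`. [tidy()] returns the combined long table;
#'   [glance()] one wide row per definition x protocol.
#' @examples
#' pop <- generate_population(synthetic_config(n_participants = 40))
#' ev <- evaluate_protocols(pop$charts, protocols = c("FULL_MOUTH", "CPITN"))
#' glance(ev)
#' @export
evaluate_protocols <- function(charts,
                               definitions = c("CDC_AAP_2012", "EFP_AAP_2018"),
                               protocols = c("RAMFJORD", "CPITN", "MB_B",
                                             "MB_B_DB", "MB_B_DL"),
                               ci_level = 0.95,
                               detectable_cal_mm = 1) {
  if (nrow(charts) == 0L) abort("need at least one chart.")
  definitions <- normalise_definition(definitions)
  if (!is.list(protocols)) protocols <- lapply(protocols, make_protocol)
  protocols <- lapply(protocols, function(p) {
    if (inherits(p, "prp_protocol")) p else make_protocol(p)
  })

  presence <- list(); staging <- list(); diagnoses <- list(); prevalence <- list()
  for (def in definitions) {
    ref <- classify_charts(charts, def, selector = NULL,
                           detectable_cal_mm = detectable_cal_mm)
    prevalence[[def]] <- tibble(definition = def,
                                n = nrow(ref),
                                n_cases = sum(ref$is_case),
                                prevalence = mean(ref$is_case))
    for (proto in protocols) {
      test <- diagnose_under_protocol(charts, proto, def,
                                      detectable_cal_mm = detectable_cal_mm)
      test <- left_join(select(ref, "participant_id",
                               ref_case = "is_case", ref_stage = "stage"),
                        select(test, "participant_id", "protocol",
                               test_case = "is_case", test_stage = "stage"),
                        by = "participant_id")
      key <- paste(def, proto$name)
      diagnoses[[key]] <- mutate(test, definition = def, .before = 1L)

      ind <- indicators(confusion(test$ref_case, test$test_case),
                        ci_level = ci_level)
      presence[[key]] <- tidy(ind) |>
        mutate(definition = def, protocol = proto$name, .before = 1L)

      mc_auc <- if (n_distinct(test$ref_stage) >= 2L) {
        multiclass_auc(test$ref_stage, test$test_stage)
      } else {
        NA_real_
      }
      staging[[key]] <- bind_rows(
        tibble(measure = "multiclass_auc", stage = NA_integer_,
               estimate = mc_auc, conf.low = NA_real_, conf.high = NA_real_),
        per_stage_precision(test$ref_stage, test$test_stage) |>
          mutate(measure = "stage_precision", .before = 1L)
      ) |>
        mutate(definition = def, protocol = proto$name, .before = 1L)
    }
  }

  structure(
    list(
      presence = bind_rows(presence),
      staging = bind_rows(staging),
      diagnoses = bind_rows(diagnoses),
      prevalence = bind_rows(prevalence),
      ci_level = ci_level
    ),
    class = "prp_evaluation"
  )
}

#' @export
print.prp_evaluation <- function(x, ...) {
  cat(sprintf("<prp_evaluation: %d definitions x %d protocols, n = %d>\n",
              n_distinct(x$presence$definition),
              n_distinct(x$presence$protocol),
              x$prevalence$n[1]))
  print(glance(x))
  invisible(x)
}

#' @rdname evaluate_protocols
#' @param x,object A `prp_evaluation`.
#' @param ... Unused.
#' @export
tidy.prp_evaluation <- function(x, ...) {
  bind_rows(
    mutate(x$presence, panel = "presence", stage = NA_integer_),
    x$staging |>
      rename(indicator = "measure") |>
      mutate(panel = "staging")
  ) |>
    select("panel", "definition", "protocol", "indicator", "stage",
           "estimate", "conf.low", "conf.high")
}

#' @rdname evaluate_protocols
#' @export
glance.prp_evaluation <- function(x, ...) {
  wide <- x$presence |>
    select("definition", "protocol", "indicator", "estimate") |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "estimate")
  mc <- x$staging |>
    filter(.data$measure == "multiclass_auc") |>
    select("definition", "protocol", staging_auc = "estimate")
  left_join(wide, mc, by = c("definition", "protocol"))
}

#' @rdname evaluate_protocols
#' @export
autoplot.prp_evaluation <- function(object, ...) {
  d <- filter(object$presence,
              .data$indicator %in% c("sensitivity", "specificity",
                                     "accuracy", "precision", "auc", "f1"))
  ggplot(d, aes(x = .data$protocol, y = .data$estimate,
                ymin = .data$conf.low, ymax = .data$conf.high,
                colour = .data$definition)) +
    geom_pointrange(position = position_dodge(width = 0.5)) +
    facet_wrap(~.data$indicator) +
    labs(x = NULL, y = "estimate (proportion)", colour = "case definition") +
    theme_minimal()
}
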