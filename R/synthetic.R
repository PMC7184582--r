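# Synthetic NHANES-like chart population generator.

#' Configuration for the synthetic chart generator
#'
#' The generator emulates the structure of a full-mouth surveillance
#' examination: a mixture of latent severity classes drives (i) tooth loss
#' (base rate plus a class increment per tooth), (ii) site-level attachment
#' loss built from a class mean, a shared tooth-level random effect (giving
#' within-tooth correlation) and independent site noise, rounded to integer
#' millimetres and truncated at zero, and (iii) probing depth as a shrunken
#' function of CAL plus a pocket offset, truncated to `[0, CAL + 3]`. The
#' latent class is generative only: analysis ground truth is always the
#' full-mouth rule-based diagnosis.
#'
#' Defaults describe a dentate adult (30-80 y) surveillance population with
#' roughly two-fifths full-mouth periodontitis prevalence and all four
#' severity classes well represented.
#'
#' @param n_participants Number of charts to generate.
#' @param class_mixture Named probabilities over
#'   `healthy`/`mild`/`moderate`/`severe`, summing to 1.
#' @param tooth_loss_base Per-tooth baseline probability of being absent.
#' @param tooth_loss_per_class Named per-class additions to the loss rate.
#' @param cal_mean_per_class Named per-class mean (mm) of the latent
#'   Gaussian site CAL before rounding and truncation at 0; a negative mean
#'   describes a class whose sites mostly show no measurable loss.
#' @param site_sd Total site-level standard deviation of CAL (mm).
#' @param within_tooth_corr Share of site variance carried by the shared
#'   tooth effect, in `[0, 1)`.
#' @param ppd_shrink Multiplier taking CAL into expected PPD.
#' @param ppd_offset_mean,ppd_offset_sd Pocket offset (mm), mean and SD.
#' @param age_range Two integers, inclusive uniform age range.
#' @param missing_rate Probability a measured site is dropped (both PPD and
#'   CAL missing); default 0, i.e. complete periodontal status.
#' @param max_mm Measurement ceiling (mm).
#' @param seed Default RNG seed used by [generate_population()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 2000,
                             class_mixture = c(healthy = 0.45, mild = 0.20,
                                               moderate = 0.20, severe = 0.15),
                             tooth_loss_base = 0.05,
                             tooth_loss_per_class = c(healthy = 0, mild = 0.05,
                                                      moderate = 0.10, severe = 0.25),
                             cal_mean_per_class = c(healthy = -2.0, mild = 1.2,
                                                    moderate = 2.8, severe = 5.0),
                             site_sd = 1.2,
                             within_tooth_corr = 0.5,
                             ppd_shrink = 0.6,
                             ppd_offset_mean = 1.2,
                             ppd_offset_sd = 0.8,
                             age_range = c(30L, 80L),
                             missing_rate = 0,
                             max_mm = 19,
                             seed = 20200427) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    class_mixture = class_mixture,
    tooth_loss_base = tooth_loss_base,
    tooth_loss_per_class = tooth_loss_per_class,
    cal_mean_per_class = cal_mean_per_class,
    site_sd = site_sd,
    within_tooth_corr = within_tooth_corr,
    ppd_shrink = ppd_shrink,
    ppd_offset_mean = ppd_offset_mean,
    ppd_offset_sd = ppd_offset_sd,
    age_range = as.integer(age_range),
    missing_rate = missing_rate,
    max_mm = as.integer(max_mm),
    seed = as.integer(seed)
  )
  classes <- c("healthy", "mild", "moderate", "severe")
  if (cfg$n_participants < 1L) abort("n_participants must be >= 1.",
                                     class = "perioprp_config_error")
  for (fld in c("class_mixture", "tooth_loss_per_class", "cal_mean_per_class")) {
    if (!identical(sort(names(cfg[[fld]])), sort(classes))) {
      abort(sprintf("%s must be named over %s.", fld, paste(classes, collapse = "/")),
            class = "perioprp_config_error")
    }
    cfg[[fld]] <- cfg[[fld]][classes]
  }
  if (abs(sum(cfg$class_mixture) - 1) > 1e-9 || any(cfg$class_mixture < 0)) {
    abort("class_mixture must be non-negative and sum to 1.",
          class = "perioprp_config_error")
  }
  if (cfg$site_sd < 0 || cfg$ppd_offset_sd < 0) {
    abort("standard deviations must be >= 0.", class = "perioprp_config_error")
  }
  if (cfg$within_tooth_corr < 0 || cfg$within_tooth_corr >= 1) {
    abort("within_tooth_corr must be in [0, 1).", class = "perioprp_config_error")
  }
  loss <- cfg$tooth_loss_base + cfg$tooth_loss_per_class
  if (any(loss < 0 | loss > 1) || cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    abort("probabilities must lie in [0, 1].", class = "perioprp_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

# round() uses banker's rounding; measurements round half away from zero,
# matching whole-mm clinical recording.
round_half_up <- function(x) floor(x + 0.5)

#' Generate a synthetic chart population
#'
#' Fully reproducible from `(config, seed)`: identical inputs yield a
#' bit-identical population.
#'
#' @param config A [synthetic_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list of class `synthetic_population`: `charts` (validated
#'   chart tibble) and `latent` (tibble `participant_id`, `latent_class`).
#' @examples
#' pop <- generate_population(synthetic_config(n_participants = 5))
#' dplyr::count(pop$latent, latent_class)
#' @export
generate_population <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  classes <- names(config$class_mixture)
  withr::with_seed(seed, {
    n <- config$n_participants
    ids <- sprintf("S%05d", seq_len(n))
    latent <- sample(classes, n, replace = TRUE, prob = config$class_mixture)
    ages <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)

    teeth <- tidyr::expand_grid(idx = seq_len(n), tooth_fdi = fdi_teeth())
    loss_p <- pmin(1, pmax(0, config$tooth_loss_base +
                             config$tooth_loss_per_class[latent[teeth$idx]]))
    teeth$present <- runif(nrow(teeth)) >= loss_p
    tooth_sd <- config$site_sd * sqrt(config$within_tooth_corr)
    site_noise_sd <- config$site_sd * sqrt(1 - config$within_tooth_corr)
    teeth$tooth_effect <- rnorm(nrow(teeth), 0, tooth_sd)

    sites <- tidyr::expand_grid(row = seq_len(nrow(teeth)), site = site_codes())
    sites$idx <- teeth$idx[sites$row]
    sites$tooth_fdi <- teeth$tooth_fdi[sites$row]
    sites$present <- teeth$present[sites$row]
    mu <- config$cal_mean_per_class[latent[sites$idx]] +
      teeth$tooth_effect[sites$row]
    cal_raw <- mu + rnorm(nrow(sites), 0, site_noise_sd)
    cal <- pmin(config$max_mm, pmax(0, round_half_up(cal_raw)))
    ppd_raw <- config$ppd_shrink * cal +
      rnorm(nrow(sites), config$ppd_offset_mean, config$ppd_offset_sd)
    ppd <- pmin(cal + 3, pmax(0, round_half_up(ppd_raw)))
    ppd <- pmin(config$max_mm, ppd)
    drop <- config$missing_rate > 0 & runif(nrow(sites)) < config$missing_rate
    keep <- sites$present & !drop

    charts <- tibble(
      participant_id = ids[sites$idx],
      age_years = as.integer(ages[sites$idx]),
      medically_excluded = FALSE,
      tooth_fdi = sites$tooth_fdi,
      present = sites$present,
      site = sites$site,
      ppd_mm = ifelse(keep, as.integer(ppd), NA_integer_),
      cal_mm = ifelse(keep, as.integer(cal), NA_integer_)
    ) |>
      arrange(.data$participant_id, .data$tooth_fdi,
              match(.data$site, site_codes()))
    validate_charts(charts, max_mm = config$max_mm)
    structure(
      list(charts = charts,
           latent = tibble(participant_id = ids,
                           latent_class = factor(latent, levels = classes)),
           config = config, seed = as.integer(seed)),
      class = "synthetic_population"
    )
  })
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population: %d charts, seed %d>\n",
              nrow(x$latent), x$seed))
  print(dplyr::count(x$latent, .data$latent_class))
  invisible(x)
}
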