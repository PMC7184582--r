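# Fixture builders shared across test files.

lesion <- function(tooth_fdi, site, ppd_mm = 0, cal_mm = 0) {
  data.frame(tooth_fdi = tooth_fdi, site = site, ppd_mm = ppd_mm, cal_mm = cal_mm)
}

# A batch of random small charts (each participant has `max_teeth` or fewer
# present teeth) as one long chart tibble. Values are skewed towards low
# millimetre readings so all rule branches get exercised; a share of sites
# is missing.
random_small_charts <- function(n, seed, max_teeth = 6, max_mm = 8,
                                na_rate = 0.1) {
  withr::with_seed(seed, {
    ids <- sprintf("R%05d", seq_len(n))
    k <- sample(seq_len(max_teeth), n, replace = TRUE)
    chosen <- lapply(k, function(kk) sample(fdi_teeth(), kk))
    grid <- tidyr::expand_grid(idx = seq_len(n), tooth_fdi = fdi_teeth(),
                               site = site_codes())
    pres <- matrix(FALSE, n, 28)
    for (i in seq_len(n)) pres[i, match(chosen[[i]], fdi_teeth())] <- TRUE
    present <- pres[cbind(grid$idx, match(grid$tooth_fdi, fdi_teeth()))]
    m <- nrow(grid)
    probs <- c(8, 4, 3, 2, 2, 1.5, 1, 0.7, 0.5)[seq_len(max_mm + 1)]
    cal <- sample(0:max_mm, m, replace = TRUE, prob = probs)
    ppd <- sample(0:max_mm, m, replace = TRUE, prob = probs)
    na_cal <- runif(m) < na_rate
    na_ppd <- runif(m) < na_rate
    tibble::tibble(
      participant_id = ids[grid$idx],
      age_years = 45L,
      medically_excluded = FALSE,
      tooth_fdi = grid$tooth_fdi,
      present = present,
      site = grid$site,
      ppd_mm = ifelse(present & !na_ppd, as.integer(ppd), NA_integer_),
      cal_mm = ifelse(present & !na_cal, as.integer(cal), NA_integer_)
    )
  })
}

# A random sub-selector of the full grid with at least one position.
random_selector <- function(p = 0.5) {
  grid <- full_mouth_selector()
  keep <- stats::runif(nrow(grid)) < p
  if (!any(keep)) keep[sample(nrow(grid), 1)] <- TRUE
  grid[keep, ]
}
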