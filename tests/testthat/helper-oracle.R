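# Independent brute-force oracles. Deliberately written as explicit
# enumerations over site pairs, sharing no code with the package engines.

# Adjacency re-derived from explicit arch sequences.
.oracle_arches <- list(
  maxilla = c(17, 16, 15, 14, 13, 12, 11, 21, 22, 23, 24, 25, 26, 27),
  mandible = c(47, 46, 45, 44, 43, 42, 41, 31, 32, 33, 34, 35, 36, 37)
)

oracle_adjacent <- function(a, b) {
  for (arch in .oracle_arches) {
    ia <- match(a, arch); ib <- match(b, arch)
    if (!is.na(ia) && !is.na(ib)) return(abs(ia - ib) == 1)
  }
  FALSE
}

# Measured site records of one participant restricted to a selector:
# data frame with tooth, site, cal, ppd (NA allowed).
oracle_sites <- function(chart, selector) {
  key <- paste(chart$tooth_fdi, chart$site)
  skey <- paste(selector$tooth_fdi, selector$site)
  rows <- chart[key %in% skey & chart$present, ]
  data.frame(tooth = rows$tooth_fdi, site = rows$site,
             cal = rows$cal_mm, ppd = rows$ppd_mm)
}

.ip <- c("MB", "DB", "ML", "DL")

# 2012 CDC/AAP oracle: enumerate all site pairs explicitly.
oracle_stage_2012 <- function(chart, selector = full_mouth_selector()) {
  s <- oracle_sites(chart, selector)
  s <- s[s$site %in% .ip, ]
  n <- nrow(s)
  cal_pair_teeth <- function(thr) {   # pair of qualifying sites on distinct teeth
    if (n < 2) return(FALSE)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(s$cal[i]) && !is.na(s$cal[j]) &&
          s$cal[i] >= thr && s$cal[j] >= thr && s$tooth[i] != s$tooth[j]) {
        return(TRUE)
      }
    }
    FALSE
  }
  ppd_pair_teeth <- function(thr) {
    if (n < 2) return(FALSE)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(s$ppd[i]) && !is.na(s$ppd[j]) &&
          s$ppd[i] >= thr && s$ppd[j] >= thr && s$tooth[i] != s$tooth[j]) {
        return(TRUE)
      }
    }
    FALSE
  }
  cal_pair_any <- function(thr) sum(!is.na(s$cal) & s$cal >= thr) >= 2
  ppd_any <- function(thr) any(!is.na(s$ppd) & s$ppd >= thr)

  if (cal_pair_teeth(6) && ppd_any(5)) return(3L)
  if (cal_pair_teeth(4) || ppd_pair_teeth(5)) return(2L)
  if (cal_pair_any(3) && (ppd_pair_teeth(4) || ppd_any(5))) return(1L)
  0L
}

# 2018 EFP/AAP oracle.
oracle_stage_2018 <- function(chart, selector = full_mouth_selector(),
                              detectable = 1) {
  s <- oracle_sites(chart, selector)
  ip <- s[s$site %in% .ip, ]
  md <- s[s$site %in% c("B", "L"), ]
  qual <- unique(ip$tooth[!is.na(ip$cal) & ip$cal >= detectable])
  pathway_a <- FALSE
  if (length(qual) >= 2) {
    for (i in seq_along(qual)) for (j in seq_along(qual)) {
      if (i < j && !oracle_adjacent(qual[i], qual[j])) pathway_a <- TRUE
    }
  }
  bo <- !is.na(md$cal) & md$cal >= 3 & !is.na(md$ppd) & md$ppd > 3
  pathway_b <- length(unique(md$tooth[bo])) >= 2
  if (!pathway_a && !pathway_b) return(0L)
  mx <- max(c(ip$cal[!is.na(ip$cal)], 0))
  if (mx >= 5) 3L else if (mx >= 3) 2L else 1L
}

# Stage an entire chart collection with an oracle, one participant at a time.
oracle_stage_all <- function(charts, fun, ...) {
  out <- vapply(split(as.data.frame(charts), charts$participant_id),
                fun, integer(1), ...)
  out[order(names(out))]
}

# Literal indicator formulas, written straight from their definitions.
oracle_indicators <- function(tp, fp, tn, fn) {
  tp <- as.double(tp); fp <- as.double(fp)
  tn <- as.double(tn); fn <- as.double(fn)
  n <- tp + fp + tn + fn
  list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / n,
    precision = tp / (tp + fp),
    youden = tp / (tp + fn) + tn / (tn + fp) - 1,
    f1 = 2 * tp / (2 * tp + fp + fn),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
    auc = (tp / (tp + fn) + tn / (tn + fp)) / 2,
    dor = (tp / fn) / (fp / tn)
  )
}

# Brute-force pairwise label AUC: average over all (i-class, j-class)
# observation pairs of the indicator that the j observation scores higher,
# ties half.
oracle_pairwise_auc <- function(ref, test, ci, cj) {
  lo <- test[ref == ci]; hi <- test[ref == cj]
  tot <- 0
  for (a in lo) for (b in hi) tot <- tot + (b > a) + 0.5 * (b == a)
  tot / (length(lo) * length(hi))
}

oracle_multiclass_auc <- function(ref, test) {
  cls <- sort(unique(ref))
  vals <- c()
  for (i in seq_along(cls)) for (j in seq_along(cls)) {
    if (i < j) vals <- c(vals, oracle_pairwise_auc(ref, test, cls[i], cls[j]))
  }
  mean(vals)
}
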