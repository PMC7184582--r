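# Confusion counts, indicator battery, AUCs and reclassification.

test_that("confusion tabulates binary labels correctly", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(unlist(cc[c("tp", "fp", "tn", "fn")]),
                   c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  agree <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_identical(agree$fp + agree$fn, 0L)
  allneg <- confusion(rep(0, 10), rep(0, 10))
  expect_identical(allneg$tn, 10L)
  expect_identical(allneg$tp + allneg$fp + allneg$fn, 0L)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
  expect_error(confusion_counts(0, 0, 0, 0), "at least one")
})

test_that("indicators agree with the literal formulas on random tables", {
  tables <- withr::with_seed(99, replicate(1000, {
    repeat {
      cells <- rpois(4, lambda = sample(c(2, 20, 200), 1))
      if (sum(cells) >= 1) break
    }
    cells
  }))
  for (k in seq_len(ncol(tables))) {
    cells <- tables[, k]
    cc <- confusion_counts(cells[1], cells[2], cells[3], cells[4])
    got <- glance(indicators(cc))
    want <- oracle_indicators(tp = cells[1], fp = cells[2],
                              tn = cells[3], fn = cells[4])
    for (ind in c("sensitivity", "specificity", "accuracy", "precision",
                  "youden", "f1", "mcc", "auc")) {
      w <- want[[ind]]
      if (is.nan(w) || is.infinite(w)) {
        expect_true(is.na(got[[ind]]))
      } else {
        expect_equal(got[[ind]], w, tolerance = 1e-12)
      }
    }
    if (all(cells > 0)) {
      expect_equal(got$dor, want$dor, tolerance = 1e-12)
    }
  }
})

test_that("perfect and textbook classifiers score as expected", {
  perfect <- glance(indicators(confusion_counts(tp = 50, fp = 0, tn = 50, fn = 0)))
  for (ind in c("sensitivity", "specificity", "accuracy", "precision",
                "youden", "f1", "mcc", "auc")) {
    expect_equal(perfect[[ind]], 1)
  }
  g <- glance(indicators(confusion_counts(tp = 50, fn = 50, tn = 90, fp = 10)))
  expect_equal(g$sensitivity, 0.5)
  expect_equal(g$specificity, 0.9)
  expect_equal(g$youden, 0.4)
  expect_equal(g$accuracy, 0.7)
  expect_equal(g$precision, 50 / 60)
  expect_equal(g$auc, 0.7)
})

test_that("empty denominators yield NA rather than zero", {
  no_pos <- glance(indicators(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 0)))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$precision))
  expect_true(is.na(no_pos$youden))
  expect_true(is.na(no_pos$auc))
  expect_equal(no_pos$specificity, 1)
})

test_that("DOR and its log-scale interval follow the stated formula", {
  sym <- dor_ci(confusion_counts(tp = 25, fp = 25, tn = 25, fn = 25))
  expect_equal(sym$dor, 1)
  expect_equal(sym$conf.low, 1 / sym$conf.high)

  d <- dor_ci(confusion_counts(tp = 90, fn = 10, fp = 10, tn = 90))
  expect_equal(d$dor, 81)
  se <- sqrt(1 / 90 + 1 / 10 + 1 / 10 + 1 / 90)
  expect_equal(d$conf.low, exp(log(81) - 1.96 * se), tolerance = 1e-3)
  expect_equal(d$conf.high, exp(log(81) + 1.96 * se), tolerance = 1e-3)
  expect_equal(round(d$conf.low, 1), 32.2)
  expect_equal(round(d$conf.high, 1), 204.1)
  expect_equal(d$log10_dor, log10(81))
  expect_false(d$corrected)

  z <- dor_ci(confusion_counts(tp = 10, fn = 0, fp = 2, tn = 8))
  expect_true(z$corrected)
  expect_equal(z$dor, (10.5 / 0.5) / (2.5 / 8.5))
})

test_that("hard-label AUC identities hold exactly", {
  expect_equal(binary_auc_from_labels(confusion_counts(10, 0, 10, 0)), 1)
  expect_equal(binary_auc_from_labels(confusion_counts(5, 5, 5, 5)), 0.5)
  withr::with_seed(12, {
    for (i in 1:50) {
      cells <- rpois(4, 30) + 1
      cc <- confusion_counts(cells[1], cells[2], cells[3], cells[4])
      g <- glance(indicators(cc))
      expect_identical(binary_auc_from_labels(cc), (g$sensitivity + g$specificity) / 2)
      expect_identical(binary_auc_from_labels(cc), (g$youden + 1) / 2)
      expect_true(g$mcc >= -1 && g$mcc <= 1)
    }
  })
})

test_that("MCC is 1 exactly when there are no errors and both classes occur", {
  expect_equal(glance(indicators(confusion_counts(3, 0, 7, 0)))$mcc, 1)
  expect_true(glance(indicators(confusion_counts(3, 1, 7, 0)))$mcc < 1)
  expect_equal(glance(indicators(confusion_counts(0, 7, 0, 3)))$mcc, -1)
})

test_that("duplicating negatives changes prevalence-dependent indicators only", {
  base <- confusion_counts(tp = 30, fp = 8, tn = 42, fn = 20)
  k <- 5L
  dup <- confusion_counts(tp = 30, fp = 8 * k, tn = 42 * k, fn = 20)
  g1 <- glance(indicators(base)); g2 <- glance(indicators(dup))
  for (ind in c("sensitivity", "specificity", "dor", "auc", "youden")) {
    expect_equal(g1[[ind]], g2[[ind]], tolerance = 1e-12)
  }
  for (ind in c("accuracy", "precision", "f1", "mcc")) {
    expect_false(isTRUE(all.equal(g1[[ind]], g2[[ind]])))
  }
})

test_that("Wilson intervals match prop.test without continuity correction", {
  cases <- list(c(8, 10), c(1, 50), c(999, 1000), c(0, 20), c(35, 35))
  for (cs in cases) {
    got <- perioprp:::wilson_ci(cs[1], cs[2])
    want <- stats::prop.test(cs[1], cs[2], correct = FALSE)$conf.int
    expect_equal(got, as.numeric(want), tolerance = 1e-9)
  }
})

test_that("multiclass AUC reduces to binary and matches brute force", {
  # perfect agreement over four classes
  ref <- rep(0:3, each = 5)
  expect_equal(multiclass_auc(ref, ref), 1)

  # two classes present: equals the hard-label binary AUC of the 2x2 table
  ref2 <- c(rep(0, 12), rep(1, 8))
  tst2 <- withr::with_seed(3, sample(0:1, 20, replace = TRUE))
  expect_equal(multiclass_auc(ref2, tst2),
               binary_auc_from_labels(confusion(ref2, tst2)))

  # small fixed instance against pairwise enumeration
  ref3 <- c(0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 0, 1)
  tst3 <- c(0, 1, 0, 1, 2, 0, 1, 2, 2, 1, 2, 1)
  expect_equal(multiclass_auc(ref3, tst3), oracle_multiclass_auc(ref3, tst3))

  # random instances, including test labels outside the reference pair
  withr::with_seed(8, {
    for (i in 1:20) {
      n <- sample(8:30, 1)
      ref <- sample(0:3, n, replace = TRUE)
      if (length(unique(ref)) < 2) next
      tst <- sample(0:3, n, replace = TRUE)
      expect_equal(multiclass_auc(ref, tst), oracle_multiclass_auc(ref, tst))
    }
  })

  expect_error(multiclass_auc(rep(1, 5), c(0, 1, 2, 3, 0)),
               class = "perioprp_config_error")
})

test_that("multiclass AUC is invariant under consistent relabelling", {
  withr::with_seed(21, {
    ref <- sample(0:3, 40, replace = TRUE)
    tst <- pmin(3, pmax(0, ref + sample(-1:1, 40, replace = TRUE)))
    base <- multiclass_auc(ref, tst)
    perm <- c(5, 7, 11, 13)  # strictly increasing relabelling
    expect_equal(multiclass_auc(perm[ref + 1], perm[tst + 1]), base)
  })
})

test_that("multiclass AUC agrees with pROC on ordinal predictions", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    ref <- sample(0:3, 300, replace = TRUE)
    tst <- pmin(3, pmax(0, ref + sample(-1:1, 300, replace = TRUE,
                                        prob = c(.2, .5, .3))))
  })
  got <- multiclass_auc(ref, tst)
  want <- suppressMessages(
    as.numeric(pROC::multiclass.roc(ref, tst, direction = "<")$auc))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("reclassification cross-tab counts transitions", {
  ident <- reclassification_table(c(0, 1, 2, 3, 2), c(0, 1, 2, 3, 2))
  expect_identical(sum(ident), 5L)
  expect_identical(sum(diag(unclass(ident))), 5L)

  downgraded <- reclassification_table(c(2, 1), c(0, 0))
  expect_identical(downgraded["2", "0"], 1L)
  expect_identical(downgraded["1", "0"], 1L)
  expect_identical(sum(downgraded), 2L)

  expect_error(reclassification_table(integer(), integer()))
  expect_error(reclassification_table(c(0, 4), c(0, 0)))

  edges <- tidy(downgraded)
  expect_identical(nrow(edges), 16L)
  expect_identical(sum(edges$count), 2L)
})

test_that("evaluate_protocols produces the full battery with expected shape", {
  pop <- generate_population(synthetic_config(n_participants = 120, seed = 77))
  ev <- evaluate_protocols(pop$charts,
                           protocols = c("FULL_MOUTH", "RAMFJORD", "CPITN"))
  g <- glance(ev)
  expect_identical(nrow(g), 2L * 3L)

  fm <- dplyr::filter(g, protocol == "FULL_MOUTH")
  for (ind in c("sensitivity", "specificity", "accuracy", "precision",
                "f1", "mcc", "auc")) {
    expect_true(all(fm[[ind]] == 1))
  }
  expect_true(all(fm$staging_auc == 1))

  # partial protocols cannot create false positives against the reference
  spec_rows <- dplyr::filter(ev$presence, indicator == "specificity")
  expect_true(all(spec_rows$estimate == 1))

  # per-stage precision rows exist for all four stages
  prec <- dplyr::filter(ev$staging, measure == "stage_precision")
  expect_identical(nrow(prec), 2L * 3L * 4L)
  td <- tidy(ev)
  expect_true(all(c("panel", "indicator", "estimate") %in% names(td)))
})

test_that("a healthy-only population propagates NA for positive-class rates", {
  cfg <- synthetic_config(n_participants = 30,
                          class_mixture = c(healthy = 1, mild = 0,
                                            moderate = 0, severe = 0),
                          cal_mean_per_class = c(healthy = 0, mild = 1,
                                                 moderate = 3, severe = 5),
                          site_sd = 0, seed = 5)
  pop <- generate_population(cfg)
  expect_false(any(classify_2018(pop$charts)$is_case))
  expect_false(any(classify_2012(pop$charts)$is_case))
  ev <- evaluate_protocols(pop$charts, protocols = "CPITN")
  sens <- dplyr::filter(ev$presence, indicator == "sensitivity")
  expect_true(all(is.na(sens$estimate)))
})

test_that("autoplot methods return ggplot objects", {
  pop <- generate_population(synthetic_config(n_participants = 60, seed = 9))
  ev <- evaluate_protocols(pop$charts, protocols = c("CPITN", "MB_B"))
  expect_s3_class(autoplot(ev), "ggplot")
  ct <- reclassification_table(c(0, 1, 2, 3), c(0, 0, 2, 3))
  expect_s3_class(autoplot(ct), "ggplot")
})
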