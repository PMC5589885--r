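breast_panel <- function() {
  marker_panel("breast", c(DRAQ5 = 20, CD45 = 30, CD66b = 30, CD16 = 30,
                           EpCAM = 147))
}

test_that("positivity is strict-greater-than the panel threshold", {
  p <- breast_panel()
  ev <- c(DRAQ5 = 100, CD45 = 0, CD66b = 0, CD16 = 0, EpCAM = 200)
  calls <- call_positivity(ev, p)
  expect_true(calls[["EpCAM"]])
  ev["EpCAM"] <- 147  # exactly at threshold -> negative
  expect_false(call_positivity(ev, p)[["EpCAM"]])
  zero <- setNames(rep(0, 5), names(ev))
  expect_true(all(!call_positivity(zero, p)))
  expect_error(call_positivity(c(DRAQ5 = 1), p), "missing marker")
})

test_that("epithelial CTC rule requires nucleus, exclusion and EpCAM", {
  p <- breast_panel()
  ok <- c(DRAQ5 = TRUE, CD45 = FALSE, CD66b = FALSE, CD16 = FALSE,
          EpCAM = TRUE)
  expect_true(call_ctc(ok, p))
  expect_false(call_ctc(replace(ok, "CD45", TRUE), p))
  expect_false(call_ctc(replace(ok, "DRAQ5", FALSE), p))
  expect_false(call_ctc(replace(ok, "EpCAM", FALSE), p))
})

test_that("melanoma CTC rule requires both CD146 and NG2", {
  p <- marker_panel("melanoma", c(DRAQ5 = 20, CD45 = 30, CD66b = 30,
                                  CD16 = 30, CD146 = 50, NG2 = 50))
  base <- c(DRAQ5 = TRUE, CD45 = FALSE, CD66b = FALSE, CD16 = FALSE,
            CD146 = TRUE, NG2 = TRUE)
  expect_true(call_ctc(base, p))
  expect_false(call_ctc(replace(base, "NG2", FALSE), p))
})

test_that("deconvolution recovers each archetype and flags the rest", {
  expect_equal(deconvolve_contaminant(archetype_calls("leukocyte")),
               "leukocyte")
  expect_equal(deconvolve_contaminant(archetype_calls("erythroblast")),
               "erythroblast")
  expect_equal(deconvolve_contaminant(archetype_calls("bare_nucleus")),
               "bare_nucleus")
  expect_equal(deconvolve_contaminant(archetype_calls("megakaryocyte")),
               "megakaryocyte")
  # conflicting pattern matches no rule
  mixed <- archetype_calls("leukocyte")
  mixed["GlyA"] <- TRUE
  expect_equal(deconvolve_contaminant(mixed), "unclassified")
  # non-nucleated events are out of assay scope
  bare <- archetype_calls("bare_nucleus")
  bare["DRAQ5"] <- FALSE
  expect_error(deconvolve_contaminant(bare), "DRAQ5")
  # satellite platelets veto the megakaryocyte call
  expect_equal(deconvolve_contaminant(archetype_calls("megakaryocyte"),
                                      satellite_platelets = TRUE),
               "unclassified")
})

test_that("noise-free archetype mixtures are recovered completely", {
  cfg <- synth_config(seed = 31)
  mix <- c(bare_nucleus = 0.46, WBC = 0.28, erythroblast = 0.16,
           megakaryocyte = 0.10)
  pop <- sample_population(cfg, 500, mix)
  calls <- as.data.frame(t(vapply(pop$class_label, archetype_calls,
                                  logical(6))))
  labels <- deconvolve_events(calls)
  expect_true(all(labels != "unclassified"))
  expect_equal(mean(labels == "bare_nucleus"),
               mean(pop$class_label == "bare_nucleus"))
})

test_that("dropout-degraded accounting matches its closed form", {
  # each positive call independently lost with probability p; an event is
  # accounted iff all its archetype positives survive, so the expected
  # accounted fraction among nucleated events is sum_c w_c (1-p)^(k_c - 1)
  # with k_c positives including DRAQ5
  cfg <- synth_config(seed = 33)
  mix4 <- c(bare_nucleus = 0.46, WBC = 0.28, erythroblast = 0.16,
            megakaryocyte = 0.017)
  mix4 <- mix4 / sum(mix4)
  n <- 20000
  pop <- sample_population(cfg, n, mix4)
  calls <- as.data.frame(t(vapply(pop$class_label, archetype_calls,
                                  logical(6))))
  p <- 0.05
  noisy <- drop_positive_calls(calls, p, seed = 34)
  nucleated <- noisy$DRAQ5
  labels <- deconvolve_events(noisy[nucleated, ])
  acc <- mean(labels %in% c("leukocyte", "erythroblast", "bare_nucleus",
                            "megakaryocyte"))
  k <- c(bare_nucleus = 2, WBC = 3, erythroblast = 2, megakaryocyte = 2)
  expected <- sum(mix4 * (1 - p)^(k[names(mix4)] - 1))
  mc_sigma <- sqrt(expected * (1 - expected) / sum(nucleated))
  expect_lt(abs(acc - expected), 4 * mc_sigma)
})

test_that("marker bins reproduce printed tallies and conserve counts", {
  # 86 events: 19 PSMA+/EpCAM-, 17 EpCAM+/PSMA-, 50 double positive
  calls <- data.frame(
    PSMA = rep(c(TRUE, FALSE, TRUE), c(19, 17, 50)),
    EpCAM = rep(c(FALSE, TRUE, TRUE), c(19, 17, 50)))
  bins <- marker_bins(calls, c("PSMA", "EpCAM"))
  expect_equal(sum(bins$count), 86)
  get <- function(b) bins$percent_reported[bins$bin == b]
  expect_equal(get("PSMA+/EpCAM-"), 22)
  expect_equal(get("PSMA-/EpCAM+"), 20)
  expect_equal(get("PSMA+/EpCAM+"), 58)
  expect_lte(abs(sum(bins$percent) - 100), 1e-9)

  # 236 breast events, 17 cytokeratin-negative -> 7%
  ck <- data.frame(CK = rep(c(FALSE, TRUE), c(17, 219)))
  b2 <- marker_bins(ck, "CK")
  expect_equal(b2$percent_reported[b2$bin == "CK-"], 7)

  one <- marker_bins(data.frame(CK = TRUE), "CK")
  expect_equal(one$percent, 100)
  expect_error(marker_bins(data.frame(CK = logical(0)), "CK"), "empty")
})

test_that("classification assigns exactly one label per event", {
  cfg <- synth_config(seed = 35)
  mix <- c(bare_nucleus = 0.4, WBC = 0.3, erythroblast = 0.2,
           megakaryocyte = 0.1)
  pop <- sample_population(cfg, 300, mix)
  calls <- as.data.frame(t(vapply(pop$class_label, archetype_calls,
                                  logical(6))))
  labels <- deconvolve_events(drop_positive_calls(calls, 0.2, seed = 36))
  expect_length(labels, nrow(pop))
  expect_true(all(labels %in% c("leukocyte", "erythroblast",
                                "bare_nucleus", "megakaryocyte",
                                "unclassified")))
})
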