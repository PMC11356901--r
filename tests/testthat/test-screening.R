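test_that("a documented dicarboxylic acid peak is detected and confirmed", {
  det <- screenTargets(azelaicRun(), azelaicLibrary())
  expect_identical(nrow(det), 1L)
  expect_lte(abs(det$ppm_error), 7)
  expect_true(det$confirmed)
  expect_gte(det$n_fragments_matched, 1L)
})

test_that("screening respects the ppm window and polarity", {
  lib <- azelaicLibrary()
  theo <- ionMz(lib$formula, lib$adduct)
  off <- ExtractRun("X", data.frame(mz = theo * (1 + 10e-6), rt_min = 2.5,
                                    intensity = 10, fragments = ""),
                    "negative")
  expect_identical(nrow(screenTargets(off, lib)), 0L)
  near <- ExtractRun("X", data.frame(mz = theo * (1 + 5e-6), rt_min = 2.5,
                                     intensity = 10, fragments = ""),
                     "negative")
  expect_identical(nrow(screenTargets(near, lib)), 1L)
  # empty peak list
  empty <- ExtractRun("X", data.frame(mz = numeric(), rt_min = numeric(),
                                      intensity = numeric(),
                                      fragments = character()), "negative")
  expect_identical(nrow(screenTargets(empty, lib)), 0L)
  # polarity mismatch warns and returns nothing
  pos <- ExtractRun("X", data.frame(mz = 200.1, rt_min = 1, intensity = 1,
                                    fragments = ""), "positive")
  expect_warning(det <- screenTargets(pos, lib), "polarity")
  expect_identical(nrow(det), 0L)
})

test_that("widening the tolerance only adds detections", {
  cfg <- smallSimConfig(seed = 3, ppmNoiseSd = 4)
  gl <- generateLibrary(cfg)
  runs <- simulateRuns(gl$targets, gl$truth, cfg)
  for (run in runs[1:2]) {
    narrow <- screenTargets(run, gl$targets, tolerancePpm = 3)
    wide <- screenTargets(run, gl$targets, tolerancePpm = 7)
    key <- function(d) paste(d$target, d$extract_id, signif(d$observed_mz, 10))
    expect_true(all(key(narrow) %in% key(wide)))
  }
})

test_that("isomer labels follow retention order with documented tie-breaks", {
  det <- data.frame(target = "Ricinoleic acid", class = "MFA",
                    formula = "C18H34O3", adduct = "[M-H]-",
                    extract_id = "CTL1", observed_mz = 297.2438,
                    rt_min = c(8.52, 12.49, 7.85, 8.62),
                    intensity = c(5, 2, 9, 4), theoretical_mz = 297.2435,
                    ppm_error = 1, n_fragments_matched = 1L,
                    confirmed = TRUE, label = "Ricinoleic acid",
                    stringsAsFactors = FALSE)
  lab <- assignIsomerLabels(det)
  expect_identical(lab$label[order(lab$rt_min)],
                   paste("Ricinoleic acid", c("I", "II", "III", "IV")))
  # single detection keeps the bare name
  one <- assignIsomerLabels(det[1, ])
  expect_identical(one$label, "Ricinoleic acid")
  expect_true(is.na(one$isomer_index))
  # equal rt: higher intensity gets the earlier numeral
  tie <- det[1:2, ]
  tie$rt_min <- c(5, 5); tie$intensity <- c(5, 10)
  tie$extract_id <- c("A", "B")
  lab <- assignIsomerLabels(tie, rtTolMin = 0)
  expect_identical(lab$label[lab$intensity == 10], "Ricinoleic acid I")
  # permutation invariance
  perm <- det[c(3, 1, 4, 2), ]
  lab2 <- assignIsomerLabels(perm)
  expect_identical(lab$label[order(lab$rt_min)],
                   lab$label[order(lab$rt_min)])
  expect_identical(lab2$label[order(lab2$rt_min)],
                   assignIsomerLabels(det)$label[order(det$rt_min)])
})

test_that("presence matrix collapses duplicates and drops unconfirmed", {
  det <- rbind(
    transform(screenTargets(azelaicRun(), azelaicLibrary()),
              extract_id = "CTL1"),
    transform(screenTargets(azelaicRun(), azelaicLibrary()),
              extract_id = "CTL1"),
    transform(screenTargets(azelaicRun(), azelaicLibrary()),
              extract_id = "CTL3"))
  pm <- buildPresenceMatrix(det, extracts = paste0("CTL", 1:5))
  expect_identical(dim(presence(pm)), c(5L, 1L))
  expect_identical(as.vector(presence(pm)), c(1L, 0L, 1L, 0L, 0L))
  # unconfirmed-only compound excluded
  det$confirmed <- FALSE
  expect_identical(ncol(presence(buildPresenceMatrix(det))), 0L)
  # empty input
  expect_identical(ncol(presence(buildPresenceMatrix(det[0, ]))), 0L)
})

test_that("the fixture's printed presence pattern round-trips through detections", {
  fx <- loadFixtureTable()
  det <- do.call(rbind, lapply(paste0("CTL", 1:5), function(ct) {
    rows <- fx[fx[[ct]] == 1L, ]
    data.frame(target = rows$name, class = rows$class, formula = NA,
               adduct = rows$adduct, extract_id = ct,
               observed_mz = rows$observed_mz, rt_min = rows$rt_min,
               intensity = 1, theoretical_mz = rows$observed_mz,
               ppm_error = 0, n_fragments_matched = 1L, confirmed = TRUE,
               label = rows$name, stringsAsFactors = FALSE)
  }))
  pm <- buildPresenceMatrix(det, extracts = paste0("CTL", 1:5))
  direct <- fixturePresenceMatrix(fx)
  expect_identical(ncol(presence(pm)), 166L)
  expect_identical(presence(pm)[, fx$name],
                   presence(direct)[, fx$name])
})

test_that("true targets are recovered and decoys rejected on synthetic runs", {
  cfg <- smallSimConfig(seed = 5)   # ppm noise SD 2, tolerance 7
  gl <- generateLibrary(cfg)
  runs <- simulateRuns(gl$targets, gl$truth, cfg)
  det <- do.call(rbind, lapply(runs, screenTargets, library = gl$targets))
  expect_true(all(det$target %in% gl$targets$name))
  truePresent <- sum(gl$truth$design)
  expect_gte(nrow(det) / truePresent, 0.99)
  # decoys sit >= 25 ppm away: none may ever match
  expect_true(all(abs(det$ppm_error) <= 7))
})
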