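test_that("neutral-loss matching recovers the documented loss patterns", {
  m <- matchNeutralLosses(187.0982, c(169.0861, 143.1065, 125.0966))
  expect_true(all(c("H2O", "H2O+CO2") %in% m$loss))
  m <- matchNeutralLosses(147.0457, 103.0542)
  expect_identical(m$loss, "CO2")
  m <- matchNeutralLosses(187.0982, numeric())
  expect_identical(nrow(m), 0L)
  # rule masses are the exact neutral-molecule masses
  nl <- neutralLossRules()
  expect_equal(nl$mass[nl$loss == "H2O"], 18.010565, tolerance = 1e-4)
  expect_equal(nl$mass[nl$loss == "H2O+CO2"], 62.000395, tolerance = 1e-4)
})

test_that("head-group series matching works against theory and printed values", {
  s <- headGroupSeries()
  expect_equal(s$mz, c(74.0600, 88.0757, 102.0913, 116.1070),
               tolerance = 1e-4)
  expect_equal(diff(s$mz), rep(14.015650, 3), tolerance = 1e-5)
  # printed stearamide fragments match 3 members at 0.01 Da
  expect_identical(nrow(matchHeadGroup(c(116.1121, 102.0851, 88.0821))), 3L)
  expect_identical(nrow(matchHeadGroup(500.0)), 0L)
  expect_identical(nrow(matchHeadGroup(s$mz)), 4L)
})

test_that("class decision rules reproduce the worked identifications", {
  # linoleamide: C18 amide with two chain double bonds
  a <- classifyCompound("C18H33NO", "[M+H]+",
                        fragments = headGroupSeries()$mz)
  expect_identical(a$class, "FAA")
  expect_identical(a$chainCarbons, 18L)
  expect_identical(a$ccDoubleBonds, 2L)
  expect_match(a$evidence, "headgroup")
  # saturated C18 diacid via carboxyl losses, no hint needed
  b <- classifyCompound("C18H34O4", "[M-H]-",
                        fragments = c(295.2280, 269.2425, 251.2289),
                        precursorMz = 313.2375)
  expect_identical(b$class, "DFA")
  expect_identical(b$ccDoubleBonds, 0L)
  # linolenic acid: MFA with three double bonds
  d <- classifyCompound("C18H30O2", "[M-H]-")
  expect_identical(d$class, "MFA")
  expect_identical(d$ccDoubleBonds, 3L)
  # phenylpropanoid window
  expect_identical(classifyCompound("C9H6O2", "[M+H]+")$class, "CAD")
  # amide with too many oxygens is unclassifiable
  expect_identical(classifyCompound("C10H21NO3", "[M+H]+")$class,
                   "unclassified")
  # purity: identical calls agree
  expect_identical(classifyCompound("C18H33NO", "[M+H]+"),
                   classifyCompound("C18H33NO", "[M+H]+"))
})

test_that("the saturated homologous series is uniformly MFA", {
  for (n in 7:30) {
    f <- formulaString(c(C = n, H = 2 * n, O = 2))
    a <- classifyCompound(f, "[M-H]-")
    expect_identical(a$class, "MFA")
    expect_identical(a$ccDoubleBonds, 0L)
  }
})

test_that("hinted classification matches the fixture's class column exactly", {
  fx <- loadFixtureTable()
  ann <- annotateTable(fx)
  expect_identical(sum(ann$assigned_class == fx$class), 166L)
  expect_false(anyNA(ann$formula))
  # DBE conservation: chain double bonds + class carbonyls reconstruct DBE
  carbonyls <- c(MFA = 1L, DFA = 2L, FAA = 1L)
  fa <- ann$assigned_class %in% names(carbonyls)
  expect_equal(ann$ccDoubleBonds[fa] + carbonyls[ann$assigned_class[fa]],
               as.integer(ann$rdbe[fa]), ignore_attr = TRUE)
})

test_that("hint-free classification flags few ambiguous boundary cases", {
  fx <- loadFixtureTable()
  ann <- annotateTable(fx, useHints = FALSE)
  expect_lte(sum(ann$ambiguous), 10)
  # the boundary only affects the DFA/oxygenated-MFA split
  wrong <- ann$assigned_class != fx$class
  expect_true(all(fx$class[wrong] %in% c("MFA", "DFA")))
})

test_that("class tallies on the fixture reproduce the study's counts", {
  fx <- loadFixtureTable()
  ann <- annotateTable(fx)
  cnt <- countByClass(data.frame(class = ann$assigned_class,
                                 ccDoubleBonds = ann$ccDoubleBonds,
                                 oxygenExcess = ann$oxygenExcess,
                                 oxoFlag = FALSE))
  expect_identical(as.integer(cnt$classes[c("MFA", "DFA", "FAA", "CAD")]),
                   c(66L, 52L, 27L, 21L))
  expect_identical(cnt$total, 166L)
  expect_identical(unname(cnt$saturated["FAA"]), 16L)
  expect_identical(unname(cnt$monoUnsaturated["FAA"]), 8L)
  # empty input gives all-zero tallies
  empty <- countByClass(data.frame(class = character(),
                                   ccDoubleBonds = integer(),
                                   oxygenExcess = integer(),
                                   oxoFlag = logical()))
  expect_true(all(empty$classes == 0L))
  expect_identical(empty$total, 0L)
})
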