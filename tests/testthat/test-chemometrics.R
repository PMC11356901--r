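test_that("Venn regions partition the compound set", {
  pm <- fixturePresenceMatrix()
  venn <- vennPartition(pm)
  expect_identical(sum(venn$sizes), 166L)
  expect_lte(length(venn$sizes), 31L)
  # disjoint: no compound in two regions
  all_members <- unlist(venn$regions, use.names = FALSE)
  expect_identical(anyDuplicated(all_members), 0L)
  expect_setequal(all_members, compoundNames(pm))
})

test_that("fixture exclusive regions match the study's lists", {
  venn <- vennPartition(fixturePresenceMatrix())
  expect_identical(vennRegion(venn, "CTL1"), "Protocatechuic acid")
  expect_identical(vennRegion(venn, "CTL2"), "Linoleamide II")
  expect_identical(vennRegion(venn, "CTL3"), "4-Hydroxycinnamic acid")
  expect_setequal(vennRegion(venn, "CTL4"),
                  c("Nonendioic acid", "Eicosadienoic acid I",
                    "Ceriporic acid III"))
  expect_identical(length(vennRegion(venn, "CTL5")), 0L)
})

test_that("PCA handles degenerate, rank-one and full-rank binary input", {
  constant <- PresenceMatrix(matrix(1L, 5, 4,
                                    dimnames = list(paste0("E", 1:5), letters[1:4])))
  expect_error(runPCA(constant), "degenerate")
  # a single differential compound gives one component explaining everything
  m <- matrix(1L, 5, 4, dimnames = list(paste0("E", 1:5), letters[1:4]))
  m[1:2, 2] <- 0L
  p1 <- runPCA(PresenceMatrix(m))
  expect_equal(p1$explainedFraction[1], 1.0, tolerance = 1e-12)
  # full fixture: fractions sum to 1, reconstruction is exact
  p <- runPCA(fixturePresenceMatrix(), polarity = "negative")
  expect_equal(sum(p$explainedFraction), 1, tolerance = 1e-12)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - p$centered)), 1e-8)
  expect_lte(ncol(p$scores), min(nrow(p$scores), nrow(p$loadings)))
})

test_that("PCA score-space outlier on the fixture is the high-pressure extract", {
  # on the published binary occurrence data CTL5 (500 bar), the extract
  # with the fewest compounds, is the score-space outlier in both modes
  p <- runPCA(fixturePresenceMatrix(), polarity = "negative")
  expect_identical(pcaOutlier(p), "CTL5")
})

test_that("Ward clustering is monotone, deterministic and permutation-stable", {
  m <- matrix(c(1L, 0L, 1L, 0L,
                1L, 0L, 1L, 0L,
                0L, 1L, 0L, 1L), 3, 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), letters[1:4]))
  hc <- wardCluster(PresenceMatrix(m))
  expect_equal(hc$height[1], 0)          # identical rows merge first at 0
  expect_true(!is.unsorted(hc$height))
  expect_error(wardCluster(PresenceMatrix(m[1, , drop = FALSE])), "2 extracts")
  # permutation of input rows gives the same tree on sorted labels
  pmA <- PresenceMatrix(presence(fixturePresenceMatrix()))
  pmB <- PresenceMatrix(presence(fixturePresenceMatrix())[c(3, 5, 1, 4, 2), ])
  hA <- wardCluster(pmA); hB <- wardCluster(pmB)
  expect_identical(hA$labels, hB$labels)
  expect_equal(hA$height, hB$height)
  expect_identical(hA$merge, hB$merge)
})

test_that("the fixture Ward outgroup is the sparsest extract", {
  hc <- wardCluster(fixturePresenceMatrix(), polarity = "negative")
  expect_identical(wardOutgroup(hc), "CTL5")
})

test_that("correlation matrix has the expected structure", {
  m <- matrix(c(1L, 0L, 1L, 0L, 1L,
                1L, 0L, 1L, 0L, 1L,
                0L, 1L, 0L, 1L, 0L), 3, 5, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), letters[1:5]))
  r <- correlateExtracts(PresenceMatrix(m))$r
  expect_equal(r["A", "B"], 1)
  expect_equal(r["A", "C"], -1)
  expect_identical(r, t(r))
  expect_true(all(diag(r) == 1))
  # zero-variance extract reported as NA with a warning
  m2 <- rbind(m, D = rep(1L, 5))
  expect_warning(r2 <- correlateExtracts(PresenceMatrix(m2))$r, "zero-variance")
  expect_true(all(is.na(r2["D", c("A", "B", "C")])))
  # positive semidefinite within tolerance
  rF <- correlateExtracts(fixturePresenceMatrix())$r
  expect_gte(min(eigen(rF, symmetric = TRUE)$values), -1e-8)
})
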