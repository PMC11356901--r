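# Independent brute-force decomposition oracle: a plain quadruple loop over
# the full (C, H, N, O) grid, no derived H bounds.  Kept deliberately
# separate from the package's enumeration path.
bruteForceDecompose <- function(observedMz, adduct, tolerancePpm,
                                bounds = c(C = 40, H = 80, N = 1, O = 8),
                                dbeRange = c(0, 12)) {
  em <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)
  delta <- if (adduct == "[M+H]+") 1.00727646688 else -1.00727646688
  grid <- expand.grid(C = 0:bounds[["C"]], H = 0:bounds[["H"]],
                      N = 0:bounds[["N"]], O = 0:bounds[["O"]])
  grid <- grid[rowSums(grid) >= 1, ]
  theo <- grid$C * em[["C"]] + grid$H * em[["H"]] + grid$N * em[["N"]] +
    grid$O * em[["O"]] + delta
  ppm <- 1e6 * (observedMz - theo) / theo
  dbe <- grid$C - grid$H / 2 + grid$N / 2 + 1
  keep <- abs(ppm) <= tolerancePpm & dbe %% 1 == 0 &
    dbe >= dbeRange[1] & dbe <= dbeRange[2]
  out <- grid[keep, , drop = FALSE]
  out$ppmError <- ppm[keep]
  out$rdbe <- dbe[keep]
  out[order(out$C, out$H, out$N, out$O), , drop = FALSE]
}

# canonical (C,H,N,O,ppm) key for comparing candidate sets
decompositionKey <- function(df) {
  if (!nrow(df)) return(character())
  sort(sprintf("C%d H%d N%d O%d %.4f", df$C, df$H, df$N, df$O, df$ppmError))
}

# small single-target run used across screening tests
azelaicRun <- function(extraPeaks = NULL) {
  pk <- data.frame(mz = 187.0982, rt_min = 2.47, intensity = 1e5,
                   fragments = "169.0861;143.1065;125.0966",
                   stringsAsFactors = FALSE)
  if (!is.null(extraPeaks)) pk <- rbind(pk, extraPeaks)
  ExtractRun("CTL1", pk, "negative", pressure = 100, temperature = 55)
}

azelaicLibrary <- function() {
  data.frame(name = "Azelaic acid", formula = "C9H16O4", class = "DFA",
             adduct = "[M-H]-", fragments = "169.0856;143.1078;125.0972",
             rt_min = 2.47, stringsAsFactors = FALSE)
}

# tiny simulator configuration for fast property tests
smallSimConfig <- function(seed = 11L, nDecoys = 10, ...) {
  simConfig(nPerClass = c(MFA = 10, DFA = 8, FAA = 6, CAD = 4),
            nDecoys = nDecoys, seed = seed, ...)
}
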