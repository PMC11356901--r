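# evaluate code under a seed without disturbing the caller's RNG state
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for the synthetic MSE run generator
#'
#' Defaults emulate the study conditions of the screening workflow the
#' package implements: five supercritical-CO2 extracts at 100/150/250/300/
#' 500 bar and 55 degC, a 166-target library split 66/52/27/21 over the
#' four compound classes, ppm-scale precursor mass noise (SD 2 ppm, so
#' essentially all true peaks fall inside the 7 ppm screening window), and
#' retention times increasing linearly with chain length for saturated
#' homologs.
#'
#' @param nPerClass Named counts of compounds to generate per class.
#' @param chainRange Carbon-chain interval for fatty compounds; must lie
#'   within [7, 30].
#' @param extracts data.frame with columns \code{label}, \code{pressure},
#'   \code{temperature}.
#' @param ppmNoiseSd Precursor m/z noise SD in ppm.
#' @param fragmentNoiseSd Fragment m/z noise SD in Da.
#' @param rtModel Named vector: \code{intercept} (min), \code{slope}
#'   (min per chain carbon), \code{unsatOffset} (min per C=C),
#'   \code{oxygenOffset} (min per extra oxygen), \code{jitterSd} (min).
#' @param intensityLognormal Named vector \code{meanlog}, \code{sdlog}.
#' @param commonFraction Fraction of compounds designed present in every
#'   extract; the remainder are dropped from 1-2 random extracts.
#' @param nDecoys Decoy peaks per run, placed >= 25 ppm from every target.
#' @param presenceDesign Optional compounds x extracts 0/1 matrix
#'   overriding the generated design.
#' @param seed Integer seed driving all randomness.
#' @return Validated config list of class \code{"simConfig"}.
#' @export
simConfig <- function(nPerClass = c(MFA = 66, DFA = 52, FAA = 27, CAD = 21),
                      chainRange = c(7, 26),
                      extracts = data.frame(
                        label = paste0("CTL", 1:5),
                        pressure = c(100, 150, 250, 300, 500),
                        temperature = 55),
                      ppmNoiseSd = 2,
                      fragmentNoiseSd = 0.003,
                      rtModel = c(intercept = 1, slope = 0.55,
                                  unsatOffset = -0.4, oxygenOffset = -1.2,
                                  jitterSd = 0.02),
                      intensityLognormal = c(meanlog = log(1e5), sdlog = 1),
                      commonFraction = 0.85,
                      nDecoys = 20,
                      presenceDesign = NULL,
                      seed = 1L) {
  stopifnot(all(c("MFA", "DFA", "FAA", "CAD") %in% names(nPerClass)),
            all(nPerClass >= 0),
            length(chainRange) == 2, chainRange[1] >= 7, chainRange[2] <= 30,
            chainRange[1] <= chainRange[2],
            ppmNoiseSd >= 0, fragmentNoiseSd >= 0,
            rtModel[["slope"]] > 0,
            commonFraction >= 0, commonFraction <= 1, nDecoys >= 0)
  cfg <- list(nPerClass = nPerClass, chainRange = chainRange,
              extracts = extracts, ppmNoiseSd = ppmNoiseSd,
              fragmentNoiseSd = fragmentNoiseSd, rtModel = rtModel,
              intensityLognormal = intensityLognormal,
              commonFraction = commonFraction, nDecoys = nDecoys,
              presenceDesign = presenceDesign, seed = as.integer(seed))
  class(cfg) <- "simConfig"
  cfg
}

# phenylpropanoid-type catalog used for the CAD class
cadCatalog <- function() {
  data.frame(
    name = c("Cinnamic acid", "4-Hydroxycinnamic acid",
             "4-Methoxycinnamic acid", "Ferulic acid", "Sinapic acid",
             "Caffeic acid", "Benzoic acid", "Salicylic acid",
             "Protocatechuic acid", "Gallic acid", "Vanillin",
             "Syringaldehyde", "Coumarin", "Cinnamaldehyde",
             "Cinnamyl alcohol", "Cinnamyl acetate", "Methylcinnamic acid",
             "Hydrocinnamic acid", "Coniferyl alcohol", "Sinapaldehyde",
             "Abscisic acid", "3-(4-Hydroxyphenyl)lactic acid"),
    formula = c("C9H8O2", "C9H8O3", "C10H10O3", "C10H10O4", "C11H12O5",
                "C9H8O4", "C7H6O2", "C7H6O3", "C7H6O4", "C7H6O5", "C8H8O3",
                "C9H10O4", "C9H6O2", "C9H8O", "C9H10O", "C11H12O2",
                "C10H10O2", "C9H10O2", "C10H12O3", "C11H12O4", "C15H20O4",
                "C9H10O4"),
    adduct = c("[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-",
               "[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-", "[M+H]+",
               "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M-H]-",
               "[M-H]-", "[M+H]+", "[M-H]-", "[M-H]-"),
    stringsAsFactors = FALSE)
}

fattyFormula <- function(class, chain, unsat, extraO) {
  h <- switch(class,
              MFA = 2 * chain - 2 * unsat,
              DFA = 2 * chain - 2 - 2 * unsat,
              FAA = 2 * chain + 1 - 2 * unsat)
  if (h <= 0)
    stop("infeasible class/chain combination: ", class, " chain ", chain,
         " with ", unsat, " double bonds")
  o <- switch(class, MFA = 2 + extraO, DFA = 4 + extraO, FAA = 1)
  n <- if (class == "FAA") 1L else 0L
  formulaString(c(C = chain, H = h, N = n, O = o))
}

classFragments <- function(class, adduct, theoMz) {
  nl <- neutralLossRules()
  lm <- function(loss) theoMz - nl$mass[nl$loss == loss]
  switch(class,
         MFA = c(lm("H2O"), lm("CO2")),
         DFA = c(lm("H2O"), lm("CO2"), lm("H2O+CO2")),
         FAA = headGroupSeries()$mz,
         CAD = if (adduct == "[M-H]-") c(lm("CO2"), lm("H2O")) else lm("H2O"))
}

#' Generate a synthetic target library with ground truth
#'
#' Fatty classes are enumerated as homologous series over the configured
#' chain range, sweeping unsaturation (0-3 C=C) and, for the acids, extra
#' oxygenation; cinnamic acid derivatives come from a fixed phenylpropanoid
#' catalog.  Every entry carries class-consistent diagnostic fragments
#' (carboxyl neutral losses, the amide head-group series, CO2 loss for the
#' aromatic acids).  The presence design marks \code{commonFraction} of
#' compounds present in every extract and drops each remaining compound
#' from one or two seeded-random extracts.
#'
#' @param config A \code{\link{simConfig}}.
#' @return List with \code{targets} (library data.frame: \code{name},
#'   \code{formula}, \code{class}, \code{adduct}, \code{fragments},
#'   \code{rt_min}) and \code{truth} (per-compound ground truth:
#'   \code{chain}, \code{unsat}, \code{extraO}, \code{theoreticalMz},
#'   plus the \code{design} matrix as an attribute-free list element).
#' @export
generateLibrary <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  chains <- seq(config$chainRange[1], config$chainRange[2])
  rows <- list()
  for (cls in c("MFA", "DFA", "FAA")) {
    n <- config$nPerClass[[cls]]
    if (n == 0) next
    maxX <- switch(cls, MFA = 2, DFA = 1, FAA = 0)
    combos <- expand.grid(chain = chains, unsat = 0:3, extraO = 0:maxX)
    # polyunsaturation pushing DBE into the aromatic window (>= 4) only
    # occurs on long chains in plant lipids; short-chain trienes would be
    # formula-indistinguishable from phenylpropanoids
    baseDbe <- switch(cls, MFA = 1, DFA = 2, FAA = 1)
    combos <- combos[combos$unsat + baseDbe < 4 | combos$chain > 15, ]
    combos <- combos[order(combos$extraO, combos$unsat, combos$chain), ]
    if (n > nrow(combos))
      stop("infeasible request: ", n, " ", cls, " compounds exceed the ",
           nrow(combos), " distinct homologs in chain range ",
           paste(config$chainRange, collapse = "-"))
    combos <- combos[seq_len(n), ]
    adduct <- if (cls == "FAA") "[M+H]+" else "[M-H]-"
    for (i in seq_len(n)) {
      ch <- combos$chain[i]; u <- combos$unsat[i]; x <- combos$extraO[i]
      f <- fattyFormula(cls, ch, u, x)
      nm <- sprintf("%s C%d:%d%s", cls, ch, u,
                    if (x > 0) paste0("+", x, "O") else "")
      rows[[length(rows) + 1L]] <-
        data.frame(name = nm, formula = f, class = cls, adduct = adduct,
                   chain = ch, unsat = u, extraO = x,
                   stringsAsFactors = FALSE)
    }
  }
  nCad <- config$nPerClass[["CAD"]]
  if (nCad > 0) {
    cat_ <- cadCatalog()
    if (nCad > nrow(cat_))
      stop("infeasible request: ", nCad, " CAD compounds exceed the catalog (",
           nrow(cat_), ")")
    cat_ <- cat_[seq_len(nCad), ]
    cat_$chain <- vapply(cat_$formula, function(f) parseFormula(f)[["C"]], 0)
    cat_$unsat <- NA_integer_; cat_$extraO <- NA_integer_
    cat_$class <- "CAD"
    rows[[length(rows) + 1L]] <-
      cat_[, c("name", "formula", "class", "adduct", "chain", "unsat", "extraO")]
  }
  if (!length(rows)) {
    lib <- data.frame(name = character(), formula = character(),
                      class = character(), adduct = character(),
                      fragments = character(), rt_min = numeric(),
                      stringsAsFactors = FALSE)
    return(list(targets = lib,
                truth = list(compounds = lib, design = matrix(0L, 0, nrow(config$extracts)))))
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  truth$theoreticalMz <- mapply(ionMz, truth$formula, truth$adduct)

  # deterministic retention model (jitter is added at simulation time)
  rt <- numeric(nrow(truth))
  fa <- truth$class != "CAD"
  m <- config$rtModel
  rt[fa] <- m[["intercept"]] + m[["slope"]] * truth$chain[fa] +
    m[["unsatOffset"]] * truth$unsat[fa] +
    m[["oxygenOffset"]] * truth$extraO[fa]
  rt[!fa] <- 1 + 0.1 * seq_len(sum(!fa))
  truth$rt_min <- pmin(pmax(rt, 0.2), 19.8)

  targets <- truth[, c("name", "formula", "class", "adduct", "rt_min")]
  targets$fragments <- vapply(seq_len(nrow(truth)), function(i)
    formatFragments(classFragments(truth$class[i], truth$adduct[i],
                                   truth$theoreticalMz[i])), character(1))

  design <- config$presenceDesign
  nex <- nrow(config$extracts)
  if (is.null(design)) {
    design <- withSeed(config$seed, {
      d <- matrix(1L, nrow(truth), nex,
                  dimnames = list(truth$name, config$extracts$label))
      nCommon <- floor(config$commonFraction * nrow(d))
      if (nrow(d) > nCommon) for (i in (nCommon + 1):nrow(d)) {
        drop <- sample(nex, sample(1:2, 1))
        d[i, drop] <- 0L
      }
      d
    })
  } else {
    stopifnot(nrow(design) == nrow(truth), ncol(design) == nex)
    rownames(design) <- truth$name
    colnames(design) <- config$extracts$label
  }
  list(targets = targets,
       truth = list(compounds = truth, design = design))
}

#' Simulate MSE extract runs from a library and ground truth
#'
#' Each designed presence emits one peak: theoretical m/z perturbed by
#' Normal(0, ppmNoiseSd) ppm, retention time from the linear chain model
#' plus jitter, lognormal intensity, and the target's diagnostic fragments
#' perturbed by Normal(0, fragmentNoiseSd) Da.  Decoy peaks are placed at
#' least 25 ppm from every same-polarity target ion.  Output is
#' byte-identical for a fixed config seed.
#'
#' @param library Target library from \code{\link{generateLibrary}}.
#' @param truth Ground-truth list from \code{\link{generateLibrary}}.
#' @param config The same \code{\link{simConfig}}.
#' @return List of \linkS4class{ExtractRun} objects, one per extract per
#'   polarity present in the library.
#' @export
simulateRuns <- function(library, truth, config = simConfig()) {
  stopifnot(inherits(config, "simConfig"),
            nrow(truth$design) == nrow(library))
  comp <- truth$compounds
  withSeed(config$seed + 1L, {
    runs <- list()
    for (e in seq_len(nrow(config$extracts))) {
      lab <- config$extracts$label[e]
      for (pol in c("negative", "positive")) {
        ad <- if (pol == "positive") "[M+H]+" else "[M-H]-"
        sel <- which(comp$adduct == ad & truth$design[, e] == 1L)
        if (!length(sel) && config$nDecoys == 0) next
        if (!any(comp$adduct == ad)) next
        mz <- comp$theoreticalMz[sel] *
          (1 + stats::rnorm(length(sel), 0, config$ppmNoiseSd) * 1e-6)
        rt <- comp$rt_min[sel] +
          stats::rnorm(length(sel), 0, config$rtModel[["jitterSd"]])
        frag <- vapply(sel, function(i) {
          f <- classFragments(comp$class[i], comp$adduct[i],
                              comp$theoreticalMz[i])
          formatFragments(f + stats::rnorm(length(f), 0,
                                           config$fragmentNoiseSd))
        }, character(1))
        inten <- stats::rlnorm(length(sel),
                               config$intensityLognormal[["meanlog"]],
                               config$intensityLognormal[["sdlog"]])
        pk <- data.frame(mz = mz, rt_min = pmin(pmax(rt, 0.05), 19.95),
                         intensity = inten, fragments = frag,
                         stringsAsFactors = FALSE)
        if (config$nDecoys > 0) {
          targMz <- comp$theoreticalMz[comp$adduct == ad]
          dm <- numeric(0)
          while (length(dm) < config$nDecoys) {
            cand <- stats::runif(config$nDecoys, 60, 1150)
            far <- vapply(cand, function(x)
              all(abs(1e6 * (x - targMz) / targMz) >= 25), logical(1))
            dm <- c(dm, cand[far])
          }
          dm <- dm[seq_len(config$nDecoys)]
          pk <- rbind(pk, data.frame(
            mz = dm, rt_min = stats::runif(length(dm), 0.5, 19.5),
            intensity = stats::rlnorm(length(dm),
                                      config$intensityLognormal[["meanlog"]],
                                      config$intensityLognormal[["sdlog"]]),
            fragments = "", stringsAsFactors = FALSE))
        }
        pk <- pk[order(pk$rt_min, pk$mz), , drop = FALSE]
        rownames(pk) <- NULL
        runs[[length(runs) + 1L]] <-
          ExtractRun(lab, pk, pol,
                     pressure = config$extracts$pressure[e],
                     temperature = config$extracts$temperature[e])
      }
    }
    runs
  })
}
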