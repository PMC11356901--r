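#' Diagnostic neutral-loss rules for carboxylic acids
#'
#' Losses observed from deprotonated fatty acids in the high-energy channel:
#' water, decarboxylation, formic acid, and the combined water + CO2 loss.
#' Shipped as a machine-readable resource under
#' \code{extdata/neutral_losses.csv} so the rule set can be extended without
#' code changes.
#'
#' @return data.frame with columns \code{loss}, \code{formula},
#'   \code{mass} (Da) and \code{classes} (semicolon-separated applicable
#'   classes).
#' @export
neutralLossRules <- function() {
  data.frame(
    loss = c("H2O", "CO2", "HCOOH", "H2O+CO2"),
    formula = c("H2O", "CO2", "CH2O2", "CH2O3"),
    mass = c(monoisotopicMass("H2O"), monoisotopicMass("CO2"),
             monoisotopicMass("CH2O2"), monoisotopicMass("H2O") +
               monoisotopicMass("CO2")),
    classes = c("MFA;DFA;CAD", "MFA;DFA;CAD", "MFA;DFA;CAD", "MFA;DFA"),
    stringsAsFactors = FALSE)
}

# losses that require a carboxyl group beyond the one every fatty acid has;
# used to discriminate dicarboxylic from hydroxylated monocarboxylic acids
carboxylLosses <- c("CO2", "HCOOH", "H2O+CO2")

#' Match neutral losses against a fragment list
#'
#' A rule matches iff some observed fragment lies within \code{tolDa} of
#' (precursor m/z - loss mass).
#'
#' @param precursorMz Precursor ion m/z.
#' @param fragments Numeric vector of high-energy fragment m/z values.
#' @param rules Rule table as from \code{\link{neutralLossRules}}.
#' @param tolDa Absolute fragment tolerance in Da (default 0.01).
#' @return Subset of \code{rules} with an extra column
#'   \code{matchedFragment}; zero rows when nothing matches.
#' @export
#' @examples
#' matchNeutralLosses(187.0982, c(169.0861, 143.1065, 125.0966))
matchNeutralLosses <- function(precursorMz, fragments,
                               rules = neutralLossRules(), tolDa = 0.01) {
  stopifnot(tolDa > 0, precursorMz > max(c(0, rules$mass)))
  if (!length(fragments)) {
    out <- rules[0, ]
    out$matchedFragment <- numeric()
    return(out)
  }
  hit <- integer(); frag <- numeric()
  for (i in seq_len(nrow(rules))) {
    expect <- precursorMz - rules$mass[i]
    d <- abs(fragments - expect)
    if (any(d <= tolDa)) {
      hit <- c(hit, i)
      frag <- c(frag, fragments[which.min(d)])
    }
  }
  out <- rules[hit, ]
  out$matchedFragment <- frag
  rownames(out) <- NULL
  out
}

#' Amide head-group fragment ion series
#'
#' The C3-C6 protonated head-group fragments of primary fatty acid amides,
#' consecutive members differing by CH2.  Matching any member is
#' amide-grade evidence.
#'
#' @return data.frame with columns \code{ion} (e.g. \code{"[C3H8NO]+"}),
#'   \code{neutral} and \code{mz} (theoretical).
#' @export
headGroupSeries <- function() {
  neutrals <- sprintf("C%dH%dNO", 3:6, 2 * (3:6) + 1)
  data.frame(ion = sprintf("[C%dH%dNO]+", 3:6, 2 * (3:6) + 2),
             neutral = neutrals,
             mz = vapply(neutrals, ionMz, numeric(1), adduct = "[M+H]+",
                         USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Match head-group series members in a fragment list
#'
#' @param fragments Numeric fragment m/z vector.
#' @param tolDa Absolute tolerance in Da (default 0.01).
#' @param series Reference series, by default the theoretical
#'   \code{\link{headGroupSeries}}.
#' @return Matched subset of the series with a \code{matchedFragment}
#'   column.
#' @export
matchHeadGroup <- function(fragments, tolDa = 0.01, series = headGroupSeries()) {
  stopifnot(tolDa > 0)
  if (!length(fragments)) {
    out <- series[0, ]; out$matchedFragment <- numeric(); return(out)
  }
  hit <- integer(); frag <- numeric()
  for (i in seq_len(nrow(series))) {
    d <- abs(fragments - series$mz[i])
    if (any(d <= tolDa)) { hit <- c(hit, i); frag <- c(frag, fragments[which.min(d)]) }
  }
  out <- series[hit, ]
  out$matchedFragment <- frag
  rownames(out) <- NULL
  out
}

unclassifiedAssignment <- function(formula, dbe) {
  data.frame(formula = formulaString(formula), class = "unclassified",
             chainCarbons = NA_integer_, ccDoubleBonds = NA_integer_,
             oxygenExcess = NA_integer_, oxoFlag = FALSE, rdbe = dbe,
             ambiguous = FALSE, evidence = "", stringsAsFactors = FALSE)
}

#' Classify a CHNO neutral into the screened compound classes
#'
#' Rule-based assignment into monocarboxylic fatty acid (MFA), dicarboxylic
#' fatty acid (DFA), fatty acid amide (FAA) or cinnamic acid derivative
#' (CAD).  Decision order: (1) one N and one O is an amide; (2) N-free
#' formulas with DBE >= 4 and 7-15 carbons fall in the phenylpropanoid
#' window; (3) N-free, O >= 4, DBE >= 2 formulas sit on the contested
#' DFA/oxygenated-MFA boundary, resolved by a library hint when given, else
#' by carboxyl-specific neutral losses (CO2, HCOOH, H2O+CO2) in the
#' fragment list, else defaulting to MFA with \code{ambiguous = TRUE};
#' (4) any other N-free formula with O >= 2 is an MFA.  Anything else is
#' \code{"unclassified"}.
#'
#' Chain unsaturation is derived from DBE by removing the carbonyl
#' equivalents of the class (1 for MFA/FAA, 2 for DFA, minus one more if an
#' oxo group is declared); \code{oxygenExcess} counts oxygens beyond the
#' class head group(s).
#'
#' @param formula Neutral formula (string or counts).
#' @param adduct Adduct under which the compound was observed (metadata
#'   only; the formula must already be the neutral).
#' @param fragments Numeric fragment m/z vector (may be empty).
#' @param precursorMz Precursor m/z for neutral-loss matching; defaults to
#'   the theoretical ion m/z of \code{formula} under \code{adduct}.
#' @param hint Optional library class hint (\code{"MFA"}, \code{"DFA"},
#'   \code{"FAA"}, \code{"CAD"}); consulted only on the MFA/DFA boundary.
#' @param oxo Logical, TRUE when an oxo (keto) group is known from a
#'   library hint or an explicit diagnostic; affects the unsaturation
#'   bookkeeping only.
#' @param fragmentTolDa Fragment tolerance in Da (default 0.01).
#' @return One-row data.frame: \code{formula}, \code{class},
#'   \code{chainCarbons}, \code{ccDoubleBonds}, \code{oxygenExcess},
#'   \code{oxoFlag}, \code{rdbe}, \code{ambiguous}, \code{evidence}.
#' @export
#' @examples
#' classifyCompound("C18H33NO", "[M+H]+",
#'                  fragments = c(116.1070, 102.0913))
classifyCompound <- function(formula, adduct = "[M-H]-",
                             fragments = numeric(), precursorMz = NULL,
                             hint = NULL, oxo = FALSE, fragmentTolDa = 0.01) {
  counts <- parseFormula(formula)
  C <- counts[["C"]]; N <- counts[["N"]]; O <- counts[["O"]]
  dbe <- rdbe(counts)
  if (dbe < 0 || dbe %% 1 != 0)
    stop("classifyCompound expects a neutral with nonnegative integer DBE")
  if (!is.null(hint)) stopifnot(hint %in% c("MFA", "DFA", "FAA", "CAD"))
  adduct <- normalizeAdduct(adduct)
  if (is.null(precursorMz)) precursorMz <- ionMz(counts, adduct)

  evid <- character()
  losses <- matchNeutralLosses(precursorMz, fragments, tolDa = fragmentTolDa)
  if (nrow(losses))
    evid <- c(evid, paste0("loss:", losses$loss))
  head <- matchHeadGroup(fragments, tolDa = fragmentTolDa)
  if (nrow(head))
    evid <- c(evid, paste0("headgroup:", head$ion))

  mk <- function(class, cc, oxExcess, ambiguous = FALSE) {
    data.frame(formula = formulaString(counts), class = class,
               chainCarbons = as.integer(C), ccDoubleBonds = as.integer(cc),
               oxygenExcess = as.integer(oxExcess), oxoFlag = oxo,
               rdbe = dbe, ambiguous = ambiguous,
               evidence = paste(evid, collapse = ";"),
               stringsAsFactors = FALSE)
  }

  if (N == 1L && O == 1L) {
    cc <- dbe - 1
    if (cc < 0) return(unclassifiedAssignment(counts, dbe))
    return(mk("FAA", cc, 0L))
  }
  if (N == 0L && dbe >= 4 && C >= 7 && C <= 15)
    return(mk("CAD", NA_integer_, NA_integer_))
  if (N == 0L && O >= 4L && dbe >= 2) {
    if (!is.null(hint) && hint %in% c("MFA", "DFA")) {
      if (hint == "DFA") return(mk("DFA", dbe - 2 - oxo, O - 4L))
      return(mk("MFA", dbe - 1 - oxo, O - 2L))
    }
    if (any(losses$loss %in% carboxylLosses))
      return(mk("DFA", dbe - 2 - oxo, O - 4L, ambiguous = FALSE))
    # both readings viable, no discriminating evidence: default to MFA
    return(mk("MFA", dbe - 1 - oxo, O - 2L, ambiguous = TRUE))
  }
  if (N == 0L && O >= 2L) {
    cc <- dbe - 1 - oxo
    if (cc < 0) return(unclassifiedAssignment(counts, dbe))
    return(mk("MFA", cc, O - 2L))
  }
  unclassifiedAssignment(counts, dbe)
}

#' Tally class assignments
#'
#' @param assignments data.frame of stacked \code{\link{classifyCompound}}
#'   rows (or the result of \code{\link{annotateTable}}).
#' @return List with \code{classes} (named counts over MFA/DFA/FAA/CAD and
#'   unclassified), \code{byClass} (counts keyed by class, chain double
#'   bonds and oxygen excess), \code{saturated} (per class, zero chain
#'   double bonds and no extra oxygenation), \code{monoUnsaturated}
#'   (exactly one chain double bond, no extra oxygenation),
#'   \code{oxygenated} (extra oxygens or oxo flag) and \code{total}.
#' @export
countByClass <- function(assignments) {
  stopifnot(all(c("class", "ccDoubleBonds", "oxygenExcess") %in%
                  names(assignments)))
  lev <- c("MFA", "DFA", "FAA", "CAD", "unclassified")
  cls <- factor(assignments$class, levels = lev)
  classes <- table(cls, dnn = NULL)
  ok <- assignments$class != "unclassified"
  a <- assignments[ok, , drop = FALSE]
  byClass <- as.data.frame(table(class = a$class,
                                 ccDoubleBonds = a$ccDoubleBonds,
                                 oxygenExcess = a$oxygenExcess),
                           stringsAsFactors = FALSE)
  byClass <- byClass[byClass$Freq > 0, , drop = FALSE]
  names(byClass)[names(byClass) == "Freq"] <- "n"
  rownames(byClass) <- NULL
  tallyBy <- function(cond) {
    v <- table(factor(a$class[cond], levels = c("MFA", "DFA", "FAA", "CAD")),
               dnn = NULL)
    as.vector(v, mode = "integer") -> n; names(n) <- names(v); n
  }
  plain <- !is.na(a$ccDoubleBonds) & a$oxygenExcess == 0 & !a$oxoFlag
  list(classes = c(classes),
       byClass = byClass,
       saturated = tallyBy(plain & a$ccDoubleBonds == 0),
       monoUnsaturated = tallyBy(plain & a$ccDoubleBonds == 1),
       oxygenated = tallyBy(!is.na(a$oxygenExcess) &
                              (a$oxygenExcess > 0 | a$oxoFlag)),
       total = sum(ok))
}
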