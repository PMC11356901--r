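#' Monoisotopic element masses used throughout the package
#'
#' Masses are CODATA/IUPAC monoisotopic values on the carbon-12 scale
#' (\code{C} is exactly 12 by definition).  The same table is shipped as a
#' machine-readable resource under \code{extdata/element_masses.csv}.
#'
#' @return Named numeric vector of monoisotopic masses in Da for the
#'   elements supported in formula arithmetic (C, H, N, O).
#' @export
#' @examples
#' elementMasses()[["H"]]
elementMasses <- function() {
  c(C = 12,
    H = 1.00782503207,
    N = 14.0030740048,
    O = 15.9949146196)
}

#' Proton mass used for adduct arithmetic
#'
#' The protonation/deprotonation mass delta.  The electron mass is folded
#' into this convention, as is standard for singly charged quasimolecular
#' ions.
#'
#' @return Proton mass in Da.
#' @export
protonMass <- function() 1.00727646688

#' Supported adducts
#'
#' Only singly protonated and singly deprotonated quasimolecular ions are
#' supported: \code{[M+H]+} and \code{[M-H]-}.
#'
#' @return data.frame with columns \code{name}, \code{charge} and
#'   \code{massDelta} (signed proton mass, Da).
#' @export
adducts <- function() {
  data.frame(name = c("[M+H]+", "[M-H]-"),
             charge = c(1L, -1L),
             massDelta = c(protonMass(), -protonMass()),
             stringsAsFactors = FALSE)
}

# normalize typographic minus / spacing in adduct names
normalizeAdduct <- function(adduct) {
  a <- gsub("[−–]", "-", adduct)
  a <- gsub("[[:space:]]", "", a)
  ok <- a %in% adducts()$name
  if (!all(ok))
    stop("unsupported adduct(s): ", paste(unique(adduct[!ok]), collapse = ", "),
         "; supported: ", paste(adducts()$name, collapse = ", "))
  a
}

#' Parse a molecular formula string
#'
#' @param x Formula string such as \code{"C18H33NO"}, or an already-parsed
#'   named count vector (returned unchanged after validation).
#' @return Named integer vector with one entry per supported element,
#'   in the order C, H, N, O.
#' @export
#' @examples
#' parseFormula("C9H16O4")
parseFormula <- function(x) {
  elems <- names(elementMasses())
  if (is.numeric(x)) {
    if (is.null(names(x)) || !all(names(x) %in% elems))
      stop("named count vector must use elements ",
           paste(elems, collapse = ", "))
    counts <- stats::setNames(integer(length(elems)), elems)
    counts[names(x)] <- as.integer(x)
    if (any(counts < 0)) stop("negative element count")
    return(counts)
  }
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("[[:space:]]", "", x)
  counts <- stats::setNames(integer(length(elems)), elems)
  if (s == "") return(counts)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: ", x)
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (n == "") 1L else as.integer(n)
    if (!el %in% elems)
      stop("unknown element '", el, "' in formula ", x)
    counts[el] <- counts[el] + n
  }
  counts
}

#' Format a count vector as a formula string
#'
#' @param counts Named element count vector (or formula string, normalized).
#' @return Hill-like formula string; empty counts give \code{""}.
#' @export
formulaString <- function(counts) {
  counts <- parseFormula(counts)
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Formula string or named count vector.
#' @return Monoisotopic mass in Da (0 for the empty formula).
#' @export
#' @examples
#' monoisotopicMass("C9H16O4")
monoisotopicMass <- function(formula) {
  counts <- parseFormula(formula)
  sum(counts * elementMasses()[names(counts)])
}

#' Theoretical m/z of a quasimolecular ion
#'
#' @param formula Neutral molecule formula.
#' @param adduct \code{"[M+H]+"} or \code{"[M-H]-"}.
#' @return m/z in Th.
#' @export
#' @examples
#' ionMz("C28H37N5O7", "[M+H]+")  # leucine enkephalin lock mass
ionMz <- function(formula, adduct) {
  adduct <- normalizeAdduct(adduct)
  ad <- adducts()
  monoisotopicMass(formula) + ad$massDelta[match(adduct, ad$name)]
}

#' Signed ppm mass error
#'
#' Convention: \code{1e6 * (observed - theoretical) / theoretical}.
#'
#' @param observed,theoretical m/z values; \code{theoretical} must be > 0.
#' @return Signed error in ppm (vectorized).
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Ring-and-double-bond equivalents of a CHNO neutral
#'
#' DBE = C - H/2 + N/2 + 1.  A saturated acyclic monocarboxylic acid or
#' primary amide has DBE 1.  Negative or non-integer values are returned
#' as-is; downstream filters treat them as invalid.
#'
#' @param formula Neutral formula (string or count vector).
#' @return DBE (unitless, possibly half-integer or negative).
#' @export
#' @examples
#' rdbe("C18H33NO")  # linoleamide neutral: 3
rdbe <- function(formula) {
  counts <- parseFormula(formula)
  counts[["C"]] - counts[["H"]] / 2 + counts[["N"]] / 2 + 1
}

#' Bounded CHNO formula decomposition of an accurate mass
#'
#' Exhaustively enumerates all CHNO neutral formulas whose theoretical
#' quasimolecular ion lies within \code{tolerancePpm} of the observed m/z.
#' Candidates with negative or non-integer DBE, or DBE outside
#' \code{dbeRange}, are removed.  The default nitrogen bound of 1 reflects
#' the single-nitrogen chemistry of fatty acid amides; the DBE ceiling of 12
#' comfortably covers phenylpropanoid aromatics.
#'
#' @param observedMz Observed ion m/z (Th).
#' @param adduct \code{"[M+H]+"} or \code{"[M-H]-"}.
#' @param tolerancePpm Mass tolerance in ppm (default 7).
#' @param bounds Named upper bounds for element counts
#'   (default \code{c(C = 40, H = 80, N = 1, O = 8)}).
#' @param dbeRange Closed DBE interval accepted (default \code{c(0, 12)}).
#' @return data.frame with columns \code{formula}, \code{C}, \code{H},
#'   \code{N}, \code{O}, \code{theoreticalMz}, \code{ppmError}, \code{rdbe},
#'   sorted by |ppm error|, ties broken by fewer heteroatoms then fewer
#'   atoms.  Zero rows when nothing falls in the window.
#' @export
#' @examples
#' decomposeMass(187.0982, "[M-H]-")  # azelaic acid
decomposeMass <- function(observedMz, adduct, tolerancePpm = 7,
                          bounds = c(C = 40, H = 80, N = 1, O = 8),
                          dbeRange = c(0, 12)) {
  stopifnot(tolerancePpm > 0, observedMz > 0, all(is.finite(bounds)))
  adduct <- normalizeAdduct(adduct)
  ad <- adducts()
  delta <- ad$massDelta[match(adduct, ad$name)]
  target <- observedMz - delta          # neutral monoisotopic mass window
  win <- observedMz * tolerancePpm * 1e-6
  em <- elementMasses()

  rows <- vector("list", 64L)
  k <- 0L
  for (C in 0:bounds[["C"]]) {
    mC <- C * em[["C"]]
    if (mC > target + win) break
    for (N in 0:bounds[["N"]]) {
      mCN <- mC + N * em[["N"]]
      if (mCN > target + win) break
      for (O in 0:bounds[["O"]]) {
        base <- mCN + O * em[["O"]]
        if (base > target + win) break
        hLo <- max(0L, as.integer(ceiling((target - win - base) / em[["H"]] - 1e-9)))
        hHi <- min(bounds[["H"]],
                   as.integer(floor((target + win - base) / em[["H"]] + 1e-9)))
        if (hHi < hLo) next
        for (H in hLo:hHi) {
          if (C + H + N + O < 1L) next
          dbe <- C - H / 2 + N / 2 + 1
          if (dbe %% 1 != 0 || dbe < dbeRange[1] || dbe > dbeRange[2]) next
          theo <- base + H * em[["H"]] + delta
          ppm <- ppmError(observedMz, theo)
          if (abs(ppm) > tolerancePpm) next
          k <- k + 1L
          if (k > length(rows)) rows <- c(rows, vector("list", length(rows)))
          rows[[k]] <- c(C = C, H = H, N = N, O = O,
                         theoreticalMz = theo, ppmError = ppm, rdbe = dbe)
        }
      }
    }
  }
  if (k == 0L)
    return(data.frame(formula = character(), C = integer(), H = integer(),
                      N = integer(), O = integer(), theoreticalMz = numeric(),
                      ppmError = numeric(), rdbe = numeric(),
                      stringsAsFactors = FALSE))
  out <- as.data.frame(do.call(rbind, rows[seq_len(k)]))
  out$formula <- vapply(seq_len(k), function(i) {
    formulaString(c(C = out$C[i], H = out$H[i], N = out$N[i], O = out$O[i]))
  }, character(1))
  ord <- order(abs(out$ppmError), out$N + out$O, out$C + out$H + out$N + out$O)
  out <- out[ord, c("formula", "C", "H", "N", "O",
                    "theoreticalMz", "ppmError", "rdbe")]
  rownames(out) <- NULL
  out$C <- as.integer(out$C); out$H <- as.integer(out$H)
  out$N <- as.integer(out$N); out$O <- as.integer(out$O)
  out
}
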