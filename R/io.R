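#' Load the packaged identification-table fixture
#'
#' The packaged table transcribes the 166 tentatively identified compounds
#' of the screening study: retention time, printed and normalized compound
#' names, class, molecular-ion adduct, observed mass, the printed ppm error
#' (informational; it is not reproducible from any single convention and is
#' never used in computation), the high-energy fragment list, and the five
#' presence/absence flags for extracts CTL1-CTL5
#' (100/150/250/300/500 bar at 55 degC).
#'
#' @param path CSV path; defaults to the packaged resource.
#' @return Validated data.frame of 166 rows.
#' @export
loadFixtureTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ctl_table1.csv", package = "mzscreen",
                        mustWork = TRUE)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("peak", "rt_min", "name", "name_printed", "class", "adduct",
            "observed_mz", "error_ppm", "fragments", paste0("CTL", 1:5))
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("fixture validation: missing column(s) ", paste(miss, collapse = ", "))
  fail <- function(rule, rows)
    stop("fixture validation: ", rule, " (row ",
         paste(utils::head(rows, 5), collapse = ", "), ")")
  if (nrow(tb) != 166)
    stop("fixture validation: expected 166 rows, found ", nrow(tb))
  bad <- which(!tb$class %in% c("MFA", "DFA", "FAA", "CAD"))
  if (length(bad)) fail("unknown chemical class", tb$peak[bad])
  bad <- which(!tb$adduct %in% adducts()$name)
  if (length(bad)) fail("unknown adduct", tb$peak[bad])
  bad <- which(is.na(tb$observed_mz) | tb$observed_mz < 50 |
                 tb$observed_mz > 1200)
  if (length(bad)) fail("observed mass outside scan range [50, 1200]",
                        tb$peak[bad])
  bad <- which(is.na(tb$rt_min) | tb$rt_min < 0 | tb$rt_min > 20)
  if (length(bad)) fail("retention time outside [0, 20] min", tb$peak[bad])
  for (ct in paste0("CTL", 1:5)) {
    bad <- which(!tb[[ct]] %in% c(0L, 1L))
    if (length(bad)) fail(paste("presence flag not 0/1 in", ct), tb$peak[bad])
  }
  if (anyDuplicated(tb$name))
    fail("duplicate normalized compound label",
         tb$peak[duplicated(tb$name)])
  tally <- table(tb$class)
  expect <- c(CAD = 21L, DFA = 52L, FAA = 27L, MFA = 66L)
  if (!identical(as.integer(tally[names(expect)]), unname(expect)))
    stop("fixture validation: class tallies ",
         paste(names(tally), as.integer(tally), collapse = " "),
         " differ from the expected 66 MFA / 52 DFA / 27 FAA / 21 CAD")
  tb$fragments[is.na(tb$fragments)] <- ""
  tb
}

#' Presence/absence matrix straight from the fixture's printed flags
#'
#' @param fixture Table from \code{\link{loadFixtureTable}}.
#' @return A \linkS4class{PresenceMatrix} (5 extracts x 166 compounds).
#' @export
fixturePresenceMatrix <- function(fixture = loadFixtureTable()) {
  m <- t(as.matrix(fixture[paste0("CTL", 1:5)]))
  colnames(m) <- fixture$name
  meta <- data.frame(name = fixture$name, class = fixture$class,
                     adduct = fixture$adduct, stringsAsFactors = FALSE)
  PresenceMatrix(m, meta)
}

hintConsistent <- function(cand, hint) {
  keep <- switch(hint,
                 FAA = cand$N == 1 & cand$O == 1,
                 CAD = cand$N == 0 & cand$rdbe >= 4 & cand$C >= 7 & cand$C <= 15,
                 DFA = cand$N == 0 & cand$O >= 4 & cand$rdbe >= 2,
                 MFA = cand$N == 0 & cand$O >= 2)
  cand[keep, , drop = FALSE]
}

#' Decompose and classify every row of an identification table
#'
#' For each observed mass, enumerates CHNO formula candidates under an
#' escalating tolerance ladder, keeping the first tolerance at which a
#' candidate consistent with the row's class hint appears (printed masses
#' are not uniformly accurate to the screening tolerance, so the ladder
#' recovers rows whose transcription error exceeds 7 ppm); the best
#' candidate (smallest |ppm error|) is then classified by the DBE and
#' fragment rules.
#'
#' @param tab data.frame with columns \code{observed_mz}, \code{adduct},
#'   \code{fragments} and (when \code{useHints}) \code{class}; typically
#'   \code{\link{loadFixtureTable}} output or a target-library-shaped
#'   table.
#' @param toleranceLadder Increasing ppm tolerances tried in turn
#'   (default \code{c(7, 15, 50)}).
#' @param useHints Use the \code{class} column to filter candidates and
#'   resolve the MFA/DFA boundary (default TRUE).
#' @param fragmentTolDa Fragment tolerance in Da.
#' @return The input with appended columns \code{formula},
#'   \code{theoretical_mz}, \code{ppm_error}, \code{tol_used},
#'   \code{rdbe}, \code{assigned_class}, \code{chainCarbons},
#'   \code{ccDoubleBonds}, \code{oxygenExcess}, \code{ambiguous},
#'   \code{evidence}.
#' @export
annotateTable <- function(tab, toleranceLadder = c(7, 15, 50),
                          useHints = TRUE, fragmentTolDa = 0.01) {
  stopifnot(all(c("observed_mz", "adduct", "fragments") %in% names(tab)),
            all(diff(toleranceLadder) > 0) || length(toleranceLadder) == 1)
  n <- nrow(tab)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    hint <- if (useHints && "class" %in% names(tab)) tab$class[i] else NULL
    cand <- NULL; tolUsed <- NA_real_
    for (tol in toleranceLadder) {
      cc <- decomposeMass(tab$observed_mz[i], tab$adduct[i], tol)
      if (!is.null(hint) && nrow(cc)) cc <- hintConsistent(cc, hint)
      if (nrow(cc)) { cand <- cc[1, ]; tolUsed <- tol; break }
    }
    if (is.null(cand)) {
      res[[i]] <- data.frame(formula = NA_character_,
                             theoretical_mz = NA_real_, ppm_error = NA_real_,
                             tol_used = NA_real_, rdbe = NA_real_,
                             assigned_class = "unclassified",
                             chainCarbons = NA_integer_,
                             ccDoubleBonds = NA_integer_,
                             oxygenExcess = NA_integer_, ambiguous = FALSE,
                             evidence = "", stringsAsFactors = FALSE)
      next
    }
    cl <- classifyCompound(cand$formula, tab$adduct[i],
                           fragments = parseFragments(tab$fragments[i]),
                           precursorMz = tab$observed_mz[i], hint = hint,
                           fragmentTolDa = fragmentTolDa)
    res[[i]] <- data.frame(formula = cand$formula,
                           theoretical_mz = cand$theoreticalMz,
                           ppm_error = cand$ppmError, tol_used = tolUsed,
                           rdbe = cand$rdbe, assigned_class = cl$class,
                           chainCarbons = cl$chainCarbons,
                           ccDoubleBonds = cl$ccDoubleBonds,
                           oxygenExcess = cl$oxygenExcess,
                           ambiguous = cl$ambiguous, evidence = cl$evidence,
                           stringsAsFactors = FALSE)
  }
  cbind(tab, do.call(rbind, res))
}

#' Read a peak table CSV into an ExtractRun
#'
#' Dialect: header columns \code{mz}, \code{rt_min}, \code{intensity},
#' \code{fragments} (semicolon-separated m/z), one file per extract per
#' polarity.
#'
#' @param path CSV file.
#' @param extractId Extract label.
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @param pressure,temperature Optional extraction condition.
#' @return An \linkS4class{ExtractRun}.
#' @export
readPeakTable <- function(path, extractId, polarity,
                          pressure = NA, temperature = NA) {
  pk <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fragments = "character"))
  need <- c("mz", "rt_min", "intensity", "fragments")
  miss <- setdiff(need, names(pk))
  if (length(miss))
    stop("peak table ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  ExtractRun(extractId, pk[need], polarity, pressure, temperature)
}

#' Write an ExtractRun's peaks to CSV
#'
#' @param run An \linkS4class{ExtractRun}.
#' @param path Output CSV.
#' @return \code{path}, invisibly.
#' @export
writePeakTable <- function(run, path) {
  utils::write.csv(peaks(run), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write a target library CSV
#'
#' Columns: \code{name}, \code{formula}, \code{class}, \code{adduct},
#' \code{fragments} (semicolon-separated), optional \code{rt_min}.
#'
#' @param path CSV file.
#' @return data.frame target library.
#' @export
readTargetLibrary <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(fragments = "character"))
  need <- c("name", "formula", "class", "adduct", "fragments")
  miss <- setdiff(need, names(lib))
  if (length(miss))
    stop("target library ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  lib$adduct <- normalizeAdduct(lib$adduct)
  lib
}

#' @rdname readTargetLibrary
#' @param library Target library data.frame.
#' @export
writeTargetLibrary <- function(library, path) {
  utils::write.csv(library, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Full pipeline report on the packaged fixture
#'
#' Decomposes and classifies every fixture row (library hints on), builds
#' the presence matrix from the printed flags, and summarizes class
#' tallies, saturation tallies and the Venn partition.
#'
#' @param fixture Table from \code{\link{loadFixtureTable}}.
#' @param useHints Passed to \code{\link{annotateTable}}.
#' @return List of class \code{"screeningReport"} with elements
#'   \code{annotated}, \code{counts}, \code{venn}, \code{perExtract}.
#' @export
screeningReport <- function(fixture = loadFixtureTable(), useHints = TRUE) {
  ann <- annotateTable(fixture, useHints = useHints)
  ann$class <- ann$assigned_class
  counts <- countByClass(
    data.frame(class = ann$assigned_class,
               ccDoubleBonds = ann$ccDoubleBonds,
               oxygenExcess = ann$oxygenExcess,
               oxoFlag = FALSE, stringsAsFactors = FALSE))
  pm <- fixturePresenceMatrix(fixture)
  venn <- vennPartition(pm)
  out <- list(annotated = ann, counts = counts, venn = venn,
              perExtract = rowSums(presence(pm)))
  class(out) <- "screeningReport"
  out
}

#' @export
print.screeningReport <- function(x, ...) {
  cat("Post-targeted screening report\n")
  cat("  compounds classified:", x$counts$total, "\n")
  cl <- x$counts$classes
  cat("  classes:", paste(names(cl), as.integer(cl), collapse = ", "), "\n")
  cat("  saturated:", paste(names(x$counts$saturated),
                            x$counts$saturated, collapse = ", "), "\n")
  cat("  per extract:", paste(names(x$perExtract), x$perExtract,
                              collapse = ", "), "\n")
  all5 <- paste(x$venn$extracts, collapse = "&")
  cat("  common to all extracts:",
      if (all5 %in% names(x$venn$sizes)) x$venn$sizes[[all5]] else 0, "\n")
  invisible(x)
}
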