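#' Post-targeted screening of a target library against one run
#'
#' For every library target whose adduct polarity matches the run, peaks
#' within \code{tolerancePpm} of the target's theoretical quasimolecular
#' m/z become candidate detections.  A candidate is confirmed when at least
#' one declared diagnostic fragment matches within \code{fragmentTolDa},
#' or when the target's class is listed in \code{precursorOnlyClasses}
#' (fatty acid quasimolecular ions largely resist fragmentation, so the
#' precursor alone is accepted for them).  Unconfirmed candidates are
#' retained with \code{confirmed = FALSE}.
#'
#' When several peaks of one run match the same target,
#' \code{keep = "best"} retains only the peak with the smallest |ppm error|
#' (extracted-ion-chromatogram apexing); \code{keep = "all"} retains every
#' match, which is appropriate when the library declares isomers.
#'
#' @param run An \linkS4class{ExtractRun}.
#' @param library Target library data.frame with columns \code{name},
#'   \code{formula}, \code{class}, \code{adduct}, \code{fragments}
#'   (semicolon-separated m/z, may be empty) and optionally \code{rt_min}.
#' @param tolerancePpm Precursor tolerance in ppm (default 7).
#' @param fragmentTolDa Fragment tolerance in Da (default 0.01).
#' @param precursorOnlyClasses Classes confirmed on the precursor alone.
#' @param minIntensity Minimum peak intensity considered (default 0).
#' @param keep \code{"best"} or \code{"all"} (see Details).
#' @return data.frame of detections: \code{target}, \code{class},
#'   \code{formula}, \code{adduct}, \code{extract_id}, \code{observed_mz},
#'   \code{rt_min}, \code{intensity}, \code{theoretical_mz},
#'   \code{ppm_error}, \code{n_fragments_matched}, \code{confirmed},
#'   \code{label}.  Zero rows when nothing matches; a polarity mismatch
#'   between the run and every target yields zero rows with a warning.
#' @export
screenTargets <- function(run, library, tolerancePpm = 7,
                          fragmentTolDa = 0.01,
                          precursorOnlyClasses = c("MFA", "DFA"),
                          minIntensity = 0, keep = c("best", "all")) {
  stopifnot(is(run, "ExtractRun"), nrow(library) > 0, tolerancePpm > 0)
  keep <- match.arg(keep)
  library$adduct <- normalizeAdduct(library$adduct)
  runPol <- if (polarity(run) == "positive") "[M+H]+" else "[M-H]-"
  lib <- library[library$adduct == runPol, , drop = FALSE]
  empty <- data.frame(target = character(), class = character(),
                      formula = character(), adduct = character(),
                      extract_id = character(), observed_mz = numeric(),
                      rt_min = numeric(), intensity = numeric(),
                      theoretical_mz = numeric(), ppm_error = numeric(),
                      n_fragments_matched = integer(), confirmed = logical(),
                      label = character(), stringsAsFactors = FALSE)
  if (!nrow(lib)) {
    warning("no library target matches the run polarity (", polarity(run), ")")
    return(empty)
  }
  pk <- peaks(run)
  pk <- pk[pk$intensity >= minIntensity, , drop = FALSE]
  if (!nrow(pk)) return(empty)

  res <- vector("list", nrow(lib))
  for (i in seq_len(nrow(lib))) {
    theo <- ionMz(lib$formula[i], lib$adduct[i])
    ppm <- ppmError(pk$mz, theo)
    sel <- which(abs(ppm) <= tolerancePpm)
    if (!length(sel)) next
    if (keep == "best") sel <- sel[which.min(abs(ppm[sel]))]
    diag <- parseFragments(lib$fragments[i])
    rows <- lapply(sel, function(j) {
      obsFrag <- parseFragments(pk$fragments[j])
      nMatch <- if (length(diag) && length(obsFrag))
        sum(vapply(diag, function(f) any(abs(obsFrag - f) <= fragmentTolDa),
                   logical(1)))
      else 0L
      data.frame(target = lib$name[i], class = lib$class[i],
                 formula = lib$formula[i], adduct = lib$adduct[i],
                 extract_id = extractId(run), observed_mz = pk$mz[j],
                 rt_min = pk$rt_min[j], intensity = pk$intensity[j],
                 theoretical_mz = theo, ppm_error = ppm[j],
                 n_fragments_matched = as.integer(nMatch),
                 confirmed = nMatch >= 1L ||
                   lib$class[i] %in% precursorOnlyClasses,
                 label = lib$name[i], stringsAsFactors = FALSE)
    })
    res[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Assign Roman-numeral isomer labels by retention order
#'
#' Detections sharing a target name but eluting at distinct retention times
#' are isomers; within each such group, labels I, II, ... are appended in
#' strictly ascending retention-time order.  Retention times closer than
#' \code{rtTolMin} (across extracts) are treated as the same chromatographic
#' species.  Groups with a single species keep the bare name.  Exact
#' retention-time ties are broken by descending intensity, then by input
#' order (documented, deterministic).
#'
#' @param detections Detection data.frame from \code{\link{screenTargets}}
#'   (rows from several runs may be stacked).
#' @param rtTolMin Retention-time coalescing window in minutes
#'   (default 0.1).
#' @return The detections with the \code{label} column isomer-resolved and
#'   an added integer \code{isomer_index} (NA for singletons).
#' @export
assignIsomerLabels <- function(detections, rtTolMin = 0.1) {
  if (!nrow(detections)) {
    detections$isomer_index <- integer()
    return(detections)
  }
  det <- detections
  det$isomer_index <- NA_integer_
  det$label <- det$target
  for (nm in unique(det$target)) {
    idx <- which(det$target == nm)
    ord <- idx[order(det$rt_min[idx], -det$intensity[idx], idx)]
    # coalesce retention times into isomer groups
    grp <- integer(length(ord)); g <- 1L; grp[1] <- 1L
    if (length(ord) > 1) for (k in 2:length(ord)) {
      # gaps of at least rtTolMin open a new chromatographic species
      if (det$rt_min[ord[k]] - det$rt_min[ord[k - 1]] >= rtTolMin - 1e-9)
        g <- g + 1L
      grp[k] <- g
    }
    if (g > 1L) {
      det$isomer_index[ord] <- grp
      det$label[ord] <- paste(nm, as.character(utils::as.roman(grp)))
    }
  }
  det
}

#' Build the presence/absence matrix from confirmed detections
#'
#' @param detections Stacked detection rows carrying isomer-resolved
#'   \code{label}s (run \code{\link{assignIsomerLabels}} first if isomers
#'   are possible).
#' @param extracts Character vector of extract labels defining the row
#'   order (defaults to those seen in the detections).
#' @param confirmedOnly Use only confirmed detections (default TRUE).
#' @return A \linkS4class{PresenceMatrix}.  Duplicate (extract, compound)
#'   detections collapse to a single 1; compounds never confirmed anywhere
#'   are excluded.
#' @export
buildPresenceMatrix <- function(detections,
                                extracts = unique(detections$extract_id),
                                confirmedOnly = TRUE) {
  det <- detections
  if (confirmedOnly && nrow(det)) det <- det[det$confirmed, , drop = FALSE]
  if (!nrow(det)) {
    m <- matrix(integer(), nrow = length(extracts), ncol = 0,
                dimnames = list(extracts, NULL))
    return(PresenceMatrix(m))
  }
  if (!"label" %in% names(det)) det$label <- det$target
  first <- det[!duplicated(det$label), , drop = FALSE]
  first <- first[order(first$rt_min, first$label), , drop = FALSE]
  comp <- first$label
  m <- matrix(0L, nrow = length(extracts), ncol = length(comp),
              dimnames = list(extracts, comp))
  ij <- cbind(match(det$extract_id, extracts), match(det$label, comp))
  ij <- ij[!is.na(ij[, 1]), , drop = FALSE]
  m[ij] <- 1L
  meta <- data.frame(name = comp, class = first$class, adduct = first$adduct,
                     formula = first$formula, stringsAsFactors = FALSE)
  PresenceMatrix(m, meta)
}
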