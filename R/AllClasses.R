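#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ExtractRun: one MSE acquisition of one extract in one polarity
#'
#' Container for a per-extract peak list.  Peaks carry the low-energy
#' precursor m/z, retention time, intensity and the list of high-energy
#' fragment m/z values observed in the same chromatographic peak.
#'
#' @slot extractId Extract label, e.g. \code{"CTL1"}.
#' @slot pressure Extraction pressure in bar (may be NA).
#' @slot temperature Extraction temperature in degrees C (may be NA).
#' @slot polarity \code{"positive"} or \code{"negative"}.
#' @slot peaks data.frame with columns \code{mz}, \code{rt_min},
#'   \code{intensity} and \code{fragments} (semicolon-separated m/z string,
#'   possibly empty).
#' @export
setClass("ExtractRun",
         representation(extractId = "character",
                        pressure = "numeric",
                        temperature = "numeric",
                        polarity = "character",
                        peaks = "data.frame"))

setValidity("ExtractRun", function(object) {
  msg <- character()
  if (length(object@extractId) != 1L || !nzchar(object@extractId))
    msg <- c(msg, "extractId must be a single non-empty string")
  if (!object@polarity %in% c("positive", "negative"))
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  pk <- object@peaks
  need <- c("mz", "rt_min", "intensity", "fragments")
  if (!all(need %in% names(pk)))
    msg <- c(msg, paste("peaks must have columns", paste(need, collapse = ", ")))
  else if (nrow(pk)) {
    if (any(pk$mz < 50 | pk$mz > 1200))
      msg <- c(msg, "peak m/z outside the scan range [50, 1200]")
    if (any(pk$rt_min < 0 | pk$rt_min > 20))
      msg <- c(msg, "retention time outside [0, 20] min")
    if (any(pk$intensity < 0))
      msg <- c(msg, "negative intensity")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExtractRun
#'
#' @param extractId Extract label.
#' @param peaks data.frame with columns \code{mz}, \code{rt_min},
#'   \code{intensity}, \code{fragments}.
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @param pressure,temperature Extraction condition (bar, degrees C).
#' @return An \linkS4class{ExtractRun}.
#' @export
ExtractRun <- function(extractId, peaks, polarity,
                       pressure = NA_real_, temperature = NA_real_) {
  peaks$fragments <- as.character(peaks$fragments)
  peaks$fragments[is.na(peaks$fragments)] <- ""
  new("ExtractRun", extractId = extractId, peaks = peaks,
      polarity = polarity, pressure = as.numeric(pressure),
      temperature = as.numeric(temperature))
}

#' PresenceMatrix: binary compound occurrence across extracts
#'
#' Rows are extracts, columns are (isomer-resolved) compound labels; a cell
#' is 1 iff a confirmed detection of that compound exists in that extract.
#'
#' @slot presence Integer 0/1 matrix, extracts x compounds.
#' @slot compounds data.frame of per-column metadata with at least
#'   \code{name}, \code{class} and \code{adduct}.
#' @export
setClass("PresenceMatrix",
         representation(presence = "matrix", compounds = "data.frame"))

setValidity("PresenceMatrix", function(object) {
  msg <- character()
  p <- object@presence
  if (length(p) && !all(p %in% c(0L, 1L)))
    msg <- c(msg, "presence cells must be 0 or 1")
  if (is.null(rownames(p)) && nrow(p))
    msg <- c(msg, "presence matrix needs extract row names")
  if (ncol(p) != nrow(object@compounds))
    msg <- c(msg, "compound metadata must have one row per matrix column")
  if (ncol(p) && anyDuplicated(colnames(p)))
    msg <- c(msg, "compound column labels must be unique")
  if (ncol(p) && !identical(colnames(p), object@compounds$name))
    msg <- c(msg, "column names must equal compounds$name")
  if (length(msg)) msg else TRUE
})

#' Construct a PresenceMatrix
#'
#' @param presence 0/1 matrix (extracts x compounds) with dimnames.
#' @param compounds data.frame with columns \code{name}, \code{class},
#'   \code{adduct} matching the matrix columns.  Defaults to a bare frame
#'   built from the column names.
#' @return A \linkS4class{PresenceMatrix}.
#' @export
PresenceMatrix <- function(presence, compounds = NULL) {
  storage.mode(presence) <- "integer"
  if (is.null(compounds)) {
    nm <- colnames(presence)
    if (is.null(nm)) nm <- character(ncol(presence))
    compounds <- data.frame(name = nm,
                            class = rep(NA_character_, ncol(presence)),
                            adduct = rep(NA_character_, ncol(presence)),
                            stringsAsFactors = FALSE)
  }
  new("PresenceMatrix", presence = presence, compounds = compounds)
}

#' @describeIn PresenceMatrix the 0/1 matrix
#' @param x A PresenceMatrix.
#' @export
presence <- function(x) x@presence

#' @describeIn PresenceMatrix extract (row) labels
#' @export
extractNames <- function(x) rownames(x@presence)

#' @describeIn PresenceMatrix compound (column) labels
#' @export
compoundNames <- function(x) colnames(x@presence)

#' @describeIn PresenceMatrix per-compound metadata
#' @export
compoundData <- function(x) x@compounds

#' Generic for run polarity
#' @param object An ExtractRun.
#' @export
setGeneric("polarity", function(object) standardGeneric("polarity"))

#' @describeIn ExtractRun run polarity
#' @param object An ExtractRun.
#' @export
setMethod("polarity", "ExtractRun", function(object) object@polarity)

#' Generic for a run's peak table
#' @param object An ExtractRun.
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @describeIn ExtractRun the peak table
#' @export
setMethod("peaks", "ExtractRun", function(object) object@peaks)

#' @describeIn ExtractRun the extract label
#' @export
setGeneric("extractId", function(object) standardGeneric("extractId"))

#' @rdname ExtractRun-class
#' @export
setMethod("extractId", "ExtractRun", function(object) object@extractId)

setMethod("show", "ExtractRun", function(object) {
  cat("ExtractRun", object@extractId,
      sprintf("(%s mode)", object@polarity), "\n")
  if (!is.na(object@pressure))
    cat("  condition:", object@pressure, "bar /", object@temperature, "degC\n")
  cat(" ", nrow(object@peaks), "peaks\n")
})

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@presence), "extracts x",
      ncol(object@presence), "compounds\n")
  cl <- table(object@compounds$class)
  if (length(cl))
    cat("  classes:", paste(names(cl), as.integer(cl), collapse = ", "), "\n")
})

# parse a semicolon-separated fragment string into numeric m/z
parseFragments <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(numeric())
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

formatFragments <- function(x) paste(format(x, trim = TRUE), collapse = ";")
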