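selectMode <- function(pm, polarity = c("all", "positive", "negative")) {
  polarity <- match.arg(polarity)
  m <- presence(pm)
  if (polarity == "all") return(m)
  want <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  m[, compoundData(pm)$adduct == want, drop = FALSE]
}

#' Principal component analysis of a presence/absence matrix
#'
#' Columns constant across extracts (present everywhere or nowhere) carry
#' no variance and are removed before the decomposition.  The matrix is
#' column mean-centered; unit-variance scaling is off by default because
#' on binary data it inflates the influence of rare compounds.
#'
#' @param pm A \linkS4class{PresenceMatrix}.
#' @param polarity \code{"all"}, \code{"positive"} or \code{"negative"}
#'   (mode of the molecular ion column).
#' @param scale. Scale columns to unit variance (default FALSE).
#' @return List of class \code{"screenPCA"}: \code{scores} (extracts x
#'   components), \code{loadings} (compounds x components),
#'   \code{explainedFraction}, \code{centered} (the centered input).
#' @export
runPCA <- function(pm, polarity = "all", scale. = FALSE) {
  m <- selectMode(pm, polarity)
  if (nrow(m) < 2) stop("PCA needs at least 2 extracts")
  keep <- apply(m, 2, function(x) stats::var(x) > 0)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 1)
    stop("degenerate input: no informative (non-constant) compound columns")
  p <- stats::prcomp(m, center = TRUE, scale. = scale.)
  ev <- p$sdev^2
  out <- list(scores = p$x, loadings = p$rotation,
              explainedFraction = ev / sum(ev),
              centered = scale(m, center = TRUE, scale = FALSE))
  class(out) <- "screenPCA"
  out
}

#' @export
print.screenPCA <- function(x, ...) {
  cat("PCA of presence/absence matrix:", nrow(x$scores), "extracts,",
      nrow(x$loadings), "informative compounds\n")
  ef <- round(100 * x$explainedFraction[1:min(2, length(x$explainedFraction))], 1)
  cat("  explained variance:", paste0("PC", seq_along(ef), " ", ef, "%",
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Extract most distant from the centroid of the others in PCA score space
#'
#' @param pca A \code{"screenPCA"} object.
#' @return Extract label of the score-space outlier.
#' @export
pcaOutlier <- function(pca) {
  sc <- pca$scores
  d <- vapply(seq_len(nrow(sc)), function(i)
    sqrt(sum((sc[i, ] - colMeans(sc[-i, , drop = FALSE]))^2)), numeric(1))
  rownames(sc)[which.max(d)]
}

#' Ward hierarchical clustering of extracts
#'
#' Agglomerative clustering of the extract rows with the Ward
#' minimum-variance criterion in its squared-Euclidean-updating form
#' (\code{"ward.D2"}) on Euclidean distances.  Rows are ordered
#' lexicographically by label before clustering so that exact distance ties
#' are broken deterministically and the tree is invariant under input row
#' permutation (up to relabeling).
#'
#' @param pm A \linkS4class{PresenceMatrix}.
#' @param polarity Mode filter as in \code{\link{runPCA}}.
#' @return An \code{\link[stats]{hclust}} tree over the extracts.
#' @export
wardCluster <- function(pm, polarity = "all") {
  m <- selectMode(pm, polarity)
  if (nrow(m) < 2) stop("clustering needs at least 2 extracts")
  m <- m[order(rownames(m)), , drop = FALSE]
  stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
}

#' Last singleton extract to join a dendrogram (the outgroup)
#'
#' @param hc An \code{hclust} tree as from \code{\link{wardCluster}}.
#' @return Label of the leaf merged last as a singleton.
#' @export
wardOutgroup <- function(hc) {
  steps <- vapply(seq_along(hc$labels), function(i)
    which(apply(hc$merge, 1, function(r) any(r == -i)))[1], numeric(1))
  hc$labels[which.max(steps)]
}

#' Pairwise Pearson correlation between extracts
#'
#' Correlates the compound presence vectors of every pair of extracts.
#' An extract with zero variance (all compounds present, or none) yields
#' \code{NA} correlations for its pairs.
#'
#' @param pm A \linkS4class{PresenceMatrix}.
#' @param polarity Mode filter as in \code{\link{runPCA}}.
#' @return List with \code{r} (correlation matrix) and \code{r2}
#'   (squared).
#' @export
correlateExtracts <- function(pm, polarity = "all") {
  m <- selectMode(pm, polarity)
  if (ncol(m) < 2) stop("correlation needs at least 2 compounds")
  zeroVar <- apply(m, 1, function(x) stats::var(x) == 0)
  r <- suppressWarnings(stats::cor(t(m), method = "pearson"))
  if (any(zeroVar)) {
    warning("zero-variance extract(s): ",
            paste(rownames(m)[zeroVar], collapse = ", "),
            "; correlations reported as NA")
    r[zeroVar, ] <- NA_real_; r[, zeroVar] <- NA_real_
    diag(r) <- 1
  }
  list(r = r, r2 = r^2)
}

#' n-set Venn partition of a presence/absence matrix
#'
#' Every compound is assigned to exactly one region: the subset of extracts
#' it occurs in.  Regions are disjoint and their sizes sum to the number of
#' compounds.
#'
#' @param pm A \linkS4class{PresenceMatrix}.
#' @param polarity Mode filter as in \code{\link{runPCA}}.
#' @return List of class \code{"vennPartition"}: \code{regions} (named list
#'   mapping signature strings such as \code{"CTL1&CTL4"} to compound
#'   labels), \code{sizes}, and \code{extracts}.
#' @export
vennPartition <- function(pm, polarity = "all") {
  m <- selectMode(pm, polarity)
  if (!ncol(m)) {
    out <- list(regions = list(), sizes = integer(), extracts = rownames(m))
    class(out) <- "vennPartition"
    return(out)
  }
  if (any(colSums(m) == 0))
    warning("compound(s) absent everywhere assigned to no region")
  sig <- apply(m, 2, function(col)
    paste(rownames(m)[col == 1L], collapse = "&"))
  keep <- nzchar(sig)
  regions <- split(colnames(m)[keep], sig[keep])
  out <- list(regions = regions,
              sizes = vapply(regions, length, integer(1)),
              extracts = rownames(m))
  class(out) <- "vennPartition"
  out
}

#' @export
print.vennPartition <- function(x, ...) {
  cat("Venn partition over", length(x$extracts), "extracts:",
      sum(x$sizes), "compounds in", length(x$sizes), "regions\n")
  all5 <- paste(x$extracts, collapse = "&")
  if (all5 %in% names(x$sizes))
    cat("  common to all:", x$sizes[[all5]], "\n")
  excl <- x$sizes[names(x$sizes) %in% x$extracts]
  if (length(excl))
    cat("  exclusive:", paste(names(excl), excl, collapse = ", "), "\n")
  invisible(x)
}

#' Region of compounds present in exactly one given extract set
#'
#' @param venn A \code{"vennPartition"}.
#' @param extracts Character vector naming the exact extract subset.
#' @return Character vector of compound labels (possibly empty).
#' @export
vennRegion <- function(venn, extracts) {
  key <- paste(sort(extracts), collapse = "&")
  # signatures are stored in matrix row order; normalize both sides
  stored <- vapply(names(venn$regions), function(s)
    paste(sort(strsplit(s, "&", fixed = TRUE)[[1]]), collapse = "&"),
    character(1))
  hit <- which(stored == key)
  if (!length(hit)) character() else venn$regions[[hit]]
}

#' Serialize chemometrics results to JSON
#'
#' @param x List of results (e.g. PCA fractions, correlation matrix, Venn
#'   sizes); anything \code{jsonlite} can encode.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeChemometricsJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
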