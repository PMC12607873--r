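#' Accessors for hmaFidelity classes
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors percent relative-abundance matrix of a TaxonTable.
#' @export
raValues <- function(x) {
  stopifnot(is(x, "TaxonTable"))
  assay(x, "ra")
}

#' @describeIn accessors taxon identifiers (row names).
#' @export
taxa <- function(x) rownames(x)

#' @describeIn accessors sample identifiers (column names).
#' @export
sampleIds <- function(x) {
  if (is(x, "CorrelationMatrix")) x@ids else colnames(x)
}

#' @describeIn accessors declared taxonomic rank of a TaxonTable.
#' @export
taxonRank <- function(x) x@rank

#' @describeIn accessors whether columns are known to sum to 100.
#' @export
isRenormalized <- function(x) x@renormalized

#' @describeIn accessors donor sample ids of a PairingMap, one per pair.
#' @export
pairDonors <- function(x) x@donor

#' @describeIn accessors recipient-group ids of a PairingMap, one per pair.
#' @export
pairGroups <- function(x) x@group

#' @describeIn accessors mouse sample ids per recipient group (named list).
#' @export
groupMembers <- function(x) x@members

#' @describeIn accessors number of pairs in a PairingMap.
#' @export
nPairs <- function(x) length(x@group)

#' @describeIn accessors coordinates of an Ordination.
#' @export
ordCoordinates <- function(x) x@coordinates

#' @describeIn accessors eigenvalues of an Ordination (descending).
#' @export
ordEigenvalues <- function(x) x@eigenvalues

#' @describeIn accessors per-axis fraction of positive-eigenvalue sum.
#' @export
proportionExplained <- function(x) x@proportionExplained

#' @describeIn accessors observed statistic of a permutation test.
#' @export
testStatistic <- function(x) x@statistic

#' @describeIn accessors R-squared of a PERMANOVA result (NA for PERMDISP).
#' @export
testRSquared <- function(x) x@rSquared

#' @describeIn accessors permutation p-value.
#' @export
testPValue <- function(x) x@pValue

#' @describeIn accessors Pearson coefficient matrix of a CorrelationMatrix.
#' @export
corValues <- function(x) x@r

#' @describeIn accessors Fisher-z matrix of a CorrelationMatrix.
#' @export
zValues <- function(x) x@z

#' @describeIn accessors taxon pool of a SyntheticTruth.
#' @export
taxonPool <- function(x) x@taxonPool

#' @describeIn accessors per-taxon engraftment probabilities.
#' @export
engraftmentProb <- function(x) x@engraftmentProb

#' @describeIn accessors per-taxon mouse fitness multipliers.
#' @export
mouseFitness <- function(x) x@mouseFitness

#' @describeIn accessors consortium taxon subset of a SyntheticTruth.
#' @export
consortiumTaxa <- function(x) x@consortiumTaxa

setMethod("show", "TaxonTable", function(object) {
  cat(sprintf("TaxonTable: %d taxa x %d samples (rank: %s, %s)\n",
              nrow(object), ncol(object), object@rank,
              if (object@renormalized) "renormalized" else "raw"))
  if (ncol(object)) {
    cs <- colSums(assay(object, "ra"))
    cat(sprintf("  column sums: %.4g .. %.4g\n", min(cs), max(cs)))
  }
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("%s: pseudo-F = %.4g", toupper(object@method), object@statistic))
  if (!is.na(object@rSquared)) cat(sprintf(", R2 = %.4g", object@rSquared))
  cat(sprintf(", p = %.4g (%d permutations, seed %d)\n",
              object@pValue, object@nPermutations, object@seed))
})

setMethod("show", "PairingMap", function(object) {
  cat(sprintf("PairingMap: %d donor-recipient pairs, group sizes %s\n",
              length(object@group),
              paste(range(lengths(object@members[object@group])),
                    collapse = "-")))
})

setMethod("show", "Ordination", function(object) {
  k <- ncol(object@coordinates)
  cat(sprintf("Ordination: %d samples, %d axes; axis-1 explains %.1f%%\n",
              nrow(object@coordinates), k,
              100 * object@proportionExplained[1]))
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d samples, mean off-diagonal r = %.3f\n",
              length(object@ids),
              mean(object@r[upper.tri(object@r)], na.rm = TRUE)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d taxa (%d consortium), engraftment prob %.2f-%.2f, noise sd %.2f\n",
    length(object@taxonPool), length(object@consortiumTaxa),
    min(object@engraftmentProb), max(object@engraftmentProb),
    object@noiseSd))
})

#' @describeIn accessors plain base matrix from a DistMatrix.
#' @param ... unused.
#' @export
setMethod("as.matrix", "DistMatrix", function(x, ...) {
  m <- x@.Data
  m
})
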