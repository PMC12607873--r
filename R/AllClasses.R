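#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-` SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom stats setNames
NULL

TAXON_RANKS <- c("species", "genus")
HOST_LEVELS <- c("human", "mouse")
TIMEPOINT_LEVELS <- c("T0", "T2", "baseline", "SPF", "other")
ROUTE_LEVELS <- c("HTR", "MTR", "none")

#' TaxonTable: taxa-by-sample percent relative abundances
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' assay \code{"ra"} of percent relative abundances (0--100 scale) for taxa
#' (rows) at a declared taxonomic rank across samples (columns).
#'
#' @slot rank character(1), \code{"species"} or \code{"genus"}.
#' @slot renormalized logical(1), \code{TRUE} once every column has been
#'   scaled to sum exactly 100 (see \code{\link{renormalize}}).
#'
#' @details Percent (0--100), not proportion, is the canonical internal unit;
#' Bray-Curtis is scale-invariant after renormalization so no conversion is
#' ever needed downstream. Columns of raw input may sum to less than 100
#' (e.g. dropped unclassified fractions); loaders flag this in
#' \code{metadata(x)$needs_renormalization} rather than failing.
#'
#' @export
setClass("TaxonTable",
  contains = "SummarizedExperiment",
  representation(rank = "character", renormalized = "logical")
)

setValidity("TaxonTable", function(object) {
  msg <- character()
  if (length(object@rank) != 1L || !object@rank %in% TAXON_RANKS)
    msg <- c(msg, sprintf("rank must be one of: %s",
                          paste(TAXON_RANKS, collapse = ", ")))
  if (!"ra" %in% names(assays(object)))
    msg <- c(msg, "assay 'ra' is required")
  else {
    ra <- assay(object, "ra")
    if (!is.numeric(ra) || any(!is.finite(ra)))
      msg <- c(msg, "all abundances must be finite numbers")
    else if (any(ra < 0))
      msg <- c(msg, "abundances must be non-negative")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate taxon identifiers: %s",
      paste(unique(rownames(object)[duplicated(rownames(object))]),
            collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicate sample identifiers: %s",
      paste(unique(colnames(object)[duplicated(colnames(object))]),
            collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a TaxonTable
#'
#' @param values numeric matrix, taxa x samples, percent relative abundance
#'   with taxon row names and sample column names. Identifiers are
#'   whitespace-trimmed and case-sensitive.
#' @param rank taxonomic rank of the rows, \code{"species"} or \code{"genus"}.
#' @param renormalized logical(1); set \code{TRUE} only when columns are
#'   known to sum to 100.
#' @return a \linkS4class{TaxonTable}.
#' @examples
#' m <- matrix(c(60, 40, 0, 20, 30, 50), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' TaxonTable(m, rank = "species")
#' @export
TaxonTable <- function(values, rank = c("species", "genus"),
                       renormalized = FALSE) {
  rank <- match.arg(rank)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have taxon row names and sample column names")
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = list(ra = values))
  new("TaxonTable", se, rank = rank, renormalized = renormalized)
}

#' DistMatrix: symmetric sample dissimilarities
#'
#' A numeric matrix subclass with zero diagonal, symmetry and shared
#' row/column identifiers, as produced by \code{\link{brayCurtis}}.
#' @export
setClass("DistMatrix", contains = "matrix")

setValidity("DistMatrix", function(object) {
  m <- object@.Data
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "row and column identifiers must match")
  if (any(!is.finite(m))) msg <- c(msg, "all entries must be finite")
  else {
    if (max(abs(m - t(m))) > 1e-12) msg <- c(msg, "must be symmetric")
    if (any(abs(diag(m)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    if (any(m < -1e-12)) msg <- c(msg, "entries must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname DistMatrix-class
#' @param m square symmetric numeric matrix with matching dimnames.
#' @return a \linkS4class{DistMatrix}.
#' @export
DistMatrix <- function(m) {
  m <- as.matrix(m)
  m <- (m + t(m)) / 2   # kill numerically trivial asymmetry
  diag(m) <- 0
  new("DistMatrix", m)
}

#' Ordination: principal-coordinate embedding
#'
#' @slot coordinates n x k matrix of sample coordinates.
#' @slot eigenvalues all n eigenvalues, sorted descending (negative ones are
#'   retained for diagnostics / dispersion correction).
#' @slot proportionExplained per returned axis, the fraction of the
#'   positive-eigenvalue sum (0 for non-positive axes).
#' @export
setClass("Ordination",
  representation(coordinates = "matrix", eigenvalues = "numeric",
                 proportionExplained = "numeric")
)

setValidity("Ordination", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be sorted descending")
  pos <- object@eigenvalues[object@eigenvalues > 0]
  if (length(pos)) {
    pe <- object@eigenvalues[object@eigenvalues > 0] / sum(pos)
    k <- min(length(pe), length(object@proportionExplained))
    if (k && max(abs(object@proportionExplained[seq_len(k)] - pe[seq_len(k)])) > 1e-9)
      msg <- c(msg, "proportionExplained inconsistent with eigenvalues")
  }
  if (length(msg)) msg else TRUE
})

#' PermutationTestResult: PERMANOVA / PERMDISP output
#'
#' @slot statistic observed pseudo-F.
#' @slot rSquared between-group fraction of total sum of squares
#'   (PERMANOVA; \code{NA} for PERMDISP).
#' @slot pValue permutation p-value, (1+b)/(1+m) estimator so never 0.
#' @slot nPermutations number of label permutations drawn.
#' @slot seed RNG seed used for the permutations.
#' @slot method \code{"permanova"} or \code{"permdisp"}.
#' @export
setClass("PermutationTestResult",
  representation(statistic = "numeric", rSquared = "numeric",
                 pValue = "numeric", nPermutations = "integer",
                 seed = "integer", method = "character")
)

setValidity("PermutationTestResult", function(object) {
  msg <- character()
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (object@nPermutations > 0 &&
      object@pValue < 1 / (object@nPermutations + 1) - 1e-12)
    msg <- c(msg, "pValue below permutation resolution 1/(m+1)")
  if (length(msg)) msg else TRUE
})

#' PairingMap: donor sample to recipient-group pairing
#'
#' @slot donor donor (human) sample identifier per pair.
#' @slot group recipient-group identifier per pair; each group appears once.
#' @slot members named list mapping recipient-group id to the mouse sample
#'   ids that constitute it (cage mates seeded from one stool).
#' @export
setClass("PairingMap",
  representation(donor = "character", group = "character", members = "list")
)

setValidity("PairingMap", function(object) {
  msg <- character()
  if (length(object@donor) != length(object@group))
    msg <- c(msg, "donor and group vectors must be parallel")
  if (anyDuplicated(object@group))
    msg <- c(msg, "a recipient group may appear in exactly one pair")
  if (!all(object@group %in% names(object@members)))
    msg <- c(msg, "every paired group needs a members entry")
  if (any(lengths(object@members[object@group]) < 1L))
    msg <- c(msg, "every recipient group must have at least one mouse sample")
  if (length(msg)) msg else TRUE
})

#' EngraftmentTable: per-taxon engraftment statistics
#'
#' A \linkS4class{DFrame} subclass with one row per taxon (and study), with
#' columns \code{taxon}, \code{study_id}, \code{n_donors_with_taxon},
#' \code{n_pairs_engrafted}, \code{percent_engraftment}, \code{stratum}.
#' @export
setClass("EngraftmentTable", contains = "DFrame")

ENGRAFTMENT_COLS <- c("taxon", "study_id", "n_donors_with_taxon",
                      "n_pairs_engrafted", "percent_engraftment", "stratum")

setValidity("EngraftmentTable", function(object) {
  msg <- character()
  missing <- setdiff(ENGRAFTMENT_COLS, colnames(object))
  if (length(missing))
    msg <- c(msg, sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  else {
    bad <- object$n_pairs_engrafted > object$n_donors_with_taxon
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "n_pairs_engrafted may not exceed n_donors_with_taxon")
    pe <- object$percent_engraftment
    if (any(pe < -1e-9 | pe > 100 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "percent_engraftment must lie in [0, 100]")
    if (!all(object$stratum %in% c("high", "medium", "low", "unassigned")))
      msg <- c(msg, "unknown stratum label")
  }
  if (length(msg)) msg else TRUE
})

EngraftmentTable <- function(df) {
  new("EngraftmentTable", DataFrame(df))
}

#' CorrelationMatrix: cross-sample Pearson correlations with Fisher z
#'
#' @slot ids sample identifiers (possibly pooled across studies).
#' @slot r symmetric matrix of Pearson coefficients (unit diagonal);
#'   \code{NA} marks pairs involving a zero-variance profile.
#' @slot z elementwise Fisher transform atanh(r) after clamping |r| to
#'   1 - 1e-15, so z is always finite where r is defined.
#' @export
setClass("CorrelationMatrix",
  representation(ids = "character", r = "matrix", z = "matrix")
)

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  if (nrow(object@r) != length(object@ids) ||
      !identical(dim(object@r), dim(object@z)))
    msg <- c(msg, "r and z must be square over ids")
  fin <- object@r[is.finite(object@r)]
  if (length(fin) && max(abs(fin)) > 1 + 1e-12)
    msg <- c(msg, "|r| must be at most 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: hidden parameters of the host-filter cohort model
#'
#' @slot taxonPool taxon identifiers of the simulated pool.
#' @slot engraftmentProb per-taxon probability that a donor-carried taxon
#'   colonizes that donor's mouse lineage (one draw per donor-taxon).
#' @slot mouseFitness per-taxon multiplicative abundance factor applied in
#'   the mouse gut (>1 for mouse-adapted taxa).
#' @slot mu,sigma per-taxon log-normal location/scale of donor abundance
#'   (natural-log scale, arbitrary pre-normalization units).
#' @slot noiseSd replicate-mouse log-scale noise standard deviation.
#' @slot consortiumTaxa subset of the pool administered as the therapeutic
#'   consortium spike-in.
#' @slot seed integer seed recorded at construction (sidecar provenance).
#' @export
setClass("SyntheticTruth",
  representation(taxonPool = "character", engraftmentProb = "numeric",
                 mouseFitness = "numeric", mu = "numeric", sigma = "numeric",
                 noiseSd = "numeric", consortiumTaxa = "character",
                 seed = "integer")
)

setValidity("SyntheticTruth", function(object) {
  n <- length(object@taxonPool)
  msg <- character()
  if (anyDuplicated(object@taxonPool))
    msg <- c(msg, "taxonPool must be unique")
  for (s in c("engraftmentProb", "mouseFitness", "mu", "sigma"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("%s must have one value per taxon", s))
  if (any(object@engraftmentProb < 0 | object@engraftmentProb > 1))
    msg <- c(msg, "engraftmentProb must lie in [0, 1]")
  if (any(object@mouseFitness < 0))
    msg <- c(msg, "mouseFitness must be non-negative")
  if (any(object@sigma < 0)) msg <- c(msg, "sigma must be non-negative")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (!all(object@consortiumTaxa %in% object@taxonPool))
    msg <- c(msg, "every consortium taxon must be in taxonPool")
  if (length(msg)) msg else TRUE
})
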