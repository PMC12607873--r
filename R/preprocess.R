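#' Average replicate mice to avoid pseudo-replication
#'
#' Mice seeded from the same donor stool are cage-mate technical replicates,
#' not independent biological units; treating them as independent inflates
#' sample size. Each mouse \code{replicate_group} is collapsed into a single
#' profile (arithmetic mean of member columns) named by the group id; human
#' samples pass through unchanged. The result is renormalized (means of
#' 100-sum columns already sum to 100, so this is a guard, not a change).
#'
#' @param x a \linkS4class{TaxonTable} whose columns are sample ids in
#'   \code{meta}.
#' @param meta sample metadata (see \code{\link{asSampleMeta}}); every mouse
#'   sample needs a replicate_group.
#' @return a \linkS4class{TaxonTable} with one column per human sample
#'   (original order) followed by one per replicate group (order of first
#'   appearance).
#' @export
averageReplicates <- function(x, meta) {
  stopifnot(is(x, "TaxonTable"))
  meta <- asSampleMeta(meta)
  ids <- colnames(x)
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss))
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  m <- meta[ids, , drop = FALSE]
  spanning <- intersect(unique(m$replicate_group[m$host == "human"]),
                        unique(m$replicate_group[m$host == "mouse"]))
  spanning <- setdiff(spanning, c("", "none", NA))
  if (length(spanning))
    stop("replicate_group spans both host species: ",
         paste(spanning, collapse = ", "))
  ra <- raValues(x)
  humanIds <- ids[m$host == "human"]
  mouseIdx <- which(m$host == "mouse")
  if (any(!nzchar(m$replicate_group[mouseIdx])))
    stop("every mouse sample needs a replicate_group")
  groups <- unique(m$replicate_group[mouseIdx])
  cols <- cbind(
    ra[, humanIds, drop = FALSE],
    vapply(groups, function(g) {
      rowMeans(ra[, ids[mouseIdx][m$replicate_group[mouseIdx] == g],
                  drop = FALSE])
    }, numeric(nrow(ra)))
  )
  colnames(cols) <- c(humanIds, groups)
  renormalize(TaxonTable(cols, rank = x@rank))
}

#' Metadata for a replicate-averaged table
#'
#' One row per column of \code{\link{averageReplicates}} output: human rows
#' unchanged, one mouse row per replicate group (keyed by the group id).
#'
#' @param meta sample metadata of the un-averaged cohort.
#' @return a metadata DataFrame whose sample_id values match the averaged
#'   table's column names.
#' @export
collapseMeta <- function(meta) {
  meta <- asSampleMeta(meta)
  humans <- meta[meta$host == "human", , drop = FALSE]
  mice <- as.data.frame(meta[meta$host == "mouse", , drop = FALSE])
  gm <- mice[!duplicated(mice$replicate_group), , drop = FALSE]
  gm$sample_id <- gm$replicate_group
  asSampleMeta(rbind(as.data.frame(humans), gm))
}

#' Drop rare taxa by maximum relative abundance
#'
#' A taxon is retained iff its maximum percent RA across samples is at
#' least \code{minRaPercent}; the paper-standard 0.1\% cutoff removes taxa
#' that never reach 0.1\% in any one sample ("less than" is removed, so
#' exactly 0.1\% survives). No renormalization is applied: the filter feeds
#' association/correlation stages where column totals are not reused.
#'
#' @param x a \linkS4class{TaxonTable}.
#' @param minRaPercent minimum max-RA in percent (default 0.1).
#' @return the filtered \linkS4class{TaxonTable}.
#' @export
filterLowAbundance <- function(x, minRaPercent = 0.1) {
  stopifnot(is(x, "TaxonTable"), minRaPercent >= 0)
  keep <- apply(raValues(x), 1L, max) >= minRaPercent
  out <- TaxonTable(raValues(x)[keep, , drop = FALSE], rank = x@rank,
                    renormalized = x@renormalized)
  metadata(out) <- metadata(x)
  out
}

#' Display transform: log10 percent RA with a floor for zeros
#'
#' Zeros have no logarithm; for display they are conventionally pinned to a
#' floor below the detection limit (default -3, i.e. 0.001\%).
#'
#' @param x a \linkS4class{TaxonTable} or non-negative numeric matrix/vector.
#' @param floor value assigned to zeros (default -3).
#' @return matrix (or vector) of log10 percent RA.
#' @export
logDisplay <- function(x, floor = -3) {
  v <- if (is(x, "TaxonTable")) raValues(x) else x
  if (any(v < 0)) stop("negative relative abundances are invalid")
  pos <- v > 0
  if (any(pos) && floor >= min(log10(v[pos])))
    warning("floor is not below the smallest positive log10 abundance")
  out <- v
  out[pos] <- log10(v[pos])
  out[!pos] <- floor
  out
}
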