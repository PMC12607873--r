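#' Presence/absence matrix from relative abundances
#'
#' A taxon is called present in a sample iff its RA strictly exceeds the
#' detection threshold (default 0: any positive abundance counts, matching
#' a profiler whose reported values are already detection-filtered).
#'
#' @param x a \linkS4class{TaxonTable}.
#' @param detectionThresholdPercent non-negative threshold in percent RA.
#' @return logical taxa x samples matrix.
#' @export
presenceMatrix <- function(x, detectionThresholdPercent = 0) {
  stopifnot(is(x, "TaxonTable"), detectionThresholdPercent >= 0)
  raValues(x) > detectionThresholdPercent
}

#' Per-taxon percent engraftment across donor-recipient pairs
#'
#' For each taxon: the denominator is the number of distinct human donors
#' carrying the taxon (among donors in the pairing); the numerator is the
#' number of those donors whose paired recipient group also carries it,
#' where a recipient group is positive if any member mouse is (replicate
#' mice share one colonization event). Percent engraftment =
#' 100 * engrafted / carrying. Taxa absent from every donor are excluded
#' (undefined denominator).
#'
#' @param presence logical taxa x samples matrix covering all pairing ids.
#' @param pairing a \linkS4class{PairingMap} (non-empty).
#' @param studyId study label recorded in the output (default
#'   \code{"study1"}).
#' @return an \linkS4class{EngraftmentTable}, strata \code{"unassigned"}
#'   until \code{\link{stratifyEngrafters}}.
#' @export
percentEngraftment <- function(presence, pairing, studyId = "study1") {
  if (!is(pairing, "PairingMap") || nPairs(pairing) == 0L)
    stop("a non-empty PairingMap is required")
  need <- unique(c(pairDonors(pairing), unlist(groupMembers(pairing))))
  miss <- setdiff(need, colnames(presence))
  if (length(miss))
    stop("pairing ids absent from presence matrix: ",
         paste(miss, collapse = ", "))
  donors <- unique(pairDonors(pairing))
  donorHas <- presence[, donors, drop = FALSE]
  # group presence: OR over member mice
  grpHas <- vapply(pairGroups(pairing), function(g) {
    rowSums(presence[, groupMembers(pairing)[[g]], drop = FALSE]) > 0
  }, logical(nrow(presence)))
  grpHas <- matrix(grpHas, nrow = nrow(presence),
                   dimnames = list(rownames(presence), pairGroups(pairing)))
  # per donor: engrafted if any of its paired groups shares the taxon
  donorEngrafted <- vapply(donors, function(dn) {
    gs <- pairGroups(pairing)[pairDonors(pairing) == dn]
    presence[, dn] & (rowSums(grpHas[, gs, drop = FALSE]) > 0)
  }, logical(nrow(presence)))
  donorEngrafted <- matrix(donorEngrafted, nrow = nrow(presence),
                           dimnames = list(rownames(presence), donors))
  nDon <- rowSums(donorHas)
  nEng <- rowSums(donorEngrafted)
  keep <- nDon > 0
  EngraftmentTable(data.frame(
    taxon = rownames(presence)[keep], study_id = studyId,
    n_donors_with_taxon = as.integer(nDon[keep]),
    n_pairs_engrafted = as.integer(nEng[keep]),
    percent_engraftment = 100 * nEng[keep] / nDon[keep],
    stratum = "unassigned", row.names = NULL))
}

#' Keep taxa engrafting in a minimum number of pairs
#'
#' Mirrors the ">4 mice" inclusion rule for engraftment displays: the
#' default \code{minPairs = 5} removes taxa with 4 or fewer engrafted
#' pairs and keeps exactly 5.
#'
#' @param x an \linkS4class{EngraftmentTable}.
#' @param minPairs minimum \code{n_pairs_engrafted} (default 5).
#' @return the filtered table.
#' @export
filterEngrafters <- function(x, minPairs = 5L) {
  stopifnot(is(x, "EngraftmentTable"))
  x[x$n_pairs_engrafted >= minPairs, , drop = FALSE]
}

#' Stratify taxa by mean percent engraftment across studies
#'
#' Per taxon, averages percent engraftment over the studies where it has a
#' defined value, then labels: high if mean > 80, medium if 60 <= mean <=
#' 80, low if mean < 60 (the only boundary convention that partitions
#' [0, 100] given exclusive ">80" and "<60" definitions). Taxa defined in
#' no study get \code{"unassigned"}.
#'
#' @param tables list of per-study \linkS4class{EngraftmentTable}s.
#' @return a combined \linkS4class{EngraftmentTable} (study_id
#'   \code{"mean"}) with pooled counts, mean percent engraftment and strata.
#' @export
stratifyEngrafters <- function(tables) {
  if (is(tables, "EngraftmentTable")) tables <- list(tables)
  if (!length(tables)) stop("at least one study table is required")
  dfs <- lapply(tables, as.data.frame)
  all_ <- do.call(rbind, dfs)
  taxa_ <- unique(all_$taxon)
  agg <- do.call(rbind, lapply(taxa_, function(tx) {
    rows <- all_[all_$taxon == tx & !is.na(all_$percent_engraftment), ,
                 drop = FALSE]
    data.frame(taxon = tx, study_id = "mean",
               n_donors_with_taxon = sum(rows$n_donors_with_taxon),
               n_pairs_engrafted = sum(rows$n_pairs_engrafted),
               percent_engraftment = if (nrow(rows))
                 mean(rows$percent_engraftment) else NA_real_)
  }))
  agg$stratum <- engraftmentStratum(agg$percent_engraftment)
  EngraftmentTable(agg)
}

#' @rdname stratifyEngrafters
#' @param meanPercent numeric mean percent engraftment values.
#' @return for \code{engraftmentStratum}: character strata labels.
#' @export
engraftmentStratum <- function(meanPercent) {
  ifelse(is.na(meanPercent), "unassigned",
         ifelse(meanPercent > 80, "high",
                ifelse(meanPercent < 60, "low", "medium")))
}

#' Per-donor fraction of donor taxa recovered in the paired recipients
#'
#' For every donor-recipient pair: 100 * |donor taxa also present in the
#' recipient group| / |donor taxa| - the per-donor engraftment breadth.
#'
#' @inheritParams percentEngraftment
#' @return data.frame with columns donor, group, n_donor_taxa, n_shared,
#'   percent.
#' @export
donorEngraftmentFraction <- function(presence, pairing) {
  if (!is(pairing, "PairingMap") || nPairs(pairing) == 0L)
    stop("a non-empty PairingMap is required")
  res <- lapply(seq_len(nPairs(pairing)), function(k) {
    dn <- pairDonors(pairing)[k]; gp <- pairGroups(pairing)[k]
    dHas <- presence[, dn]
    if (!any(dHas)) stop("donor sample with zero taxa present: ", dn)
    gHas <- rowSums(presence[, groupMembers(pairing)[[gp]],
                             drop = FALSE]) > 0
    data.frame(donor = dn, group = gp,
               n_donor_taxa = sum(dHas), n_shared = sum(dHas & gHas),
               percent = 100 * sum(dHas & gHas) / sum(dHas))
  })
  do.call(rbind, res)
}

#' Correlation between percent engraftment and mean recipient abundance
#'
#' Pearson correlation (with t-distribution p-value) between each taxon's
#' percent engraftment and its mean percent RA across recipient mouse
#' samples, paired by taxon identifier.
#'
#' @param x an \linkS4class{EngraftmentTable}.
#' @param mouseTable a \linkS4class{TaxonTable} of recipient mouse samples.
#' @return list with \code{r}, \code{p} and \code{n} (shared taxa).
#' @export
engraftmentAbundanceCorrelation <- function(x, mouseTable) {
  stopifnot(is(x, "EngraftmentTable"), is(mouseTable, "TaxonTable"))
  meanRa <- rowMeans(raValues(mouseTable))
  shared <- intersect(x$taxon, names(meanRa))
  if (length(shared) < 3L)
    stop("need >= 3 taxa shared between engraftment table and mouse table")
  pe <- setNames(x$percent_engraftment, x$taxon)[shared]
  ct <- stats::cor.test(pe, meanRa[shared], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
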