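#' Construct the hidden truth of a synthetic cohort
#'
#' @param taxonPool taxon identifiers.
#' @param engraftmentProb,mouseFitness,mu,sigma per-taxon parameters (see
#'   \linkS4class{SyntheticTruth}).
#' @param noiseSd replicate-mouse log-scale noise sd.
#' @param consortiumTaxa consortium subset of the pool.
#' @param seed integer provenance seed recorded in the object.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
SyntheticTruth <- function(taxonPool, engraftmentProb, mouseFitness, mu,
                           sigma, noiseSd = 0.3,
                           consortiumTaxa = character(), seed = NA_integer_) {
  new("SyntheticTruth", taxonPool = as.character(taxonPool),
      engraftmentProb = as.numeric(engraftmentProb),
      mouseFitness = as.numeric(mouseFitness), mu = as.numeric(mu),
      sigma = as.numeric(sigma), noiseSd = as.numeric(noiseSd),
      consortiumTaxa = as.character(consortiumTaxa),
      seed = as.integer(seed))
}

#' Default host-filter truth emulating an HMA mouse study
#'
#' A 120-taxon pool in which 20 "core" mouse-adapted taxa (think
#' Bacteroides, Parabacteroides, Akkermansia and kin) are abundant in every
#' donor (high mu), engraft with probability 0.95 and enjoy a fitness
#' advantage in the mouse gut, while the remaining 100 variable taxa are
#' patchily distributed across donors and engraft with probability 0.03 -
#' a strong, shared host filter. The 30-member consortium mixes 10 core
#' (high-engrafting) and 20 variable (low-engrafting) taxa, mirroring a
#' cultured therapeutic consortium whose members span the engraftment
#' spectrum.
#'
#' @param nTaxa pool size (default 120).
#' @param nShared number of core host-filtered taxa (default 20).
#' @param nConsortium consortium size (default 30).
#' @param seed RNG seed for the per-taxon parameter draws.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
defaultTruth <- function(nTaxa = 120L, nShared = 20L, nConsortium = 30L,
                         seed = 1L) {
  stopifnot(nShared < nTaxa, nConsortium <= nTaxa)
  withSeed(seed, {
    pool <- sprintf("taxon_%03d", seq_len(nTaxa))
    core <- seq_len(nShared)
    nVar <- nTaxa - nShared
    # Core taxa: abundant everywhere with low donor-to-donor scatter (the
    # convergent, mouse-adapted block); variable taxa: a flat expected
    # profile with heavy per-donor realization noise, i.e. donor-specific
    # dominants that never engraft.
    mu <- c(stats::rnorm(nShared, mean = 2.3, sd = 0.7),
            stats::rnorm(nVar, mean = -0.3, sd = 0.15))
    sigma <- c(stats::runif(nShared, 0.25, 0.5),
               stats::runif(nVar, 1.5, 2.2))
    prob <- c(rep(0.95, nShared), rep(0.03, nVar))
    fitness <- c(exp(stats::rnorm(nShared, log(2), 0.1)),
                 rep(0.6, nVar))
    nCons1 <- min(10L, nShared, nConsortium)
    cons <- c(pool[core][seq_len(nCons1)],
              pool[-core][seq_len(nConsortium - nCons1)])
    SyntheticTruth(pool, prob, fitness, mu, sigma, noiseSd = 0.3,
                   consortiumTaxa = cons, seed = seed)
  })
}

# Abundance-occupancy rule: donor carriage probability derived from the
# taxon's log-abundance location, saturating at 1 for the abundant core.
prevalenceFromMu <- function(mu) {
  pmin(1, stats::plogis(mu) * 1.15)
}

#' Simulate a panel of human donor communities
#'
#' Per donor and taxon: carriage is Bernoulli with probability derived from
#' the taxon's abundance location mu (abundance-occupancy rule, saturating
#' for the core taxa); carried abundance is log-normal exp(N(mu, sigma));
#' columns renormalized to 100.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nDonors number of donors (>= 1).
#' @param seed RNG seed.
#' @param timepoint metadata timepoint for the donor samples.
#' @param studyId metadata study label.
#' @param donorPrefix prefix for donor identifiers.
#' @return list with \code{table} (\linkS4class{TaxonTable}, renormalized)
#'   and \code{meta} (metadata DataFrame).
#' @export
generateDonorPanel <- function(truth, nDonors, seed, timepoint = "T0",
                               studyId = "synthetic", donorPrefix = "d") {
  stopifnot(is(truth, "SyntheticTruth"), nDonors >= 1)
  prev <- prevalenceFromMu(truth@mu)
  if (all(prev <= 0)) stop("degenerate truth: all prevalences are zero")
  nT <- length(truth@taxonPool)
  donorIds <- sprintf("%s%02d", donorPrefix, seq_len(nDonors))
  sampleIds <- paste0(donorIds, "_", timepoint)
  ra <- withSeed(seed, {
    occ <- matrix(stats::rbinom(nT * nDonors, 1L, rep(prev, nDonors)),
                  nrow = nT)
    ab <- matrix(exp(stats::rnorm(nT * nDonors, mean = rep(truth@mu, nDonors),
                                  sd = rep(truth@sigma, nDonors))), nrow = nT)
    occ * ab
  })
  dimnames(ra) <- list(truth@taxonPool, sampleIds)
  if (any(colSums(ra) <= 0))
    stop("degenerate truth: a donor has no carried taxa")
  tbl <- renormalize(TaxonTable(ra, rank = "genus"))
  meta <- asSampleMeta(data.frame(
    sample_id = sampleIds, host = "human", donor_id = donorIds,
    timepoint = timepoint, study_id = studyId, route = "none",
    replicate_group = "none"))
  list(table = tbl, meta = meta)
}

#' Pass donor communities through the host filter into replicate mice
#'
#' Engraftment is modelled as a colonization event at the lineage level:
#' for every donor-taxon with positive donor abundance, one Bernoulli draw
#' with the taxon's engraftment probability decides whether it establishes
#' in that donor's mouse lineage; all replicate mice of the lineage share
#' the draw (cage mates seeded from one stool are technical replicates).
#' Engrafted abundance per mouse is donor RA x mouse fitness x
#' exp(N(0, noiseSd)), then renormalized.
#'
#' @param donors donor panel: a \linkS4class{TaxonTable} (or the list
#'   returned by \code{\link{generateDonorPanel}}).
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nMicePerDonor replicate mice per donor (>= 1).
#' @param seed RNG seed.
#' @param timepoint metadata timepoint for the mouse samples.
#' @param route exposure route recorded for the mice (HTR/MTR/none).
#' @param donorMeta metadata of the donor samples (for donor_id lookup);
#'   defaults to parsing ids as \code{<donor>_<timepoint>}.
#' @param studyId metadata study label.
#' @return list with \code{table}, \code{meta}, \code{pairing}
#'   (\linkS4class{PairingMap}) and \code{engrafted} (logical taxa x donors
#'   matrix of the hidden colonization draws).
#' @export
applyHostFilter <- function(donors, truth, nMicePerDonor, seed,
                            timepoint = "T0", route = "HTR",
                            donorMeta = NULL, studyId = "synthetic") {
  if (is.list(donors) && !is(donors, "TaxonTable")) {
    donorMeta <- donors$meta
    donors <- donors$table
  }
  stopifnot(is(donors, "TaxonTable"), is(truth, "SyntheticTruth"),
            nMicePerDonor >= 1)
  if (!all(rownames(donors) %in% truth@taxonPool))
    stop("donor table contains taxa outside the truth pool")
  ra <- raValues(donors)
  nT <- nrow(ra)
  prob <- setNames(truth@engraftmentProb, truth@taxonPool)[rownames(ra)]
  fit <- setNames(truth@mouseFitness, truth@taxonPool)[rownames(ra)]
  donorSamples <- colnames(ra)
  donorIds <- if (!is.null(donorMeta))
    setNames(asSampleMeta(donorMeta)$donor_id,
             asSampleMeta(donorMeta)$sample_id)[donorSamples]
  else sub("_[^_]*$", "", donorSamples)
  res <- withSeed(seed, {
    engrafted <- matrix(FALSE, nT, length(donorSamples),
                        dimnames = list(rownames(ra), donorSamples))
    mouseCols <- list()
    for (j in seq_along(donorSamples)) {
      carried <- ra[, j] > 0
      engrafted[carried, j] <-
        stats::rbinom(sum(carried), 1L, prob[carried]) == 1L
      base <- ra[, j] * fit * engrafted[, j]
      for (k in seq_len(nMicePerDonor)) {
        noise <- exp(stats::rnorm(nT, 0, truth@noiseSd))
        mouseCols[[paste0(donorSamples[j], "_", route, "_m", k)]] <-
          base * noise
      }
    }
    list(engrafted = engrafted, cols = mouseCols)
  })
  mra <- do.call(cbind, res$cols)
  rownames(mra) <- rownames(ra)
  if (any(colSums(mra) <= 0))
    stop("a simulated mouse engrafted no taxa; raise engraftment ",
         "probabilities or donor richness")
  tbl <- renormalize(TaxonTable(mra, rank = taxonRank(donors)))
  groupIds <- paste0(donorSamples, "_", route, "_mice")
  mouseMeta <- data.frame(
    sample_id = colnames(mra), host = "mouse",
    donor_id = rep(donorIds, each = nMicePerDonor),
    timepoint = timepoint, study_id = studyId, route = route,
    replicate_group = rep(groupIds, each = nMicePerDonor))
  members <- split(mouseMeta$sample_id, mouseMeta$replicate_group)
  pairing <- new("PairingMap", donor = donorSamples, group = groupIds,
                 members = members[groupIds])
  list(table = tbl, meta = asSampleMeta(mouseMeta), pairing = pairing,
       engrafted = res$engrafted)
}

#' Spike a therapeutic consortium into community profiles
#'
#' Non-consortium abundance is scaled down to (100 - dose)% and the dose is
#' distributed over the consortium members in fixed equal proportions, so a
#' community initially free of consortium taxa carries exactly
#' \code{dosePercent}\% consortium after the spike. Columns stay at 100.
#'
#' @param x a renormalized \linkS4class{TaxonTable} containing the
#'   consortium taxa among its rows.
#' @param truth a \linkS4class{SyntheticTruth} with a non-empty consortium.
#' @param dosePercent consortium dose in percent of the final community,
#'   in [0, 100); 0 is the identity.
#' @return the spiked \linkS4class{TaxonTable}.
#' @export
spikeConsortium <- function(x, truth, dosePercent) {
  stopifnot(is(x, "TaxonTable"), is(truth, "SyntheticTruth"))
  if (!length(truth@consortiumTaxa)) stop("empty consortium")
  if (dosePercent < 0 || dosePercent >= 100)
    stop("dosePercent must lie in [0, 100)")
  if (dosePercent == 0) return(x)
  cons <- truth@consortiumTaxa
  miss <- setdiff(cons, rownames(x))
  if (length(miss))
    stop("consortium taxa absent from table rows: ",
         paste(miss, collapse = ", "))
  ra <- raValues(x)
  cs <- colSums(ra)
  out <- sweep(ra, 2L, (100 - dosePercent) / cs, "*")
  out[cons, ] <- out[cons, ] + dosePercent / length(cons)
  renormalize(TaxonTable(out, rank = taxonRank(x)))
}

#' Generate a full synthetic donor/recipient cohort
#'
#' Two designs mirroring the routes of consortium exposure:
#' \describe{
#'   \item{HTR (human-treated route)}{donors sampled at T0 and at T2 (the
#'     T0 community drifted by mild log-normal noise, then spiked with the
#'     consortium); separate mouse lineages are seeded from each
#'     timepoint's donor stool.}
#'   \item{MTR (mouse-treated route)}{mice are seeded from T0 donor stool;
#'     at T2 the consortium is administered to the mice directly, with each
#'     newly introduced consortium taxon subject to its engraftment
#'     probability (one draw per lineage-taxon; taxa already resident
#'     simply receive the spike).}
#' }
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nDonors number of human donors.
#' @param nMice replicate mice per donor lineage.
#' @param design \code{"HTR"} or \code{"MTR"}.
#' @param seed RNG seed driving every draw.
#' @param dosePercent consortium dose (default 20).
#' @param driftSd donor T0-to-T2 log-scale drift sd (HTR; default 0.2).
#' @param studyId metadata study label.
#' @return list with \code{table} (combined humans + mice), \code{meta},
#'   \code{pairing}, \code{truth} and \code{engrafted} draws per lineage.
#' @export
generateCohort <- function(truth, nDonors = 6L, nMice = 3L,
                           design = c("HTR", "MTR"), seed,
                           dosePercent = 20, driftSd = 0.2,
                           studyId = "synthetic") {
  design <- match.arg(design)
  stopifnot(is(truth, "SyntheticTruth"))
  if (missing(seed)) stop("seed is mandatory")
  seeds <- withSeed(seed, sample.int(2^31 - 2L, 4L))
  t0 <- generateDonorPanel(truth, nDonors, seed = seeds[1L],
                           timepoint = "T0", studyId = studyId)
  mice0 <- applyHostFilter(t0, truth, nMice, seed = seeds[2L],
                           timepoint = "T0",
                           route = if (design == "HTR") "HTR" else "MTR",
                           studyId = studyId)
  if (design == "HTR") {
    drifted <- withSeed(seeds[3L], {
      ra <- raValues(t0$table)
      ra * exp(matrix(stats::rnorm(length(ra), 0, driftSd), nrow(ra)))
    })
    t2tab <- spikeConsortium(
      renormalize(TaxonTable(drifted, rank = taxonRank(t0$table))),
      truth, dosePercent)
    colnames(t2tab) <- sub("_T0$", "_T2", colnames(t2tab))
    t2meta <- as.data.frame(t0$meta)
    t2meta$sample_id <- colnames(t2tab)
    t2meta$timepoint <- "T2"
    t2 <- list(table = t2tab, meta = asSampleMeta(t2meta))
    mice2 <- applyHostFilter(t2, truth, nMice, seed = seeds[4L],
                             timepoint = "T2", route = "HTR",
                             studyId = studyId)
    humanTabs <- list(t0$table, t2$table)
    humanMeta <- rbind(as.data.frame(t0$meta), as.data.frame(t2$meta))
    mouseTabs <- list(mice0$table, mice2$table)
    mouseMeta <- rbind(as.data.frame(mice0$meta), as.data.frame(mice2$meta))
    pairing <- new("PairingMap",
                   donor = c(pairDonors(mice0$pairing),
                             pairDonors(mice2$pairing)),
                   group = c(pairGroups(mice0$pairing),
                             pairGroups(mice2$pairing)),
                   members = c(groupMembers(mice0$pairing),
                               groupMembers(mice2$pairing)))
    engrafted <- list(T0 = mice0$engrafted, T2 = mice2$engrafted)
  } else {
    mice2 <- directSpike(mice0, truth, dosePercent, seed = seeds[4L],
                         studyId = studyId)
    humanTabs <- list(t0$table)
    humanMeta <- as.data.frame(t0$meta)
    mouseTabs <- list(mice0$table, mice2$table)
    mouseMeta <- rbind(as.data.frame(mice0$meta), as.data.frame(mice2$meta))
    pairing <- mice0$pairing
    engrafted <- list(T0 = mice0$engrafted, T2_spike = mice2$engrafted)
  }
  allTabs <- c(humanTabs, mouseTabs)
  combined <- do.call(cbind, lapply(allTabs, raValues))
  tbl <- renormalize(TaxonTable(combined, rank = taxonRank(t0$table)))
  meta <- asSampleMeta(rbind(humanMeta, mouseMeta))
  list(table = tbl, meta = meta, pairing = pairing, truth = truth,
       engrafted = engrafted)
}

# MTR T2: spike the consortium directly into each mouse lineage, gating
# newly introduced taxa by their engraftment probability.
directSpike <- function(mice0, truth, dosePercent, seed, studyId) {
  ra <- raValues(mice0$table)
  cons <- truth@consortiumTaxa
  prob <- setNames(truth@engraftmentProb, truth@taxonPool)
  groups <- pairGroups(mice0$pairing)
  members <- groupMembers(mice0$pairing)
  out <- withSeed(seed, {
    cols <- list()
    for (g in groups) {
      pres <- rowSums(ra[, members[[g]], drop = FALSE]) > 0
      admitted <- pres[cons] |
        (stats::rbinom(length(cons), 1L, prob[cons]) == 1L)
      addShare <- ifelse(admitted, dosePercent / length(cons), 0)
      for (ms in members[[g]]) {
        v <- ra[, ms] * (100 - dosePercent) / 100
        v[cons] <- v[cons] + addShare
        cols[[sub("_m([0-9]+)$", "_T2_m\\1", ms)]] <- v
      }
    }
    cols
  })
  mra <- do.call(cbind, out)
  rownames(mra) <- rownames(ra)
  tbl <- renormalize(TaxonTable(mra, rank = taxonRank(mice0$table)))
  m0 <- as.data.frame(mice0$meta)
  m2 <- m0
  m2$sample_id <- sub("_m([0-9]+)$", "_T2_m\\1", m0$sample_id)
  m2$timepoint <- "T2"
  m2$replicate_group <- paste0(m0$replicate_group, "_T2")
  list(table = tbl, meta = asSampleMeta(m2), engrafted = NULL)
}

#' Write / read the truth sidecar
#'
#' The sidecar is a per-taxon TSV (taxon, engraftment_prob, mouse_fitness,
#' mu, sigma, is_consortium) plus a JSON manifest (seed, noise sd, counts)
#' so simulated cohorts stay auditable and recovery tests can read back the
#' hidden parameters.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param dir output directory (created if missing).
#' @return invisible character vector of the two file paths.
#' @export
writeTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "truth.tsv")
  js <- file.path(dir, "truth_manifest.json")
  writeTsv(data.frame(
    taxon = truth@taxonPool, engraftment_prob = truth@engraftmentProb,
    mouse_fitness = truth@mouseFitness, mu = truth@mu, sigma = truth@sigma,
    is_consortium = truth@taxonPool %in% truth@consortiumTaxa), tsv)
  jsonlite::write_json(list(seed = truth@seed, noise_sd = truth@noiseSd,
                            n_taxa = length(truth@taxonPool),
                            n_consortium = length(truth@consortiumTaxa)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' @rdname writeTruth
#' @export
readTruth <- function(dir) {
  df <- readTsv(file.path(dir, "truth.tsv"))
  man <- jsonlite::read_json(file.path(dir, "truth_manifest.json"),
                             simplifyVector = TRUE)
  SyntheticTruth(df$taxon, as.numeric(df$engraftment_prob),
                 as.numeric(df$mouse_fitness), as.numeric(df$mu),
                 as.numeric(df$sigma), noiseSd = man$noise_sd,
                 consortiumTaxa = df$taxon[df$is_consortium == "TRUE"],
                 seed = man$seed)
}
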