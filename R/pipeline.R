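#' Run the full fidelity analysis pipeline on a simulated cohort
#'
#' Orchestrates simulate -> preprocess -> beta diversity -> engraftment ->
#' concordance into one reproducible run. Each stage's TSV outputs are
#' written before the next stage starts; every statistic lands in a single
#' \code{summary.json}; stage progress goes to a run log. Identical config
#' plus seed yields a byte-identical summary.
#'
#' @param config a named list or path to a YAML file. Required fields:
#'   \code{seed} (integer), \code{n_donors}, \code{n_mice}, \code{design}
#'   ("HTR"/"MTR"), \code{permutations} (>= 0). Optional: \code{dose_percent}
#'   (default 20), \code{min_ra_percent} (0.1), \code{min_pairs} (5),
#'   \code{detection_threshold} (0), \code{replicate_averaging} (TRUE).
#' @param outdir output directory (created; stage files, truth sidecar,
#'   \code{summary.json}, \code{run.log}).
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config, outdir) {
  cfg <- validateConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outdir, "run.log")
  cat(sprintf("[%s] pipeline start (seed %d, design %s)\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), cfg$seed,
              cfg$design), file = logFile)
  logStage <- function(stage, t0) {
    line <- sprintf("[%s] stage %-12s done (%.2fs)\n",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                    as.numeric(Sys.time()) - t0)
    cat(line, file = logFile, append = TRUE)
    message(trimws(line))
  }

  # -- simulate ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  truth <- defaultTruth(seed = cfg$seed)
  cohort <- generateCohort(truth, nDonors = cfg$n_donors,
                           nMice = cfg$n_mice, design = cfg$design,
                           seed = cfg$seed, dosePercent = cfg$dose_percent)
  writeTaxonTable(cohort$table, file.path(outdir, "cohort_table.tsv"))
  writeSampleMeta(cohort$meta, file.path(outdir, "cohort_meta.tsv"))
  writeTruth(truth, outdir)
  logStage("simulate", t0)

  # -- preprocess -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (cfg$replicate_averaging) {
    avg <- averageReplicates(cohort$table, cohort$meta)
    avgMeta <- collapseMeta(cohort$meta)
  } else {
    avg <- renormalize(cohort$table)
    avgMeta <- cohort$meta
  }
  filtered <- filterLowAbundance(avg, cfg$min_ra_percent)
  writeTaxonTable(avg, file.path(outdir, "averaged_table.tsv"))
  writeTaxonTable(filtered, file.path(outdir, "filtered_table.tsv"))
  logStage("preprocess", t0)

  # -- beta diversity ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  d <- brayCurtis(avg)
  writeDistMatrix(d, file.path(outdir, "bray_curtis.tsv"))
  hosts <- setNames(avgMeta$host, avgMeta$sample_id)[rownames(d)]
  pmv <- permanova(d, hosts, nPerm = cfg$permutations, seed = cfg$seed)
  pds <- permdisp(d, hosts, nPerm = cfg$permutations, seed = cfg$seed)
  ord <- pcoa(d, k = 2L)
  writeTsv(data.frame(id = rownames(d), ordCoordinates(ord),
                      check.names = FALSE),
           file.path(outdir, "pcoa_coordinates.tsv"))
  gd <- extractGroupDissimilarities(d, avgMeta, cohort$pairing)
  gdUse <- gd[lengths(gd) >= 2L]
  gdTest <- if (length(gdUse) >= 2L)
    compareGroups(gdUse, method = "kruskal_dunn") else NULL
  writeTsv(data.frame(
    category = rep(names(gd), lengths(gd)),
    dissimilarity = unlist(gd, use.names = FALSE)),
    file.path(outdir, "grouped_dissimilarities.tsv"))
  logStage("beta_diversity", t0)

  # -- engraftment ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  pres <- presenceMatrix(cohort$table, cfg$detection_threshold)
  eng <- percentEngraftment(pres, cohort$pairing, studyId = cfg$design)
  engFlt <- filterEngrafters(eng, cfg$min_pairs)
  strat <- stratifyEngrafters(list(eng))
  donorFrac <- donorEngraftmentFraction(pres, cohort$pairing)
  mouseIds <- cohort$meta$sample_id[cohort$meta$host == "mouse"]
  mouseTab <- TaxonTable(raValues(cohort$table)[, mouseIds, drop = FALSE],
                         rank = taxonRank(cohort$table))
  engCor <- engraftmentAbundanceCorrelation(eng, mouseTab)
  writeTsv(as.data.frame(strat), file.path(outdir, "engraftment.tsv"))
  writeTsv(donorFrac, file.path(outdir, "donor_engraftment_fraction.tsv"))
  logStage("engraftment", t0)

  # -- concordance ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  corr <- sampleCorrelationMatrix(avg)
  corSum <- groupCorrelationSummary(corr, avgMeta)
  writeTsv(corSum$summary, file.path(outdir, "correlation_summary.tsv"))
  conc <- NULL
  if (cfg$design == "HTR") {
    dDel <- deltaRA(cohort$table, cohort$meta, host = "human")
    rDel <- deltaRA(cohort$table, cohort$meta, host = "mouse")
    ov <- overlapTaxa(cohort$table, cohort$meta)
    conc <- deltaConcordance(dDel, rDel, overlapTaxa = ov)
    writeTsv(data.frame(taxon = conc$taxa, donor_delta = conc$donor_delta,
                        recipient_delta = conc$recipient_delta),
             file.path(outdir, "delta_ra.tsv"))
  }
  logStage("concordance", t0)

  # -- summary ----------------------------------------------------------
  strataCounts <- table(factor(strat$stratum,
                               levels = c("high", "medium", "low",
                                          "unassigned")))
  summary_ <- list(
    config = cfg,
    permanova = list(F = testStatistic(pmv), R2 = testRSquared(pmv),
                     p = testPValue(pmv)),
    permdisp = list(F = testStatistic(pds), p = testPValue(pds)),
    grouped_dissimilarity_means = lapply(gd, function(v)
      if (length(v)) mean(v) else NULL),
    kruskal_dunn = if (!is.null(gdTest))
      list(H = gdTest$statistic, p = gdTest$p_value) else NULL,
    engraftment = list(
      n_taxa = nrow(eng), n_taxa_min_pairs = nrow(engFlt),
      strata_counts = as.list(strataCounts),
      donor_fraction_min = min(donorFrac$percent),
      donor_fraction_max = max(donorFrac$percent),
      abundance_correlation_r = engCor$r),
    correlation_means = as.list(corSum$category_means),
    correlation_means_z = as.list(corSum$category_means_z),
    delta_concordance = if (!is.null(conc))
      list(r = conc$pearson_r, p = conc$p_value,
           quadrants = as.list(conc$quadrant_fractions)) else NULL
  )
  jsonlite::write_json(summary_, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary_)
}

# Validate and default-fill the pipeline configuration before any
# computation happens; schema violations fail fast.
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path")
  required <- c("seed", "n_donors", "n_mice", "design", "permutations")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("config missing required field(s): ", paste(miss, collapse = ", "))
  defaults <- list(dose_percent = 20, min_ra_percent = 0.1, min_pairs = 5L,
                   detection_threshold = 0, replicate_averaging = TRUE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  num1 <- function(nm) {
    v <- config[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("config field '", nm, "' must be a single finite number")
    v
  }
  cfg <- list(
    seed = as.integer(num1("seed")),
    n_donors = as.integer(num1("n_donors")),
    n_mice = as.integer(num1("n_mice")),
    design = match.arg(config$design, c("HTR", "MTR")),
    permutations = as.integer(num1("permutations")),
    dose_percent = num1("dose_percent"),
    min_ra_percent = num1("min_ra_percent"),
    min_pairs = as.integer(num1("min_pairs")),
    detection_threshold = num1("detection_threshold"),
    replicate_averaging = isTRUE(config$replicate_averaging))
  if (cfg$permutations < 0) stop("permutations must be >= 0")
  if (cfg$n_donors < 2 || cfg$n_mice < 1)
    stop("need n_donors >= 2 and n_mice >= 1")
  if (cfg$min_ra_percent < 0 || cfg$detection_threshold < 0)
    stop("abundance thresholds must be non-negative")
  cfg
}
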