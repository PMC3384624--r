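#' Default run configuration
#'
#' The configuration consumed by [runPipeline()] and the command-line
#' interface; a plain named list that round-trips losslessly through YAML.
#'
#' @param ... overrides of individual entries.
#' @return named list: `n_subjects`, `panel`, `seed`, `exposure`,
#'   `covariates`, `transform`, `alpha`, `threshold_method`,
#'   `fixed_threshold`, `p_gain_cutoff` (`NULL` = number of metabolites after
#'   QC), `r_cutoff`, `ggm_alpha`, `strata`, `cv_threshold`,
#'   `miss_threshold`, `outlier_k`, `r_dependence`, `max_independent`,
#'   `merge_lipids`, `network_format`.
#' @export
runConfig <- function(...) {
  cfg <- list(n_subjects = 965L, panel = "p180", seed = 1L,
              exposure = "ffmi", covariates = c("age", "sex", "batch"),
              transform = "lognormal_z", alpha = 0.05,
              threshold_method = "effective", fixed_threshold = NULL,
              p_gain_cutoff = NULL, r_cutoff = 0.3, ggm_alpha = 0.01,
              strata = "bmi30", cv_threshold = 0.25, miss_threshold = 0.05,
              outlier_k = 5, r_dependence = 0.70, max_independent = 3,
              merge_lipids = FALSE, network_format = "graphml")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) cfg[nm] <- dots[nm]   # keeps NULL entries
  cfg
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @return for `readRunConfig`, the configuration list (unknown keys are an
#'   error).
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @param cfg configuration list from [runConfig()].
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulation (or user data), quality control, metabolome-wide association,
#' intra-class ratios with p-gain, and the partial-correlation network, with
#' all result tables and the network written to an output directory.  Two
#' runs with identical configuration and seed produce byte-identical result
#' files (numeric formatting fixed at 6 significant digits).
#'
#' @param cfg configuration from [runConfig()].
#' @param out output directory (created if needed).
#' @param cohort optional [MetaboCohort-class]; if NULL a cohort is
#'   simulated from the configuration.
#' @return invisibly, a list with the QC'd cohort and all result objects.
#' @export
runPipeline <- function(cfg = runConfig(), out, cohort = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out, "run.log")
  cfgHash <- fnv1aHash(paste(deparse(cfg), collapse = ""))
  logLines(log, c(paste("metabnet", as.character(utils::packageVersion("metabnet")),
                        "on R", paste(R.version$major, R.version$minor, sep = ".")),
                  paste("seed:", cfg$seed), paste("config hash:", cfgHash)))
  if (is.null(cohort)) {
    cohort <- simulateCohort(simConfig(nSubjects = cfg$n_subjects,
                                       panel = panelPreset(cfg$panel),
                                       seed = cfg$seed))
    logLines(log, "simulated cohort")
  }
  writeConcentrations(cohort, file.path(out, "concentrations.tsv"))
  writePheno(cohort, file.path(out, "phenotypes.tsv"))

  qcd <- runQC(cohort, cv_threshold = cfg$cv_threshold,
               miss_threshold = cfg$miss_threshold, k = cfg$outlier_k,
               r_threshold = cfg$r_dependence,
               max_independent = cfg$max_independent, seed = cfg$seed)
  rep <- qcReport(qcd)
  writeResultTable(rep@excludedMetabolites,
                   file.path(out, "qc_excluded_metabolites.tsv"))
  writeResultTable(rep@excludedSubjects,
                   file.path(out, "qc_excluded_subjects.tsv"))
  writeResultTable(rep@outlierCells, file.path(out, "qc_outlier_cells.tsv"))
  writeConcentrations(qcd, file.path(out, "qc_concentrations.tsv"))
  logLines(log, sprintf("qc: %d metabolites, %d subjects retained",
                        nrow(qcd), ncol(qcd)))

  qcd2 <- addCompositeTraits(qcd)
  single <- mwas(qcd2, exposure = cfg$exposure,
                 covariates = cfg$covariates, transform = cfg$transform,
                 alpha = cfg$alpha, threshold_method = cfg$threshold_method,
                 fixed_threshold = cfg$fixed_threshold)
  writeResultTable(single, file.path(out, "associations.tsv"))
  logLines(log, sprintf("mwas: %d/%d significant at %.3g",
                        sum(single$significant), nrow(single),
                        single$threshold[1]))

  pairs <- enumerateRatioPairs(panel(qcd), merge_lipids = cfg$merge_lipids)
  rat <- ratioMwas(qcd, single, pairs, cutoff = cfg$p_gain_cutoff,
                   transform = cfg$transform)
  writeResultTable(rat, file.path(out, "ratio_associations.tsv"))
  logLines(log, sprintf("ratios: %d/%d significant",
                        sum(rat$significant, na.rm = TRUE), nrow(rat)))

  ggmCov <- unique(c(cfg$covariates, cfg$exposure))
  pcm <- partialCorrelations(qcd, covariates = ggmCov,
                             transform = cfg$transform)
  edges <- testEdges(pcm, alpha = cfg$ggm_alpha)
  net <- buildNetwork(pcm, edges, single, r_cutoff = cfg$r_cutoff)
  netPath <- file.path(out, paste0("network.",
                                   switch(cfg$network_format,
                                          graphml = "graphml", gml = "gml",
                                          tsv_edgelist = "tsv")))
  exportNetwork(net, netPath, format = cfg$network_format)
  writeResultTable(net@edges, file.path(out, "network_edges.tsv"))
  logLines(log, sprintf("ggm: %d edges", nrow(net@edges)))

  strat <- NULL
  if (!is.null(cfg$strata) && !identical(cfg$strata, "none")) {
    strat <- suppressWarnings(
      stratifiedMwas(qcd2, strata = cfg$strata, exposure = cfg$exposure,
                     covariates = cfg$covariates, transform = cfg$transform,
                     alpha = cfg$alpha,
                     threshold_method = cfg$threshold_method))
    if (length(strat))
      writeResultTable(stratifiedSummaryTable(strat),
                       file.path(out, "stratified_associations.tsv"))
  }

  tab <- traitSummaryTable(qcd2, single, rat)
  writeResultTable(tab, file.path(out, "trait_summary.tsv"))
  comp <- compositeTraits(qcd)
  if (!is.null(comp) && "Sum BCAAs" %in% rownames(comp)) {
    writeResultTable(quintileTable(qcd, comp["Sum BCAAs", ]),
                     file.path(out, "quintile_characteristics.tsv"))
    writeResultTable(quintileLong(qcd, comp["Sum BCAAs", ],
                                  exposure = cfg$exposure),
                     file.path(out, "quintile_boxplot_long.tsv"))
  }
  logLines(log, "done")
  invisible(list(cohort = qcd, single = single, ratios = rat, pcm = pcm,
                 network = net, stratified = strat))
}

writePheno <- function(cohort, path) {
  p <- as.data.frame(phenotypes(cohort))
  d <- cbind(subject_id = rownames(p), p)
  for (cn in colnames(d)) if (is.numeric(d[[cn]])) d[[cn]] <- fmtNum(d[[cn]])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
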