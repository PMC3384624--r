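#' Valid metabolite chemical classes
#'
#' The eight chemical classes of a Biocrates-style targeted panel:
#' amino acids, biogenic amines, acylcarnitines (including free carnitine C0),
#' lyso-phosphatidylcholines, diacyl and acyl-alkyl phosphatidylcholines,
#' sphingomyelins (including hydroxylated species) and the hexose sum
#' parameter.
#'
#' @return character vector of class labels.
#' @export
metaboliteClasses <- function() {
  c("amino_acid", "biogenic_amine", "acylcarnitine", "lysoPC",
    "PC_aa", "PC_ae", "sphingomyelin", "hexose")
}

#' Metabolite panel definition
#'
#' Ordered list of metabolite descriptors: identifier, chemical class and,
#' for lipid species named \code{Cx:y}, the side-chain carbon and double-bond
#' counts.  Drives QC bookkeeping and intra-class ratio enumeration.
#'
#' @slot panelName single string, e.g. `"p180"`.
#' @slot info `DataFrame` with columns `name`, `chem_class`, `carbons`,
#'   `double_bonds`.
#' @export
setClass("MetaboPanel",
  slots = c(panelName = "character", info = "DataFrame"))

setValidity("MetaboPanel", function(object) {
  info <- object@info
  msgs <- character()
  need <- c("name", "chem_class", "carbons", "double_bonds")
  if (!all(need %in% colnames(info)))
    return(paste("panel info must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(info$name))
    msgs <- c(msgs, "metabolite names must be unique within a panel")
  bad <- setdiff(unique(info$chem_class),
                 c(metaboliteClasses(), "composite"))
  if (length(bad))
    msgs <- c(msgs, paste("unknown chemical class:", paste(bad, collapse = ", ")))
  cx <- info$carbons[!is.na(info$carbons)]
  dx <- info$double_bonds[!is.na(info$double_bonds)]
  if (any(cx < 0) || any(dx < 0))
    msgs <- c(msgs, "carbons/double_bonds must be non-negative when present")
  if (length(object@panelName) != 1L)
    msgs <- c(msgs, "panelName must be a single string")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Plate-replicated reference-sample measurements
#'
#' Long-format container of repeated measurements of a common reference
#' sample, several replicates per plate, used to compute per-plate
#' coefficients of variation for metabolite-level QC.
#'
#' @slot data `data.frame` with columns `plate`, `metabolite`, `value`
#'   (concentration in micromol/l).
#' @export
setClass("ReferenceReplicates", slots = c(data = "data.frame"))

setValidity("ReferenceReplicates", function(object) {
  d <- object@data
  if (!all(c("plate", "metabolite", "value") %in% colnames(d)))
    return("data must have columns plate, metabolite, value")
  if (nrow(d) && any(d$value < 0, na.rm = TRUE))
    return("reference concentrations must be non-negative")
  TRUE
})

#' Cohort container: concentrations, panel and phenotypes
#'
#' Extends [SummarizedExperiment::SummarizedExperiment-class]; rows are
#' metabolites (the panel lives in `rowData`), columns are subjects
#' (phenotypes live in `colData`), and the `"conc"` assay holds concentrations
#' in micromol/l with `NA` marking missing values.  Reference replicates,
#' simulation ground truth and QC reports ride along in `metadata()`.
#'
#' @export
setClass("MetaboCohort", contains = "SummarizedExperiment")

setValidity("MetaboCohort", function(object) {
  msgs <- character()
  if (!"conc" %in% SummarizedExperiment::assayNames(object))
    return("MetaboCohort requires a 'conc' assay")
  m <- SummarizedExperiment::assay(object, "conc")
  if (any(m < 0, na.rm = TRUE))
    msgs <- c(msgs, "all non-missing concentrations must be >= 0")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "metabolite (row) names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "subject (column) ids must be present and unique")
  if (!"chem_class" %in% colnames(SummarizedExperiment::rowData(object)))
    msgs <- c(msgs, "rowData must carry the panel (chem_class column)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Quality-control report
#'
#' Complete record of a [runQC()] pass: which metabolites were excluded and
#' why (coefficient of variation or missingness), which subjects were dropped
#' by the independent-outlier rule, every flagged outlier cell, and every
#' imputed cell.  Together with the seed this fully determines the
#' transformation from the input matrix to the QC'd matrix.
#'
#' @slot excludedMetabolites `data.frame` with columns `metabolite`, `reason`
#'   (`"cv"` or `"missingness"`), `value` (the offending statistic).
#' @slot excludedSubjects `data.frame` with columns `subject`,
#'   `n_independent_outliers`.
#' @slot outlierCells `data.frame` with columns `subject`, `metabolite`,
#'   `value`, `z`.
#' @slot imputedCells `data.frame` with columns `subject`, `metabolite`,
#'   `imputed_value`, `method`.
#' @slot cvTable `data.frame` with columns `metabolite`, `mean_cv`.
#' @slot seed integer seed used by the imputation step.
#' @export
setClass("QcReport",
  slots = c(excludedMetabolites = "data.frame",
            excludedSubjects = "data.frame",
            outlierCells = "data.frame",
            imputedCells = "data.frame",
            cvTable = "data.frame",
            seed = "integer"))

setValidity("QcReport", function(object) {
  em <- object@excludedMetabolites
  if (nrow(em) && !all(em$reason %in% c("cv", "missingness")))
    return("each excluded metabolite carries exactly one reason: cv or missingness")
  TRUE
})

#' Simulation configuration
#'
#' All knobs of the synthetic-cohort generator.  Defaults emulate a
#' population cohort of 965 adults measured on the p180 panel: sex-specific
#' FFMI, height and body-fat distributions; planted standardized FFMI effects
#' on selected metabolites; a sparse within-class partial-correlation
#' (precision-matrix) dependence structure; additive log-scale batch shifts;
#' injected outliers, missingness and plate-replicated reference samples.
#'
#' @slot nSubjects integer cohort size.
#' @slot panel a `MetaboPanel`.
#' @slot seed integer RNG seed; all generators are pure functions of
#'   (config, seed).
#' @slot effectTable named numeric, standardized beta per kg/m^2 FFMI on the
#'   transformed (log z-score) metabolite scale.
#' @slot gammaAge,gammaSex standardized nuisance effect sizes.
#' @slot edgeDensity within-class edge density of the planted precision
#'   matrix.
#' @slot pcorRange length-2 numeric, magnitude range of planted partial
#'   correlations (signs random).
#' @slot batchCount,batchSd number of measurement batches and SD of the
#'   additive log-scale batch shift.
#' @slot outlierRate,missingRate per-cell rates in [0, 1].
#' @slot outlierDisplacement length-2 numeric; injected outliers are placed
#'   at mean +/- U(lo, hi) * SD on the raw scale.
#' @slot nPlates,nReplicates reference-sample design.
#' @slot targetCv named numeric of reference-sample coefficients of
#'   variation (names must cover the panel, or length 1 to recycle).
#' @slot concMean,concSd named numeric targets for raw-scale marginal
#'   mean/SD in micromol/l (defaults from published cohort values where
#'   available, class-typical values otherwise).
#' @slot phenoParams named list of phenotype population parameters (see
#'   [simConfig()]).
#' @slot obeseNull logical; if TRUE the planted FFMI effects are switched off
#'   in obese subjects (BMI >= 30), emulating obesity-restricted effect
#'   modification.
#' @export
setClass("SimulationConfig",
  slots = c(nSubjects = "integer", panel = "MetaboPanel", seed = "integer",
            effectTable = "numeric", gammaAge = "numeric", gammaSex = "numeric",
            edgeDensity = "numeric", pcorRange = "numeric",
            batchCount = "integer", batchSd = "numeric",
            outlierRate = "numeric", missingRate = "numeric",
            outlierDisplacement = "numeric",
            nPlates = "integer", nReplicates = "integer",
            targetCv = "numeric", concMean = "numeric", concSd = "numeric",
            phenoParams = "list", obeseNull = "logical"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  rates <- c(outlierRate = object@outlierRate, missingRate = object@missingRate,
             edgeDensity = object@edgeDensity)
  if (any(rates < 0 | rates > 1))
    msgs <- c(msgs, "rates (outlierRate, missingRate, edgeDensity) must lie in [0, 1]")
  if (object@nSubjects < 2L) msgs <- c(msgs, "nSubjects must be >= 2")
  if (length(object@pcorRange) != 2L || any(object@pcorRange < 0) ||
      any(object@pcorRange >= 1) || diff(object@pcorRange) < 0)
    msgs <- c(msgs, "pcorRange must be increasing magnitudes in [0, 1)")
  if (length(object@outlierDisplacement) != 2L ||
      diff(object@outlierDisplacement) < 0)
    msgs <- c(msgs, "outlierDisplacement must be an increasing length-2 range")
  bad <- setdiff(names(object@effectTable), object@panel@info$name)
  if (length(bad))
    msgs <- c(msgs, paste("effectTable names not in panel:",
                          paste(bad, collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Simulation ground truth
#'
#' Emitted alongside each simulated cohort so that downstream stages can be
#' validated against known answers.
#'
#' @slot betas named numeric; planted standardized FFMI effects (zero for
#'   unnamed metabolites).
#' @slot precision planted precision matrix (metabolites x metabolites) of
#'   the latent log-scale Gaussian.
#' @slot partialCor implied partial-correlation matrix
#'   \eqn{-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}} of the final (ridged)
#'   precision matrix.
#' @slot outlierMask,missingMask logical metabolite x subject matrices of
#'   injected outliers / missing cells.
#' @slot trueCv named numeric; reference-sample target coefficients of
#'   variation.
#' @slot ridge total diagonal ridge applied to reach positive definiteness.
#' @export
setClass("GroundTruth",
  slots = c(betas = "numeric", precision = "matrix", partialCor = "matrix",
            outlierMask = "matrix", missingMask = "matrix",
            trueCv = "numeric", ridge = "numeric"))

setValidity("GroundTruth", function(object) {
  if (nrow(object@precision) != ncol(object@precision))
    return("precision matrix must be square")
  if (nrow(object@outlierMask) && !identical(dim(object@outlierMask),
                                             dim(object@missingMask)))
    return("outlier and missing masks must share dimensions")
  TRUE
})

#' Full-order partial-correlation matrix
#'
#' Symmetric matrix of partial correlations between metabolites, each
#' conditioned on all remaining metabolites and on the model covariates
#' (removed beforehand by residualisation).
#'
#' @slot estimate symmetric numeric matrix, unit diagonal, entries in
#'   [-1, 1].
#' @slot nSamples number of subjects used.
#' @slot nControls number of conditioned variables per pair (covariates plus
#'   the M - 2 remaining metabolites); used as `k` in the Fisher-z test.
#' @slot ridge ridge added to the residual covariance before inversion
#'   (0 = unregularised).
#' @export
setClass("PartialCorrelationMatrix",
  slots = c(estimate = "matrix", nSamples = "integer", nControls = "integer",
            ridge = "numeric"))

setValidity("PartialCorrelationMatrix", function(object) {
  m <- object@estimate
  if (nrow(m) != ncol(m)) return("estimate must be square")
  if (nrow(m) && max(abs(m - t(m))) > 1e-8) return("estimate must be symmetric")
  if (nrow(m) && max(abs(diag(m) - 1)) > 1e-8) return("diagonal must be 1")
  if (nrow(m) && (min(m) < -1 - 1e-12 || max(m) > 1 + 1e-12))
    return("entries must lie in [-1, 1]")
  TRUE
})

#' Gaussian graphical model network
#'
#' Nodes are metabolites coloured by their phenotype association (red:
#' positive and significant, blue: negative and significant, white: not
#' significant); edges are partial correlations that pass both the
#' Bonferroni-corrected Fisher-z test and the |r| cutoff.
#'
#' @slot nodes `data.frame`: `metabolite`, `colour`, `beta`, `p`,
#'   `significant`.
#' @slot edges `data.frame`: `from`, `to`, `r_partial`, `p_partial`,
#'   `significant`, `passes_cutoff` (edge present iff both are TRUE).
#' @slot rCutoff,alpha thresholds used to build the network.
#' @export
setClass("GgmNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame",
            rCutoff = "numeric", alpha = "numeric"))

setValidity("GgmNetwork", function(object) {
  if (nrow(object@nodes) && !all(object@nodes$colour %in% c("red", "blue", "white")))
    return("node colours must be red, blue or white")
  e <- object@edges
  if (nrow(e) && !all(e$significant & e$passes_cutoff))
    return("edges must be significant AND pass the |r| cutoff")
  TRUE
})
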