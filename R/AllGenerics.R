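#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom stats coef complete.cases cor cov lm.fit median pnorm pt qnorm
#'   quantile rbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table head combn
NULL

#' Panel accessor
#'
#' Extract the metabolite panel definition attached to an object.
#'
#' @param x a `MetaboCohort` or other object carrying a panel.
#' @return a [MetaboPanel-class] object.
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))

#' Concentration matrix accessor
#'
#' @param x a `MetaboCohort`.
#' @return numeric matrix, metabolites in rows, subjects in columns,
#'   concentrations in micromol/l with `NA` marking missing cells.
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname concentrations
#' @param value replacement matrix.
#' @export
setGeneric("concentrations<-", function(x, value) standardGeneric("concentrations<-"))

#' Phenotype table accessor
#'
#' @param x a `MetaboCohort`.
#' @return a [S4Vectors::DataFrame-class] of per-subject phenotypes.
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' Reference-replicate accessor
#'
#' @param x a `MetaboCohort`.
#' @return a [ReferenceReplicates-class] object or `NULL`.
#' @export
setGeneric("refReplicates", function(x) standardGeneric("refReplicates"))

#' Ground-truth accessor
#'
#' @param x a simulated `MetaboCohort`.
#' @return a [GroundTruth-class] object or `NULL` for non-simulated cohorts.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' QC report accessor
#'
#' @param x a `MetaboCohort` that went through [runQC()].
#' @return a [QcReport-class] object or `NULL`.
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' Chemical class accessor
#'
#' @param x a `MetaboPanel` or `MetaboCohort`.
#' @return character vector of chemical classes, parallel to the metabolites.
#' @export
setGeneric("chemClass", function(x) standardGeneric("chemClass"))
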