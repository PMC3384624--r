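#' Construct a MetaboCohort
#'
#' @param concentrations numeric matrix of concentrations in micromol/l,
#'   either metabolites x subjects or subjects x metabolites (orientation is
#'   resolved against the panel); `NA` marks missing cells.
#' @param panel a [MetaboPanel-class] matching the metabolite dimension.
#' @param phenotypes `data.frame`/`DataFrame` of per-subject phenotypes with
#'   rownames (or a `subject_id` column) matching the subject dimension.
#' @param refReplicates optional [ReferenceReplicates-class].
#' @param plateOfSubject optional named vector mapping subjects to plates.
#' @return a [MetaboCohort-class].
#' @export
MetaboCohort <- function(concentrations, panel, phenotypes = NULL,
                         refReplicates = NULL, plateOfSubject = NULL) {
  pn <- names(panel)
  if (!is.matrix(concentrations)) concentrations <- as.matrix(concentrations)
  if (!is.null(colnames(concentrations)) &&
      all(pn %in% colnames(concentrations)) &&
      !all(pn %in% rownames(concentrations))) {
    concentrations <- t(concentrations)  # came in as subjects x metabolites
  }
  if (is.null(rownames(concentrations)))
    stop("concentration matrix must carry metabolite names")
  missingMet <- setdiff(pn, rownames(concentrations))
  extraMet <- setdiff(rownames(concentrations), pn)
  if (length(missingMet) || length(extraMet))
    stop("concentration columns do not match the panel; missing: ",
         paste(head(missingMet, 5), collapse = ", "),
         if (length(extraMet)) paste0("; not in panel: ",
                                      paste(head(extraMet, 5), collapse = ", ")))
  concentrations <- concentrations[pn, , drop = FALSE]
  if (is.null(colnames(concentrations)))
    colnames(concentrations) <- sprintf("S%04d", seq_len(ncol(concentrations)))

  if (is.null(phenotypes)) {
    cd <- S4Vectors::DataFrame(row.names = colnames(concentrations))
  } else {
    cd <- S4Vectors::DataFrame(phenotypes, check.names = FALSE)
    if ("subject_id" %in% colnames(cd)) {
      rownames(cd) <- cd$subject_id
      cd$subject_id <- NULL
    }
    if (!setequal(rownames(cd), colnames(concentrations)))
      stop("phenotype subjects do not match concentration subjects")
    cd <- cd[colnames(concentrations), , drop = FALSE]
  }
  md <- list()
  if (!is.null(refReplicates)) md$referenceReplicates <- refReplicates
  if (!is.null(plateOfSubject)) md$plateOfSubject <- plateOfSubject
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(conc = concentrations),
    rowData = panel@info[match(pn, panel@info$name), , drop = FALSE],
    colData = cd, metadata = md)
  rownames(se) <- pn
  new("MetaboCohort", se)
}

#' @describeIn MetaboCohort the panel reconstructed from `rowData`
#' @param x a `MetaboCohort`.
#' @export
setMethod("panel", "MetaboCohort", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  new("MetaboPanel",
      panelName = if (!is.null(S4Vectors::metadata(x)$panelName))
        S4Vectors::metadata(x)$panelName else "cohort",
      info = S4Vectors::DataFrame(name = rownames(x),
                                  chem_class = rd$chem_class,
                                  carbons = rd$carbons,
                                  double_bonds = rd$double_bonds))
})

#' @describeIn MetaboCohort concentration assay (metabolites x subjects)
#' @export
setMethod("concentrations", "MetaboCohort",
          function(x) SummarizedExperiment::assay(x, "conc"))

#' @describeIn MetaboCohort replace the concentration assay
#' @param value replacement matrix.
#' @export
setMethod("concentrations<-", "MetaboCohort", function(x, value) {
  SummarizedExperiment::assay(x, "conc") <- value
  x
})

#' @describeIn MetaboCohort per-subject phenotypes (`colData`)
#' @export
setMethod("phenotypes", "MetaboCohort",
          function(x) SummarizedExperiment::colData(x))

#' @describeIn MetaboCohort reference replicates stored in `metadata()`
#' @export
setMethod("refReplicates", "MetaboCohort",
          function(x) S4Vectors::metadata(x)$referenceReplicates)

#' @describeIn MetaboCohort simulation ground truth stored in `metadata()`
#' @export
setMethod("groundTruth", "MetaboCohort",
          function(x) S4Vectors::metadata(x)$groundTruth)

#' @describeIn MetaboCohort QC report stored in `metadata()` by [runQC()]
#' @export
setMethod("qcReport", "MetaboCohort",
          function(x) S4Vectors::metadata(x)$qcReport)

#' @describeIn MetaboCohort chemical class per metabolite
#' @export
setMethod("chemClass", "MetaboCohort",
          function(x) setNames(SummarizedExperiment::rowData(x)$chem_class,
                               rownames(x)))

setMethod("show", "MetaboCohort", function(object) {
  m <- concentrations(object)
  cat("MetaboCohort: ", nrow(m), " metabolites x ", ncol(m), " subjects\n",
      sep = "")
  cat("  missing cells: ", sum(is.na(m)), "\n", sep = "")
  cat("  phenotypes: ", paste(colnames(phenotypes(object)), collapse = ", "),
      "\n", sep = "")
  extras <- intersect(c("referenceReplicates", "groundTruth", "qcReport"),
                      names(S4Vectors::metadata(object)))
  if (length(extras)) cat("  metadata: ", paste(extras, collapse = ", "),
                          "\n", sep = "")
})

#' Read a concentration table
#'
#' Tab- or comma-separated file, one row per subject, first column
#' `subject_id`, remaining columns one per metabolite (any order; they are
#' aligned to the panel order).  Empty cells and `NA` are missing; any other
#' unparseable cell is coerced to missing with a message.  Negative
#' concentrations are an error.
#'
#' @param path file path.
#' @param panel a [MetaboPanel-class]; the header must contain exactly the
#'   panel's metabolites.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return a [MetaboCohort-class] with empty phenotypes.
#' @export
readConcentrations <- function(path, panel, sep = "\t") {
  d <- read.delim(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"subject_id" %in% colnames(d))
    stop("first column must be 'subject_id'")
  ids <- as.character(d$subject_id)
  if (anyDuplicated(ids))
    stop("duplicate subject id: ", ids[duplicated(ids)][1])
  have <- setdiff(colnames(d), "subject_id")
  missingMet <- setdiff(names(panel), have)
  extraMet <- setdiff(have, names(panel))
  if (length(missingMet) || length(extraMet))
    stop("header/panel mismatch; missing columns: ",
         paste(missingMet, collapse = ", "),
         if (length(extraMet)) paste0("; unknown columns: ",
                                      paste(extraMet, collapse = ", ")))
  vals <- d[, names(panel), drop = FALSE]
  coerced <- 0L
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      coerced <- coerced + sum(is.na(num) & !is.na(v))
      v <- num
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (any(m < 0, na.rm = TRUE)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative concentration for subject '", rownames(m)[idx[1]],
         "', metabolite '", colnames(m)[idx[2]], "'")
  }
  if (coerced > 0)
    message(coerced, " unparseable cell(s) coerced to missing")
  MetaboCohort(t(m), panel)
}

#' Write a concentration table
#'
#' Inverse of [readConcentrations()]: one row per subject, first column
#' `subject_id`, missing cells written as empty fields.  Values round-trip
#' bit-identically through the default 17-significant-digit formatting.
#'
#' @param cohort a [MetaboCohort-class].
#' @param path output file path.
#' @param sep field separator.
#' @export
writeConcentrations <- function(cohort, path, sep = "\t") {
  m <- t(concentrations(cohort))
  d <- data.frame(subject_id = rownames(m), check.names = FALSE,
                  stringsAsFactors = FALSE)
  for (j in colnames(m)) d[[j]] <- sprintf("%.17g", m[, j])
  for (j in colnames(m)) d[[j]][is.na(m[, j])] <- ""
  write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated file with fixed column names: `subject_id`, `age`, `sex`
#' (`male`/`female` or 0/1), `height_cm` (or `height_m`), `weight_kg`,
#' `ffm_kg`, `fm_kg`, and optionally `activity`, `batch`,
#' `weight_baseline_kg`, `weight_followup_kg`, `years_elapsed` and exclusion
#' flags (`flag_mi`, `flag_stroke`, `flag_diabetes`, `flag_cancer`,
#' `flag_ace_inhibitor`, `flag_antilipidemic`).  Height is stored in metres
#' internally.
#'
#' @param path file path.
#' @return a `DataFrame` keyed by subject id, with `height` in metres.
#' @export
readPhenotypes <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
  if (!"subject_id" %in% colnames(d)) stop("phenotype file needs 'subject_id'")
  if ("height_cm" %in% colnames(d)) {
    d$height <- d$height_cm / 100
    d$height_cm <- NULL
  } else if ("height_m" %in% colnames(d)) {
    d$height <- d$height_m
    d$height_m <- NULL
  }
  ren <- c(weight_kg = "weight", ffm_kg = "ffm", fm_kg = "fm",
           weight_baseline_kg = "weight_baseline",
           weight_followup_kg = "weight_followup")
  for (old in names(ren)) if (old %in% colnames(d)) {
    d[[ren[[old]]]] <- d[[old]]; d[[old]] <- NULL
  }
  if ("sex" %in% colnames(d) && !is.numeric(d$sex))
    d$sex <- factor(d$sex, levels = c("female", "male"))
  cd <- S4Vectors::DataFrame(d, check.names = FALSE)
  rownames(cd) <- as.character(d$subject_id)
  cd$subject_id <- NULL
  validatePhenotypes(cd)
  cd
}

validatePhenotypes <- function(p) {
  if ("height" %in% colnames(p) && any(p$height <= 0, na.rm = TRUE))
    stop("height must be > 0")
  if ("age" %in% colnames(p) && any(p$age <= 0, na.rm = TRUE))
    stop("age must be > 0")
  if (all(c("ffm", "fm", "weight") %in% colnames(p))) {
    bad <- which(p$ffm + p$fm > p$weight * 1.05)
    if (length(bad))
      stop("ffm + fm exceeds weight (5% tolerance) for subject(s): ",
           paste(head(rownames(p)[bad], 5), collapse = ", "))
  }
  invisible(p)
}
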