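#' Derived anthropometric indices
#'
#' Height-normalised body-composition indices: FFMI = fat free mass /
#' height^2, BFMI = body fat mass / height^2, BMI = weight / height^2 (all
#' kg/m^2) and percentage body fat.  Whenever weight = ffm + fm, BMI is the
#' sum of FFMI and BFMI.
#'
#' @param pheno `data.frame`/`DataFrame` with columns `height` (m), `weight`,
#'   `ffm`, `fm` (kg).
#' @return `data.frame` with columns `ffmi`, `bfmi`, `bmi`, `fat_pct`, one
#'   row per subject.
#' @examples
#' computeIndices(data.frame(height = 1.8, weight = 81, ffm = 54, fm = 27))
#' @export
computeIndices <- function(pheno) {
  need <- c("height", "weight", "ffm", "fm")
  miss <- setdiff(need, colnames(pheno))
  if (length(miss)) stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  if (any(pheno$height <= 0, na.rm = TRUE)) stop("height must be > 0")
  h2 <- pheno$height^2
  out <- data.frame(ffmi = pheno$ffm / h2,
                    bfmi = pheno$fm / h2,
                    bmi = pheno$weight / h2,
                    fat_pct = 100 * pheno$fm / pheno$weight)
  rownames(out) <- rownames(pheno)
  out
}

#' Weight-stability filter
#'
#' Keeps subjects whose annualised relative weight change between baseline
#' and follow-up does not exceed `max_rate` (default 0.5% per year); the
#' boundary value is kept.
#'
#' @param pheno phenotype table with `weight_baseline`, `weight_followup`,
#'   `years_elapsed`.
#' @param max_rate maximum |weight change| / baseline / year, as a fraction.
#' @return character vector of retained subject ids.
#' @export
weightStableFilter <- function(pheno, max_rate = 0.005) {
  need <- c("weight_baseline", "weight_followup", "years_elapsed")
  miss <- setdiff(need, colnames(pheno))
  if (length(miss)) stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  if (any(pheno$years_elapsed <= 0, na.rm = TRUE))
    stop("years_elapsed must be > 0")
  rate <- abs(pheno$weight_followup - pheno$weight_baseline) /
    pheno$weight_baseline / pheno$years_elapsed
  keep <- !is.na(rate) & rate <= max_rate
  rownames(pheno)[keep]
}

#' Medical-history and medication exclusion filter
#'
#' Removes subjects with any exclusion flag set (history of myocardial
#' infarction, stroke, diabetes or cancer; intake of ACE inhibitors or
#' anti-lipidemic drugs).  Missing flags are treated as absent.
#'
#' @param pheno phenotype table; flag columns are those starting `flag_`.
#' @return character vector of retained subject ids.
#' @export
exclusionFilter <- function(pheno) {
  flagCols <- grep("^flag_", colnames(pheno), value = TRUE)
  if (!length(flagCols)) return(rownames(pheno))
  flags <- as.matrix(as.data.frame(pheno[, flagCols, drop = FALSE]))
  nMissing <- sum(is.na(flags))
  if (nMissing > 0)
    message(nMissing, " missing exclusion flag(s) treated as absent")
  flags[is.na(flags)] <- FALSE
  any_flag <- rowSums(flags != 0) > 0
  if (all(any_flag)) warning("all subjects carry an exclusion flag")
  rownames(pheno)[!any_flag]
}
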