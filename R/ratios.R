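#' Enumerate intra-class metabolite ratio traits
#'
#' All unordered pairs of metabolites sharing a chemical class, one trait
#' per pair, oriented lexicographically (numerator sorts before
#' denominator).  With `merge_lipids = TRUE` the three
#' phosphatidylcholine-derived classes (PC aa, PC ae, lysoPC) are pooled
#' into one ratio class, mirroring analyses that treat the
#' glycerophospholipids as a single group.  The exact class partition behind
#' a published pair count is generally not recoverable, hence the
#' configurable grouping.
#'
#' @param panel a [MetaboPanel-class] (typically after QC).
#' @param merge_lipids pool PC aa / PC ae / lysoPC into one class.
#' @return `data.frame` with columns `numerator`, `denominator`,
#'   `chem_class`.
#' @examples
#' nrow(enumerateRatioPairs(panelPreset("p180")))
#' @export
enumerateRatioPairs <- function(panel, merge_lipids = FALSE) {
  cls <- chemClass(panel)
  cls <- cls[cls != "composite"]
  if (merge_lipids)
    cls[cls %in% c("PC_aa", "PC_ae", "lysoPC")] <- "glycerophospholipid"
  out <- lapply(unique(cls), function(cl) {
    mets <- names(cls)[cls == cl]
    if (length(mets) < 2L) return(NULL)
    prs <- combn(sort(mets), 2)
    data.frame(numerator = prs[1, ], denominator = prs[2, ],
               chem_class = cl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(numerator = character(), denominator = character(),
                      chem_class = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-subject values of a ratio trait
#'
#' Element-wise numerator / denominator concentration (micromol/micromol).
#' Cells with a zero denominator become missing with a message.
#'
#' @param cohort a [MetaboCohort-class] or metabolites x subjects matrix.
#' @param numerator,denominator metabolite names.
#' @return named numeric vector over subjects.
#' @export
ratioValues <- function(cohort, numerator, denominator) {
  m <- if (is(cohort, "MetaboCohort")) concentrations(cohort) else cohort
  if (!all(c(numerator, denominator) %in% rownames(m)))
    stop("unknown metabolite in ratio: ", numerator, "/", denominator)
  den <- m[denominator, ]
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    message(sum(zero), " zero-denominator cell(s) set to missing for ",
            numerator, "/", denominator)
    den[zero] <- NA
  }
  m[numerator, ] / den
}

#' The p-gain statistic
#'
#' Fold decrease in the association p-value of a metabolite ratio relative
#' to the smaller of the two single-metabolite p-values:
#' `p_gain = min(p_m1, p_m2) / p_ratio`.  A large p-gain indicates that the
#' ratio carries information beyond either constituent (e.g. a shared
#' confounding factor cancelling in the quotient).  Computation is done in
#' log space so p-values far below double precision do not underflow when
#' supplied as `log10p`.
#'
#' @param p_m1,p_m2 single-metabolite association p-values in (0, 1].
#' @param p_ratio ratio association p-value in (0, 1].
#' @param log10p if TRUE the three arguments are log10 p-values and the
#'   log10 p-gain is returned.
#' @return positive p-gain (or its log10).
#' @examples
#' pGain(1.96e-11, 1, 1.61e-14)  # 1.22e3 at 3 s.f.
#' @export
pGain <- function(p_m1, p_m2, p_ratio, log10p = FALSE) {
  if (log10p) return(pmin(p_m1, p_m2) - p_ratio)
  if (any(c(p_m1, p_m2, p_ratio) <= 0) || any(c(p_m1, p_m2, p_ratio) > 1))
    stop("p-values must lie in (0, 1]; for underflowing p-values use ",
         "log10p = TRUE")
  pmin(p_m1, p_m2) / p_ratio
}

#' Ratio-wide association with p-gain scoring
#'
#' Fits every ratio trait with the same transform, model and covariates as
#' the single-metabolite analysis, then scores it with the p-gain against
#' the single-metabolite p-values.  A ratio association is significant iff
#' its p-value is below the metabolite-wide threshold AND its p-gain
#' strictly exceeds the cutoff; the default cutoff is the number of
#' metabolites after QC (a Bonferroni-flavoured correction), overridable to
#' replay published cut-offs such as 170 or 150.
#'
#' @param cohort a QC'd [MetaboCohort-class].
#' @param single result of [mwas()] on the same cohort (supplies single
#'   p-values and the significance threshold).
#' @param pairs ratio traits from [enumerateRatioPairs()]; defaults to all
#'   intra-class pairs of the cohort's panel.
#' @param cutoff p-gain cutoff (default: number of metabolites).
#' @param transform transform kind.
#' @return `DataFrame`: numerator, denominator, chem_class, beta, se, p,
#'   log10p, r2_adj, n, direction, p_gain, log10_p_gain, min_single_p,
#'   p_gain_pass, significant, threshold.  Degenerate ratios (zero variance)
#'   are skipped with a message.
#' @export
ratioMwas <- function(cohort, single, pairs = NULL, cutoff = NULL,
                      transform = "lognormal_z") {
  m <- concentrations(cohort)
  if (is.null(pairs)) pairs <- enumerateRatioPairs(panel(cohort))
  if (is.null(cutoff)) cutoff <- nrow(m)
  md <- S4Vectors::metadata(single)
  exposure <- md$exposure %||% "ffmi"
  covariates <- md$covariates %||% c("age", "sex")
  threshold <- if (length(single$threshold)) single$threshold[1] else 0.05
  if (!nrow(pairs)) {
    out <- S4Vectors::DataFrame(pairs)
    return(out)
  }
  rv <- m[pairs$numerator, , drop = FALSE] / m[pairs$denominator, , drop = FALSE]
  rownames(rv) <- paste(pairs$numerator, pairs$denominator, sep = "/")
  z <- transformMatrixSafe(rv, transform)
  X <- buildDesign(phenotypes(cohort), exposure, covariates)
  stats <- olsStats(X, t(z$z[!z$failed, , drop = FALSE]))
  out <- data.frame(pairs, beta = NA_real_, se = NA_real_, p = NA_real_,
                    log10p = NA_real_, r2_adj = NA_real_, n = ncol(m),
                    direction = NA_character_, stringsAsFactors = FALSE)
  idx <- match(rownames(stats),
               paste(out$numerator, out$denominator, sep = "/"))
  for (cn in c("beta", "se", "p", "log10p", "r2_adj", "n"))
    out[[cn]][idx] <- stats[[cn]]
  out$direction[idx] <- ifelse(stats$beta >= 0, "pos", "neg")
  lookup <- setNames(single$log10p, single$trait)
  l1 <- lookup[out$numerator]
  l2 <- lookup[out$denominator]
  minLog <- pmin(l1, l2)
  out$min_single_p <- 10^minLog
  out$log10_p_gain <- pGain(l1, l2, out$log10p, log10p = TRUE)
  out$p_gain <- 10^out$log10_p_gain
  out$p_gain_pass <- !is.na(out$log10_p_gain) &
    out$log10_p_gain > log10(cutoff)
  out$significant <- !is.na(out$p) & out$p < threshold & out$p_gain_pass
  out$threshold <- threshold
  res <- S4Vectors::DataFrame(out, row.names = NULL)
  S4Vectors::metadata(res) <- list(cutoff = cutoff, exposure = exposure,
                                   covariates = covariates)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
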