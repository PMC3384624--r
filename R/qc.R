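#' Per-plate and mean coefficients of variation
#'
#' For every metabolite and plate with at least two replicates, CV = sample
#' SD / mean of the reference replicates; the metabolite-level summary is
#' the unweighted mean CV over plates.  Plates with mean zero have an
#' undefined CV and are dropped from the summary with a warning.
#'
#' @param refs a [ReferenceReplicates-class].
#' @return list with `perPlate` (`data.frame`: metabolite, plate, cv, n) and
#'   `meanCv` (named numeric per metabolite).
#' @export
computeCV <- function(refs) {
  d <- refs@data
  if (!nrow(d)) stop("no reference replicates")
  sp <- split(d$value, list(metabolite = d$metabolite, plate = d$plate),
              drop = TRUE, sep = "\r")
  key <- strsplit(names(sp), "\r", fixed = TRUE)
  per <- data.frame(
    metabolite = vapply(key, `[`, "", 1),
    plate = vapply(key, `[`, "", 2),
    n = lengths(sp),
    cv = vapply(sp, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NA_real_)
      m <- mean(v)
      if (m == 0) return(NaN)
      sd(v) / m
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (any(is.nan(per$cv)))
    warning("plate(s) with zero mean excluded from the mean CV")
  usable <- per[!is.na(per$cv) & !is.nan(per$cv), , drop = FALSE]
  meanCv <- tapply(usable$cv, usable$metabolite, mean)
  noCv <- setdiff(unique(per$metabolite), names(meanCv))
  if (length(noCv))
    stop("no plate with >= 2 replicates for metabolite(s): ",
         paste(head(noCv, 5), collapse = ", "))
  list(perPlate = per, meanCv = setNames(as.numeric(meanCv), names(meanCv)))
}

#' Metabolite filter on reference-sample CV
#'
#' Removes metabolites whose mean CV over plates is strictly greater than
#' the threshold (default 25%); a mean CV of exactly 25% is kept.
#'
#' @param cohort a [MetaboCohort-class].
#' @param refs reference replicates; defaults to those stored in the cohort.
#' @param threshold CV threshold (fraction).
#' @return list with the reduced `cohort`, `removed` (`data.frame` of
#'   excluded metabolites with their mean CV) and `meanCv`.
#' @export
filterByCV <- function(cohort, refs = refReplicates(cohort), threshold = 0.25) {
  if (is.null(refs)) stop("no reference replicates available")
  cv <- computeCV(refs)$meanCv
  known <- intersect(rownames(cohort), names(cv))
  bad <- names(cv)[cv > threshold]
  bad <- intersect(bad, rownames(cohort))
  removed <- data.frame(metabolite = bad, reason = rep("cv", length(bad)),
                        value = as.numeric(cv[bad]), stringsAsFactors = FALSE)
  list(cohort = cohort[setdiff(rownames(cohort), bad), ], removed = removed,
       meanCv = cv[known])
}

#' Metabolite filter on missingness
#'
#' Removes metabolites whose fraction of missing values strictly exceeds the
#' threshold (default 5%).
#'
#' @param cohort a [MetaboCohort-class].
#' @param threshold missing-fraction threshold.
#' @return list with the reduced `cohort` and `removed` (`data.frame`).
#' @export
filterByMissingness <- function(cohort, threshold = 0.05) {
  m <- concentrations(cohort)
  frac <- rowMeans(is.na(m))
  bad <- rownames(m)[frac > threshold]
  removed <- data.frame(metabolite = bad,
                        reason = rep("missingness", length(bad)),
                        value = as.numeric(frac[bad]), stringsAsFactors = FALSE)
  list(cohort = cohort[setdiff(rownames(cohort), bad), ], removed = removed)
}

#' Detect concentration outliers
#'
#' A cell is an outlier iff its value is strictly greater than mean + k SD or
#' strictly less than mean - k SD of its metabolite over the whole
#' population (single pass: mean and SD include the candidate value; no
#' re-estimation after flagging).
#'
#' @param cohort a [MetaboCohort-class] or a metabolites x subjects matrix.
#' @param k number of standard deviations (default 5).
#' @return `data.frame` with columns `subject`, `metabolite`, `value`, `z`.
#' @export
detectOutliers <- function(cohort, k = 5) {
  m <- if (is(cohort, "MetaboCohort")) concentrations(cohort) else cohort
  nOk <- rowSums(!is.na(m))
  if (any(nOk < 3L))
    stop("need >= 3 non-missing values per metabolite for outlier detection")
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1, sd, na.rm = TRUE)
  zeroVar <- sdv == 0
  if (any(zeroVar)) {
    warning("zero-variance metabolite(s), no outliers flagged: ",
            paste(head(rownames(m)[zeroVar], 5), collapse = ", "))
    sdv[zeroVar] <- Inf
  }
  z <- (m - mu) / sdv
  hit <- which(!is.na(z) & abs(z) > k, arr.ind = TRUE)
  data.frame(subject = colnames(m)[hit[, 2]],
             metabolite = rownames(m)[hit[, 1]],
             value = m[hit], z = z[hit],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count independent outliers per subject
#'
#' Two flagged metabolites of the same subject are dependent if the absolute
#' Pearson correlation of their full concentration columns
#' (pairwise-complete, over all subjects) is at least `r_threshold`; the
#' subject's independent-outlier count is the number of connected components
#' of the dependency graph on the subject's flagged metabolites.
#'
#' @param cohort a [MetaboCohort-class] or matrix.
#' @param outliers output of [detectOutliers()].
#' @param r_threshold dependence threshold on |r| (default 0.70).
#' @return named integer vector: independent-outlier count per subject that
#'   has at least one flagged cell.
#' @export
independentOutlierGroups <- function(cohort, outliers, r_threshold = 0.70) {
  m <- if (is(cohort, "MetaboCohort")) concentrations(cohort) else cohort
  if (!nrow(outliers)) return(setNames(integer(0), character(0)))
  mets <- unique(outliers$metabolite)
  cm <- suppressWarnings(cor(t(m[mets, , drop = FALSE]),
                             use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  bySubject <- split(outliers$metabolite, outliers$subject)
  vapply(bySubject, function(flagged) {
    flagged <- unique(flagged)
    if (length(flagged) == 1L) return(1L)
    sub <- abs(cm[flagged, flagged, drop = FALSE]) >= r_threshold
    diag(sub) <- TRUE
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    as.integer(igraph::components(g)$no)
  }, integer(1))
}

#' Apply the subject-level outlier policy
#'
#' Subjects with strictly more than `max_independent` independent outlying
#' metabolite concentrations are excluded entirely; for the remaining
#' subjects only the flagged data points are set to missing.
#'
#' @param cohort a [MetaboCohort-class].
#' @param outliers output of [detectOutliers()].
#' @param counts output of [independentOutlierGroups()].
#' @param max_independent subject-exclusion threshold (default 3).
#' @return list with the reduced `cohort` and `excludedSubjects`
#'   (`data.frame`: subject, n_independent_outliers).
#' @export
applyOutlierPolicy <- function(cohort, outliers, counts, max_independent = 3) {
  dropSubjects <- names(counts)[counts > max_independent]
  excluded <- data.frame(subject = dropSubjects,
                         n_independent_outliers = as.integer(counts[dropSubjects]),
                         stringsAsFactors = FALSE)
  keep <- setdiff(colnames(cohort), dropSubjects)
  out <- cohort[, keep]
  m <- concentrations(out)
  cells <- outliers[!(outliers$subject %in% dropSubjects), , drop = FALSE]
  if (nrow(cells))
    m[cbind(match(cells$metabolite, rownames(m)),
            match(cells$subject, colnames(m)))] <- NA
  concentrations(out) <- m
  list(cohort = out, excludedSubjects = excluded)
}

#' Regression imputation of missing concentrations
#'
#' Chained-equations single imputation: metabolites with missing cells are
#' visited in decreasing order of missingness; each is regressed (on the log
#' scale) on its `m` most-correlated fellow metabolites, using current
#' working values, and missing cells are filled with the linear prediction,
#' optionally plus residual noise drawn with the given seed.  Five sweeps
#' are run; a single completed dataset is returned.  Ill-conditioned designs
#' fall back to the metabolite mean for the affected cells (logged).
#'
#' @param cohort a [MetaboCohort-class]; every metabolite must have at least
#'   50% observed values.
#' @param seed integer seed for the residual-noise draws.
#' @param m number of predictor metabolites (default 10).
#' @param sweeps number of chained sweeps (default 5).
#' @param noise add residual noise to the fills (default TRUE); FALSE gives
#'   the conditional-mean fill.
#' @return list with the completed `cohort` and `imputed` (`data.frame`:
#'   subject, metabolite, imputed_value, method).
#' @export
imputeMissing <- function(cohort, seed = 1L, m = 10L, sweeps = 5L,
                          noise = TRUE) {
  conc <- concentrations(cohort)
  nMiss <- rowSums(is.na(conc))
  if (!any(nMiss > 0)) {
    return(list(cohort = cohort,
                imputed = data.frame(subject = character(), metabolite = character(),
                                     imputed_value = numeric(), method = character(),
                                     stringsAsFactors = FALSE)))
  }
  if (any(nMiss > 0.5 * ncol(conc)))
    stop("imputation requires >= 50% observed values per metabolite")
  lx <- log(conc)
  missIdx <- lapply(seq_len(nrow(lx)), function(j) which(is.na(lx[j, ])))
  targets <- order(nMiss, decreasing = TRUE)
  targets <- targets[nMiss[targets] > 0]
  method <- setNames(rep("regression", nrow(lx)), rownames(lx))
  work <- lx
  # initial fill: metabolite mean
  for (j in targets) work[j, missIdx[[j]]] <- mean(lx[j, ], na.rm = TRUE)
  withLocalSeed(seed, {
    for (sweep in seq_len(sweeps)) {
      cm <- suppressWarnings(cor(t(work)))
      diag(cm) <- 0
      cm[is.na(cm)] <- 0
      for (j in targets) {
        idx <- missIdx[[j]]
        preds <- order(abs(cm[j, ]), decreasing = TRUE)
        preds <- preds[seq_len(min(m, length(preds)))]
        preds <- preds[abs(cm[j, preds]) > 0]
        obs <- setdiff(seq_len(ncol(work)), idx)
        if (!length(preds)) { method[j] <- "mean"; next }
        X <- cbind(1, t(work[preds, obs, drop = FALSE]))
        fit <- tryCatch(lm.fit(X, lx[j, obs]), error = function(e) NULL)
        if (is.null(fit) || anyNA(fit$coefficients) ||
            fit$rank < ncol(X)) {
          method[j] <- "mean"
          work[j, idx] <- mean(lx[j, ], na.rm = TRUE)
          next
        }
        pred <- drop(cbind(1, t(work[preds, idx, drop = FALSE])) %*%
                       fit$coefficients)
        if (noise) {
          s2 <- sum(fit$residuals^2) / max(length(obs) - ncol(X), 1)
          pred <- pred + rnorm(length(idx), 0, sqrt(s2))
        }
        work[j, idx] <- pred
      }
    }
  })
  completed <- exp(work)
  completed[!is.na(conc)] <- conc[!is.na(conc)]
  hit <- which(is.na(conc), arr.ind = TRUE)
  imputed <- data.frame(subject = colnames(conc)[hit[, 2]],
                        metabolite = rownames(conc)[hit[, 1]],
                        imputed_value = completed[hit],
                        method = method[rownames(conc)[hit[, 1]]],
                        stringsAsFactors = FALSE, row.names = NULL)
  if (any(imputed$method == "mean"))
    message(sum(imputed$method == "mean"),
            " cell(s) fell back to metabolite-mean imputation")
  concentrations(cohort) <- completed
  list(cohort = cohort, imputed = imputed)
}

#' Run the full two-step quality control
#'
#' Fixed order: reference-sample CV filter, missingness filter, outlier
#' detection (mean +/- 5 SD, single pass), independent-outlier subject
#' policy, regression imputation.  The returned cohort carries a
#' [QcReport-class] in `metadata()` that fully determines the transformation;
#' no missing values remain afterwards.
#'
#' @param cohort a [MetaboCohort-class] with reference replicates.
#' @param refs reference replicates (default: stored in the cohort).
#' @param cv_threshold CV threshold (default 0.25).
#' @param miss_threshold missingness threshold (default 0.05).
#' @param k outlier SD multiplier (default 5).
#' @param r_threshold outlier-dependence correlation threshold (default 0.70).
#' @param max_independent subject-exclusion count threshold (default 3).
#' @param seed imputation seed.
#' @param impute_noise add residual noise in the imputation fills.
#' @return the QC'd [MetaboCohort-class] (use [qcReport()] for the record).
#' @export
runQC <- function(cohort, refs = refReplicates(cohort), cv_threshold = 0.25,
                  miss_threshold = 0.05, k = 5, r_threshold = 0.70,
                  max_independent = 3, seed = 1L, impute_noise = TRUE) {
  s1 <- filterByCV(cohort, refs, cv_threshold)
  s2 <- filterByMissingness(s1$cohort, miss_threshold)
  outliers <- detectOutliers(s2$cohort, k)
  counts <- independentOutlierGroups(s2$cohort, outliers, r_threshold)
  s3 <- applyOutlierPolicy(s2$cohort, outliers, counts, max_independent)
  s4 <- imputeMissing(s3$cohort, seed = seed, noise = impute_noise)
  report <- new("QcReport",
                excludedMetabolites = rbind(s1$removed, s2$removed),
                excludedSubjects = s3$excludedSubjects,
                outlierCells = outliers,
                imputedCells = s4$imputed,
                cvTable = data.frame(metabolite = names(s1$meanCv),
                                     mean_cv = as.numeric(s1$meanCv),
                                     stringsAsFactors = FALSE),
                seed = as.integer(seed))
  out <- s4$cohort
  S4Vectors::metadata(out)$qcReport <- report
  out
}

setMethod("show", "QcReport", function(object) {
  cat("QcReport\n")
  cat("  excluded metabolites: ", nrow(object@excludedMetabolites),
      " (cv: ", sum(object@excludedMetabolites$reason == "cv"),
      ", missingness: ",
      sum(object@excludedMetabolites$reason == "missingness"), ")\n", sep = "")
  cat("  excluded subjects:    ", nrow(object@excludedSubjects), "\n", sep = "")
  cat("  outlier cells:        ", nrow(object@outlierCells), "\n", sep = "")
  cat("  imputed cells:        ", nrow(object@imputedCells), "\n", sep = "")
})
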