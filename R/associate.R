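# Build the model design matrix from the phenotype table.
# Sex is coded 0/1 (male = 1), batch as indicator contrasts; the exposure
# column comes second so its coefficient index is fixed.
buildDesign <- function(pheno, exposure, covariates) {
  if (exposure %in% covariates)
    stop("exposure must not appear among the covariates")
  cols <- list(`(Intercept)` = rep(1, nrow(pheno)))
  getNum <- function(nm) {
    v <- pheno[[nm]]
    if (is.null(v)) stop("phenotype column not found: ", nm)
    if (nm == "sex") return(as.numeric(v == "male" | v == 1))
    if (is.factor(v)) {
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, levels(v)[-1])
      return(mm)
    }
    as.numeric(v)
  }
  cols[[exposure]] <- getNum(exposure)
  for (cv in covariates) cols[[cv]] <- getNum(cv)
  X <- do.call(cbind, lapply(names(cols), function(nm) {
    v <- cols[[nm]]
    if (is.matrix(v)) v else matrix(v, ncol = 1, dimnames = list(NULL, nm))
  }))
  rownames(X) <- rownames(pheno)
  X
}

# Multi-response OLS of each column of Y on design X; returns per-response
# beta/SE/p/adjusted R^2 for the coefficient in column `coefIdx` of X.
olsStats <- function(X, Y, coefIdx = 2L) {
  n <- nrow(X); p <- ncol(X)
  if (ncol(Y) == 0L)
    return(data.frame(beta = numeric(), se = numeric(), p = numeric(),
                      log10p = numeric(), r2_adj = numeric(), n = integer()))
  if (n <= p + 2) stop("too few observations for the model (n <= p + 2)")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("collinear design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  # undo pivoting
  piv <- qrX$pivot
  XtXinv <- XtXinv[order(piv), order(piv), drop = FALSE]
  se <- sqrt(sigma2 * XtXinv[coefIdx, coefIdx])
  beta <- B[coefIdx, ]
  tval <- beta / se
  log10p <- (pt(abs(tval), df = n - p, lower.tail = FALSE, log.p = TRUE) +
               log(2)) / log(10)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  r2 <- 1 - rss / tss
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  data.frame(beta = unname(beta), se = unname(se),
             p = pmin(10^log10p, 1), log10p = unname(log10p),
             r2_adj = unname(r2adj), n = n, row.names = colnames(Y))
}

#' Fit a single covariate-adjusted linear model
#'
#' Ordinary least squares of a standardized trait on the exposure plus
#' covariates; reports the exposure coefficient with its two-sided t-test
#' and the adjusted R^2 of the full model.
#'
#' @param y numeric response (already transformed), no missing values among
#'   used rows.
#' @param pheno phenotype table.
#' @param exposure phenotype name of the explanatory variable (e.g.
#'   `"ffmi"`).
#' @param covariates character vector of adjustment variables (e.g.
#'   `c("age", "sex")`; add `"batch"` for multi-batch datasets).
#' @return one-row `data.frame`: beta, se, p, log10p, r2_adj, n, direction.
#' @export
fitLinear <- function(y, pheno, exposure = "ffmi",
                      covariates = c("age", "sex")) {
  ok <- !is.na(y)
  X <- buildDesign(pheno[ok, , drop = FALSE], exposure, covariates)
  out <- olsStats(X, matrix(y[ok], ncol = 1,
                            dimnames = list(NULL, "trait")))
  out$direction <- ifelse(out$beta >= 0, "pos", "neg")
  out
}

#' Effective number of tests and significance threshold
#'
#' `method = "effective"` (default) estimates the effective number of
#' independent tests from the eigenvalues of the trait correlation matrix
#' (Li & Ji estimator: `M_eff = sum(I(lambda >= 1) + (lambda - floor(lambda)))`)
#' and returns `alpha / M_eff`; with uncorrelated traits this equals the
#' Bonferroni threshold `alpha / M`, and with perfectly correlated traits it
#' returns `alpha`.  `method = "fixed"` replays a user-supplied threshold
#' (e.g. the published 3.12e-4 / 3.5e-4 values).
#'
#' @param z metabolites x subjects matrix of transformed values (ignored for
#'   `method = "fixed"`).
#' @param alpha family-wise level (default 0.05).
#' @param method `"effective"`, `"bonferroni"` or `"fixed"`.
#' @param fixed threshold value for `method = "fixed"`.
#' @return list with `threshold`, `mEff`, `method`, `alpha`.
#' @export
multipleTestingThreshold <- function(z, alpha = 0.05,
                                     method = c("effective", "bonferroni",
                                                "fixed"),
                                     fixed = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed)) stop("method 'fixed' requires a threshold value")
    return(list(threshold = fixed, mEff = alpha / fixed, method = method,
                alpha = alpha))
  }
  M <- nrow(z)
  if (method == "bonferroni")
    return(list(threshold = alpha / M, mEff = M, method = method,
                alpha = alpha))
  cm <- suppressWarnings(cor(t(z), use = "pairwise.complete.obs"))
  if (any(!is.finite(cm)))
    stop("non-finite correlations; cannot estimate effective tests")
  lambda <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 0] <- 0
  lambda <- round(lambda, 8)   # guard floor() against 4 - eps eigenvalues
  mEff <- sum((lambda >= 1) + (lambda - floor(lambda)))
  list(threshold = alpha / mEff, mEff = mEff, method = method, alpha = alpha)
}

#' Metabolome-wide association study
#'
#' Transforms every metabolite with the inverse log-normal z-score (or the
#' rank-based alternative) and regresses it on the exposure plus covariates;
#' the significance threshold accounts for the dependence among metabolites
#' via the effective number of tests unless a fixed threshold is supplied.
#'
#' @param cohort a QC'd [MetaboCohort-class] (no missing values).
#' @param exposure,covariates model specification (see [fitLinear()]).
#' @param transform transform kind passed to [transformConcentrations()].
#' @param alpha family-wise level.
#' @param threshold_method,fixed_threshold see [multipleTestingThreshold()].
#' @return `DataFrame` with one row per metabolite: trait, beta, se, p,
#'   log10p, r2_adj, n, direction, significant, threshold; metadata carries
#'   the threshold details.  Per-metabolite fit errors are logged and the
#'   affected traits returned with `NA` statistics.
#' @export
mwas <- function(cohort, exposure = "ffmi", covariates = c("age", "sex"),
                 transform = "lognormal_z", alpha = 0.05,
                 threshold_method = "effective", fixed_threshold = NULL) {
  m <- concentrations(cohort)
  if (nrow(m) == 0L)
    return(S4Vectors::DataFrame(trait = character(), beta = numeric(),
                                se = numeric(), p = numeric(),
                                log10p = numeric(), r2_adj = numeric(),
                                n = integer(), direction = character(),
                                significant = logical(),
                                threshold = numeric()))
  pheno <- phenotypes(cohort)
  covariates <- usableCovariates(pheno, covariates)
  z <- transformMatrixSafe(m, transform)
  thr <- multipleTestingThreshold(z$z, alpha, threshold_method,
                                  fixed_threshold)
  X <- buildDesign(pheno, exposure, covariates)
  stats <- olsStats(X, t(z$z[!z$failed, , drop = FALSE]))
  out <- data.frame(trait = rownames(m), beta = NA_real_, se = NA_real_,
                    p = NA_real_, log10p = NA_real_, r2_adj = NA_real_,
                    n = nrow(pheno), direction = NA_character_,
                    stringsAsFactors = FALSE)
  idx <- match(rownames(stats), out$trait)
  for (cn in c("beta", "se", "p", "log10p", "r2_adj", "n"))
    out[[cn]][idx] <- stats[[cn]]
  out$direction[idx] <- ifelse(stats$beta >= 0, "pos", "neg")
  out$significant <- !is.na(out$p) & out$p < thr$threshold
  out$threshold <- thr$threshold
  res <- S4Vectors::DataFrame(out)
  S4Vectors::metadata(res) <- list(threshold = thr, exposure = exposure,
                                   covariates = covariates,
                                   transform = transform)
  res
}

# transform each row, recording (not propagating) per-trait failures
transformMatrixSafe <- function(m, kind) {
  failed <- logical(nrow(m))
  z <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(nrow(m))) {
    zz <- tryCatch(transformConcentrations(m[j, ], kind = kind),
                   error = function(e) NULL)
    if (is.null(zz)) failed[j] <- TRUE else z[j, ] <- zz
  }
  if (any(failed))
    message(sum(failed), " trait(s) skipped (transform failed): ",
            paste(head(rownames(m)[failed], 5), collapse = ", "))
  list(z = z, failed = failed)
}

usableCovariates <- function(pheno, covariates) {
  keep <- covariates[vapply(covariates, function(cv) {
    v <- pheno[[cv]]
    !is.null(v) && (is.numeric(v) || length(unique(v[!is.na(v)])) > 1L)
  }, logical(1))]
  if (!identical(keep, covariates))
    message("dropping constant/absent covariate(s): ",
            paste(setdiff(covariates, keep), collapse = ", "))
  keep
}

#' Stratified metabolome-wide association
#'
#' Runs [mwas()] within each stratum of a partition; built-in partitions are
#' `sex`, `age65` (> 65 vs <= 65 years), `activity` and `bmi30` (BMI >= 30
#' vs < 30 kg/m^2).  Thresholds are recomputed within each stratum; strata
#' below the minimum size are skipped with a warning.
#'
#' @param cohort a QC'd [MetaboCohort-class].
#' @param strata either the name of a built-in partition or a factor/vector
#'   over subjects.
#' @param min_n minimum stratum size (default 50).
#' @param ... passed to [mwas()].
#' @return named list of `DataFrame` results, one per stratum.
#' @export
stratifiedMwas <- function(cohort, strata = "bmi30", min_n = 50, ...) {
  pheno <- phenotypes(cohort)
  if (is.character(strata) && length(strata) == 1L) {
    strata <- switch(strata,
      sex = as.character(pheno$sex),
      age65 = ifelse(pheno$age > 65, "age_gt65", "age_le65"),
      activity = as.character(pheno$activity),
      bmi30 = ifelse(pheno$bmi >= 30, "obese", "non_obese"),
      stop("unknown built-in partition: ", strata))
  }
  strata <- as.character(strata)
  if (length(strata) != ncol(cohort))
    stop("stratum labels must cover all subjects")
  out <- list()
  for (lv in unique(strata)) {
    sel <- which(strata == lv)
    if (length(sel) < min_n) {
      warning("stratum '", lv, "' skipped (n = ", length(sel), " < ",
              min_n, ")")
      next
    }
    out[[lv]] <- mwas(cohort[, sel], ...)
  }
  out
}

#' SNP-metabolite association under an additive genetic model
#'
#' Each transformed metabolite is regressed on the SNP allele dosage plus
#' age, sex (and batch where present), assuming additive allelic effects.
#' Monomorphic SNPs are skipped with a message.  Significance uses either a
#' fixed threshold (e.g. the published 4.73e-6 / 5.3e-6 values) or
#' Bonferroni over all SNP x metabolite pairs.
#'
#' @param dosages subjects x SNPs numeric matrix with entries in [0, 2].
#' @param cohort a QC'd [MetaboCohort-class].
#' @param covariates adjustment variables.
#' @param alpha family-wise level.
#' @param fixed_threshold optional fixed significance threshold.
#' @param transform transform kind.
#' @return `DataFrame`: snp, trait, beta, se, p, n, significant, threshold.
#' @export
snpAssociation <- function(dosages, cohort, covariates = c("age", "sex"),
                           alpha = 0.05, fixed_threshold = NULL,
                           transform = "lognormal_z") {
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp%03d", seq_len(ncol(dosages)))
  pheno <- phenotypes(cohort)
  if (!identical(rownames(dosages), colnames(cohort)))
    dosages <- dosages[colnames(cohort), , drop = FALSE]
  covariates <- usableCovariates(pheno, covariates)
  z <- transformMatrixSafe(concentrations(cohort), transform)
  Y <- t(z$z[!z$failed, , drop = FALSE])
  mono <- apply(dosages, 2, function(v) length(unique(v[!is.na(v)])) < 2L)
  if (any(mono))
    message("skipping monomorphic SNP(s): ",
            paste(colnames(dosages)[mono], collapse = ", "))
  snps <- colnames(dosages)[!mono]
  nPairs <- length(snps) * ncol(Y)
  threshold <- if (!is.null(fixed_threshold)) fixed_threshold else
    alpha / nPairs
  res <- lapply(snps, function(s) {
    ph <- pheno
    ph$dosage <- dosages[, s]
    X <- buildDesign(ph, "dosage", covariates)
    st <- olsStats(X, Y)
    data.frame(snp = s, trait = rownames(st), beta = st$beta, se = st$se,
               p = st$p, n = st$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < threshold
  out$threshold <- threshold
  res <- S4Vectors::DataFrame(out, row.names = NULL)
  S4Vectors::metadata(res) <- list(n_pairs = nPairs, alpha = alpha)
  res
}
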