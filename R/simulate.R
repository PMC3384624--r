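#' Build a simulation configuration
#'
#' Defaults describe a population cohort of 965 adults measured on the p180
#' panel.  Phenotype moments (sex-specific FFMI, body-fat index, height; age)
#' follow published cohort descriptives; concentration mean/SD targets come
#' from published per-metabolite values where available and class-typical
#' values otherwise; planted FFMI effects default to the published
#' standardized betas of the non-obese stratum for the strongly associated
#' single metabolites.  Reference-sample coefficients of variation default to
#' 7%, with the 19 biogenic amines and acylcarnitine C3:1 planted at 35% so
#' that CV-based QC removes exactly 20 metabolites, leaving 166.
#'
#' @param nSubjects cohort size.
#' @param panel a [MetaboPanel-class].
#' @param seed integer seed.
#' @param effectTable named numeric of standardized FFMI effects per kg/m^2
#'   on the transformed metabolite scale.
#' @param gammaAge,gammaSex standardized nuisance effects of z-scored age and
#'   of male sex on the latent log scale.
#' @param edgeDensity within-class edge density of the planted precision
#'   matrix.
#' @param pcorRange magnitude range of planted partial correlations.
#' @param batchCount,batchSd measurement batches and log-scale shift SD.
#' @param outlierRate,missingRate per-cell injection rates.
#' @param outlierDisplacement outliers placed at mean +/- U(lo, hi) * SD.
#' @param nPlates,nReplicates reference-sample design (default 10 plates x 5
#'   replicates).
#' @param targetCv reference-sample CV per metabolite (length 1 recycles;
#'   `NULL` uses the default plant described above).
#' @param concMean,concSd raw-scale marginal targets in micromol/l (`NULL`
#'   uses the packaged defaults).
#' @param phenoParams named list overriding individual phenotype population
#'   parameters (see Details).
#' @param obeseNull if TRUE, planted FFMI effects are zeroed in obese
#'   subjects (BMI >= 30 kg/m^2), emulating obesity-restricted effect
#'   modification.
#'
#' @details `phenoParams` entries and defaults: `pMale` 0.5; `ageMean` 63.2,
#' `ageSd` 5.5, `ageRange` c(51, 80) (truncated normal); sex-specific
#' `ffmiMean` c(female = 16.99, male = 19.71), `ffmiSd` c(1.85, 1.66),
#' `bfmiMean` c(11.24, 8.34), `bfmiSd` c(3.08, 2.29), `heightMean` in metres
#' c(1.5933, 1.7226), `heightSd` c(0.0596, 0.0635); `pActive` 0.43;
#' `yearsElapsed` 7 and `weightRateSd` 0.004 for the baseline/follow-up
#' weight pair.
#'
#' @return a [SimulationConfig-class].
#' @export
simConfig <- function(nSubjects = 965L, panel = panelPreset("p180"), seed = 1L,
                      effectTable = NULL, gammaAge = 0.05, gammaSex = 0.05,
                      edgeDensity = 0.02, pcorRange = c(0.3, 0.6),
                      batchCount = 3L, batchSd = 0.05,
                      outlierRate = 0, missingRate = 0,
                      outlierDisplacement = c(6, 9),
                      nPlates = 10L, nReplicates = 5L,
                      targetCv = NULL, concMean = NULL, concSd = NULL,
                      phenoParams = list(), obeseNull = FALSE) {
  pn <- names(panel)
  if (is.null(effectTable)) {
    effectTable <- defaultEffectTable()
    effectTable <- effectTable[names(effectTable) %in% pn]
  }
  if (is.null(targetCv)) {
    targetCv <- setNames(rep(0.07, length(pn)), pn)
    plant <- c(pn[chemClass(panel) == "biogenic_amine"],
               intersect("C3:1", pn))
    targetCv[plant] <- 0.60
  } else if (length(targetCv) == 1L) {
    targetCv <- setNames(rep(targetCv, length(pn)), pn)
  }
  tgt <- defaultConcTargets(panel)
  if (!is.null(concMean)) tgt$mean[names(concMean)] <- concMean
  if (!is.null(concSd)) tgt$sd[names(concSd)] <- concSd
  pp <- defaultPhenoParams()
  pp[names(phenoParams)] <- phenoParams
  new("SimulationConfig",
      nSubjects = as.integer(nSubjects), panel = panel, seed = as.integer(seed),
      effectTable = effectTable, gammaAge = gammaAge, gammaSex = gammaSex,
      edgeDensity = edgeDensity, pcorRange = as.numeric(pcorRange),
      batchCount = as.integer(batchCount), batchSd = batchSd,
      outlierRate = outlierRate, missingRate = missingRate,
      outlierDisplacement = as.numeric(outlierDisplacement),
      nPlates = as.integer(nPlates), nReplicates = as.integer(nReplicates),
      targetCv = targetCv, concMean = tgt$mean, concSd = tgt$sd,
      phenoParams = pp, obeseNull = obeseNull)
}

defaultEffectTable <- function() {
  c(Val = 0.14, Ile = 0.13, Leu = 0.13, Ala = 0.12, Tyr = 0.14, Phe = 0.10,
    C5 = 0.14, C3 = 0.13, C0 = 0.09,
    `PC aa C38:3` = 0.08, `PC ae C42:3` = -0.16, `PC ae C36:2` = -0.09,
    `lysoPC a C18:1` = -0.07, `lysoPC a C18:2` = -0.07)
}

defaultPhenoParams <- function() {
  list(pMale = 0.5, ageMean = 63.2, ageSd = 5.5, ageRange = c(51, 80),
       ffmiMean = c(female = 16.99, male = 19.71),
       ffmiSd = c(female = 1.85, male = 1.66),
       bfmiMean = c(female = 11.24, male = 8.34),
       bfmiSd = c(female = 3.08, male = 2.29),
       heightMean = c(female = 1.5933, male = 1.7226),
       heightSd = c(female = 0.0596, male = 0.0635),
       pActive = 0.43, yearsElapsed = 7, weightRateSd = 0.004)
}

# class-typical raw-scale targets, overridden by published per-metabolite
# values from the packaged reference table
defaultConcTargets <- function(panel) {
  cls <- chemClass(panel)
  classMean <- c(amino_acid = 200, biogenic_amine = 2, acylcarnitine = 0.15,
                 lysoPC = 20, PC_aa = 30, PC_ae = 10, sphingomyelin = 50,
                 hexose = 5180)
  cvDefault <- 0.25
  mn <- setNames(classMean[cls], names(cls))
  sdv <- mn * cvDefault
  ref <- reportedAssociations()
  ref <- ref[!grepl("/", ref$trait, fixed = TRUE) &
               ref$trait %in% names(cls), , drop = FALSE]
  mn[ref$trait] <- ref$mean_umol_l
  sdv[ref$trait] <- ref$sd_umol_l
  list(mean = mn, sd = sdv)
}

#' QC validation fixture configuration
#'
#' A small cohort designed for exact validation of the QC stage: tight
#' biological dispersion (5% CV) so the natural rate of |z| > 5 cells is
#' negligible and the injected-outlier mask is recoverable exactly; outlier
#' displacement 12-15 SD so injected cells stay beyond 5 sample SDs even
#' when several injections land on the same metabolite and inflate its
#' sample SD; injection rates high enough that some subjects exceed three
#' independent outliers.
#'
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
qcFixtureConfig <- function(seed = 1L) {
  panel <- panelPreset("p180")
  mn <- defaultConcTargets(panel)$mean
  simConfig(nSubjects = 500L, panel = panel, seed = seed,
            outlierRate = 0.005, missingRate = 0.01,
            outlierDisplacement = c(12, 15),
            concMean = mn, concSd = mn * 0.05)
}

# run expr under a temporary RNG state seeded with `seed`
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# variance of a standard normal truncated to [a, b], as a factor of 1
truncVarFactor <- function(a, b) {
  z <- pnorm(b) - pnorm(a)
  m <- (stats::dnorm(a) - stats::dnorm(b)) / z
  1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - m^2
}

#' Generate a phenotype table
#'
#' Sex is Bernoulli(pMale); FFMI, body fat mass index and height are drawn
#' from sex-specific normals; age from a truncated normal; fat free mass and
#' fat mass are back-computed as index x height^2, weight as their sum.
#' A baseline/follow-up weight pair with a random annual drift supports the
#' weight-stability filter.
#'
#' @param config a [SimulationConfig-class].
#' @return a `DataFrame` keyed by subject id.
#' @export
generatePhenotypes <- function(config) {
  validObject(config)
  pp <- config@phenoParams
  n <- config@nSubjects
  withLocalSeed(config@seed, {
    sex <- factor(ifelse(rbinom(n, 1, pp$pMale) == 1, "male", "female"),
                  levels = c("female", "male"))
    sx <- as.character(sex)
    ffmi <- rnorm(n, pp$ffmiMean[sx], pp$ffmiSd[sx])
    bfmi <- pmax(rnorm(n, pp$bfmiMean[sx], pp$bfmiSd[sx]), 1)
    height <- rnorm(n, pp$heightMean[sx], pp$heightSd[sx])
    age <- rtruncnorm(n, pp$ageMean, pp$ageSd, pp$ageRange[1], pp$ageRange[2])
    activity <- factor(ifelse(rbinom(n, 1, pp$pActive) == 1,
                              "active", "inactive"),
                       levels = c("inactive", "active"))
    batch <- factor(sample.int(config@batchCount, n, replace = TRUE))
    drift <- rnorm(n, 0, pp$weightRateSd)
    ffm <- ffmi * height^2
    fm <- bfmi * height^2
    weight <- ffm + fm
    d <- S4Vectors::DataFrame(
      age = age, sex = sex, height = height, weight = weight,
      ffm = ffm, fm = fm, ffmi = ffmi, bfmi = bfmi, bmi = ffmi + bfmi,
      fat_pct = 100 * fm / weight, activity = activity, batch = batch,
      weight_baseline = weight,
      weight_followup = weight * (1 + drift * pp$yearsElapsed),
      years_elapsed = pp$yearsElapsed)
    rownames(d) <- sprintf("S%04d", seq_len(n))
    d
  })
}

#' Generate a block-structured sparse precision matrix
#'
#' Within each chemical class, edges are selected at the configured density
#' and assigned partial correlations drawn uniformly from the configured
#' magnitude range with random signs; cross-class edges are absent.  The
#' matrix starts with unit diagonal (so off-diagonal entries equal minus the
#' drawn partial correlation) and, if not positive definite, is shrunk
#' towards the identity (`(Omega + lambda I) / (1 + lambda)`) until the
#' smallest eigenvalue clears a safety margin; the implied partial
#' correlations after shrinkage are recorded as the truth.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `precision` (matrix), `partialCor` (implied
#'   \eqn{-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}} matrix), `edges`
#'   (`data.frame` of planted pairs with their final partial correlation) and
#'   `ridge` (total shrinkage applied).
#' @export
generatePrecisionMatrix <- function(config) {
  validObject(config)
  pn <- names(config@panel)
  M <- length(pn)
  cls <- chemClass(config@panel)
  withLocalSeed(config@seed + 1L, {
    omega <- diag(M)
    dimnames(omega) <- list(pn, pn)
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      if (length(idx) < 2L) next
      prs <- combn(idx, 2)
      on <- runif(ncol(prs)) < config@edgeDensity
      if (!any(on)) next
      rho <- runif(sum(on), config@pcorRange[1], config@pcorRange[2]) *
        sample(c(-1, 1), sum(on), replace = TRUE)
      prs <- prs[, on, drop = FALSE]
      for (k in seq_len(ncol(prs))) {
        omega[prs[1, k], prs[2, k]] <- -rho[k]
        omega[prs[2, k], prs[1, k]] <- -rho[k]
      }
    }
    lambda <- 0
    margin <- 0.02
    omega0 <- omega
    while (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) <
           margin) {
      lambda <- lambda + 0.05
      if (lambda > 2)
        stop("cannot reach positive definiteness within the ridge budget; ",
             "lower edgeDensity or pcorRange")
      omega <- (omega0 + lambda * diag(M)) / (1 + lambda)
    }
    pc <- -omega / sqrt(outer(diag(omega), diag(omega)))
    diag(pc) <- 1
    ut <- which(upper.tri(pc) & pc != 0 &
                  row(pc) != col(pc), arr.ind = TRUE)
    edges <- data.frame(from = pn[ut[, 1]], to = pn[ut[, 2]],
                        pcor = pc[ut], stringsAsFactors = FALSE)
    list(precision = omega, partialCor = pc, edges = edges, ridge = lambda)
  })
}

#' Generate a concentration matrix with planted effects and ground truth
#'
#' Per subject, a latent Gaussian vector on the log scale receives the
#' planted FFMI effect, small age/sex nuisance effects, an additive batch
#' shift and correlated noise with covariance equal to the inverse of the
#' planted precision matrix; it is then mapped to micromol/l by a
#' per-metabolite location/scale chosen so the raw-scale marginal mean and SD
#' approximate the configured targets.  The FFMI effect is calibrated
#' analytically so that the planted value equals the standardized regression
#' coefficient recovered by the association stage (log-z-score transform,
#' adjusted model).  Outliers (cells displaced to mean +/- U(lo,hi) * SD on
#' the raw scale) and completely-at-random missingness are injected last and
#' recorded in the ground-truth masks (disjoint cell sets).
#'
#' @param config a [SimulationConfig-class].
#' @param pheno output of [generatePhenotypes()].
#' @param prec output of [generatePrecisionMatrix()].
#' @return list with `conc` (metabolites x subjects matrix) and `truth`
#'   (a [GroundTruth-class]).
#' @export
generateConcentrations <- function(config, pheno, prec) {
  pn <- names(config@panel)
  M <- length(pn)
  n <- nrow(pheno)
  if (!identical(rownames(prec$precision), pn))
    stop("precision matrix does not match the panel")
  pp <- config@phenoParams
  Sigma <- chol2inv(chol(prec$precision))
  sigma_jj <- diag(Sigma)

  # population moments used to calibrate the standardized effect size
  p <- pp$pMale
  dmu <- pp$ffmiMean[["male"]] - pp$ffmiMean[["female"]]
  V_F <- p * pp$ffmiSd[["male"]]^2 + (1 - p) * pp$ffmiSd[["female"]]^2 +
    p * (1 - p) * dmu^2
  mu_F <- p * pp$ffmiMean[["male"]] + (1 - p) * pp$ffmiMean[["female"]]
  C_FS <- p * (1 - p) * dmu
  V_S <- p * (1 - p)
  aR <- (pp$ageRange - pp$ageMean) / pp$ageSd
  V_Az <- truncVarFactor(aR[1], aR[2])
  V_B <- if (config@batchCount > 1L) config@batchSd^2 else 0

  betas <- setNames(rep(0, M), pn)
  betas[names(config@effectTable)] <- config@effectTable

  # solve sigma_x for each metabolite so that c = b * sigma_x gives a true
  # standardized coefficient equal to b:
  #   sigma_x^2 (1 - b^2 V_F) - 2 b gamma_s C_FS sigma_x - K = 0
  K <- config@gammaAge^2 * V_Az + config@gammaSex^2 * V_S + V_B + sigma_jj
  A <- 1 - betas^2 * V_F
  if (any(A <= 0)) stop("planted effect too large for the FFMI variance")
  sigma_x <- (betas * config@gammaSex * C_FS +
                sqrt(betas^2 * config@gammaSex^2 * C_FS^2 + A * K)) / A
  cc <- betas * sigma_x

  withLocalSeed(config@seed + 2L, {
    eps <- crossprod(chol(Sigma), matrix(rnorm(M * n), M, n))
    Fc <- pheno$ffmi - mu_F
    if (config@obeseNull) Fc <- Fc * (pheno$bmi < 30)
    Az <- (pheno$age - pp$ageMean) / pp$ageSd
    S <- as.numeric(pheno$sex == "male")
    shifts <- matrix(rnorm(M * config@batchCount, 0, config@batchSd),
                     M, config@batchCount)
    if (config@batchCount == 1L) shifts[] <- 0
    x <- cc %o% Fc + config@gammaAge * outer(rep(1, M), Az) * 1 +
      config@gammaSex * outer(rep(1, M), S) +
      shifts[, as.integer(pheno$batch), drop = FALSE] + eps
    cv <- config@concSd[pn] / config@concMean[pn]
    s_t <- sqrt(log1p(cv^2))
    m_t <- log(config@concMean[pn]) - s_t^2 / 2
    conc <- exp(m_t + (s_t / sigma_x) * x)
    dimnames(conc) <- list(pn, rownames(pheno))

    outlierMask <- missingMask <- matrix(FALSE, M, n, dimnames = dimnames(conc))
    if (config@outlierRate > 0) {
      ncell <- M * n
      cells <- which(runif(ncell) < config@outlierRate)
      if (length(cells)) {
        rowMean <- rowMeans(conc)
        rowSd <- apply(conc, 1, sd)
        j <- ((cells - 1L) %% M) + 1L
        d <- runif(length(cells), config@outlierDisplacement[1],
                   config@outlierDisplacement[2])
        sgn <- sample(c(-1, 1), length(cells), replace = TRUE)
        v <- rowMean[j] + sgn * d * rowSd[j]
        v[v < 0] <- rowMean[j][v < 0] + d[v < 0] * rowSd[j][v < 0]
        conc[cells] <- v
        outlierMask[cells] <- TRUE
      }
    }
    if (config@missingRate > 0) {
      candidates <- which(!outlierMask)
      drop <- candidates[runif(length(candidates)) < config@missingRate]
      conc[drop] <- NA
      missingMask[drop] <- TRUE
    }
    truth <- new("GroundTruth", betas = betas, precision = prec$precision,
                 partialCor = prec$partialCor, outlierMask = outlierMask,
                 missingMask = missingMask, trueCv = config@targetCv,
                 ridge = prec$ridge)
    list(conc = conc, truth = truth)
  })
}

#' Generate plate-replicated reference-sample measurements
#'
#' Each metabolite is measured `nReplicates` times on each of `nPlates`
#' plates; replicate draws are log-normal around a common reference level
#' with log-scale dispersion tuned so the raw-scale coefficient of variation
#' matches the configured target.  A target CV of zero yields identical
#' replicates.
#'
#' @param config a [SimulationConfig-class].
#' @return a [ReferenceReplicates-class].
#' @export
generateReferenceReplicates <- function(config) {
  pn <- names(config@panel)
  cvs <- config@targetCv[pn]
  withLocalSeed(config@seed + 3L, {
    s <- sqrt(log1p(cvs^2))
    m <- log(config@concMean[pn]) - s^2 / 2
    nrep <- config@nPlates * config@nReplicates
    vals <- exp(m + s * matrix(rnorm(length(pn) * nrep), length(pn), nrep))
    d <- data.frame(
      plate = rep(rep(seq_len(config@nPlates), each = config@nReplicates),
                  each = length(pn)),
      metabolite = rep(pn, times = nrep),
      value = as.vector(vals),
      stringsAsFactors = FALSE)
    new("ReferenceReplicates", data = d)
  })
}

#' Simulate a full cohort
#'
#' Chains [generatePhenotypes()], [generatePrecisionMatrix()],
#' [generateConcentrations()] and [generateReferenceReplicates()] and packs
#' the result into a [MetaboCohort-class] whose `metadata()` carries the
#' ground truth, the reference replicates and the configuration.  The whole
#' simulation is a pure function of the configuration (including its seed).
#'
#' @param config a [SimulationConfig-class]; see [simConfig()].
#' @return a [MetaboCohort-class].
#' @examples
#' cohort <- simulateCohort(simConfig(nSubjects = 50, seed = 7))
#' cohort
#' @export
simulateCohort <- function(config = simConfig()) {
  validObject(config)
  pheno <- generatePhenotypes(config)
  prec <- generatePrecisionMatrix(config)
  gen <- generateConcentrations(config, pheno, prec)
  refs <- generateReferenceReplicates(config)
  cohort <- MetaboCohort(gen$conc, config@panel, phenotypes = pheno,
                         refReplicates = refs)
  S4Vectors::metadata(cohort)$groundTruth <- gen$truth
  S4Vectors::metadata(cohort)$config <- config
  S4Vectors::metadata(cohort)$panelName <- config@panel@panelName
  S4Vectors::metadata(cohort)$plateOfSubject <-
    setNames(rep(seq_len(config@nPlates), length.out = config@nSubjects),
             rownames(pheno))
  cohort
}
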