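test_that("the log z-score transform matches an independent oracle", {
  set.seed(6)
  x <- rlnorm(500, 3, 0.5)
  z <- transformConcentrations(x)
  oracle <- (log(x) - mean(log(x))) / sd(log(x))
  expect_equal(z, oracle, tolerance = 1e-12)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_true(all(diff(z[order(x)]) > 0))           # monotone

  zr <- transformConcentrations(x, kind = "rank_inverse_normal")
  expect_true(all(diff(zr[order(x)]) > 0))
  expect_lt(abs(mean(zr)), 0.01)

  expect_error(transformConcentrations(rep(2, 10)), "zero variance")
  expect_message(z0 <- transformConcentrations(c(0, 1, 2, 4)),
                 "zero value")
  expect_true(all(is.finite(z0)))
  expect_error(transformConcentrations(x, epsilon = 0), "epsilon")
})

test_that("single linear fits recover exact and degenerate cases", {
  n <- 50
  ph <- data.frame(ffmi = seq_len(n) / 10, age = rnorm(n, 60, 5),
                   row.names = sprintf("S%04d", 1:n))
  y <- 2 * ph$ffmi
  fit <- fitLinear(y, ph, exposure = "ffmi", covariates = character(0))
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-10)
  expect_lt(fit$p, 1e-30)
  expect_equal(fit$direction, "pos")

  ph$dup <- ph$ffmi
  expect_error(fitLinear(y, ph, exposure = "ffmi", covariates = "dup"),
               "collinear.*dup")
})

test_that("null p-values are uniform (KS over 500 replicate fits)", {
  withr::with_seed(99, {
    n <- 1000
    pvals <- vapply(1:500, function(i) {
      x <- rnorm(n)
      y <- rnorm(n)
      X <- cbind(1, x)
      qrX <- qr(X)
      b <- qr.coef(qrX, y)
      res <- y - X %*% b
      s2 <- sum(res^2) / (n - 2)
      se <- sqrt(s2 * chol2inv(qr.R(qrX))[2, 2])
      2 * pt(abs(b[2] / se), n - 2, lower.tail = FALSE)
    }, numeric(1))
    # cross-check our fitLinear against the inline oracle on one draw
    x <- rnorm(n); y <- rnorm(n)
    ph <- data.frame(ffmi = x, row.names = sprintf("S%04d", 1:n))
    fit <- fitLinear(y, ph, covariates = character(0))
    oracle <- summary(lm(y ~ x))$coefficients[2, ]
    expect_equal(fit$beta, oracle[["Estimate"]], tolerance = 1e-10)
    expect_equal(fit$p, oracle[["Pr(>|t|)"]], tolerance = 1e-9)
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("inference is invariant to rescaling raw concentrations", {
  co <- simulateCohort(simConfig(nSubjects = 120L, seed = 33,
                                 panel = smallPanel(), targetCv = 0.1))
  r1 <- mwas(co, covariates = c("age", "sex"))
  co2 <- co
  concentrations(co2) <- concentrations(co) * 1000
  r2 <- mwas(co2, covariates = c("age", "sex"))
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-12)
})

test_that("mwas is order-invariant and significance follows the threshold", {
  co <- simulateCohort(simConfig(nSubjects = 250L, seed = 44,
                                 panel = smallPanel(),
                                 effectTable = c(Val = 0.4), targetCv = 0.1))
  res <- mwas(co, covariates = c("age", "sex"))
  perm <- sample(nrow(co))
  resPerm <- mwas(co[perm, ], covariates = c("age", "sex"))
  idx <- match(res$trait, resPerm$trait)
  expect_equal(res$beta, resPerm$beta[idx], tolerance = 1e-12)
  expect_true(res$significant[res$trait == "Val"])
  expect_false(any(res$significant[res$trait %in% c("Gly", "C0")]))
  expect_identical(res$significant, res$p < res$threshold)
  expect_identical(res$direction, ifelse(res$beta >= 0, "pos", "neg"))

  empty <- mwas(co[integer(0), ])
  expect_equal(nrow(empty), 0L)
})

test_that("the effective-tests threshold behaves at both extremes", {
  set.seed(55)
  z <- matrix(rnorm(166 * 2000), 166, 2000)  # uncorrelated traits
  thr <- multipleTestingThreshold(z)
  expect_equal(thr$mEff, 166, tolerance = 0.02)
  expect_equal(thr$threshold, 0.05 / 166, tolerance = 0.02)
  expect_equal(multipleTestingThreshold(z, method = "bonferroni")$threshold,
               0.05 / 166)

  base <- rnorm(500)
  zPerf <- rbind(base, 2 * base + 3, -base, 0.5 * base)
  thrP <- multipleTestingThreshold(zPerf)
  expect_equal(thrP$mEff, 1, tolerance = 1e-8)
  expect_equal(thrP$threshold, 0.05, tolerance = 1e-8)

  expect_equal(multipleTestingThreshold(z, method = "fixed",
                                        fixed = 3.12e-4)$threshold, 3.12e-4)
  expect_error(multipleTestingThreshold(z, method = "fixed"), "requires")
})

test_that("covariate adjustment removes confounding that unadjusted fits keep", {
  withr::with_seed(66, {
    n <- 400
    hits <- c(adj = 0, unadj = 0)
    for (i in 1:40) {
      age <- rnorm(n, 60, 5)
      ffmi <- 18 - 0.1 * (age - 60) + rnorm(n, 0, 1.5)
      y <- exp(0.08 * (age - 60) + rnorm(n))   # age-driven, no ffmi effect
      z <- transformConcentrations(y)
      ph <- data.frame(ffmi = ffmi, age = age,
                       row.names = sprintf("S%04d", 1:n))
      hits["adj"] <- hits["adj"] +
        (fitLinear(z, ph, covariates = "age")$p < 0.05)
      hits["unadj"] <- hits["unadj"] +
        (fitLinear(z, ph, covariates = character(0))$p < 0.05)
    }
    expect_lte(hits[["adj"]], 6)        # ~ nominal 5% of 40
    expect_gte(hits[["unadj"]], 20)     # grossly inflated when confounded
  })
})

test_that("stratified analysis partitions subjects and recomputes thresholds", {
  co <- simulateCohort(simConfig(nSubjects = 400L, seed = 77))
  qcd <- suppressMessages(runQC(co))
  bySex <- suppressMessages(stratifiedMwas(qcd, "sex",
                                           covariates = c("age", "batch")))
  expect_setequal(names(bySex), c("male", "female"))
  expect_equal(bySex$male$n[1] + bySex$female$n[1], ncol(qcd))

  one <- suppressMessages(stratifiedMwas(qcd, rep("all", ncol(qcd)),
                                         covariates = c("age", "sex", "batch")))
  whole <- suppressMessages(mwas(qcd, covariates = c("age", "sex", "batch")))
  expect_equal(one$all$beta, whole$beta, tolerance = 1e-12)

  expect_warning(stratifiedMwas(qcd, c("tiny", rep("rest", ncol(qcd) - 1)),
                                covariates = c("age", "sex")),
                 "skipped")
})

test_that("effects planted only in the non-obese stratum are found only there", {
  co <- simulateCohort(simConfig(nSubjects = 965L, seed = 88,
                                 obeseNull = TRUE))
  qcd <- suppressMessages(runQC(co))
  strat <- suppressMessages(stratifiedMwas(qcd, "bmi30",
                                           covariates = c("age", "sex", "batch")))
  planted <- names(which(abs(groundTruth(co)@betas) >= 0.13))
  nonObese <- strat$non_obese
  obese <- strat$obese
  sigNon <- nonObese$significant[match(planted, nonObese$trait)]
  sigOb <- obese$significant[match(planted, obese$trait)]
  expect_gte(mean(sigNon), 0.8)
  expect_equal(sum(sigOb), 0L)
})

test_that("SNP associations use additive dosages and skip monomorphic SNPs", {
  co <- simulateCohort(simConfig(nSubjects = 300L, seed = 91,
                                 panel = smallPanel(), targetCv = 0.1,
                                 effectTable = setNames(numeric(0),
                                                        character(0))))
  n <- ncol(co)
  withr::with_seed(12, {
    dos <- cbind(snpA = rbinom(n, 2, 0.3), snpMono = rep(0, n))
    rownames(dos) <- colnames(co)
    # plant an additive effect of 0.5 SD per allele on Val
    m <- concentrations(co)
    m["Val", ] <- m["Val", ] * exp(0.5 * sd(log(m["Val", ])) * dos[, "snpA"])
    concentrations(co) <- m
  })
  expect_message(res <- snpAssociation(dos, co, covariates = c("age", "sex")),
                 "monomorphic")
  expect_false("snpMono" %in% res$snp)
  hit <- res[res$snp == "snpA" & res$trait == "Val", ]
  expect_true(hit$significant)
  expect_lt(hit$p, 1e-4)
  nullP <- res$p[res$trait != "Val"]
  expect_gt(min(nullP), res$threshold[1])   # no false positives in this draw
  expect_error(snpAssociation(dos + 3, co), "\\[0, 2\\]")
})
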