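test_that("coefficient of variation follows sd/mean per plate", {
  r <- refsFromList("A", list(rep(10, 5)))
  expect_equal(computeCV(r)$meanCv[["A"]], 0)

  # two plates with hand-computable CVs averaged without weights
  p1 <- c(8, 12)            # mean 10, sd 2*sqrt(2) -> cv = 0.2*sqrt(2)
  p2 <- c(5, 15)            # mean 10, sd 5*sqrt(2) -> cv = 0.5*sqrt(2)
  r2 <- refsFromList("A", list(p1, p2))
  expect_equal(computeCV(r2)$meanCv[["A"]],
               mean(c(sd(p1) / mean(p1), sd(p2) / mean(p2))))

  # 10 plates x 5 replicates against an independently coded oracle
  set.seed(31)
  plateVals <- replicate(10, rlnorm(5, 0, 0.2), simplify = FALSE)
  r3 <- refsFromList("A", plateVals)
  oracle <- mean(vapply(plateVals, function(v) {
    mu <- sum(v) / length(v)
    s <- sqrt(sum((v - mu)^2) / (length(v) - 1))
    s / mu
  }, numeric(1)))
  expect_equal(computeCV(r3)$meanCv[["A"]], oracle, tolerance = 1e-12)

  expect_error(computeCV(refsFromList("A", list(3))), ">= 2 replicates")
  expect_warning(cv0 <- computeCV(refsFromList("A", list(c(0, 0), c(8, 12)))),
                 "zero mean")
  expect_equal(cv0$meanCv[["A"]], sd(c(8, 12)) / 10)
})

test_that("CV filter is strictly greater-than and removes the planted set", {
  pan <- MetaboPanel(c("A", "B"), c("amino_acid", "amino_acid"))
  m <- matrix(rlnorm(20, 2, 0.1), 10, 2, dimnames = list(NULL, c("A", "B")))
  co <- toyCohort(m, pan)
  refs <- new("ReferenceReplicates",
              data = rbind(refsFromList("A", list(c(8, 12), c(8, 12)))@data,
                           refsFromList("B", list(c(9, 11), c(9, 11)))@data))
  cvA <- computeCV(refs)$meanCv[["A"]]
  keptAtOwn <- filterByCV(co, refs, threshold = cvA)
  expect_true("A" %in% rownames(keptAtOwn$cohort))    # boundary kept
  removedBelow <- filterByCV(co, refs, threshold = cvA - 1e-9)
  expect_false("A" %in% rownames(removedBelow$cohort))
  expect_equal(removedBelow$removed$reason, "cv")

  cfg <- qcFixtureConfig(seed = 5)
  sim <- simulateCohort(cfg)
  out <- filterByCV(sim)
  planted <- names(which(groundTruth(sim)@trueCv > 0.25))
  expect_setequal(out$removed$metabolite, planted)
  expect_length(planted, 20L)
})

test_that("missingness filter strictly exceeds its threshold", {
  pan <- MetaboPanel(c("A", "B"), c("amino_acid", "amino_acid"))
  m <- matrix(rlnorm(200, 2, 0.1), 100, 2, dimnames = list(NULL, c("A", "B")))
  m[1:6, 1] <- NA   # 6% -> removed
  m[1:5, 2] <- NA   # 5% -> kept (strict)
  out <- filterByMissingness(toyCohort(m, pan))
  expect_equal(out$removed$metabolite, "A")
  expect_true("B" %in% rownames(out$cohort))
})

test_that("outlier detection is single-pass and strict at 5 SD", {
  pan <- MetaboPanel("A", "amino_acid")
  # a symmetric two-spike column c(a, -a, 0 x 49) has mean exactly 0 and
  # z = +/- sqrt((n-1)/2) for the spikes: exactly 5 at n = 51
  m <- matrix(c(10, -10, rep(0, 49)) + 20, ncol = 1,
              dimnames = list(NULL, "A"))
  expect_equal((30 - mean(m)) / sd(m), 5)                    # exact boundary
  expect_equal(nrow(detectOutliers(toyCohort(m, pan))), 0L)  # strict: kept
  m2 <- matrix(c(10, -10, rep(0, 53)) + 20, ncol = 1,        # z ~ 5.24
               dimnames = list(NULL, "A"))
  out <- detectOutliers(toyCohort(m2, pan))
  expect_equal(nrow(out), 2L)
  expect_true(all(abs(out$z) > 5))

  mConst <- matrix(5, 20, 1, dimnames = list(NULL, "A"))
  expect_warning(none <- detectOutliers(toyCohort(mConst, pan)),
                 "zero-variance")
  expect_equal(nrow(none), 0L)
})

test_that("independent outliers are counted via dependency components", {
  pan <- MetaboPanel(paste0("M", 1:4), rep("amino_acid", 4))
  set.seed(12)
  n <- 200
  base <- rnorm(n)
  m <- cbind(M1 = base + rnorm(n, 0, 0.2),       # M1, M2 correlated ~0.9
             M2 = base + rnorm(n, 0, 0.2),
             M3 = rnorm(n), M4 = rnorm(n)) + 20
  m[1, c("M1", "M2")] <- 27                      # two dependent flags
  m[2, c("M1", "M3", "M4")] <- 27                # mostly independent flags
  co <- toyCohort(m, pan)
  out <- detectOutliers(co)
  counts <- independentOutlierGroups(co, out)
  expect_equal(counts[["S0001"]], 1L)
  expect_equal(counts[["S0002"]], 3L)

  # random fixture: component counts equal a hand-rolled BFS oracle
  bfsComponents <- function(adj) {
    nv <- nrow(adj); seen <- rep(FALSE, nv); comp <- 0L
    for (s in seq_len(nv)) {
      if (seen[s]) next
      comp <- comp + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (seen[v]) next
        seen[v] <- TRUE
        queue <- c(queue, which(adj[v, ] & !seen))
      }
    }
    comp
  }
  set.seed(77)
  for (rep in 1:5) {
    nm <- 6
    panr <- MetaboPanel(paste0("X", 1:nm), rep("amino_acid", nm))
    L <- matrix(rnorm(nm * nm), nm)
    mr <- matrix(rnorm(100 * nm), 100, nm) %*% L
    mr <- mr + abs(min(mr)) + 1
    colnames(mr) <- paste0("X", 1:nm)
    flagged <- sample(nm, 4)
    mr[1, flagged] <- max(mr) * 3
    cor6 <- cor(mr)
    cox <- toyCohort(mr, panr)
    outr <- detectOutliers(cox)
    cnt <- independentOutlierGroups(cox, outr)
    fl <- unique(outr$metabolite[outr$subject == "S0001"])
    adj <- abs(cor(mr[, fl, drop = FALSE])) >= 0.70
    diag(adj) <- FALSE
    expect_equal(cnt[["S0001"]], bfsComponents(adj))
  }
})

test_that("the subject policy drops at > 3 independent outliers only", {
  pan <- MetaboPanel(paste0("M", 1:8), rep("amino_acid", 8))
  set.seed(3)
  m <- matrix(rnorm(100 * 8, 50, 2), 100, 8,
              dimnames = list(NULL, paste0("M", 1:8)))
  m[1, 1:4] <- 70   # 4 independent outliers (columns share no other spikes)
  m[2, 5:7] <- 70   # 3 independent outliers
  co <- toyCohort(m, pan)
  out <- detectOutliers(co)
  counts <- independentOutlierGroups(co, out)
  pol <- applyOutlierPolicy(co, out, counts)
  expect_false("S0001" %in% colnames(pol$cohort))
  expect_true("S0002" %in% colnames(pol$cohort))
  expect_equal(sum(is.na(concentrations(pol$cohort)[, "S0002"])), 3L)
  expect_equal(pol$excludedSubjects$subject, "S0001")
  expect_equal(pol$excludedSubjects$n_independent_outliers, 4L)

  noOut <- detectOutliers(toyCohort(m[3:50, ], pan))
  polId <- applyOutlierPolicy(toyCohort(m[3:50, ], pan),
                              noOut[0, ], setNames(integer(0), character(0)))
  expect_equal(dim(polId$cohort), c(8L, 48L))
  expect_equal(sum(is.na(concentrations(polId$cohort))), 0L)
})

test_that("regression imputation is near-oracle and reproducible", {
  cfg <- simConfig(nSubjects = 400L, seed = 14, edgeDensity = 0.5,
                   panel = MetaboPanel(paste0("M", 1:12),
                                       rep("amino_acid", 12)),
                   effectTable = setNames(numeric(0), character(0)),
                   targetCv = 0.1)
  full <- simulateCohort(cfg)
  m <- concentrations(full)
  co0 <- toyCohort(t(m), panel(full))
  expect_identical(concentrations(imputeMissing(co0)$cohort), m)

  rmse <- function(a, b) sqrt(mean((a - b)^2))
  ratios <- vapply(1:3, function(s) {
    set.seed(100 + s)
    miss <- which(matrix(runif(length(m)) < 0.01, nrow(m)))
    mm <- m
    mm[miss] <- NA
    co <- toyCohort(t(mm), panel(full))
    imp <- suppressMessages(imputeMissing(co, seed = s, noise = FALSE))
    got <- log(concentrations(imp$cohort)[miss])
    # oracle: per-metabolite linear prediction from the true complete data
    lm_pred <- log(m)
    for (j in unique(((miss - 1L) %% nrow(m)) + 1L)) {
      idx <- miss[((miss - 1L) %% nrow(m)) + 1L == j]
      cols <- ((idx - 1L) %/% nrow(m)) + 1L
      preds <- setdiff(order(abs(cor(t(log(m)))[j, ]),
                             decreasing = TRUE), j)[1:10]
      fit <- lm.fit(cbind(1, t(log(m)[preds, ])), log(m)[j, ])
      lm_pred[j, cols] <- (cbind(1, t(log(m)[preds, cols, drop = FALSE])) %*%
                             fit$coefficients)
    }
    rmse(got, log(m)[miss]) / rmse(lm_pred[miss], log(m)[miss])
  }, numeric(1))
  expect_lt(mean(ratios), 1.1)

  set.seed(200)
  miss <- which(matrix(runif(length(m)) < 0.02, nrow(m)))
  mm <- m; mm[miss] <- NA
  co <- toyCohort(t(mm), panel(full))
  i1 <- imputeMissing(co, seed = 5)
  i2 <- imputeMissing(co, seed = 5)
  expect_identical(concentrations(i1$cohort), concentrations(i2$cohort))
  expect_equal(nrow(i1$imputed), length(miss))
})

test_that("runQC is deterministic, ordered and leaves no missing values", {
  cfg <- qcFixtureConfig(seed = 8)
  co <- simulateCohort(cfg)
  q1 <- suppressMessages(runQC(co, seed = 2))
  q2 <- suppressMessages(runQC(co, seed = 2))
  expect_identical(concentrations(q1), concentrations(q2))
  expect_equal(sum(is.na(concentrations(q1))), 0L)
  expect_true(all(rownames(q1) %in% rownames(co)))
  expect_true(all(colnames(q1) %in% colnames(co)))
  rep <- qcReport(q1)
  expect_true(all(rep@excludedMetabolites$reason %in% c("cv", "missingness")))
  # the report replays the transformation: excluded entities are really gone
  expect_length(intersect(rep@excludedMetabolites$metabolite, rownames(q1)), 0)
  expect_length(intersect(rep@excludedSubjects$subject, colnames(q1)), 0)
})
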