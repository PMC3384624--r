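# regress-each-pair-on-everything-else oracle for partial correlations
pcorOracle <- function(Z, X = NULL) {
  M <- ncol(Z)
  n <- nrow(Z)
  out <- diag(M)
  for (i in seq_len(M - 1)) for (j in (i + 1):M) {
    others <- Z[, -c(i, j), drop = FALSE]
    D <- cbind(1, X, others)
    ri <- qr.resid(qr(D), Z[, i])
    rj <- qr.resid(qr(D), Z[, j])
    out[i, j] <- out[j, i] <- cor(ri, rj)
  }
  dimnames(out) <- list(colnames(Z), colnames(Z))
  out
}

ggmCohort <- function(Z, pheno = NULL) {
  # Z: subjects x metabolites on the transformed scale; exponentiate so the
  # package's log z-score transform recovers it up to an affine map
  pan <- MetaboPanel(colnames(Z), rep("amino_acid", ncol(Z)))
  toyCohort(exp(Z), pan, pheno)
}

test_that("conditional independence in a Markov chain gives zero", {
  Sigma <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3)
  Z <- exactCovData(60, Sigma, seed = 2)
  colnames(Z) <- c("A", "B", "C")
  pcm <- partialCorrelations(ggmCohort(Z), covariates = character(0))
  expect_lt(abs(pcm@estimate["A", "C"]), 1e-10)
  expect_equal(diag(pcm@estimate), c(A = 1, B = 1, C = 1))
})

test_that("with two metabolites the estimate is the residual Pearson r", {
  set.seed(4)
  n <- 80
  ph <- toyPheno(n)
  Z <- cbind(A = rnorm(n) + 0.3 * ph$ffmi, B = rnorm(n) + 0.2 * ph$age / 10)
  Z[, 2] <- Z[, 2] + 0.5 * Z[, 1]
  co <- ggmCohort(Z, ph)
  pcm <- partialCorrelations(co, covariates = c("age", "sex", "ffmi"))
  X <- cbind(ph$age, as.numeric(ph$sex == "male"), ph$ffmi)
  zz <- apply(Z, 2, function(v) (v - mean(v)) / sd(v))
  ra <- qr.resid(qr(cbind(1, X)), zz[, 1])
  rb <- qr.resid(qr(cbind(1, X)), zz[, 2])
  expect_equal(pcm@estimate["A", "B"], cor(ra, rb), tolerance = 1e-10)
  expect_equal(pcm@nControls, 3L)   # covariates only, M - 2 = 0
})

test_that("precision route equals the brute-force regression oracle", {
  set.seed(11)
  for (rep in 1:10) {
    M <- sample(4:8, 1)
    n <- 40 + M
    A <- matrix(rnorm(M * M), M)
    Sigma <- crossprod(A) + diag(M)
    Z <- exactCovData(n, Sigma, seed = rep)
    colnames(Z) <- paste0("V", seq_len(M))
    ph <- toyPheno(n, seed = 5000 + rep)   # independent of the latent draws
    pcm <- partialCorrelations(ggmCohort(Z, ph),
                               covariates = c("age", "ffmi"))
    zz <- apply(Z, 2, function(v) (v - mean(v)) / sd(v))
    oracle <- pcorOracle(zz, X = cbind(ph$age, ph$ffmi))
    expect_equal(pcm@estimate, oracle, tolerance = 1e-10)
  }
})

test_that("partial correlations are invariant to per-metabolite rescaling", {
  set.seed(20)
  Z <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("V", 1:4)))
  co <- ggmCohort(Z)
  p1 <- partialCorrelations(co, covariates = character(0))
  co2 <- co
  concentrations(co2) <- concentrations(co)^1 *
    matrix(c(1000, 0.01, 7, 1), 4, 50)
  p2 <- partialCorrelations(co2, covariates = character(0))
  expect_equal(p1@estimate, p2@estimate, tolerance = 1e-12)
})

test_that("Fisher-z edge tests match the normal-CDF oracle", {
  mk <- function(r, n, k) {
    est <- diag(2)
    est[1, 2] <- est[2, 1] <- r
    dimnames(est) <- list(c("A", "B"), c("A", "B"))
    new("PartialCorrelationMatrix", estimate = est, nSamples = as.integer(n),
        nControls = as.integer(k), ridge = 0)
  }
  et0 <- testEdges(mk(0, 100, 3))
  expect_equal(et0$p_partial, 1)

  et <- testEdges(mk(0.3, 965, 167))
  oracle <- 2 * pnorm(abs(atanh(0.3) * sqrt(965 - 167 - 3)),
                      lower.tail = FALSE)
  expect_equal(et$p_partial, oracle, tolerance = 1e-10)

  ps <- vapply(c(300, 500, 965, 2000), function(n)
    testEdges(mk(0.2, n, 167))$p_partial, numeric(1))
  expect_true(all(diff(ps) < 0))            # p strictly decreasing in n
  expect_error(testEdges(mk(0.2, 100, 167)), "too few samples")
})

test_that("network assembly enforces both the test and the |r| cutoff", {
  est <- diag(3)
  est[1, 2] <- est[2, 1] <- 0.29
  est[1, 3] <- est[3, 1] <- 0.35
  est[2, 3] <- est[3, 2] <- 0.01
  dimnames(est) <- list(c("A", "B", "C"), c("A", "B", "C"))
  pcm <- new("PartialCorrelationMatrix", estimate = est,
             nSamples = 965L, nControls = 4L, ridge = 0)
  et <- testEdges(pcm, alpha = 0.01)
  assoc <- S4Vectors::DataFrame(trait = c("A", "B"),
                                beta = c(0.2, -0.1),
                                p = c(1e-6, 1e-5),
                                significant = c(TRUE, TRUE))
  expect_warning(net <- buildNetwork(pcm, et, assoc, r_cutoff = 0.3),
                 "coloured white")
  edges <- net@edges
  expect_equal(nrow(edges), 1L)             # only the 0.35 edge survives
  expect_setequal(c(edges$from, edges$to), c("A", "C"))
  cols <- setNames(net@nodes$colour, net@nodes$metabolite)
  expect_equal(cols[["A"]], "red")
  expect_equal(cols[["B"]], "blue")
  expect_equal(cols[["C"]], "white")
})

test_that("network export round-trips attributes in every format", {
  est <- diag(3)
  est[1, 2] <- est[2, 1] <- 0.42345678901234
  dimnames(est) <- list(c("A", "B", "C"), c("A", "B", "C"))
  pcm <- new("PartialCorrelationMatrix", estimate = est,
             nSamples = 965L, nControls = 4L, ridge = 0)
  et <- testEdges(pcm)
  assoc <- S4Vectors::DataFrame(trait = c("A", "B", "C"),
                                beta = c(0.123456789012345, -0.2, 0),
                                p = c(1e-7, 1e-3, 0.5),
                                significant = c(TRUE, FALSE, FALSE))
  net <- buildNetwork(pcm, et, assoc)
  for (fmt in c("graphml", "gml", "tsv_edgelist")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    exportNetwork(net, f, format = fmt)
    back <- readNetwork(f, format = fmt)
    idx <- match(net@nodes$metabolite, back@nodes$metabolite)
    expect_equal(back@nodes$beta[idx], net@nodes$beta, tolerance = 1e-12)
    expect_equal(back@nodes$colour[idx], net@nodes$colour)
    expect_equal(nrow(back@edges), nrow(net@edges))
    expect_equal(sort(back@edges$r_partial), sort(net@edges$r_partial),
                 tolerance = 1e-12)
  }
  # empty network still exports a valid file
  emptyNet <- buildNetwork(pcm, et[et$p_partial > 2, ], assoc)
  f2 <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(emptyNet, f2, format = "graphml")
  back2 <- readNetwork(f2, format = "graphml")
  expect_equal(nrow(back2@edges), 0L)
  expect_equal(nrow(back2@nodes), 3L)
})

test_that("population partial correlations vanish off the planted edges", {
  cfg <- simConfig(seed = 6)
  prec <- generatePrecisionMatrix(cfg)
  pc <- prec$partialCor
  onEdge <- prec$precision != 0 & row(prec$precision) != col(prec$precision)
  expect_true(all(pc[upper.tri(pc)][!onEdge[upper.tri(onEdge)]] == 0))
  # and from the covariance side: Sigma -> -cov2cor(solve(Sigma)) recovers it
  Sigma <- chol2inv(chol(prec$precision))
  om <- solve(Sigma)
  rec <- -om / sqrt(outer(diag(om), diag(om)))
  diag(rec) <- 1
  expect_equal(unname(rec), unname(pc), tolerance = 1e-8)
})
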