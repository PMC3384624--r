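#' Full-order partial correlations between metabolites
#'
#' Covariates (by default age, sex and the exposure FFMI; add batch for
#' multi-batch data) are removed from every transformed metabolite by linear
#' residualisation; the precision matrix of the residuals then yields the
#' partial correlation of each metabolite pair conditioned on the covariates
#' and all remaining metabolites:
#' \eqn{\rho_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}}}.
#'
#' @param cohort a QC'd [MetaboCohort-class]; requires
#'   `n_subjects > n_metabolites + n_covariates + 3`.
#' @param covariates phenotype columns to residualise out.
#' @param transform transform kind.
#' @param ridge ridge added to the residual covariance before inversion
#'   (default 0; a positive value marks the result as regularised, for use
#'   when M approaches n).
#' @return a [PartialCorrelationMatrix-class].
#' @export
partialCorrelations <- function(cohort, covariates = c("age", "sex", "ffmi"),
                                transform = "lognormal_z", ridge = 0) {
  m <- concentrations(cohort)
  pheno <- phenotypes(cohort)
  covariates <- usableCovariates(pheno, covariates)
  M <- nrow(m)
  n <- ncol(m)
  nCov <- length(covariates)
  if (n <= M + nCov + 3)
    stop("need n_subjects > n_metabolites + n_covariates + 3 ",
         "(n = ", n, ", M = ", M, ", covariates = ", nCov, ")")
  z <- transformConcentrations(m, kind = transform)
  X <- if (length(covariates))
    buildDesign(pheno, exposure = covariates[1], covariates = covariates[-1])
  else matrix(1, n, 1)
  res <- qr.resid(qr(X), t(z))
  S <- cov(res)
  if (ridge > 0) S <- S + ridge * diag(M)
  omega <- tryCatch(chol2inv(chol(S)), error = function(e)
    stop("residual covariance is singular; consider the ridge option ",
         "(ridge > 0)"))
  pc <- -omega / sqrt(outer(diag(omega), diag(omega)))
  diag(pc) <- 1
  dimnames(pc) <- list(rownames(m), rownames(m))
  new("PartialCorrelationMatrix", estimate = pc, nSamples = n,
      nControls = as.integer(nCov + M - 2L), ridge = ridge)
}

setMethod("show", "PartialCorrelationMatrix", function(object) {
  cat("PartialCorrelationMatrix: ", nrow(object@estimate), " metabolites, n = ",
      object@nSamples, ", k = ", object@nControls,
      if (object@ridge > 0) paste0(" (regularised, ridge = ", object@ridge, ")"),
      "\n", sep = "")
})

#' Fisher-z significance tests for partial-correlation edges
#'
#' For each pair, `z = atanh(r) * sqrt(n - k - 3)` with `k` the number of
#' conditioned variables (covariates plus the M - 2 remaining metabolites);
#' two-sided normal p-values, compared against the Bonferroni bound
#' `alpha / choose(M, 2)`.
#'
#' @param pcm a [PartialCorrelationMatrix-class].
#' @param alpha family-wise level (default 0.01).
#' @return `data.frame`: from, to, r_partial, p_partial, significant; the
#'   Bonferroni bound is attached as attribute `"bound"`.
#' @export
testEdges <- function(pcm, alpha = 0.01) {
  r <- pcm@estimate
  M <- nrow(r)
  df <- pcm@nSamples - pcm@nControls - 3L
  if (df <= 0)
    stop("n - k - 3 <= 0: too few samples for the Fisher-z test")
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  zstat <- atanh(pmin(pmax(rv, -1 + 1e-15), 1 - 1e-15)) * sqrt(df)
  p <- 2 * pnorm(abs(zstat), lower.tail = FALSE)
  bound <- alpha / choose(M, 2)
  out <- data.frame(from = rownames(r)[ut[, 1]], to = colnames(r)[ut[, 2]],
                    r_partial = rv, p_partial = p,
                    significant = p < bound, stringsAsFactors = FALSE)
  attr(out, "bound") <- bound
  attr(out, "alpha") <- alpha
  out
}

#' Assemble the Gaussian graphical model network
#'
#' Edges are the tested pairs that are Bonferroni-significant AND have
#' `|r_partial| >= r_cutoff` (inclusive).  Nodes are coloured from the
#' single-metabolite association results: red for a significant positive
#' beta, blue for a significant negative beta, white otherwise; metabolites
#' absent from the association results become white nodes with a warning.
#'
#' @param pcm a [PartialCorrelationMatrix-class].
#' @param edge_tests output of [testEdges()].
#' @param assoc result of [mwas()] (may be NULL: all nodes white).
#' @param r_cutoff partial-correlation magnitude cutoff (default 0.3).
#' @return a [GgmNetwork-class].
#' @export
buildNetwork <- function(pcm, edge_tests, assoc = NULL, r_cutoff = 0.3) {
  mets <- rownames(pcm@estimate)
  beta <- setNames(rep(NA_real_, length(mets)), mets)
  p <- setNames(rep(NA_real_, length(mets)), mets)
  sig <- setNames(rep(FALSE, length(mets)), mets)
  if (!is.null(assoc)) {
    known <- intersect(mets, assoc$trait)
    idx <- match(known, assoc$trait)
    beta[known] <- assoc$beta[idx]
    p[known] <- assoc$p[idx]
    sig[known] <- assoc$significant[idx]
    orphan <- setdiff(mets, assoc$trait)
    if (length(orphan))
      warning(length(orphan), " metabolite(s) missing from association ",
              "results; coloured white: ",
              paste(head(orphan, 5), collapse = ", "))
  }
  colour <- ifelse(sig & !is.na(beta) & beta > 0, "red",
                   ifelse(sig & !is.na(beta) & beta < 0, "blue", "white"))
  nodes <- data.frame(metabolite = mets, colour = colour, beta = beta,
                      p = p, significant = sig,
                      stringsAsFactors = FALSE, row.names = NULL)
  e <- edge_tests
  e$passes_cutoff <- abs(e$r_partial) >= r_cutoff
  edges <- e[e$significant & e$passes_cutoff, , drop = FALSE]
  rownames(edges) <- NULL
  new("GgmNetwork", nodes = nodes, edges = edges, rCutoff = r_cutoff,
      alpha = attr(edge_tests, "alpha") %||% 0.01)
}

setMethod("show", "GgmNetwork", function(object) {
  cat("GgmNetwork: ", nrow(object@nodes), " nodes, ", nrow(object@edges),
      " edges (|r| >= ", object@rCutoff, ", alpha = ", object@alpha, ")\n",
      sep = "")
  cat("  node colours:",
      paste(names(table(object@nodes$colour)),
            table(object@nodes$colour), collapse = ", "), "\n")
})
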