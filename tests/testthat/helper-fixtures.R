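# Small in-code fixtures shared across tests.

smallPanel <- function() {
  MetaboPanel(c("Val", "Ile", "Leu", "Gly", "C0", "C3"),
              c("amino_acid", "amino_acid", "amino_acid", "amino_acid",
                "acylcarnitine", "acylcarnitine"))
}

# cohort from an explicit subjects x metabolites matrix
toyCohort <- function(m, panel, pheno = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%04d", seq_len(nrow(m)))
  MetaboCohort(t(m), panel, phenotypes = pheno)
}

# phenotype table with independent covariates for model tests
toyPheno <- function(n, seed = 1) {
  withr::with_seed(seed, {
    data.frame(age = rnorm(n, 60, 5),
               sex = factor(sample(c("female", "male"), n, TRUE),
                            levels = c("female", "male")),
               ffmi = rnorm(n, 18, 2),
               row.names = sprintf("S%04d", seq_len(n)))
  })
}

# reference replicates with the exact values supplied per plate
refsFromList <- function(metabolite, plateValues) {
  d <- do.call(rbind, lapply(seq_along(plateValues), function(i) {
    data.frame(plate = i, metabolite = metabolite,
               value = plateValues[[i]], stringsAsFactors = FALSE)
  }))
  new("ReferenceReplicates", data = d)
}

# data matrix (n x M) whose sample covariance is exactly Sigma
exactCovData <- function(n, Sigma, seed = 1) {
  M <- ncol(Sigma)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * M), n, M)
    X <- scale(X, center = TRUE, scale = FALSE)
    W <- chol(cov(X))
    Z <- X %*% solve(W) %*% chol(Sigma)
    Z
  })
}
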