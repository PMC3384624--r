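#' Composite amino-acid and lipid sum traits
#'
#' The standard sum traits treated as additional association traits: sum of
#' BCAAs (valine + isoleucine + leucine), sum of aromatic amino acids
#' (tyrosine + phenylalanine + tryptophan), sum of glucogenic amino acids
#' (alanine + glycine + serine), sum of all PC ae species and sum of all
#' lysoPC species.  Sums are raw concentrations in micromol/l; components
#' missing from the cohort cause the trait to be skipped with a message.
#'
#' @param cohort a [MetaboCohort-class].
#' @return matrix (composite traits x subjects).
#' @export
compositeTraits <- function(cohort) {
  m <- concentrations(cohort)
  cls <- chemClass(cohort)
  defs <- list(`Sum BCAAs` = c("Val", "Ile", "Leu"),
               `Sum aromatic AAs` = c("Tyr", "Phe", "Trp"),
               `Sum glucogenic AAs` = c("Ala", "Gly", "Ser"),
               `Sum PC ae` = names(cls)[cls == "PC_ae"],
               `Sum lysoPC` = names(cls)[cls == "lysoPC"])
  rows <- lapply(names(defs), function(nm) {
    comp <- defs[[nm]]
    if (!length(comp) || !all(comp %in% rownames(m))) {
      message("composite trait skipped (missing components): ", nm)
      return(NULL)
    }
    colSums(m[comp, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(defs)[keep]
  out
}

#' Append composite traits to a cohort
#'
#' Adds the [compositeTraits()] rows to the concentration matrix with
#' chemical class `"composite"`; composites take part in the
#' metabolome-wide association but are excluded from ratio enumeration and
#' from the GGM.
#'
#' @param cohort a [MetaboCohort-class].
#' @return an extended [MetaboCohort-class].
#' @export
addCompositeTraits <- function(cohort) {
  comp <- compositeTraits(cohort)
  if (is.null(comp) || !nrow(comp)) return(cohort)
  p <- panel(cohort)
  info <- rbind(as.data.frame(p@info),
                data.frame(name = rownames(comp),
                           chem_class = "composite",
                           carbons = NA_integer_, double_bonds = NA_integer_))
  newPanel <- new("MetaboPanel", panelName = p@panelName,
                  info = S4Vectors::DataFrame(info))
  md <- S4Vectors::metadata(cohort)
  out <- MetaboCohort(rbind(concentrations(cohort), comp), newPanel,
                      phenotypes = phenotypes(cohort))
  S4Vectors::metadata(out) <- md
  out
}

#' Quintile assignment
#'
#' Subjects are ranked on `x` (ties broken by input order) and split into
#' five groups whose sizes differ by at most one; boundary values fall to
#' the lower quintile.
#'
#' @param x numeric vector.
#' @return integer vector of quintile indices 1-5.
#' @export
assignQuintiles <- function(x) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(5 * r / length(x)))
}

#' Association result table (trait-level summary)
#'
#' Combines single-metabolite and ratio results into one table with the
#' columns of a standard trait summary: trait, raw-scale mean and SD,
#' direction, p-value, adjusted R^2 and (for ratios) the p-gain.
#'
#' @param cohort the QC'd [MetaboCohort-class] the results were computed on.
#' @param single [mwas()] result.
#' @param ratios optional [ratioMwas()] result.
#' @param significant_only keep only significant traits (default TRUE).
#' @return `data.frame` sorted by p-value.
#' @export
traitSummaryTable <- function(cohort, single, ratios = NULL,
                              significant_only = TRUE) {
  m <- concentrations(cohort)
  s <- as.data.frame(single)
  s$mean <- rowMeans(m)[s$trait]
  s$sd <- apply(m, 1, sd)[s$trait]
  s$p_gain <- rep(NA_real_, nrow(s))
  tab <- s[, c("trait", "mean", "sd", "direction", "p", "r2_adj", "p_gain",
               "significant")]
  if (!is.null(ratios) && nrow(ratios)) {
    r <- as.data.frame(ratios)
    rv <- m[r$numerator, , drop = FALSE] / m[r$denominator, , drop = FALSE]
    tab2 <- data.frame(trait = paste(r$numerator, r$denominator, sep = "/"),
                       mean = rowMeans(rv), sd = apply(rv, 1, sd),
                       direction = r$direction, p = r$p, r2_adj = r$r2_adj,
                       p_gain = r$p_gain, significant = r$significant,
                       stringsAsFactors = FALSE)
    tab <- rbind(tab, tab2)
  }
  if (significant_only) tab <- tab[!is.na(tab$p) & tab$significant, ]
  tab <- tab[order(tab$p), ]
  rownames(tab) <- NULL
  tab
}

#' Stratified comparison table
#'
#' Side-by-side betas, p-values and adjusted R^2 for two strata (e.g. obese
#' vs non-obese), one row per trait.
#'
#' @param strat named list of [mwas()] results from [stratifiedMwas()].
#' @return `data.frame` with one beta/p/r2_adj column set per stratum.
#' @export
stratifiedSummaryTable <- function(strat) {
  stopifnot(length(strat) >= 1)
  base <- data.frame(trait = strat[[1]]$trait, stringsAsFactors = FALSE)
  for (nm in names(strat)) {
    s <- as.data.frame(strat[[nm]])
    idx <- match(base$trait, s$trait)
    base[[paste0("beta_", nm)]] <- s$beta[idx]
    base[[paste0("p_", nm)]] <- s$p[idx]
    base[[paste0("r2_adj_", nm)]] <- s$r2_adj[idx]
  }
  base
}

#' Cohort characteristics by quintiles of a trait
#'
#' Mean and SD of the continuous phenotypes (and percentages of the discrete
#' ones) within quintiles of a chosen variable, e.g. the sum of BCAAs.
#'
#' @param cohort a [MetaboCohort-class].
#' @param values numeric vector over subjects defining the quintiles (e.g. a
#'   row of [compositeTraits()]).
#' @param phenoVars continuous phenotype columns to summarise.
#' @return `data.frame`: one row per statistic, one column per quintile,
#'   plus the quintile concentration ranges.
#' @export
quintileTable <- function(cohort, values,
                          phenoVars = c("age", "weight", "height", "bmi",
                                        "ffm", "fm", "ffmi", "bfmi")) {
  pheno <- as.data.frame(phenotypes(cohort))
  phenoVars <- intersect(phenoVars, colnames(pheno))
  q <- assignQuintiles(values)
  fmt <- function(v) vapply(1:5, function(k)
    sprintf("%.2f+-%.2f", mean(v[q == k]), sd(v[q == k])), character(1))
  rows <- list(`range` = vapply(1:5, function(k)
    sprintf("%.4g-%.4g", min(values[q == k]), max(values[q == k])),
    character(1)))
  for (pv in phenoVars) rows[[pv]] <- fmt(pheno[[pv]])
  if ("sex" %in% colnames(pheno)) {
    rows[["pct_male"]] <- vapply(1:5, function(k)
      sprintf("%.2f%% (%d)", 100 * mean(pheno$sex[q == k] == "male"),
              sum(pheno$sex[q == k] == "male")), character(1))
  }
  if ("activity" %in% colnames(pheno)) {
    rows[["pct_active"]] <- vapply(1:5, function(k)
      sprintf("%.2f%% (%d)", 100 * mean(pheno$activity[q == k] == "active"),
              sum(pheno$activity[q == k] == "active")), character(1))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(out) <- paste0("Q", 1:5)
  cbind(statistic = names(rows), out, row.names = NULL)
}

#' Long-format data for a boxplot by exposure quintile
#'
#' One row per subject with the exposure quintile and the chosen variable,
#' ready for plotting a concentration-by-quintile boxplot.
#'
#' @param cohort a [MetaboCohort-class].
#' @param values numeric vector over subjects (the plotted variable).
#' @param exposure phenotype column defining the quintiles (default
#'   `"ffmi"`).
#' @return `data.frame`: subject, quintile, exposure value, variable value.
#' @export
quintileLong <- function(cohort, values, exposure = "ffmi") {
  pheno <- phenotypes(cohort)
  ev <- pheno[[exposure]]
  data.frame(subject = colnames(cohort),
             quintile = assignQuintiles(ev),
             exposure = ev, value = as.numeric(values),
             stringsAsFactors = FALSE)
}
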