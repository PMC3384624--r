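#' Published KORA S4 association summary
#'
#' The packaged reference table of selected metabolic traits significantly
#' associated with FFMI in the KORA S4 cohort (n = 965; linear models
#' adjusted for age and sex): raw-scale mean and SD in micromol/l,
#' association direction, multiple-testing-adjusted p-value, adjusted R^2
#' and, for ratio traits, the printed p-gain.  The
#' `internally_consistent` flag marks the seven ratio rows whose printed
#' p-gain is exactly reproduced (to 3 significant figures) by
#' `min(printed single p-values) / printed ratio p-value`; for the flagged
#' rows with only one constituent printed, that single p-value is the
#' minimum.  The table doubles as the source of the simulator's default
#' concentration targets.
#'
#' @return `data.frame` with columns `trait`, `mean_umol_l`, `sd_umol_l`,
#'   `direction`, `p_adj`, `r2_adj`, `p_gain`, `internally_consistent`.
#' @examples
#' head(reportedAssociations())
#' @export
reportedAssociations <- function() {
  path <- system.file("extdata", "kora_s4_reported_traits.tsv",
                      package = "metabnet", mustWork = TRUE)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                  fill = TRUE)
  d$internally_consistent[is.na(d$internally_consistent)] <- 0
  d$internally_consistent <- d$internally_consistent == 1
  d
}

#' Recompute p-gains from the published summary
#'
#' For each ratio row of [reportedAssociations()] whose constituents can be
#' looked up in the same table, recomputes
#' `p_gain = min(single p-values) / ratio p-value` and compares it with the
#' printed value.
#'
#' @param consistent_only restrict to the internally consistent rows
#'   (default TRUE).
#' @return `data.frame`: trait, printed p-gain, recomputed p-gain, and their
#'   agreement at 3 significant figures.
#' @export
recomputeReportedPGains <- function(consistent_only = TRUE) {
  d <- reportedAssociations()
  singles <- d[!grepl("/", d$trait, fixed = TRUE), ]
  lookup <- setNames(singles$p_adj, singles$trait)
  ratios <- d[grepl("/", d$trait, fixed = TRUE) & !is.na(d$p_gain), ]
  if (consistent_only) ratios <- ratios[ratios$internally_consistent, ]
  parts <- strsplit(ratios$trait, "/", fixed = TRUE)
  rec <- vapply(seq_len(nrow(ratios)), function(i) {
    ps <- lookup[parts[[i]]]
    ps <- ps[!is.na(ps)]
    if (!length(ps)) return(NA_real_)
    min(ps) / ratios$p_adj[i]
  }, numeric(1))
  data.frame(trait = ratios$trait, printed = ratios$p_gain, recomputed = rec,
             agree_3sf = signif(rec, 3) == signif(ratios$p_gain, 3),
             stringsAsFactors = FALSE, row.names = NULL)
}
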