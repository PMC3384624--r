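#' Construct a metabolite panel
#'
#' @param name character vector of metabolite identifiers (unique).
#' @param chem_class character vector of chemical classes, one of
#'   [metaboliteClasses()].
#' @param carbons,double_bonds optional integer vectors (NA where not
#'   applicable); when omitted they are parsed from `Cx:y` substrings of the
#'   names, the standard abbreviation for a lipid side chain with `x` carbons
#'   and `y` double bonds.
#' @param panelName label for the panel (e.g. `"p180"`).
#' @return a [MetaboPanel-class].
#' @examples
#' MetaboPanel(c("Val", "PC aa C38:3"), c("amino_acid", "PC_aa"))
#' @export
MetaboPanel <- function(name, chem_class, carbons = NULL, double_bonds = NULL,
                        panelName = "custom") {
  name <- as.character(name)
  if (is.null(carbons) || is.null(double_bonds)) {
    xy <- parseSideChain(name)
    if (is.null(carbons)) carbons <- xy$carbons
    if (is.null(double_bonds)) double_bonds <- xy$double_bonds
  }
  info <- S4Vectors::DataFrame(name = name,
                               chem_class = as.character(chem_class),
                               carbons = as.integer(carbons),
                               double_bonds = as.integer(double_bonds))
  new("MetaboPanel", panelName = panelName, info = info)
}

#' Parse lipid side-chain composition from metabolite names
#'
#' @param name character vector.
#' @return list with integer vectors `carbons` and `double_bonds` (NA where
#'   no `Cx:y` pattern is present).
#' @keywords internal
parseSideChain <- function(name) {
  m <- regmatches(name, regexpr("C[0-9]+:[0-9]+", name))
  has <- grepl("C[0-9]+:[0-9]+", name)
  carbons <- double_bonds <- rep(NA_integer_, length(name))
  if (any(has)) {
    parts <- strsplit(sub("^C", "", m), ":", fixed = TRUE)
    carbons[has] <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    double_bonds[has] <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  }
  list(carbons = carbons, double_bonds = double_bonds)
}

#' Read a panel definition file
#'
#' Tab-separated file with columns `name`, `chem_class` and optionally
#' `carbons`, `double_bonds`.
#'
#' @param path file path.
#' @param panelName panel label; defaults to the file base name.
#' @return a [MetaboPanel-class].
#' @export
readPanel <- function(path, panelName = sub("\\.tsv$", "", basename(path))) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("name", "chem_class") %in% colnames(d)))
    stop("panel file must have columns 'name' and 'chem_class': ", path)
  MetaboPanel(d$name, d$chem_class,
              carbons = if ("carbons" %in% colnames(d)) d$carbons,
              double_bonds = if ("double_bonds" %in% colnames(d)) d$double_bonds,
              panelName = panelName)
}

#' Packaged panel presets
#'
#' The two shipped panel definitions: `"p180"` (186 metabolites: 21 amino
#' acids, 19 biogenic amines, 40 acylcarnitines including free carnitine,
#' 14 lysoPC, 38 PC aa, 38 PC ae, 15 sphingomyelins, hexose) and `"p150"`
#' (163 metabolites, no biogenic amines, leucine and isoleucine combined as
#' xLeu).  The diacyl/acyl-alkyl split of the phosphatidylcholines is a
#' convention of these presets; user panel files override the presets.
#'
#' @param name `"p180"` or `"p150"`.
#' @return a [MetaboPanel-class].
#' @examples
#' length(panelPreset("p180"))  # 186
#' @export
panelPreset <- function(name = c("p180", "p150")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("panel_", name, ".tsv"),
                      package = "metabnet", mustWork = TRUE)
  readPanel(path, panelName = name)
}

#' @describeIn MetaboPanel number of metabolites
#' @param x a `MetaboPanel`.
#' @export
setMethod("length", "MetaboPanel", function(x) nrow(x@info))

#' @describeIn MetaboPanel metabolite identifiers
#' @export
setMethod("names", "MetaboPanel", function(x) x@info$name)

#' @describeIn MetaboPanel chemical class per metabolite (named)
#' @export
setMethod("chemClass", "MetaboPanel",
          function(x) setNames(x@info$chem_class, x@info$name))

#' @describeIn MetaboPanel subset a panel by metabolite name or index
#' @param i index or character vector of metabolite names.
#' @param j,drop unused.
#' @param ... unused.
#' @export
setMethod("[", "MetaboPanel", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$name)
  if (anyNA(i)) stop("unknown metabolite name in panel subset")
  initialize(x, info = x@info[i, , drop = FALSE])
})

setMethod("show", "MetaboPanel", function(object) {
  cat("MetaboPanel '", object@panelName, "': ", nrow(object@info),
      " metabolites\n", sep = "")
  tab <- table(factor(object@info$chem_class, levels = metaboliteClasses()))
  print(tab[tab > 0])
})
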