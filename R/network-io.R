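#' Export a GGM network
#'
#' Writes the network with node attributes (colour, beta, p) and edge
#' attributes (r_partial, p_partial) as GraphML or GML (via igraph, full
#' double precision) or as a TSV edge list with a companion `<path>.nodes.tsv`
#' node table.  [readNetwork()] round-trips all attribute values exactly.
#'
#' @param net a [GgmNetwork-class].
#' @param path output file path.
#' @param format `"graphml"`, `"gml"` or `"tsv_edgelist"`.
#' @return the path, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "gml",
                                                "tsv_edgelist")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", dir, ": no such directory")
  if (format == "tsv_edgelist") {
    e <- net@edges[, c("from", "to", "r_partial", "p_partial"), drop = FALSE]
    writeTsv17 <- function(d, f) {
      for (cn in colnames(d)) if (is.numeric(d[[cn]]))
        d[[cn]] <- sprintf("%.17g", d[[cn]])
      write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeTsv17(e, path)
    n <- net@nodes[, c("metabolite", "colour", "beta", "p"), drop = FALSE]
    writeTsv17(n, paste0(path, ".nodes.tsv"))
    return(invisible(path))
  }
  g <- asIgraph(net)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Convert a GgmNetwork to an igraph object
#'
#' @param net a [GgmNetwork-class].
#' @return an igraph graph with the node and edge attributes.
#' @export
asIgraph <- function(net) {
  nodes <- net@nodes
  edges <- net@edges
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) edges[, c("from", "to", "r_partial", "p_partial")]
        else data.frame(from = character(), to = character(),
                        r_partial = numeric(), p_partial = numeric()),
    directed = FALSE,
    vertices = data.frame(name = nodes$metabolite, colour = nodes$colour,
                          beta = ifelse(is.na(nodes$beta), 0, nodes$beta),
                          p = ifelse(is.na(nodes$p), 1, nodes$p),
                          stringsAsFactors = FALSE))
  g
}

#' Re-import an exported network
#'
#' @param path file written by [exportNetwork()].
#' @param format the format it was written in.
#' @param r_cutoff,alpha thresholds to record on the rebuilt object.
#' @return a [GgmNetwork-class].
#' @export
readNetwork <- function(path, format = c("graphml", "gml", "tsv_edgelist"),
                        r_cutoff = 0.3, alpha = 0.01) {
  format <- match.arg(format)
  if (format == "tsv_edgelist") {
    e <- read.delim(path, stringsAsFactors = FALSE)
    n <- read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE)
    nodes <- data.frame(metabolite = as.character(n$metabolite),
                        colour = n$colour, beta = n$beta, p = n$p,
                        significant = n$colour != "white",
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = as.character(e$from), to = as.character(e$to),
                        r_partial = e$r_partial, p_partial = e$p_partial,
                        significant = rep(TRUE, nrow(e)),
                        passes_cutoff = rep(TRUE, nrow(e)),
                        stringsAsFactors = FALSE)
    return(new("GgmNetwork", nodes = nodes, edges = edges,
               rCutoff = r_cutoff, alpha = alpha))
  }
  g <- igraph::read_graph(path, format = format)
  va <- igraph::vertex_attr(g)
  nm <- if (!is.null(va$name)) va$name else as.character(va$id)
  nodes <- data.frame(metabolite = nm, colour = va$colour, beta = va$beta,
                      p = va$p, significant = va$colour != "white",
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  ea <- igraph::edge_attr(g)
  edges <- data.frame(from = if (nrow(el)) el[, 1] else character(),
                      to = if (nrow(el)) el[, 2] else character(),
                      # GML drops underscores from attribute names
                      r_partial = ea$r_partial %||% ea$rpartial %||% numeric(),
                      p_partial = ea$p_partial %||% ea$ppartial %||% numeric(),
                      significant = rep(TRUE, nrow(el)),
                      passes_cutoff = rep(TRUE, nrow(el)),
                      stringsAsFactors = FALSE)
  new("GgmNetwork", nodes = nodes, edges = edges, rCutoff = r_cutoff,
      alpha = alpha)
}
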