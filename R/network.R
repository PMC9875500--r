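#' Read a protein-protein interaction edge list
#'
#' Reads a STRING-style whitespace- or tab-delimited edge list with two
#' gene-symbol columns and an optional confidence score column. A header row
#' is auto-detected (a non-numeric cell in the score column, or no score
#' column and a first row matching common STRING column names). Symmetric
#' duplicates (A,B)/(B,A) are collapsed and self-loops dropped with a
#' reported count.
#'
#' @param path edge-list file.
#' @param score_column name of the confidence column (e.g.
#'   `"combined_score"`), required when `min_score` is given.
#' @param min_score edges scoring below this are removed. STRING scores run
#'   0-1000; 400 is the conventional medium-confidence cutoff.
#' @return data.frame with columns `from`, `to` (lexicographically ordered
#'   within each row, unique rows).
#' @export
load_edge_list <- function(path, score_column = NULL, min_score = NULL) {
  if (!file.exists(path)) stop("edge list not found: ", path, call. = FALSE)
  first <- strsplit(trimws(readLines(path, n = 1L)), "[\t ]+")[[1L]]
  looks_header <- length(first) >= 3L &&
    is.na(suppressWarnings(as.numeric(first[3L]))) ||
    any(tolower(first) %in% c("protein1", "protein2", "gene1", "gene2",
                              "combined_score", "score", "from", "to"))
  tab <- utils::read.table(path, header = looks_header,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  if (ncol(tab) < 2L) stop("edge list needs at least two columns", call. = FALSE)
  bad <- which(is.na(tab[[1L]]) | is.na(tab[[2L]]) |
                 trimws(tab[[1L]]) == "" | trimws(tab[[2L]]) == "")
  if (length(bad))
    stop(sprintf("malformed edge at line %d of %s",
                 bad[1L] + as.integer(looks_header), path), call. = FALSE)
  a <- trimws(as.character(tab[[1L]]))
  b <- trimws(as.character(tab[[2L]]))

  if (!is.null(min_score)) {
    if (is.null(score_column))
      stop("`min_score` given but no `score_column` named", call. = FALSE)
    if (!score_column %in% colnames(tab))
      stop("score column '", score_column, "' not found", call. = FALSE)
    s <- suppressWarnings(as.numeric(tab[[score_column]]))
    if (anyNA(s))
      stop(sprintf("non-numeric score at line %d",
                   which(is.na(s))[1L] + as.integer(looks_header)),
           call. = FALSE)
    keep <- s >= min_score
    a <- a[keep]; b <- b[keep]
  }

  loops <- a == b
  if (any(loops))
    message(sprintf("load_edge_list: dropped %d self-loop(s)", sum(loops)))
  a2 <- pmin(a[!loops], b[!loops])
  b2 <- pmax(a[!loops], b[!loops])
  keep <- !duplicated(paste(a2, b2, sep = "\r"))
  data.frame(from = a2[keep], to = b2[keep], stringsAsFactors = FALSE)
}

#' Build the global template network
#'
#' Restricts a PPI edge set to the measured genes and drops every node that
#' becomes isolated under that restriction, yielding the undirected template
#' graph from which local (ego) networks are drawn. Because nodes are defined
#' as the endpoints of surviving edges, isolation is impossible by
#' construction.
#'
#' @param edges data.frame with columns `from`, `to` (as returned by
#'   [load_edge_list()]), or a two-column character matrix.
#' @param measured_genes character vector of genes present in the expression
#'   matrix.
#' @return An object of class `"template_network"`: list with `graph`
#'   (an undirected [igraph::igraph] object), `nodes`, `edges` and a
#'   `provenance` record of the applied filters.
#' @export
build_template_network <- function(edges, measured_genes) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  measured_genes <- trimws(as.character(measured_genes))
  inside <- edges[[1L]] %in% measured_genes & edges[[2L]] %in% measured_genes
  n_dropped_edges <- sum(!inside)
  e <- edges[inside, 1:2, drop = FALSE]
  if (!nrow(e))
    stop("template network is empty after restriction to measured genes",
         call. = FALSE)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_dropped_edges > 0L)
    message(sprintf("build_template_network: dropped %d edge(s) outside the measured genes",
                    n_dropped_edges))
  nodes <- sort(igraph::V(g)$name)
  structure(list(graph = g, nodes = nodes,
                 n_edges = as.integer(igraph::ecount(g)),
                 provenance = list(n_input_edges = nrow(edges),
                                   n_dropped_edges = n_dropped_edges,
                                   n_measured = length(measured_genes))),
            class = "template_network")
}

#' @method print template_network
#' @export
print.template_network <- function(x, ...) {
  cat(sprintf("template_network: %d genes, %d undirected edges\n",
              length(x$nodes), x$n_edges))
  invisible(x)
}

#' @export
edge_table <- function(network) {
  stopifnot(inherits(network, "template_network"))
  el <- igraph::as_edgelist(network$graph)
  data.frame(from = pmin(el[, 1L], el[, 2L]),
             to = pmax(el[, 1L], el[, 2L]), stringsAsFactors = FALSE)
}

#' Extract the local (ego) network of a gene
#'
#' The local network of a gene is the gene itself plus its first-order
#' neighbours in the template network; it is the unit over which the local
#' SCLE score is computed. Neighbours are returned sorted lexicographically
#' so all downstream computation is deterministic.
#'
#' @param network a [build_template_network()] object.
#' @param gene gene symbol, must be a node of the network.
#' @return List with `center`, `neighbors` (sorted) and `Q` (neighbour count).
#' @export
local_network <- function(network, gene) {
  stopifnot(inherits(network, "template_network"))
  if (!gene %in% network$nodes)
    stop("gene '", gene, "' is not in the template network", call. = FALSE)
  nb <- sort(igraph::neighbors(network$graph, gene)$name)
  structure(list(center = gene, neighbors = nb, Q = length(nb)),
            class = "local_network")
}

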