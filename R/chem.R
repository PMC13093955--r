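#' Convert a SMILES string to a labeled molecular graph
#'
#' Parses the SMILES via the chemistry toolkit and returns an undirected
#' igraph whose vertices are atoms labeled by element symbol and whose edges
#' are bonds (bond order kept as an edge attribute). Hydrogens are implicit.
#'
#' @param smiles A valid SMILES string.
#' @return An `igraph` object with vertex attribute `label` and edge
#'   attribute `order`.
#' @export
smiles_to_graph <- function(smiles) {
  can <- smiles_canonicalize(smiles)
  if (is.na(can)) stop("smiles_to_graph: invalid SMILES ", sQuote(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  g <- igraph::make_empty_graph(n = length(elements), directed = FALSE)
  igraph::V(g)$label <- elements
  if (!is.null(bb) && nrow(bb) > 0) {
    edges <- as.vector(t(bb[, 1:2, drop = FALSE]))
    g <- igraph::add_edges(g, edges)
    igraph::E(g)$order <- as.numeric(bb[, 3])
  }
  g
}
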