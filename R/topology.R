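#' Node and edge topological properties of a ceRNA network
#'
#' Unweighted, undirected definitions of the four node properties — degree,
#' shortest-path betweenness, local clustering coefficient and closeness —
#' plus edge betweenness.
#'
#' Betweenness is reported both unnormalized (raw count of shortest-path
#' pair fractions) and normalized by `(n-1)(n-2)/2`. Closeness on
#' disconnected graphs is computed within each node's component:
#' `(|C|-1) / sum of distances to the other members of C`, 0 for isolated
#' nodes; `closeness_variant = "harmonic"` instead averages inverse
#' distances over ALL other nodes (unreachable contributing 0). Clustering
#' coefficient of nodes with degree < 2 is defined as 0.
#'
#' @param network igraph object.
#' @param closeness_variant `"component"` (default) or `"harmonic"`.
#' @return List with `nodes` (data.frame: `node`, `degree`, `betweenness`,
#'   `betweenness_normalized`, `closeness`, `clustering`) and `edges`
#'   (data.frame: `from`, `to`, `edge_betweenness`).
#' @export
compute_topology <- function(network,
                             closeness_variant = c("component", "harmonic")) {
  closeness_variant <- match.arg(closeness_variant)
  n <- igraph::vcount(network)
  if (n == 0L) {
    return(list(nodes = data.frame(node = character(), degree = integer(),
                                   betweenness = numeric(),
                                   betweenness_normalized = numeric(),
                                   closeness = numeric(),
                                   clustering = numeric()),
                edges = data.frame(from = character(), to = character(),
                                   edge_betweenness = numeric())))
  }
  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, directed = FALSE, normalized = FALSE)
  btw_norm <- if (n > 2L) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  clus <- igraph::transitivity(network, type = "local", isolates = "zero")
  clus[deg < 2L] <- 0
  d <- igraph::distances(network)
  comp <- igraph::components(network)$membership
  clo <- vapply(seq_len(n), function(i) {
    if (closeness_variant == "harmonic") {
      if (n == 1L) return(0)
      inv <- 1 / d[i, -i]
      inv[!is.finite(inv)] <- 0
      return(mean(inv))
    }
    members <- which(comp == comp[i])
    if (length(members) < 2L) return(0)
    (length(members) - 1) / sum(d[i, setdiff(members, i)])
  }, numeric(1L))
  el <- igraph::as_data_frame(network, what = "edges")
  eb <- igraph::edge_betweenness(network, directed = FALSE)
  list(
    nodes = data.frame(node = igraph::V(network)$name, degree = deg,
                       betweenness = btw, betweenness_normalized = btw_norm,
                       closeness = clo, clustering = clus,
                       row.names = NULL, stringsAsFactors = FALSE),
    edges = data.frame(from = el$from, to = el$to, edge_betweenness = eb,
                       stringsAsFactors = FALSE)
  )
}

#' Histogram table of one topological property
#'
#' @param topology Result of [compute_topology()].
#' @param property Column of the node table (or `"edge_betweenness"`).
#' @param breaks Number of bins or explicit break points.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
topology_distribution <- function(topology, property, breaks = 20L) {
  x <- if (property == "edge_betweenness") topology$edges$edge_betweenness
       else topology$nodes[[property]]
  if (is.null(x)) stop("unknown property '", property, "'", call. = FALSE)
  histogram_table(x, breaks)
}
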