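#' Detect network modules
#'
#' Louvain community detection on the unweighted graph, restricted to
#' connected nodes (isolated nodes stay unassigned, mirroring the network
#' summary convention). Node order is canonicalized (sorted symbols) and the
#' random seed fixed before detection, so a given seed always reproduces the
#' same partition. MCL, MCODE and EPCA are recognized names but not
#' implemented.
#'
#' @param network igraph object.
#' @param algorithm `"louvain"` (others raise "not implemented").
#' @param resolution Louvain resolution parameter (default 1; larger values
#'   favour more, smaller modules).
#' @param seed Integer seed controlling the algorithm's randomness.
#' @return A `cn_partition` list: `module_of` (named integer vector over
#'   connected nodes, module ids 1..k), `algorithm`, `resolution`, `seed`.
#' @export
detect_modules <- function(network, algorithm = "louvain", resolution = 1,
                           seed = 0L) {
  supported <- c("louvain")
  registered <- c("louvain", "mcl", "mcode", "epca")
  if (!algorithm %in% registered) {
    stop("unknown algorithm '", algorithm, "'; registered: ",
         paste(registered, collapse = ", "), call. = FALSE)
  }
  if (!algorithm %in% supported) {
    stop("algorithm '", algorithm, "' is not implemented; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  deg <- igraph::degree(network)
  conn <- igraph::induced_subgraph(network, igraph::V(network)[deg > 0])
  if (igraph::vcount(conn) == 0L) {
    stop("network has no connected nodes to cluster", call. = FALSE)
  }
  perm <- order(igraph::V(conn)$name)
  conn <- igraph::permute(conn, order(perm))
  cl <- withr::with_seed(seed,
                         igraph::cluster_louvain(conn,
                                                 resolution = resolution))
  module_of <- setNames(as.integer(igraph::membership(cl)),
                        igraph::V(conn)$name)
  structure(list(module_of = module_of, algorithm = algorithm,
                 resolution = resolution, seed = seed),
            class = "cn_partition")
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \sum_c \left[ \frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2
#'   \right]}
#' over modules `c`, where `m` is the number of edges among partitioned
#' nodes, `e_c` the number of intra-module edges and `d_c` the total degree
#' of module `c`.
#'
#' @param network igraph object.
#' @param partition A `cn_partition`, or a named vector node -> module id.
#' @return Modularity in \[-0.5, 1\].
#' @export
modularity_score <- function(network, partition) {
  module_of <- if (inherits(partition, "cn_partition"))
    partition$module_of else partition
  sub <- igraph::induced_subgraph(
    network, igraph::V(network)[igraph::V(network)$name %in%
                                  names(module_of)])
  m <- igraph::ecount(sub)
  if (m == 0L) return(0)
  el <- igraph::as_data_frame(sub, what = "edges")
  mem <- module_of[igraph::V(sub)$name]
  deg <- igraph::degree(sub)
  q <- 0
  for (c_id in unique(mem)) {
    nodes_c <- names(mem)[mem == c_id]
    e_c <- sum(el$from %in% nodes_c & el$to %in% nodes_c)
    d_c <- sum(deg[nodes_c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Per-module report with associated microRNAs
#'
#' For each module: size, internal edge count, density
#' `e_c / choose(size, 2)` (0 for singletons), and the associated miRNA set
#' — the union of the shared-miRNA annotations over the module's internal
#' edges. Globally: module count, modularity, and the unweighted mean module
#' density.
#'
#' @param network igraph object whose edges carry a `shared_mirnas`
#'   attribute (semicolon-joined symbols; may be absent).
#' @param partition A `cn_partition` from [detect_modules()].
#' @return A list with `modules` (data.frame: `module`, `size`, `n_edges`,
#'   `density`, `mirnas`), `n_modules`, `modularity`, `mean_density`.
#' @export
module_report <- function(network, partition) {
  module_of <- partition$module_of
  el <- igraph::as_data_frame(network, what = "edges")
  has_mir <- "shared_mirnas" %in% colnames(el)
  ids <- sort(unique(module_of))
  rows <- lapply(ids, function(c_id) {
    nodes_c <- names(module_of)[module_of == c_id]
    internal <- el$from %in% nodes_c & el$to %in% nodes_c
    e_c <- sum(internal)
    size <- length(nodes_c)
    dens <- if (size < 2L) 0 else e_c / choose(size, 2L)
    mirs <- if (has_mir && e_c > 0L) {
      sort(unique(unlist(strsplit(el$shared_mirnas[internal], ";",
                                  fixed = TRUE))))
    } else character()
    data.frame(module = c_id, size = size, n_edges = e_c, density = dens,
               mirnas = paste(setdiff(mirs, ""), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  modules <- do.call(rbind, rows)
  list(modules = modules,
       n_modules = length(ids),
       modularity = modularity_score(network, partition),
       mean_density = mean(modules$density))
}

#' Scan module-detection parameters
#'
#' Runs [detect_modules()] + [module_report()] over a resolution grid and a
#' set of seeds, one summary row per (resolution, seed).
#'
#' @param network igraph object.
#' @param algorithm Passed to [detect_modules()].
#' @param resolutions Numeric vector of resolution values.
#' @param seeds Integer vector of seeds.
#' @return data.frame: `resolution`, `seed`, `n_modules`, `modularity`,
#'   `mean_density`, `max_size`.
#' @export
parameter_scan <- function(network, algorithm = "louvain",
                           resolutions = c(0.5, 1, 2), seeds = 0L) {
  grid <- expand.grid(resolution = resolutions, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- detect_modules(network, algorithm, grid$resolution[i],
                        grid$seed[i])
    rep <- module_report(network, p)
    data.frame(resolution = grid$resolution[i], seed = grid$seed[i],
               n_modules = rep$n_modules, modularity = rep$modularity,
               mean_density = rep$mean_density,
               max_size = max(rep$modules$size))
  })
  do.call(rbind, rows)
}
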