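#' Enumerate candidate gene pairs for selected group pairs
#'
#' All unordered gene pairs whose sorted group-pair label is among
#' `group_pairs`. Pairs are canonicalized (`gene1 < gene2`) and returned in
#' deterministic lexicographic order.
#'
#' @param grouping Named character vector symbol -> group.
#' @param group_pairs `"all"`, or a character vector of labels
#'   `"GroupA|GroupB"` (sorted halves; within-group is `"G|G"`). A list of
#'   2-vectors is also accepted.
#' @return data.frame with columns `gene1`, `gene2`, `group_pair`.
#' @export
#' @examples
#' grp <- c(a = "Coding", b = "Coding", x = "Noncoding")
#' enumerate_pairs(grp, "Coding|Noncoding")
enumerate_pairs <- function(grouping, group_pairs = "all") {
  genes <- sort(names(grouping))
  if (length(genes) < 2L) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      group_pair = character(), stringsAsFactors = FALSE))
  }
  if (is.list(group_pairs)) {
    group_pairs <- vapply(group_pairs,
                          function(p) group_pair_label(p[1L], p[2L]),
                          character(1L))
  }
  idx <- utils::combn(length(genes), 2L)
  g1 <- genes[idx[1L, ]]
  g2 <- genes[idx[2L, ]]
  lab <- group_pair_label(grouping[g1], grouping[g2])
  if (!identical(group_pairs, "all")) {
    if (!length(group_pairs)) stop("empty group-pair selection",
                                   call. = FALSE)
    unknown <- setdiff(group_pairs, unique(lab))
    keep <- lab %in% group_pairs
    if (!any(keep) && length(unknown)) {
      stop("no pairs match the selected group pair(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    g1 <- g1[keep]; g2 <- g2[keep]; lab <- lab[keep]
  }
  data.frame(gene1 = unname(g1), gene2 = unname(g2),
             group_pair = unname(lab), stringsAsFactors = FALSE)
}

#' Compute the selected measures for every candidate pair
#'
#' Evaluates [measure_pair()] over a pair table, optionally in parallel.
#' Per-pair computation is pure and results are reduced in the input order,
#' so the table is identical for any worker count.
#'
#' @param pairs data.frame from [enumerate_pairs()] (columns `gene1`,
#'   `gene2`, optionally `group_pair`).
#' @param cerna_expr,mirna_expr Expression matrices over identical samples.
#' @param interactions Interaction data.frame.
#' @param measures Character subset of `c("MS","PCC","MI","CMI","LA")`.
#' @param hooks Named list of user measure functions `function(x, y, ctx)`.
#' @param universe miRNA universe; default: miRNAs present in both
#'   `mirna_expr` and the interaction table.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param n_bins,disc_method Discretization controls.
#' @return data.frame, one row per pair: `gene1`, `gene2`, `group_pair`,
#'   `t`, `shared_mirnas` (semicolon-joined), and one numeric column per
#'   measure (NA where undefined).
#' @export
compute_measures <- function(pairs, cerna_expr, mirna_expr, interactions,
                             measures = c("MS", "PCC"), hooks = list(),
                             universe = NULL, workers = 1L,
                             n_bins = NULL, disc_method = "equal_frequency") {
  known <- c("MS", "PCC", "MI", "CMI", "LA")
  bad <- setdiff(measures, known)
  if (length(bad)) {
    stop("unknown measure(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(known, collapse = ", "), call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- sort(intersect(rownames(mirna_expr),
                               unique(interactions$mirna)))
  }
  if (!"group_pair" %in% colnames(pairs)) pairs$group_pair <- "All|All"
  one <- function(i) {
    measure_pair(pairs$gene1[i], pairs$gene2[i], cerna_expr, mirna_expr,
                 interactions, universe, measures, hooks, n_bins,
                 disc_method)
  }
  n <- nrow(pairs)
  recs <- if (workers > 1L && requireNamespace("parallel", quietly = TRUE) &&
              .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n), one)
  }
  value_cols <- c(measures, names(hooks))
  out <- data.frame(
    gene1 = pairs$gene1, gene2 = pairs$gene2,
    group_pair = pairs$group_pair,
    t = vapply(recs, function(r) r$t, integer(1L)),
    shared_mirnas = vapply(recs, function(r)
      paste(r$shared_mirnas, collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
  for (v in value_cols) {
    out[[v]] <- vapply(recs, function(r) as.numeric(r[[v]]), numeric(1L))
  }
  n_skip <- if (any(c("CMI", "LA") %in% value_cols))
    sum(out$t == 0) else 0L
  if (n_skip > 0L) {
    .cn_msg(n_skip, " pair(s) share no miRNA: CMI/LA reported as NA")
  }
  out
}

#' Density/histogram table of a measure, per group pair
#'
#' Batch replacement for the on-screen density plots: bins the non-missing
#' values of one measure separately for each group-pair label.
#'
#' @param table PairMeasureTable from [compute_measures()].
#' @param measure Measure column name.
#' @param breaks Number of bins (shared grid across group pairs).
#' @return data.frame with columns `group_pair`, `bin_lo`, `bin_hi`,
#'   `count`, `density`.
#' @export
measure_density <- function(table, measure, breaks = 30L) {
  if (!measure %in% colnames(table)) {
    stop("measure '", measure, "' not present in table", call. = FALSE)
  }
  vals <- table[[measure]]
  ok <- !is.na(vals)
  if (!any(ok)) stop("no non-missing values for '", measure, "'",
                     call. = FALSE)
  rng <- range(vals[ok])
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1L], rng[2L], length.out = breaks + 1L)
  out <- lapply(split(vals[ok], table$group_pair[ok]), function(v) {
    h <- graphics::hist(v, breaks = edges, plot = FALSE,
                        include.lowest = TRUE)
    data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
               count = h$counts, density = h$density)
  })
  res <- do.call(rbind, Map(function(gp, d) cbind(group_pair = gp, d),
                            names(out), out))
  rownames(res) <- NULL
  res
}

#' Add a multiplicity-adjusted copy of a measure column
#'
#' The enrichment significance is thresholded raw by default (as in the
#' reference analysis); for users who prefer a multiplicity-corrected
#' cutoff this adds a `<measure>_adj` column (adjusted within each
#' group-pair label) that [threshold_spec()] can target instead.
#'
#' @param table PairMeasureTable from [compute_measures()].
#' @param measure P-value-like measure column (typically `"MS"`).
#' @param method Adjustment method for [stats::p.adjust()] (default BH).
#' @return `table` with an extra `<measure>_adj` column.
#' @export
adjust_measure <- function(table, measure = "MS", method = "BH") {
  if (!measure %in% colnames(table)) {
    stop("measure '", measure, "' not present in table", call. = FALSE)
  }
  adj <- rep(NA_real_, nrow(table))
  for (gp in unique(table$group_pair)) {
    idx <- which(table$group_pair == gp)
    adj[idx] <- p.adjust(table[[measure]][idx], method = method)
  }
  table[[paste0(measure, "_adj")]] <- adj
  table
}

#' Build a threshold specification
#'
#' One directional cutoff for one measure, applying either to a single
#' group-pair label or to all (`group_pair = "all"`). Inequalities are
#' strict: a value exactly at the cutoff fails.
#'
#' @param measure Measure name (must be computed).
#' @param direction `"lt"` (keep values `< cutoff`, e.g. MS significance) or
#'   `"gt"` (keep values `> cutoff`, e.g. PCC).
#' @param cutoff Numeric threshold.
#' @param group_pair Label `"A|B"` or `"all"`.
#' @return A `cn_threshold` list.
#' @export
threshold_spec <- function(measure, direction = c("lt", "gt"), cutoff,
                           group_pair = "all") {
  direction <- match.arg(direction)
  structure(list(measure = measure, direction = direction,
                 cutoff = cutoff, group_pair = group_pair),
            class = "cn_threshold")
}

#' Apply threshold specifications to a pair-measure table
#'
#' A pair becomes an edge iff, for EVERY spec matching its group pair, its
#' measure value strictly satisfies the directional inequality. A missing
#' (NA) value for any thresholded measure fails. Duplicate
#' (measure, group_pair) specs and specs on uncomputed measures are errors.
#'
#' @param table PairMeasureTable from [compute_measures()].
#' @param specs List of [threshold_spec()] objects (possibly empty: every
#'   pair passes).
#' @return The subset of `table` rows that satisfy all matching thresholds.
#' @export
apply_thresholds <- function(table, specs) {
  if (!length(specs)) return(table)
  keys <- vapply(specs, function(s) paste(s$measure, s$group_pair),
                 character(1L))
  if (anyDuplicated(keys)) {
    stop("duplicate threshold spec for ",
         keys[duplicated(keys)][1L], call. = FALSE)
  }
  keep <- rep(TRUE, nrow(table))
  for (s in specs) {
    if (!s$measure %in% colnames(table)) {
      stop("threshold on uncomputed measure '", s$measure, "'",
           call. = FALSE)
    }
    applies <- if (identical(s$group_pair, "all")) rep(TRUE, nrow(table))
               else table$group_pair == s$group_pair
    v <- table[[s$measure]]
    pass <- !is.na(v) & if (s$direction == "lt") v < s$cutoff else v > s$cutoff
    keep <- keep & (!applies | pass)
  }
  table[keep, , drop = FALSE]
}

#' Assemble the ceRNA network
#'
#' Builds an undirected igraph graph from the surviving edge table. All
#' genes in `all_nodes` become vertices, so genes that gained no edge remain
#' as isolated nodes. Vertices carry `group` (and any annotation columns);
#' edges carry the measure values, `t` and the semicolon-joined shared-miRNA
#' symbols. Duplicate edges collapse to one (logged); self-loops are
#' dropped.
#'
#' @param edges Edge table (a filtered PairMeasureTable).
#' @param all_nodes Character vector of node symbols (defaults to the genes
#'   appearing in `edges`).
#' @param grouping Optional named vector symbol -> group.
#' @param annotation Optional annotation data.frame (first column `symbol`)
#'   whose extra columns become vertex attributes.
#' @return An igraph object.
#' @export
build_network <- function(edges, all_nodes = NULL, grouping = NULL,
                          annotation = NULL) {
  if (is.null(all_nodes)) all_nodes <- union(edges$gene1, edges$gene2)
  all_nodes <- sort(unique(all_nodes))
  edges <- edges[edges$gene1 != edges$gene2, , drop = FALSE]
  cp <- .canonical_pair(edges$gene1, edges$gene2)
  edges$gene1 <- cp$gene1
  edges$gene2 <- cp$gene2
  dup <- duplicated(paste(edges$gene1, edges$gene2, sep = "\r"))
  if (any(dup)) {
    .cn_msg("collapsed ", sum(dup), " duplicate edge submissions")
    edges <- edges[!dup, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene1", "gene2",
              setdiff(colnames(edges), c("gene1", "gene2"))),
          drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE))
  if (!is.null(grouping)) {
    igraph::V(g)$group <- unname(grouping[igraph::V(g)$name])
  }
  if (!is.null(annotation)) {
    idx <- match(igraph::V(g)$name, annotation$symbol)
    for (col in setdiff(colnames(annotation), "symbol")) {
      g <- igraph::set_vertex_attr(g, col, value = annotation[[col]][idx])
    }
  }
  g
}

#' Summarize a ceRNA network
#'
#' Counts connected nodes (degree >= 1), isolated nodes, edges and connected
#' components. Components are counted among connected nodes only — isolated
#' nodes are not singleton components.
#'
#' @param network igraph object from [build_network()].
#' @return List with `n_connected_nodes`, `n_isolated_nodes`, `n_edges`,
#'   `n_components`.
#' @export
summarize_network <- function(network) {
  deg <- igraph::degree(network)
  connected <- igraph::induced_subgraph(network,
                                        igraph::V(network)[deg > 0])
  list(
    n_connected_nodes = sum(deg > 0),
    n_isolated_nodes = sum(deg == 0),
    n_edges = igraph::ecount(network),
    n_components = if (igraph::vcount(connected) == 0L) 0L
                   else igraph::components(connected)$no
  )
}

#' Export a network to GraphML and plain edge/node tables
#'
#' @param network igraph object.
#' @param prefix Output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`.
#' @return Invisibly, the three paths.
#' @export
export_network <- function(network, prefix) {
  paths <- paste0(prefix, c(".graphml", "_edges.tsv", "_nodes.tsv"))
  igraph::write_graph(network, paths[1L], format = "graphml")
  ed <- igraph::as_data_frame(network, what = "edges")
  nd <- igraph::as_data_frame(network, what = "vertices")
  write.table(ed, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(nd, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
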