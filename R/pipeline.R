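# Declarative batch pipeline: each subcommand reads a YAML (or JSON) config,
# validates it against a key schema, runs, and writes its artifacts plus a
# manifest (config echo, package version, input checksums, seed) under the
# output directory.

.cn_schema <- list(
  validate = list(
    required = c("cerna_expr", "mirna_expr", "interactions", "annotation"),
    optional = c("delimiter", "out")),
  preprocess = list(
    required = c("cerna_expr", "mirna_expr", "interactions", "annotation"),
    optional = c("delimiter", "out", "grouping", "sample_filter",
                 "gene_filter", "transform")),
  construct = list(
    required = c("cerna_expr", "mirna_expr", "interactions", "annotation"),
    optional = c("delimiter", "out", "grouping", "group_pairs", "measures",
                 "thresholds", "n_bins", "disc_method", "workers")),
  topology = list(required = "network",
                  optional = c("out", "closeness_variant")),
  modules = list(required = "network",
                 optional = c("out", "algorithm", "resolution", "seed")),
  enrich = list(required = c("query", "gene_sets", "universe"),
                optional = c("out", "delimiter")),
  survival = list(required = c("survival_table", "expression",
                               "module_genes"),
                  optional = c("out", "delimiter", "rule", "seed")),
  simulate = list(required = character(),
                  optional = c("out", "seed", "n_samples", "n_mirnas",
                               "n_coding", "n_noncoding",
                               "n_planted_triads", "noise_sd",
                               "repression_strength", "n_shared_mirnas"))
)

#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) mapping of configuration keys.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg))) {
    stop("config must be a mapping of keys to values", call. = FALSE)
  }
  cfg
}

#' Validate a configuration against a subcommand's schema
#'
#' Unknown keys and missing required keys are field-level errors raised
#' before any computation starts.
#'
#' @param config Named list.
#' @param subcommand One of the pipeline subcommands.
#' @return Invisibly, the config.
#' @export
validate_config <- function(config, subcommand) {
  if (!subcommand %in% names(.cn_schema)) {
    stop("unknown subcommand '", subcommand, "'; supported: ",
         paste(names(.cn_schema), collapse = ", "), call. = FALSE)
  }
  sch <- .cn_schema[[subcommand]]
  missing_keys <- setdiff(sch$required, names(config))
  if (length(missing_keys)) {
    stop("config for '", subcommand, "' is missing required key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(config), c(sch$required, sch$optional))
  if (length(unknown)) {
    stop("config for '", subcommand, "' has unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

.write_manifest <- function(out, subcommand, config, seed = NULL) {
  inputs <- unlist(config[vapply(config, function(v)
    is.character(v) && length(v) == 1L && file.exists(v) &&
      !dir.exists(v), logical(1L))])
  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("cernanet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else
      list())
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

.threshold_specs_from_config <- function(thresholds) {
  lapply(thresholds, function(th) {
    threshold_spec(measure = th$measure,
                   direction = if (!is.null(th$direction)) th$direction
                               else "gt",
                   cutoff = th$cutoff,
                   group_pair = if (!is.null(th$group_pair)) th$group_pair
                                else "all")
  })
}

.load_inputs <- function(config) {
  delim <- if (is.null(config$delimiter)) "auto" else config$delimiter
  list(
    cerna_expr = read_expression(config$cerna_expr, delim),
    mirna_expr = read_expression(config$mirna_expr, delim),
    interactions = read_interactions(config$interactions, delim),
    annotation = read_annotation(config$annotation, delim))
}

.grouping_from_config <- function(config, annotation) {
  g <- config$grouping
  if (is.null(g)) {
    return(assign_groups(annotation, colnames(annotation)[2L],
                         c(protein_coding = "Coding"), "Noncoding"))
  }
  assign_groups(annotation, g$attribute, unlist(g$rule),
                if (is.null(g$default_group)) "All" else g$default_group)
}

#' Run one pipeline subcommand
#'
#' Entry point behind the `cernanet` command-line script. Validates the
#' config, executes the subcommand, writes all artifacts and a manifest
#' under the output directory, and never mutates its inputs.
#'
#' Subcommands: `validate`, `preprocess`, `construct`, `topology`,
#' `modules`, `enrich`, `survival`, `simulate`.
#'
#' @param subcommand Subcommand name.
#' @param config Config list or path to a YAML/JSON config file.
#' @param out Output directory (overrides the config's `out`).
#' @param seed Integer seed (overrides the config's `seed`).
#' @param workers Worker count for `construct` (overrides config).
#' @return Invisibly, a list of the subcommand's main results.
#' @export
cn_run <- function(subcommand, config, out = NULL, seed = NULL,
                   workers = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  if (!is.null(out)) config$out <- out
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(workers)) config$workers <- workers
  validate_config(config, subcommand)
  out <- if (is.null(config$out)) "." else config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- switch(subcommand,
    validate = .run_validate(config, out),
    preprocess = .run_preprocess(config, out),
    construct = .run_construct(config, out),
    topology = .run_topology(config, out),
    modules = .run_modules(config, out),
    enrich = .run_enrich(config, out),
    survival = .run_survival(config, out),
    simulate = .run_simulate(config, out))
  .write_manifest(out, subcommand, config, config$seed)
  invisible(res)
}

.run_validate <- function(config, out) {
  inp <- .load_inputs(config)
  sets <- harmonize(inp$cerna_expr, inp$mirna_expr, inp$interactions,
                    inp$annotation)
  jsonlite::write_json(
    list(n_valid_cernas = length(sets$valid_cernas),
         n_valid_mirnas = length(sets$valid_mirnas),
         n_valid_samples = length(sets$valid_samples)),
    file.path(out, "harmonized_sets.json"), auto_unbox = TRUE)
  print(sets)
  sets
}

.run_preprocess <- function(config, out) {
  inp <- .load_inputs(config)
  sets <- harmonize(inp$cerna_expr, inp$mirna_expr, inp$interactions,
                    inp$annotation)
  r <- restrict_to(sets, inp$cerna_expr, inp$mirna_expr, inp$interactions,
                   inp$annotation)
  grouping <- .grouping_from_config(config, r$annotation)

  sf <- config$sample_filter
  if (!is.null(sf)) {
    keep <- if (!is.null(sf$drop_lowest))
      list(drop_lowest = unlist(sf$drop_lowest))
    else list(min_ratio = unlist(sf$min_ratio))
    fs <- filter_samples(r$cerna_expr, r$mirna_expr,
                         sf$cerna_detect_threshold,
                         sf$mirna_detect_threshold, keep)
    r$cerna_expr <- fs$cerna_expr
    r$mirna_expr <- fs$mirna_expr
    write.table(histogram_table(fs$report$cerna_ratio),
                file.path(out, "cerna_sample_ratio_hist.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(histogram_table(fs$report$mirna_ratio),
                file.path(out, "mirna_sample_ratio_hist.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    fs <- NULL
  }

  gf <- config$gene_filter
  if (!is.null(gf)) {
    rules <- lapply(gf$groups, function(x)
      list(min_expr = x$min_expr, min_fraction = x$min_fraction))
    names(rules) <- vapply(gf$groups, `[[`, character(1L), "group")
    fg_c <- filter_genes(r$cerna_expr, grouping, rules)
    r$cerna_expr <- fg_c$expr
    if (!is.null(gf$mirna)) {
      fg_m <- filter_genes(r$mirna_expr, NULL,
                           list(All = list(
                             min_expr = gf$mirna$min_expr,
                             min_fraction = gf$mirna$min_fraction)))
      r$mirna_expr <- fg_m$expr
    } else {
      fg_m <- NULL
    }
  } else {
    fg_c <- fg_m <- NULL
  }

  tr <- config$transform
  if (!is.null(tr)) {
    # fixed order: log first, normalization second
    if (isTRUE(tr$log$enabled) || !is.null(tr$log$base)) {
      base <- if (is.null(tr$log$base)) 2 else tr$log$base
      pc <- if (is.null(tr$log$pseudocount)) 0 else tr$log$pseudocount
      r$cerna_expr <- log_transform(r$cerna_expr, base, pc)
      if (isTRUE(tr$log$mirna)) {
        r$mirna_expr <- log_transform(r$mirna_expr, base, pc)
      }
    }
    if (!is.null(tr$normalize)) {
      r$cerna_expr <- normalize_expression(r$cerna_expr, tr$normalize)
    }
  }

  write_expression(r$cerna_expr, file.path(out, "cerna_expr_filtered.tsv"))
  write_expression(r$mirna_expr, file.path(out, "mirna_expr_filtered.tsv"))
  write.table(r$interactions, file.path(out, "interactions_filtered.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(r$annotation, file.path(out, "annotation_filtered.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    n_cernas = nrow(r$cerna_expr), n_mirnas = nrow(r$mirna_expr),
    n_samples = ncol(r$cerna_expr),
    removed_samples = if (is.null(fs)) character() else fs$report$removed,
    removed_cernas = if (is.null(fg_c)) character() else
      fg_c$report$removed,
    removed_mirnas = if (is.null(fg_m)) character() else
      fg_m$report$removed,
    group_sizes = as.list(table(grouping[rownames(r$cerna_expr)])))
  jsonlite::write_json(report, file.path(out, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cerna_expr = r$cerna_expr, mirna_expr = r$mirna_expr,
                 interactions = r$interactions, annotation = r$annotation,
                 grouping = grouping, report = report))
}

.run_construct <- function(config, out) {
  inp <- .load_inputs(config)
  grouping <- .grouping_from_config(config, inp$annotation)
  grouping <- grouping[rownames(inp$cerna_expr)]
  measures <- if (is.null(config$measures)) c("MS", "PCC") else
    unlist(config$measures)
  specs <- if (is.null(config$thresholds)) list() else
    .threshold_specs_from_config(config$thresholds)
  for (s in specs) {
    if (!s$measure %in% measures) {
      stop("threshold on measure '", s$measure,
           "' which is not selected for computation", call. = FALSE)
    }
  }
  gp <- if (is.null(config$group_pairs)) "all" else
    unlist(config$group_pairs)
  pairs <- enumerate_pairs(grouping, gp)
  tab <- compute_measures(
    pairs, inp$cerna_expr, inp$mirna_expr, inp$interactions,
    measures = measures,
    workers = if (is.null(config$workers)) 1L else config$workers,
    n_bins = config$n_bins,
    disc_method = if (is.null(config$disc_method)) "equal_frequency" else
      config$disc_method)
  write.table(tab, file.path(out, "pair_measures.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (m in measures) {
    dens <- try(measure_density(tab, m), silent = TRUE)
    if (!inherits(dens, "try-error")) {
      write.table(dens, file.path(out, paste0("density_", m, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  edges <- apply_thresholds(tab, specs)
  net <- build_network(edges, all_nodes = rownames(inp$cerna_expr),
                       grouping = grouping, annotation = inp$annotation)
  export_network(net, file.path(out, "network"))
  summ <- summarize_network(net)
  jsonlite::write_json(summ, file.path(out, "network_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .cn_msg(sprintf(
    "network: %d connected nodes, %d isolated, %d edges, %d components",
    summ$n_connected_nodes, summ$n_isolated_nodes, summ$n_edges,
    summ$n_components))
  invisible(list(table = tab, network = net, summary = summ))
}

.run_topology <- function(config, out) {
  net <- igraph::read_graph(config$network, format = "graphml")
  variant <- if (is.null(config$closeness_variant)) "component" else
    config$closeness_variant
  topo <- compute_topology(net, variant)
  write.table(topo$nodes, file.path(out, "topology_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(topo$edges, file.path(out, "topology_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (p in c("degree", "betweenness", "closeness", "clustering")) {
    write.table(topology_distribution(topo, p),
                file.path(out, paste0("dist_", p, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(topo)
}

.run_modules <- function(config, out) {
  net <- igraph::read_graph(config$network, format = "graphml")
  part <- detect_modules(
    net,
    algorithm = if (is.null(config$algorithm)) "louvain" else
      config$algorithm,
    resolution = if (is.null(config$resolution)) 1 else config$resolution,
    seed = if (is.null(config$seed)) 0L else config$seed)
  rep <- module_report(net, part)
  write.table(data.frame(node = names(part$module_of),
                         module = unname(part$module_of)),
              file.path(out, "module_membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rep$modules, file.path(out, "module_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rep[c("n_modules", "modularity", "mean_density")],
                       file.path(out, "module_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(partition = part, report = rep))
}

.run_enrich <- function(config, out) {
  collection <- read_gmt(config$gene_sets)
  query <- readLines(config$query, warn = FALSE)
  query <- trimws(query[nzchar(trimws(query))])
  universe <- readLines(config$universe, warn = FALSE)
  universe <- trimws(universe[nzchar(trimws(universe))])
  res <- ora(query, collection, universe)
  write.table(res, file.path(out, "ora_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(res)
}

.run_survival <- function(config, out) {
  st <- read_survival_table(config$survival_table)
  expr <- read_expression(config$expression)
  module_genes <- readLines(config$module_genes, warn = FALSE)
  module_genes <- trimws(module_genes[nzchar(trimws(module_genes))])
  expr <- expr[, st$sample, drop = FALSE]
  strat <- stratify_by_module(
    expr, module_genes,
    rule = if (is.null(config$rule)) "median" else config$rule,
    seed = if (is.null(config$seed)) 0L else config$seed)
  labels <- strat$labels[st$sample]
  lr <- logrank(labels, st$time, st$event)
  curves <- lapply(split(seq_len(nrow(st)), labels), function(idx)
    km_curve(st$time[idx], st$event[idx]))
  km_rows <- do.call(rbind, lapply(names(curves), function(g)
    data.frame(group = g, time = curves[[g]]$time,
               survival = curves[[g]]$survival)))
  write.table(km_rows, file.path(out, "km_curves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(logrank_statistic = lr$statistic, df = lr$df,
         p_value = lr$p_value,
         group_sizes = as.list(table(labels)),
         median_survival = lapply(curves, `[[`, "median")),
    file.path(out, "survival_summary.json"), auto_unbox = TRUE,
    pretty = TRUE, null = "null")
  invisible(list(stratification = strat, logrank = lr, curves = curves))
}

.run_simulate <- function(config, out) {
  keys <- intersect(names(config),
                    setdiff(names(formals(fixture_spec)), ""))
  spec <- do.call(fixture_spec, config[keys])
  fx <- generate_fixture(spec)
  write_fixture(fx, out)
  invisible(fx)
}
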