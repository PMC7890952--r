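#' Read a GMT-style gene-set file
#'
#' One set per line: set name, description, then member symbols, all
#' tab-delimited.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set name -> symbols); set
#'   descriptions attached as attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop("GMT line ", bad[1L], " has fewer than 3 fields", call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  attr(sets, "descriptions") <- setNames(
    vapply(parts, `[[`, character(1L), 2L), names(sets))
  sets
}

#' Over-representation analysis of a gene set against a collection
#'
#' For each collection set, the hypergeometric upper-tail probability of
#' observing at least the actual overlap between the query and the set,
#' given the universe — the same tail statistic as [ms()] (one
#' implementation, two call sites): `p = ms(t, |set|, |query|, |universe|)`
#' with `t` the overlap. P-values are Benjamini-Hochberg adjusted across the
#' collection. Collection sets are first restricted to the universe (the
#' out-of-universe count is reported).
#'
#' @param query Character vector of gene symbols (restricted to the
#'   universe).
#' @param collection Named list of gene sets, e.g. from [read_gmt()].
#' @param universe Character vector: the background gene universe (must be
#'   non-empty).
#' @return data.frame: `set`, `set_size`, `overlap`, `p_value`, `q_value`,
#'   `genes` (semicolon-joined overlap), sorted by p-value.
#' @export
ora <- function(query, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- intersect(unique(query), universe)
  restricted <- lapply(collection, intersect, universe)
  n_out <- sum(lengths(collection) - lengths(restricted))
  if (n_out > 0L) {
    .cn_msg("restricted collection to universe: ", n_out,
            " out-of-universe symbols dropped")
  }
  rows <- lapply(names(restricted), function(nm) {
    set <- restricted[[nm]]
    hit <- intersect(query, set)
    data.frame(set = nm, set_size = length(set), overlap = length(hit),
               p_value = ms(length(hit), length(set), length(query),
                            length(universe)),
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), c("set", "set_size", "overlap", "p_value",
                                   "q_value", "genes")]
  rownames(out) <- NULL
  out
}
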