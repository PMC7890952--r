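#' Read an expression matrix from delimited text
#'
#' The file layout is genes x samples: the first row holds sample names, the
#' first column gene (or miRNA) symbols. Fields may be separated by tab,
#' comma, semicolon or space; `delimiter = "auto"` sniffs the separator from
#' the header line with priority tab > comma > semicolon > space.
#'
#' All cells must be numeric and finite; duplicated gene symbols or sample
#' names are a hard error. The returned object is a plain numeric matrix with
#' `rownames` = gene symbols and `colnames` = sample names, the container used
#' by every downstream measure.
#'
#' @param path Path to the delimited text file.
#' @param delimiter A single character, or `"auto"` (default).
#' @return A numeric matrix (genes x samples) with dimnames.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' write_expression(m, f)
#' read_expression(f)
read_expression <- function(path, delimiter = "auto") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .resolve_delimiter(path, delimiter)
  df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("expression file '", path,
                          "' needs a symbol column plus >=1 sample",
                          call. = FALSE)
  symbols <- df[[1L]]
  dup <- unique(symbols[duplicated(symbols)])
  if (length(dup)) {
    stop("duplicate gene symbols in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  samples <- colnames(df)[-1L]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop("duplicate sample names in '", path, "': ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric or non-finite cell in '%s' at gene '%s', sample '%s' ('%s')",
      path, symbols[bad[1L, 1L]], samples[bad[1L, 2L]],
      vals[bad[1L, 1L], bad[1L, 2L]]), call. = FALSE)
  }
  dimnames(num) <- list(symbols, samples)
  num
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: first column gene symbols (header
#' `symbol`), remaining columns one per sample.
#'
#' @param expr Numeric matrix with dimnames.
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, delimiter = "\t") {
  df <- data.frame(symbol = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' Two columns: miRNA symbol, target symbol. Duplicate rows are collapsed
#' (the number of collapsed duplicates is reported); rows with an empty field
#' are a hard error naming the line. A header line is skipped when
#' `header = TRUE`; with `header = "auto"` the first line is treated as a
#' header if its fields don't look like data (never re-appear in the body).
#'
#' @param path Path to the delimited text file.
#' @param delimiter A single character or `"auto"`.
#' @param header `TRUE`, `FALSE`, or `"auto"` (default `FALSE`).
#' @return A data.frame with columns `mirna`, `target`, one row per unique
#'   pair, ordered as first seen.
#' @export
read_interactions <- function(path, delimiter = "auto", header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) {
    warning("interaction file '", path, "' is empty", call. = FALSE)
    return(data.frame(mirna = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  sep <- .resolve_delimiter(path, delimiter)
  parts <- strsplit(lines[lines_keep], sep, fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields < 2L | vapply(parts, function(p)
    any(!nzchar(trimws(p[1:2]))), logical(1L)))
  if (length(bad)) {
    stop("interaction file '", path, "': missing field at line ",
         lines_keep[bad[1L]], call. = FALSE)
  }
  mirna <- vapply(parts, function(p) trimws(p[1L]), character(1L))
  target <- vapply(parts, function(p) trimws(p[2L]), character(1L))
  drop_first <- isTRUE(header)
  if (identical(header, "auto") && length(mirna) > 1L) {
    drop_first <- !(mirna[1L] %in% mirna[-1L]) &&
      !(target[1L] %in% target[-1L]) &&
      !(mirna[1L] %in% target[-1L])
  }
  if (drop_first) {
    mirna <- mirna[-1L]
    target <- target[-1L]
  }
  key <- paste(mirna, target, sep = "\r")
  dups <- duplicated(key)
  if (any(dups)) .cn_msg("collapsed ", sum(dups), " duplicate interaction rows")
  data.frame(mirna = mirna[!dups], target = target[!dups],
             stringsAsFactors = FALSE)
}

#' Read a gene annotation table
#'
#' First column gene symbol, remaining columns attributes (e.g. `biotype`).
#' Exactly one record per symbol; duplicated symbols are a hard error.
#' Missing attribute values are kept as empty strings with a warning.
#'
#' @inheritParams read_interactions
#' @param header Logical; the file's first line holds column names
#'   (default `TRUE`).
#' @return A data.frame whose first column is named `symbol`.
#' @export
read_annotation <- function(path, delimiter = "auto", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .resolve_delimiter(path, delimiter)
  df <- read.table(path, header = header, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   comment.char = "", quote = "\"", fill = TRUE)
  if (!ncol(df)) stop("annotation file '", path, "' has no columns",
                      call. = FALSE)
  colnames(df)[1L] <- "symbol"
  dup <- unique(df$symbol[duplicated(df$symbol)])
  if (length(dup)) {
    stop("duplicate annotation symbols in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (ncol(df) > 1L) {
    empties <- vapply(df[-1L], function(col) sum(is.na(col) | !nzchar(col)),
                      integer(1L))
    if (any(empties > 0L)) {
      warning(sum(empties), " empty attribute value(s) kept as ''",
              call. = FALSE)
      df[-1L] <- lapply(df[-1L], function(col) {
        col[is.na(col)] <- ""
        col
      })
    }
  }
  df
}

#' Harmonize symbols across the four input tables
#'
#' Computes the three symbol sets that gate all downstream analysis:
#' \describe{
#'   \item{valid_cernas}{candidate-ceRNA symbols present in the ceRNA
#'     expression matrix AND among interaction targets AND in the annotation.}
#'   \item{valid_mirnas}{miRNA symbols present in the miRNA expression matrix
#'     AND among interaction miRNAs.}
#'   \item{valid_samples}{sample names shared by the two expression matrices.}
#' }
#' Symbol matching is exact, case-sensitive string equality. Any empty
#' intersection is a hard error naming the offending set; counts of dropped
#' symbols are reported.
#'
#' @param cerna_expr,mirna_expr Expression matrices from [read_expression()].
#' @param interactions Interaction table from [read_interactions()].
#' @param annotation Annotation table from [read_annotation()].
#' @return A list of class `cn_harmonized` with character vectors
#'   `valid_cernas`, `valid_mirnas`, `valid_samples` (sorted).
#' @export
harmonize <- function(cerna_expr, mirna_expr, interactions, annotation) {
  valid_cernas <- sort(intersect(intersect(rownames(cerna_expr),
                                           unique(interactions$target)),
                                 annotation$symbol))
  valid_mirnas <- sort(intersect(rownames(mirna_expr),
                                 unique(interactions$mirna)))
  valid_samples <- sort(intersect(colnames(cerna_expr), colnames(mirna_expr)))
  if (!length(valid_cernas)) {
    stop("harmonize: no candidate ceRNA symbol is shared by the expression ",
         "matrix, interaction targets and annotation", call. = FALSE)
  }
  if (!length(valid_mirnas)) {
    stop("harmonize: no miRNA symbol is shared by the miRNA expression ",
         "matrix and the interaction table", call. = FALSE)
  }
  if (!length(valid_samples)) {
    stop("harmonize: the two expression matrices share no sample names",
         call. = FALSE)
  }
  .cn_msg(sprintf(
    "harmonized: %d ceRNAs (of %d in expression), %d miRNAs (of %d), %d samples",
    length(valid_cernas), nrow(cerna_expr),
    length(valid_mirnas), nrow(mirna_expr), length(valid_samples)))
  structure(list(valid_cernas = valid_cernas,
                 valid_mirnas = valid_mirnas,
                 valid_samples = valid_samples),
            class = "cn_harmonized")
}

#' Restrict the inputs to their harmonized symbol sets
#'
#' Subsets both expression matrices, the interaction table and the annotation
#' to the symbols and samples in `sets`, preserving harmonized order.
#'
#' @inheritParams harmonize
#' @param sets Result of [harmonize()].
#' @return A list with elements `cerna_expr`, `mirna_expr`, `interactions`,
#'   `annotation`.
#' @export
restrict_to <- function(sets, cerna_expr, mirna_expr, interactions,
                        annotation) {
  keep <- interactions$mirna %in% sets$valid_mirnas &
    interactions$target %in% sets$valid_cernas
  n_drop <- sum(!keep)
  if (n_drop) {
    .cn_msg("dropped ", n_drop,
            " interaction rows outside the harmonized symbol sets")
  }
  list(
    cerna_expr = cerna_expr[sets$valid_cernas, sets$valid_samples,
                            drop = FALSE],
    mirna_expr = mirna_expr[sets$valid_mirnas, sets$valid_samples,
                            drop = FALSE],
    interactions = interactions[keep, , drop = FALSE],
    annotation = annotation[annotation$symbol %in% sets$valid_cernas, ,
                            drop = FALSE]
  )
}

#' @export
print.cn_harmonized <- function(x, ...) {
  cat("Harmonized symbol sets:\n",
      "  valid ceRNAs:  ", length(x$valid_cernas), "\n",
      "  valid miRNAs:  ", length(x$valid_mirnas), "\n",
      "  valid samples: ", length(x$valid_samples), "\n", sep = "")
  invisible(x)
}
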