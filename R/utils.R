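#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist median phyper qnorm quantile rbinom rexp rnorm
#'   runif sd setNames p.adjust pchisq
#' @importFrom utils read.table write.table head
NULL

# Candidate delimiters in priority order: tab > comma > semicolon > space.
.cn_delims <- c("\t", ",", ";", " ")

#' Sniff the field delimiter of a delimited text file
#'
#' Inspects the header line only and returns the first delimiter (priority
#' order: tab, comma, semicolon, space) that splits it into more than one
#' field.
#'
#' @param path Path to a text file.
#' @return A single character: `"\t"`, `","`, `";"` or `" "`.
#' @keywords internal
sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) {
    stop("cannot sniff delimiter: '", path, "' is empty", call. = FALSE)
  }
  for (d in .cn_delims) {
    if (length(strsplit(header, d, fixed = TRUE)[[1L]]) > 1L) return(d)
  }
  stop("cannot sniff delimiter of '", path,
       "': header contains none of tab, comma, semicolon, space",
       call. = FALSE)
}

.resolve_delimiter <- function(path, delimiter) {
  if (identical(delimiter, "auto")) sniff_delimiter(path) else delimiter
}

.cn_msg <- function(...) message("[cernanet] ", ...)

# Canonical unordered pair: gene1 < gene2 lexicographically.
.canonical_pair <- function(a, b) {
  swap <- a > b
  g1 <- ifelse(swap, b, a)
  g2 <- ifelse(swap, a, b)
  list(gene1 = g1, gene2 = g2)
}

# Sorted "A|B" group-pair label; within-group pairs give "g|g".
group_pair_label <- function(ga, gb) {
  paste(pmin(ga, gb), pmax(ga, gb), sep = "|")
}
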