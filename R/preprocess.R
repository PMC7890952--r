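#' Assign candidate ceRNAs to groups from an annotation attribute
#'
#' Maps an annotation column (typically `biotype`) through a user rule to a
#' group label; unmapped values fall into `default_group`. The case-study
#' convention puts biotype `"protein_coding"` into group `"Coding"` and
#' everything else into `"Noncoding"`.
#'
#' @param annotation Annotation data.frame (first column `symbol`).
#' @param attribute Name of the annotation column to group on.
#' @param rule Named character vector: attribute value -> group label. An
#'   empty rule sends every gene to `default_group`.
#' @param default_group Label for unmapped attribute values.
#' @return Named character vector: gene symbol -> group label.
#' @export
#' @examples
#' ann <- data.frame(symbol = c("A", "B", "C"),
#'                   biotype = c("protein_coding", "lincRNA", "protein_coding"))
#' assign_groups(ann, "biotype", c(protein_coding = "Coding"), "Noncoding")
assign_groups <- function(annotation, attribute, rule = character(),
                          default_group = "All") {
  if (!attribute %in% colnames(annotation)) {
    stop("annotation has no attribute '", attribute, "'", call. = FALSE)
  }
  vals <- annotation[[attribute]]
  groups <- unname(rule[vals])
  groups[is.na(groups)] <- default_group
  setNames(groups, annotation$symbol)
}

#' Fraction of detected genes per sample
#'
#' For each sample, the fraction of genes whose expression is strictly above
#' `detect_threshold`. Used to spot low-quality samples.
#'
#' @param expr Expression matrix (genes x samples).
#' @param detect_threshold Detection threshold; strictly greater counts.
#' @return Named numeric vector over samples, values in \[0, 1\].
#' @export
detected_ratio_per_sample <- function(expr, detect_threshold) {
  colMeans(expr > detect_threshold)
}

#' Fraction of expressing samples per gene
#'
#' For each gene, the fraction of samples where its expression is strictly
#' above `min_expr`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param min_expr Minimal expression level; strictly greater counts.
#' @return Named numeric vector over genes, values in \[0, 1\].
#' @export
expressing_sample_ratio <- function(expr, min_expr) {
  rowMeans(expr > min_expr)
}

#' Remove low-quality samples from both expression matrices
#'
#' Computes per-sample detected-RNA ratios in each matrix (ceRNA and miRNA,
#' each with its own detection threshold) and removes samples that fail
#' either criterion. Two selection modes:
#' \describe{
#'   \item{min_ratio}{`keep = list(min_ratio = c(cerna, mirna))` — a sample
#'     survives a matrix if its ratio is >= that matrix's minimum.}
#'   \item{drop_lowest}{`keep = list(drop_lowest = c(cerna, mirna))` — the k
#'     samples with the lowest ratio in each matrix are dropped (ties broken
#'     by sample-name order).}
#' }
#' A sample is retained only if it survives in BOTH matrices; both returned
#' matrices end with the identical retained sample set, in original order.
#'
#' @param cerna_expr,mirna_expr Expression matrices sharing sample names.
#' @param cerna_detect_threshold,mirna_detect_threshold Detection thresholds.
#' @param keep A one-element list, `list(min_ratio = c(r1, r2))` or
#'   `list(drop_lowest = c(k1, k2))` (ceRNA first, miRNA second; a scalar is
#'   recycled).
#' @return A list with `cerna_expr`, `mirna_expr` (filtered) and `report`, a
#'   list holding both ratio vectors and the removed/retained sample names.
#' @export
filter_samples <- function(cerna_expr, mirna_expr,
                           cerna_detect_threshold, mirna_detect_threshold,
                           keep = list(drop_lowest = c(0, 0))) {
  stopifnot(identical(sort(colnames(cerna_expr)), sort(colnames(mirna_expr))))
  mirna_expr <- mirna_expr[, colnames(cerna_expr), drop = FALSE]
  r_cerna <- detected_ratio_per_sample(cerna_expr, cerna_detect_threshold)
  r_mirna <- detected_ratio_per_sample(mirna_expr, mirna_detect_threshold)
  mode <- names(keep)
  if (length(mode) != 1L || !mode %in% c("min_ratio", "drop_lowest")) {
    stop("keep must be list(min_ratio = ...) or list(drop_lowest = ...)",
         call. = FALSE)
  }
  par2 <- rep_len(keep[[1L]], 2L)
  if (mode == "min_ratio") {
    ok <- r_cerna >= par2[1L] & r_mirna >= par2[2L]
  } else {
    drop_k <- function(r, k) {
      if (k <= 0L) return(character())
      names(sort(r))[seq_len(min(k, length(r)))]
    }
    dropped <- union(drop_k(r_cerna, par2[1L]), drop_k(r_mirna, par2[2L]))
    ok <- !(names(r_cerna) %in% dropped)
  }
  retained <- colnames(cerna_expr)[ok]
  removed <- colnames(cerna_expr)[!ok]
  if (!length(retained)) {
    stop("sample filtering removed every sample", call. = FALSE)
  }
  .cn_msg("sample filter: retained ", length(retained), " of ",
          ncol(cerna_expr), " samples")
  list(cerna_expr = cerna_expr[, retained, drop = FALSE],
       mirna_expr = mirna_expr[, retained, drop = FALSE],
       report = list(cerna_ratio = r_cerna, mirna_ratio = r_mirna,
                     removed = removed, retained = retained))
}

#' Remove non-expressed genes by per-group ratio thresholds
#'
#' A gene is retained iff its expressing-sample ratio at its group's
#' `min_expr` is strictly greater than the group's `min_fraction` (matching
#' the "expression value > 1 in > 80% of cells" style rule). For a miRNA
#' matrix, pass `grouping = NULL` and a single-element `rules` list named
#' `"All"`.
#'
#' @param expr Expression matrix.
#' @param grouping Named character vector symbol -> group (from
#'   [assign_groups()]), or `NULL` to treat all rows as one `"All"` group.
#' @param rules Named list: group label -> `list(min_expr=, min_fraction=)`.
#'   Every group present must have a rule.
#' @return A list with `expr` (filtered matrix) and `report` (per-gene ratio,
#'   group, removed/retained symbols).
#' @export
filter_genes <- function(expr, grouping = NULL, rules) {
  if (is.null(grouping)) {
    grouping <- setNames(rep("All", nrow(expr)), rownames(expr))
  }
  grouping <- grouping[rownames(expr)]
  missing_rule <- setdiff(unique(grouping), names(rules))
  if (length(missing_rule)) {
    stop("no filter rule for group(s): ",
         paste(missing_rule, collapse = ", "), call. = FALSE)
  }
  ratio <- numeric(nrow(expr))
  names(ratio) <- rownames(expr)
  ok <- logical(nrow(expr))
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    r <- expressing_sample_ratio(expr[idx, , drop = FALSE],
                                 rules[[g]]$min_expr)
    ratio[idx] <- r
    ok[idx] <- r > rules[[g]]$min_fraction
    if (!any(ok[idx])) {
      warning("gene filter removed every gene of group '", g, "'",
              call. = FALSE)
    }
  }
  retained <- rownames(expr)[ok]
  .cn_msg("gene filter: retained ", length(retained), " of ", nrow(expr),
          " genes")
  list(expr = expr[retained, , drop = FALSE],
       report = list(ratio = ratio, group = grouping,
                     removed = rownames(expr)[!ok], retained = retained))
}

#' Log-transform an expression matrix
#'
#' `value -> log_base(value + pseudocount)`; every shifted value must be
#' strictly positive.
#'
#' @param expr Expression matrix.
#' @param base Logarithm base: 2 (default), `exp(1)` or 10.
#' @param pseudocount Non-negative constant added before the log.
#' @return Transformed matrix of the same shape.
#' @export
log_transform <- function(expr, base = 2, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  shifted <- expr + pseudocount
  if (any(shifted <= 0)) {
    stop("log_transform: non-positive value after adding pseudocount ",
         pseudocount, call. = FALSE)
  }
  log(shifted, base = base)
}

#' Normalize an expression matrix row-wise
#'
#' Per-gene scaling: `minmax` maps each row to \[0, 1\] via
#' `(r - min) / (max - min)`; `zscore` to `(r - mean) / sd` with the sample
#' standard deviation (denominator N-1). A custom function of one row vector
#' may be supplied instead. Degenerate rows (zero range / zero sd) become
#' all-zero with a warning. When combined with a log transform, the log is
#' applied first and normalization second.
#'
#' @param expr Expression matrix.
#' @param method `"minmax"`, `"zscore"`, or a function mapping a numeric
#'   vector to a numeric vector of the same length.
#' @return Normalized matrix of the same shape.
#' @export
normalize_expression <- function(expr, method = c("minmax", "zscore")) {
  if (is.function(method)) {
    out <- t(apply(expr, 1L, method))
    dimnames(out) <- dimnames(expr)
    return(out)
  }
  method <- match.arg(method)
  n_flat <- 0L
  fun <- switch(method,
    minmax = function(r) {
      rng <- range(r)
      if (rng[1L] == rng[2L]) {
        n_flat <<- n_flat + 1L
        return(rep(0, length(r)))
      }
      (r - rng[1L]) / (rng[2L] - rng[1L])
    },
    zscore = function(r) {
      s <- sd(r)
      if (s == 0) {
        n_flat <<- n_flat + 1L
        return(rep(0, length(r)))
      }
      (r - mean(r)) / s
    })
  out <- t(apply(expr, 1L, fun))
  dimnames(out) <- dimnames(expr)
  if (n_flat > 0L) {
    warning(n_flat, " constant row(s) set to all-zero under ", method,
            " scaling", call. = FALSE)
  }
  out
}

#' Histogram table of a ratio vector
#'
#' Bins a vector of ratios (or any numeric values) into a plain table of bin
#' edges and counts — the batch replacement for on-screen histograms.
#'
#' @param x Numeric vector.
#' @param breaks Number of bins or explicit break points.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
histogram_table <- function(x, breaks = 20L) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(bin_lo = h$breaks[-length(h$breaks)],
             bin_hi = h$breaks[-1L],
             count = h$counts)
}
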