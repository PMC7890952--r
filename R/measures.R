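#' Shared-miRNA enrichment significance (MS)
#'
#' Hypergeometric upper-tail probability that two transcripts share at least
#' their observed number of targeting miRNAs:
#' \deqn{MS = 1 - \sum_{i=0}^{t-1} \binom{T_1}{i}\binom{Q-T_1}{T_2-i} /
#'   \binom{Q}{T_2} = P(X \ge t)}
#' with population size `Q` (the miRNA universe), `T1` miRNAs targeting the
#' first gene, `T2` draws (miRNAs targeting the second gene) and `t` shared
#' miRNAs. Computed through the hypergeometric survival function, which
#' evaluates the tail in a numerically safe way. `t = 0` gives exactly 1
#' (empty sum). Small values mean the pair shares more miRNAs than chance
#' predicts.
#'
#' @param t Number of shared miRNAs, `0 <= t <= min(T1, T2)`.
#' @param T1,T2 Number of miRNAs targeting each gene, both `<= Q`.
#' @param Q Total number of considered miRNAs.
#' @return Probability in \[0, 1\]. Vectorized over its arguments.
#' @export
#' @examples
#' ms(3, 4, 5, 10)  # 66/252
ms <- function(t, T1, T2, Q) {
  if (any(t < 0 | T1 < 0 | T2 < 0 | Q < 0 | t > pmin(T1, T2) |
          T1 > Q | T2 > Q)) {
    stop("ms: need 0 <= t <= min(T1, T2) and T1, T2 <= Q", call. = FALSE)
  }
  ifelse(t == 0, 1,
         phyper(t - 1, m = T1, n = Q - T1, k = T2, lower.tail = FALSE))
}

#' Pearson correlation coefficient of two expression vectors
#'
#' Standard product-moment correlation. A constant vector has no defined
#' correlation: the result is `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("pcc undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)
}

#' Discretize an expression vector into bins
#'
#' `equal_frequency` (default) assigns bin `floor((rank - 1) / N * n_bins)`
#' using average ranks, so tied values always share a bin and, absent ties,
#' bin sizes differ by at most one. `equal_width` partitions
#' `[min(x), max(x)]` into `n_bins` uniform intervals, final bin
#' right-closed. A constant vector occupies the single bin 0 with a warning.
#'
#' @param x Numeric vector, `length(x) >= n_bins`.
#' @param n_bins Number of bins (>= 2); default `max(2, floor(sqrt(N)))`, a
#'   standard plug-in rule for MI estimation.
#' @param method `"equal_frequency"` or `"equal_width"`.
#' @return Integer vector of 0-based bin labels, attribute `n_bins` attached.
#' @export
discretize <- function(x, n_bins = max(2L, floor(sqrt(length(x)))),
                       method = c("equal_frequency", "equal_width")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(n_bins >= 2L, n >= n_bins)
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    warning("discretize: constant vector occupies a single bin",
            call. = FALSE)
    labels <- rep(0L, n)
  } else if (method == "equal_frequency") {
    r <- rank(x, ties.method = "average")
    labels <- as.integer(pmin(floor((r - 1) / n * n_bins), n_bins - 1L))
  } else {
    width <- (rng[2L] - rng[1L]) / n_bins
    labels <- as.integer(pmin(floor((x - rng[1L]) / width), n_bins - 1L))
  }
  attr(labels, "n_bins") <- as.integer(n_bins)
  labels
}

#' Mutual information of two discretized vectors
#'
#' Plug-in estimator from the empirical joint frequency table,
#' \deqn{MI = \sum_{r_1, r_2} p(r_1, r_2) \log \frac{p(r_1, r_2)}
#'   {p(r_1)\,p(r_2)}}
#' in nats (natural log), with the convention `0 log 0 = 0`.
#'
#' @param dx,dy Discretized label vectors of equal length (see
#'   [discretize()]).
#' @return Non-negative mutual information in nats.
#' @export
mi <- function(dx, dy) {
  stopifnot(length(dx) == length(dy))
  joint <- table(dx, dy) / length(dx)
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  sum(terms[joint > 0])
}

#' Conditional mutual information given a discretized conditioning variable
#'
#' Plug-in estimator of `CMI(X; Y | Z)` from the empirical three-way joint:
#' \deqn{CMI = \sum_{r_1, r_2, z} p(r_1, r_2, z)
#'   \log \frac{p(z)\,p(r_1, r_2, z)}{p(r_1, z)\,p(r_2, z)}}
#' in nats, `0 log 0 = 0`. In the ceRNA setting `dz` is the discretized sum
#' of the pair's shared-miRNA expression; conditioning on a constant reduces
#' CMI to plain MI.
#'
#' @param dx,dy,dz Discretized label vectors of equal length.
#' @return Non-negative conditional mutual information in nats.
#' @export
cmi <- function(dx, dy, dz) {
  stopifnot(length(dx) == length(dy), length(dx) == length(dz))
  n <- length(dx)
  joint <- table(dx, dy, dz) / n
  pz <- apply(joint, 3L, sum)
  pxz <- apply(joint, c(1L, 3L), sum)
  pyz <- apply(joint, c(2L, 3L), sum)
  total <- 0
  for (k in seq_along(pz)) {
    jk <- joint[, , k]
    denom <- outer(pxz[, k], pyz[, k])
    pos <- jk > 0
    total <- total + sum(jk[pos] * log(pz[k] * jk[pos] / denom[pos]))
  }
  total
}

#' Van der Waerden normal scores
#'
#' Rank-based normal scores \eqn{\Phi^{-1}(r_i / (N + 1))} with average ranks
#' for ties. Invariant under strictly monotone transforms of the input.
#'
#' @param v Numeric vector, length >= 3.
#' @return Numeric vector of normal scores.
#' @export
#' @examples
#' vdw_scores(c(10, 20, 30))  # qnorm(c(.25, .5, .75))
vdw_scores <- function(v) {
  stopifnot(length(v) >= 3L)
  qnorm(rank(v, ties.method = "average") / (length(v) + 1))
}

#' Liquid association of a gene pair with respect to a modulator profile
#'
#' \deqn{LA = \frac{1}{N} \sum_{i=1}^{N} z_i(x)\, z_i(y)\, norm_i(m)}
#' where `z` is the per-vector z-score (sample sd, denominator N-1 — the
#' same convention as [normalize_expression()]) and `norm` the Van der
#' Waerden scores of the modulator `m` (here: summed shared-miRNA
#' expression). Measures how the modulator level modulates the pair's
#' co-expression. Constant `x` or `y` gives `NA` with a warning; a constant
#' modulator gives exactly 0 (all VdW scores are \eqn{\Phi^{-1}(1/2) = 0}).
#'
#' @param x,y Expression vectors of the gene pair.
#' @param m Modulator expression vector (summed shared-miRNA expression).
#' @return Liquid association score, or `NA`.
#' @export
la <- function(x, y, m) {
  stopifnot(length(x) == length(y), length(x) == length(m), length(x) >= 3L)
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) {
    warning("la undefined for a constant expression vector", call. = FALSE)
    return(NA_real_)
  }
  zx <- (x - mean(x)) / sx
  zy <- (y - mean(y)) / sy
  mean(zx * zy * vdw_scores(m))
}

#' Shared-miRNA context of a candidate ceRNA pair
#'
#' Collects everything the miRNA-dependent measures need for one pair: the
#' shared targeting miRNAs within the considered universe, the counts
#' `T1`, `T2`, `t`, `Q` feeding [ms()], and the per-sample sum of the shared
#' miRNAs' expression (the modulator for [cmi()] and [la()]; `NULL` when
#' `t = 0`).
#'
#' @param gene1,gene2 Gene symbols.
#' @param interactions Interaction data.frame (`mirna`, `target`).
#' @param mirna_expr miRNA expression matrix (miRNAs x samples), or `NULL`
#'   if no expression-based measure is needed.
#' @param universe Character vector: the miRNA universe `Q` (the valid
#'   miRNAs that survive preprocessing and appear in the interaction table).
#' @return List with `gene1`, `gene2`, `shared_mirnas`, `t`, `T1`, `T2`,
#'   `Q`, `summed_mirna_expression`.
#' @export
pair_context <- function(gene1, gene2, interactions, mirna_expr = NULL,
                         universe) {
  m1 <- intersect(interactions$mirna[interactions$target == gene1], universe)
  m2 <- intersect(interactions$mirna[interactions$target == gene2], universe)
  shared <- intersect(m1, m2)
  summed <- NULL
  if (length(shared) && !is.null(mirna_expr)) {
    summed <- colSums(mirna_expr[shared, , drop = FALSE])
  }
  list(gene1 = gene1, gene2 = gene2, shared_mirnas = sort(shared),
       t = length(shared), T1 = length(m1), T2 = length(m2),
       Q = length(universe), summed_mirna_expression = summed)
}

#' Compute selected measures for one candidate pair
#'
#' Low-level single-pair driver used by [compute_measures()]: builds the
#' shared-miRNA context and evaluates each requested measure. CMI and LA are
#' undefined (NA) when the pair shares no miRNA.
#'
#' @param gene1,gene2 Gene symbols present in `cerna_expr`.
#' @param cerna_expr,mirna_expr Expression matrices over identical samples.
#' @param interactions Interaction data.frame.
#' @param universe miRNA universe for [ms()].
#' @param measures Character subset of `c("MS","PCC","MI","CMI","LA")`.
#' @param hooks Named list of user-defined measure functions
#'   `function(x, y, context)`; each contributes one extra column.
#' @param n_bins,disc_method Discretization controls (see [discretize()]).
#' @return Named list: context counts plus one value per measure.
#' @export
measure_pair <- function(gene1, gene2, cerna_expr, mirna_expr, interactions,
                         universe, measures = c("MS", "PCC"), hooks = list(),
                         n_bins = NULL, disc_method = "equal_frequency") {
  ctx <- pair_context(gene1, gene2, interactions, mirna_expr, universe)
  x <- cerna_expr[gene1, ]
  y <- cerna_expr[gene2, ]
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(length(x))))
  out <- list(gene1 = ctx$gene1, gene2 = ctx$gene2, t = ctx$t,
              shared_mirnas = ctx$shared_mirnas)
  dx <- dy <- NULL
  need_disc <- any(c("MI", "CMI") %in% measures)
  if (need_disc) {
    dx <- suppressWarnings(discretize(x, n_bins, disc_method))
    dy <- suppressWarnings(discretize(y, n_bins, disc_method))
  }
  for (mname in measures) {
    out[[mname]] <- switch(mname,
      MS = ms(ctx$t, ctx$T1, ctx$T2, ctx$Q),
      PCC = suppressWarnings(pcc(x, y)),
      MI = mi(dx, dy),
      CMI = if (ctx$t == 0) NA_real_ else {
        dz <- suppressWarnings(discretize(ctx$summed_mirna_expression,
                                          n_bins, disc_method))
        cmi(dx, dy, dz)
      },
      LA = if (ctx$t == 0) NA_real_ else
        suppressWarnings(la(x, y, ctx$summed_mirna_expression)),
      stop("unknown measure '", mname, "'", call. = FALSE))
  }
  for (hname in names(hooks)) {
    out[[hname]] <- hooks[[hname]](x, y, ctx)
  }
  out
}
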