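#' Specification for the synthetic ceRNA fixture generator
#'
#' The generator emulates the shape of a single-cell miRNA/mRNA
#' co-sequencing experiment: FPKM-like non-negative ceRNA values, log-like
#' miRNA values, a sparse bipartite miRNA-target table and a biotype
#' annotation — plus planted competing-endogenous structure. Each planted
#' triad `(m, R1, R2)` couples two genes to one high-variance driver miRNA
#' through shared repression, `e_R = a - b * e_m + noise`, which induces the
#' positive target-target correlation the pair measures are designed to
#' detect; both genes are listed as targets of the driver and of a common
#' set of decoy miRNAs so their shared-miRNA enrichment is strong.
#'
#' @param n_samples Number of samples (default 60).
#' @param n_mirnas Number of miRNAs (default 30).
#' @param n_coding,n_noncoding Numbers of coding / noncoding genes
#'   (defaults 80 / 20).
#' @param n_planted_triads Number of planted triads (default 20).
#' @param noise_sd Gene-level noise sd around the repression line
#'   (default 0.3).
#' @param repression_strength Slope `b` of the miRNA -> target repression
#'   (default 0.8).
#' @param n_shared_mirnas Shared miRNAs per planted pair, driver included
#'   (default 4).
#' @param seed Integer seed; fully determines the output.
#' @return A `cn_fixture_spec` list.
#' @export
fixture_spec <- function(n_samples = 60L, n_mirnas = 30L, n_coding = 80L,
                         n_noncoding = 20L, n_planted_triads = 20L,
                         noise_sd = 0.3, repression_strength = 0.8,
                         n_shared_mirnas = 4L, seed = 0L) {
  spec <- list(n_samples = n_samples, n_mirnas = n_mirnas,
               n_coding = n_coding, n_noncoding = n_noncoding,
               n_planted_triads = n_planted_triads, noise_sd = noise_sd,
               repression_strength = repression_strength,
               n_shared_mirnas = n_shared_mirnas, seed = seed)
  n_genes <- n_coding + n_noncoding
  if (2L * n_planted_triads > n_genes) {
    stop("infeasible spec: ", n_planted_triads, " triads need ",
         2L * n_planted_triads, " genes but only ", n_genes, " exist",
         call. = FALSE)
  }
  if (n_planted_triads > n_mirnas || n_shared_mirnas > n_mirnas) {
    stop("infeasible spec: not enough miRNAs for the planted triads",
         call. = FALSE)
  }
  if (n_samples < 4L) stop("infeasible spec: need >= 4 samples",
                           call. = FALSE)
  structure(spec, class = "cn_fixture_spec")
}

#' Generate a synthetic ceRNA dataset with planted triads
#'
#' See [fixture_spec()] for the generative model. All randomness flows from
#' the single spec seed; two calls with the same spec are identical.
#'
#' @param spec A [fixture_spec()].
#' @return List with `cerna_expr`, `mirna_expr` (matrices),
#'   `interactions`, `annotation` (data.frames), and `ground_truth`
#'   (data.frame: canonical `gene1`, `gene2`, driver `mirna`).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "cn_fixture_spec"))
  withr::with_seed(spec$seed, {
    samples <- sprintf("S%03d", seq_len(spec$n_samples))
    mirnas <- sprintf("mir%03d", seq_len(spec$n_mirnas))
    genes <- c(sprintf("GC%04d", seq_len(spec$n_coding)),
               sprintf("GN%04d", seq_len(spec$n_noncoding)))
    biotype <- c(rep("protein_coding", spec$n_coding),
                 rep("lincRNA", spec$n_noncoding))

    # log2-like miRNA expression; drivers get extra per-sample variance
    mirna_expr <- matrix(rnorm(spec$n_mirnas * spec$n_samples, 5, 1),
                         spec$n_mirnas, spec$n_samples,
                         dimnames = list(mirnas, samples))
    drivers <- sample(mirnas, spec$n_planted_triads)
    mirna_expr[drivers, ] <- matrix(
      rnorm(length(drivers) * spec$n_samples, 5, 2),
      length(drivers), spec$n_samples)

    planted_genes <- sample(genes, 2L * spec$n_planted_triads)
    baseline <- runif(length(genes), 8, 12)
    names(baseline) <- genes
    cerna_expr <- matrix(0, length(genes), spec$n_samples,
                         dimnames = list(genes, samples))
    inter <- list()
    gt <- list()
    for (i in seq_len(spec$n_planted_triads)) {
      r1 <- planted_genes[2L * i - 1L]
      r2 <- planted_genes[2L * i]
      m <- drivers[i]
      decoys <- sample(setdiff(mirnas, m), spec$n_shared_mirnas - 1L)
      shared <- c(m, decoys)
      for (g in c(r1, r2)) {
        cerna_expr[g, ] <- baseline[g] -
          spec$repression_strength * mirna_expr[m, ] +
          rnorm(spec$n_samples, 0, spec$noise_sd)
        inter[[length(inter) + 1L]] <- data.frame(
          mirna = shared, target = g, stringsAsFactors = FALSE)
      }
      cp <- .canonical_pair(r1, r2)
      gt[[i]] <- data.frame(gene1 = cp$gene1, gene2 = cp$gene2, mirna = m,
                            stringsAsFactors = FALSE)
    }
    background <- setdiff(genes, planted_genes)
    for (g in background) {
      cerna_expr[g, ] <- baseline[g] + rnorm(spec$n_samples, 0, 1)
      inter[[length(inter) + 1L]] <- data.frame(
        mirna = sample(mirnas, 2L), target = g, stringsAsFactors = FALSE)
    }
    cerna_expr <- pmax(cerna_expr, 0.01)  # FPKM-like: non-negative

    interactions <- do.call(rbind, inter)
    interactions <- interactions[order(interactions$mirna,
                                       interactions$target), ]
    rownames(interactions) <- NULL
    list(cerna_expr = cerna_expr, mirna_expr = mirna_expr,
         interactions = interactions,
         annotation = data.frame(symbol = genes, biotype = biotype,
                                 stringsAsFactors = FALSE),
         ground_truth = if (length(gt)) do.call(rbind, gt) else
           data.frame(gene1 = character(), gene2 = character(),
                      mirna = character(), stringsAsFactors = FALSE))
  })
}

#' Write a generated fixture to a directory as delimited text
#'
#' Emits the four pipeline inputs plus the ground-truth pair list:
#' `cerna_expr.tsv`, `mirna_expr.tsv`, `interactions.tsv`,
#' `annotation.tsv`, `ground_truth.tsv`.
#'
#' @param fixture Result of [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the five paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cerna_expr.tsv", "mirna_expr.tsv",
                            "interactions.tsv", "annotation.tsv",
                            "ground_truth.tsv"))
  write_expression(fixture$cerna_expr, paths[1L])
  write_expression(fixture$mirna_expr, paths[2L])
  write.table(fixture$interactions, paths[3L], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(fixture$annotation, paths[4L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fixture$ground_truth, paths[5L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Generate synthetic survival data driven by a module score
#'
#' Stand-in for a clinical cohort: per-patient expression of the module
#' genes is standard normal, the patient score is the mean per-gene z-score,
#' and event times are exponential with hazard
#' `base_hazard * exp(effect_size * score)` (so `effect_size = 0` is the
#' null), administratively censored at `horizon`.
#'
#' @param n_patients Number of patients.
#' @param module_genes Character vector of gene symbols.
#' @param effect_size Log-hazard slope per unit score (default 1).
#' @param base_hazard Baseline exponential hazard (default 0.2).
#' @param horizon Censoring horizon (default 10).
#' @param seed Integer seed.
#' @return List with `surv_table` (data.frame `sample`, `time`, `event`)
#'   and `expr` (genes x patients matrix).
#' @export
generate_survival <- function(n_patients, module_genes, effect_size = 1,
                              base_hazard = 0.2, horizon = 10, seed = 0L) {
  stopifnot(n_patients >= 4L, length(module_genes) >= 1L)
  withr::with_seed(seed, {
    patients <- sprintf("P%04d", seq_len(n_patients))
    expr <- matrix(rnorm(length(module_genes) * n_patients),
                   length(module_genes), n_patients,
                   dimnames = list(module_genes, patients))
    z <- suppressWarnings(normalize_expression(expr, "zscore"))
    score <- colMeans(z)
    raw <- rexp(n_patients, rate = base_hazard * exp(effect_size * score))
    event <- as.numeric(raw <= horizon)
    time <- pmin(raw, horizon)
    list(surv_table = data.frame(sample = patients, time = time,
                                 event = event, stringsAsFactors = FALSE),
         expr = expr)
  })
}
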