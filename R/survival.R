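#' Kaplan-Meier product-limit survival curve
#'
#' \deqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over distinct event times `t_i` with `d_i` events among `n_i` at risk.
#' With no censoring this reproduces the empirical survival function. An
#' all-censored input yields a flat curve at 1 with a warning.
#'
#' @param times Positive event/censoring times.
#' @param events Event indicator, 1 = event, 0 = censored.
#' @return A list with `time` (distinct event times), `n_risk`, `n_event`,
#'   `survival` (curve values at each event time) and `median` (smallest
#'   time with survival <= 0.5, NA if never reached).
#' @export
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 0))$survival  # 2/3, 1/3
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  if (!any(events == 1)) {
    warning("no events: survival curve is flat at 1", call. = FALSE)
    return(list(time = numeric(), n_risk = integer(), n_event = integer(),
                survival = numeric(), median = NA_real_))
  }
  ev_times <- sort(unique(times[events == 1]))
  n_risk <- vapply(ev_times, function(tt) sum(times >= tt), numeric(1L))
  n_event <- vapply(ev_times, function(tt) sum(times == tt & events == 1),
                    numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) ev_times[which(surv <= 0.5)[1L]] else
    NA_real_
  list(time = ev_times, n_risk = as.integer(n_risk),
       n_event = as.integer(n_event), survival = surv, median = med)
}

#' Log-rank test for two or more survival groups
#'
#' Standard (unweighted) log-rank: at each distinct event time the observed
#' per-group event counts are compared with their hypergeometric
#' expectations given the risk sets; the chi-square statistic aggregates
#' `(O - E)` against the variance-covariance of the increments, with
#' `k - 1` degrees of freedom for `k` groups.
#'
#' @param group_labels Group membership per subject (>= 2 groups, each
#'   non-empty).
#' @param times,events As in [km_curve()].
#' @return List with `statistic`, `df`, `p_value`, and the per-group
#'   `observed` and `expected` event counts.
#' @export
logrank <- function(group_labels, times, events) {
  stopifnot(length(group_labels) == length(times),
            length(times) == length(events))
  groups <- sort(unique(group_labels))
  k <- length(groups)
  if (k < 2L) stop("log-rank needs >= 2 groups", call. = FALSE)
  ev_times <- sort(unique(times[events == 1]))
  if (!length(ev_times)) stop("log-rank needs >= 1 event", call. = FALSE)
  O <- E <- setNames(numeric(k), groups)
  V <- matrix(0, k, k, dimnames = list(groups, groups))
  for (tt in ev_times) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    d <- sum(times == tt & events == 1)
    n_g <- vapply(groups, function(g) sum(at_risk & group_labels == g),
                  numeric(1L))
    d_g <- vapply(groups, function(g)
      sum(times == tt & events == 1 & group_labels == g), numeric(1L))
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      # hypergeometric variance-covariance of the event-count increment
      V <- V + d * (n - d) / (n - 1) *
        (diag(n_g / n, k) - outer(n_g / n, n_g / n))
    }
  }
  keep <- seq_len(k - 1L)
  diff <- (O - E)[keep]
  Vsub <- V[keep, keep, drop = FALSE]
  stat <- tryCatch(drop(t(diff) %*% solve(Vsub, diff)),
                   error = function(e) {
                     drop(t(diff) %*% MASS_ginv(Vsub) %*% diff)
                   })
  df <- k - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       observed = O, expected = E)
}

# Moore-Penrose pseudoinverse via SVD; fallback for a singular log-rank
# variance matrix (e.g. a group with no one at risk past the first events).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1L]
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Stratify patients by module expression
#'
#' Scores each patient by the mean of the per-gene z-scores of the module
#' genes (z over patients, sample sd), then splits at the median score:
#' `"low"` when strictly below the median, `"high"` otherwise. This is a
#' concrete default for "patient clustering by module expression";
#' `rule = "kmeans"` (2-means on the score, seeded) is an alternative.
#'
#' @param expr Expression matrix, genes x patients.
#' @param module_genes Character vector of module gene symbols; those absent
#'   from `expr` are dropped with a message (none found is an error).
#' @param rule `"median"` (default) or `"kmeans"`.
#' @param seed Seed for the kmeans rule.
#' @return List with `labels` (named "low"/"high" per patient) and `score`.
#' @export
stratify_by_module <- function(expr, module_genes, rule = c("median",
                                                            "kmeans"),
                               seed = 0L) {
  rule <- match.arg(rule)
  found <- intersect(module_genes, rownames(expr))
  if (!length(found)) {
    stop("none of the module genes are in the expression matrix",
         call. = FALSE)
  }
  if (length(found) < length(module_genes)) {
    .cn_msg(length(module_genes) - length(found),
            " module gene(s) absent from patient expression; dropped")
  }
  z <- suppressWarnings(
    normalize_expression(expr[found, , drop = FALSE], "zscore"))
  score <- colMeans(z)
  if (rule == "median") {
    med <- median(score)
    labels <- ifelse(score < med, "low", "high")
    if (all(labels == "high")) {
      warning("degenerate scores: every patient labelled 'high'",
              call. = FALSE)
    }
  } else {
    km <- withr::with_seed(seed, stats::kmeans(score, centers = 2L))
    lo <- which.min(km$centers)
    labels <- ifelse(km$cluster == lo, "low", "high")
  }
  list(labels = setNames(labels, colnames(expr)), score = score)
}

#' Cox proportional hazards fit (thin adapter)
#'
#' Delegates to [survival::coxph()]; returns hazard ratios with 95%
#' confidence intervals. Convergence or separation problems are surfaced
#' verbatim.
#'
#' @param surv_table data.frame with columns `time`, `event`, plus the
#'   covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return data.frame: `covariate`, `hr`, `ci_lo`, `ci_hi`, `p_value`; the
#'   fitted model as attribute `fit`.
#' @export
cox_fit <- function(surv_table, covariates) {
  missing_cov <- setdiff(covariates, colnames(surv_table))
  if (length(missing_cov)) {
    stop("covariate(s) not in table: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  for (cv in covariates) {
    v <- surv_table[[cv]]
    if ((is.numeric(v) && stats::var(v) == 0) ||
        (!is.numeric(v) && length(unique(v)) < 2L)) {
      stop("covariate '", cv, "' is constant; hazard ratio undefined",
           call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = surv_table)
  sm <- summary(fit)
  out <- data.frame(covariate = rownames(sm$coefficients),
                    hr = sm$coefficients[, "exp(coef)"],
                    ci_lo = sm$conf.int[, "lower .95"],
                    ci_hi = sm$conf.int[, "upper .95"],
                    p_value = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Read a survival table from delimited text
#'
#' Columns: sample id, time, event (0/1), then optional covariates.
#'
#' @inheritParams read_annotation
#' @return data.frame with columns `sample`, `time`, `event`, ...
#' @export
read_survival_table <- function(path, delimiter = "auto", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .resolve_delimiter(path, delimiter)
  df <- read.table(path, header = header, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("survival table needs >= 3 columns", call. = FALSE)
  colnames(df)[1:3] <- c("sample", "time", "event")
  df$time <- as.numeric(df$time)
  df$event <- as.numeric(df$event)
  if (any(!is.finite(df$time)) || any(df$time < 0)) {
    stop("survival times must be non-negative numbers", call. = FALSE)
  }
  if (!all(df$event %in% c(0, 1))) {
    stop("event indicator must be 0 or 1", call. = FALSE)
  }
  df
}
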