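#' Paired two-tailed Student's t-test (closed form)
#'
#' Computes the paired t statistic and two-tailed p-value for one miRNA,
#' with explicit handling of the zero-variance pathology that
#' limit-of-detection imputation creates (all paired differences identical,
#' e.g. all cells censored at the ceiling): such records are flagged
#' *degenerate* and carry an undefined (NA) p-value rather than a fabricated
#' one.
#'
#' @param pre,post numeric vectors of equal length `n >= 2`, aligned by
#'   patient.
#' @return list with `t_stat`, `p_value`, `df`, and logical `degenerate`.
#'   For degenerate records `t_stat` and `p_value` are `NA`.
#' @details `t = mean(d) / (sd(d)/sqrt(n))` with `d = post - pre` and the
#'   sample (n-1) standard deviation; `p` is the two-tailed tail probability
#'   of Student's t with `n - 1` degrees of freedom.
#' @export
paired_t_test <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have the same length (got ", length(pre),
         " and ", length(post), ")")
  n <- length(pre)
  if (n < 2L) stop("paired t-test needs n >= 2 pairs, got ", n)
  d <- post - pre
  s <- stats::sd(d)
  if (s == 0)
    return(list(t_stat = NA_real_, p_value = NA_real_, df = n - 1L,
                degenerate = TRUE))
  t_stat <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), df = n - 1L, lower.tail = FALSE)
  list(t_stat = t_stat, p_value = p, df = n - 1L, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment producing q-values: with p-values sorted
#' ascending, `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1 and mapped
#' back to the input order. Undefined entries (`NA`, e.g. degenerate
#' zero-variance records) are excluded before adjustment — `m` counts only
#' defined p-values — and stay `NA` in the output.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`; `NA` allowed.
#' @return numeric vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Paired differential expression table
#'
#' For every miRNA: the log2 fold change (mean post minus mean pre
#' expression on the \eqn{-\Delta CT} scale), paired two-tailed t-test,
#' Benjamini-Hochberg q-value across all testable miRNAs, per-patient
#' direction counts, a directional-consistency call, and the significance
#' flag at `q < q_threshold` (strict).
#'
#' Patients are paired by `patient_id`; the consistency call is `"down"`
#' when at least `consistency_min` patients have a negative paired
#' difference, `"up"` for positive, else `"none"` (zero differences count
#' toward neither direction). Degenerate zero-variance records are excluded
#' from the BH adjustment and are never significant.
#'
#' @param x an `expression_matrix` from [normalize_spike_in()].
#' @param q_threshold FDR significance threshold (default 0.2, strict `<`).
#' @param consistency_min minimum number of same-direction patients for a
#'   consistency call (default 3).
#' @return A data.frame (one row per miRNA) with columns `mirna`, `log2fc`,
#'   `t_stat`, `p_value`, `q_value`, `n_down`, `n_up`, `n_zero`,
#'   `consistent`, `significant`, `degenerate`.
#' @export
run_differential_expression <- function(x, q_threshold = 0.2,
                                        consistency_min = 3) {
  stopifnot(inherits(x, "expression_matrix"))
  s <- x$samples
  .check_paired(s)
  patients <- sort(unique(s$patient_id))
  pre_cols <- vapply(patients, function(p)
    s$sample_id[s$patient_id == p & s$timepoint == "pre"], character(1))
  post_cols <- vapply(patients, function(p)
    s$sample_id[s$patient_id == p & s$timepoint == "post"], character(1))
  pre <- x$expr[, pre_cols, drop = FALSE]
  post <- x$expr[, post_cols, drop = FALSE]
  d <- post - pre

  n <- length(patients)
  res <- data.frame(
    mirna = rownames(x$expr),
    log2fc = rowMeans(post) - rowMeans(pre),
    t_stat = NA_real_, p_value = NA_real_, q_value = NA_real_,
    n_down = as.integer(rowSums(d < 0)),
    n_up = as.integer(rowSums(d > 0)),
    n_zero = as.integer(rowSums(d == 0)),
    consistent = "none", significant = FALSE, degenerate = FALSE,
    stringsAsFactors = FALSE, row.names = NULL)

  for (i in seq_len(nrow(res))) {
    tt <- paired_t_test(pre[i, ], post[i, ])
    res$t_stat[i] <- tt$t_stat
    res$p_value[i] <- tt$p_value
    res$degenerate[i] <- tt$degenerate
  }
  res$q_value <- benjamini_hochberg(res$p_value)
  res$consistent <- ifelse(res$n_down >= consistency_min, "down",
                           ifelse(res$n_up >= consistency_min, "up", "none"))
  res$significant <- !is.na(res$q_value) & res$q_value < q_threshold
  attr(res, "q_threshold") <- q_threshold
  attr(res, "consistency_min") <- consistency_min
  attr(res, "n_patients") <- n
  res
}

#' Top-k miRNAs by nominal p-value
#'
#' Selects the `k` miRNAs with the smallest defined p-values (the selection
#' rule behind "top 25 by p-value" heatmaps). Ties on p are broken by larger
#' `|log2fc|`, then lexicographic miRNA identifier, so the selection is
#' deterministic.
#'
#' @param de a DE table from [run_differential_expression()].
#' @param k number of miRNAs to return (default 25); if fewer testable
#'   records exist, all are returned.
#' @return character vector of miRNA identifiers, p ascending.
#' @export
top_k_by_p <- function(de, k = 25) {
  ok <- !is.na(de$p_value)
  d <- de[ok, , drop = FALSE]
  ord <- order(d$p_value, -abs(d$log2fc), d$mirna)
  d$mirna[ord][seq_len(min(k, nrow(d)))]
}

#' PCA sample scores of an expression matrix
#'
#' Principal component analysis with samples as observations and miRNAs as
#' features. Features are centered but not scaled (all features are already
#' on the common \eqn{-\Delta CT} log2 scale); scores come from the singular
#' value decomposition. For reproducibility, each component's sign is fixed
#' so that the feature with the largest absolute loading has a positive
#' loading.
#'
#' @param x an `expression_matrix`.
#' @param n_components number of components to keep (default 2); must not
#'   exceed `min(n_samples - 1, n_features)`.
#' @param scale. scale features to unit variance? Default `FALSE`.
#' @return list with `sample_ids`, `scores` (sample x component matrix),
#'   `explained_variance_ratio`, and `rotation` (feature loadings).
#' @export
pca_scores <- function(x, n_components = 2, scale. = FALSE) {
  stopifnot(inherits(x, "expression_matrix"))
  X <- t(x$expr)
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples")
  max_comp <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_comp)
    stop("n_components (", n_components, ") exceeds min(samples - 1, ",
         "features) = ", max_comp)
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(n_components)
  scores <- pc$x[, keep, drop = FALSE]
  rot <- pc$rotation[, keep, drop = FALSE]
  for (c in keep) {
    j <- which.max(abs(rot[, c]))
    if (rot[j, c] < 0) {
      rot[, c] <- -rot[, c]
      scores[, c] <- -scores[, c]
    }
  }
  list(sample_ids = rownames(X), scores = scores,
       explained_variance_ratio = evr[keep], rotation = rot)
}
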