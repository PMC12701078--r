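#' Detection-based assay filtering
#'
#' Applies the quality-control filter used for sparse EV-miRNA qPCR data:
#' a target assay is retained iff it was detected (CT below the ceiling) in
#' at least `min_detected` of the pre-intervention samples **or** at least
#' `min_detected` of the post-intervention samples. This keeps miRNAs that
#' are specifically switched on or off by the intervention (fully detected
#' on one side, censored on the other) while discarding assays that are
#' essentially never measured.
#'
#' The spike-in assay is never a candidate miRNA: it is excluded from all
#' report counts but kept in the returned `ct_matrix` so that
#' [normalize_spike_in()] can use it.
#'
#' @param x a [ct_matrix()].
#' @param min_detected minimum number of detected samples required in either
#'   group (default 2); must not exceed the number of patients.
#' @return A list with elements
#'   \describe{
#'     \item{ct}{the filtered `ct_matrix` (retained assays + spike-in).}
#'     \item{report}{a `filter_report`: counts of the three-stage cascade
#'       (`n_assays_total`, `n_detected_any`, `n_retained`) and a data.frame
#'       `dropped_ids` with a drop reason per removed assay
#'       (`"never_detected"` or `"insufficient_detection"`).}
#'   }
#' @export
filter_by_detection <- function(x, min_detected = 2) {
  stopifnot(inherits(x, "ct_matrix"))
  n_pat <- length(unique(x$samples$patient_id))
  if (min_detected > n_pat)
    stop("min_detected (", min_detected, ") exceeds the group size (",
         n_pat, ")")
  targets <- assay_ids(x)
  pre <- x$samples$sample_id[x$samples$timepoint == "pre"]
  post <- x$samples$sample_id[x$samples$timepoint == "post"]
  det <- x$detected[targets, , drop = FALSE]
  n_pre <- rowSums(det[, pre, drop = FALSE])
  n_post <- rowSums(det[, post, drop = FALSE])
  any_det <- (n_pre + n_post) >= 1L
  retained <- n_pre >= min_detected | n_post >= min_detected

  dropped <- targets[!retained]
  reason <- ifelse(any_det[!retained], "insufficient_detection",
                   "never_detected")
  report <- structure(
    list(n_assays_total = length(targets),
         n_detected_any = sum(any_det),
         n_retained = sum(retained),
         min_detected = min_detected,
         dropped_ids = data.frame(assay = dropped, reason = reason,
                                  stringsAsFactors = FALSE)),
    class = "filter_report")

  keep <- c(targets[retained], x$spike_in)
  out <- x
  out$ct <- x$ct[keep, , drop = FALSE]
  out$detected <- x$detected[keep, , drop = FALSE]
  list(ct = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Detection filtering cascade (spike-in excluded):\n")
  cat(sprintf("  %4d target assays on the array\n", x$n_assays_total))
  cat(sprintf("  %4d detected in >=1 sample of either group\n",
              x$n_detected_any))
  cat(sprintf("  %4d retained (detected in >=%d samples of either group)\n",
              x$n_retained, x$min_detected))
  invisible(x)
}

#' Spike-in delta-CT normalization to log2-scale expression
#'
#' Converts CT values to relative log2-scale expression against the
#' exogenous spike-in control added at extraction: for retained miRNA i and
#' sample j,
#' \deqn{expr_{ij} = -\Delta CT_{ij} = -(CT_{ij} - CT_{spike,j}).}
#' Under the usual PCR efficiency-2 assumption, \eqn{-\Delta CT} is
#' log2-scale relative expression: one cycle earlier than the spike-in means
#' a doubling. Per-sample technical offsets (extraction yield, input volume)
#' that shift every assay including the spike-in cancel exactly.
#'
#' Cells imputed at the limit of detection enter the formula with their
#' ceiling value; partially detected miRNAs retained by
#' [filter_by_detection()] therefore contribute censored-at-floor
#' expression values downstream.
#'
#' @param x a [ct_matrix()], normally after [filter_by_detection()].
#' @return An object of class `expression_matrix`: list with `expr`
#'   (miRNA x sample matrix of \eqn{-\Delta CT} values) and `samples`
#'   (the sample metadata). The spike-in assay is excluded from the rows.
#' @export
normalize_spike_in <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  if (!all(x$detected[x$spike_in, ]))
    stop("spike-in '", x$spike_in, "' not detected in every sample; ",
         "normalization undefined")
  targets <- assay_ids(x)
  spike <- x$ct[x$spike_in, ]
  expr <- -sweep(x$ct[targets, , drop = FALSE], 2L, spike, "-")
  structure(list(expr = expr, samples = x$samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$expr), "miRNAs x", ncol(x$expr),
      "samples (-deltaCT, log2 scale)\n")
  invisible(x)
}

#' Write the expression matrix as TSV
#' @param x an `expression_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(mirna = rownames(x$expr), x$expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a filter report as TSV (counts) or JSON
#' @param report a `filter_report` from [filter_by_detection()].
#' @param path output path; `.json` extension selects JSON.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(n_assays_total = report$n_assays_total,
           n_detected_any = report$n_detected_any,
           n_retained = report$n_retained,
           min_detected = report$min_detected,
           dropped = report$dropped_ids),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(
      stage = c("target_assays", "detected_any", "retained"),
      n = c(report$n_assays_total, report$n_detected_any, report$n_retained))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
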