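#' Construct a CT matrix object
#'
#' Low-level constructor for the package's raw-data container: an
#' assay x sample matrix of qPCR cycle-threshold (CT) values together with a
#' detection-status matrix, per-sample metadata for a paired pre/post design,
#' and the identity of the exogenous spike-in assay used for normalization.
#' Most users should obtain a `ct_matrix` from [read_ct_table()] or
#' [simulate_ct()] rather than calling this directly.
#'
#' Cells at or above `ceiling` represent the limit of detection: they hold
#' exactly `ceiling` and are flagged not-detected. The constructor enforces
#' this (clamping and re-flagging as needed) so that the invariant
#' `detected[i,j] <=> ct[i,j] < ceiling` holds for every cell.
#'
#' @param ct numeric matrix of CT values (PCR cycles), assays in rows,
#'   samples in columns; rownames are assay identifiers.
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `timepoint` (values `"pre"`/`"post"`), one row per column of `ct`.
#' @param spike_in assay identifier of the spike-in normalizer
#'   (e.g. `"cel-miR-39-3p"`); must be a row of `ct` and detected in every
#'   sample.
#' @param ceiling CT value representing the limit of detection (default 40).
#' @param detected optional logical matrix; if omitted it is derived as
#'   `ct < ceiling`.
#' @return An object of class `ct_matrix`: a list with elements `ct`,
#'   `detected`, `samples`, `spike_in`, `ceiling`.
#' @seealso [read_ct_table()], [filter_by_detection()], [normalize_spike_in()]
#' @export
ct_matrix <- function(ct, samples, spike_in, ceiling = 40, detected = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix")
  if (is.null(rownames(ct)))
    stop("`ct` must have assay identifiers as rownames")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate assay identifiers in `ct`")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "timepoint")
  if (!all(req %in% names(samples)))
    stop("`samples` needs columns: ", paste(req, collapse = ", "))
  if (nrow(samples) != ncol(ct))
    stop("`samples` rows (", nrow(samples), ") != ct columns (", ncol(ct), ")")
  samples$sample_id <- as.character(samples$sample_id)
  samples$patient_id <- as.character(samples$patient_id)
  samples$timepoint <- as.character(samples$timepoint)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in `samples`")
  if (!all(samples$timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'")
  colnames(ct) <- samples$sample_id
  if (anyNA(ct))
    stop("`ct` contains NA; undetermined cells must be imputed to the ceiling")

  # clamp at the limit of detection and derive/repair detection flags
  nd <- ct >= ceiling
  ct[nd] <- ceiling
  if (is.null(detected)) {
    detected <- !nd
  } else {
    if (!identical(dim(detected), dim(ct)))
      stop("`detected` and `ct` dimensions differ")
    detected <- detected & !nd
    ct[!detected] <- ceiling
  }
  dimnames(detected) <- dimnames(ct)

  if (!spike_in %in% rownames(ct))
    stop("spike-in assay '", spike_in, "' not present in the CT table")
  if (!all(detected[spike_in, ]))
    stop("spike-in assay '", spike_in, "' not detected in sample(s): ",
         paste(samples$sample_id[!detected[spike_in, ]], collapse = ", "),
         " (normalization undefined)")
  .check_paired(samples)

  structure(
    list(ct = ct, detected = detected, samples = samples,
         spike_in = spike_in, ceiling = ceiling),
    class = "ct_matrix"
  )
}

.check_paired <- function(samples) {
  for (p in unique(samples$patient_id)) {
    tps <- samples$timepoint[samples$patient_id == p]
    if (!(sum(tps == "pre") == 1 && sum(tps == "post") == 1))
      stop("patient '", p, "' must have exactly one 'pre' and one 'post' ",
           "sample (found: ", paste(tps, collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("ct_matrix:", nrow(x$ct), "assays x", ncol(x$ct), "samples\n")
  cat("  patients:", length(unique(x$samples$patient_id)),
      "(paired pre/post)\n")
  cat("  spike-in:", x$spike_in, " ceiling:", x$ceiling, "cycles\n")
  tgt <- setdiff(rownames(x$ct), x$spike_in)
  cat("  detection:", sum(x$detected[tgt, , drop = FALSE]), "of",
      length(tgt) * ncol(x$ct), "target cells below ceiling\n")
  invisible(x)
}

#' Assay identifiers of a CT matrix
#' @param x a `ct_matrix`.
#' @param include_spike_in include the spike-in assay? Default `FALSE`.
#' @return character vector of assay identifiers.
#' @export
assay_ids <- function(x, include_spike_in = FALSE) {
  stopifnot(inherits(x, "ct_matrix"))
  ids <- rownames(x$ct)
  if (!include_spike_in) ids <- setdiff(ids, x$spike_in)
  ids
}

# Parse one vector of raw CT tokens. "undetermined" (any case) and empty
# cells are imputed at the ceiling and flagged not-detected; numeric values
# >= ceiling are clamped likewise; anything else non-numeric is a fatal
# error reported with its position.
.parse_ct_tokens <- function(tokens, ceiling, where) {
  tokens <- trimws(as.character(tokens))
  undet <- tolower(tokens) == "undetermined" | tokens == "" | is.na(tokens)
  ct <- suppressWarnings(as.numeric(tokens))
  bad <- !undet & is.na(ct)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("non-numeric CT value '", tokens[i], "' at ", where[i],
         " (only numbers or 'undetermined' are allowed)")
  }
  ct[undet] <- ceiling
  detected <- !undet & ct < ceiling
  ct[!detected] <- ceiling
  list(ct = ct, detected = detected)
}

.read_delim_guess <- function(path, sep = NULL, header = TRUE) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, sep = sep, header = header, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

.resolve_sample_meta <- function(sample_meta, sep = NULL) {
  if (is.character(sample_meta) && length(sample_meta) == 1L) {
    if (!file.exists(sample_meta))
      stop("sample metadata file not found: ", sample_meta)
    sample_meta <- .read_delim_guess(sample_meta, sep)
  }
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "timepoint")
  if (!all(req %in% names(sample_meta)))
    stop("sample metadata needs columns: ", paste(req, collapse = ", "))
  sample_meta[req]
}

#' Read a qPCR CT export into a `ct_matrix`
#'
#' Reads a tabular CT export in one of two documented dialects and applies
#' the limit-of-detection imputation policy: cells whose value is the literal
#' `"undetermined"` (case-insensitive) or empty are imputed to `ceiling` and
#' flagged not-detected; numeric cells at or above `ceiling` are clamped to
#' `ceiling` and flagged not-detected; numeric cells below `ceiling` are kept
#' and flagged detected.
#'
#' Dialects:
#' \describe{
#'   \item{wide}{first column = assay identifier; one column per sample.
#'     Sample metadata (patient, timepoint) must be supplied via
#'     `sample_meta`.}
#'   \item{long}{columns `assay`, `sample`, `ct`, optionally `patient` and
#'     `timepoint` inline (the canonical format written by
#'     [write_ct_table()]); otherwise metadata comes from `sample_meta`.}
#' }
#'
#' @param path path to a CSV/TSV file (UTF-8, header row required; separator
#'   guessed from the extension unless `sep` is given).
#' @param format `"wide"` or `"long"`.
#' @param spike_in assay identifier of the spike-in normalizer; it must be
#'   present and detected in every sample, otherwise the read fails.
#' @param ceiling imputation ceiling in cycles (default 40): the CT value
#'   representing the limit of detection.
#' @param sample_meta data.frame (or path to a TSV/CSV) with columns
#'   `sample_id`, `patient_id`, `timepoint`; required for the wide dialect
#'   and for long files without inline metadata columns.
#' @param sep field separator; `NULL` (default) guesses from the extension.
#' @return A [ct_matrix()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "assay\tS1\tS2",
#'   "cel-miR-39-3p\t20\t20.5",
#'   "hsa-miR-21-5p\t27.31\tundetermined"), tf)
#' meta <- data.frame(sample_id = c("S1", "S2"),
#'                    patient_id = c("P1", "P1"),
#'                    timepoint = c("pre", "post"))
#' x <- read_ct_table(tf, "wide", spike_in = "cel-miR-39-3p",
#'                    sample_meta = meta)
#' x$ct["hsa-miR-21-5p", ]      # 27.31, 40 (imputed)
#' x$detected["hsa-miR-21-5p", ]
#' @export
read_ct_table <- function(path, format = c("wide", "long"), spike_in,
                          ceiling = 40, sample_meta = NULL, sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- .read_delim_guess(path, sep)
  if (format == "wide") {
    if (ncol(tab) < 2L) stop("wide CT table needs an assay column plus at ",
                             "least one sample column: ", path)
    assays <- trimws(tab[[1L]])
    if (anyDuplicated(assays))
      stop("duplicate assay row(s) in wide table: ",
           paste(unique(assays[duplicated(assays)]), collapse = ", "))
    sample_ids <- colnames(tab)[-1L]
    ct <- matrix(NA_real_, nrow(tab), length(sample_ids),
                 dimnames = list(assays, sample_ids))
    det <- ct == 0
    for (j in seq_along(sample_ids)) {
      parsed <- .parse_ct_tokens(
        tab[[j + 1L]], ceiling,
        sprintf("row %d, column '%s'", seq_len(nrow(tab)) + 1L,
                sample_ids[j]))
      ct[, j] <- parsed$ct
      det[, j] <- parsed$detected
    }
    if (is.null(sample_meta))
      stop("wide format requires `sample_meta` (sample_id, patient_id, ",
           "timepoint)")
    meta <- .resolve_sample_meta(sample_meta, sep)
  } else {
    names(tab) <- tolower(names(tab))
    if (!all(c("assay", "sample", "ct") %in% names(tab)))
      stop("long CT table needs columns assay, sample, ct: ", path)
    key <- paste(tab$assay, tab$sample, sep = "\r")
    if (anyDuplicated(key)) {
      d <- tab[duplicated(key), , drop = FALSE][1L, ]
      stop("duplicate (assay, sample) record in long table: ('",
           d$assay, "', '", d$sample, "')")
    }
    parsed <- .parse_ct_tokens(
      tab$ct, ceiling, sprintf("row %d, column 'ct'", seq_len(nrow(tab)) + 1L))
    assays <- unique(trimws(tab$assay))
    sample_ids <- unique(trimws(tab$sample))
    ct <- matrix(NA_real_, length(assays), length(sample_ids),
                 dimnames = list(assays, sample_ids))
    det <- matrix(FALSE, length(assays), length(sample_ids),
                  dimnames = list(assays, sample_ids))
    idx <- cbind(match(trimws(tab$assay), assays),
                 match(trimws(tab$sample), sample_ids))
    ct[idx] <- parsed$ct
    det[idx] <- parsed$detected
    if (anyNA(ct)) {
      miss <- which(is.na(ct), arr.ind = TRUE)[1L, ]
      stop("long table is not complete: no record for assay '",
           assays[miss[1L]], "', sample '", sample_ids[miss[2L]], "'")
    }
    if (all(c("patient", "timepoint") %in% names(tab)) &&
        is.null(sample_meta)) {
      meta <- unique(data.frame(sample_id = trimws(tab$sample),
                                patient_id = trimws(tab$patient),
                                timepoint = trimws(tab$timepoint),
                                stringsAsFactors = FALSE))
      if (anyDuplicated(meta$sample_id))
        stop("inconsistent patient/timepoint metadata for a sample in ", path)
    } else {
      if (is.null(sample_meta))
        stop("long format without inline patient/timepoint columns requires ",
             "`sample_meta`")
      meta <- .resolve_sample_meta(sample_meta, sep)
    }
  }
  meta <- meta[match(colnames(ct), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (anyNA(meta$sample_id))
    stop("sample metadata is missing entries for: ",
         paste(setdiff(colnames(ct), meta$sample_id), collapse = ", "))
  ct_matrix(ct, meta, spike_in = spike_in, ceiling = ceiling, detected = det)
}

#' Write a `ct_matrix` in the canonical long format
#'
#' Emits one row per (assay, sample) cell with columns
#' `assay, sample, patient, timepoint, ct, detected`, tab-separated. Cells at
#' the limit of detection can alternatively be written as the literal token
#' `"undetermined"` (as a raw instrument export would), in which case the
#' `detected` column is omitted.
#'
#' @param x a `ct_matrix`.
#' @param path output file path.
#' @param censored_as `"numeric"` writes the imputed ceiling value plus a
#'   `detected` column; `"undetermined"` writes the literal token for
#'   censored cells.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, censored_as = c("numeric", "undetermined")) {
  stopifnot(inherits(x, "ct_matrix"))
  censored_as <- match.arg(censored_as)
  long <- data.frame(
    assay = rep(rownames(x$ct), times = ncol(x$ct)),
    sample = rep(colnames(x$ct), each = nrow(x$ct)),
    stringsAsFactors = FALSE
  )
  m <- x$samples[match(long$sample, x$samples$sample_id), ]
  long$patient <- m$patient_id
  long$timepoint <- m$timepoint
  # %.17g so that re-reading reproduces the doubles bit-for-bit
  ctv <- sprintf("%.17g", as.vector(x$ct))
  if (censored_as == "numeric") {
    long$ct <- ctv
    long$detected <- as.vector(x$detected)
  } else {
    ctv[!as.vector(x$detected)] <- "undetermined"
    long$ct <- ctv
  }
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
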