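#' Normalize a miRNA identifier
#'
#' Cleans a raw assay-style miRNA label into a canonical matching key plus a
#' display form, so that array annotations can be joined against target
#' databases. Cleaning: trim whitespace, drop assay-suffix decorations
#' (anything after the first internal whitespace or underscore), and ensure
#' a species prefix (`default_species` is prepended when the name starts
#' with `mir`/`let`). The matching key is the lower-cased cleaned name; the
#' display form keeps the conventional capitalisation of the input
#' (e.g. `"hsa-miR-505-3p"`).
#'
#' @param raw character vector of raw identifiers.
#' @param default_species species prefix assumed when absent
#'   (default `"hsa"`).
#' @return list with character vectors `key` and `display`, same length as
#'   `raw`.
#' @examples
#' normalize_mirna_id(" HSA-MIR-505-3P ")$key   # "hsa-mir-505-3p"
#' normalize_mirna_id("miR-21-5p")$key          # "hsa-mir-21-5p"
#' normalize_mirna_id("hsa-miR-181b-5p_002284")$display # "hsa-miR-181b-5p"
#' @export
normalize_mirna_id <- function(raw, default_species = "hsa") {
  raw <- as.character(raw)
  cleaned <- trimws(raw)
  cleaned <- sub("[[:space:]_].*$", "", cleaned)
  if (any(cleaned == ""))
    stop("miRNA identifier empty after cleaning: '",
         raw[which(cleaned == "")[1L]], "'")
  no_prefix <- grepl("^(mir|let)", tolower(cleaned))
  cleaned[no_prefix] <- paste0(default_species, "-", cleaned[no_prefix])
  list(key = tolower(cleaned), display = cleaned)
}

#' Read a miRNA-to-target-gene map
#'
#' Loads a two-column TSV of experimentally validated miRNA-target
#' interactions (miRTarBase-style: `mirna`, `gene`; header optional;
#' duplicate rows allowed). Identifiers are normalized with
#' [normalize_mirna_id()]; gene symbols are trimmed and upper-cased; rows
#' with a missing field are skipped and counted.
#'
#' @param path TSV file path.
#' @param default_species passed to [normalize_mirna_id()].
#' @return A `target_map`: named list, canonical miRNA key -> sorted unique
#'   character vector of gene symbols; attribute `n_malformed` counts the
#'   skipped rows.
#' @export
read_target_map <- function(path, default_species = "hsa") {
  if (!file.exists(path)) stop("target map file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "\"",
                           colClasses = "character", fill = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("target map must have two columns (mirna, gene): ",
                           path)
  tab <- tab[, 1:2]
  names(tab) <- c("mirna", "gene")
  # header row is optional; recognise common column labels
  h1 <- tolower(trimws(tab$mirna[1L])); h2 <- tolower(trimws(tab$gene[1L]))
  if (h1 %in% c("mirna", "mir", "mirna_id", "microrna") ||
      h2 %in% c("gene", "target", "gene_symbol", "symbol", "target_gene"))
    tab <- tab[-1L, , drop = FALSE]
  mir <- trimws(tab$mirna)
  gene <- toupper(trimws(tab$gene))
  bad <- mir == "" | gene == "" | is.na(mir) | is.na(gene)
  n_malformed <- sum(bad)
  if (n_malformed > 0)
    warning(n_malformed, " malformed row(s) skipped in ", path)
  mir <- mir[!bad]; gene <- gene[!bad]
  if (length(mir) == 0L) stop("no valid (mirna, gene) rows in ", path)
  key <- normalize_mirna_id(mir, default_species)$key
  map <- lapply(split(gene, key), function(g) sort(unique(g)))
  structure(map, class = "target_map", n_malformed = n_malformed)
}

#' @export
print.target_map <- function(x, ...) {
  cat("target_map:", length(x), "miRNAs ->",
      length(unique(unlist(x, use.names = FALSE))), "unique genes\n")
  invisible(x)
}

#' Ranked target-gene list from differential miRNA expression
#'
#' Translates per-miRNA fold changes into a ranked list of their validated
#' target genes using the inverse-regulation convention: since a miRNA
#' represses its targets, a *down*-regulated miRNA predicts *de-repression*
#' of its targets. Each gene receives the score
#' `metric = -log2FC` of its most strongly regulated targeting miRNA
#' (largest `|log2FC|`; ties broken by smaller p-value, then lexicographic
#' miRNA key), and genes are sorted by metric, non-increasing (gene-symbol
#' ties lexicographic), ready for preranked GSEA.
#'
#' @param de a DE table from [run_differential_expression()].
#' @param targets a `target_map` from [read_target_map()] or
#'   [simulate_targets_and_sets()].
#' @param selection which miRNAs feed the ranking: `"all_retained"`
#'   (default; every testable miRNA, giving GSEA a dense background) or
#'   `"nominal_p"` (only miRNAs with p < 0.05).
#' @return A data.frame with columns `gene`, `metric`, `provenance`
#'   (canonical key of the scoring miRNA), sorted by metric descending.
#' @export
build_ranked_list <- function(de, targets,
                              selection = c("all_retained", "nominal_p")) {
  selection <- match.arg(selection)
  stopifnot(is.data.frame(de), inherits(targets, "target_map"))
  keep <- !is.na(de$log2fc)
  if (selection == "nominal_p")
    keep <- keep & !is.na(de$p_value) & de$p_value < 0.05
  de <- de[keep, , drop = FALSE]
  if (nrow(de) == 0L) stop("no miRNAs selected for ranking")
  key <- normalize_mirna_id(de$mirna)$key
  in_map <- key %in% names(targets)
  if (!any(in_map))
    stop("no selected miRNA has targets in the map; DE keys: ",
         paste(utils::head(sort(key), 5), collapse = ", "),
         " ... map keys: ",
         paste(utils::head(sort(names(targets)), 5), collapse = ", "))
  de <- de[in_map, , drop = FALSE]
  key <- key[in_map]

  genes_per_mirna <- targets[key]
  long <- data.frame(
    gene = unlist(genes_per_mirna, use.names = FALSE),
    key = rep(key, lengths(genes_per_mirna)),
    log2fc = rep(de$log2fc, lengths(genes_per_mirna)),
    p = rep(de$p_value, lengths(genes_per_mirna)),
    stringsAsFactors = FALSE)
  # per gene: miRNA with the largest |log2FC|, ties by p then key
  ord <- order(long$gene, -abs(long$log2fc), long$p, long$key,
               na.last = TRUE)
  long <- long[ord, , drop = FALSE]
  best <- long[!duplicated(long$gene), , drop = FALSE]
  out <- data.frame(gene = best$gene, metric = -best$log2fc,
                    provenance = best$key, stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a ranked gene list as an RNK-style TSV
#' @param ranked data.frame from [build_ranked_list()].
#' @param path output path (two columns gene, metric; no header).
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(
    data.frame(ranked$gene,
               format(ranked$metric, digits = 15, trim = TRUE,
                      scientific = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}
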