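#' Build the tripartite miRNA-gene-pathway network
#'
#' Integrates the three analysis layers into one thresholded network:
#' miRNA nodes are those with nominal `p < mirna_p` (strict); pathway nodes
#' are enriched sets with `q_fdr < pathway_q` (strict); gene nodes are the
#' genes that are **both** validated targets of at least one included miRNA
#' **and** members of at least one included pathway's leading edge (the two
#' conditions hold independently, not necessarily for a linked pair).
#' Edges are typed: `mirna -> gene` (`"targets"`) and `gene -> pathway`
#' (`"leading_edge_member"`), drawn only between included nodes where the
#' defining relation holds.
#'
#' An empty network is a valid result (returned with zero rows), e.g. when
#' no miRNA passes the p threshold.
#'
#' @param de DE table from [run_differential_expression()].
#' @param targets a `target_map`.
#' @param enrich enrichment results from [prerank_gsea()].
#' @param mirna_p nominal p-value threshold for miRNA inclusion
#'   (default 0.05, strict).
#' @param pathway_q FDR threshold for pathway inclusion (default 0.2,
#'   strict).
#' @return A `tripartite_network`: list with data.frames `nodes`
#'   (`id`, `type`, `log2fc`, `p_value`, `nes`, `q_fdr`; statistics are NA
#'   for types they do not apply to) and `edges` (`source`, `type`,
#'   `target`), both in deterministic order (type, then label).
#' @export
build_network <- function(de, targets, enrich, mirna_p = 0.05,
                          pathway_q = 0.2) {
  stopifnot(is.data.frame(de), inherits(targets, "target_map"),
            is.data.frame(enrich))
  inc_m <- !is.na(de$p_value) & de$p_value < mirna_p
  dm <- de[inc_m, , drop = FALSE]
  mkey <- if (nrow(dm)) normalize_mirna_id(dm$mirna)$key else character(0)

  inc_p <- !is.na(enrich$q_fdr) & enrich$q_fdr < pathway_q
  dp <- enrich[inc_p, , drop = FALSE]

  target_union <- unique(unlist(targets[intersect(mkey, names(targets))],
                                use.names = FALSE))
  leading_union <- unique(unlist(dp$leading_edge, use.names = FALSE))
  genes <- sort(intersect(target_union, leading_union))

  # edges between included nodes where the defining relation holds
  e_mg <- data.frame(source = character(0), type = character(0),
                     target = character(0), stringsAsFactors = FALSE)
  if (nrow(dm) && length(genes)) {
    el <- lapply(seq_len(nrow(dm)), function(i) {
      g <- intersect(targets[[mkey[i]]], genes)
      if (length(g)) data.frame(source = dm$mirna[i], type = "targets",
                                target = g, stringsAsFactors = FALSE)
    })
    el <- el[!vapply(el, is.null, logical(1))]
    if (length(el)) e_mg <- do.call(rbind, el)
  }
  e_gp <- data.frame(source = character(0), type = character(0),
                     target = character(0), stringsAsFactors = FALSE)
  if (nrow(dp) && length(genes)) {
    el <- lapply(seq_len(nrow(dp)), function(i) {
      g <- intersect(dp$leading_edge[[i]], genes)
      if (length(g)) data.frame(source = g, type = "leading_edge_member",
                                target = dp$set[i], stringsAsFactors = FALSE)
    })
    el <- el[!vapply(el, is.null, logical(1))]
    if (length(el)) e_gp <- do.call(rbind, el)
  }

  node_block <- function(id, type, log2fc = NA_real_, p_value = NA_real_,
                         nes = NA_real_, q_fdr = NA_real_) {
    n <- length(id)
    data.frame(id = id, type = rep_len(type, n),
               log2fc = rep_len(log2fc, n), p_value = rep_len(p_value, n),
               nes = rep_len(nes, n), q_fdr = rep_len(q_fdr, n),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    node_block(dm$mirna, "mirna", log2fc = dm$log2fc, p_value = dm$p_value),
    node_block(genes, "gene"),
    node_block(dp$set, "pathway", nes = dp$nes, q_fdr = dp$q_fdr))
  type_rank <- match(nodes$type, c("mirna", "gene", "pathway"))
  nodes <- nodes[order(type_rank, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- rbind(e_mg, e_gp)
  edges <- edges[order(match(edges$type, c("targets", "leading_edge_member")),
                       edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 thresholds = c(mirna_p = mirna_p, pathway_q = pathway_q)),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  tab <- table(factor(x$nodes$type, c("mirna", "gene", "pathway")))
  cat("tripartite_network:", nrow(x$nodes), "nodes (",
      tab[["mirna"]], "miRNA,", tab[["gene"]], "gene,", tab[["pathway"]],
      "pathway ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Per-miRNA target-gene degree summary
#'
#' Counts, for every miRNA node in the network, the number of incident
#' target-gene edges (the "targeting k genes" statistic of network hubs),
#' in descending order.
#'
#' @param net a `tripartite_network`.
#' @return data.frame with columns `mirna`, `n_genes`, sorted by `n_genes`
#'   descending (ties by label).
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  mir <- net$nodes$id[net$nodes$type == "mirna"]
  if (length(mir) == 0L)
    return(data.frame(mirna = character(0), n_genes = integer(0)))
  e <- net$edges[net$edges$type == "targets", , drop = FALSE]
  n <- vapply(mir, function(m) sum(e$source == m), integer(1))
  out <- data.frame(mirna = mir, n_genes = n, stringsAsFactors = FALSE)
  out <- out[order(-out$n_genes, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a tripartite network
#'
#' Writes the network with deterministic node and edge ordering, either as
#' GraphML (node type and statistic attributes carried on the vertices,
#' edge type on the edges) or as a plain edge-list TSV
#' (`source`, `type`, `target`) with a node-attribute TSV sidecar
#' (`<path>.nodes.tsv`). Two exports of the same network are byte-identical.
#'
#' @param net a `tripartite_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @seealso [import_network()]
#' @export
export_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  stopifnot(inherits(net, "tripartite_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      data.frame(from = net$edges$source, to = net$edges$target,
                 type = net$edges$type, stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = net$nodes$id, ntype = net$nodes$type,
                            log2fc = net$nodes$log2fc,
                            p_value = net$nodes$p_value,
                            nes = net$nodes$nes, q_fdr = net$nodes$q_fdr,
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Re-import an exported tripartite network
#'
#' Inverse of [export_network()]: reconstructs the `tripartite_network`
#' (thresholds are not stored in the export and are set to `NA`).
#'
#' @param path file written by [export_network()].
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return a `tripartite_network`.
#' @export
import_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    num <- function(a) { a <- as.numeric(a); a[is.nan(a)] <- NA_real_; a }
    nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                        type = igraph::vertex_attr(g, "ntype"),
                        log2fc = num(igraph::vertex_attr(g, "log2fc")),
                        p_value = num(igraph::vertex_attr(g, "p_value")),
                        nes = num(igraph::vertex_attr(g, "nes")),
                        q_fdr = num(igraph::vertex_attr(g, "q_fdr")),
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(source = el[, 1L],
                        type = igraph::edge_attr(g, "type"),
                        target = el[, 2L], stringsAsFactors = FALSE)
  } else {
    edges <- utils::read.table(path, sep = "\t", header = TRUE,
                               colClasses = "character",
                               stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8")
    nodes <- utils::read.table(paste0(path, ".nodes.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE,
                               colClasses = c("character", "character",
                                              rep("numeric", 4)),
                               fileEncoding = "UTF-8")
  }
  type_rank <- match(nodes$type, c("mirna", "gene", "pathway"))
  nodes <- nodes[order(type_rank, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(match(edges$type, c("targets", "leading_edge_member")),
                       edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 thresholds = c(mirna_p = NA_real_, pathway_q = NA_real_)),
            class = "tripartite_network")
}
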