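# Fixture builders and independent oracles used across the suite.
# The oracles deliberately use the most literal formulation available
# (element-by-element loops, double loops) so they stay independent of the
# package's vectorised implementations.

# -- fixtures ----------------------------------------------------------------

make_meta <- function(n_patients) {
  patients <- sprintf("P%02d", seq_len(n_patients))
  data.frame(
    sample_id = c(paste0(patients, "_pre"), paste0(patients, "_post")),
    patient_id = rep(patients, 2L),
    timepoint = rep(c("pre", "post"), each = n_patients),
    stringsAsFactors = FALSE)
}

# ct rows: named list assay -> numeric vector (length 2*n_patients, order
# pre then post); a spike-in row at CT 20 is added unless present
make_ct <- function(rows, n_patients = 5, ceiling = 40,
                    spike_in = "cel-miR-39-3p") {
  meta <- make_meta(n_patients)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  if (!spike_in %in% rownames(m))
    m <- rbind(m, matrix(20, 1, ncol(m), dimnames = list(spike_in, NULL)))
  colnames(m) <- meta$sample_id
  ct_matrix(m, meta, spike_in = spike_in, ceiling = ceiling)
}

make_expression <- function(expr, n_patients = ncol(expr) / 2) {
  meta <- make_meta(n_patients)
  colnames(expr) <- meta$sample_id
  structure(list(expr = expr, samples = meta), class = "expression_matrix")
}

# dyadic grid: doubles exactly representable with few mantissa bits, so
# additive identities hold bit-for-bit
snap <- function(x, k = 8) round(x * 2^k) / 2^k

make_target_map <- function(lst) {
  key <- normalize_mirna_id(names(lst))$key
  structure(stats::setNames(lapply(lst, function(g) sort(unique(toupper(g)))),
                            key),
            class = "target_map", n_malformed = 0L)
}

make_collection <- function(lst) {
  structure(list(sets = lapply(lst, function(g) unique(toupper(g))),
                 descriptions = stats::setNames(rep("", length(lst)),
                                                names(lst))),
            class = "gene_set_collection")
}

make_ranked <- function(genes, metric) {
  data.frame(gene = genes, metric = metric, provenance = NA_character_,
             stringsAsFactors = FALSE)
}

make_de_row <- function(mirna, log2fc = 0, p = NA_real_, q = NA_real_) {
  data.frame(mirna = mirna, log2fc = log2fc, t_stat = NA_real_,
             p_value = p, q_value = q, n_down = 0L, n_up = 0L, n_zero = 0L,
             consistent = "none", significant = FALSE, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

make_enrich_row <- function(set, nes = 1, q = 0.01, leading = character(0)) {
  out <- data.frame(set = set, es = sign(nes) * 0.5, nes = nes,
                    p_nominal = 0.01, q_fdr = q, n_hits = length(leading),
                    stringsAsFactors = FALSE)
  out$leading_edge <- list(leading)
  out
}

# -- independent oracles -----------------------------------------------------

# literal step-by-step running sum, no vectorisation
oracle_es <- function(genes, metric, members, weight = 1) {
  N <- length(genes)
  hit <- genes %in% members
  nh <- sum(hit)
  S <- sum(abs(metric[hit])^weight)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      cur <- cur + if (S == 0) 1 / nh else abs(metric[i])^weight / S
    } else {
      cur <- cur - 1 / (N - nh)
    }
    running[i] <- cur
  }
  # earliest position wins a (numerically) tied maximum deviation
  M <- max(abs(running))
  peak <- which(abs(running) >= M - 1e-9)[1L]
  list(es = running[peak], running = running, peak = peak)
}

# brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, evaluated
# literally from the definition for every i
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# brute-force network node/edge derivation by direct set algebra
oracle_network_sets <- function(de, targets, enrich, mirna_p, pathway_q) {
  mir <- de$mirna[!is.na(de$p_value) & de$p_value < mirna_p]
  keys <- if (length(mir)) normalize_mirna_id(mir)$key else character(0)
  paths <- enrich$set[!is.na(enrich$q_fdr) & enrich$q_fdr < pathway_q]
  tu <- character(0)
  for (k in keys) if (k %in% names(targets)) tu <- union(tu, targets[[k]])
  lu <- character(0)
  for (s in paths)
    lu <- union(lu, enrich$leading_edge[[which(enrich$set == s)]])
  list(mirnas = sort(mir), pathways = sort(paths),
       genes = sort(intersect(tu, lu)))
}
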