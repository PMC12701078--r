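#' Read a GMT gene-set collection
#'
#' Parses the standard tab-separated GMT distribution format
#' (`name<TAB>description<TAB>member1<TAB>member2...`). Member symbols are
#' upper-cased and de-duplicated within each set.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    stop("GMT line ", short[1L], " has fewer than 3 fields in ", path)
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name in ", path, ": ",
         nm[duplicated(nm)][1L])
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    g <- toupper(trimws(f[-(1:2)]))
    unique(g[nzchar(g)])
  })
  if (any(lengths(sets) == 0L))
    stop("empty gene set in ", path, ": ", nm[lengths(sets) == 0L][1L])
  names(sets) <- nm
  names(desc) <- nm
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets, sizes",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}

.ranked_to_vectors <- function(ranked) {
  if (is.data.frame(ranked)) {
    list(genes = as.character(ranked$gene), metric = as.numeric(ranked$metric))
  } else if (is.numeric(ranked) && !is.null(names(ranked))) {
    list(genes = names(ranked), metric = as.numeric(ranked))
  } else stop("`ranked` must be a ranked-list data.frame (gene, metric) or ",
              "a named numeric vector")
}

#' Weighted running-sum enrichment score
#'
#' The classic weighted Kolmogorov-Smirnov-like statistic of gene-set
#' enrichment analysis: walking down the ranked list, the running sum is
#' incremented at each set member ("hit") by `|metric|^weight` normalized by
#' the total hit weight, and decremented at each non-member by
#' `1/(N - n_hits)`. The enrichment score (ES) is the signed value of the
#' running sum at its maximum absolute deviation from zero. If all hit
#' metrics are zero under a positive weight, hit increments fall back to the
#' unweighted `1/n_hits`. A numerically tied maximum deviation (the trough
#' before the first hit can exactly mirror the peak after the last one)
#' resolves to the earliest position in the walk.
#'
#' @param ranked a ranked-list data.frame (`gene`, `metric`, metric
#'   non-increasing) from [build_ranked_list()], or a named numeric vector
#'   sorted decreasing.
#' @param members character vector of set member gene symbols. Must overlap
#'   the ranked genes but not cover them all (the miss decrement is
#'   undefined otherwise).
#' @param weight exponent applied to `|metric|` in the hit increments
#'   (default 1; 0 gives the unweighted statistic).
#' @return list with `es`, `running` (length-N running-sum vector),
#'   `peak` (index of the maximum absolute deviation), `n_hits`, and
#'   `hit_index`.
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  rv <- .ranked_to_vectors(ranked)
  N <- length(rv$genes)
  hit <- rv$genes %in% members
  nh <- sum(hit)
  if (nh == 0L) stop("gene set has no members in the ranked list")
  if (nh == N) stop("gene set covers the entire ranked list; ",
                    "miss decrement undefined")
  w <- abs(rv$metric[hit])^weight
  S <- sum(w)
  inc <- if (S == 0) rep(1 / nh, nh) else w / S
  step <- rep(-1 / (N - nh), N)
  step[hit] <- inc
  running <- cumsum(step)
  peak <- .peak_pick(running)
  list(es = running[peak], running = running, peak = peak,
       n_hits = nh, hit_index = which(hit))
}

# Index of the maximum absolute running-sum deviation. With few hits the
# trough before the first hit and the peak after the last can tie exactly
# (both are whole multiples of the miss step); such ties resolve to the
# earliest position in the walk, with a small tolerance so the outcome does
# not depend on floating-point accumulation order.
.peak_pick <- function(v) {
  M <- max(abs(v))
  which(abs(v) >= M - 1e-9)[1L]
}

# ES only, from hit positions, without materialising the length-N walk.
# Between hits the running sum decreases linearly, so the extrema can only
# occur immediately after a hit (positive candidates) or immediately before
# one (negative candidates). Used for the permutation null.
.es_from_positions <- function(absw, pos, N, uniform_fallback) {
  k <- length(pos)
  w <- absw[pos]
  S <- sum(w)
  inc <- if (S == 0) rep(1 / k, k) else w / S
  cs <- cumsum(inc)
  miss <- (pos - seq_len(k)) / (N - k)
  after <- cs - miss
  before <- c(0, cs[-k]) - miss
  # interleave so candidates appear in walk order; ties then resolve to the
  # earliest position, matching enrichment_score()
  cand <- as.vector(rbind(before, after))
  cand[.peak_pick(cand)]
}

#' Preranked gene-set enrichment analysis
#'
#' From-scratch preranked GSEA: for each eligible gene set, the observed
#' weighted running-sum enrichment score ([enrichment_score()]), a
#' gene-label permutation null (random same-size gene draws from the ranked
#' universe), an add-one-smoothed sign-matched nominal p-value, the
#' normalized enrichment score (NES = ES divided by the mean |null ES| of
#' the matching sign), a tail-wise permutation FDR q-value computed
#' separately for positive and negative NES and made monotone, and the
#' leading-edge genes (set members at or before the running-sum peak for
#' positive ES; at or after it for negative ES).
#'
#' @param ranked ranked gene list (see [enrichment_score()]).
#' @param collection a `gene_set_collection` from [read_gmt()] or
#'   [simulate_targets_and_sets()].
#' @param n_perm number of gene-label permutations (default 1000).
#' @param weight running-sum weight exponent (default 1).
#' @param min_size,max_size eligibility bounds on the set size *after*
#'   intersection with the ranked genes (defaults 15 and 500).
#' @param seed integer seed; results are bit-identical for a fixed seed.
#' @return A data.frame, one row per eligible set, with columns `set`, `es`,
#'   `nes`, `p_nominal`, `q_fdr`, `n_hits`, and list-column `leading_edge`;
#'   sets whose members do not overlap the ranked list (or exceed the size
#'   bounds) are skipped and recorded in attribute `skipped`.
#' @export
prerank_gsea <- function(ranked, collection, n_perm = 1000, weight = 1,
                         min_size = 15, max_size = 500, seed = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  rv <- .ranked_to_vectors(ranked)
  N <- length(rv$genes)
  absw <- abs(rv$metric)^weight

  sizes <- vapply(collection$sets,
                  function(g) sum(g %in% rv$genes), integer(1))
  eligible <- sizes >= max(min_size, 1L) & sizes <= min(max_size, N - 1L)
  if (!any(eligible))
    stop("no eligible gene sets: intersection sizes ",
         paste(range(sizes), collapse = "-"), " vs bounds [", min_size,
         ", ", max_size, "] on a ranked list of ", N, " genes")
  skipped <- names(collection$sets)[!eligible]
  set_names <- names(collection$sets)[eligible]

  obs <- lapply(collection$sets[eligible], function(g)
    enrichment_score(ranked, g, weight))
  es <- vapply(obs, `[[`, numeric(1), "es")

  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    null_es <- lapply(sizes[eligible], function(k) {
      vapply(seq_len(n_perm), function(b)
        .es_from_positions(absw, sort.int(sample.int(N, k)), N, TRUE),
        numeric(1))
    })
  })

  p_nominal <- numeric(length(es))
  nes <- numeric(length(es))
  nes_null <- vector("list", length(es))
  for (i in seq_along(es)) {
    nl <- null_es[[i]]
    pos <- nl[nl >= 0]
    neg <- nl[nl < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    if (es[i] >= 0) {
      p_nominal[i] <- (sum(pos >= es[i]) + 1) / (length(pos) + 1)
      nes[i] <- if (is.na(mpos) || mpos == 0) NA_real_ else es[i] / mpos
    } else {
      p_nominal[i] <- (sum(neg <= es[i]) + 1) / (length(neg) + 1)
      nes[i] <- if (is.na(mneg) || mneg == 0) NA_real_ else abs(es[i]) / mneg * -1
    }
    nn <- rep(NA_real_, length(nl))
    if (!is.na(mpos) && mpos > 0) nn[nl >= 0] <- nl[nl >= 0] / mpos
    if (!is.na(mneg) && mneg > 0) nn[nl < 0] <- nl[nl < 0] / mneg
    nes_null[[i]] <- nn[!is.na(nn)]
  }

  q_fdr <- .gsea_fdr(nes, unlist(nes_null, use.names = FALSE))

  leading <- lapply(obs, function(o) {
    hi <- o$hit_index
    idx <- if (o$es >= 0) hi[hi <= o$peak] else hi[hi >= o$peak]
    rv$genes[idx]
  })

  out <- data.frame(set = set_names, es = es, nes = nes,
                    p_nominal = p_nominal, q_fdr = q_fdr,
                    n_hits = sizes[eligible],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$leading_edge <- unname(leading)
  attr(out, "skipped") <- skipped
  attr(out, "n_perm") <- n_perm
  out
}

# Tail-wise permutation FDR, the standard preranked-GSEA convention:
# for an observed NES* >= 0, q = [fraction of pooled null NES >= NES* among
# null NES >= 0] / [fraction of observed NES >= NES* among observed >= 0],
# capped at 1; mirrored for the negative tail; made monotone so a less
# extreme NES never has a smaller q than a more extreme one.
.gsea_fdr <- function(nes, nes_null) {
  q <- rep(NA_real_, length(nes))
  for (side in c(1, -1)) {
    if (side > 0) {
      obs_t <- which(!is.na(nes) & nes >= 0)
      null_t <- nes_null[nes_null >= 0]
    } else {
      obs_t <- which(!is.na(nes) & nes < 0)
      null_t <- nes_null[nes_null < 0]
    }
    if (length(obs_t) == 0L) next
    for (i in obs_t) {
      thr <- nes[i]
      num <- if (length(null_t) == 0L) 1 else {
        if (side > 0) mean(null_t >= thr) else mean(null_t <= thr)
      }
      den <- if (side > 0) mean(nes[obs_t] >= thr) else mean(nes[obs_t] <= thr)
      q[i] <- min(1, num / den)
    }
    # monotone: q non-decreasing as |NES| decreases
    ord <- obs_t[order(-side * nes[obs_t])]   # most extreme first
    q[ord] <- rev(cummin(rev(q[ord])))
  }
  q
}

#' Filter enrichment results at an FDR threshold
#'
#' @param results data.frame from [prerank_gsea()].
#' @param q_threshold strict FDR cutoff (default 0.2): a set with
#'   `q_fdr` equal to the threshold is excluded.
#' @return the significant rows, ordered by `q_fdr` then `|nes|` descending.
#' @export
significant_pathways <- function(results, q_threshold = 0.2) {
  keep <- !is.na(results$q_fdr) & results$q_fdr < q_threshold
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$q_fdr, -abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' Leading-edge genes are comma-joined; the same columns serve as the
#' dot-plot-ready table (nes, q, leading-edge size).
#' @param results data.frame from [prerank_gsea()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  df <- results
  df$n_leading_edge <- lengths(df$leading_edge)
  df$leading_edge <- vapply(df$leading_edge, paste, character(1),
                            collapse = ",")
  df$es <- format(df$es, digits = 15, trim = TRUE, scientific = FALSE)
  df$nes <- format(df$nes, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
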