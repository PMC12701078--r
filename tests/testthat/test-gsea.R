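test_that("GMT collections parse, validate and round-trip", {
  tf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tA", "S2\tdesc2\tb\tC"), tf)
  gc <- read_gmt(tf)
  expect_equal(gc$sets$S1, c("A", "B"))         # duplicates collapsed
  expect_equal(gc$sets$S2, c("B", "C"))         # symbols upper-cased

  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), tf)
  expect_error(read_gmt(tf), "duplicate gene-set name")
  writeLines("S1\tdesc", tf)
  expect_error(read_gmt(tf), "fewer than 3 fields")
  writeLines(character(0), tf)
  expect_error(read_gmt(tf), "empty")

  # a Hallmark-sized collection survives write_gmt / read_gmt unchanged
  set.seed(31)
  sets <- lapply(stats::setNames(1:50, sprintf("HM_SET_%02d", 1:50)),
                 function(i) sort(sample(sprintf("G%03d", 1:300), 20)))
  gc2 <- make_collection(sets)
  tf2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gc2, tf2)
  gc3 <- read_gmt(tf2)
  expect_equal(gc3$sets, gc2$sets)
})

test_that("enrichment score reproduces hand-computed walks", {
  ranked <- make_ranked(paste0("G", 1:5), c(5, 4, 3, 2, 1))
  # single hit at the top: +1.0 at index 1, then four -0.25 steps
  r <- enrichment_score(ranked, "G1")
  expect_equal(r$es, 1.0)
  expect_equal(r$peak, 1L)
  expect_equal(r$running, c(1, 0.75, 0.5, 0.25, 0))
  # single hit at the bottom: the walk reaches -1.0 just before the hit
  r2 <- enrichment_score(ranked, "G5")
  expect_equal(r2$es, -1.0)
  expect_equal(r2$running, c(-0.25, -0.5, -0.75, -1, 0))

  # weight 0 ignores the metric values entirely
  r3 <- enrichment_score(ranked, c("G1", "G3"), weight = 0)
  expect_equal(r3$running[1], 0.5)
  r4 <- enrichment_score(make_ranked(paste0("G", 1:5), c(100, 4, 3, 2, 1)),
                         c("G1", "G3"), weight = 0)
  expect_equal(r3$running, r4$running)

  # all-zero metrics fall back to uniform increments under weight 1
  r5 <- enrichment_score(make_ranked(paste0("G", 1:5), rep(0, 5)),
                         c("G1", "G3"), weight = 1)
  expect_equal(r5$running[1], 0.5)

  expect_error(enrichment_score(ranked, "ABSENT"), "no members")
  expect_error(enrichment_score(ranked, paste0("G", 1:5)), "entire ranked")
})

test_that("running sum starts/ends at zero and ES stays in [-1, 1]", {
  set.seed(37)
  for (rep in 1:50) {
    N <- sample(10:60, 1)
    ranked <- make_ranked(sprintf("G%03d", 1:N),
                          sort(rnorm(N, 0, 3), decreasing = TRUE))
    k <- sample(seq_len(N - 1), 1)
    members <- sample(ranked$gene, k)
    w <- sample(c(0, 1, 1.5, 2), 1)
    r <- enrichment_score(ranked, members, weight = w)
    expect_lte(abs(r$es), 1)
    expect_lt(abs(r$running[N]), 1e-9)
    # the fast hit-position form used for permutations agrees exactly
    fast <- evmirna:::.es_from_positions(abs(ranked$metric)^w,
                                         which(ranked$gene %in% members),
                                         N, TRUE)
    expect_equal(fast, r$es, tolerance = 1e-12)
  }
})

test_that("reversing the ranked list negates the unweighted ES", {
  set.seed(41)
  for (rep in 1:20) {
    N <- 30
    ranked <- make_ranked(sprintf("G%03d", 1:N),
                          sort(rnorm(N), decreasing = TRUE))
    members <- sample(ranked$gene, 7)
    rev_ranked <- ranked[N:1, ]
    a <- enrichment_score(ranked, members, weight = 0)$es
    b <- enrichment_score(rev_ranked, members, weight = 0)$es
    expect_equal(b, -a, tolerance = 1e-12)
  }
})

test_that("preranked GSEA is seed-deterministic and flags clear enrichment", {
  set.seed(43)
  N <- 200
  ranked <- make_ranked(sprintf("G%03d", 1:N),
                        sort(rnorm(N, 0, 2), decreasing = TRUE))
  sets <- c(list(TOP = ranked$gene[1:20]),
            lapply(stats::setNames(1:5, paste0("RAND", 1:5)),
                   function(i) sample(ranked$gene, 20)))
  gc <- make_collection(sets)

  r1 <- prerank_gsea(ranked, gc, n_perm = 500, min_size = 5, seed = 99)
  r2 <- prerank_gsea(ranked, gc, n_perm = 500, min_size = 5, seed = 99)
  expect_identical(r1, r2)

  top <- r1[r1$set == "TOP", ]
  expect_gt(top$es, 0)
  expect_gt(top$nes, 0)
  expect_lte(top$p_nominal, 0.01)   # smallest attainable for ~B/2 same-sign nulls
  expect_lt(top$q_fdr, 0.2)
  # leading edge of a positive ES comes from before the peak, within the set
  obs <- enrichment_score(ranked, gc$sets$TOP)
  expect_true(all(top$leading_edge[[1]] %in% gc$sets$TOP))
  expect_true(all(match(top$leading_edge[[1]], ranked$gene) <= obs$peak))
  expect_equal(sign(r1$nes), sign(r1$es))

  expect_error(prerank_gsea(ranked, gc, n_perm = 0), "n_perm")
  expect_error(prerank_gsea(ranked, gc, min_size = 100, max_size = 120),
               "no eligible")
})

test_that("ES agrees with an independent reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(47)
  N <- 100
  metric <- sort(rnorm(N, 0, 2), decreasing = TRUE)
  genes <- sprintf("G%03d", 1:N)
  ranked <- make_ranked(genes, metric)
  stats_vec <- stats::setNames(metric, genes)
  for (rep in 1:20) {
    idx <- sort(sample(N, 15))
    ours <- enrichment_score(ranked, genes[idx], weight = 1)$es
    ref <- fgsea::calcGseaStat(stats_vec, selectedStats = idx, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("significant_pathways filters strictly and orders by q then |NES|", {
  res <- rbind(make_enrich_row("A", nes = 2.0, q = 0.001),
               make_enrich_row("B", nes = -1.5, q = 0.2),
               make_enrich_row("C", nes = 1.2, q = 0.19),
               make_enrich_row("D", nes = 2.5, q = 0.001))
  out <- significant_pathways(res, 0.2)
  expect_equal(out$set, c("D", "A", "C"))     # q 0.2 exactly is excluded
  expect_equal(nrow(significant_pathways(res[0, ], 0.2)), 0)
})
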