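test_that("paired t-test matches its closed form and stats::t.test", {
  # d = (1, 2, 3): t = mean/sd * sqrt(n) = 2/1 * sqrt(3)
  r <- paired_t_test(pre = c(0, 0, 0), post = c(1, 2, 3))
  expect_equal(r$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(2 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)

  set.seed(101)
  for (n in c(3, 5, 10)) {
    for (rep in 1:25) {
      pre <- rnorm(n); post <- rnorm(n, 0.5)
      r <- paired_t_test(pre, post)
      ref <- t.test(post, pre, paired = TRUE)
      expect_equal(r$t_stat, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
      # label-swap antisymmetry
      sw <- paired_t_test(post, pre)
      expect_identical(sw$t_stat, -r$t_stat)
      expect_identical(sw$p_value, r$p_value)
    }
  }
})

test_that("zero-variance differences are flagged degenerate, not significant", {
  r <- paired_t_test(pre = c(0, 0, 0, 0, 0), post = c(1, 1, 1, 1, 1))
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
  expect_error(paired_t_test(1, 2), "n >= 2")
  expect_error(paired_t_test(1:3, 1:4), "same length")

  # fully censored miRNA: constant expression, must not reach significance
  rows <- list("hsa-miR-a" = rep(40, 10),
               "hsa-miR-b" = c(30, 31, 29, 30.5, 30, 34, 35, 33, 34.5, 36))
  e <- normalize_spike_in(make_ct(rows))
  de <- run_differential_expression(e)
  a <- de[de$mirna == "hsa-miR-a", ]
  expect_true(a$degenerate)
  expect_false(a$significant)
  expect_true(is.na(a$q_value))
})

test_that("BH adjustment matches the hand step-up and keeps NA aside", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  p <- c(0.01, NA, 0.5, 0.04)
  q <- benjamini_hochberg(p)
  expect_true(is.na(q[2]))
  expect_equal(q[!is.na(q)], oracle_bh(p[!is.na(p)]))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (rep in 1:50) {
    p <- runif(sample(1:50, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # order-preserving
  }
})

test_that("DE table: log2FC, direction counts and consistency calls", {
  # patient diffs with signs (-, -, -, +, 0)
  pre <- c(10, 10, 10, 10, 10)
  post <- c(8, 9, 7, 11, 10)
  expr <- make_expression(matrix(c(pre, post), 1,
                                 dimnames = list("hsa-miR-x", NULL)))
  de <- run_differential_expression(expr)
  expect_equal(de$n_down, 3L)
  expect_equal(de$n_up, 1L)
  expect_equal(de$n_zero, 1L)
  expect_equal(de$consistent, "down")
  expect_equal(de$n_down + de$n_up + de$n_zero, 5L)
  expect_equal(de$log2fc, mean(post) - mean(pre))

  # post mean -8, pre mean -5 -> log2fc -3
  expr2 <- make_expression(matrix(c(rep(-5, 3), rep(-8, 3)) + c(-1, 0, 1),
                                  1, dimnames = list("hsa-miR-y", NULL)),
                           n_patients = 3)
  expect_equal(run_differential_expression(expr2)$log2fc, -3)
})

test_that("significance is strict at the q threshold", {
  set.seed(15)
  m <- matrix(rnorm(60, sd = 1), 6,
              dimnames = list(sprintf("hsa-miR-%d", 1:6), NULL))
  m[1, 6:10] <- m[1, 6:10] - 6       # one strong down effect
  expr <- make_expression(m)
  out <- run_differential_expression(expr, q_threshold = 0.2)
  expect_identical(out$significant, !is.na(out$q_value) & out$q_value < 0.2)
  # setting the threshold exactly at an attained q excludes that miRNA
  q1 <- out$q_value[1]
  out2 <- run_differential_expression(expr, q_threshold = q1)
  expect_false(out2$significant[1])
})

test_that("label swap flips log2fc and t but not p or q", {
  sim <- simulate_ct(sim_config(n_patients = 5, n_assays = 30,
                                fraction_near_lod = 0,
                                planted_effects = c("1" = 4)), seed = 3)
  e <- normalize_spike_in(filter_by_detection(sim$ct)$ct)
  de1 <- run_differential_expression(e)
  e2 <- e
  e2$samples$timepoint <- ifelse(e2$samples$timepoint == "pre", "post", "pre")
  de2 <- run_differential_expression(e2)
  expect_equal(de2$log2fc, -de1$log2fc)
  expect_equal(de2$t_stat, -de1$t_stat)
  expect_equal(de2$p_value, de1$p_value)
  expect_equal(de2$q_value, de1$q_value)
})

test_that("top-k selection orders by p with documented tie-breaks", {
  de <- rbind(make_de_row("hsa-miR-a", log2fc = -1, p = 0.01),
              make_de_row("hsa-miR-b", log2fc = -5, p = 0.2),
              make_de_row("hsa-miR-c", log2fc = -2, p = 0.2),
              make_de_row("hsa-miR-d", log2fc = 0, p = NA))
  expect_equal(top_k_by_p(de, 1), "hsa-miR-a")
  # tie on p broken by |log2fc| descending
  expect_equal(top_k_by_p(de, 3), c("hsa-miR-a", "hsa-miR-b", "hsa-miR-c"))
  # k beyond the table returns all defined-p records
  expect_length(top_k_by_p(de, 99), 3)
})

test_that("PCA scores: symmetry, distance preservation, planted shift", {
  m <- matrix(rnorm(40), 10)
  m[, 2] <- m[, 1]                      # two identical samples
  expr <- make_expression(m, n_patients = 2)
  pc <- pca_scores(expr, n_components = 2)
  expect_equal(pc$scores[1, ], pc$scores[2, ])
  expect_true(all(diff(pc$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pc$explained_variance_ratio), 1 + 1e-12)
  expect_error(pca_scores(expr, n_components = 5), "exceeds")

  # full-rank scores are a rigid motion of the centered data
  m2 <- matrix(rnorm(6 * 20), 20)
  e2 <- make_expression(m2, n_patients = 3)
  pc2 <- pca_scores(e2, n_components = 5)
  d_scores <- dist(pc2$scores)
  d_data <- dist(scale(t(m2), center = TRUE, scale = FALSE))
  expect_equal(as.vector(d_scores), as.vector(d_data), tolerance = 1e-9)

  # a uniform post shift over many miRNAs separates pre from post on PC1
  sim <- simulate_ct(sim_config(n_patients = 5, n_assays = 60,
                                fraction_near_lod = 0,
                                noise_sd_within_patient = 0.3,
                                planted_effects = stats::setNames(
                                  rep(3, 30), as.character(1:30))), seed = 5)
  e3 <- normalize_spike_in(filter_by_detection(sim$ct)$ct)
  pc3 <- pca_scores(e3, n_components = 2)
  tp <- e3$samples$timepoint[match(pc3$sample_ids,
                                   e3$samples$sample_id)]
  disp <- pc3$scores[tp == "post", 1] - pc3$scores[tp == "pre", 1]
  expect_true(all(disp > 0) || all(disp < 0))
})
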