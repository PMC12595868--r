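test_that("alpha diversity matches closed forms on toy communities", {
  uni <- toy_table(matrix(c(5, 5, 5, 5), 1))
  a <- alpha_diversity(uni, c("observed", "shannon", "simpson"))
  expect_equal(a$value[a$metric == "shannon"], log(4), tolerance = 1e-12)
  expect_equal(a$value[a$metric == "simpson"], 0.75, tolerance = 1e-12)
  expect_equal(a$value[a$metric == "observed"], 4)

  one <- toy_table(matrix(7, 1))
  a1 <- alpha_diversity(one, c("observed", "shannon", "simpson"))
  expect_equal(a1$value, c(1, 0, 0))

  # S_obs = 5 with two singletons and one doubleton: 5 + 2*1/(2*2) = 5.5
  ch <- toy_table(matrix(c(1, 1, 2, 5, 9), 1))
  expect_equal(alpha_diversity(ch, "chao1")$value, 5.5)
})

test_that("chao1 agrees with the vegan estimator and rejects scaled data", {
  for (seed in 1:5) {
    tbl <- random_table(6, 40, seed = seed)
    ours <- alpha_diversity(tbl, "chao1")$value
    ref <- unname(vegan::estimateR(asv_matrix(tbl))["S.chao1", ])
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  expect_error(alpha_diversity(normalize_cpt(random_table(3, 10, 1)), "chao1"),
               "integer counts")
})

test_that("alpha metrics satisfy their range invariants", {
  tbl <- random_table(8, 30, seed = 11)
  a <- tidyr::pivot_wider(alpha_diversity(tbl), names_from = "metric",
                          values_from = "value")
  expect_true(all(a$observed == round(a$observed) & a$observed >= 0))
  expect_true(all(a$shannon >= 0))
  expect_true(all(a$simpson >= 0 & a$simpson <= 1))
  expect_true(all(a$chao1 >= a$observed))
})

test_that("Bray-Curtis matches hand values and a brute-force double loop", {
  same <- toy_table(matrix(c(1, 2, 1, 2), 2, byrow = TRUE))
  expect_equal(as.vector(bray_curtis(same)), 0)
  disj <- toy_table(matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  expect_equal(as.vector(bray_curtis(disj)), 1)
  toy <- toy_table(matrix(c(10, 0, 5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(as.vector(bray_curtis(toy)), 10 / 30, tolerance = 1e-12)

  brute <- function(m) {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
    d
  }
  for (seed in 1:5) {
    tbl <- normalize_cpt(random_table(5, 8, seed = seed))
    expect_equal(as.matrix(bray_curtis(tbl)), brute(asv_matrix(tbl)),
                 tolerance = 1e-12)
  }
  expect_error(bray_curtis(toy_table(matrix(c(0, 0, 1, 1), 2, byrow = TRUE))),
               "all-zero")
})

test_that("PERMANOVA partitions variance and finds clean group structure", {
  # two groups of four: distance 0.05 within, 0.95 between
  n <- 8
  lab <- sprintf("s%d", 1:n)
  m <- matrix(0.05, n, n, dimnames = list(lab, lab))
  diag(m) <- 0
  grp <- rep(c("A", "B"), each = 4)
  m[outer(grp, grp, "!=")] <- 0.95
  d <- stats::as.dist(m)
  md <- toy_metadata(lab, crop = grp)
  res <- permanova(d, md, "crop", n_perm = 999, seed = 3)
  expect_equal(sum(res$r_squared), 1, tolerance = 1e-9)
  expect_gt(res$r_squared[res$term == "crop"], 0.9)
  expect_lt(res$p_value[res$term == "crop"], 0.05)
  expect_gte(res$p_value[res$term == "crop"], 1 / 1000)

  expect_error(permanova(d, md, "country", n_perm = 99, seed = 1),
               "fewer than two levels")
})

test_that("PERMANOVA p-values are uniform under a true null", {
  ps <- vapply(1:200, function(seed) {
    tbl <- normalize_cpt(random_table(12, 10, seed = 1000 + seed))
    md <- toy_metadata(sample_ids(tbl),
                       crop = rep(c("Kernza", "wheat"), each = 6))
    permanova(bray_curtis(tbl), md, "crop", n_perm = 199,
              seed = seed)$p_value[1]
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("PERMANOVA r-squared is invariant to sample relabeling", {
  tbl <- normalize_cpt(random_table(10, 15, seed = 77))
  md <- toy_metadata(sample_ids(tbl), crop = rep(c("Kernza", "wheat"), 5))
  d <- bray_curtis(tbl)
  r1 <- permanova(d, md, "crop", n_perm = 99, seed = 1)$r_squared
  set.seed(4)
  ord <- sample(10)
  d2 <- stats::as.dist(as.matrix(d)[ord, ord])
  r2 <- permanova(d2, md, "crop", n_perm = 99, seed = 1)$r_squared
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("pairwise Wilcoxon + BH behaves on hand-enumerable cases", {
  same <- list(g1 = c(1, 2, 3), g2 = c(1, 2, 3))
  expect_equal(wilcoxon_bh(same)$p_raw, 1, tolerance = 0.01)
  # fully separated n=3 vs 3: the extreme rank-sum, exact two-sided p = 0.1
  sep <- wilcoxon_bh(list(lo = c(1, 2, 3), hi = c(10, 11, 12)))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_raw, 0.1, tolerance = 1e-12)
  # data-frame-first form agrees with the list form
  df <- data.frame(value = c(1, 2, 3, 10, 11, 12),
                   group = rep(c("lo", "hi"), each = 3))
  expect_equal(wilcoxon_bh(df)$p_raw, sep$p_raw)
  expect_error(wilcoxon_bh(list(a = 1:3, b = 1:4), paired = TRUE),
               "equal group lengths")
})

test_that("BH adjustment is a monotone fixed point never exceeding 1", {
  expect_equal(stats::p.adjust(rep(0.03, 7), "BH"), rep(0.03, 7))
  for (seed in 1:5) {
    set.seed(seed)
    p <- stats::runif(20)
    adj <- stats::p.adjust(p, "BH")
    expect_true(all(adj <= 1))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))
    expect_true(all(adj >= p))
  }
})
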