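mu_cell <- function(mu, cell) mu$mu_d[mu$cell == cell]

test_that("mu_D cells match hand-computed pair means", {
  # identical communities inside each group, disjoint between groups
  m <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2, byrow = TRUE,
              dimnames = list(sprintf("s%d", 1:4), c("x", "y")))
  md <- toy_metadata(rownames(m), crop = c("Kernza", "Kernza",
                                           "wheat", "wheat"))
  mu <- group_mean_dissimilarity(bray_curtis(toy_table(m)), md, "crop")
  expect_equal(mu_cell(mu, "within:Kernza"), 0)
  expect_equal(mu_cell(mu, "within:wheat"), 0)
  expect_equal(mu_cell(mu, "between:Kernza|wheat"), 1)
  expect_equal(mu$n_pairs[mu$cell == "between:Kernza|wheat"], 4L)
})

test_that("mu_D equals a brute-force mean over every pair, per cell", {
  tbl <- normalize_cpt(random_table(6, 12, seed = 9))
  md <- toy_metadata(sample_ids(tbl), crop = rep(c("Kernza", "wheat"), each = 3))
  d <- as.matrix(bray_curtis(tbl))
  mu <- group_mean_dissimilarity(stats::as.dist(d), md, "crop")
  brute <- function(ids_a, ids_b) {
    v <- c()
    for (i in ids_a) for (j in ids_b) if (i < j || !(j %in% ids_a)) {
      v <- c(v, d[i, j])
    }
    mean(v)
  }
  k <- md$sample_id[md$crop == "Kernza"]; w <- md$sample_id[md$crop == "wheat"]
  expect_equal(mu_cell(mu, "within:Kernza"), brute(k, k))
  expect_equal(mu_cell(mu, "within:wheat"), brute(w, w))
  expect_equal(mu_cell(mu, "between:Kernza|wheat"),
               mean(d[k, w]))
  # within-cell pair counts are n(n-1)/2
  expect_equal(mu$n_pairs[mu$cell == "within:Kernza"], choose(3, 2))
})

test_that("cell means conserve the overall pair mean and ignore sample order", {
  for (seed in 1:5) {
    tbl <- normalize_cpt(random_table(9, 15, seed = seed))
    md <- toy_metadata(sample_ids(tbl),
                       crop = sample(rep(c("Kernza", "wheat", "mix"), 3)))
    d <- bray_curtis(tbl)
    mu <- group_mean_dissimilarity(d, md, "crop")
    overall <- mean(as.vector(d))
    expect_equal(sum(mu$mu_d * mu$n_pairs) / sum(mu$n_pairs), overall,
                 tolerance = 1e-12)
    expect_true(all(mu$mu_d >= vapply(mu$values, min, 0) - 1e-12))
    expect_true(all(mu$mu_d <= vapply(mu$values, max, 0) + 1e-12))
    ord <- sample(9)
    d2 <- stats::as.dist(as.matrix(d)[ord, ord])
    mu2 <- group_mean_dissimilarity(d2, md, "crop")
    expect_equal(mu2$mu_d[order(mu2$cell)], mu$mu_d[order(mu$cell)])
  }
})

test_that("mu_D requires two samples per within-group cell", {
  tbl <- normalize_cpt(random_table(3, 8, seed = 1))
  md <- toy_metadata(sample_ids(tbl), crop = c("Kernza", "Kernza", "wheat"))
  expect_error(group_mean_dissimilarity(bray_curtis(tbl), md, "crop"),
               "wheat")
})

test_that("cell comparisons use exact rank tests with BH over the family", {
  cells <- tibble::tibble(
    cell = c("a", "b"), type = "within", group_a = c("a", "b"),
    group_b = c("a", "b"), mu_d = c(0, 1), n_pairs = 3L,
    values = list(c(0, 0, 0), c(1, 1, 1)))
  out <- compare_mu_d(cells)
  expect_equal(out$p_raw, 0.1, tolerance = 1e-12)
  cells3 <- dplyr::bind_rows(cells, tibble::tibble(
    cell = "c", type = "within", group_a = "c", group_b = "c",
    mu_d = 0.5, n_pairs = 3L, values = list(c(0.4, 0.5, 0.6))))
  expect_equal(nrow(compare_mu_d(cells3)), 3L)
  same <- cells; same$values <- list(c(0.2, 0.3), c(0.2, 0.3))
  expect_equal(compare_mu_d(same)$p_raw, 1, tolerance = 0.01)
})

test_that("delta-RA ratios follow per-year crop means", {
  # two ASVs engineered to halve and double their relative abundance
  m <- matrix(c(200, 400, 400,
                200, 400, 400,
                100, 800, 100,
                100, 800, 100), 4, 3, byrow = TRUE,
              dimnames = list(sprintf("s%d", 1:4), c("half", "dbl", "rest")))
  md <- toy_metadata(rownames(m), year = c(2021L, 2021L, 2022L, 2022L))
  dra <- delta_ra_stability(normalize_cpt(toy_table(m)), md, "Kernza",
                            pseudocount = 0)
  expect_equal(dra$per_asv$ratio[dra$per_asv$asv_id == "half"], 0.5)
  expect_equal(dra$per_asv$ratio[dra$per_asv$asv_id == "dbl"], 2)
  expect_equal(dra$mean_delta_ra, mean(c(0.5, 2, 0.25)))

  # identical years: every ratio is exactly 1, sd 0
  m2 <- m[c(1, 2, 1, 2), ]
  rownames(m2) <- sprintf("s%d", 1:4)
  dra2 <- delta_ra_stability(normalize_cpt(toy_table(m2)), md, "Kernza")
  expect_true(all(dra2$per_asv$ratio == 1))
  expect_equal(dra2$mean_delta_ra, 1)
  expect_equal(dra2$sd_delta_ra, 0)
})

test_that("delta-RA guards its degenerate configurations", {
  tbl <- normalize_cpt(random_table(4, 6, seed = 3))
  md <- toy_metadata(sample_ids(tbl), year = c(2021L, 2021L, 2022L, 2022L))
  expect_error(delta_ra_stability(tbl, md, "wheat"), "no samples")
  expect_error(delta_ra_stability(tbl, md, "Kernza", pseudocount = 0,
                                  inclusion = "detected_either_year"),
               "divide by zero")
  md1 <- md; md1$year <- 2021L
  expect_error(delta_ra_stability(tbl, md1, "Kernza"), "two years")
})

test_that("per-stratum delta-RA averaging is available and consistent", {
  d <- synthetic_design(n_asv = 120, depth_reads = 5000, seed = 21)
  rz <- generate_rhizosphere(d)
  cpt <- normalize_cpt(rz$table)
  pooled <- delta_ra_stability(cpt, rz$metadata, "Kernza")
  strat <- delta_ra_stability(cpt, rz$metadata, "Kernza", by = "country")
  expect_gt(length(intersect(pooled$per_asv$asv_id, strat$per_asv$asv_id)),
            100)
  expect_true(all(is.finite(strat$per_asv$ratio)))
})
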