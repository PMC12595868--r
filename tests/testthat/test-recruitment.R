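paired_fixture <- function() {
  rhizo <- toy_table(matrix(c(0, 5, 3, 2,
                              1, 1, 1, 1), 2, byrow = TRUE,
                            dimnames = list(c("r1", "r2"),
                                            c("a", "b", "c", "d"))))
  endo <- toy_table(matrix(c(4, 2, 1, 0,
                             1, 1, 1, 1,
                             0, 0, 2, 0), 3, byrow = TRUE,
                           dimnames = list(c("e1", "e2", "e3"),
                                           c("a", "b", "c", "x"))))
  md <- dplyr::bind_rows(
    toy_metadata(c("r1", "r2"), crop = c("Kernza", "wheat")),
    toy_metadata(c("e1", "e2", "e3"), crop = c("Kernza", "wheat", "wheat"),
                 compartment = "endosphere",
                 pair_id = c("r1", "r2", "r2")))
  list(rhizo = rhizo, endo = endo, md = md)
}

test_that("per-pair overlap counts shared detections", {
  fx <- paired_fixture()
  rec <- pair_overlap(fx$rhizo, fx$endo, fx$md)
  # e1 detects {a,b,c}; its paired r1 detects {b,c,d}: shared {b,c}
  e1 <- rec[rec$sample_id == "e1", ]
  expect_equal(e1$shared_count, 2L)
  expect_equal(e1$endo_asv_count, 3L)
  expect_equal(e1$shared_fraction, 2 / 3, tolerance = 1e-12)
  expect_identical(e1$shared[[1]], c("b", "c"))
  # e2 detects {a,b,c,x}; r2 detects all four rhizosphere ASVs: shared 3/4
  expect_equal(rec$shared_fraction[rec$sample_id == "e2"], 3 / 4)
  # identical detected sets give fraction 1
  same <- pair_overlap(fx$rhizo, fx$rhizo,
                       toy_metadata(c("r1", "r2"), compartment = "endosphere",
                                    pair_id = c("r1", "r2")))
  expect_true(all(same$shared_fraction == 1))
})

test_that("overlap guards pairing and empty libraries", {
  fx <- paired_fixture()
  bad <- fx$md
  bad$pair_id[bad$sample_id == "e1"] <- "nope"
  expect_error(pair_overlap(fx$rhizo, fx$endo, bad), "e1")
  empty <- fx$endo
  empty[empty$sample_id == "e3", c("a", "b", "c", "x")] <- 0
  expect_error(pair_overlap(fx$rhizo, empty, fx$md), "zero detected")
})

test_that("overlap ignores ASV order and all-zero ASV padding", {
  fx <- paired_fixture()
  rec <- pair_overlap(fx$rhizo, fx$endo, fx$md)
  shuffled <- fx$endo[, c("sample_id", "x", "c", "a", "b")]
  class(shuffled) <- class(fx$endo)
  padded_m <- cbind(asv_matrix(fx$rhizo), zzz = 0)
  rec2 <- pair_overlap(toy_table(padded_m), shuffled, fx$md)
  expect_equal(rec2$shared_count, rec$shared_count)
  expect_equal(rec2$shared_fraction, rec$shared_fraction)
})

test_that("rhizosphere-denominator mode divides by the rhizosphere richness", {
  fx <- paired_fixture()
  rec <- pair_overlap(fx$rhizo, fx$endo, fx$md, denominator = "rhizosphere")
  expect_equal(rec$shared_fraction[rec$sample_id == "e1"], 2 / 3)
  expect_equal(rec$shared_fraction[rec$sample_id == "e2"], 3 / 4)
})

test_that("crop-level union partition conserves sizes and percentages", {
  summaries <- tibble::tibble(
    sample_id = c("e1", "e2"), pair_id = c("r1", "r2"),
    crop = c("Kernza", "wheat"), shared_count = c(3L, 2L),
    endo_asv_count = c(3L, 2L), shared_fraction = 1,
    shared = list(c("a", "b", "c"), c("d", "e")))
  cu <- crop_union_overlap(summaries)
  expect_equal(cu$n, c(3L, 2L, 0L))
  expect_equal(cu$percent, c(60, 40, 0))
  summaries$shared <- list(c("a", "b"), c("a", "b"))
  cu2 <- crop_union_overlap(summaries)
  expect_equal(cu2$n, c(0L, 0L, 2L))
  expect_equal(cu2$percent, c(0, 0, 100))
  expect_equal(sum(cu2$percent), 100, tolerance = 1e-9)
})

test_that("abundance correlation matches the closed-form Pearson r", {
  ids <- sprintf("a%d", 1:5)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  mk <- function(v) {
    m <- rbind(v, v * 3)
    dimnames(m) <- list(c("s1", "s2"), ids)
    toy_table(m)
  }
  out <- abundance_correlation(mk(x), mk(y), ids)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(abundance_correlation(mk(x), mk(x), ids)$r, 1)
  expect_equal(abundance_correlation(mk(x), mk(max(x) + 1 - x), ids)$r, -1)
  expect_error(abundance_correlation(mk(rep(2, 5)), mk(y), ids), "constant")
  expect_error(abundance_correlation(mk(x), mk(y), ids[1:2]), "three")
})

test_that("preferential screen demands parity outside and bias inside roots", {
  set.seed(8)
  n <- 20
  crops <- rep(c("Kernza", "wheat"), each = n / 2)
  rhizo_m <- matrix(rpois(n * 6, 40) + 10, n, 6,
                    dimnames = list(sprintf("r%d", 1:n), sprintf("a%d", 1:6)))
  # a dominant filler keeps the composition of the others stable when one
  # ASV is perturbed
  rhizo_m <- cbind(rhizo_m, fill = 10000)
  # a2 is crop-biased already in the rhizosphere: parity must fail
  rhizo_m[crops == "Kernza", "a2"] <- rhizo_m[crops == "Kernza", "a2"] * 10
  endo_m <- rhizo_m
  rownames(endo_m) <- sprintf("e%d", 1:n)
  # a1 is at rhizosphere parity but 10x enriched in Kernza roots
  endo_m[crops == "Kernza", "a1"] <- endo_m[crops == "Kernza", "a1"] * 10
  md <- dplyr::bind_rows(
    toy_metadata(rownames(rhizo_m), crop = crops),
    toy_metadata(rownames(endo_m), crop = crops, compartment = "endosphere",
                 pair_id = rownames(rhizo_m)))
  rhizo <- normalize_cpt(toy_table(rhizo_m))
  hits <- preferential_screen(rhizo, normalize_cpt(toy_table(endo_m)),
                              md, sprintf("a%d", 1:6))
  expect_true("a1" %in% hits$asv_id)
  expect_identical(hits$crop_favoured[hits$asv_id == "a1"], "Kernza")
  expect_false("a2" %in% hits$asv_id)
  # an ASV identical everywhere is never reported
  expect_false("a3" %in% hits$asv_id)
  expect_error(preferential_screen(rhizo, rhizo, md, character(0)), "empty")
})

test_that("the rank-based screen finds large fold changes only", {
  set.seed(12)
  n <- 16
  m <- matrix(rpois(n * 5, 50) + 20, n, 5,
              dimnames = list(sprintf("s%d", 1:n), sprintf("a%d", 1:5)))
  g <- rep(c("Kernza", "wheat"), each = 8)
  m[g == "Kernza", "a1"] <- m[g == "Kernza", "a1"] * 8
  md <- toy_metadata(rownames(m), crop = g)
  scr <- rank_da_screen(normalize_cpt(toy_table(m)), md, "crop")
  expect_true(scr$selected[scr$asv_id == "a1"])
  expect_lt(sum(scr$selected), 3)
  expect_identical(consistent_across(list(c("a", "b", "c"), c("b", "c"),
                                          c("c", "b", "z"))), c("b", "c"))
})
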