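# in-code fixtures shared across the suite

toy_table <- function(counts, sample_ids = NULL, asv_ids = NULL, ...) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sample_ids %||% sprintf("s%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- asv_ids %||% sprintf("a%d", seq_len(ncol(counts)))
  }
  asv_table(counts, ...)
}

toy_metadata <- function(sample_ids, crop = "Kernza", country = "SE",
                         year = 2021L, depth = "5-15",
                         compartment = "rhizosphere",
                         pair_id = sample_ids) {
  tibble::tibble(sample_id = sample_ids, crop = crop, country = country,
                 year = as.integer(year), depth = depth,
                 compartment = compartment, pair_id = pair_id)
}

random_table <- function(n_samples, n_asvs, seed, max_count = 50,
                         zero_prob = 0.3) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_asvs, max_count / 3),
              n_samples, n_asvs)
  m[matrix(stats::runif(length(m)) < zero_prob, nrow(m))] <- 0
  m[rowSums(m) == 0, 1] <- 1  # keep every sample non-empty
  toy_table(m)
}

# two-crop, two-year toy metadata over one country
two_crop_metadata <- function(n_per_cell = 3) {
  grid <- expand.grid(crop = c("Kernza", "wheat"), year = c(2021L, 2022L),
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  ids <- sprintf("s_%s_%d_%d", substr(grid$crop, 1, 1), grid$year, grid$rep)
  toy_metadata(ids, crop = grid$crop, year = grid$year)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
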