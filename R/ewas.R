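#' Trim a 5' prefix from representative sequences
#'
#' Amplicon databases built from differently primed studies are made
#' comparable by trimming a fixed number of leading nucleotides before
#' exact matching. Sequences are uppercased on the way through.
#'
#' @param sequences Named character vector of DNA sequences.
#' @param n Number of leading nucleotides to remove; default 5.
#' @return Named character vector of trimmed, uppercase sequences.
#' @export
#' @examples
#' trim_prefix(c(asv1 = "AAAAACGTG"))
trim_prefix <- function(sequences, n = 5) {
  stopifnot(n >= 0)
  short <- nchar(sequences) <= n
  if (n > 0 && any(short)) {
    stop("sequence(s) not longer than the trim length: ",
         paste(names(sequences)[short], collapse = ", "))
  }
  stats::setNames(toupper(substring(sequences, n + 1)), names(sequences))
}

#' Read an indicator database table
#'
#' TSV with columns `sequence, category, indicator_value`: each row
#' annotates one (already-trimmed) V4 sequence as an indicator of an
#' environmental category (grassland, rhizosphere, no_till, ...).
#'
#' @param path Path to the TSV.
#' @return A validated tibble.
#' @export
read_indicator_db <- function(path) {
  db <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sequence = "c", category = "c",
                          indicator_value = "d"))
  validate_indicator_db(db)
}

#' @rdname read_indicator_db
#' @param db A data frame with columns `sequence, category,
#'   indicator_value`.
#' @export
validate_indicator_db <- function(db) {
  stopifnot(all(c("sequence", "category", "indicator_value") %in% names(db)))
  db$sequence <- toupper(db$sequence)
  if (any(grepl("[^ACGT]", db$sequence))) {
    stop("database sequences must be ACGT only")
  }
  if (anyDuplicated(db[c("sequence", "category")])) {
    stop("duplicate (sequence, category) pair(s) in database")
  }
  tibble::as_tibble(db)
}

#' Match study ASVs to an indicator database by exact sequence
#'
#' Case-insensitive exact string equality on (trimmed) sequences; an ASV
#' may match several categories, and unmatched ASVs are absent from the
#' result.
#'
#' @param sequences Named character vector of trimmed ASV sequences.
#' @param db Indicator database tibble (see [read_indicator_db()]).
#' @return An `ewas_matches` tibble: `asv_id`, `category`,
#'   `indicator_value`; attribute `match_rate` = matched ASVs / total
#'   ASVs.
#' @export
match_to_db <- function(sequences, db) {
  db <- validate_indicator_db(db)
  q <- tibble::tibble(asv_id = names(sequences),
                      sequence = toupper(unname(sequences)))
  out <- dplyr::inner_join(q, db, by = "sequence") |>
    dplyr::select("asv_id", "category", "indicator_value") |>
    dplyr::arrange(.data$asv_id, .data$category)
  attr(out, "match_rate") <- length(unique(out$asv_id)) / length(sequences)
  attr(out, "n_query") <- length(sequences)
  class(out) <- c("ewas_matches", class(out))
  out
}

#' Fraction of query ASVs matched to the database
#'
#' @param matches An `ewas_matches` tibble.
#' @return A number in `[0, 1]`.
#' @export
match_rate <- function(matches) attr(matches, "match_rate")

#' Aggregate matched abundance per category and contrast crops
#'
#' For each requested category, the counts-per-thousand abundances of
#' its matched ASVs are summed per sample, and the two crops are
#' contrasted with an unpaired Wilcoxon rank-sum test on those
#' per-sample aggregates; BH adjustment runs across the categories of
#' the invocation (one family per run).
#'
#' @param x A `cpt_tbl`.
#' @param metadata Metadata covering `x`.
#' @param matches An `ewas_matches` tibble from [match_to_db()].
#' @param categories Categories to test; default all present in
#'   `matches`.
#' @return An `ewas_res` object: `$summary` tibble (`category`,
#'   `matched_asv_count`, per-crop means, `p_raw`, `p_adj`) and
#'   `$per_sample` tibble (`sample_id`, `crop`, `category`,
#'   `aggregate`).
#' @export
category_aggregate_contrast <- function(x, metadata, matches,
                                        categories = NULL) {
  m <- asv_matrix(x)
  md <- align_metadata(x, metadata)
  crops <- sort(unique(md$crop))
  if (length(crops) != 2) stop("exactly two crops required")
  if (is.null(categories)) categories <- sort(unique(matches$category))
  per_sample <- list(); rows <- list()
  for (cat in categories) {
    ids <- intersect(unique(matches$asv_id[matches$category == cat]),
                     colnames(m))
    if (length(ids) == 0) stop("category with zero matched ASVs: ", cat)
    agg <- rowSums(m[, ids, drop = FALSE])
    per_sample[[cat]] <- tibble::tibble(sample_id = rownames(m),
                                        crop = md$crop, category = cat,
                                        aggregate = unname(agg))
    wt <- suppressWarnings(stats::wilcox.test(agg[md$crop == crops[1]],
                                              agg[md$crop == crops[2]]))
    rows[[cat]] <- tibble::tibble(
      category = cat, matched_asv_count = length(ids),
      mean_a = mean(agg[md$crop == crops[1]]),
      mean_b = mean(agg[md$crop == crops[2]]),
      p_raw = wt$p.value)
  }
  summary <- dplyr::bind_rows(rows)
  names(summary)[names(summary) == "mean_a"] <- paste0("mean_", crops[1])
  names(summary)[names(summary) == "mean_b"] <- paste0("mean_", crops[2])
  summary$p_adj <- stats::p.adjust(summary$p_raw, "BH")
  structure(list(summary = summary,
                 per_sample = dplyr::bind_rows(per_sample),
                 crops = crops),
            class = "ewas_res")
}

#' @export
print.ewas_res <- function(x, ...) {
  cat("Environment-wide association contrast (",
      paste(x$crops, collapse = " vs "), ")\n", sep = "")
  print(x$summary)
  invisible(x)
}
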