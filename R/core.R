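#' Abundance-occupancy core membership
#'
#' An ASV is a core member of a crop's rhizomicrobiome when it holds at
#' least `min_total_ra` of the crop's total reads AND is detected
#' (count > 0) in at least `min_occupancy` of the crop's samples. Both
#' statistics are computed over all the crop's samples pooled across
#' countries, years and depths.
#'
#' @param x An `asv_tbl` of counts (the table whose filters preceded core
#'   detection; record them via its provenance).
#' @param metadata Metadata covering the samples of `x`.
#' @param crop Crop level to analyse.
#' @param min_total_ra Minimum share of the crop's total reads; default
#'   0.001 (0.1%).
#' @param min_occupancy Minimum fraction of the crop's samples the ASV is
#'   detected in; default 0.90.
#' @param abundance `"total_reads"` (default) scores each ASV's summed
#'   counts over the crop's total reads; `"mean_ra"` scores the mean of
#'   its per-sample relative abundances instead.
#' @return A `core_set` tibble: `asv_id`, `crop`, `occupancy`,
#'   `total_ra`, `member`, ordered lexicographically by `asv_id`.
#' @export
#' @examples
#' m <- matrix(c(10, 10, 1, 0), 2,
#'             dimnames = list(c("s1", "s2"), c("a", "b")))
#' md <- tibble::tibble(sample_id = c("s1", "s2"), crop = "Kernza",
#'                      country = "SE", year = 2021L, depth = "5-15",
#'                      compartment = "rhizosphere", pair_id = sample_id)
#' core_set(asv_table(m), md, "Kernza")
core_set <- function(x, metadata, crop, min_total_ra = 0.001,
                     min_occupancy = 0.90,
                     abundance = c("total_reads", "mean_ra")) {
  abundance <- match.arg(abundance)
  m <- asv_matrix(x)
  md <- align_metadata(x, metadata)
  sel <- md$crop == crop
  if ("compartment" %in% names(md)) sel <- sel & md$compartment == "rhizosphere"
  if (!any(sel)) stop("no samples for crop `", crop, "`")
  m <- m[sel, , drop = FALSE]
  occupancy <- colSums(m > 0) / nrow(m)
  total_ra <- if (abundance == "total_reads") {
    colSums(m) / sum(m)
  } else {
    colMeans(m / rowSums(m))
  }
  out <- tibble::tibble(
    asv_id = colnames(m), crop = crop,
    occupancy = unname(occupancy), total_ra = unname(total_ra),
    member = unname(occupancy >= min_occupancy & total_ra >= min_total_ra)
  )
  out <- out[order(out$asv_id), , drop = FALSE]
  attr(out, "thresholds") <- c(min_total_ra = min_total_ra,
                               min_occupancy = min_occupancy)
  attr(out, "abundance") <- abundance
  class(out) <- c("core_set", class(out))
  out
}

#' Member ASV ids of a core set
#'
#' @param x A `core_set`.
#' @return Character vector, lexicographic order.
#' @export
core_members <- function(x) sort(x$asv_id[x$member])

#' Overlap of two core sets (Venn partition)
#'
#' @param a,b `core_set` tibbles (or plain character vectors of ASV ids).
#' @return A list with `shared`, `only_a`, `only_b` (sorted character
#'   vectors) and a `counts` tibble of the three partition sizes.
#' @export
core_overlap <- function(a, b) {
  ia <- if (is.character(a)) sort(a) else core_members(a)
  ib <- if (is.character(b)) sort(b) else core_members(b)
  out <- list(shared = intersect(ia, ib),
              only_a = setdiff(ia, ib),
              only_b = setdiff(ib, ia))
  out$counts <- tibble::tibble(
    partition = c("shared", "only_a", "only_b"),
    n = lengths(out[c("shared", "only_a", "only_b")])
  )
  out
}
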