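#' Per-pair rhizosphere-to-endosphere ASV overlap
#'
#' Each endosphere (root endophyte) library is linked through its
#' `pair_id` to the single rhizosphere library collected at the same
#' spot; one rhizosphere library may serve many endosphere libraries.
#' Recruitment is quantified per endosphere library as the number and
#' fraction of its detected ASVs that are also detected in the paired
#' rhizosphere library. The fraction's denominator is the endosphere
#' library's detected ASV count (recruitment of the endophyte community
#' from rhizosphere populations); `denominator = "rhizosphere"` flips it.
#'
#' @param rhizo,endo `asv_tbl` tables for the two compartments.
#' @param metadata Metadata covering both tables (endosphere rows carry
#'   the rhizosphere `sample_id` in `pair_id`).
#' @param denominator `"endosphere"` (default) or `"rhizosphere"`.
#' @return A `recruitment_tbl` tibble: `sample_id`, `pair_id`, `crop`,
#'   `shared_count`, `endo_asv_count`, `shared_fraction`, plus a
#'   `shared` list-column of the shared ASV ids (sorted).
#' @export
pair_overlap <- function(rhizo, endo, metadata,
                         denominator = c("endosphere", "rhizosphere")) {
  denominator <- match.arg(denominator)
  rm_ <- asv_matrix(rhizo) > 0
  em <- asv_matrix(endo) > 0
  emd <- align_metadata(endo, metadata)
  bad <- !(emd$pair_id %in% rownames(rm_))
  if (any(bad)) {
    stop("endosphere sample(s) with unresolvable pair_id: ",
         paste(emd$sample_id[bad], collapse = ", "))
  }
  res <- lapply(seq_len(nrow(em)), function(i) {
    e_asvs <- colnames(em)[em[i, ]]
    if (length(e_asvs) == 0) {
      stop("endosphere library with zero detected ASVs: ", rownames(em)[i])
    }
    r_row <- rm_[emd$pair_id[i], ]
    r_asvs <- colnames(rm_)[r_row]
    shared <- sort(intersect(e_asvs, r_asvs))
    denom <- if (denominator == "endosphere") length(e_asvs) else length(r_asvs)
    tibble::tibble(sample_id = rownames(em)[i], pair_id = emd$pair_id[i],
                   crop = emd$crop[i], shared_count = length(shared),
                   endo_asv_count = length(e_asvs),
                   shared_fraction = length(shared) / denom,
                   shared = list(shared))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("recruitment_tbl", class(out))
  out
}

#' Mean recruitment per crop (x-bar recruitment)
#'
#' @param summaries A `recruitment_tbl` from [pair_overlap()].
#' @return Tibble: `crop`, `n_pairs`, `mean_shared_count`,
#'   `mean_shared_fraction`.
#' @export
recruitment_means <- function(summaries) {
  summaries |>
    dplyr::group_by(.data$crop) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_shared_count = mean(.data$shared_count),
                     mean_shared_fraction = mean(.data$shared_fraction),
                     .groups = "drop")
}

#' Crop-level partition of recruited ASVs
#'
#' Pools the shared (recruited) ASVs of each crop's endosphere libraries
#' and partitions their union into crop-A-only, crop-B-only and common
#' sets, with percentages over the union.
#'
#' @param summaries A `recruitment_tbl` from [pair_overlap()].
#' @return Tibble: `partition` (`only_<cropA>`, `only_<cropB>`,
#'   `common`), `n`, `percent` (sums to 100), plus an `asv_ids`
#'   list-column.
#' @export
crop_union_overlap <- function(summaries) {
  crops <- sort(unique(summaries$crop))
  if (length(crops) != 2) stop("exactly two crops required, found ",
                               length(crops))
  rec <- lapply(crops, function(cr) {
    sort(unique(unlist(summaries$shared[summaries$crop == cr])))
  })
  common <- intersect(rec[[1]], rec[[2]])
  only_a <- setdiff(rec[[1]], rec[[2]])
  only_b <- setdiff(rec[[2]], rec[[1]])
  n <- c(length(only_a), length(only_b), length(common))
  tibble::tibble(
    partition = c(paste0("only_", crops), "common"),
    n = n,
    percent = if (sum(n) > 0) 100 * n / sum(n) else rep(0, 3),
    asv_ids = list(only_a, only_b, common)
  )
}

#' Correlation of endosphere vs rhizosphere mean abundance
#'
#' Correlates each ASV's mean relative abundance in the endosphere
#' libraries against its mean in the paired rhizosphere libraries, over
#' a given ASV subset (e.g. a differential-abundance-derived endophyte
#' set, or all ASVs).
#'
#' @param rhizo,endo `cpt_tbl` tables.
#' @param asv_subset Character vector of ASV ids (must appear in both
#'   tables' column sets; ids missing from a table count as abundance 0).
#' @param method `"pearson"` or `"spearman"`.
#' @param log Take `log10(x + pseudocount)` of the mean abundances first.
#' @param pseudocount Used only when `log = TRUE`; default half the
#'   smallest nonzero mean.
#' @return Tibble: `method`, `r`, `p_value`, `n_asv`.
#' @export
abundance_correlation <- function(rhizo, endo, asv_subset,
                                  method = c("pearson", "spearman"),
                                  log = FALSE, pseudocount = NULL) {
  method <- match.arg(method)
  if (length(asv_subset) < 3) stop("need at least three ASVs")
  mean_of <- function(tbl) {
    m <- asv_matrix(tbl)
    v <- stats::setNames(rep(0, length(asv_subset)), asv_subset)
    hit <- intersect(asv_subset, colnames(m))
    v[hit] <- colMeans(m[, hit, drop = FALSE])
    v
  }
  xr <- mean_of(rhizo); xe <- mean_of(endo)
  if (log) {
    if (is.null(pseudocount)) pseudocount <- min(c(xr[xr > 0], xe[xe > 0])) / 2
    xr <- log10(xr + pseudocount); xe <- log10(xe + pseudocount)
  }
  if (stats::sd(xr) == 0 || stats::sd(xe) == 0) {
    stop("constant abundance vector; correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(xr, xe, method = method))
  tibble::tibble(method = method, r = unname(ct$estimate),
                 p_value = ct$p.value, n_asv = length(asv_subset))
}

#' Preferential recruitment screen
#'
#' Flags endophyte ASVs occurring at similar relative abundance in the
#' rhizosphere of both crops (crop-contrast Wilcoxon `p_adj >= alpha`:
#' rhizosphere parity) but differentially abundant between crops in the
#' endosphere (`p_adj < alpha`: endosphere bias) — the signature of a
#' taxon one crop preferentially recruits into its roots. BH adjustment
#' is applied within each compartment's family of tests.
#'
#' @param rhizo,endo `cpt_tbl` tables.
#' @param metadata Metadata covering both tables.
#' @param endophyte_set Character vector of candidate ASV ids (from an
#'   upstream differential-abundance analysis; see [rank_da_screen()]
#'   for a built-in approximate screen).
#' @param alpha Significance level; default 0.05.
#' @return Tibble of the flagged ASVs: `asv_id`, `crop_favoured`,
#'   `rhizo_p_adj`, `endo_p_adj`, `rhizosphere_parity`,
#'   `endosphere_bias`.
#' @export
preferential_screen <- function(rhizo, endo, metadata, endophyte_set,
                                alpha = 0.05) {
  if (length(endophyte_set) == 0) stop("empty endophyte set")
  contrast <- function(tbl) {
    m <- asv_matrix(tbl)
    md <- align_metadata(tbl, metadata)
    crops <- sort(unique(md$crop))
    stopifnot(length(crops) == 2)
    ids <- intersect(endophyte_set, colnames(m))
    p <- vapply(ids, function(a) {
      suppressWarnings(stats::wilcox.test(
        m[md$crop == crops[1], a], m[md$crop == crops[2], a]))$p.value
    }, numeric(1))
    means <- matrix(vapply(crops, function(cr)
      colMeans(m[md$crop == cr, ids, drop = FALSE]),
      numeric(length(ids))), ncol = 2)
    list(ids = ids, p_adj = stats::p.adjust(p, "BH"),
         favoured = crops[max.col(means, ties.method = "first")])
  }
  rc <- contrast(rhizo)
  ec <- contrast(endo)
  ids <- intersect(rc$ids, ec$ids)
  rp <- rc$p_adj[match(ids, rc$ids)]
  ep <- ec$p_adj[match(ids, ec$ids)]
  keep <- rp >= alpha & ep < alpha
  tibble::tibble(
    asv_id = ids[keep],
    crop_favoured = ec$favoured[match(ids, ec$ids)][keep],
    rhizo_p_adj = rp[keep], endo_p_adj = ep[keep],
    rhizosphere_parity = TRUE, endosphere_bias = TRUE
  ) |> dplyr::arrange(.data$asv_id)
}

#' Approximate rank-based differential-abundance screen
#'
#' Plumbing helper producing a candidate differential set from
#' counts-per-thousand values: per ASV, a Wilcoxon rank-sum test between
#' the two levels of `factor` plus a log2 fold-change of group mean CPT,
#' BH-adjusted. This is a rank-based approximation, not a
#' negative-binomial differential-abundance model; sets derived from
#' dedicated tools can be supplied to downstream functions instead.
#'
#' @param x A `cpt_tbl`.
#' @param metadata Metadata covering `x`.
#' @param factor Two-level metadata column to contrast.
#' @param alpha BH-adjusted significance threshold.
#' @param min_l2fc Minimum absolute log2 fold-change.
#' @param pseudocount Added before the fold-change log; default half the
#'   smallest nonzero value.
#' @return Tibble: `asv_id`, `l2fc`, `p_raw`, `p_adj`, `selected`.
#' @export
rank_da_screen <- function(x, metadata, factor, alpha = 0.05,
                           min_l2fc = 1, pseudocount = NULL) {
  m <- asv_matrix(x)
  md <- align_metadata(x, metadata)
  g <- base::factor(md[[factor]])
  if (nlevels(g) != 2) stop("factor `", factor, "` must have two levels")
  if (is.null(pseudocount)) pseudocount <- min(m[m > 0]) / 2
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  i1 <- g == levels(g)[1]
  p <- vapply(seq_len(ncol(m)), function(j) {
    suppressWarnings(stats::wilcox.test(m[i1, j], m[!i1, j]))$p.value
  }, numeric(1))
  l2fc <- log2((colMeans(m[!i1, , drop = FALSE]) + pseudocount) /
               (colMeans(m[i1, , drop = FALSE]) + pseudocount))
  p_adj <- stats::p.adjust(p, "BH")
  tibble::tibble(asv_id = colnames(m), l2fc = unname(l2fc),
                 p_raw = p, p_adj = p_adj,
                 selected = p_adj < alpha & abs(l2fc) >= min_l2fc) |>
    dplyr::arrange(.data$asv_id)
}

#' Intersection of per-stratum differential sets
#'
#' "Consistently identified" across strata (e.g. countries) means
#' membership in every stratum's set.
#'
#' @param sets A list of character vectors.
#' @return Sorted character vector of the common elements.
#' @export
consistent_across <- function(sets) {
  stopifnot(length(sets) >= 1)
  sort(Reduce(intersect, sets))
}
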