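#' Mean pairwise dissimilarity within and between groups
#'
#' The homogeneity statistic mu_D is the mean of all pairwise Bray-Curtis
#' dissimilarities in a cell: either all pairs inside one group ("within")
#' or all pairs straddling two groups ("between"). A lower mu_D means a
#' more homogeneous set of communities, on the 0-1 scale of the distance.
#' The full pairwise value list is kept per cell because the downstream
#' group comparisons ([compare_mu_d()]) are rank tests on those lists.
#'
#' @param d A `dist` of pairwise dissimilarities.
#' @param metadata Metadata tibble covering the samples of `d`.
#' @param group_by Character vector of metadata columns defining the
#'   grouping (e.g. `c("crop", "year")`).
#' @param compartment Restrict to one compartment before grouping
#'   (default `"rhizosphere"` when a `compartment` column is present;
#'   `NULL` uses all samples). Between-cells therefore never mix
#'   compartments unless explicitly requested.
#' @return A `mu_d_tbl` tibble: `cell`, `type` (within/between),
#'   `group_a`, `group_b`, `mu_d`, `n_pairs` and a `values` list-column
#'   of the pairwise dissimilarities.
#' @export
group_mean_dissimilarity <- function(d, metadata, group_by,
                                     compartment = "rhizosphere") {
  m <- as.matrix(d)
  md <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for samples in `d`")
  if (!is.null(compartment) && "compartment" %in% names(md)) {
    keep <- md$compartment == compartment
    if (!any(keep)) stop("no samples in compartment `", compartment, "`")
    m <- m[keep, keep, drop = FALSE]
    md <- md[keep, , drop = FALSE]
  }
  miss <- setdiff(group_by, names(md))
  if (length(miss)) stop("unknown grouping column(s): ",
                         paste(miss, collapse = ", "))
  grp <- do.call(paste, c(md[group_by], sep = "."))
  sizes <- table(grp)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than two samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  idx <- which(upper.tri(m), arr.ind = TRUE)
  ga <- grp[idx[, 1]]; gb <- grp[idx[, 2]]
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  cell <- ifelse(lo == hi, paste0("within:", lo),
                 paste0("between:", lo, "|", hi))
  vals <- split(m[idx], cell)
  cells <- names(vals)
  within <- startsWith(cells, "within:")
  out <- tibble::tibble(
    cell    = cells,
    type    = ifelse(within, "within", "between"),
    group_a = ifelse(within, sub("^within:", "", cells),
                     sub("^between:([^|]*)\\|.*$", "\\1", cells)),
    group_b = ifelse(within, sub("^within:", "", cells),
                     sub("^between:[^|]*\\|", "", cells)),
    mu_d    = unname(vapply(vals, mean, numeric(1))),
    n_pairs = unname(lengths(vals)),
    values  = unname(vals)
  )
  out <- out[order(out$type, out$cell, method = "radix", decreasing = c(TRUE, FALSE)), ]
  attr(out, "grouping") <- group_by
  class(out) <- c("mu_d_tbl", class(out))
  out
}

#' Compare mu_D cells by rank test
#'
#' Unpaired Wilcoxon rank-sum tests between the pairwise-dissimilarity
#' lists of every pair of cells, BH-adjusted across the family. Pairs
#' built from shared samples are not independent; the test is the field's
#' conventional screen for these comparisons and is reported as such.
#'
#' @param cells A `mu_d_tbl` from [group_mean_dissimilarity()] (optionally
#'   subset to the cells of interest).
#' @return Tibble: `group_a`, `group_b` (cell labels), `statistic`,
#'   `p_raw`, `p_adj`.
#' @export
compare_mu_d <- function(cells) {
  if (any(lengths(cells$values) < 2)) {
    stop("cell(s) with fewer than two pairwise values: ",
         paste(cells$cell[lengths(cells$values) < 2], collapse = ", "))
  }
  wilcoxon_bh(stats::setNames(cells$values, cells$cell))
}

#' Inter-annual relative-abundance stability (delta-RA)
#'
#' For one crop, each ASV's mean relative abundance is computed across
#' that crop's samples separately for the two years, and the year-on-year
#' ratio `(RA_y2 + pc) / (RA_y1 + pc)` summarised by its mean and standard
#' deviation over the included ASVs. Because relative abundances are
#' compositional (they close to a constant sum), the mean ratio sits near
#' 1 for stable and unstable communities alike; the dispersion of the
#' ratios — the s.d., or the scale-symmetric `mean_abs_log_ratio` also
#' reported — is what shrinks when a community is inter-annually stable.
#'
#' @param x A `cpt_tbl` (counts-per-thousand) table.
#' @param metadata Metadata covering the samples of `x`.
#' @param crop Crop level to analyse.
#' @param pseudocount Added to numerator and denominator; default half the
#'   smallest nonzero value in the table. Must be > 0 when
#'   `inclusion = "detected_either_year"`.
#' @param inclusion `"detected_both_years"` (default) keeps ASVs with
#'   nonzero mean abundance in both years; `"detected_either_year"` keeps
#'   ASVs detected in at least one.
#' @param by Optional metadata column (e.g. `"country"`): ratios are then
#'   computed per level first and averaged per ASV across qualifying
#'   levels, instead of pooling all the crop's samples per year.
#' @return A `delta_ra` object; see [tidy.delta_ra()] and
#'   [glance.delta_ra()].
#' @export
delta_ra_stability <- function(x, metadata, crop,
                               pseudocount = NULL,
                               inclusion = c("detected_both_years",
                                             "detected_either_year"),
                               by = NULL) {
  inclusion <- match.arg(inclusion)
  m <- asv_matrix(x)
  md <- align_metadata(x, metadata)
  if ("compartment" %in% names(md)) {
    sel <- md$compartment == "rhizosphere"
    m <- m[sel, , drop = FALSE]; md <- md[sel, , drop = FALSE]
  }
  sel <- md$crop == crop
  if (!any(sel)) stop("no samples for crop `", crop, "`")
  m <- m[sel, , drop = FALSE]; md <- md[sel, , drop = FALSE]
  years <- sort(unique(md$year))
  if (length(years) != 2) {
    stop("crop `", crop, "` needs samples in exactly two years, found ",
         length(years))
  }
  if (is.null(pseudocount)) {
    nz <- asv_matrix(x)[asv_matrix(x) > 0]
    pseudocount <- min(nz) / 2
  }
  if (pseudocount == 0 && inclusion == "detected_either_year") {
    stop("pseudocount 0 with `detected_either_year` can divide by zero")
  }
  ratio_tbl <- function(mm, mdmd) {
    ra1 <- colMeans(mm[mdmd$year == years[1], , drop = FALSE])
    ra2 <- colMeans(mm[mdmd$year == years[2], , drop = FALSE])
    inc <- if (inclusion == "detected_both_years") ra1 > 0 & ra2 > 0
           else ra1 > 0 | ra2 > 0
    tibble::tibble(asv_id = colnames(mm)[inc],
                   ra_year1 = unname(ra1[inc]), ra_year2 = unname(ra2[inc]),
                   ratio = unname((ra2[inc] + pseudocount) /
                                    (ra1[inc] + pseudocount)))
  }
  per_asv <- if (is.null(by)) {
    ratio_tbl(m, md)
  } else {
    lv <- split(seq_len(nrow(md)), md[[by]])
    lv <- lv[vapply(lv, function(i) length(unique(md$year[i])) == 2, logical(1))]
    parts <- lapply(lv, function(i) ratio_tbl(m[i, , drop = FALSE], md[i, , drop = FALSE]))
    dplyr::bind_rows(parts) |>
      dplyr::group_by(.data$asv_id) |>
      dplyr::summarise(dplyr::across(c("ra_year1", "ra_year2", "ratio"), mean),
                       .groups = "drop")
  }
  per_asv <- per_asv[order(per_asv$asv_id), , drop = FALSE]
  structure(list(
    crop = crop, years = years, per_asv = per_asv,
    mean_delta_ra = mean(per_asv$ratio),
    sd_delta_ra = stats::sd(per_asv$ratio),
    mean_abs_log_ratio = mean(abs(log(per_asv$ratio))),
    pseudocount = pseudocount, inclusion = inclusion, by = by
  ), class = "delta_ra")
}

#' @export
print.delta_ra <- function(x, ...) {
  cat(sprintf(
    "delta-RA stability for %s (%d -> %d): mean = %.3f, s.d. = %.3f over %d ASVs\n",
    x$crop, x$years[1], x$years[2], x$mean_delta_ra, x$sd_delta_ra,
    nrow(x$per_asv)))
  invisible(x)
}
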