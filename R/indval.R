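#' Indicator species analysis (IndVal)
#'
#' For each ASV and candidate group, specificity `A` is the ASV's mean
#' relative abundance in the group divided by the sum of its group means,
#' and fidelity `B` is the fraction of the group's samples the ASV is
#' detected in. The indicator statistic is `sqrt(A * B)`; each ASV is
#' reported for its best group only. Significance comes from a seeded
#' permutation null in which one shuffled label vector scores all ASVs
#' per iteration (labels are exchangeable under the null, and sharing
#' shuffles keeps the test fast):
#' `p = (1 + #{perm stat >= observed}) / (1 + n_perm)`.
#'
#' The mean-based `A` corrects for unequal group sizes; `specificity =
#' "total"` uses raw group totals instead (the size-uncorrected classic
#' form). The two coincide on balanced designs.
#'
#' @param x A `cpt_tbl` (or any `asv_tbl`; rows are rescaled to relative
#'   abundance internally).
#' @param metadata Metadata covering the samples of `x`.
#' @param factor Metadata column defining the groups (>= 2 levels).
#' @param n_perm Number of label permutations; default 10000.
#' @param seed Integer seed.
#' @param specificity `"mean"` (default) or `"total"`.
#' @return An `indval_res` tibble: `asv_id`, `group`, `A`, `B`, `stat`,
#'   `p_value`, `passes` (at the default alpha = 0.05, min_stat = 0.35
#'   thresholds; re-derived by [filter_indicators()]). ASVs absent from
#'   every sample are excluded (undefined specificity).
#' @export
indval <- function(x, metadata, factor, n_perm = 10000, seed = 1L,
                   specificity = c("mean", "total")) {
  specificity <- match.arg(specificity)
  m <- asv_matrix(x)
  m <- m / rowSums(m)
  md <- align_metadata(x, metadata)
  g <- base::factor(md[[factor]])
  if (nlevels(g) < 2) stop("factor `", factor, "` has a single level")
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  pres <- (m > 0) + 0
  sizes <- as.vector(table(g))

  stat_of <- function(gg) {
    agg <- rowsum(m, gg)
    if (specificity == "mean") agg <- agg / sizes
    A <- agg / rep(colSums(agg), each = nrow(agg))
    B <- rowsum(pres, gg) / sizes
    sqrt(A * B)
  }
  col_max <- function(s) {
    best <- s[1, ]
    if (nrow(s) > 1) for (l in 2:nrow(s)) best <- pmax(best, s[l, ])
    best
  }

  s_obs <- stat_of(g)
  best_grp <- levels(g)[max.col(t(s_obs), ties.method = "first")]
  obs <- col_max(s_obs)

  set.seed(seed)
  exceed <- numeric(ncol(m))
  for (i in seq_len(n_perm)) {
    exceed <- exceed + (col_max(stat_of(sample(g))) >= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)

  idx <- cbind(match(best_grp, levels(g)), seq_len(ncol(m)))
  agg <- rowsum(m, g)
  if (specificity == "mean") agg <- agg / sizes
  A <- (agg / rep(colSums(agg), each = nrow(agg)))[idx]
  B <- (rowsum(pres, g) / sizes)[idx]
  out <- tibble::tibble(
    asv_id = colnames(m), group = best_grp,
    A = A, B = B, stat = unname(obs),
    p_value = unname(p),
    passes = unname(p) < 0.05 & unname(obs) >= 0.35
  )
  out <- out[order(out$asv_id), , drop = FALSE]
  attr(out, "n_perm") <- n_perm
  attr(out, "factor") <- factor
  class(out) <- c("indval_res", class(out))
  out
}

#' Screen indicator results on significance and effect size
#'
#' Keeps ASVs with `p_value < alpha` and `stat >= min_stat` (defaults:
#' alpha 0.05, minimum indicator value 0.35) and sets `passes`
#' accordingly.
#'
#' @param results An `indval_res` tibble.
#' @param alpha Significance level.
#' @param min_stat Minimum indicator statistic.
#' @return The filtered tibble.
#' @export
filter_indicators <- function(results, alpha = 0.05, min_stat = 0.35) {
  keep <- results$p_value < alpha & results$stat >= min_stat
  out <- results[keep, , drop = FALSE]
  out$passes <- TRUE
  out
}
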