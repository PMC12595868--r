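#' Alpha diversity per sample
#'
#' Computes observed richness, bias-corrected Chao1, Shannon (natural log
#' by default) or Gini-Simpson diversity for every sample. Shannon and
#' Simpson are proportion-based and indifferent to the counts-per-thousand
#' scale; Chao1 depends on singleton and doubleton counts and therefore
#' requires raw integer counts — passing a normalized table is an error
#' rather than a silently wrong answer.
#'
#' @param x An `asv_tbl` (counts or counts-per-thousand).
#' @param metric One or more of `"observed"`, `"chao1"`, `"shannon"`,
#'   `"simpson"`.
#' @param base Logarithm base for Shannon; default `exp(1)`.
#' @return A tibble with columns `sample_id`, `metric`, `value`.
#' @export
#' @examples
#' m <- matrix(c(5, 5, 5, 5), 1, dimnames = list("s1", paste0("a", 1:4)))
#' alpha_diversity(asv_table(m), c("observed", "shannon"))
alpha_diversity <- function(x, metric = c("observed", "chao1", "shannon",
                                          "simpson"),
                            base = exp(1)) {
  metric <- match.arg(metric, several.ok = TRUE)
  m <- asv_matrix(x)
  if (any(rowSums(m) == 0)) {
    stop("empty sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  one <- function(met) {
    v <- switch(met,
      observed = rowSums(m > 0),
      shannon  = vegan::diversity(m, index = "shannon", base = base),
      simpson  = vegan::diversity(m, index = "simpson"),
      chao1    = {
        if (isTRUE(attr(x, "normalized")) ||
            any(abs(m - round(m)) > 1e-8)) {
          stop("chao1 requires raw integer counts, not normalized values")
        }
        apply(m, 1, chao1_bc)
      })
    tibble::tibble(sample_id = rownames(m), metric = met,
                   value = unname(v))
  }
  dplyr::bind_rows(lapply(metric, one))
}

# bias-corrected Chao1: S_obs + F1(F1-1) / (2(F2+1))
chao1_bc <- function(counts) {
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  sum(counts > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d[i, j] = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` over the sample
#' rows of a (normally counts-per-thousand) table.
#'
#' @param x An `asv_tbl` with at least two samples.
#' @return A `stats::dist` object labelled by sample id.
#' @export
bray_curtis <- function(x) {
  m <- asv_matrix(x)
  if (nrow(m) < 2) stop("at least two samples required")
  if (any(rowSums(m) == 0)) {
    stop("all-zero sample(s) have undefined Bray-Curtis distance: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  vegan::vegdist(m, method = "bray")
}

#' Long-format view of a distance matrix
#'
#' @param d A `dist` with labels.
#' @return Tibble with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `distance`.
#' @export
dist_pairs <- function(d) {
  m <- as.matrix(d)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(sample_a = rownames(m)[idx[, 1]],
                 sample_b = colnames(m)[idx[, 2]],
                 distance = m[idx])
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Sequential (Type I) partition of the squared-dissimilarity total across
#' the given factors in the given order, with a permutation test per term
#' (`vegan::adonis2`, `by = "terms"`). The permutation p-value convention
#' is `(1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param d A `dist` of pairwise dissimilarities.
#' @param metadata Metadata tibble covering the samples of `d`.
#' @param factors Character vector of metadata column names, in the order
#'   variance is to be attributed.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `permanova_res` tibble: `term`, `df`, `sum_of_sqs`,
#'   `r_squared`, `pseudo_f`, `p_value`, `n_perm`. Terms plus `Residual`
#'   r_squared sum to 1.
#' @export
permanova <- function(d, metadata, factors, n_perm = 999, seed = 1L) {
  labs <- attr(d, "Labels")
  idx <- match(labs, metadata$sample_id)
  if (anyNA(idx)) stop("metadata missing for sample(s) in the distance matrix")
  md <- as.data.frame(metadata[idx, , drop = FALSE])
  for (f in factors) {
    if (!f %in% names(md)) stop("unknown factor: ", f)
    md[[f]] <- factor(md[[f]])
    if (nlevels(md[[f]]) < 2) {
      stop("factor `", f, "` has fewer than two levels among these samples")
    }
  }
  fml <- stats::reformulate(factors, response = quote(d))
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = md, permutations = n_perm, by = "terms")
  out <- tibble::tibble(
    term       = rownames(fit),
    df         = fit$Df,
    sum_of_sqs = fit$SumOfSqs,
    r_squared  = fit$R2,
    pseudo_f   = fit$F,
    p_value    = fit$`Pr(>F)`,
    n_perm     = n_perm
  )
  out <- out[out$term != "Total", , drop = FALSE]
  class(out) <- c("permanova_res", class(out))
  out
}

# exact two-sided rank-sum p with midranks: enumerate every assignment of
# the group-a positions when that is tractable, otherwise NULL
exact_rank_sum_p <- function(a, b, max_enum = 20000) {
  la <- length(a); n <- la + length(b)
  if (choose(n, la) > max_enum) return(NULL)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(la)])
  centre <- la * (n + 1) / 2
  sums <- utils::combn(n, la, function(ix) sum(r[ix]))
  mean(abs(sums - centre) >= abs(obs - centre) - 1e-12)
}

# exact two-sided signed-rank p with midranks over all sign assignments
exact_signed_rank_p <- function(a, b, max_enum = 20000) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  if (2^n > max_enum) return(NULL)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  centre <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% r)
  mean(abs(sums - centre) >= abs(obs - centre) - 1e-12)
}

#' Pairwise Wilcoxon tests with Benjamini-Hochberg correction
#'
#' Runs all pairwise two-sided Wilcoxon tests between groups (rank-sum when
#' unpaired, signed-rank when paired) and adjusts the family with BH.
#' Small samples get an exact enumeration over all label (or sign)
#' assignments with midranks — valid in the presence of ties, unlike the
#' classical exact distribution; larger samples use midranks with the
#' normal approximation (`stats::wilcox.test`).
#'
#' @param data A data frame with a value and a group column, or a named
#'   list of numeric vectors.
#' @param value,group Column names when `data` is a data frame.
#' @param paired Logical; paired tests require equal-length groups aligned
#'   by position.
#' @return Tibble: `group_a`, `group_b`, `statistic`, `p_raw`, `p_adj`.
#' @export
wilcoxon_bh <- function(data, value = "value", group = "group",
                        paired = FALSE) {
  groups <- if (is.data.frame(data)) {
    split(data[[value]], data[[group]])
  } else {
    data
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named")
  }
  if (any(lengths(groups) == 0)) stop("empty group present")
  cmb <- utils::combn(names(groups), 2)
  res <- apply(cmb, 2, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (paired && length(a) != length(b)) {
      stop("paired test requires equal group lengths (",
           pr[1], " vs ", pr[2], ")")
    }
    p_exact <- if (paired) exact_signed_rank_p(a, b) else exact_rank_sum_p(a, b)
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = FALSE))
    c(statistic = unname(wt$statistic), p = p_exact %||% wt$p.value)
  })
  tibble::tibble(
    group_a = cmb[1, ], group_b = cmb[2, ],
    statistic = unname(res["statistic", ]),
    p_raw = unname(res["p", ]),
    p_adj = unname(stats::p.adjust(res["p", ], method = "BH"))
  )
}
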