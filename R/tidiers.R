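#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PERMANOVA result
#'
#' @param x A `permanova_res`.
#' @param ... Unused.
#' @return The result as a plain tibble, one row per model term.
#' @export
tidy.permanova_res <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "permanova_res")
  out
}

#' @rdname tidy.permanova_res
#' @return For `glance`: a one-row tibble with the best term, its
#'   `r_squared`, and the permutation count.
#' @export
glance.permanova_res <- function(x, ...) {
  terms <- x[x$term != "Residual", ]
  top <- terms[which.max(terms$r_squared), ]
  tibble::tibble(top_term = top$term, top_r_squared = top$r_squared,
                 n_terms = nrow(terms), n_perm = top$n_perm)
}

#' Tidy a delta-RA stability result
#'
#' @param x A `delta_ra` object.
#' @param ... Unused.
#' @return `tidy`: the per-ASV table (`asv_id`, `ra_year1`, `ra_year2`,
#'   `ratio`). `glance`: one row with the crop, mean, s.d., ASV count
#'   and pseudocount.
#' @export
tidy.delta_ra <- function(x, ...) x$per_asv

#' @rdname tidy.delta_ra
#' @export
glance.delta_ra <- function(x, ...) {
  tibble::tibble(crop = x$crop, mean_delta_ra = x$mean_delta_ra,
                 sd_delta_ra = x$sd_delta_ra,
                 mean_abs_log_ratio = x$mean_abs_log_ratio,
                 n_asv = nrow(x$per_asv),
                 pseudocount = x$pseudocount, inclusion = x$inclusion)
}

#' Tidy an environment-wide association result
#'
#' @param x An `ewas_res`.
#' @param ... Unused.
#' @return `tidy`: the per-category summary. `glance`: one row with the
#'   number of categories and the count significant at `p_adj < 0.05`.
#' @export
tidy.ewas_res <- function(x, ...) x$summary

#' @rdname tidy.ewas_res
#' @export
glance.ewas_res <- function(x, ...) {
  tibble::tibble(n_categories = nrow(x$summary),
                 n_significant = sum(x$summary$p_adj < 0.05))
}
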