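# broom-style tidy()/glance() methods for fitted objects.

#' Tidy an OLS fit
#'
#' @param x A `bft_ols` object.
#' @param ... Unused.
#' @return Tibble: term, estimate, std_error, statistic, df, p.
#' @export
tidy.bft_ols <- function(x, ...) x$coefficients

#' @rdname tidy.bft_ols
#' @return `glance()`: one-row tibble with r_squared, adj_r_squared,
#'   df_residual, n_used, n_dropped.
#' @export
glance.bft_ols <- function(x, ...) {
  tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
         df_residual = x$df_residual, n_used = x$n_used,
         n_dropped = x$n_dropped)
}

#' Tidy a per-gene mixed-model fit
#'
#' @param x A `bft_mixed` object.
#' @param ... Unused.
#' @return One-row tibble: gene, term, estimate, std_error, statistic, df,
#'   p.
#' @export
tidy.bft_mixed <- function(x, ...) {
  tibble(gene = x$gene, term = "expression", estimate = x$slope,
         std_error = x$se, statistic = x$statistic, df = x$df, p = x$p)
}

#' @rdname tidy.bft_mixed
#' @return `glance()`: one-row tibble with the variance components,
#'   variance ratio, singular flag and n.
#' @export
glance.bft_mixed <- function(x, ...) {
  tibble(donor_variance = x$donor_variance,
         residual_variance = x$residual_variance,
         lambda = x$lambda, singular = x$singular, n = x$n, test = x$test)
}

#' Glance at moderation hyperparameters
#'
#' @param x A `bft_moderation` object.
#' @param ... Unused.
#' @return One-row tibble: d0, s0_sq, n_genes.
#' @export
glance.bft_moderation <- function(x, ...) {
  tibble(d0 = x$d0, s0_sq = x$s0_sq, n_genes = x$n_genes)
}
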