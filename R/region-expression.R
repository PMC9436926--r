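# Region-specific expression: per-gene linear models with donor and region
# terms, empirical-Bayes variance moderation, FDR, and signed ranking.

#' Per-gene donor + region linear models
#'
#' Fits, for every gene, ordinary least squares of expression on donor
#' indicator blocks plus a target-region indicator, restricted to donors
#' that sampled both basal-forebrain regions. All genes share one design,
#' so the fit is a single multi-response least-squares solve.
#'
#' @param gene_expression Gene x sample matrix (one probe per gene).
#' @param samples Sample tibble (sample_id, donor_id, structure_label).
#' @param target_region Structure label(s) forming the contrast's target
#'   (e.g. `"Ch1-3"`, `"NBM"`, or both for a BF-vs-rest contrast).
#' @param contrast `"vs_rest"` (default: target vs all other sampled
#'   structures pooled) or `"pairwise"` (target vs the other BF region
#'   only).
#' @param bf_regions Structure labels counted as basal forebrain when
#'   restricting donors (default `c("Ch1-3", "NBM")`).
#' @return Tibble of class `bft_genefits`: gene, beta (region coefficient,
#'   log2 units), s_g_sq (residual variance), d_g (residual df), v_g
#'   (unscaled coefficient variance), degenerate flag. Attributes carry the
#'   design metadata.
#' @export
fit_gene_models <- function(gene_expression, samples,
                            target_region = "Ch1-3",
                            contrast = c("vs_rest", "pairwise"),
                            bf_regions = c("Ch1-3", "NBM")) {
  contrast <- match.arg(contrast)
  samples <- filter(samples, .data$sample_id %in% colnames(gene_expression))
  bf_by_donor <- table(samples$donor_id[samples$structure_label %in%
                                          bf_regions],
                       samples$structure_label[samples$structure_label %in%
                                                 bf_regions])
  donors_ok <- rownames(bf_by_donor)[rowSums(bf_by_donor > 0) ==
                                       length(bf_regions)]
  if (length(donors_ok) < 2) {
    bft_stop("Need >= 2 donors sampling every basal-forebrain region.",
             "bftrans_error_invalid_argument")
  }
  samples <- filter(samples, .data$donor_id %in% donors_ok)
  if (contrast == "pairwise") {
    samples <- filter(samples, .data$structure_label %in% bf_regions)
  }
  if (!any(samples$structure_label %in% target_region)) {
    bft_stop("Target region absent after donor restriction.",
             "bftrans_error_invalid_argument")
  }
  y <- gene_expression[, samples$sample_id, drop = FALSE]
  donor <- factor(samples$donor_id)
  target <- as.numeric(samples$structure_label %in% target_region)
  X <- model.matrix(~ donor + target)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bft_stop("Design is rank deficient (a donor's samples are all in the target region).",
             "bftrans_error_collinearity")
  }
  n <- nrow(X)
  d_g <- n - qx$rank
  xtx_inv <- chol2inv(qr.R(qx))
  v_g <- xtx_inv[ncol(X), ncol(X)]
  B <- qr.coef(qx, t(y))
  res <- t(y) - X %*% B
  s_g_sq <- colSums(res^2) / d_g
  out <- tibble(
    gene = rownames(y),
    beta = unname(B[ncol(X), ]),
    s_g_sq = unname(s_g_sq),
    d_g = d_g,
    v_g = v_g,
    degenerate = s_g_sq <= .Machine$double.eps^0.5
  )
  attr(out, "design") <- list(target_region = target_region,
                              contrast = contrast,
                              donors = levels(donor),
                              n_samples = n, n_target = sum(target))
  class(out) <- c("bft_genefits", class(out))
  out
}

# Solve trigamma(x) = y by Newton iteration on 1/x (monotone, convex).
trigamma_inverse <- function(y) {
  vapply(y, function(v) {
    if (v <= 0) return(Inf)
    if (v > 1e7) return(1 / sqrt(v))
    x <- 0.5 + 1 / v
    for (i in 1:60) {
      tg <- trigamma(x)
      dif <- tg * (1 - tg / v) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1))
}

#' Estimate empirical-Bayes moderation hyperparameters
#'
#' Fits the scaled-F model for per-gene residual variances by matching the
#' moments of `log(s_g^2)` with digamma/trigamma equations: the prior
#' degrees of freedom `d0` solve
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` with
#' `e = log(s2) - digamma(d_g/2) + log(d_g/2)`, and the prior variance
#' follows from the mean of `e`. When the observed spread of `log(s_g^2)`
#' does not exceed its expected sampling variance, `d0` is infinite and all
#' posterior variances equal `s0_sq`.
#'
#' @param s_g_sq Per-gene residual variances.
#' @param d_g Per-gene residual degrees of freedom (scalar or vector).
#' @return List of class `bft_moderation`: `d0`, `s0_sq`, `n_genes`.
#' @export
estimate_moderation <- function(s_g_sq, d_g) {
  d_g <- rep_len(d_g, length(s_g_sq))
  ok <- is.finite(s_g_sq) & s_g_sq > 0 & d_g >= 1
  if (sum(ok) < 10) {
    bft_stop("Need >= 10 genes with positive variance and d_g >= 1.",
             "bftrans_error_insufficient_data")
  }
  s2 <- s_g_sq[ok]; df <- d_g[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond sampling noise: variances are exchangeable
    # around a single prior value, estimated by their mean
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_genes = n),
            class = "bft_moderation")
}

#' @export
print.bft_moderation <- function(x, ...) {
  cat(sprintf("<bft_moderation> d0 = %s, s0_sq = %.5g (from %d genes)\n",
              format(x$d0), x$s0_sq, x$n_genes))
  invisible(x)
}

#' Moderated t-statistics with FDR and signed ranking
#'
#' Shrinks each gene's residual variance towards the prior,
#' `s_post^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, forms
#' `t = beta / sqrt(s_post^2 v_g)` on `d_g + d0` degrees of freedom, and
#' attaches BH-FDR q-values and the signed significance score
#' `-log10(p) * sign(t)` used for ranking. Genes flagged degenerate get NA
#' statistics.
#'
#' @param fits A [fit_gene_models()] result.
#' @param hyper A [estimate_moderation()] result (estimated from the
#'   non-degenerate fits by default).
#' @param fdr_grid FDR thresholds at which passing-gene lists are computed
#'   (default 0.10, 0.05, 0.01).
#' @return Tibble of class `bft_genestats`: gene, beta, s_g_sq, s_post_sq,
#'   t_mod, df_total, p, q, rank_score; attribute `fdr_lists` holds the
#'   gene lists per threshold, `hyper` the hyperparameters.
#' @export
moderated_t <- function(fits, hyper = NULL, fdr_grid = c(0.10, 0.05, 0.01)) {
  ok <- !fits$degenerate
  if (is.null(hyper)) {
    hyper <- estimate_moderation(fits$s_g_sq[ok], fits$d_g[ok])
  }
  if (!is.finite(hyper$s0_sq) || hyper$s0_sq <= 0 ||
      (is.finite(hyper$d0) && hyper$d0 < 0)) {
    bft_stop("Moderation hyperparameters must be positive.",
             "bftrans_error_invalid_argument")
  }
  d0 <- hyper$d0; s0 <- hyper$s0_sq
  s_post <- if (is.infinite(d0)) rep(s0, nrow(fits)) else
    (d0 * s0 + fits$d_g * fits$s_g_sq) / (d0 + fits$d_g)
  df_total <- fits$d_g + d0
  t_mod <- fits$beta / sqrt(s_post * fits$v_g)
  t_mod[!ok] <- NA_real_
  p <- rep(NA_real_, nrow(fits))
  p[ok] <- t_tail_p(t_mod[ok], df_total[ok])
  q <- rep(NA_real_, nrow(fits))
  q[ok] <- bh_fdr(p[ok])$q
  out <- tibble(
    gene = fits$gene, beta = fits$beta, s_g_sq = fits$s_g_sq,
    s_post_sq = s_post, t_mod = t_mod, df_total = df_total,
    p = p, q = q,
    rank_score = -log10(p) * sign(t_mod)
  )
  lists <- lapply(setNames(fdr_grid, paste0("fdr_", fdr_grid)),
                  function(th) out$gene[!is.na(out$q) & out$q < th])
  attr(out, "fdr_lists") <- lists
  attr(out, "hyper") <- hyper
  attr(out, "design") <- attr(fits, "design")
  class(out) <- c("bft_genestats", class(out))
  out
}

#' Region-specific expression analysis
#'
#' Convenience wrapper: per-gene donor+region models, moderation
#' hyperparameters (refit per contrast), moderated t, FDR lists and signed
#' ranking for one target region.
#'
#' @inheritParams fit_gene_models
#' @inheritParams moderated_t
#' @return A `bft_genestats` tibble (see [moderated_t()]).
#' @export
region_expression_analysis <- function(gene_expression, samples,
                                       target_region = "Ch1-3",
                                       contrast = "vs_rest",
                                       fdr_grid = c(0.10, 0.05, 0.01)) {
  fits <- fit_gene_models(gene_expression, samples, target_region,
                          contrast = contrast)
  moderated_t(fits, fdr_grid = fdr_grid)
}
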