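# Imaging transcriptomics: explain BF-cortical covariance with gene
# expression via per-gene random-intercept (donor) mixed models.

#' Assemble the per-vertex design for imaging-transcriptomic models
#'
#' One row per retained sample-to-vertex match: the covariance-map r at the
#' matched vertex, the sample's donor, and the gene expression columns.
#' Matched vertices missing from the map are dropped and counted; duplicate
#' vertices among retained matches are an integrity error.
#'
#' @param covmap A [map_covariance()] result (cortical structure).
#' @param matches A [match_samples_to_vertices()] result.
#' @param gene_expression Gene x sample matrix.
#' @param samples Sample tibble supplying `donor_id`.
#' @return List of class `bft_txdesign`: `data` (tibble sample_id,
#'   vertex_id, donor_id, r), `expression` (gene x retained-sample matrix),
#'   `n_dropped` (matches without a map vertex).
#' @export
assemble_design <- function(covmap, matches, gene_expression, samples) {
  kept <- filter(as_tibble(matches), .data$retained)
  if (nrow(kept) == 0) {
    bft_stop("No retained sample-to-vertex matches.",
             "bftrans_error_empty_result")
  }
  if (anyDuplicated(kept$vertex_id)) {
    bft_stop("Retained matches contain duplicate vertices.",
             "bftrans_error_integrity")
  }
  map_tb <- select(as_tibble(covmap), "vertex_id", "r")
  dat <- inner_join(kept, map_tb, by = "vertex_id")
  n_dropped <- nrow(kept) - nrow(dat)
  dat <- inner_join(dat,
                    select(samples, "sample_id", "donor_id"),
                    by = "sample_id")
  dat <- arrange(select(dat, "sample_id", "vertex_id", "donor_id", "r"),
                 .data$sample_id)
  if (nrow(dat) == 0) {
    bft_stop("No matched vertices present in the covariance map.",
             "bftrans_error_empty_result")
  }
  expr <- gene_expression[, dat$sample_id, drop = FALSE]
  structure(list(data = dat, expression = expr, n_dropped = n_dropped),
            class = "bft_txdesign")
}

# Profiled REML machinery for y ~ 1 + x + (1 | donor).
# For V = I + lambda Z Z' with a random intercept, V^{-1} is block
# diagonal: I - (lambda / (1 + lambda n_i)) J within donor i, so all
# quantities reduce to per-donor sums.
reml_parts <- function(y, x, donor) {
  X <- cbind(1, x)
  idx <- split(seq_along(y), donor)
  list(
    X = X, y = y, n = length(y),
    xtx = crossprod(X), xty = crossprod(X, y), yty = sum(y^2),
    S = t(vapply(idx, function(i) colSums(X[i, , drop = FALSE]),
                 numeric(2))),
    T = vapply(idx, function(i) sum(y[i]), numeric(1)),
    ni = lengths(idx)
  )
}

reml_eval <- function(parts, lambda, reml = TRUE, p = 2) {
  ci <- lambda / (1 + lambda * parts$ni)
  A <- parts$xtx - crossprod(parts$S * sqrt(ci))
  b <- parts$xty - colSums(parts$S * (ci * parts$T))
  yvy <- parts$yty - sum(ci * parts$T^2)
  A <- A[seq_len(p), seq_len(p), drop = FALSE]
  b <- b[seq_len(p)]
  beta <- solve(A, b)
  rss <- max(yvy - sum(b * beta), .Machine$double.eps)
  logdetV <- sum(log1p(lambda * parts$ni))
  crit <- if (reml) {
    (parts$n - p) * log(rss) + logdetV + determinant(A)$modulus[1]
  } else {
    parts$n * log(rss) + logdetV
  }
  list(crit = crit, beta = beta, rss = rss, A = A)
}

#' Fit one gene's random-intercept mixed model
#'
#' Restricted maximum likelihood for `r ~ expression + (1 | donor)`,
#' profiled down to a one-dimensional search over the variance ratio
#' `lambda = donor variance / residual variance`. The slope is tested by a
#' Wald t with `df = n - 2`; an optional likelihood-ratio test (ML fits
#' with and without the slope) is available. Fits whose donor variance
#' collapses to zero fall back to OLS and are flagged singular rather than
#' dropped.
#'
#' @param design A [assemble_design()] result.
#' @param gene Gene identifier (row of the expression matrix).
#' @param test `"wald"` (default) or `"lrt"`.
#' @return List of class `bft_mixed`: gene, slope, se, statistic, df, p,
#'   donor_variance, residual_variance, lambda, singular, n, test.
#' @export
fit_mixed_per_gene <- function(design, gene, test = c("wald", "lrt")) {
  test <- match.arg(test)
  dat <- design$data
  if (length(unique(dat$donor_id)) < 2 || nrow(dat) < 6) {
    bft_stop("Need >= 2 donors and >= 6 rows.",
             "bftrans_error_insufficient_data")
  }
  x <- design$expression[gene, ]
  y <- dat$r
  parts <- reml_parts(y, x, dat$donor_id)
  opt <- optimize(function(lt) reml_eval(parts, exp(lt))$crit,
                  interval = c(-30, 12), tol = 1e-9)
  lambda <- exp(opt$minimum)
  at0 <- reml_eval(parts, 0)
  singular <- FALSE
  if (at0$crit <= opt$objective + 1e-8 || lambda < 1e-8) {
    lambda <- 0
    singular <- TRUE
  }
  fit <- reml_eval(parts, lambda)
  n <- parts$n
  sigma2 <- fit$rss / (n - 2)
  se <- sqrt(sigma2 * solve(fit$A)[2, 2])
  slope <- unname(fit$beta[2])
  df <- n - 2
  if (test == "wald") {
    stat <- slope / se
    p <- t_tail_p(stat, df)
  } else {
    full <- optimize(function(lt) reml_eval(parts, exp(lt), reml = FALSE)$crit,
                     interval = c(-30, 12), tol = 1e-9)
    full_c <- min(full$objective, reml_eval(parts, 0, reml = FALSE)$crit)
    null <- optimize(function(lt) reml_eval(parts, exp(lt), reml = FALSE,
                                            p = 1)$crit,
                     interval = c(-30, 12), tol = 1e-9)
    null_c <- min(null$objective, reml_eval(parts, 0, reml = FALSE,
                                            p = 1)$crit)
    stat <- max(null_c - full_c, 0)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(gene = gene, slope = slope, se = se, statistic = stat,
                 df = df, p = p,
                 donor_variance = lambda * sigma2,
                 residual_variance = sigma2, lambda = lambda,
                 singular = singular, n = n, test = test),
            class = "bft_mixed")
}

#' @export
print.bft_mixed <- function(x, ...) {
  cat(sprintf("<bft_mixed> %s: slope = %.4g (t = %.3f, df = %d, p = %.3g)%s\n",
              x$gene, x$slope, x$statistic, x$df, x$p,
              if (x$singular) " [singular: OLS fallback]" else ""))
  invisible(x)
}

#' Fit mixed models for every gene
#'
#' Repeats [fit_mixed_per_gene()] across the expression matrix; a gene
#' whose fit fails yields NA statistics with a diagnostic, never an abort.
#'
#' @inheritParams fit_mixed_per_gene
#' @param genes Genes to fit (default: all rows).
#' @return Tibble of class `bft_imgstats`: gene, slope, statistic, df, p,
#'   q, donor_variance, residual_variance, singular.
#' @export
fit_imaging_models <- function(design, genes = NULL, test = "wald") {
  genes <- genes %||% rownames(design$expression)
  rows <- map(genes, function(g) {
    f <- tryCatch(fit_mixed_per_gene(design, g, test = test),
                  error = function(e) NULL)
    if (is.null(f)) {
      return(tibble(gene = g, slope = NA_real_, statistic = NA_real_,
                    df = NA_real_, p = NA_real_, donor_variance = NA_real_,
                    residual_variance = NA_real_, singular = NA))
    }
    tibble(gene = g, slope = f$slope, statistic = f$statistic, df = f$df,
           p = f$p, donor_variance = f$donor_variance,
           residual_variance = f$residual_variance, singular = f$singular)
  })
  out <- list_rbind(rows)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- bh_fdr(out$p[ok])$q
  class(out) <- c("bft_imgstats", class(out))
  out
}

#' Rank genes and slice deciles
#'
#' Ranks genes by t-statistic, flags the top and bottom `decile` fractions
#' (sizes `floor(decile * n)`, ties broken by gene identifier), and counts
#' FDR-passing genes at each threshold.
#'
#' @param stats A `bft_imgstats` (or any tibble with gene, statistic, q).
#' @param decile Fraction for each tail (default 0.10).
#' @param fdr_grid FDR thresholds to count (default 0.10, 0.05, 0.01).
#' @return List: `stats` (input + `decile_flag`), `top`, `bottom` (gene
#'   vectors, ranked), `fdr_counts` (named integer vector).
#' @export
rank_and_slice <- function(stats, decile = 0.10,
                           fdr_grid = c(0.10, 0.05, 0.01)) {
  if (nrow(stats) == 0) {
    bft_stop("Empty stats table.", "bftrans_error_invalid_argument")
  }
  usable <- !is.na(stats$statistic)
  ord <- order(-stats$statistic[usable],
               stats$gene[usable])
  ranked <- stats$gene[usable][ord]
  k <- floor(decile * length(ranked))
  top <- head(ranked, k)
  bottom <- rev(ranked)[seq_len(k)]
  stats$decile_flag <- "none"
  stats$decile_flag[stats$gene %in% top] <- "top10"
  stats$decile_flag[stats$gene %in% bottom] <- "bottom10"
  counts <- vapply(fdr_grid, function(th) sum(stats$q < th, na.rm = TRUE),
                   integer(1))
  names(counts) <- paste0("fdr_", fdr_grid)
  list(stats = stats, top = top, bottom = bottom, fdr_counts = counts)
}
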