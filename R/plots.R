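# ggplot2 displays for the main result types.

#' Plot a structural covariance map
#'
#' Distribution of seed-to-vertex correlations per structure, with the
#' FDR-passing vertices highlighted.
#'
#' @param object A [map_covariance()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bft_covmap <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$r, fill = .data$passes_fdr)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::facet_wrap(~structure, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "q < 0.10") +
    ggplot2::labs(x = sprintf("Pearson r (seed: %s)",
                              attr(object, "seed") %||% "BF"),
                  y = "vertices") +
    ggplot2::theme_minimal()
}

#' Volcano plot of gene-level statistics
#'
#' @param stats A `bft_genestats` or `bft_imgstats` tibble (columns for the
#'   t statistic, p and q).
#' @param q_line FDR level marked by the dashed line (default 0.05).
#' @param label_genes Genes to annotate (default none).
#' @return A ggplot.
#' @export
plot_volcano <- function(stats, q_line = 0.05, label_genes = character()) {
  tcol <- if ("t_mod" %in% names(stats)) "t_mod" else "statistic"
  dat <- tibble(gene = stats$gene, t = stats[[tcol]], p = stats$p,
                q = stats$q)
  dat <- filter(dat, !is.na(.data$p))
  pass <- dat$q < q_line
  thr <- if (any(pass)) max(dat$p[pass]) else NA_real_
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t,
                                          y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$q < q_line),
                        size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = sprintf("q < %.2g", q_line)) +
    ggplot2::labs(x = "t statistic", y = "-log10 p") +
    ggplot2::theme_minimal()
  if (!is.na(thr)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(thr),
                                   linetype = "dashed")
  }
  lab <- filter(dat, .data$gene %in% label_genes)
  if (nrow(lab)) {
    gg <- gg + ggplot2::geom_text(data = lab,
                                  ggplot2::aes(label = .data$gene),
                                  vjust = -0.6, size = 3)
  }
  gg
}

#' Plot a CSEA grid
#'
#' Cell types against pSI thresholds; point size mirrors the nested
#' marker-set specificity (stricter thresholds draw smaller), colour marks
#' significance after FDR.
#'
#' @param object A [csea_enrich()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bft_csea <- function(object, ...) {
  dat <- mutate(as_tibble(object),
                threshold = factor(.data$threshold,
                                   levels = sort(unique(.data$threshold),
                                                 decreasing = TRUE)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cell_type,
                                    y = .data$threshold)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$set_size,
                                     colour = .data$significant)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick"),
                                 name = "q < 0.10") +
    ggplot2::labs(x = NULL, y = "pSI threshold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot choline-microstructure coupling by group
#'
#' Scatter of dACC choline against a BF region's values with per-group
#' least-squares lines — the decoupling display.
#'
#' @param subjects,roi Cohort tables.
#' @param region,metric ROI selection (default left NBM qT1).
#' @return A ggplot.
#' @export
plot_coupling <- function(subjects, roi, region = "nbm_l", metric = "qt1") {
  v <- roi_value(roi, region, metric)[subjects$subject_id]
  dat <- tibble(value = v, choline = subjects$choline,
                group = subjects$group)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, y = .data$choline,
                                    colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = sprintf("%s %s", region, metric),
                  y = "dACC choline") +
    ggplot2::theme_minimal()
}
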