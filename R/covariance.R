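# Seed-to-brain structural covariance: correlate a basal-forebrain seed's
# per-subject qT1 with every cortical / subcortical vertex, FDR within
# structure.

#' Map structural covariance from a BF seed
#'
#' For each vertex, the across-subject Pearson correlation between the seed
#' ROI's values and the vertex values, with BH-FDR computed within each
#' structure separately (`q < fdr_q` flags `passes_fdr`) and a subthreshold
#' fallback flag at `p < 0.05`. Subjects are pooled across groups by
#' default; a stratified mode restricts to one group. Constant vertices are
#' excluded and counted; vertices missing in more than `max_missing` of
#' subjects are excluded.
#'
#' @param surface A [simulate_surface()]-style object (`vertices` tibble +
#'   `qt1` subject x vertex matrix).
#' @param roi Long ROI tibble (subject_id, region, metric, value).
#' @param seed_region Seed ROI region identifier (default `"nbm_l"`).
#' @param metric ROI metric (default `"qt1"`).
#' @param structures Structures to map (default: all in `surface$vertices`).
#' @param group_filter Optional subject-id subset (stratified mode).
#' @param fdr_q FDR threshold within structure (default 0.10).
#' @param max_missing Maximum fraction of missing subjects per vertex.
#' @return Tibble of class `bft_covmap`: seed, structure, vertex_id, n, r,
#'   p, q, passes_fdr, subthreshold. Attribute `n_excluded` counts dropped
#'   vertices.
#' @export
map_covariance <- function(surface, roi, seed_region = "nbm_l",
                           metric = "qt1", structures = NULL,
                           group_filter = NULL, fdr_q = 0.10,
                           max_missing = 0.2) {
  seed_vals <- roi_value(roi, seed_region, metric)
  subj <- intersect(names(seed_vals), rownames(surface$qt1))
  if (!is.null(group_filter)) subj <- intersect(subj, group_filter)
  if (length(subj) < 5) {
    bft_stop("Fewer than 5 overlapping subjects between seed and surface.",
             "bftrans_error_insufficient_data")
  }
  seed_vals <- seed_vals[subj]
  mat <- surface$qt1[subj, , drop = FALSE]
  structures <- structures %||% unique(surface$vertices$structure)

  n_excluded <- 0L
  out <- map(structures, function(st) {
    vids <- surface$vertices$vertex_id[surface$vertices$structure == st]
    sub <- mat[, vids, drop = FALSE]
    miss <- colMeans(is.na(sub))
    sds <- apply(sub, 2, sd, na.rm = TRUE)
    keep <- miss <= max_missing & is.finite(sds) & sds > 0
    n_excluded <<- n_excluded + sum(!keep)
    vids <- vids[keep]
    if (!length(vids)) return(NULL)
    sub <- sub[, vids, drop = FALSE]
    n_eff <- unname(colSums(!is.na(sub) & !is.na(seed_vals)))
    r <- suppressWarnings(
      as.vector(cor(seed_vals, sub, use = "pairwise.complete.obs")))
    df <- n_eff - 2
    stat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- t_tail_p(stat, pmax(df, 1))
    p[abs(r) >= 1] <- 0
    q <- bh_fdr(p)$q
    tibble(seed = seed_region, structure = st, vertex_id = vids,
           n = as.integer(n_eff), r = r, p = p, q = q,
           passes_fdr = q < fdr_q, subthreshold = p < 0.05)
  })
  out <- list_rbind(out)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "seed") <- seed_region
  attr(out, "metric") <- metric
  attr(out, "n_subjects") <- length(subj)
  class(out) <- c("bft_covmap", class(out))
  out
}

#' Summarise a covariance map over labels
#'
#' Deterministic per-label aggregation: mean r, number of vertices, number
#' passing FDR, and the top vertices by |r|.
#'
#' @param map A [map_covariance()] result.
#' @param labels Tibble (vertex_id, label) covering all map vertices;
#'   defaults to the map's `structure` column.
#' @param top_n Top vertices reported per label (default 3).
#' @return Tibble: label, n_vertices, mean_r, n_passing, top_vertices
#'   (comma-separated), ordered by label.
#' @export
summarize_map <- function(map, labels = NULL, top_n = 3) {
  if (is.null(labels)) {
    labels <- tibble(vertex_id = map$vertex_id, label = map$structure)
  }
  if (!all(map$vertex_id %in% labels$vertex_id)) {
    bft_stop("`labels` must cover every vertex in the map.",
             "bftrans_error_invalid_argument")
  }
  joined <- left_join(as_tibble(map), labels, by = "vertex_id")
  out <- summarise(
    group_by(joined, .data$label),
    n_vertices = n(),
    mean_r = mean(.data$r),
    n_passing = sum(.data$passes_fdr),
    top_vertices = paste(.data$vertex_id[order(-abs(.data$r))][
      seq_len(min(top_n, n()))], collapse = ","),
    .groups = "drop"
  )
  arrange(out, .data$label)
}
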