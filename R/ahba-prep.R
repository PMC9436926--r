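# Expression preprocessing: probe QC and one-probe-per-gene collapsing,
# declarative sample QC, and coordinate-based assignment of expression
# samples to surface vertices.

#' Collapse probes to one per gene
#'
#' Keeps QC-passing probes only, then selects for each gene the probe with
#' the highest correlation to RNA-seq; ties break on the lowest probe id.
#' Genes whose probes all fail QC are dropped and counted.
#'
#' @param probes Probe tibble (probe_id, gene, qc_pass, rnaseq_r).
#' @param expression Probe x sample matrix with probe ids as row names.
#' @return List: `expression` (gene x sample matrix), `mapping` (tibble
#'   gene, probe_id, rnaseq_r), `dropped_genes` (character).
#' @export
select_probes <- function(probes, expression) {
  if (nrow(probes) == 0) {
    bft_stop("Empty probe table.", "bftrans_error_invalid_argument")
  }
  if (!all(probes$probe_id %in% rownames(expression))) {
    bft_stop("All probes must be present in the expression matrix.",
             "bftrans_error_invalid_argument")
  }
  passing <- filter(probes, .data$qc_pass)
  mapping <- slice(
    group_by(arrange(passing, .data$gene, -.data$rnaseq_r, .data$probe_id),
             .data$gene), 1)
  mapping <- select(ungroup(mapping), "gene", "probe_id", "rnaseq_r")
  dropped <- sort(setdiff(unique(probes$gene), mapping$gene))
  mat <- expression[mapping$probe_id, , drop = FALSE]
  rownames(mat) <- mapping$gene
  list(expression = mat, mapping = mapping, dropped_genes = dropped)
}

#' Declarative sample QC rules
#'
#' Rule constructors for [qc_samples()]: keep samples whose structure label
#' is allow-listed; require coordinates of given structures to fall in a
#' bounding region; exclude explicit sample ids.
#'
#' @param labels Allowed structure labels.
#' @return A rule object.
#' @export
rule_allowed_labels <- function(labels) {
  structure(list(type = "allowed_labels", labels = labels),
            class = "bft_qc_rule")
}

#' @rdname rule_allowed_labels
#' @param structures Structure labels the box applies to.
#' @param min,max Length-3 numeric bounds (mm).
#' @export
rule_bounding_box <- function(structures, min, max) {
  structure(list(type = "bounding_box", structures = structures,
                 min = min, max = max), class = "bft_qc_rule")
}

#' @rdname rule_allowed_labels
#' @param ids Sample ids to exclude.
#' @export
rule_exclude <- function(ids) {
  structure(list(type = "exclude", ids = ids), class = "bft_qc_rule")
}

#' Apply sample QC rules
#'
#' Applies declarative rules in order, logging removals per rule. An
#' exclusion list naming an unknown id warns rather than errors.
#'
#' @param samples Sample tibble (sample_id, structure_label, x, y, z, ...).
#' @param rules List of rule objects (see [rule_allowed_labels()]).
#' @return List: `samples` (filtered tibble), `log` (tibble rule,
#'   n_removed, removed_ids).
#' @export
qc_samples <- function(samples, rules = list()) {
  needed <- c("sample_id", "structure_label", "x", "y", "z")
  if (!all(needed %in% names(samples))) {
    bft_stop(paste("`samples` must contain columns:",
                   paste(needed, collapse = ", ")),
             "bftrans_error_invalid_argument")
  }
  log <- list()
  for (rule in rules) {
    before <- samples$sample_id
    if (rule$type == "allowed_labels") {
      samples <- filter(samples, .data$structure_label %in% rule$labels)
    } else if (rule$type == "bounding_box") {
      inside <- !(samples$structure_label %in% rule$structures) |
        (samples$x >= rule$min[1] & samples$x <= rule$max[1] &
           samples$y >= rule$min[2] & samples$y <= rule$max[2] &
           samples$z >= rule$min[3] & samples$z <= rule$max[3])
      samples <- samples[inside, , drop = FALSE]
    } else if (rule$type == "exclude") {
      unknown <- setdiff(rule$ids, samples$sample_id)
      if (length(unknown)) {
        warn(paste("Exclusion list names unknown sample ids:",
                   paste(unknown, collapse = ", ")))
      }
      samples <- filter(samples, !(.data$sample_id %in% rule$ids))
    } else {
      bft_stop(paste("Unknown rule type:", rule$type),
               "bftrans_error_invalid_argument")
    }
    removed <- setdiff(before, samples$sample_id)
    log[[length(log) + 1]] <- tibble(
      rule = rule$type, n_removed = length(removed),
      removed_ids = paste(removed, collapse = ","))
  }
  list(samples = samples,
       log = if (length(log)) list_rbind(log) else
         tibble(rule = character(), n_removed = integer(),
                removed_ids = character()))
}

#' Match expression samples to surface vertices
#'
#' Assigns each cortical sample to its nearest vertex by Euclidean
#' distance. Samples farther than `max_distance` mm are removed (by
#' default before deduplication); where several samples share a nearest
#' vertex, the closest is retained and the others are marked
#' `duplicate_vertex`. Distance ties break on lowest vertex id, then
#' lowest sample id, so matching is order-invariant.
#'
#' @param samples Cortical sample tibble (sample_id, x, y, z; a
#'   `structure_label` column, if present, is filtered to cortical labels).
#' @param vertices Vertex tibble (vertex_id, structure, x, y, z).
#' @param max_distance Distance cutoff in mm (default 10).
#' @param hemisphere `"left"` (default; cortex-L vertices only) or
#'   `"both"`.
#' @param cutoff_before_dedup Remove over-distance samples before resolving
#'   duplicates (default TRUE).
#' @return Tibble of class `bft_matches`: sample_id, vertex_id, distance,
#'   retained, removal_reason; attribute `summary` holds n_retained and
#'   distance statistics.
#' @export
match_samples_to_vertices <- function(samples, vertices, max_distance = 10,
                                      hemisphere = c("left", "both"),
                                      cutoff_before_dedup = TRUE) {
  hemisphere <- match.arg(hemisphere)
  if ("structure_label" %in% names(samples)) {
    samples <- filter(samples, startsWith(.data$structure_label, "cortex"))
    if (hemisphere == "left") {
      samples <- filter(samples, .data$structure_label == "cortex-L")
    }
  }
  keep_struct <- if (hemisphere == "left") "cortex-L" else
    c("cortex-L", "cortex-R")
  vertices <- filter(vertices, .data$structure %in% keep_struct)
  if (nrow(vertices) == 0) {
    bft_stop("Empty vertex set.", "bftrans_error_invalid_argument")
  }
  if (nrow(samples) == 0) {
    out <- tibble(sample_id = character(), vertex_id = character(),
                  distance = numeric(), retained = logical(),
                  removal_reason = character())
    class(out) <- c("bft_matches", class(out))
    return(out)
  }
  vertices <- arrange(vertices, .data$vertex_id)
  d <- cross_dist(samples[, c("x", "y", "z")],
                  vertices[, c("x", "y", "z")])
  # nearest vertex; distance ties resolved to the lowest vertex_id because
  # vertices are sorted and max.col(..., "first") takes the earliest max
  nearest <- max.col(-d, ties.method = "first")
  rec <- tibble(
    sample_id = samples$sample_id,
    vertex_id = vertices$vertex_id[nearest],
    distance = d[cbind(seq_len(nrow(d)), nearest)],
    retained = TRUE,
    removal_reason = "none"
  )
  rec <- arrange(rec, .data$sample_id)

  flag_over <- function(r) {
    over <- r$distance > max_distance & r$retained
    r$retained[over] <- FALSE
    r$removal_reason[over] <- "over_distance"
    r
  }
  dedup <- function(r) {
    live <- which(r$retained)
    ord <- live[order(r$distance[live], r$vertex_id[live],
                      r$sample_id[live])]
    dup <- ord[duplicated(r$vertex_id[ord])]
    r$retained[dup] <- FALSE
    r$removal_reason[dup] <- "duplicate_vertex"
    r
  }
  rec <- if (cutoff_before_dedup) dedup(flag_over(rec)) else
    flag_over(dedup(rec))

  kept <- rec$distance[rec$retained]
  attr(rec, "summary") <- list(
    n_samples = nrow(rec), n_retained = sum(rec$retained),
    mean_distance = mean(kept), sd_distance = sd(kept),
    range_distance = if (length(kept)) range(kept) else c(NA_real_, NA_real_)
  )
  class(rec) <- c("bft_matches", class(rec))
  rec
}
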