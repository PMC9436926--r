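# Synthetic atlas-style expression bundle: probes x samples with donor
# structure, BF-labelled samples, planted region-enriched and
# field-coupled genes, and the planted QC cases.

#' Configuration for the synthetic expression bundle
#'
#' Emulates a six-donor microarray atlas: left-hemisphere cortical samples
#' from all donors, right-hemisphere cortical samples from only two donors,
#' and basal-forebrain samples from four donors (9 NBM and 9 Ch1-3, one of
#' which is planted as misplaced so that 8 Ch1-3 remain after QC). Two
#' right-hemisphere cortical samples are displaced more than 10 mm from any
#' vertex (the distance-cutoff QC case). Expression is on a log2 intensity
#' scale with additive per-donor, per-gene random intercepts.
#'
#' Planted signal: `n_bf_genes` genes are elevated by `bf_effect` total-SD
#' units in BF-labelled samples (the cholinergic marker genes CHAT, ACHE,
#' CHRM2 and CHRNA3 are among them); `n_field_genes` genes track the
#' projection field across cortical sample positions (half positively,
#' including CHRNA3, half negatively, including CHRNA2). Effects are scaled
#' by each gene's total expression SD (donor + residual variance).
#'
#' @param n_genes Number of genes (default 2000).
#' @param frac_two_probe Fraction of genes carrying two probes.
#' @param frac_qc_fail Per-probe probability of failing QC.
#' @param donor_sd SD of per-donor, per-gene intercepts (log2 units).
#' @param resid_sd_range Range of per-gene residual SDs (log2 units).
#' @param bf_effect Planted BF enrichment in total-SD units.
#' @param n_bf_genes,n_field_genes Numbers of planted genes.
#' @param field_coupling Slope of field-coupled genes, in total-SD units per
#'   unit of normalised field.
#' @param n_cortical_left,n_cortical_right Cortical sample counts.
#' @param n_displaced_right Right-hemisphere samples displaced > 10 mm.
#' @param nbm_counts,ch13_counts BF samples per contributing donor.
#' @return A list of class `bft_expression_config`.
#' @export
expression_config <- function(n_genes = 2000,
                              frac_two_probe = 0.15,
                              frac_qc_fail = 0.08,
                              donor_sd = 0.3,
                              resid_sd_range = c(0.2, 0.45),
                              bf_effect = 1.0,
                              n_bf_genes = 30,
                              n_field_genes = 30,
                              field_coupling = 1.0,
                              n_cortical_left = 120,
                              n_cortical_right = 30,
                              n_displaced_right = 2,
                              nbm_counts = c(2, 2, 2, 3),
                              ch13_counts = c(2, 2, 2, 3)) {
  cfg <- as.list(environment())
  cfg$donors <- paste0("D", 1:6)
  cfg$bf_donors <- paste0("D", 1:4)
  cfg$right_donors <- paste0("D", 1:2)
  class(cfg) <- "bft_expression_config"
  cfg
}

#' Bounding box of plausible basal-forebrain coordinates
#'
#' The coordinate region (mm, MNI-like frame) in which NBM / Ch1-3 samples
#' are expected to fall; used by the sample-QC stage to catch misplaced or
#' mislabelled BF samples.
#'
#' @return List with `min` and `max` length-3 numeric vectors.
#' @export
bf_bounding_box <- function() {
  list(min = c(-20, -15, -25), max = c(20, 20, 5))
}

#' Generate a synthetic expression bundle
#'
#' @param surface A [simulate_surface()] result (sample coordinates are
#'   drawn near its cortical vertices; field-coupled genes read the planted
#'   projection field).
#' @param config An [expression_config()].
#' @param seed Integer seed.
#' @return List of class `bft_expression`: `expression` (probe x sample
#'   log2 matrix), `probes` (tibble: probe_id, gene, qc_pass, rnaseq_r),
#'   `samples` (tibble: sample_id, donor_id, structure_label, hemisphere,
#'   x, y, z), `truth` (planted genes, QC cases, donor effects).
#' @export
simulate_expression <- function(surface, config = expression_config(),
                                seed = 1L) {
  if (!inherits(surface, "bft_surface")) {
    bft_stop("`surface` must come from simulate_surface().",
             "bftrans_error_invalid_argument")
  }
  if (length(config$donors) < 2) {
    bft_stop("Need at least 2 donors.", "bftrans_error_invalid_argument")
  }
  set.seed(seed)
  ng <- config$n_genes

  named <- c("CHAT", "ACHE", "CHRM2", "CHRNA3", "CHRNA2")
  genes <- c(named, sprintf("G%04d", seq_len(ng - length(named))))
  bf_genes <- c("CHAT", "ACHE", "CHRM2", "CHRNA3",
                sample(setdiff(genes, named), config$n_bf_genes - 4))
  pool <- setdiff(genes, c(bf_genes, "CHRNA2"))
  half <- config$n_field_genes %/% 2
  field_pos <- c("CHRNA3", sample(pool, half - 1))
  field_neg <- c("CHRNA2", sample(setdiff(pool, field_pos), half - 1))

  # probes
  two <- runif(ng) < config$frac_two_probe
  probes <- tibble(
    gene = rep(genes, times = 1 + two),
    probe_id = NA_character_,
    qc_pass = runif(sum(1 + two)) > config$frac_qc_fail,
    rnaseq_r = round(runif(sum(1 + two), -0.2, 0.95), 4)
  )
  probes$probe_id <- sprintf("P%05d", seq_len(nrow(probes)))
  probes <- select(probes, "probe_id", "gene", "qc_pass", "rnaseq_r")

  # samples
  vtx <- surface$vertices
  coords <- as.matrix(vtx[, c("x", "y", "z")])
  draw_cortical <- function(n, hemi, donors) {
    idx <- sample(which(vtx$structure == paste0("cortex-", hemi)), n,
                  replace = n > sum(vtx$structure == paste0("cortex-", hemi)))
    tibble(donor_id = sample(rep(donors, length.out = n)),
           structure_label = paste0("cortex-", hemi),
           hemisphere = hemi,
           x = coords[idx, 1] + rnorm(n, 0, 1.5),
           y = coords[idx, 2] + rnorm(n, 0, 1.5),
           z = coords[idx, 3] + rnorm(n, 0, 1.5),
           near_vertex = vtx$vertex_id[idx])
  }
  left <- draw_cortical(config$n_cortical_left, "L", config$donors)
  right <- draw_cortical(config$n_cortical_right, "R", config$right_donors)
  # displaced right-hemisphere samples: pushed 30 mm radially outward from
  # the surface so no part of the curved sheet can fall within the cutoff
  disp <- draw_cortical(config$n_displaced_right, "R", config$right_donors)
  nrm <- sqrt(disp$x^2 + disp$y^2 + disp$z^2)
  scl <- (nrm + 30) / nrm
  disp$x <- disp$x * scl; disp$y <- disp$y * scl; disp$z <- disp$z * scl

  draw_bf <- function(counts, label) {
    n <- sum(counts)
    side <- sample(c(-1, 1), n, replace = TRUE)
    tibble(donor_id = rep(config$bf_donors, counts),
           structure_label = label, hemisphere = ifelse(side < 0, "L", "R"),
           x = side * 4 + rnorm(n, 0, 2),
           y = 3 + rnorm(n, 0, 2),
           z = -9 + rnorm(n, 0, 2),
           near_vertex = NA_character_)
  }
  nbm <- draw_bf(config$nbm_counts, "NBM")
  ch13 <- draw_bf(config$ch13_counts, "Ch1-3")
  # plant the misplaced/mislabelled Ch1-3 sample far from the BF
  mis <- nrow(ch13)
  ch13$x[mis] <- 50; ch13$y[mis] <- -70; ch13$z[mis] <- 40

  samples <- bind_rows(left, right, disp, nbm, ch13)
  samples <- mutate(samples,
                    sample_id = sprintf("A%04d", row_number()),
                    .before = 1)
  misplaced_id <- samples$sample_id[samples$structure_label == "Ch1-3" &
                                      samples$x > 40]
  displaced_ids <- samples$sample_id[seq(config$n_cortical_left +
                                           config$n_cortical_right + 1,
                                         length.out = config$n_displaced_right)]

  # expression: gene-level signal, then probe-level offsets
  ns <- nrow(samples)
  base <- rnorm(ng, 7, 1.5)
  resid_sd <- runif(ng, config$resid_sd_range[1], config$resid_sd_range[2])
  total_sd <- sqrt(resid_sd^2 + config$donor_sd^2)
  donor_int <- matrix(rnorm(ng * length(config$donors), 0, config$donor_sd),
                      ng, dimnames = list(genes, config$donors))

  gene_expr <- base +
    donor_int[, samples$donor_id] +
    matrix(rnorm(ng * ns, 0, resid_sd), ng, ns)

  is_bf <- samples$structure_label %in% c("NBM", "Ch1-3")
  gene_expr[bf_genes, is_bf] <- gene_expr[bf_genes, is_bf] +
    config$bf_effect * total_sd[match(bf_genes, genes)]

  fmax <- max(abs(surface$truth$field))
  field_z <- rep(0, ns)
  cortical <- !is.na(samples$near_vertex)
  field_z[cortical] <-
    surface$truth$field[samples$near_vertex[cortical]] / fmax
  for (g in field_pos) {
    gene_expr[g, ] <- gene_expr[g, ] +
      config$field_coupling * total_sd[match(g, genes)] * field_z
  }
  for (g in field_neg) {
    gene_expr[g, ] <- gene_expr[g, ] -
      config$field_coupling * total_sd[match(g, genes)] * field_z
  }

  probe_offset <- rnorm(nrow(probes), 0, 0.2)
  expression <- gene_expr[probes$gene, , drop = FALSE] + probe_offset +
    matrix(rnorm(nrow(probes) * ns, 0, 0.1), nrow(probes), ns)
  dimnames(expression) <- list(probes$probe_id, samples$sample_id)

  truth <- list(
    seed = seed,
    bf_genes = bf_genes,
    field_genes_positive = field_pos,
    field_genes_negative = field_neg,
    misplaced_sample = misplaced_id,
    displaced_samples = displaced_ids,
    donor_sd = config$donor_sd,
    bf_effect = config$bf_effect,
    field_coupling = config$field_coupling
  )
  structure(list(expression = expression,
                 probes = probes,
                 samples = select(samples, -"near_vertex"),
                 truth = truth),
            class = "bft_expression")
}

#' @export
print.bft_expression <- function(x, ...) {
  cat(sprintf("<bft_expression> %d probes x %d samples, %d donors\n",
              nrow(x$expression), ncol(x$expression),
              length(unique(x$samples$donor_id))))
  invisible(x)
}

#' Simulate cell-type mean expression profiles
#'
#' A gene x cell-type matrix of mean expression used to build pSI marker
#' sets: marker genes are boosted in their own cell type. The planted
#' BF-enriched genes act as the cholinergic-neuron markers so that CSEA of
#' a recovered BF gene list should flag cholinergic neurons.
#'
#' @param genes Character vector of gene identifiers.
#' @param marker_sets Named list of marker gene vectors; defaults to a
#'   cholinergic set you supply plus random disjoint sets.
#' @param cholinergic_markers Genes to use as cholinergic-neuron markers.
#' @param n_other_types Number of additional cell types.
#' @param markers_per_type Markers per additional type.
#' @param boost Marker over-expression in log2 units (default 2.5).
#' @param seed Integer seed.
#' @return Gene x cell-type numeric matrix.
#' @export
simulate_cell_profiles <- function(genes, cholinergic_markers,
                                   marker_sets = NULL,
                                   n_other_types = 7,
                                   markers_per_type = 30,
                                   boost = 2.5, seed = 1L) {
  set.seed(seed)
  if (is.null(marker_sets)) {
    others <- setdiff(genes, cholinergic_markers)
    types <- c("cortical_neurons", "interneurons", "astrocytes",
               "oligodendrocytes", "microglia", "endothelial",
               "ependymal")[seq_len(n_other_types)]
    marker_sets <- list(cholinergic_neurons = cholinergic_markers)
    for (ty in types) {
      marker_sets[[ty]] <- sample(others, markers_per_type)
      others <- setdiff(others, marker_sets[[ty]])
    }
  }
  mat <- matrix(rnorm(length(genes) * length(marker_sets), 5, 0.7),
                length(genes),
                dimnames = list(genes, names(marker_sets)))
  for (ty in names(marker_sets)) {
    mk <- intersect(marker_sets[[ty]], genes)
    mat[mk, ty] <- mat[mk, ty] + boost
  }
  mat
}

#' Simulate disease gene-set collections
#'
#' Builds GMT-style named gene sets over the synthetic gene universe,
#' including a schizophrenia set that overlaps the planted BF-enriched genes
#' (so hypergeometric enrichment of a recovered BF list is positive) and
#' unrelated control sets.
#'
#' @param genes Gene universe.
#' @param bf_genes Planted BF-enriched genes.
#' @param overlap_fraction Fraction of `bf_genes` seeded into the
#'   schizophrenia set (default 0.7).
#' @param seed Integer seed.
#' @return Named list of gene sets.
#' @export
simulate_gene_sets <- function(genes, bf_genes, overlap_fraction = 0.7,
                               seed = 1L) {
  set.seed(seed)
  n <- length(genes)
  # set sizes scale with the universe (roughly the share a curated disease
  # collection occupies of the measured genome)
  size <- function(frac) max(20, round(frac * n))
  scz_core <- sample(bf_genes, round(overlap_fraction * length(bf_genes)))
  rest <- setdiff(genes, bf_genes)
  sets <- list(
    schizophrenia = c(scz_core,
                      sample(rest, max(0, size(0.08) - length(scz_core)))),
    major_depression = c(sample(bf_genes, min(6, length(bf_genes))),
                         sample(rest, size(0.06))),
    bipolar_disorder = sample(rest, size(0.05)),
    alzheimer_disease = sample(rest, size(0.07)),
    epilepsy = sample(rest, size(0.04)),
    hypertension = sample(rest, size(0.06))
  )
  lapply(sets, function(s) sort(unique(s)))
}
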