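# Synthetic cortical / subcortical surface qT1 with a planted projection
# field that drives basal-forebrain structural covariance.

#' Configuration for the synthetic surface dataset
#'
#' The surface emulates per-subject vertex-wise qT1 sampled on two cortical
#' hemispheres plus labelled subcortical structures, in one mm coordinate
#' frame shared with the expression bundle. A latent "projection field" over
#' vertices (positive frontal lobe, negative occipital lobe, strong positive
#' hippocampus weight) scales each subject's basal-forebrain latent, so that
#' seed-based covariance mapping can recover the field's sign pattern.
#'
#' @param n_vertices_per_hemi Cortical vertices per hemisphere (default 2000).
#' @param n_subcortical Vertices per subcortical structure (default 60).
#' @param field_seed,field_metric ROI region/metric whose per-subject values
#'   act as the basal-forebrain latent (default left NBM qT1).
#' @param field_amplitude Peak field strength in ms per latent SD (default 30).
#' @param smooth_sd,iid_sd Spatially smooth and white noise SDs in ms.
#' @param n_basis Number of Gaussian bumps used for the smooth noise field.
#' @param bandwidth Spatial kernel bandwidth in mm for field and noise.
#' @return A list of class `bft_surface_config`.
#' @export
surface_config <- function(n_vertices_per_hemi = 2000,
                           n_subcortical = 60,
                           field_seed = "nbm_l",
                           field_metric = "qt1",
                           field_amplitude = 30,
                           smooth_sd = 35,
                           iid_sd = 15,
                           n_basis = 60,
                           bandwidth = 25) {
  cfg <- as.list(environment())
  cfg$subcortical_structures <- c("hippocampus", "amygdala", "striatum",
                                  "thalamus", "globus_pallidum")
  class(cfg) <- "bft_surface_config"
  cfg
}

subcortical_centers <- function() {
  list(hippocampus = c(28, -20, -15),
       amygdala = c(24, -5, -20),
       striatum = c(25, 5, 0),
       thalamus = c(12, -18, 8),
       globus_pallidum = c(20, 0, 0))
}

# Field profile: sum of signed Gaussian bumps, mirrored across hemispheres.
projection_field <- function(coords, hemisphere, structure, cfg) {
  f <- numeric(nrow(coords))
  h <- cfg$bandwidth
  for (s in c(-1, 1)) {
    frontal <- c(35 * s, 60, 25)
    occipital <- c(35 * s, -75, 0)
    d_f <- sqrt(rowSums(sweep(coords, 2, frontal)^2))
    d_o <- sqrt(rowSums(sweep(coords, 2, occipital)^2))
    f <- f + exp(-d_f^2 / (2 * h^2)) - exp(-d_o^2 / (2 * h^2))
  }
  is_cortex <- startsWith(structure, "cortex")
  # subcortical structures carry a flat projection weight rather than the
  # cortical lobe profile: strong for hippocampus (CA1/subiculum-like
  # cholinergic input), weak elsewhere
  f[!is_cortex] <- ifelse(structure[!is_cortex] == "hippocampus", 0.5, 0.05)
  cfg$field_amplitude * f
}

#' Generate synthetic surface qT1 data
#'
#' Per-vertex qT1 for every cohort subject:
#' `qT1[i, v] = mean + subject_offset[i] + field[v] * latent[i] + smooth
#' noise + white noise`, with the latent taken from the configured seed ROI
#' (z-scored across subjects). Deterministic under a fixed seed.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config A [surface_config()].
#' @param seed Integer seed.
#' @return List of class `bft_surface`: `vertices` (tibble: vertex_id,
#'   hemisphere, structure, x, y, z), `qt1` (subject x vertex matrix),
#'   `truth` (field per vertex and generator parameters).
#' @export
simulate_surface <- function(cohort, config = surface_config(), seed = 1L) {
  if (!inherits(cohort, "bft_cohort")) {
    bft_stop("`cohort` must come from simulate_cohort().",
             "bftrans_error_invalid_argument")
  }
  if (config$n_vertices_per_hemi < 10) {
    bft_stop("Need at least 10 vertices per hemisphere.",
             "bftrans_error_invalid_argument")
  }
  set.seed(seed)
  nv <- config$n_vertices_per_hemi

  cortex <- list()
  for (hemi in c("L", "R")) {
    u <- matrix(rnorm(nv * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    xyz <- sweep(abs(u) * 0 + u, 2, c(60, 85, 70), `*`)
    xyz[, 1] <- (if (hemi == "L") -1 else 1) * (abs(xyz[, 1]) + 5)
    cortex[[hemi]] <- tibble(
      hemisphere = hemi, structure = paste0("cortex-", hemi),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  sub <- imap(subcortical_centers(), function(ctr, nm) {
    k <- config$n_subcortical
    side <- rep(c(-1, 1), length.out = k)
    tibble(hemisphere = ifelse(side < 0, "L", "R"), structure = nm,
           x = side * ctr[1] + rnorm(k, 0, 4),
           y = ctr[2] + rnorm(k, 0, 4),
           z = ctr[3] + rnorm(k, 0, 4))
  })
  vertices <- bind_rows(c(cortex, sub))
  vertices <- mutate(vertices,
                     vertex_id = sprintf("V%05d", row_number()),
                     .before = 1)

  coords <- as.matrix(vertices[, c("x", "y", "z")])
  field <- projection_field(coords, vertices$hemisphere,
                            vertices$structure, config)

  subj <- cohort$subjects$subject_id
  n <- length(subj)
  seed_vals <- cohort$roi$value[cohort$roi$region == config$field_seed &
                                  cohort$roi$metric == config$field_metric]
  latent <- zscore(seed_vals)

  # smooth noise through a random Gaussian basis
  centers <- coords[sample.int(nrow(coords), config$n_basis), , drop = FALSE]
  phi <- exp(-cross_dist(coords, centers)^2 / (2 * config$bandwidth^2))
  phi <- phi / sqrt(rowSums(phi^2) + 1e-12)
  noise_smooth <- matrix(rnorm(n * config$n_basis), n) %*% t(phi) *
    config$smooth_sd

  qt1 <- 1500 +
    matrix(rnorm(n, 0, 40), n, nrow(vertices)) +
    outer(latent, field) +
    noise_smooth +
    matrix(rnorm(n * nrow(vertices), 0, config$iid_sd), n)
  dimnames(qt1) <- list(subj, vertices$vertex_id)

  truth <- list(
    seed = seed,
    field = setNames(field, vertices$vertex_id),
    field_support = vertices$vertex_id[abs(field) >
                                         0.5 * max(abs(field))],
    field_seed = config$field_seed,
    field_metric = config$field_metric,
    field_amplitude = config$field_amplitude
  )
  structure(list(vertices = vertices, qt1 = qt1, truth = truth),
            class = "bft_surface")
}

#' @export
print.bft_surface <- function(x, ...) {
  cat(sprintf("<bft_surface> %d vertices (%d cortical), %d subjects\n",
              nrow(x$vertices),
              sum(startsWith(x$vertices$structure, "cortex")),
              nrow(x$qt1)))
  invisible(x)
}
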