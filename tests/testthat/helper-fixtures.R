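# Shared fixtures and independent oracles used across test files.
# Everything is generated in code; fixtures are cached per session so the
# expensive generators run once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default-size cohort (the study design: 56 FEP / 29 HC)
fix_cohort <- function(seed = 42) {
  cached(paste0("cohort_", seed), function() simulate_cohort(seed = seed))
}

# small surface + expression bundle for structural tests
fix_bundle <- function(seed = 42) {
  cached(paste0("bundle_", seed), function() {
    cohort <- fix_cohort(seed)
    surface <- simulate_surface(
      cohort, surface_config(n_vertices_per_hemi = 250, n_subcortical = 25),
      seed = seed + 1)
    bundle <- simulate_expression(
      surface, expression_config(n_genes = 400, n_cortical_left = 90),
      seed = seed + 2)
    list(cohort = cohort, surface = surface, bundle = bundle)
  })
}

fix_qc_samples <- function(bundle) {
  box <- bftrans::bf_bounding_box()
  qc_samples(bundle$samples, list(
    rule_allowed_labels(c("cortex-L", "cortex-R", "NBM", "Ch1-3")),
    rule_bounding_box(c("NBM", "Ch1-3"), box$min, box$max)))$samples
}

# --- independent oracles ----------------------------------------------------

# brute-force least squares via the normal equations
oracle_ols <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# permutation p-value for a Pearson correlation
oracle_perm_p <- function(x, y, n_perm = 20000) {
  r_obs <- abs(cor(x, y))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(cor(x, sample(y))) >= r_obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# all-pairs nearest-vertex matching with cutoff-then-dedup
oracle_match <- function(samples, vertices, max_distance = 10) {
  d <- as.matrix(dist(rbind(as.matrix(samples[, c("x", "y", "z")]),
                            as.matrix(vertices[, c("x", "y", "z")]))))
  d <- d[seq_len(nrow(samples)), nrow(samples) + seq_len(nrow(vertices)),
         drop = FALSE]
  res <- data.frame(sample_id = samples$sample_id,
                    vertex_id = NA_character_, distance = NA_real_,
                    retained = TRUE, reason = "none",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(samples))) {
    ranked <- order(d[i, ], vertices$vertex_id)
    res$vertex_id[i] <- vertices$vertex_id[ranked[1]]
    res$distance[i] <- d[i, ranked[1]]
  }
  over <- res$distance > max_distance
  res$retained[over] <- FALSE
  res$reason[over] <- "over_distance"
  for (v in unique(res$vertex_id[res$retained])) {
    idx <- which(res$retained & res$vertex_id == v)
    if (length(idx) > 1) {
      keep <- idx[order(res$distance[idx], res$sample_id[idx])][1]
      drop <- setdiff(idx, keep)
      res$retained[drop] <- FALSE
      res$reason[drop] <- "duplicate_vertex"
    }
  }
  res[order(res$sample_id), ]
}

# hypergeometric upper tail by explicit enumeration
oracle_hyper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# profiled REML criterion evaluated by explicit dense matrix algebra
oracle_reml_crit <- function(y, x, donor, lambda) {
  X <- cbind(1, x)
  Z <- stats::model.matrix(~ 0 + factor(donor))
  V <- diag(length(y)) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Vi %*% r)
  (length(y) - 2) * log(rss) + determinant(V)$modulus[1] +
    determinant(A)$modulus[1]
}

oracle_reml_grid <- function(y, x, donor, grid = seq(0, 5, by = 1e-3)) {
  crit <- vapply(grid, function(l) oracle_reml_crit(y, x, donor, l),
                 numeric(1))
  grid[which.min(crit)]
}

# random-intercept data generator for mixed-model tests
make_mixed_data <- function(n_donor = 6, n_per = 20, slope = 0.3,
                            donor_sd = 0.2, resid_sd = 0.3, seed = 1) {
  set.seed(seed)
  donor <- rep(paste0("D", seq_len(n_donor)), each = n_per)
  x <- rnorm(n_donor * n_per)
  u <- rnorm(n_donor, 0, donor_sd)
  y <- 0.1 + slope * x + u[as.integer(factor(donor))] +
    rnorm(n_donor * n_per, 0, resid_sd)
  list(y = y, x = x, donor = donor)
}

# wrap raw vectors as a bft_txdesign for fit_mixed_per_gene
as_design <- function(y, x, donor, gene = "g1") {
  expr <- matrix(x, 1, dimnames = list(gene, paste0("s", seq_along(x))))
  structure(list(
    data = tibble::tibble(sample_id = colnames(expr),
                          vertex_id = paste0("v", seq_along(x)),
                          donor_id = donor, r = y),
    expression = expr, n_dropped = 0L), class = "bft_txdesign")
}
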