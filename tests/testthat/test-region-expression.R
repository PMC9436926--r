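# Per-gene donor+region models, empirical-Bayes moderation, moderated t.

make_region_fixture <- function(n_genes = 60, seed = 31, effect = 0,
                                donor_sd = 0.3) {
  set.seed(seed)
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    donor_id = rep(c("D1", "D2", "D3"), each = 4),
    structure_label = rep(c("Ch1-3", "NBM", "cortex-L", "cortex-L"), 3))
  genes <- sprintf("g%03d", seq_len(n_genes))
  dint <- matrix(rnorm(n_genes * 3, 0, donor_sd), n_genes)
  expr <- 5 + dint[, rep(1:3, each = 4)] +
    matrix(rnorm(n_genes * 12, 0, 0.3), n_genes) +
    effect * outer(rep(1, n_genes), samples$structure_label == "Ch1-3")
  dimnames(expr) <- list(genes, samples$sample_id)
  list(expression = expr, samples = samples)
}

test_that("fit_gene_models matches a brute-force per-gene lm solve", {
  fx <- make_region_fixture()
  fits <- fit_gene_models(fx$expression, fx$samples, "Ch1-3")
  for (g in c("g001", "g025", "g060")) {
    dat <- data.frame(y = fx$expression[g, ],
                      donor = fx$samples$donor_id,
                      target = fx$samples$structure_label == "Ch1-3")
    ref <- lm(y ~ donor + target, data = dat)
    i <- which(fits$gene == g)
    expect_equal(fits$beta[i], unname(coef(ref)["targetTRUE"]),
                 tolerance = 1e-10)
    expect_equal(fits$s_g_sq[i], summary(ref)$sigma^2, tolerance = 1e-10)
    expect_equal(fits$d_g[i], ref$df.residual)
  }
})

test_that("planted shift with no noise is recovered exactly", {
  fx <- make_region_fixture()
  expr <- fx$expression * 0 + 5 +
    outer(rep(1, nrow(fx$expression)),
          as.numeric(fx$samples$structure_label == "Ch1-3"))
  dimnames(expr) <- dimnames(fx$expression)
  fits <- fit_gene_models(expr, fx$samples, "Ch1-3")
  expect_true(all(abs(fits$beta - 1) < 1e-10))
  expect_true(all(fits$degenerate))
})

test_that("donor restriction keeps only donors sampling both BF regions", {
  fx <- make_region_fixture()
  samples <- fx$samples
  samples$structure_label[samples$donor_id == "D3" &
                            samples$structure_label == "NBM"] <- "cortex-L"
  fits <- fit_gene_models(fx$expression, samples, "Ch1-3")
  expect_setequal(attr(fits, "design")$donors, c("D1", "D2"))
})

test_that("moderation hyperparameters are recovered from a scaled chi-square", {
  set.seed(32)
  d0 <- 4; s0 <- 0.05; dg <- 8
  # s^2 ~ s0 * F-like draw: residual chi-square over dg scaled by the
  # gene-wise inverse-chi-square prior variance
  reps <- vapply(1:5, function(i) {
    sg2 <- s0 * (d0 / rchisq(5000, d0)) * (rchisq(5000, dg) / dg)
    h <- estimate_moderation(sg2, dg)
    c(h$d0, h$s0_sq)
  }, numeric(2))
  expect_lt(abs(mean(reps[1, ]) - d0) / d0, 0.25)
  expect_lt(abs(mean(reps[2, ]) - s0) / s0, 0.10)
})

test_that("identical variances give an infinite-d0 prior", {
  h <- estimate_moderation(rep(0.2, 100), 8)
  expect_equal(h$d0, Inf)
  expect_equal(h$s0_sq, 0.2)
  expect_error(estimate_moderation(c(0.1, 0.2), 8),
               class = "bftrans_error_insufficient_data")
})

test_that("moderation matches limma's fitFDist/squeezeVar exactly", {
  fx <- make_region_fixture(n_genes = 200, seed = 33)
  fits <- fit_gene_models(fx$expression, fx$samples, "Ch1-3")
  h <- estimate_moderation(fits$s_g_sq, fits$d_g)
  ref <- limma::fitFDist(fits$s_g_sq, fits$d_g[1])
  expect_equal(h$d0, ref$df2, tolerance = 1e-8)
  expect_equal(h$s0_sq, ref$scale, tolerance = 1e-8)
  st <- moderated_t(fits, h)
  sq <- limma::squeezeVar(fits$s_g_sq, fits$d_g[1])
  expect_equal(st$s_post_sq, sq$var.post, tolerance = 1e-8)
})

test_that("moderated t interpolates between raw and prior t", {
  fx <- make_region_fixture(n_genes = 100, seed = 34, effect = 0.3)
  fits <- fit_gene_models(fx$expression, fx$samples, "Ch1-3")
  h <- estimate_moderation(fits$s_g_sq, fits$d_g)
  st <- moderated_t(fits, h)
  t_raw <- fits$beta / sqrt(fits$s_g_sq * fits$v_g)
  t_prior <- fits$beta / sqrt(h$s0_sq * fits$v_g)
  lo <- pmin(t_raw, t_prior); hi <- pmax(t_raw, t_prior)
  expect_true(all(st$t_mod >= lo - 1e-10 & st$t_mod <= hi + 1e-10))
  # s_post between s_g and s0
  expect_true(all(st$s_post_sq >= pmin(fits$s_g_sq, h$s0_sq) - 1e-12))
  expect_true(all(st$s_post_sq <= pmax(fits$s_g_sq, h$s0_sq) + 1e-12))
})

test_that("d0 limits: 0 recovers the ordinary t, Inf pools variances", {
  fx <- make_region_fixture(n_genes = 80, seed = 35, effect = 0.2)
  fits <- fit_gene_models(fx$expression, fx$samples, "Ch1-3")
  st0 <- moderated_t(fits, structure(list(d0 = 1e-12, s0_sq = 1),
                                     class = "bft_moderation"))
  t_raw <- fits$beta / sqrt(fits$s_g_sq * fits$v_g)
  expect_equal(st0$t_mod, t_raw, tolerance = 1e-5)
  stI <- moderated_t(fits, structure(list(d0 = Inf, s0_sq = 0.09),
                                     class = "bft_moderation"))
  expect_true(all(abs(stI$s_post_sq - 0.09) < 1e-12))
})

test_that("rank_score ordering matches signed-p ordering", {
  fx <- make_region_fixture(n_genes = 120, seed = 36, effect = 0.25)
  st <- moderated_t(fit_gene_models(fx$expression, fx$samples, "Ch1-3"))
  ord_rank <- order(-st$rank_score)
  ord_signed <- order(-sign(st$t_mod), ifelse(st$t_mod > 0, st$p, -st$p))
  expect_equal(st$gene[ord_rank], st$gene[ord_signed])
})

test_that("null and planted-signal FDR behaviour on the full generator", {
  fx <- fix_bundle()
  qc <- fix_qc_samples(fx$bundle)
  sel <- select_probes(fx$bundle$probes, fx$bundle$expression)
  st <- region_expression_analysis(sel$expression, qc,
                                   c("Ch1-3", "NBM"))
  bf <- intersect(fx$bundle$truth$bf_genes, st$gene)
  hit <- mean(bf %in% attr(st, "fdr_lists")$fdr_0.1)
  expect_gte(hit, 0.8)
  # false positives among non-planted genes stay near the FDR level
  fp <- setdiff(attr(st, "fdr_lists")$fdr_0.1, fx$bundle$truth$bf_genes)
  expect_lte(length(fp), 0.2 * length(attr(st, "fdr_lists")$fdr_0.1) + 3)
})
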