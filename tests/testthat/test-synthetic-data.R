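# The synthetic-data generator: determinism, planted structure, and null
# calibration.

test_that("cohort generation is deterministic and structurally correct", {
  a <- simulate_cohort(seed = 11)
  b <- simulate_cohort(seed = 11)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$roi, b$roi)
  expect_false(identical(a$subjects, simulate_cohort(seed = 12)$subjects))

  s <- a$subjects
  expect_equal(sum(s$group == "FEP"), 56)
  expect_equal(sum(s$group == "HC"), 29)
  expect_true(all(is.na(s$ymrs[s$group == "HC"])))
  expect_true(all(!is.na(s$ymrs[s$group == "FEP"])))
  expect_true(all(s$choline_crlb > 0))
  expect_false(any(s$smoking[s$group == "HC"]))
  expect_true(all(a$roi$value > 0))
  expect_equal(nrow(a$roi), 85 * 3 * 3)
  expect_error(simulate_cohort(cohort_config(n_fep = 2)),
               class = "bftrans_error_invalid_argument")
})

test_that("qT1 and AxD are co-perturbed by the shared latent", {
  co <- fix_cohort()
  w <- tidyr::pivot_wider(co$roi, names_from = c("region", "metric"),
                          values_from = "value")
  expect_gt(cor(w$ch13_qt1, w$ch13_axd), 0.2)
  expect_gt(cor(w$nbm_l_qt1, w$nbm_l_rd), 0.2)
})

test_that("null cohort is calibrated: group rejection near alpha", {
  null_cfg <- cohort_config(effect_qt1_ch13 = 0, effect_axd_ch13 = 0,
                            effect_rd_ch13 = 0)
  rej <- vapply(1:300, function(s) {
    co <- simulate_cohort(null_cfg, seed = 6000 + s)
    v <- co$roi$value[co$roi$region == "ch13" & co$roi$metric == "qt1"]
    g <- co$subjects$group
    t.test(v[g == "FEP"], v[g == "HC"], var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("planted HC coupling is recovered; FEP stays decoupled", {
  # at planted R = -0.5 and n = 29 the exact power of the correlation test
  # is ~0.82, so the >= 0.8 recovery claim is tested with a Monte-Carlo
  # allowance of 2 binomial standard errors
  hits_hc <- 0; nulls_fep <- 0; n_rep <- 100
  for (s in seq_len(n_rep)) {
    co <- simulate_cohort(seed = 3000 + s)
    qt1 <- co$roi$value[co$roi$region == "nbm_l" & co$roi$metric == "qt1"]
    hc <- co$subjects$group == "HC"
    r_hc <- pearson_r_test(qt1[hc], co$subjects$choline[hc])
    r_fep <- pearson_r_test(qt1[!hc], co$subjects$choline[!hc])
    if (r_hc$estimate < 0 && r_hc$p < 0.05) hits_hc <- hits_hc + 1
    if (r_fep$p > 0.05) nulls_fep <- nulls_fep + 1
  }
  mc_slack <- 2 * sqrt(0.8 * 0.2 / n_rep)
  expect_gte(hits_hc / n_rep, 0.8 - mc_slack)
  expect_gte(nulls_fep / n_rep, 0.8 - mc_slack)
})

test_that("surface generation is deterministic with a planted field", {
  co <- fix_cohort()
  cfg <- surface_config(n_vertices_per_hemi = 150, n_subcortical = 20)
  a <- simulate_surface(co, cfg, seed = 5)
  b <- simulate_surface(co, cfg, seed = 5)
  expect_identical(a$qt1, b$qt1)
  expect_identical(a$vertices, b$vertices)
  expect_equal(nrow(a$vertices), 2 * 150 + 5 * 20)
  expect_setequal(unique(a$vertices$structure),
                  c("cortex-L", "cortex-R", "hippocampus", "amygdala",
                    "striatum", "thalamus", "globus_pallidum"))
  expect_error(simulate_surface(co, surface_config(n_vertices_per_hemi = 5)),
               class = "bftrans_error_invalid_argument")
})

test_that("field support carries stronger seed correlations than elsewhere", {
  fx <- fix_bundle()
  m <- map_covariance(fx$surface, fx$cohort$roi, "nbm_l")
  sup <- fx$surface$truth$field_support
  r_in <- abs(m$r[m$vertex_id %in% sup])
  r_out <- abs(m$r[!(m$vertex_id %in% sup) &
                     startsWith(m$structure, "cortex")])
  expect_gt(mean(r_in), mean(r_out) + 0.1)
})

test_that("null field yields FDR-calibrated covariance maps", {
  co <- fix_cohort()
  cfg <- surface_config(n_vertices_per_hemi = 200, n_subcortical = 15,
                        field_amplitude = 0)
  frac <- vapply(1:20, function(s) {
    su <- simulate_surface(co, cfg, seed = 8000 + s)
    m <- map_covariance(su, co$roi, "nbm_l", structures = "cortex-L")
    mean(m$passes_fdr)
  }, numeric(1))
  expect_lte(mean(frac), 0.10)
})

test_that("expression bundle has the atlas sampling structure", {
  fx <- fix_bundle()
  bu <- fx$bundle
  samp <- bu$samples
  expect_equal(length(unique(samp$donor_id)), 6)
  bf <- samp[samp$structure_label %in% c("NBM", "Ch1-3"), ]
  expect_setequal(unique(bf$donor_id), paste0("D", 1:4))
  expect_equal(sum(bf$structure_label == "NBM"), 9)
  expect_equal(sum(bf$structure_label == "Ch1-3"), 9)
  rh <- samp[samp$structure_label == "cortex-R", ]
  expect_setequal(unique(rh$donor_id), paste0("D", 1:2))
  expect_true(all(table(bu$probes$gene) >= 1))
  # deterministic
  again <- simulate_expression(
    fx$surface, expression_config(n_genes = 400, n_cortical_left = 90),
    seed = 44)
  expect_identical(again$expression, bu$expression)
  one_donor <- expression_config()
  one_donor$donors <- "D1"
  expect_error(simulate_expression(fx$surface, one_donor),
               class = "bftrans_error_invalid_argument")
})

test_that("planted QC cases are recovered end to end", {
  fx <- fix_bundle()
  bu <- fx$bundle
  # the misplaced Ch1-3 sample is exactly the one the bounding box removes
  box <- bf_bounding_box()
  qc <- qc_samples(bu$samples, list(
    rule_bounding_box(c("NBM", "Ch1-3"), box$min, box$max)))
  expect_equal(qc$log$n_removed, 1)
  expect_equal(qc$log$removed_ids, bu$truth$misplaced_sample)
  expect_equal(sum(qc$samples$structure_label == "Ch1-3"), 8)
  # the displaced right-hemisphere samples are exactly the > 10 mm removals
  mt <- match_samples_to_vertices(fix_qc_samples(bu), fx$surface$vertices,
                                  hemisphere = "both")
  over <- mt$sample_id[mt$removal_reason == "over_distance"]
  expect_setequal(over, bu$truth$displaced_samples)
})
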