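# Clinical-stage analyses on the synthetic cohort.

test_that("reported p-values are internally consistent with t_tail_p", {
  co <- fix_cohort()
  res <- clinical_stage(co)
  tt <- res[res$term != "levene", ]
  expect_equal(tt$p, t_tail_p(tt$statistic, tt$df))
})

test_that("Bonferroni families match the analysis plans", {
  co <- fix_cohort()
  res <- clinical_stage(co)
  fam <- unique(res[!is.na(res$n_tests),
                    c("family", "n_tests", "p_bonf_threshold")])
  expect_true(all(fam$p_bonf_threshold == 0.05 / fam$n_tests))
  expect_equal(
    unique(fam$n_tests[fam$family == "region_family"]), 3)
  expect_true(8 %in% fam$n_tests[fam$family == "clinical_family"])
  expect_equal(unique(fam$n_tests[fam$family == "cognitive_family"]), 12)
  # printed-threshold forms
  expect_lt(unique(fam$p_bonf_threshold[fam$family == "region_family"]), 0.017)
  expect_equal(unique(fam$p_bonf_threshold[fam$n_tests == 8]), 6.25e-3)
  expect_equal(signif(unique(
    fam$p_bonf_threshold[fam$family == "cognitive_family"]), 3), 4.17e-3)
})

test_that("group comparison has power for planted shifts and is null-calibrated", {
  # null: no choline group difference is planted by default
  rej <- vapply(1:40, function(s) {
    co <- simulate_cohort(seed = 1500 + s)
    mrs_group_comparison(co$subjects)$p < 0.05
  }, logical(1))
  expect_gte(mean(!rej), 0.8)
  # planted 0.8 SD shift detected reliably (covariates decoupled from
  # diagnosis so the comparison's own power is measured, not the
  # cannabis-diagnosis collinearity)
  hits <- vapply(1:60, function(s) {
    co <- simulate_cohort(seed = 2500 + s)
    su <- co$subjects
    su$cast <- rpois(nrow(su), 1)
    su$smoking <- rep(c(TRUE, FALSE), length.out = nrow(su))
    su$choline <- su$choline + 0.8 * sd(su$choline) * (su$group == "FEP")
    mrs_group_comparison(su)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  bad <- fix_cohort()$subjects
  bad$choline[bad$group == "HC"] <- NA
  expect_error(mrs_group_comparison(bad),
               class = "bftrans_error_invalid_argument")
})

test_that("structure-MRS coupling recovers the planted HC pattern", {
  hits <- vapply(1:40, function(s) {
    co <- simulate_cohort(seed = 3500 + s)
    r <- structure_mrs_coupling(co$subjects, co$roi, "HC")
    r$estimate[r$region == "nbm_l" & r$term == "pearson_r"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  co <- fix_cohort()
  r <- structure_mrs_coupling(co$subjects, co$roi, "HC")
  expect_equal(r$region[r$term == "pearson_r"], c("ch13", "nbm_l", "nbm_r"))
  # orthogonalised inputs: p approaches 1
  su <- co$subjects[co$subjects$group == "HC", ]
  v <- roi <- co$roi
  x <- rnorm(29)
  y <- resid(lm(rnorm(29) ~ x))
  expect_gt(pearson_r_test(x, y)$p, 0.5)
})

test_that("decoupling test recovers planted interaction and is null-calibrated", {
  res <- vapply(1:60, function(s) {
    co <- simulate_cohort(seed = 4500 + s)
    d <- decoupling_test(co$subjects, co$roi)
    c(sign_ok = d$estimate[d$region == "nbm_l"] > 0,
      null_ok = d$p[d$region == "ch13"] < 0.05)
  }, c(sign_ok = FALSE, null_ok = FALSE))
  # planted decoupling: FEP slope minus HC slope is positive
  expect_gte(mean(res["sign_ok", ]), 0.9)
  # no coupling planted for ch13 in either group: rejection near alpha
  expect_lt(mean(res["null_ok", ]), 0.15)
})

test_that("case-control analysis recovers planted Ch1-3 effects", {
  res <- vapply(1:40, function(s) {
    co <- simulate_cohort(seed = 5500 + s)
    r <- case_control_microstructure(co$subjects, co$roi, "qt1",
                                     levene = FALSE)
    a <- case_control_microstructure(co$subjects, co$roi, "axd",
                                     levene = FALSE)
    c(qt1 = r$estimate[r$region == "ch13"] > 0,
      axd = a$estimate[a$region == "ch13"] > 0,
      fwe = all(r$p[r$region != "ch13"] > r$p_bonf_threshold[1]))
  }, c(qt1 = FALSE, axd = FALSE, fwe = FALSE))
  expect_gte(mean(res["qt1", ]), 0.95)
  expect_gte(mean(res["axd", ]), 0.95)
  # null regions rarely pass the family threshold
  expect_gte(mean(res["fwe", ]), 0.9)
  # ICV sensitivity keeps the effect
  co <- fix_cohort()
  r <- case_control_microstructure(co$subjects, co$roi, "qt1",
                                   include_icv = TRUE, levene = FALSE)
  expect_gt(r$statistic[r$region == "ch13"], 1)
  # levene rows appear once per region
  rl <- case_control_microstructure(co$subjects, co$roi, "qt1")
  expect_equal(sum(rl$term == "levene"), 3)
})

test_that("clinical correlates recover planted couplings; shuffled scores are null", {
  co <- fix_cohort()
  cc <- clinical_correlates(co$subjects, co$roi)
  expect_gt(cc$estimate[cc$region == "nbm_l" & cc$metric == "qt1" &
                          cc$score == "ymrs" & cc$term == "pearson_r"], 0)
  expect_gt(cc$estimate[cc$region == "nbm_l" & cc$metric == "axd" &
                          cc$score == "panss8_neg" &
                          cc$term == "pearson_r"], 0)
  expect_equal(nrow(cc), 16) # 2 regions x 2 metrics x 2 scores x 2 terms
  # permutation null: shuffled scores give centred correlations
  set.seed(9)
  rs <- replicate(50, {
    su <- co$subjects
    idx <- su$group == "FEP"
    su$ymrs[idx] <- sample(su$ymrs[idx])
    r <- clinical_correlates(su, co$roi)
    r$estimate[r$region == "nbm_l" & r$metric == "qt1" &
                 r$score == "ymrs" & r$term == "pearson_r"]
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("post hoc RD analyses mirror the qT1 effects", {
  res <- vapply(1:30, function(s) {
    co <- simulate_cohort(seed = 6500 + s)
    rd <- case_control_microstructure(co$subjects, co$roi, "rd",
                                      levene = FALSE)
    qt <- case_control_microstructure(co$subjects, co$roi, "qt1",
                                      levene = FALSE)
    sign(rd$estimate[rd$region == "ch13"]) ==
      sign(qt$estimate[qt$region == "ch13"])
  }, logical(1))
  expect_gte(mean(res), 0.95)
  co <- fix_cohort()
  post <- posthoc_cognitive_and_rd(co$subjects, co$roi)
  expect_named(post, c("cognitive", "rd_coupling_hc", "rd_decoupling",
                       "rd_case_control", "rd_clinical"))
  expect_equal(nrow(post$cognitive), 24) # 12 tests x 2 groups
  # available-case n respects the planted missingness
  trails_fep <- post$cognitive[post$cognitive$score == "trails" &
                                 post$cognitive$group == "FEP", ]
  expect_true(all(trails_fep$n_used == 56 - 18))
})
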