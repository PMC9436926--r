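# Clinical-sample analyses: MRS group comparison, structure-MRS coupling
# and decoupling, case-control microstructure, clinical and cognitive
# correlates, and RD sensitivity analyses.
#
# Multiple-testing families are explicit and fixed by design: 3 tests for
# the region families (threshold 0.05/3 < 0.017), 8 for clinical
# correlations (0.05/8 = 6.25e-3), 12 for cognitive (0.05/12 < 4.17e-3).

roi_value <- function(roi, region, metric) {
  sub <- roi[roi$region == region & roi$metric == metric, ]
  setNames(sub$value, sub$subject_id)
}

apply_family <- function(tb, family, n_tests, alpha = 0.05) {
  thr <- bonferroni_threshold(n_tests, alpha)
  mutate(tb, family = family, n_tests = n_tests,
         p_bonf_threshold = thr, significant = .data$p < thr)
}

clin_row <- function(analysis, region, metric, term, tr) {
  tibble(analysis = analysis, region = region, metric = metric, term = term,
         estimate = tr$estimate, statistic = tr$statistic, df = tr$df,
         p = tr$p, n_used = tr$n_used)
}

#' MRS choline group comparison
#'
#' t-test of the diagnosis coefficient in
#' `choline ~ diagnosis + age + sex + smoking + CAST`.
#'
#' @param subjects Subject tibble (see [simulate_cohort()]).
#' @return One-row tidy result tibble.
#' @export
mrs_group_comparison <- function(subjects) {
  ok <- !is.na(subjects$choline)
  if (length(unique(subjects$group[ok])) < 2 ||
      min(table(subjects$group[ok])) < 2) {
    bft_stop("Need >= 2 subjects with choline per group.",
             "bftrans_error_invalid_argument")
  }
  design <- data.frame(group = subjects$group, age = subjects$age,
                       sex = subjects$sex, smoking = subjects$smoking,
                       cast = subjects$cast)
  fit <- ols_fit(subjects$choline, design)
  row <- fit$coefficients[fit$coefficients$term == "groupFEP", ]
  tr <- test_result(row$estimate, row$statistic, row$df, row$p,
                    n_used = fit$n_used)
  clin_row("mrs_group_comparison", NA_character_, "choline",
           "diagnosis", tr)
}

#' Structure-MRS coupling
#'
#' Pearson correlation between dACC choline and each basal-forebrain
#' region's microstructure within one group, raw and covariate-adjusted
#' (age, sex, CAST), with the 3-test Bonferroni family applied to the raw
#' correlations.
#'
#' @param subjects,roi Cohort tables.
#' @param group_filter `"HC"` or `"FEP"`.
#' @param metric ROI metric (default `"qt1"`).
#' @return Tidy result tibble, one raw and one adjusted row per region in
#'   the fixed order Ch1-3, left NBM, right NBM.
#' @export
structure_mrs_coupling <- function(subjects, roi, group_filter = "HC",
                                   metric = "qt1") {
  sub <- subjects[subjects$group == group_filter, ]
  if (all(is.na(sub$choline))) {
    bft_stop("All choline values missing in the requested group.",
             "bftrans_error_invalid_argument")
  }
  if (nrow(sub) < 5) {
    bft_stop("Need >= 5 subjects in the subset.",
             "bftrans_error_insufficient_data")
  }
  covs <- data.frame(age = sub$age, sex = sub$sex, cast = sub$cast)
  rows <- map(bf_regions(), function(region) {
    v <- roi_value(roi, region, metric)[sub$subject_id]
    raw <- pearson_r_test(v, sub$choline)
    adj <- adjusted_assoc(sub$choline, v, covs)
    bind_rows(
      clin_row("structure_mrs_coupling", region, metric, "pearson_r", raw),
      clin_row("structure_mrs_coupling", region, metric,
               "adjusted_coefficient", adj)
    )
  })
  out <- list_rbind(rows)
  out <- mutate(out, group = group_filter, .after = "analysis")
  apply_family(out, "region_family", 3)
}

#' Diagnosis-by-microstructure decoupling test
#'
#' Per region, the t-test of the diagnosis-by-value interaction on choline
#' (`choline ~ value * diagnosis + age + sex`). Smoking and CAST are
#' excluded by design: the control group contains no smokers and cannabis
#' use separates the groups, so both are collinear with the interaction's
#' group margin.
#'
#' @inheritParams structure_mrs_coupling
#' @return Tidy result tibble, one row per region.
#' @export
decoupling_test <- function(subjects, roi, metric = "qt1") {
  if (length(unique(subjects$group)) < 2) {
    bft_stop("Both groups must be present.", "bftrans_error_invalid_argument")
  }
  covs <- data.frame(age = subjects$age, sex = subjects$sex)
  rows <- map(bf_regions(), function(region) {
    v <- roi_value(roi, region, metric)[subjects$subject_id]
    tr <- interaction_model(subjects$choline, v, subjects$group, covs)
    clin_row("decoupling_test", region, metric, "diagnosis_by_value", tr)
  })
  apply_family(list_rbind(rows), "region_family", 3)
}

#' Case-control differences in BF microstructure
#'
#' Per region, the diagnosis coefficient in
#' `value ~ diagnosis + age + sex + CAST + smoking` (optionally + ICV),
#' with Levene's (Brown-Forsythe) equal-variance check attached per region.
#'
#' @inheritParams structure_mrs_coupling
#' @param include_icv Add intracranial volume as a covariate (sensitivity
#'   analysis).
#' @param levene Attach Levene rows (term `"levene"`).
#' @return Tidy result tibble.
#' @export
case_control_microstructure <- function(subjects, roi, metric = "qt1",
                                        include_icv = FALSE, levene = TRUE) {
  design <- data.frame(group = subjects$group, age = subjects$age,
                       sex = subjects$sex, cast = subjects$cast,
                       smoking = subjects$smoking)
  if (include_icv) design$icv <- subjects$icv
  rows <- map(bf_regions(), function(region) {
    v <- roi_value(roi, region, metric)[subjects$subject_id]
    fit <- ols_fit(v, design)
    row <- fit$coefficients[fit$coefficients$term == "groupFEP", ]
    out <- clin_row("case_control", region, metric, "diagnosis",
                    test_result(row$estimate, row$statistic, row$df, row$p,
                                n_used = fit$n_used))
    if (levene) {
      lv <- levene_test(v, subjects$group)
      out <- bind_rows(out, tibble(
        analysis = "case_control", region = region, metric = metric,
        term = "levene", estimate = NA_real_, statistic = lv$statistic,
        df = lv$df, p = lv$p, n_used = lv$df + 2
      ))
    }
    out
  })
  out <- list_rbind(rows)
  fam <- apply_family(filter(out, .data$term == "diagnosis"),
                      "region_family", 3)
  lev <- filter(out, .data$term == "levene")
  if (nrow(lev)) {
    lev <- mutate(lev, family = "levene", n_tests = NA_integer_,
                  p_bonf_threshold = NA_real_, significant = .data$p < 0.05)
  }
  bind_rows(fam, lev)
}

#' Clinical correlates of BF microstructure
#'
#' Within FEP: Pearson correlations (raw) and CAST/smoking-adjusted
#' coefficient tests between {left NBM, Ch1-3} x {qT1, AxD} and
#' {YMRS, PANSS-8 negative}; 8-test Bonferroni family on the raw
#' correlations.
#'
#' @inheritParams structure_mrs_coupling
#' @param metrics Metrics entering the family (default qT1 and AxD).
#' @return Tidy result tibble with a `score` column.
#' @export
clinical_correlates <- function(subjects, roi, metrics = c("qt1", "axd")) {
  fep <- subjects[subjects$group == "FEP", ]
  scores <- c("ymrs", "panss8_neg")
  if (sum(!is.na(fep$ymrs)) < 5) {
    bft_stop("Need >= 5 FEP subjects with clinical scores.",
             "bftrans_error_insufficient_data")
  }
  covs <- data.frame(cast = fep$cast, smoking = fep$smoking)
  grid <- expand.grid(region = c("nbm_l", "ch13"), metric = metrics,
                      score = scores, stringsAsFactors = FALSE)
  rows <- pmap(grid, function(region, metric, score) {
    v <- roi_value(roi, region, metric)[fep$subject_id]
    s <- fep[[score]]
    raw <- pearson_r_test(v, s)
    adj <- adjusted_assoc(s, v, covs)
    bind_rows(
      mutate(clin_row("clinical_correlates", region, metric, "pearson_r",
                      raw), score = score),
      mutate(clin_row("clinical_correlates", region, metric,
                      "adjusted_coefficient", adj), score = score)
    )
  })
  out <- list_rbind(rows)
  n_fam <- nrow(grid)
  apply_family(out, "clinical_family", n_fam)
}

#' Post hoc analyses: cognition and radial diffusivity
#'
#' Cognitive correlations (DSST, trail-making) against the three BF regions
#' and two primary metrics, per group, under the 12-test Bonferroni family;
#' plus RD reruns of the structure-MRS coupling, decoupling, case-control
#' and clinical-correlate analyses.
#'
#' @inheritParams structure_mrs_coupling
#' @return Named list of tidy tibbles: `cognitive`, `rd_coupling_hc`,
#'   `rd_decoupling`, `rd_case_control`, `rd_clinical`.
#' @export
posthoc_cognitive_and_rd <- function(subjects, roi) {
  grid <- expand.grid(score = c("dsst", "trails"),
                      region = bf_regions(),
                      metric = c("qt1", "axd"), stringsAsFactors = FALSE)
  cog <- map(c("FEP", "HC"), function(g) {
    sub <- subjects[subjects$group == g, ]
    rows <- pmap(grid, function(score, region, metric) {
      v <- roi_value(roi, region, metric)[sub$subject_id]
      tr <- pearson_r_test(v, sub[[score]])
      mutate(clin_row("cognitive", region, metric, "pearson_r", tr),
             score = score, group = g)
    })
    apply_family(list_rbind(rows), "cognitive_family", nrow(grid))
  })
  list(
    cognitive = list_rbind(cog),
    rd_coupling_hc = structure_mrs_coupling(subjects, roi, "HC", "rd"),
    rd_decoupling = decoupling_test(subjects, roi, "rd"),
    rd_case_control = case_control_microstructure(subjects, roi, "rd"),
    rd_clinical = clinical_correlates(subjects, roi, metrics = "rd")
  )
}

#' Run the full clinical stage
#'
#' Convenience wrapper executing every clinical-stage analysis on a cohort
#' and binding the results into one tidy table.
#'
#' @param cohort A [simulate_cohort()] result, or a list with `subjects`
#'   and `roi`.
#' @return Tidy tibble of all clinical-stage results.
#' @export
clinical_stage <- function(cohort) {
  s <- cohort$subjects; r <- cohort$roi
  post <- posthoc_cognitive_and_rd(s, r)
  bind_rows(
    mrs_group_comparison(s),
    structure_mrs_coupling(s, r, "HC"),
    structure_mrs_coupling(s, r, "FEP"),
    decoupling_test(s, r),
    case_control_microstructure(s, r, "qt1"),
    case_control_microstructure(s, r, "axd"),
    clinical_correlates(s, r),
    post$cognitive,
    post$rd_coupling_hc, post$rd_decoupling,
    post$rd_case_control, post$rd_clinical
  )
}
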