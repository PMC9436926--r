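# Synthetic clinical cohort: subjects, ROI microstructure, and the ground
# truth needed for recovery tests.

#' Configuration for the synthetic cohort
#'
#' Defaults encode the study design the generator emulates: 56 first-episode
#' psychosis (FEP) patients and 29 healthy controls (HC); age ~22 y and a
#' male-majority sample in both groups; no smokers among HC and markedly
#' higher cannabis use (CAST) in FEP; elevated Ch1-3 qT1 and AxD in FEP
#' (standardised effect 0.9, RD 0.7 — sized so the CAST/smoking-adjusted
#' diagnosis tests retain power despite the cannabis-diagnosis overlap the
#' covariate distributions plant); dACC choline coupled to left-NBM qT1
#' in HC with correlation -0.5 and decoupled (slope 0) in FEP; YMRS coupled
#' to left-NBM qT1 and PANSS-8 negative to left-NBM AxD within FEP.
#'
#' @param n_fep,n_hc Group sizes (>= 3 each).
#' @param effect_qt1_ch13,effect_axd_ch13,effect_rd_ch13 Standardised FEP-HC
#'   effects planted in Ch1-3; all other region effects are 0.
#' @param hc_coupling_r Choline ~ left-NBM-qT1 correlation planted in HC
#'   (negative: more myelin, more choline); the FEP slope is 0.
#' @param ymrs_coupling,panss_coupling Within-FEP standardised slopes of YMRS
#'   on left-NBM qT1 and PANSS-8 negative on left-NBM AxD.
#' @param metric_cor Latent correlation between qT1/AxD/RD within a region
#'   (shared demyelination factor).
#' @return A list of class `bft_cohort_config`.
#' @export
cohort_config <- function(n_fep = 56, n_hc = 29,
                          effect_qt1_ch13 = 0.9,
                          effect_axd_ch13 = 0.9,
                          effect_rd_ch13 = 0.7,
                          hc_coupling_r = -0.5,
                          ymrs_coupling = 0.45,
                          panss_coupling = 0.40,
                          metric_cor = 0.6) {
  cfg <- list(
    n_fep = n_fep, n_hc = n_hc,
    age_mean = c(fep = 22.34, hc = 21.72),
    age_sd = c(fep = 4.30, hc = 3.46),
    p_male = c(fep = 43 / 56, hc = 18 / 29),
    p_smoking_fep = 0.30,
    cast_lambda = c(fep = 3.5, hc = 0.4),
    # ROI baselines: qT1 in ms, diffusivities in 1e-3 mm^2/s
    roi_mean = c(qt1 = 1450, axd = 1.10, rd = 0.75),
    roi_sd = c(qt1 = 60, axd = 0.08, rd = 0.06),
    effects = c(qt1 = effect_qt1_ch13, axd = effect_axd_ch13,
                rd = effect_rd_ch13),
    hc_coupling_r = hc_coupling_r,
    ymrs_coupling = ymrs_coupling,
    panss_coupling = panss_coupling,
    metric_cor = metric_cor,
    choline_mean = 1.0, choline_sd = 0.15,
    crlb_mean = 1.88, crlb_sd = 0.52,
    dsst_mean = c(fep = 51.77, hc = 68.71),
    dsst_sd = c(fep = 13.97, hc = 11.30),
    trails_meanlog = c(fep = log(80), hc = log(53)),
    trails_sdlog = c(fep = 0.55, hc = 0.28),
    n_missing_dsst = c(fep = 1, hc = 0),
    n_missing_trails = c(fep = 18, hc = 4),
    icv_mean = 1.5e6, icv_sd = 1.4e5
  )
  class(cfg) <- "bft_cohort_config"
  cfg
}

#' ROI regions and metrics used throughout the package
#' @name bf_regions
#' @return Character vectors of region / metric identifiers.
#' @export
bf_regions <- function() c("ch13", "nbm_l", "nbm_r")

#' @rdname bf_regions
#' @export
bf_metrics <- function() c("qt1", "axd", "rd")

#' Generate a synthetic clinical cohort
#'
#' Draws a subject table (diagnosis, covariates, clinical and cognitive
#' scores, MRS choline) and a long per-subject ROI microstructure table
#' (qT1, AxD, RD for Ch1-3 and left/right NBM), plus a `truth` record of
#' every planted parameter. Deterministic under a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List of class `bft_cohort`: `subjects` (tibble), `roi` (long
#'   tibble: subject_id, region, metric, value), `truth` (list).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  if (!inherits(config, "bft_cohort_config")) {
    bft_stop("`config` must come from cohort_config().",
             "bftrans_error_invalid_argument")
  }
  if (config$n_fep < 3 || config$n_hc < 3) {
    bft_stop("Group sizes must be >= 3.", "bftrans_error_invalid_argument")
  }
  if (!all(is.finite(config$effects))) {
    bft_stop("Effect sizes must be finite.", "bftrans_error_invalid_argument")
  }
  set.seed(seed)
  n <- config$n_fep + config$n_hc
  group <- factor(rep(c("FEP", "HC"), c(config$n_fep, config$n_hc)),
                  levels = c("HC", "FEP"))
  gkey <- ifelse(group == "FEP", "fep", "hc")
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    age = rnorm(n, config$age_mean[gkey], config$age_sd[gkey]),
    sex = factor(ifelse(runif(n) < config$p_male[gkey], "M", "F"),
                 levels = c("F", "M")),
    smoking = ifelse(group == "FEP",
                     runif(n) < config$p_smoking_fep, FALSE),
    cast = rpois(n, config$cast_lambda[gkey]),
    icv = rnorm(n, config$icv_mean, config$icv_sd)
  )

  # ROI microstructure: per region a latent demyelination factor shared by
  # the three metrics; the planted group effect enters the latent so that
  # qT1/AxD/RD are co-perturbed with the same sign.
  lam <- config$metric_cor
  roi <- list()
  latents <- list()
  for (region in bf_regions()) {
    eff <- if (region == "ch13") config$effects else c(qt1 = 0, axd = 0, rd = 0)
    m <- rnorm(n)
    latents[[region]] <- m
    for (metric in bf_metrics()) {
      z <- lam * m + sqrt(1 - lam^2) * rnorm(n) +
        eff[metric] * (group == "FEP")
      val <- config$roi_mean[[metric]] + config$roi_sd[[metric]] * z
      roi[[paste(region, metric, sep = ".")]] <- tibble(
        subject_id = subjects$subject_id,
        region = region, metric = metric, value = val
      )
    }
  }
  roi <- list_rbind(unname(roi))

  qt1_nbml <- roi$value[roi$region == "nbm_l" & roi$metric == "qt1"]
  axd_nbml <- roi$value[roi$region == "nbm_l" & roi$metric == "axd"]
  is_fep <- group == "FEP"

  # Choline: coupled to left-NBM qT1 in HC only (decoupling in FEP).
  r <- config$hc_coupling_r
  chol_z <- numeric(n)
  z_hc <- zscore(qt1_nbml[!is_fep])
  chol_z[!is_fep] <- r * z_hc + sqrt(1 - r^2) * rnorm(sum(!is_fep))
  chol_z[is_fep] <- rnorm(sum(is_fep))
  # mild covariate structure on choline (age), small relative to coupling
  chol_z <- chol_z + 0.1 * zscore(subjects$age)
  subjects$choline <- config$choline_mean + config$choline_sd * chol_z
  crlb <- rnorm(n, config$crlb_mean, config$crlb_sd)
  subjects$choline_crlb <- pmax(crlb, 0.5)

  # Clinical scores, FEP only; planted couplings to left NBM.
  ymrs <- panss <- cds <- rep(NA_real_, n)
  nf <- sum(is_fep)
  ymrs[is_fep] <- round(pmax(0, 8 + 4 * (config$ymrs_coupling * zscore(qt1_nbml[is_fep]) +
    sqrt(1 - config$ymrs_coupling^2) * rnorm(nf)) + 0.4 * subjects$cast[is_fep]))
  panss[is_fep] <- round(pmax(0, 7 + 4 * (config$panss_coupling * zscore(axd_nbml[is_fep]) +
    sqrt(1 - config$panss_coupling^2) * rnorm(nf))))
  cds[is_fep] <- rpois(nf, 3.7)
  subjects$ymrs <- ymrs
  subjects$panss8_neg <- panss
  subjects$cds <- cds

  # Cognition with per-group missingness counts.
  subjects$dsst <- rnorm(n, config$dsst_mean[gkey], config$dsst_sd[gkey])
  subjects$trails <- exp(rnorm(n, config$trails_meanlog[gkey],
                               config$trails_sdlog[gkey]))
  for (g in c("fep", "hc")) {
    idx <- which(gkey == g)
    nd <- config$n_missing_dsst[[g]]
    nt <- config$n_missing_trails[[g]]
    if (nd > 0) subjects$dsst[sample(idx, nd)] <- NA_real_
    if (nt > 0) subjects$trails[sample(idx, nt)] <- NA_real_
  }

  truth <- list(
    seed = seed,
    effects_ch13 = as.list(config$effects),
    hc_coupling_r = config$hc_coupling_r,
    ymrs_coupling = config$ymrs_coupling,
    panss_coupling = config$panss_coupling,
    metric_cor = config$metric_cor,
    region_latents = latents
  )
  structure(list(subjects = subjects, roi = roi, truth = truth),
            class = "bft_cohort")
}

#' @export
print.bft_cohort <- function(x, ...) {
  cat(sprintf("<bft_cohort> %d subjects (%d FEP / %d HC), %d ROI rows\n",
              nrow(x$subjects), sum(x$subjects$group == "FEP"),
              sum(x$subjects$group == "HC"), nrow(x$roi)))
  invisible(x)
}

# Wide helper: one row per subject, columns region_metric.
roi_wide <- function(roi) {
  tidyr::pivot_wider(roi,
                     names_from = c("region", "metric"),
                     values_from = "value",
                     names_sep = "_")
}
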