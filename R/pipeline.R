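# Orchestration: configuration, stage execution over a run directory of
# canonical TSV files, manifest hashing, and input validation.

pipeline_stages <- function() {
  c("synthetic", "clinical", "covariance", "ahba_prep",
    "region_expression", "imaging_tx", "enrichment")
}

#' Pipeline run configuration
#'
#' Collects every stage's parameters and thresholds: FDR q = 0.10
#' throughout, Bonferroni families fixed by the analysis plans, 10 mm
#' match cutoff, 10% deciles, FDR grid {0.10, 0.05, 0.01}.
#'
#' @param outdir Run directory (created if missing).
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Stages to run, in dependency order; a subset re-runs only
#'   those stages against the files already in `outdir`.
#' @param cohort,surface,expression Generator configurations.
#' @param covariance_seeds BF seed regions mapped (default nbm_l and ch13).
#' @param fdr_q,match_cutoff,decile,fdr_grid Analysis thresholds.
#' @param psi_permutations Permutations for the pSI table.
#' @return List of class `bft_config`.
#' @export
run_config <- function(outdir = tempfile("bftrans_run_"), seed = 1L,
                       stages = pipeline_stages(),
                       cohort = cohort_config(),
                       surface = surface_config(),
                       expression = expression_config(),
                       covariance_seeds = c("nbm_l", "ch13"),
                       fdr_q = 0.10, match_cutoff = 10,
                       decile = 0.10, fdr_grid = c(0.10, 0.05, 0.01),
                       psi_permutations = 100) {
  unknown <- setdiff(stages, pipeline_stages())
  if (length(unknown)) {
    bft_stop(paste("Unknown stage(s):", paste(unknown, collapse = ", ")),
             "bftrans_error_invalid_argument")
  }
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              stages = stages[order(match(stages, pipeline_stages()))],
              cohort = cohort, surface = surface, expression = expression,
              covariance_seeds = covariance_seeds,
              fdr_q = fdr_q, match_cutoff = match_cutoff, decile = decile,
              fdr_grid = fdr_grid, psi_permutations = psi_permutations)
  class(cfg) <- "bft_config"
  cfg
}

path_in <- function(cfg, file) file.path(cfg$outdir, file)

need_file <- function(cfg, file, stage) {
  p <- path_in(cfg, file)
  if (!file.exists(p)) {
    bft_stop(sprintf("Stage '%s' needs missing upstream output '%s'.",
                     stage, file),
             "bftrans_error_dependency")
  }
  p
}

read_surface_dir <- function(cfg, stage) {
  vertices <- read_bft_tsv(need_file(cfg, "surface_vertices.tsv", stage))
  long <- read_bft_tsv(need_file(cfg, "surface_qt1.tsv", stage))
  wide <- tidyr::pivot_wider(long, names_from = "vertex_id",
                             values_from = "qt1")
  qt1 <- as.matrix(wide[, -1])
  rownames(qt1) <- wide$subject_id
  list(vertices = vertices, qt1 = qt1[, vertices$vertex_id, drop = FALSE])
}

read_expression_dir <- function(cfg, file, stage) {
  tb <- read_bft_tsv(need_file(cfg, file, stage))
  mat <- as.matrix(tb[, -1])
  rownames(mat) <- tb[[1]]
  mat
}

write_matrix_tsv <- function(mat, id_col, path) {
  tb <- as_tibble(mat, .name_repair = "minimal")
  tb <- bind_cols(tibble(!!id_col := rownames(mat)), tb)
  write_bft_tsv(tb, path)
}

stage_synthetic <- function(cfg) {
  cohort <- simulate_cohort(cfg$cohort, seed = cfg$seed)
  surface <- simulate_surface(cohort, cfg$surface, seed = cfg$seed + 1L)
  bundle <- simulate_expression(surface, cfg$expression,
                                seed = cfg$seed + 2L)
  cells <- simulate_cell_profiles(unique(bundle$probes$gene),
                                  cholinergic_markers = bundle$truth$bf_genes,
                                  seed = cfg$seed + 3L)
  sets <- simulate_gene_sets(unique(bundle$probes$gene),
                             bundle$truth$bf_genes, seed = cfg$seed + 4L)
  write_bft_tsv(cohort$subjects, path_in(cfg, "subjects.tsv"))
  write_bft_tsv(cohort$roi, path_in(cfg, "roi_measures.tsv"))
  write_bft_tsv(surface$vertices, path_in(cfg, "surface_vertices.tsv"))
  long <- tidyr::pivot_longer(
    bind_cols(tibble(subject_id = rownames(surface$qt1)),
              as_tibble(surface$qt1, .name_repair = "minimal")),
    -"subject_id", names_to = "vertex_id", values_to = "qt1")
  write_bft_tsv(long, path_in(cfg, "surface_qt1.tsv"))
  write_matrix_tsv(bundle$expression, "probe_id", path_in(cfg, "expression.tsv"))
  write_bft_tsv(bundle$probes, path_in(cfg, "probes.tsv"))
  write_bft_tsv(bundle$samples, path_in(cfg, "samples.tsv"))
  write_matrix_tsv(cells, "gene", path_in(cfg, "cell_profiles.tsv"))
  write_gmt(sets, path_in(cfg, "gene_sets.gmt"))
  truth <- list(cohort = cohort$truth[setdiff(names(cohort$truth),
                                              "region_latents")],
                surface = surface$truth, expression = bundle$truth)
  jsonlite::write_json(truth, path_in(cfg, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_clinical <- function(cfg) {
  subjects <- read_bft_tsv(need_file(cfg, "subjects.tsv", "clinical"))
  subjects$group <- factor(subjects$group, levels = c("HC", "FEP"))
  subjects$sex <- factor(subjects$sex, levels = c("F", "M"))
  roi <- read_bft_tsv(need_file(cfg, "roi_measures.tsv", "clinical"))
  res <- clinical_stage(list(subjects = subjects, roi = roi))
  write_bft_tsv(res, path_in(cfg, "clinical_results.tsv"))
}

stage_covariance <- function(cfg) {
  surface <- read_surface_dir(cfg, "covariance")
  roi <- read_bft_tsv(need_file(cfg, "roi_measures.tsv", "covariance"))
  for (seed_region in cfg$covariance_seeds) {
    m <- map_covariance(surface, roi, seed_region = seed_region,
                        fdr_q = cfg$fdr_q)
    write_bft_tsv(m, path_in(cfg, paste0("covariance_", seed_region, ".tsv")))
  }
}

stage_ahba_prep <- function(cfg) {
  expression <- read_expression_dir(cfg, "expression.tsv", "ahba_prep")
  probes <- read_bft_tsv(need_file(cfg, "probes.tsv", "ahba_prep"))
  samples <- read_bft_tsv(need_file(cfg, "samples.tsv", "ahba_prep"))
  vertices <- read_bft_tsv(need_file(cfg, "surface_vertices.tsv", "ahba_prep"))
  box <- bf_bounding_box()
  qc <- qc_samples(samples, list(
    rule_allowed_labels(c("cortex-L", "cortex-R", "NBM", "Ch1-3")),
    rule_bounding_box(c("NBM", "Ch1-3"), box$min, box$max)))
  sel <- select_probes(probes, expression)
  ge <- sel$expression[, qc$samples$sample_id, drop = FALSE]
  write_matrix_tsv(ge, "gene", path_in(cfg, "gene_expression.tsv"))
  write_bft_tsv(qc$samples, path_in(cfg, "samples_qc.tsv"))
  matches <- match_samples_to_vertices(qc$samples, vertices,
                                       max_distance = cfg$match_cutoff)
  write_bft_tsv(matches, path_in(cfg, "matches.tsv"))
  jsonlite::write_json(
    list(sample_qc = qc$log,
         probes_dropped_genes = sel$dropped_genes,
         match_summary = attr(matches, "summary")),
    path_in(cfg, "qc_log.json"), auto_unbox = TRUE, digits = NA)
}

stage_region_expression <- function(cfg) {
  ge <- read_expression_dir(cfg, "gene_expression.tsv", "region_expression")
  samples <- read_bft_tsv(need_file(cfg, "samples_qc.tsv", "region_expression"))
  for (target in c("Ch1-3", "NBM")) {
    stats <- region_expression_analysis(ge, samples, target_region = target,
                                        fdr_grid = cfg$fdr_grid)
    tag <- if (target == "Ch1-3") "ch13" else "nbm"
    write_bft_tsv(stats, path_in(cfg, paste0("region_stats_", tag, ".tsv")))
    lists <- attr(stats, "fdr_lists")
    for (nm in names(lists)) {
      ranked <- lists[[nm]]
      ord <- order(-stats$rank_score[match(ranked, stats$gene)])
      writeLines(ranked[ord],
                 path_in(cfg, paste0("genes_", tag, "_", nm, ".txt")))
    }
  }
}

stage_imaging_tx <- function(cfg) {
  covmap <- read_bft_tsv(need_file(cfg, paste0(
    "covariance_", cfg$covariance_seeds[1], ".tsv"), "imaging_tx"))
  covmap <- filter(covmap, .data$structure == "cortex-L")
  matches <- read_bft_tsv(need_file(cfg, "matches.tsv", "imaging_tx"))
  ge <- read_expression_dir(cfg, "gene_expression.tsv", "imaging_tx")
  samples <- read_bft_tsv(need_file(cfg, "samples_qc.tsv", "imaging_tx"))
  design <- assemble_design(covmap, matches, ge, samples)
  stats <- fit_imaging_models(design)
  sliced <- rank_and_slice(stats, decile = cfg$decile,
                           fdr_grid = cfg$fdr_grid)
  write_bft_tsv(sliced$stats, path_in(cfg, "imaging_gene_stats.tsv"))
  writeLines(sliced$top, path_in(cfg, "top10.txt"))
  writeLines(sliced$bottom, path_in(cfg, "bottom10.txt"))
  jsonlite::write_json(as.list(sliced$fdr_counts),
                       path_in(cfg, "imaging_fdr_counts.json"),
                       auto_unbox = TRUE, digits = NA)
}

stage_enrichment <- function(cfg) {
  ge <- read_expression_dir(cfg, "gene_expression.tsv", "enrichment")
  universe <- rownames(ge)
  sets <- read_gmt(need_file(cfg, "gene_sets.gmt", "enrichment"))
  collection <- gene_set_collection(sets, universe, source = "synthetic")
  cells <- read_expression_dir(cfg, "cell_profiles.tsv", "enrichment")
  psi <- compute_psi(cells[intersect(rownames(cells), universe), ],
                     n_permutations = cfg$psi_permutations,
                     seed = cfg$seed + 5L)
  out <- list(); grid <- list()
  for (tag in c("ch13", "nbm")) {
    lf <- need_file(cfg, paste0("genes_", tag, "_fdr_0.1.txt"), "enrichment")
    query <- readLines(lf)
    if (!length(query)) next
    enr <- mutate(hypergeom_enrich(query, collection), query = tag)
    out[[tag]] <- enr
    grid[[tag]] <- mutate(csea_enrich(query, psi, universe), query = tag)
  }
  for (side in c("top10", "bottom10")) {
    f <- path_in(cfg, paste0(side, ".txt"))
    if (file.exists(f)) {
      query <- readLines(f)
      if (length(query)) {
        grid[[side]] <- mutate(csea_enrich(query, psi, universe),
                               query = side)
      }
    }
  }
  write_bft_tsv(list_rbind(unname(out)), path_in(cfg, "enrichment_results.tsv"))
  write_bft_tsv(list_rbind(unname(grid)), path_in(cfg, "csea_grid.tsv"))
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order against the run
#' directory, reading each stage's inputs from the canonical TSV outputs of
#' earlier stages (so partial re-runs by stage name are exact), and writes
#' a manifest with an MD5 hash of every output file. Re-running with an
#' identical config and seed reproduces the manifest bit for bit.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "bft_config")) {
    bft_stop("`config` must come from run_config().",
             "bftrans_error_invalid_argument")
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  runners <- list(synthetic = stage_synthetic, clinical = stage_clinical,
                  covariance = stage_covariance, ahba_prep = stage_ahba_prep,
                  region_expression = stage_region_expression,
                  imaging_tx = stage_imaging_tx,
                  enrichment = stage_enrichment)
  timings <- list()
  for (st in config$stages) {
    t0 <- Sys.time()
    runners[[st]](config)
    timings[[st]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  cfg_for_hash <- config
  cfg_for_hash$outdir <- NULL
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  files <- setdiff(list.files(config$outdir), "manifest.json")
  hashes <- tools::md5sum(file.path(config$outdir, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("bftrans")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    stages_run = config$stages,
    timings_sec = timings,
    files = as.list(setNames(unname(hashes), files))
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate pipeline input files
#'
#' Report-only schema and sanity checks: required columns per known file,
#' duplicate-id detection, expression/sample id agreement, and coordinate
#' magnitudes consistent with a mm frame. Missing or empty files are
#' findings, not errors.
#'
#' @param paths Named character vector / list of file paths; names from
#'   subjects, roi_measures, surface_vertices, expression, probes, samples.
#' @return Tibble: file, check, status (`"pass"`/`"fail"`), detail.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  req <- list(
    subjects = c("subject_id", "group", "age", "sex", "choline"),
    roi_measures = c("subject_id", "region", "metric", "value"),
    surface_vertices = c("vertex_id", "structure", "x", "y", "z"),
    probes = c("probe_id", "gene", "qc_pass", "rnaseq_r"),
    samples = c("sample_id", "donor_id", "structure_label", "x", "y", "z")
  )
  out <- list()
  add <- function(file, check, ok, detail = "") {
    out[[length(out) + 1]] <<- tibble(file = file, check = check,
                                      status = if (ok) "pass" else "fail",
                                      detail = detail)
  }
  tables <- list()
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!file.exists(p)) { add(nm, "exists", FALSE, p); next }
    add(nm, "exists", TRUE)
    if (file.size(p) == 0) { add(nm, "non_empty", FALSE, "empty file"); next }
    tb <- tryCatch(read_bft_tsv(p), error = function(e) NULL)
    if (is.null(tb) || nrow(tb) == 0) {
      add(nm, "non_empty", FALSE, "no rows"); next
    }
    add(nm, "non_empty", TRUE)
    tables[[nm]] <- tb
    if (nm %in% names(req)) {
      missing <- setdiff(req[[nm]], names(tb))
      add(nm, "required_columns", length(missing) == 0,
          paste(missing, collapse = ", "))
      idcol <- req[[nm]][1]
      if (idcol %in% names(tb) && nm != "roi_measures") {
        dups <- tb[[idcol]][duplicated(tb[[idcol]])]
        add(nm, "unique_ids", length(dups) == 0,
            paste(unique(dups), collapse = ", "))
      }
    }
    if (nm %in% c("surface_vertices", "samples") &&
        all(c("x", "y", "z") %in% names(tb))) {
      mx <- max(abs(c(tb$x, tb$y, tb$z)), na.rm = TRUE)
      add(nm, "mm_frame", is.finite(mx) && mx > 5 && mx < 500,
          sprintf("max |coordinate| = %.1f", mx))
    }
  }
  if (!is.null(tables$expression) && !is.null(tables$samples)) {
    ids <- setdiff(names(tables$expression)[-1], tables$samples$sample_id)
    add("expression", "samples_match", length(ids) == 0,
        sprintf("%d expression columns missing from samples", length(ids)))
  }
  list_rbind(out)
}
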