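# Gene-set machinery: GMT I/O, hypergeometric overlap enrichment with FDR,
# specificity-index (pSI) computation, and pSI-threshold cell-type
# enrichment (CSEA-style nested marker sets).

#' Read / write GMT gene-set files
#'
#' Reading delegates to `fgsea::gmtPathways()`; writing emits the standard
#' tab-separated layout (name, description, genes...).
#'
#' @param path File path.
#' @return `read_gmt()`: named list of gene vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors.
#' @param description Description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene-set collection over a background universe
#'
#' Harmonises sets against the universe (genes outside the universe are
#' dropped; duplicates within a set collapse).
#'
#' @param sets Named list of gene vectors.
#' @param universe Background gene vector.
#' @param source Identifier for provenance (default `"custom"`).
#' @return List of class `bft_collection`: `sets`, `universe`, `source`.
#' @export
gene_set_collection <- function(sets, universe, source = "custom") {
  universe <- unique(universe)
  if (length(universe) == 0) {
    bft_stop("Empty universe.", "bftrans_error_invalid_argument")
  }
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  structure(list(sets = sets, universe = universe, source = source),
            class = "bft_collection")
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric overlap test of a query list against each set
#' in a collection, BH-FDR over sets, sorted by p with a deterministic tie
#' break on set name. Query genes outside the universe are dropped and
#' counted.
#'
#' @param query Gene vector.
#' @param collection A [gene_set_collection()].
#' @return Tibble of class `bft_enrichment`: set_name, overlap_count,
#'   set_size, query_size, universe_size, p, q, overlapping_genes
#'   (comma-separated). Attribute `n_query_dropped`.
#' @export
hypergeom_enrich <- function(query, collection) {
  if (!inherits(collection, "bft_collection")) {
    bft_stop("`collection` must come from gene_set_collection().",
             "bftrans_error_invalid_argument")
  }
  universe <- collection$universe
  query0 <- unique(query)
  query <- intersect(query0, universe)
  n_dropped <- length(query0) - length(query)
  N <- length(universe)
  n <- length(query)
  rows <- imap(collection$sets, function(set, nm) {
    K <- length(set)
    hits <- intersect(query, set)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_name = nm, overlap_count = k, set_size = K,
           query_size = n, universe_size = N, p = p,
           overlapping_genes = paste(sort(hits), collapse = ","))
  })
  out <- list_rbind(unname(rows))
  out$q <- bh_fdr(out$p)$q
  out <- arrange(out, .data$p, .data$set_name)
  out <- select(out, "set_name", "overlap_count", "set_size", "query_size",
                "universe_size", "p", "q", "overlapping_genes")
  attr(out, "n_query_dropped") <- n_dropped
  class(out) <- c("bft_enrichment", class(out))
  out
}

#' Compute specificity-index probabilities (pSI)
#'
#' For each gene and cell type, the specificity statistic is the gene's
#' mean expression in that cell type minus its mean over all other types.
#' Its probability (pSI) is calibrated against a permutation null built by
#' shuffling each gene's profile across cell types (`n_permutations`
#' replicates, pooled within statistic sign conventions): small pSI marks
#' genes specifically expressed in one cell type. Constant genes get
#' pSI = 1. Deterministic under a fixed seed.
#'
#' @param cell_expression Gene x cell-type mean expression matrix (>= 50
#'   genes, >= 2 cell types).
#' @param n_permutations Row-shuffle replicates (default 100).
#' @param seed Integer seed.
#' @param thresholds Marker thresholds carried with the table.
#' @return Gene x cell-type matrix of class `bft_psi` with a `thresholds`
#'   attribute.
#' @export
compute_psi <- function(cell_expression, n_permutations = 100, seed = 1L,
                        thresholds = c(0.05, 0.01, 0.001, 1e-4)) {
  m <- as.matrix(cell_expression)
  if (ncol(m) < 2) {
    bft_stop("Need >= 2 cell types.", "bftrans_error_invalid_argument")
  }
  if (nrow(m) < 50) {
    bft_stop("Need >= 50 genes.", "bftrans_error_invalid_argument")
  }
  set.seed(seed)
  C <- ncol(m)
  stat <- m * (C / (C - 1)) - rowMeans(m) * (C / (C - 1))
  constant <- apply(m, 1, function(r) max(r) == min(r))
  # pooled permutation null: shuffle each gene's profile across types
  null <- numeric(0)
  for (b in seq_len(n_permutations)) {
    perm <- t(apply(m, 1, sample))
    ns <- perm * (C / (C - 1)) - rowMeans(perm) * (C / (C - 1))
    null <- c(null, as.vector(ns))
  }
  null <- sort(null)
  nn <- length(null)
  # upper-tail probability with add-one correction
  psi <- matrix((nn - findInterval(stat, null) + 1) / (nn + 1),
                nrow(m), C, dimnames = dimnames(m))
  psi[psi > 1] <- 1
  psi[constant, ] <- 1
  structure(psi, thresholds = thresholds, class = c("bft_psi", "matrix"))
}

#' Marker sets at a pSI threshold
#'
#' @param psi A [compute_psi()] table.
#' @param threshold pSI cutoff; genes with `pSI < threshold` are markers.
#' @return Named list of marker gene vectors per cell type.
#' @export
psi_marker_sets <- function(psi, threshold) {
  cols <- colnames(psi)
  setNames(lapply(cols, function(ct) {
    rownames(psi)[psi[, ct] < threshold]
  }), cols)
}

#' Cell-type specific expression analysis (CSEA-style)
#'
#' At each pSI threshold, forms the per-cell-type marker set and runs the
#' hypergeometric overlap test against the query; FDR is taken jointly
#' across the whole (cell type x threshold) grid by default. Marker sets
#' at stricter thresholds are nested subsets of looser ones, giving the
#' classic nested-hexagon readout.
#'
#' @param query Gene list.
#' @param psi A [compute_psi()] table.
#' @param universe Background genes (default: pSI rownames).
#' @param thresholds Subset of the pSI table's thresholds.
#' @param joint_fdr FDR across the full grid (default) or per threshold.
#' @return Tibble of class `bft_csea`: cell_type, threshold, overlap_count,
#'   set_size, query_size, p, q, significant (q < 0.10); empty marker sets
#'   yield NA rows.
#' @export
csea_enrich <- function(query, psi, universe = NULL,
                        thresholds = NULL, joint_fdr = TRUE) {
  thresholds <- thresholds %||% attr(psi, "thresholds")
  if (!all(thresholds %in% attr(psi, "thresholds"))) {
    bft_stop("`thresholds` must be a subset of the pSI table's thresholds.",
             "bftrans_error_invalid_argument")
  }
  universe <- universe %||% rownames(psi)
  query <- intersect(unique(query), universe)
  rows <- list()
  for (th in sort(thresholds, decreasing = TRUE)) {
    markers <- psi_marker_sets(psi, th)
    for (ct in colnames(psi)) {
      set <- intersect(markers[[ct]], universe)
      if (length(set) == 0) {
        rows[[length(rows) + 1]] <- tibble(
          cell_type = ct, threshold = th, overlap_count = NA_integer_,
          set_size = 0L, query_size = length(query), p = NA_real_)
        next
      }
      k <- length(intersect(query, set))
      p <- phyper(k - 1, length(set), length(universe) - length(set),
                  length(query), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        cell_type = ct, threshold = th, overlap_count = as.integer(k),
        set_size = length(set), query_size = length(query), p = p)
    }
  }
  out <- list_rbind(rows)
  out$q <- NA_real_
  if (joint_fdr) {
    ok <- !is.na(out$p)
    if (any(ok)) out$q[ok] <- bh_fdr(out$p[ok])$q
  } else {
    for (th in unique(out$threshold)) {
      ok <- out$threshold == th & !is.na(out$p)
      if (any(ok)) out$q[ok] <- bh_fdr(out$p[ok])$q
    }
  }
  out$significant <- !is.na(out$q) & out$q < 0.10
  class(out) <- c("bft_csea", class(out))
  out
}
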