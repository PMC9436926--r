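# Internal helpers shared across modules.

bft_stop <- function(msg, class) {
  abort(msg, class = c(class, "bftrans_error"))
}

check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) {
    bft_stop(sprintf("`%s` must be numeric.", name), "bftrans_error_invalid_argument")
  }
  if (finite && any(!is.finite(x) & !is.na(x))) {
    bft_stop(sprintf("`%s` contains non-finite values.", name),
             "bftrans_error_invalid_argument")
  }
  invisible(x)
}

# Canonical number formatting so that pipeline TSV outputs are diffable:
# 6 significant digits, '.' decimal separator.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(signif(v, 6), format = "g", digits = 6)
  }, character(1))
  out
}

#' Write a table in the pipeline's canonical TSV layout
#'
#' Tab-separated, one header line, LF line ends, numeric columns rounded to
#' 6 significant digits so repeated runs are byte-identical and diffable.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bft_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- format_num(x[[j]])
  }
  write.table(x, file = path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

#' Read a canonical pipeline TSV
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_bft_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# Euclidean distance matrix between two coordinate matrices (rows = points).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

zscore <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}
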