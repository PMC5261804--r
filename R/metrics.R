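# Essentiality-matrix filters, rank percentiles, MPER and the KS rank
# enrichment statistic.

#' Drop cell lines with too many missing PPIs
#'
#' Cell lines with heavy mutation/deletion burdens lose large parts of
#' their context network, leaving many PPIs unscored. Columns whose
#' missing fraction strictly exceeds `max_missing_fraction` are removed.
#'
#' @param matrix numeric PPIs x cell lines matrix (`NA` = missing).
#' @param max_missing_fraction proportion in \[0, 1\] (default 0.2).
#' @return the filtered matrix.
#' @export
filter_cell_lines <- function(matrix, max_missing_fraction = 0.2) {
  stopifnot(is.matrix(matrix))
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("max_missing_fraction must lie in [0, 1]")
  }
  frac <- colMeans(is.na(matrix))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) {
    stop("all cell lines exceed the missing-fraction threshold of ",
         max_missing_fraction)
  }
  matrix[, keep, drop = FALSE]
}

#' Drop PPIs with uniform essentiality across cell lines
#'
#' Rows whose non-missing values have standard deviation at most
#' `epsilon` carry no between-cell-line signal and are removed. Rows
#' with fewer than two non-missing values are treated as uniform.
#'
#' @param matrix numeric PPIs x cell lines matrix.
#' @param epsilon tolerance on the standard deviation (default 1e-12).
#' @return the filtered matrix.
#' @export
filter_uniform_ppis <- function(matrix, epsilon = 1e-12) {
  stopifnot(is.matrix(matrix), epsilon >= 0)
  sds <- apply(matrix, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else stats::sd(x)
  })
  matrix[sds > epsilon, , drop = FALSE]
}

#' Rank percentiles of a vector with missing values
#'
#' Converts values to percentiles `rank / n` over the non-missing
#' entries, with average ranks for ties, so the maximum percentile is
#' exactly 1 and no percentile is 0. Missing values stay missing.
#'
#' @param values numeric vector, possibly with `NA`.
#' @return numeric vector of percentiles in (0, 1\].
#' @export
rank_percentiles <- function(values) {
  n <- sum(!is.na(values))
  if (n == 0L) stop("no non-missing values to rank")
  rank(values, na.last = "keep", ties.method = "average") / n
}

#' PPI-to-maximum-partner essentiality ratio (MPER) for one cell line
#'
#' Compares each PPI's essentiality to the stronger of its two partner
#' proteins. On the default percentile scale, each PPI is ranked among
#' all scored PPIs of the cell line and each protein among all measured
#' proteins; `mper = ppi_percentile / max(partner percentiles)`. Values
#' above 1 flag interactions more critical than either partner's
#' knockdown alone suggests. The raw-score scale
#' (`score / max(partner essentiality)`) is available via `scale`.
#'
#' @param ppi_scores named numeric vector of PPI scores for one cell
#'   line (names are [ppi_id()] identifiers; `NA` allowed).
#' @param protein_essentiality named numeric vector of protein
#'   essentialities in \[0, 1\] for the same cell line.
#' @param cell_line identifier stored in the output.
#' @param scale `"percentile"` (default) or `"raw"`.
#' @return data.frame with columns `ppi`, `cell_line`,
#'   `ppi_percentile`, `max_protein_percentile`, `mper`.
#' @export
compute_mper <- function(ppi_scores, protein_essentiality,
                         cell_line = "cell_line",
                         scale = c("percentile", "raw")) {
  scale <- match.arg(scale)
  if (is.null(names(ppi_scores)) || is.null(names(protein_essentiality))) {
    stop("ppi_scores and protein_essentiality must be named")
  }
  ok <- !is.na(ppi_scores)
  if (!any(ok)) {
    return(data.frame(ppi = character(), cell_line = character(),
                      ppi_percentile = numeric(),
                      max_protein_percentile = numeric(),
                      mper = numeric(), stringsAsFactors = FALSE))
  }
  ids <- names(ppi_scores)[ok]
  partners <- parse_ppi_id(ids)
  known <- partners[, 1L] %in% names(protein_essentiality) &
    partners[, 2L] %in% names(protein_essentiality)
  if (any(!known)) {
    message(sum(!known), " PPI record(s) skipped in '", cell_line,
            "': partner protein missing from the essentiality profile")
  }
  if (scale == "percentile") {
    ppi_pct <- rank_percentiles(ppi_scores)[ok]
    prot_pct <- rank_percentiles(protein_essentiality)
    maxp <- pmax(prot_pct[partners[, 1L]], prot_pct[partners[, 2L]])
  } else {
    ppi_pct <- ppi_scores[ok]
    maxp <- pmax(protein_essentiality[partners[, 1L]],
                 protein_essentiality[partners[, 2L]])
  }
  res <- data.frame(ppi = ids, cell_line = cell_line,
                    ppi_percentile = unname(ppi_pct),
                    max_protein_percentile = unname(maxp),
                    mper = unname(ppi_pct / maxp),
                    stringsAsFactors = FALSE)
  res <- res[known & !is.na(res$max_protein_percentile) &
               res$max_protein_percentile > 0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' MPER across all cell lines of an essentiality matrix
#'
#' @param ppi_matrix PPIs x cell lines matrix from [score_matrix()].
#' @param protein_matrix genes x cell lines matrix of protein
#'   essentialities in \[0, 1\] (e.g. columns of
#'   [normalize_protein_essentiality()]).
#' @param scale passed to [compute_mper()].
#' @return long data.frame of MPER records across cell lines.
#' @export
mper_matrix <- function(ppi_matrix, protein_matrix,
                        scale = c("percentile", "raw")) {
  scale <- match.arg(scale)
  shared <- intersect(colnames(ppi_matrix), colnames(protein_matrix))
  if (!length(shared)) stop("no shared cell lines between the matrices")
  out <- lapply(shared, function(cl) {
    prot <- protein_matrix[, cl]
    compute_mper(ppi_matrix[, cl], prot[!is.na(prot)],
                 cell_line = cl, scale = scale)
  })
  do.call(rbind, out)
}

#' Signed KS statistic of rank percentiles against uniform
#'
#' Measures whether a PPI's rank percentiles across a group of cell
#' lines sit consistently above (positive) or below (negative) the
#' uniform distribution. With sorted percentiles `x_(1) <= ... <= x_(n)`
#' and empirical CDF `F`, the one-sided deviations are
#' `D+ = max_i (x_(i) - (i - 1) / n)` and `D- = max_i (i / n - x_(i))`;
#' the statistic is `D+` when the distribution sits above uniform
#' (high ranks) and `-D-` otherwise. Values near +1 mean the PPI is
#' consistently top-ranked in the group.
#'
#' @param percentiles numeric vector in \[0, 1\].
#' @return signed statistic in \[-1, 1\].
#' @export
ks_rank_statistic <- function(percentiles) {
  x <- percentiles[!is.na(percentiles)]
  if (!length(x)) stop("no percentiles supplied")
  if (any(x < 0 | x > 1)) stop("percentiles must lie in [0, 1]")
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  d_plus <- max(x - (i - 1) / n)
  d_minus <- max(i / n - x)
  if (d_plus >= d_minus) d_plus else -d_minus
}

#' Most essential PPIs by mean essentiality
#'
#' @param matrix PPIs x cell lines essentiality matrix.
#' @param min_mean threshold on the mean over non-missing values
#'   (strictly greater; default 0.5).
#' @return data.frame `ppi`, `mean_essentiality`, `n_cell_lines`,
#'   sorted by decreasing mean with lexicographic tie-break on the PPI
#'   identifier.
#' @export
top_ppis <- function(matrix, min_mean = 0.5) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) == 0L) stop("empty essentiality matrix")
  means <- rowMeans(matrix, na.rm = TRUE)
  ns <- rowSums(!is.na(matrix))
  keep <- !is.nan(means) & means > min_mean
  res <- data.frame(ppi = rownames(matrix)[keep],
                    mean_essentiality = unname(means[keep]),
                    n_cell_lines = unname(ns[keep]),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$mean_essentiality, res$ppi), , drop = FALSE]
  rownames(res) <- NULL
  res
}
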