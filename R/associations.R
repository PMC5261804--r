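# Drug-sensitivity and mutation-stratified association screens.

#' Correlate a PPI's essentiality with drug sensitivity
#'
#' Pearson correlation between per-cell-line PPI essentiality and drug
#' sensitivity AUC, over the cell lines where both are observed (cell
#' lines in which the PPI is context-absent are excluded). The p-value
#' is the two-sided t transform with `n - 2` degrees of freedom.
#'
#' @param ppi_scores named numeric vector (cell line -> essentiality;
#'   `NA` = PPI absent).
#' @param auc named numeric vector (cell line -> AUC).
#' @return list with `r`, `p`, `n`.
#' @export
correlate_drug_sensitivity <- function(ppi_scores, auc) {
  if (is.null(names(ppi_scores)) || is.null(names(auc))) {
    stop("ppi_scores and auc must be named by cell line")
  }
  shared <- intersect(names(ppi_scores), names(auc))
  x <- ppi_scores[shared]
  y <- auc[shared]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 cell lines with both essentiality and AUC (got ",
         length(x), ")")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in essentiality or AUC vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Standardized one-sided rank-sum z (group A greater), with tie
# correction; comparable across permutations with differing group sizes.
rank_sum_z <- function(ranks, in_a, n_total, tie_term) {
  n_a <- sum(in_a)
  n_b <- n_total - n_a
  if (n_a == 0L || n_b == 0L) return(NA_real_)
  w <- sum(ranks[in_a])
  mu <- n_a * (n_total + 1) / 2
  sigma2 <- n_a * n_b / 12 * ((n_total + 1) - tie_term)
  if (sigma2 <= 0) return(0)
  (w - mu) / sqrt(sigma2)
}

#' Drug-target enrichment of PPI essentiality with permutation FDR
#'
#' Tests whether PPIs touching a compound's target genes are more
#' essential than PPIs that do not, pooling all non-missing essentiality
#' values of each group across cell lines. The statistic is the
#' standardized one-sided Wilcoxon rank-sum z (target group greater)
#' with normal-approximation p. The permutation FDR redraws the target
#' set (same size) uniformly from the network's gene universe `n_perm`
#' times and reports the fraction of relabelings whose standardized
#' statistic reaches the observed one, floored at `1 / n_perm`.
#'
#' @param matrix PPIs x cell lines essentiality matrix (rownames are
#'   [ppi_id()] identifiers).
#' @param targets character vector of target gene symbols.
#' @param n_perm number of permutations (>= 100, default 1000); 0 skips
#'   the permutation FDR (`perm_fdr = NA`).
#' @param seed optional integer seed for the permutation stream.
#' @return list with `statistic` (z), `p`, `perm_fdr`, `perm_label`,
#'   `n_target_values`, `n_other_values`, `evaluable`.
#' @export
target_enrichment <- function(matrix, targets, n_perm = 1000L,
                              seed = NULL) {
  stopifnot(is.matrix(matrix))
  if (is.null(rownames(matrix))) stop("matrix must have PPI rownames")
  if (n_perm != 0L && n_perm < 100L) {
    stop("n_perm must be 0 (skip) or at least 100")
  }
  partners <- parse_ppi_id(rownames(matrix))
  universe <- sort(unique(as.vector(partners)))
  tgt <- intersect(unique(targets), universe)
  row_is_target <- partners[, 1L] %in% tgt | partners[, 2L] %in% tgt
  if (!any(row_is_target)) {
    return(list(statistic = NA_real_, p = NA_real_, perm_fdr = NA_real_,
                perm_label = NA_character_, n_target_values = 0L,
                n_other_values = NA_integer_, evaluable = FALSE))
  }
  if (all(row_is_target)) {
    stop("degenerate split: every PPI touches a target gene; ",
         "no non-target group to compare against")
  }
  vals <- as.vector(matrix)
  row_of <- rep(seq_len(nrow(matrix)), times = ncol(matrix))
  ok <- !is.na(vals)
  vals <- vals[ok]
  row_of <- row_of[ok]
  if (!length(vals)) stop("essentiality matrix has no non-missing values")
  ranks <- rank(vals)
  n_total <- length(vals)
  ties <- table(vals)
  tie_term <- sum(ties^3 - ties) / (n_total * (n_total - 1))

  in_a <- row_is_target[row_of]
  z_obs <- rank_sum_z(ranks, in_a, n_total, tie_term)
  if (is.na(z_obs)) stop("one of the comparison groups has no values")
  p <- stats::pnorm(z_obs, lower.tail = FALSE)

  perm_fdr <- NA_real_
  perm_label <- NA_character_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    g1 <- match(partners[, 1L], universe)
    g2 <- match(partners[, 2L], universe)
    n_exceed <- 0L
    for (b in seq_len(n_perm)) {
      member <- logical(length(universe))
      member[sample.int(length(universe), length(tgt))] <- TRUE
      perm_target_row <- member[g1] | member[g2]
      z_b <- rank_sum_z(ranks, perm_target_row[row_of], n_total, tie_term)
      if (!is.na(z_b) && z_b >= z_obs) n_exceed <- n_exceed + 1L
    }
    perm_fdr <- max(n_exceed, 1L) / n_perm
    perm_label <- if (n_exceed == 0L) paste0("<", format(1 / n_perm))
                  else format(n_exceed / n_perm)
  }
  list(statistic = z_obs, p = p, perm_fdr = perm_fdr,
       perm_label = perm_label,
       n_target_values = sum(in_a), n_other_values = sum(!in_a),
       evaluable = TRUE)
}

#' Mutation-stratified differential PPI essentiality
#'
#' Compares each PPI's essentiality between mutant and wild-type cell
#' lines with a two-sample unequal-variance (Welch) t test and adjusts
#' the two-sided p-values across PPIs by Benjamini-Hochberg. PPIs with
#' fewer than two non-missing values in either group are skipped.
#' The statistic's sign is mutant minus wild-type.
#'
#' @param matrix PPIs x cell lines essentiality matrix.
#' @param group_labels named character vector (cell line -> `"mutant"`
#'   or `"wildtype"`).
#' @return data.frame `ppi`, `statistic`, `p`, `adjusted`, `n_mutant`,
#'   `n_wildtype`, sorted by adjusted then raw p.
#' @export
differential_essentiality <- function(matrix, group_labels) {
  stopifnot(is.matrix(matrix))
  if (is.null(names(group_labels))) {
    stop("group_labels must be named by cell line")
  }
  if (!all(group_labels %in% c("mutant", "wildtype"))) {
    stop("group labels must be 'mutant' or 'wildtype'")
  }
  mut <- intersect(colnames(matrix), names(group_labels)[group_labels == "mutant"])
  wt <- intersect(colnames(matrix), names(group_labels)[group_labels == "wildtype"])
  if (!length(mut) || !length(wt)) {
    stop("need at least one mutant and one wild-type cell line in the matrix")
  }
  res <- lapply(seq_len(nrow(matrix)), function(i) {
    x <- matrix[i, mut]; x <- x[!is.na(x)]
    y <- matrix[i, wt]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stat <- 0; p <- 1  # constant in both groups: no evidence either way
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(ppi = rownames(matrix)[i], statistic = stat, p = p,
               n_mutant = length(x), n_wildtype = length(y),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped > 0L) {
    message(skipped, " PPI(s) skipped: fewer than two values in a group")
  }
  res <- do.call(rbind, res)
  if (is.null(res)) {
    stop("no PPI had at least two non-missing values in both groups")
  }
  res$adjusted <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$adjusted, res$p), c("ppi", "statistic", "p",
                                           "adjusted", "n_mutant",
                                           "n_wildtype")]
  rownames(res) <- NULL
  res
}
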