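# Patient survival splitting by PPI presence: log-rank test from the
# risk-table definition, Benjamini-Yekutieli correction, QQ expectation,
# and the combined survival screen.

# Variant classes that remove a PPI when they hit a partner gene.
.loss_variant_classes <- c("nonsense", "frameshift")
# Variant classes that are recognized but do not remove a PPI.
.neutral_variant_classes <- c("missense", "silent", "splice_site",
                              "in_frame_indel", "nonstop", "wildtype",
                              "none")

#' Is a PPI present in a patient?
#'
#' A PPI is absent in a patient iff either partner gene carries a
#' nonsense mutation, a frameshift mutation, or a homozygous deletion.
#' Other recognized variant classes (e.g. missense, silent) leave the
#' PPI intact; records with an unknown variant class are ignored with a
#' warning.
#'
#' @param mutations data.frame with columns `gene`, `variant_class`
#'   and optionally `copy_state` (`"homozygous_deletion"` marks a
#'   deletion; anything else is copy-neutral).
#' @param ppi length-2 character vector of partner gene symbols, or a
#'   single [ppi_id()] identifier.
#' @return logical: `TRUE` if the patient retains the PPI.
#' @export
ppi_presence_from_patient <- function(mutations, ppi) {
  if (length(ppi) == 1L) ppi <- as.vector(parse_ppi_id(ppi))
  stopifnot(length(ppi) == 2L)
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  if (!all(c("gene", "variant_class") %in% names(mutations))) {
    stop("mutations must have columns 'gene' and 'variant_class'")
  }
  if (is.null(mutations$copy_state)) {
    mutations$copy_state <- rep("neutral", nrow(mutations))
  }
  known <- mutations$variant_class %in%
    c(.loss_variant_classes, .neutral_variant_classes)
  if (any(!known)) {
    warning(sum(!known), " mutation record(s) ignored: unknown variant class ",
            paste(unique(mutations$variant_class[!known]), collapse = ", "))
    mutations <- mutations[known, , drop = FALSE]
  }
  hit <- mutations$gene %in% ppi &
    (mutations$variant_class %in% .loss_variant_classes |
       mutations$copy_state == "homozygous_deletion")
  !any(hit)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df), implemented from the
#' risk-table definition: at each distinct event time the observed
#' group-1 deaths are compared with their hypergeometric expectation
#' given the pooled deaths and the numbers at risk, and the variance is
#' the hypergeometric variance; ties are handled by simultaneous
#' risk-set accounting.
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = death, 0 = censored).
#' @param groups two-level group labels.
#' @return list with `chisq`, `p`, `observed`, `expected` (per group),
#'   `n`, `evaluable`. If one group is empty the result is flagged not
#'   evaluable (`chisq`/`p` are `NA`).
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  if (any(is.na(times)) || any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  groups <- as.factor(as.character(groups))
  lev <- levels(groups)
  if (length(lev) > 2L) stop("log-rank test supports exactly two groups")
  if (length(lev) < 2L || any(table(groups) == 0L)) {
    return(list(chisq = NA_real_, p = NA_real_, observed = NA, expected = NA,
                n = length(times), evaluable = FALSE))
  }
  g1 <- groups == lev[1L]
  event_times <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  o2 <- e2 <- 0
  for (tj in event_times) {
    at_risk <- times >= tj
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(times == tj & events == 1)
    d1_j <- sum(times == tj & events == 1 & g1)
    o1 <- o1 + d1_j
    o2 <- o2 + (d_j - d1_j)
    exp1 <- d_j * n1_j / n_j
    e1 <- e1 + exp1
    e2 <- e2 + d_j * (n_j - n1_j) / n_j
    if (n_j > 1L) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) *
        (n_j - d_j) / (n_j - 1)
    }
  }
  if (v == 0) {
    chisq <- 0
    p <- 1
  } else {
    chisq <- (o1 - e1)^2 / v
    p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  }
  list(chisq = chisq, p = p,
       observed = stats::setNames(c(o1, o2), lev),
       expected = stats::setNames(c(e1, e2), lev),
       n = length(times), evaluable = TRUE)
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary
#' dependence: the Benjamini-Hochberg factor is inflated by the harmonic
#' sum `c(m) = sum(1 / (1:m))`; results are monotone and capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
by_correction <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BY")
}

#' Expected vs observed quantiles for a QQ plot of p-values
#'
#' @param p_values numeric vector of p-values.
#' @return data.frame with `expected` (`i / (m + 1)`), `observed`
#'   (sorted ascending) and their `-log10` transforms.
#' @export
qq_expected <- function(p_values) {
  if (!length(p_values)) stop("no p-values supplied")
  m <- length(p_values)
  obs <- sort(p_values)
  exp <- seq_len(m) / (m + 1)
  data.frame(expected = exp, observed = obs,
             neglog10_expected = -log10(exp),
             neglog10_observed = -log10(obs))
}

#' Survival screen over PPIs with cell-line essentiality gating
#'
#' Runs the two-stage screen: per PPI, a two-group log-rank test of
#' patient survival by PPI presence; across PPIs, Benjamini-Yekutieli
#' adjustment of the log-rank p-values; then selection of the PPIs that
#' pass both the nominal log-rank threshold and the KS rank-enrichment
#' threshold in the matched cell-line group (consistently top-ranked
#' essentiality, e.g. in lung adenocarcinoma lines).
#'
#' @param logrank_results data.frame with columns `ppi` and `p`
#'   (nominal log-rank p per PPI), e.g. assembled from [logrank_test()].
#' @param ks_statistics named numeric vector (PPI -> KS rank statistic
#'   from [ks_rank_statistic()]).
#' @param ks_threshold minimum KS statistic (strict; default 0.5).
#' @param alpha nominal log-rank threshold (strict; default 0.05).
#' @return data.frame of passing PPIs with `ppi`, `p`, `by_adjusted`,
#'   `ks`, sorted by nominal p.
#' @export
survival_screen <- function(logrank_results, ks_statistics,
                            ks_threshold = 0.5, alpha = 0.05) {
  logrank_results <- as.data.frame(logrank_results,
                                   stringsAsFactors = FALSE)
  if (!all(c("ppi", "p") %in% names(logrank_results))) {
    stop("logrank_results must have columns 'ppi' and 'p'")
  }
  ok <- !is.na(logrank_results$p)
  logrank_results <- logrank_results[ok, , drop = FALSE]
  logrank_results$by_adjusted <- by_correction(logrank_results$p)
  logrank_results$ks <- unname(ks_statistics[logrank_results$ppi])
  keep <- logrank_results$p < alpha & !is.na(logrank_results$ks) &
    logrank_results$ks > ks_threshold
  res <- logrank_results[keep, c("ppi", "p", "by_adjusted", "ks"),
                         drop = FALSE]
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-PPI patient survival tests from mutation and clinical tables
#'
#' Assembles, for each PPI in the superpathway (or a supplied subset),
#' the patient presence/absence split from the mutation table and runs
#' the log-rank test against the clinical follow-up data.
#'
#' @param mutations data.frame with columns `patient`, `gene`,
#'   `variant_class` and optionally `copy_state`.
#' @param clinical data.frame with columns `patient`, `time`, `event`.
#' @param ppis character vector of [ppi_id()] identifiers to test.
#' @return data.frame `ppi`, `chisq`, `p`, `n_present`, `n_absent`
#'   (log-rank `p` is `NA` when one group is empty).
#' @export
patient_ppi_logrank <- function(mutations, clinical, ppis) {
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  if (!all(c("patient", "gene", "variant_class") %in% names(mutations))) {
    stop("mutations must have columns patient, gene, variant_class")
  }
  if (!all(c("patient", "time", "event") %in% names(clinical))) {
    stop("clinical must have columns patient, time, event")
  }
  if (is.null(mutations$copy_state)) {
    mutations$copy_state <- rep("neutral", nrow(mutations))
  }
  # pre-index loss events per gene for speed
  loss <- mutations[mutations$variant_class %in% .loss_variant_classes |
                      mutations$copy_state == "homozygous_deletion",
                    c("patient", "gene")]
  res <- lapply(ppis, function(id) {
    partners <- as.vector(parse_ppi_id(id))
    absent_patients <- unique(loss$patient[loss$gene %in% partners])
    present <- !(clinical$patient %in% absent_patients)
    lr <- logrank_test(clinical$time, clinical$event,
                       ifelse(present, "present", "absent"))
    data.frame(ppi = id, chisq = lr$chisq, p = lr$p,
               n_present = sum(present), n_absent = sum(!present),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
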