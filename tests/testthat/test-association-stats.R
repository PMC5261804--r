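# Drug, mutation and survival screens.

test_that("correlate_drug_sensitivity recovers exact linear relations", {
  x <- setNames(seq(0.1, 1, length.out = 10), sprintf("CL%02d", 1:10))
  expect_equal(correlate_drug_sensitivity(x, 2 * x)$r, 1.0)
  expect_equal(correlate_drug_sensitivity(x, -x)$r, -1.0)
})

test_that("correlation matches the definitional formula oracle", {
  set.seed(14)
  x <- setNames(rnorm(8), sprintf("CL%02d", 1:8))
  y <- setNames(0.5 * x + rnorm(8), names(x))
  res <- correlate_drug_sensitivity(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_direct * sqrt((8 - 2) / (1 - r_direct^2))
  p_direct <- 2 * pt(abs(t_stat), df = 6, lower.tail = FALSE)
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  expect_equal(res$p, p_direct, tolerance = 1e-12)
  expect_equal(res$n, 8)
})

test_that("correlation validates sample size, missingness and variance", {
  x <- setNames(c(0.1, 0.5, NA), c("a", "b", "c"))
  y <- setNames(c(1, 2, 3), c("a", "b", "c"))
  expect_error(correlate_drug_sensitivity(x, y), "at least 3")
  z <- setNames(rep(1, 5), letters[1:5])
  v <- setNames(rnorm(5), letters[1:5])
  expect_error(correlate_drug_sensitivity(z, v), "zero variance")
})

test_that("target_enrichment flags a planted target-gene effect", {
  set.seed(19)
  genes <- sprintf("T%02d", 1:20)
  targets <- genes[1:4]
  pairs <- t(combn(genes, 2))
  ids <- ppi_id(pairs[, 1], pairs[, 2])
  touches <- pairs[, 1] %in% targets | pairs[, 2] %in% targets
  vals <- ifelse(touches, rbeta(length(ids), 8, 2), rbeta(length(ids), 2, 8))
  m <- matrix(vals, ncol = 1, dimnames = list(ids, "CL01"))
  res <- target_enrichment(m, targets, n_perm = 1000, seed = 2)
  expect_true(res$evaluable)
  expect_lt(res$perm_fdr, 0.01)
  expect_lt(res$p, 1e-10)
})

test_that("target_enrichment handles degenerate target sets", {
  m <- toy_matrix(runif(12), ppi_id(LETTERS[1:4], LETTERS[5:8]))
  res <- target_enrichment(m, c("ZZ1", "ZZ2"), n_perm = 0)
  expect_false(res$evaluable)
  expect_true(is.na(res$statistic))
  expect_error(target_enrichment(m, LETTERS[1:8], n_perm = 0), "degenerate")
  expect_error(target_enrichment(m, "A", n_perm = 50), "at least 100")
})

test_that("enrichment normal-approximation p matches wilcox.test", {
  set.seed(31)
  genes <- sprintf("W%02d", 1:12)
  pairs <- t(combn(genes, 2))
  ids <- ppi_id(pairs[, 1], pairs[, 2])
  m <- matrix(runif(length(ids)), ncol = 1, dimnames = list(ids, "CL01"))
  targets <- genes[1:3]
  res <- target_enrichment(m, targets, n_perm = 0)
  touches <- pairs[, 1] %in% targets | pairs[, 2] %in% targets
  wt <- wilcox.test(m[touches, 1], m[!touches, 1],
                    alternative = "greater", exact = FALSE, correct = FALSE)
  expect_equal(res$p, wt$p.value, tolerance = 1e-10)
})

test_that("permutation FDR is invariant to relabeling non-target genes", {
  set.seed(4)
  genes <- sprintf("R%02d", 1:10)
  pairs <- t(combn(genes, 2))
  ids <- ppi_id(pairs[, 1], pairs[, 2])
  vals <- runif(length(ids))
  m <- matrix(vals, ncol = 1, dimnames = list(ids, "CL01"))
  # relabel non-target genes among themselves: swap R05 <-> R09
  swap <- setNames(genes, genes)
  swap[c("R05", "R09")] <- c("R09", "R05")
  pairs2 <- matrix(swap[pairs], ncol = 2)
  ids2 <- ppi_id(pairs2[, 1], pairs2[, 2])
  m2 <- matrix(vals, ncol = 1, dimnames = list(ids2, "CL01"))
  r1 <- target_enrichment(m, c("R01", "R02"), n_perm = 200, seed = 7)
  r2 <- target_enrichment(m2, c("R01", "R02"), n_perm = 200, seed = 7)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$perm_fdr, r2$perm_fdr)
})

test_that("differential_essentiality recovers a planted mutant shift", {
  set.seed(27)
  lines <- sprintf("CL%02d", 1:24)
  labels <- setNames(rep(c("mutant", "wildtype"), each = 12), lines)
  ids <- sprintf("D%02d_E%02d", 1:40, 1:40)
  m <- matrix(runif(40 * 24, 0.2, 0.6), 40, 24,
              dimnames = list(ids, lines))
  planted <- ids[1:5]
  m[planted, labels == "mutant"] <- m[planted, labels == "mutant"] + 0.3
  res <- differential_essentiality(m, labels)
  expect_setequal(res$ppi[1:5], planted)
  expect_true(all(res$adjusted[1:5] < 0.01))
  expect_true(all(res$statistic[res$ppi %in% planted] > 0))
})

test_that("differential_essentiality is calibrated on null labels", {
  set.seed(41)
  lines <- sprintf("CL%02d", 1:30)
  labels <- setNames(rep(c("mutant", "wildtype"), c(10, 20)), lines)
  ids <- sprintf("N%03d_M%03d", 1:200, 1:200)
  m <- matrix(rnorm(200 * 30), 200, 30, dimnames = list(ids, lines))
  res <- differential_essentiality(m, labels)
  frac <- mean(res$p < 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
  # single PPI, equal group means and variances: statistic near zero
  v <- c(0.5, 0.52, 0.48, 0.51, 0.49, 0.5, 0.53, 0.47, 0.5, 0.5)
  m1 <- matrix(c(v, v), 1, 20,
               dimnames = list("A_B", sprintf("CL%02d", 1:20)))
  lab1 <- setNames(rep(c("mutant", "wildtype"), each = 10), colnames(m1))
  res1 <- differential_essentiality(m1, lab1)
  expect_lt(abs(res1$statistic), 1)
  expect_gt(res1$p, 0.3)
})

test_that("differential_essentiality enforces group structure", {
  m <- toy_matrix(runif(8), c("A_B", "C_D"))
  expect_error(differential_essentiality(m, setNames(rep("mutant", 4),
                                                     colnames(m))),
               "wild-type")
  expect_error(differential_essentiality(m, setNames(rep("bad", 4),
                                                     colnames(m))),
               "mutant")
})

test_that("ppi_presence_from_patient implements the absence rule", {
  ppi <- c("JAK1", "PIK3R1")
  expect_false(ppi_presence_from_patient(
    data.frame(gene = "JAK1", variant_class = "nonsense"), ppi))
  expect_false(ppi_presence_from_patient(
    data.frame(gene = "PIK3R1", variant_class = "frameshift"), ppi))
  expect_false(ppi_presence_from_patient(
    data.frame(gene = "JAK1", variant_class = "wildtype",
               copy_state = "homozygous_deletion"), ppi))
  expect_true(ppi_presence_from_patient(
    data.frame(gene = "PIK3R1", variant_class = "missense"), ppi))
  expect_true(ppi_presence_from_patient(
    data.frame(gene = character(), variant_class = character()), ppi))
  # other genes' losses do not matter
  expect_true(ppi_presence_from_patient(
    data.frame(gene = "TP53", variant_class = "nonsense"), ppi))
  expect_warning(
    ok <- ppi_presence_from_patient(
      data.frame(gene = "JAK1", variant_class = "garbled"), ppi),
    "unknown variant class")
  expect_true(ok)
})

test_that("logrank_test is zero on identical groups and handles empties", {
  times <- c(100, 200, 300, 400)
  events <- c(1, 1, 0, 1)
  res <- logrank_test(c(times, times), c(events, events),
                      rep(c("a", "b"), each = 4))
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)
  res2 <- logrank_test(times, events, rep("a", 4))
  expect_false(res2$evaluable)
  expect_true(is.na(res2$p))
})

test_that("logrank_test matches the risk-table oracle and survdiff", {
  # 6-subject worked example with a tie and censoring
  times <- c(50, 120, 120, 200, 250, 400)
  events <- c(1, 1, 1, 0, 1, 0)
  groups <- c("a", "b", "a", "b", "a", "b")
  res <- logrank_test(times, events, groups)
  oracle <- oracle_logrank(times, events, groups == "a")
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  expect_equal(res$chisq, unname(sd$chisq), tolerance = 1e-9)

  # larger random comparison against survdiff
  set.seed(52)
  t2 <- rexp(60, 1 / 300)
  e2 <- rbinom(60, 1, 0.7)
  g2 <- sample(c("x", "y"), 60, replace = TRUE)
  r2 <- logrank_test(t2, e2, g2)
  sd2 <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  expect_equal(r2$chisq, unname(sd2$chisq), tolerance = 1e-9)
})

test_that("logrank_test detects a planted hazard-ratio-3 effect", {
  set.seed(60)
  n <- 200
  grp <- rep(c("present", "absent"), each = n / 2)
  rate <- ifelse(grp == "present", 3 / 1500, 1 / 1500)
  t_ev <- rexp(n, rate)
  times <- pmin(t_ev, 3000)
  events <- as.integer(t_ev <= 3000)
  res <- logrank_test(times, events, grp)
  expect_lt(res$p, 0.01)
})

test_that("by_correction matches the harmonic-factor formula", {
  expect_equal(by_correction(0.03), 0.03)
  p4 <- rep(0.01, 4)
  expect_equal(by_correction(p4), rep(0.01 * (25 / 12), 4))
  set.seed(9)
  p <- runif(50)
  expect_equal(by_correction(p), oracle_by(p), tolerance = 1e-12)
  # inflation: BY >= BH >= raw
  expect_true(all(by_correction(p) >= p.adjust(p, "BH")))
  expect_true(all(p.adjust(p, "BH") >= p))
  mono <- sort(runif(10))
  expect_true(all(by_correction(mono) >= mono))
  expect_error(by_correction(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("qq_expected pairs sorted observed with i/(m+1) expectations", {
  out <- qq_expected(c(0.5, 0.1, 0.9))
  expect_equal(out$expected, c(0.25, 0.5, 0.75))
  expect_equal(out$observed, c(0.1, 0.5, 0.9))
  expect_equal(out$neglog10_observed, -log10(c(0.1, 0.5, 0.9)))
  # uniform null: points near the diagonal
  set.seed(71)
  qq <- qq_expected(runif(1000))
  expect_lt(max(abs(qq$expected - qq$observed)), 0.06)
  # planted signal: early quantiles above the diagonal in -log10 space
  qq2 <- qq_expected(c(rbeta(100, 0.2, 4), runif(900)))
  head_pts <- head(qq2, 50)
  expect_true(all(head_pts$neglog10_observed > head_pts$neglog10_expected))
})

test_that("survival_screen gates on both log-rank p and KS statistic", {
  set.seed(83)
  n_ppi <- 100
  ids <- sprintf("S%03d_T%03d", 1:n_ppi, 1:n_ppi)
  p_null <- runif(n_ppi)
  ks <- setNames(runif(n_ppi, -0.4, 0.45), ids)
  planted <- ids[1]
  p_null[1] <- 1e-4
  ks[planted] <- 0.9
  lr <- data.frame(ppi = ids, p = p_null)
  hits <- survival_screen(lr, ks, ks_threshold = 0.5, alpha = 0.05)
  expect_equal(hits$ppi, planted)
  expect_true(hits$by_adjusted >= hits$p)
  # unattainable KS bound: empty result
  expect_equal(nrow(survival_screen(lr, ks, ks_threshold = 1.0)), 0)
  # nominal filter alone passes roughly alpha * n_ppi PPIs
  expect_lt(sum(p_null < 0.05), 15)
})

test_that("patient_ppi_logrank assembles presence splits per PPI", {
  set.seed(90)
  patients <- sprintf("PT%03d", 1:60)
  absent <- patients[1:24]
  mutations <- data.frame(
    patient = c(absent, patients[25:30]),
    gene = c(rep("JAK1", 24), rep("TP53", 6)),
    variant_class = c(rep("nonsense", 24), rep("missense", 6)),
    stringsAsFactors = FALSE)
  rate <- ifelse(patients %in% absent, 1 / 1500, 3 / 1500)
  t_ev <- rexp(60, rate)
  clinical <- data.frame(patient = patients,
                         time = pmin(t_ev, 3000),
                         event = as.integer(t_ev <= 3000))
  res <- patient_ppi_logrank(mutations, clinical,
                             c("JAK1_PIK3R1", "ATM_NBN"))
  expect_equal(res$n_absent, c(24L, 0L))
  expect_lt(res$p[1], 0.05)
  expect_true(is.na(res$p[2]))  # no absent group for ATM-NBN
})
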