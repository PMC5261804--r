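# Dual-graph construction and essentiality propagation.

test_that("build_dual_graph applies the exponential kernel to shared proteins", {
  net <- context_network("cl", data.frame(a = c("A", "B"), b = c("B", "C")),
                         c(A = 0.2, B = 0.6, C = 0.9))
  dg <- build_dual_graph(net, w = 0.5)
  expect_setequal(dg$ppis, c("A_B", "B_C"))
  expect_equal(nrow(dg$edges), 1)
  expect_equal(dg$edges$shared_protein, "B")
  expect_equal(dg$edges$weight, exp(0.5 * 0.6))

  tri <- context_network("cl",
                         data.frame(a = c("A", "B", "A"), b = c("B", "C", "C")),
                         c(A = 0, B = 0, C = 0))
  dgt <- build_dual_graph(tri, w = 0.5)
  expect_equal(nrow(dgt$edges), 3)
  expect_true(all(dgt$edges$weight == 1))

  star <- context_network("cl",
                          data.frame(a = c("H", "H", "H"),
                                     b = c("X", "Y", "Z")),
                          c(H = 1, X = 0, Y = 0, Z = 0))
  dgs <- build_dual_graph(star, w = 0.5)
  expect_equal(nrow(dgs$edges), choose(3, 2))
  expect_true(all(dgs$edges$shared_protein == "H"))
  expect_true(all(dgs$edges$weight == exp(0.5)))
})

test_that("dual adjacency requires a shared protein and never duplicates", {
  net <- random_context_network(15, 25, seed = 3)
  dg <- build_dual_graph(net, w = 0.5)
  key <- paste(pmin(dg$edges$i, dg$edges$j), pmax(dg$edges$i, dg$edges$j))
  expect_equal(anyDuplicated(key), 0)
  for (r in seq_len(nrow(dg$edges))) {
    a <- dg$pairs[dg$edges$i[r], ]
    b <- dg$pairs[dg$edges$j[r], ]
    expect_length(intersect(a, b), 1)
  }
})

test_that("kernel weight is monotone in shared-protein essentiality", {
  mk <- function(pB) {
    context_network("cl", data.frame(a = c("A", "B"), b = c("B", "C")),
                    c(A = 0, B = pB, C = 0))
  }
  w_lo <- build_dual_graph(mk(0.2), w = 0.5)$edges$weight
  w_hi <- build_dual_graph(mk(0.9), w = 0.5)$edges$weight
  expect_gt(w_hi, w_lo)
  expect_equal(build_dual_graph(mk(0.9), w = 0)$edges$weight, 1)
})

test_that("build_dual_graph rejects empty networks", {
  sp <- merge_pathways(list(P = data.frame(a = "A", b = "B")))
  prof <- gene_essentiality_profile("cl", c(A = -1, B = 2))
  ctx <- cell_line_context("cl", measured_genes = "A")
  net <- apply_context(sp, ctx, prof)
  expect_error(build_dual_graph(net), "no PPIs")
})

test_that("propagate reproduces closed-form stationary scores on paths", {
  single <- context_network("cl", data.frame(a = "A", b = "B"),
                            c(A = 0.5, B = 0.5))
  sv <- propagate(build_dual_graph(single))
  expect_equal(unname(sv$scores), 1.0)

  # path A-B-C-D with w = 0: unit weights, dual strengths (1, 2, 1)
  path4 <- context_network("cl",
                           data.frame(a = c("A", "B", "C"),
                                      b = c("B", "C", "D")),
                           c(A = 0.3, B = 0.3, C = 0.3, D = 0.3))
  sv0 <- propagate(build_dual_graph(path4, w = 0))
  expect_equal(sv0$scores, c(A_B = 0.5, B_C = 1.0, C_D = 0.5),
               tolerance = 1e-8)

  # p_B = 1, p_C = 0, w = 0.5: strengths (e^.5, e^.5 + 1, 1)
  path_w <- context_network("cl",
                            data.frame(a = c("A", "B", "C"),
                                       b = c("B", "C", "D")),
                            c(A = 0.2, B = 1, C = 0, D = 0.9))
  dg <- build_dual_graph(path_w, w = 0.5)
  sv1 <- propagate(dg)
  oracle <- oracle_strength_scores(dg)
  expect_equal(sv1$scores, oracle, tolerance = 1e-8)
  expect_equal(unname(oracle),
               c(exp(0.5), exp(0.5) + 1, 1) / (exp(0.5) + 1))
})

test_that("propagation conserves total mass before normalization", {
  for (seed in 1:4) {
    dg <- build_dual_graph(random_context_network(12, 20, seed))
    sv <- propagate(dg)
    expect_equal(sum(sv$stationary), 1, tolerance = 1e-9)
  }
})

test_that("alpha = 0 is rejected and non-convergence is flagged", {
  expect_error(propagation_config(alpha = 0), "0 < alpha")
  expect_error(propagation_config(alpha = 1.2), "0 < alpha")
  dg <- build_dual_graph(random_context_network(12, 20, seed = 5))
  expect_warning(sv <- propagate(dg, propagation_config(max_iter = 2)),
                 "did not converge")
  expect_false(sv$converged)
})

test_that("averaging mode converges to consensus on connected graphs", {
  for (seed in 1:3) {
    dg <- build_dual_graph(random_context_network(12, 20, seed))
    sv <- propagate(dg, propagation_config(update_mode = "averaging"))
    expect_lt(max(sv$stationary) - min(sv$stationary), 1e-6)
    expect_true(all(abs(sv$scores - 1) < 1e-6))
  }
})

test_that("closed_form_scores agrees with propagate and splits mass by component", {
  # two disjoint components: sizes 2 and 4 dual nodes
  net <- context_network(
    "cl",
    data.frame(a = c("A", "B", "P", "Q", "R", "S"),
               b = c("B", "C", "Q", "R", "S", "P")),
    c(A = 0.5, B = 0.5, C = 0.5, P = 0.2, Q = 0.4, R = 0.6, S = 0.8))
  dg <- build_dual_graph(net)
  cf <- closed_form_scores(dg)
  it <- propagate(dg)
  expect_equal(cf$scores, it$scores, tolerance = 1e-8)
  comp_small <- c("A_B", "B_C")
  expect_equal(sum(cf$stationary[comp_small]), 1 / 3, tolerance = 1e-8)
  expect_equal(sum(cf$stationary[setdiff(dg$ppis, comp_small)]), 2 / 3,
               tolerance = 1e-8)

  # random network: elementwise agreement with the dense eigen oracle
  dg2 <- build_dual_graph(random_context_network(18, 30, seed = 9))
  cf2 <- closed_form_scores(dg2)
  expect_equal(unname(cf2$scores), unname(oracle_eigen_scores(dg2, 0.5)),
               tolerance = 1e-8)
  expect_equal(cf2$scores, propagate(dg2)$scores, tolerance = 1e-8)
})

test_that("isolated dual nodes keep their initial mass", {
  # a lone edge plus a triangle: the lone PPI is an isolated dual node
  net <- context_network(
    "cl",
    data.frame(a = c("A", "P", "Q", "R"), b = c("B", "Q", "R", "P")),
    c(A = 1, B = 1, P = 0.5, Q = 0.5, R = 0.5))
  dg <- build_dual_graph(net)
  sv <- propagate(dg)
  cf <- closed_form_scores(dg)
  expect_equal(unname(sv$stationary["A_B"]), 0.25, tolerance = 1e-10)
  expect_equal(unname(cf$stationary["A_B"]), 0.25, tolerance = 1e-10)
})

test_that("normalize_scores scales by the maximum and validates input", {
  expect_equal(normalize_scores(c(0.25, 0.5, 0.25)), c(0.5, 1.0, 0.5))
  expect_equal(normalize_scores(1.0), 1.0)
  expect_equal(normalize_scores(c(3, 1, 2)), c(1.0, 1 / 3, 2 / 3))
  expect_error(normalize_scores(numeric()), "empty")
  expect_error(normalize_scores(c(0, 0)), "zero")
  expect_error(normalize_scores(c(-1, 2)), "nonnegative")
})

test_that("score_matrix marks context-absent PPIs as missing", {
  sp <- merge_pathways(list(P = data.frame(a = c("A", "B", "C"),
                                           b = c("B", "C", "D"))))
  gene_scores <- matrix(c(-2, -1, 0, 1, -1, -3, -0.5, 0.2),
                        nrow = 4,
                        dimnames = list(c("A", "B", "C", "D"),
                                        c("cl1", "cl2")))
  ctxs <- list(
    cl1 = cell_line_context("cl1", measured_genes = c("A", "B", "C", "D")),
    cl2 = cell_line_context("cl2", lost_genes = "D",
                            measured_genes = c("A", "B", "C", "D")))
  m <- score_matrix(sp, gene_scores, ctxs)
  expect_equal(dim(m), c(3L, 2L))
  expect_false(anyNA(m[, "cl1"]))
  expect_true(is.na(m["C_D", "cl2"]))
  expect_false(anyNA(m[c("A_B", "B_C"), "cl2"]))
  expect_equal(max(m[, "cl1"]), 1)
  expect_equal(max(m[, "cl2"], na.rm = TRUE), 1)
})
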