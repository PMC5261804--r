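# Shared fixtures and independent oracles for the test suite. The
# oracles deliberately re-derive quantities from first principles
# (dense matrices, enumeration, risk tables) rather than calling the
# package's own propagation or test statistics.

# Random connected context network with uniform random essentialities.
random_context_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  n_edges <- max(min(n_edges, n_nodes * (n_nodes - 1) / 2),
                 n_nodes - 1, 2)
  # connected by construction: random spanning tree plus extra edges
  perm <- sample(n_nodes)
  tree <- cbind(perm[-1], perm[vapply(2:n_nodes,
                                      function(i) sample(i - 1, 1),
                                      integer(1))])
  all_pairs <- t(utils::combn(n_nodes, 2))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  pool <- all_pairs[!(key(all_pairs) %in% key(tree)), , drop = FALSE]
  extra <- n_edges - nrow(tree)
  em <- rbind(tree,
              pool[sample(nrow(pool), min(extra, nrow(pool))), ,
                   drop = FALSE])
  syms <- sprintf("N%03d", seq_len(n_nodes))
  p <- stats::setNames(stats::runif(n_nodes), syms)
  context_network("cl", data.frame(protein_1 = syms[em[, 1]],
                                   protein_2 = syms[em[, 2]]),
                  p)
}

# Dense symmetric dual weight matrix, built independently from the
# dual-edge list.
dual_dense_weights <- function(dg) {
  n <- length(dg$ppis)
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(dg$edges))) {
    i <- dg$edges$i[r]; j <- dg$edges$j[r]; w <- dg$edges$weight[r]
    W[i, j] <- W[i, j] + w
    W[j, i] <- W[j, i] + w
  }
  W
}

# Closed-form stationary scores of the mass walk on a CONNECTED dual
# graph: pi proportional to node strength, then divided by the max.
oracle_strength_scores <- function(dg) {
  W <- dual_dense_weights(dg)
  s <- rowSums(W)
  stats::setNames(s / max(s), dg$ppis)
}

# Dense eigendecomposition oracle: leading left eigenvector of
# M = (1 - alpha) I + alpha P on a connected dual graph.
oracle_eigen_scores <- function(dg, alpha) {
  W <- dual_dense_weights(dg)
  P <- W / rowSums(W)
  M <- (1 - alpha) * diag(nrow(P)) + alpha * P
  eg <- eigen(t(M))
  v <- Re(eg$vectors[, which.max(Re(eg$values))])
  v <- v * sign(sum(v))
  stats::setNames(v / max(v), dg$ppis)
}

# Brute-force log-rank chi-square from explicit risk tables.
oracle_logrank <- function(times, events, g1) {
  event_times <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (tj in event_times) {
    n_j <- sum(times >= tj)
    n1_j <- sum(times >= tj & g1)
    d_j <- sum(times == tj & events == 1)
    d1_j <- sum(times == tj & events == 1 & g1)
    o1 <- o1 + d1_j
    e1 <- e1 + d_j * n1_j / n_j
    if (n_j > 1) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  if (v == 0) return(list(chisq = 0, p = 1))
  chisq <- (o1 - e1)^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Direct implementation of the Benjamini-Yekutieli step-up formula.
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exact one-sided rank-sum tail p by enumeration of all group-A
# assignments (feasible for total n <= 10).
oracle_ranksum_exact_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  r <- rank(vals)
  w_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(n, length(x))
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(ws >= w_obs)
}

# Small simulation configuration used where full defaults are not
# needed; keeps unit tests fast.
small_sim_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_proteins = 60L, n_pathways = 4L,
         pathway_size_range = c(10L, 20L), n_cell_lines = 8L,
         n_patients = 60L, n_compounds = 4L),
    list(...))
  do.call(simulation_config, args)
}

# A tiny essentiality matrix with controlled rownames.
toy_matrix <- function(values, ppis, lines = NULL) {
  m <- matrix(values, nrow = length(ppis), byrow = TRUE)
  rownames(m) <- ppis
  colnames(m) <- if (is.null(lines)) sprintf("CL%02d", seq_len(ncol(m)))
                 else lines
  m
}
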