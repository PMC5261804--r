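# Dual (line) graph construction and essentiality propagation.

#' Propagation configuration
#'
#' Bundles the tunable parameters of the PPI essentiality propagation.
#' `alpha` is the smoothing parameter (0 < alpha <= 1): each iteration
#' keeps `(1 - alpha)` of a node's previous score and takes `alpha` from
#' its neighbors. `w` is the exponential kernel coefficient: a dual edge
#' through shared protein `s` carries weight `exp(w * p_s)`, so `w = 0`
#' ignores protein essentiality entirely and larger `w` makes essential
#' proteins dominate. Defaults `alpha = 0.5`, `w = 0.5`.
#'
#' @param alpha smoothing parameter in (0, 1].
#' @param w kernel coefficient, >= 0.
#' @param tol max-norm convergence tolerance for [propagate()].
#' @param max_iter iteration cap.
#' @param update_mode `"mass"` (default; stationary distribution of the
#'   weighted walk, PageRank-style) or `"averaging"` (literal
#'   neighbor-averaging; converges to consensus on connected graphs).
#' @return a `propagation_config` object.
#' @export
propagation_config <- function(alpha = 0.5, w = 0.5, tol = 1e-10,
                               max_iter = 10000L,
                               update_mode = c("mass", "averaging")) {
  update_mode <- match.arg(update_mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("alpha must satisfy 0 < alpha <= 1")
  }
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0) {
    stop("w must be >= 0")
  }
  if (tol <= 0) stop("tol must be positive")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(alpha = alpha, w = w, tol = tol,
                 max_iter = as.integer(max_iter),
                 update_mode = update_mode),
            class = "propagation_config")
}

#' Build the dual (line) graph of a context network
#'
#' Transforms a protein network into its dual: every PPI (edge) becomes a
#' dual node, and two dual nodes are adjacent iff their PPIs share a
#' protein. For a shared protein `s` with degree `d >= 2`, all
#' `choose(d, 2)` pairs of its incident PPIs are connected with weight
#' `exp(w * p_s)`, where `p_s` is the protein's essentiality in \[0, 1\].
#' In a simple graph two distinct edges share at most one endpoint, so
#' duplicate dual edges cannot arise.
#'
#' @param net a `context_network`.
#' @param w kernel coefficient (defaults to 0.5).
#' @return a `dual_graph`: list with `ppis` (identifiers), `pairs`
#'   (two-column symbol matrix) and `edges` (data.frame `i`, `j`,
#'   `shared_protein`, `weight`; `i`, `j` index `ppis`).
#' @export
build_dual_graph <- function(net, w = 0.5) {
  stopifnot(inherits(net, "context_network"))
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0) {
    stop("w must be >= 0")
  }
  e <- net$edges
  if (nrow(e) == 0L) {
    stop("context network has no PPIs to score")
  }
  p <- net$node_essentiality
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("node essentialities must lie in [0, 1]")
  }
  ids <- ppi_id(e$protein_1, e$protein_2)
  incident <- split(rep(seq_len(nrow(e)), 2L),
                    c(e$protein_1, e$protein_2))
  di <- dj <- shared <- vector("list", length(incident))
  k <- 0L
  for (s in names(incident)) {
    inc <- incident[[s]]
    if (length(inc) < 2L) next
    prs <- utils::combn(inc, 2L)
    k <- k + 1L
    di[[k]] <- prs[1L, ]
    dj[[k]] <- prs[2L, ]
    shared[[k]] <- rep(s, ncol(prs))
  }
  di <- unlist(di)
  shared <- unlist(shared)
  edges <- data.frame(
    i = if (is.null(di)) integer() else di,
    j = if (is.null(di)) integer() else unlist(dj),
    shared_protein = if (is.null(di)) character() else shared,
    weight = if (is.null(di)) numeric() else exp(w * unname(p[shared])),
    stringsAsFactors = FALSE)
  structure(list(ppis = ids,
                 pairs = cbind(protein_1 = e$protein_1,
                               protein_2 = e$protein_2),
                 edges = edges, w = w),
            class = "dual_graph")
}

#' @export
print.dual_graph <- function(x, ...) {
  cat("dual graph:", length(x$ppis), "PPIs (dual nodes),",
      nrow(x$edges), "dual edges, w =", x$w, "\n")
  invisible(x)
}

# Symmetric sparse weight matrix of a dual graph.
dual_weight_matrix <- function(dg) {
  n <- length(dg$ppis)
  e <- dg$edges
  Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                       x = c(e$weight, e$weight),
                       dims = c(n, n))
}

# Row-stochastic transition matrix; isolated dual nodes get a self-loop
# so that their mass is retained by the update.
dual_transition_matrix <- function(dg) {
  W <- dual_weight_matrix(dg)
  s <- Matrix::rowSums(W)
  iso <- which(s == 0)
  if (length(iso)) {
    W <- W + Matrix::sparseMatrix(i = iso, j = iso, x = 1,
                                  dims = dim(W))
    s[iso] <- 1
  }
  list(P = Matrix::Diagonal(x = 1 / s) %*% W, strength = s, isolated = iso)
}

#' Iterative PPI essentiality propagation
#'
#' Iterates the smoothed propagation update on the dual graph until the
#' scores are stationary. In the default `"mass"` mode the update is
#' `e(t+1) = (1 - alpha) e(t) + alpha t(P) e(t)` with `P` the
#' row-stochastic matrix of dual-edge weights: score mass flows along the
#' weighted walk and the fixed point is its stationary distribution,
#' independent of the (uniform) initialization on connected graphs. In
#' `"averaging"` mode the update is `e(t+1) = (1 - alpha) e(t) +
#' alpha P e(t)` (each node becomes the weighted average of its
#' neighbors), which on a connected graph converges to a consensus vector
#' determined by the initialization; it is provided for comparison and
#' documented as such. After convergence scores are divided by their
#' maximum, so the final essentialities lie in (0, 1\] with the top PPI
#' at exactly 1.
#'
#' @param dg a `dual_graph`.
#' @param cfg a [propagation_config()].
#' @param init optional nonnegative start vector (length = number of
#'   PPIs); defaults to uniform mass `1/n`.
#' @return a `ppi_scores` object: list with `scores` (named numeric),
#'   `iterations`, `converged`, and the pre-normalization `stationary`
#'   vector.
#' @export
propagate <- function(dg, cfg = propagation_config(), init = NULL) {
  stopifnot(inherits(dg, "dual_graph"), inherits(cfg, "propagation_config"))
  n <- length(dg$ppis)
  if (n == 0L) stop("dual graph has no nodes")
  tm <- dual_transition_matrix(dg)
  P <- tm$P
  if (is.null(init)) {
    e <- rep(1 / n, n)
  } else {
    if (length(init) != n || any(is.na(init)) || any(init < 0) ||
        sum(init) == 0) {
      stop("init must be a nonnegative vector of length ", n,
           " with positive total mass")
    }
    e <- as.numeric(init)
  }
  a <- cfg$alpha
  converged <- FALSE
  iter <- 0L
  delta_prev <- Inf
  for (iter in seq_len(cfg$max_iter)) {
    flow <- if (cfg$update_mode == "mass") {
      as.numeric(Matrix::crossprod(P, e))
    } else {
      as.numeric(P %*% e)
    }
    e_new <- (1 - a) * e + a * flow
    delta <- max(abs(e_new - e))
    e <- e_new
    # for a linearly converging iteration the distance to the fixed
    # point is bounded by delta * rho / (1 - rho); require that bound,
    # not just the raw step, to fall below tol
    tail_bound <- if (is.finite(delta_prev) && delta_prev > delta) {
      delta^2 / (delta_prev - delta)
    } else {
      Inf
    }
    # a step below tol converges once the tail bound is also below tol,
    # or once delta stops decreasing (the numerical noise floor)
    if (delta == 0 ||
        (delta < cfg$tol && (tail_bound < cfg$tol || delta >= delta_prev))) {
      converged <- TRUE
      break
    }
    delta_prev <- delta
  }
  if (!converged) {
    warning("propagation did not converge within ", cfg$max_iter,
            " iterations (mode = ", cfg$update_mode, ")")
  }
  structure(list(scores = stats::setNames(normalize_scores(e), dg$ppis),
                 stationary = stats::setNames(e, dg$ppis),
                 iterations = iter, converged = converged,
                 update_mode = cfg$update_mode),
            class = "ppi_scores")
}

#' @export
print.ppi_scores <- function(x, ...) {
  cat("ppi_scores:", length(x$scores), "PPIs;",
      if (x$converged) paste0("converged in ", x$iterations, " iterations")
      else "NOT converged", "\n")
  invisible(x)
}

#' Closed-form stationary PPI essentiality scores
#'
#' Computes the fixed point of the mass-mode propagation directly by
#' eigendecomposition, per connected component of the dual graph. On each
#' component the fixed point of `e = (1 - alpha) e + alpha t(P) e` is the
#' leading left eigenvector of `M = (1 - alpha) I + alpha P`, i.e. the
#' stationary distribution of `P` (which for the reversible walk on an
#' undirected weighted graph is proportional to node strength). Each
#' component's distribution is scaled by the component's share of the
#' uniform initial mass, matching the limit of [propagate()] from a
#' uniform start; isolated dual nodes keep their initial mass. Scores are
#' then divided by the global maximum.
#'
#' @param dg a `dual_graph`.
#' @param cfg a [propagation_config()] (only `alpha` is used).
#' @return a `ppi_scores` object (with `iterations = 0`,
#'   `converged = TRUE`).
#' @export
closed_form_scores <- function(dg, cfg = propagation_config()) {
  stopifnot(inherits(dg, "dual_graph"), inherits(cfg, "propagation_config"))
  n <- length(dg$ppis)
  if (n == 0L) stop("dual graph has no nodes")
  tm <- dual_transition_matrix(dg)
  g <- igraph::graph_from_data_frame(
    dg$edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  raw <- numeric(n)
  a <- cfg$alpha
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    m <- length(idx)
    if (m == 1L) {
      raw[idx] <- 1 / n
      next
    }
    Pc <- as.matrix(tm$P[idx, idx, drop = FALSE])
    M <- (1 - a) * diag(m) + a * Pc
    eg <- eigen(t(M))
    k <- which.max(Re(eg$values))
    v <- Re(eg$vectors[, k])
    v <- v * sign(sum(v))
    v[v < 0] <- 0
    raw[idx] <- (v / sum(v)) * (m / n)
  }
  structure(list(scores = stats::setNames(normalize_scores(raw), dg$ppis),
                 stationary = stats::setNames(raw, dg$ppis),
                 iterations = 0L, converged = TRUE,
                 update_mode = "mass"),
            class = "ppi_scores")
}

#' Scale scores so the maximum is exactly 1
#'
#' @param raw nonempty nonnegative numeric vector with a positive
#'   maximum.
#' @return `raw / max(raw)`, preserving names and order.
#' @export
normalize_scores <- function(raw) {
  if (!length(raw)) stop("cannot normalize an empty score vector")
  if (any(is.na(raw)) || any(raw < 0)) {
    stop("scores must be nonnegative and non-missing")
  }
  mx <- max(raw)
  if (mx == 0) stop("all scores are zero; nothing to normalize")
  raw / mx
}

#' Score PPI essentiality across cell lines
#'
#' Runs the full per-cell-line pipeline: normalize the gene-level scores
#' of each cell line, rewire the superpathway with that line's context,
#' build the dual graph, and propagate to converged PPI scores. Rows are
#' the superpathway's PPIs; a PPI absent from a cell line's context
#' network (partner lost or unmeasured) is `NA` in that column.
#'
#' @param sp a `superpathway`.
#' @param gene_scores numeric matrix, genes x cell lines, gene-level
#'   screen scores (more negative = more lethal).
#' @param contexts named list of [cell_line_context()] objects (default:
#'   no losses; measured genes taken from non-missing scores).
#' @param cfg a [propagation_config()].
#' @param method `"propagate"` (iterative, default) or `"closed_form"`.
#' @return numeric matrix, PPIs x cell lines, with `NA` for
#'   context-absent PPIs.
#' @export
score_matrix <- function(sp, gene_scores, contexts = NULL,
                         cfg = propagation_config(),
                         method = c("propagate", "closed_form")) {
  method <- match.arg(method)
  stopifnot(inherits(sp, "superpathway"), is.matrix(gene_scores))
  if (is.null(colnames(gene_scores)) || is.null(rownames(gene_scores))) {
    stop("gene_scores must have gene rownames and cell-line colnames")
  }
  lines <- colnames(gene_scores)
  all_ids <- ppi_id(sp$edges$protein_1, sp$edges$protein_2)
  out <- matrix(NA_real_, nrow = length(all_ids), ncol = length(lines),
                dimnames = list(all_ids, lines))
  for (cl in lines) {
    raw <- gene_scores[, cl]
    raw <- raw[!is.na(raw)]
    ctx <- if (!is.null(contexts) && !is.null(contexts[[cl]])) {
      contexts[[cl]]
    } else {
      cell_line_context(cl, measured_genes = names(raw))
    }
    profile <- gene_essentiality_profile(cl, raw)
    net <- tryCatch(apply_context(sp, ctx, profile),
                    error = function(e) NULL)
    if (is.null(net) || nrow(net$edges) == 0L) {
      warning("cell line '", cl, "' has no scorable PPIs; column left NA")
      next
    }
    dg <- build_dual_graph(net, w = cfg$w)
    sv <- if (method == "closed_form") closed_form_scores(dg, cfg)
          else propagate(dg, cfg)
    out[names(sv$scores), cl] <- sv$scores
  }
  out
}
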