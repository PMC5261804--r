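# Superpathway assembly and per-cell-line rewiring.

#' Canonical PPI identifier
#'
#' Joins two protein symbols into the canonical PPI row key: the symbols
#' sorted alphabetically and joined by an underscore. Symbols containing
#' an underscore are rejected because the identifier could not be parsed
#' back unambiguously.
#'
#' @param a,b character vectors of protein symbols (recycled pairwise).
#' @return character vector of identifiers such as `"AKT1_SRC"`.
#' @seealso [parse_ppi_id()]
#' @export
ppi_id <- function(a, b) {
  check_symbols(c(a, b))
  ifelse(a < b, paste(a, b, sep = "_"), paste(b, a, sep = "_"))
}

#' Split canonical PPI identifiers into partner symbols
#'
#' @param id character vector of identifiers produced by [ppi_id()].
#' @return a two-column character matrix (`protein_1`, `protein_2`).
#' @export
parse_ppi_id <- function(id) {
  parts <- strsplit(id, "_", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed PPI identifier (expected 'SYMBOL1_SYMBOL2'): ",
         paste(utils::head(id[bad], 3L), collapse = ", "))
  }
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("protein_1", "protein_2")
  m
}

check_symbols <- function(x) {
  x <- x[!is.na(x)]
  if (any(x == "")) stop("empty protein symbol")
  if (any(grepl("_", x, fixed = TRUE))) {
    stop("protein symbols may not contain '_': ",
         paste(unique(x[grepl("_", x, fixed = TRUE)]), collapse = ", "))
  }
  invisible(x)
}

# Normalise an edge-list input (data.frame/matrix with >= 2 columns) to a
# two-column character matrix, dropping the relation column of SIF input.
as_edge_matrix <- function(edges, what = "edge list") {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(dim(edges)) || ncol(edges) < 2L) {
    stop("malformed ", what, ": need at least two columns (nodeA, nodeB)")
  }
  if (ncol(edges) == 3L) edges <- edges[, c(1L, 3L), drop = FALSE]
  edges <- edges[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  bad <- which(is.na(edges) | edges == "", arr.ind = TRUE)
  if (length(bad)) {
    stop("malformed ", what, ": empty symbol in record ",
         bad[1L, 1L])
  }
  edges
}

#' Merge pathway edge lists into a superpathway
#'
#' Aggregates named pathway edge lists (and, optionally, novel
#' screen-derived interactions) into a single undirected simple graph on
#' protein symbols. Edges are deduplicated; an edge found in several
#' pathways carries all of their names as provenance. Self-loops are
#' dropped with a warning (the dual transform is undefined for them).
#' If a symbol-mapping table is supplied, symbols absent from it are
#' excised together with their edges.
#'
#' @param pathway_edge_lists named list; each element an edge list
#'   (data.frame or matrix, two columns, or three SIF-style columns whose
#'   middle relation column is ignored).
#' @param novel_edges optional edge list of screen-derived interactions,
#'   annotated with provenance `"novel-screen"`.
#' @param symbol_map optional two-column table (input symbol, HUGO
#'   symbol); symbols without a mapping are dropped.
#' @return a `superpathway` object: list with `nodes` (character),
#'   `edges` (data.frame `protein_1`, `protein_2`, sorted within row) and
#'   `provenance` (list keyed by PPI identifier).
#' @export
merge_pathways <- function(pathway_edge_lists, novel_edges = NULL,
                           symbol_map = NULL) {
  if (length(pathway_edge_lists) == 0L && is.null(novel_edges)) {
    stop("no pathway edge lists supplied")
  }
  if (length(pathway_edge_lists)) {
    if (is.null(names(pathway_edge_lists)) ||
        any(names(pathway_edge_lists) == "")) {
      names(pathway_edge_lists) <- paste0("pathway", seq_along(pathway_edge_lists))
    }
  }
  all <- pathway_edge_lists
  if (!is.null(novel_edges)) all[["novel-screen"]] <- novel_edges

  map <- NULL
  if (!is.null(symbol_map)) {
    symbol_map <- as.data.frame(symbol_map, stringsAsFactors = FALSE)
    if (ncol(symbol_map) < 2L) stop("symbol_map needs two columns")
    map <- stats::setNames(as.character(symbol_map[[2L]]),
                           as.character(symbol_map[[1L]]))
  }

  prov <- list()
  node_universe <- character()
  n_self <- 0L
  n_unmapped <- 0L
  for (nm in names(all)) {
    em <- as_edge_matrix(all[[nm]], what = paste0("edge list '", nm, "'"))
    if (!is.null(map)) {
      mapped <- matrix(map[em], ncol = 2L)
      # endpoints that map stay in the node universe even when the edge
      # is excised because the partner symbol has no mapping
      node_universe <- union(node_universe, mapped[!is.na(mapped)])
      keep <- !is.na(mapped[, 1L]) & !is.na(mapped[, 2L])
      n_unmapped <- n_unmapped + sum(!keep)
      em <- mapped[keep, , drop = FALSE]
    } else {
      node_universe <- union(node_universe, as.vector(em))
    }
    if (!nrow(em)) next
    self <- em[, 1L] == em[, 2L]
    if (any(self)) {
      n_self <- n_self + sum(self)
      em <- em[!self, , drop = FALSE]
    }
    if (!nrow(em)) next
    ids <- ppi_id(em[, 1L], em[, 2L])
    for (id in unique(ids)) prov[[id]] <- union(prov[[id]], nm)
  }
  if (n_self > 0L) {
    warning(n_self, " self-loop edge(s) dropped (homodimers are not scored)")
  }
  if (n_unmapped > 0L) {
    message(n_unmapped, " edge(s) excised: endpoint symbol not in mapping table")
  }

  ids <- sort(names(prov))
  pairs <- if (length(ids)) parse_ppi_id(ids) else
    matrix(character(), ncol = 2L,
           dimnames = list(NULL, c("protein_1", "protein_2")))
  nodes <- sort(node_universe)
  sp <- structure(
    list(nodes = nodes,
         edges = data.frame(protein_1 = pairs[, 1L], protein_2 = pairs[, 2L],
                            stringsAsFactors = FALSE),
         provenance = prov[ids]),
    class = "superpathway")
  sp
}

#' @export
print.superpathway <- function(x, ...) {
  cat("superpathway:", length(x$nodes), "proteins,",
      nrow(x$edges), "PPIs\n")
  src <- sort(unique(unlist(x$provenance)))
  if (length(src)) {
    cat("  sources:", paste(utils::head(src, 8L), collapse = ", "),
        if (length(src) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' Convert a superpathway or context network to an igraph graph
#'
#' @param x a `superpathway` or `context_network`.
#' @return an undirected simple `igraph` graph.
#' @export
as_igraph <- function(x) {
  UseMethod("as_igraph")
}

#' @export
as_igraph.superpathway <- function(x) {
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = data.frame(name = x$nodes))
}

#' @export
as_igraph.context_network <- function(x) {
  g <- igraph::graph_from_data_frame(
    x$edges, directed = FALSE,
    vertices = data.frame(name = names(x$node_essentiality)))
  igraph::set_vertex_attr(g, "essentiality",
                          value = x$node_essentiality[igraph::V(g)$name])
}

#' Collapse hairpin-level scores to gene level (second most lethal)
#'
#' Pooled knockdown screens report several hairpins (shRNAs) per gene;
#' single extreme hairpins are often off-target artifacts. The gene-level
#' score is therefore the second smallest (second most lethal, since more
#' negative means more lethal) hairpin score. Genes with fewer than two
#' hairpins are excluded.
#'
#' @param shrna_scores named list mapping gene symbol to a numeric vector
#'   of hairpin scores.
#' @return named numeric vector of gene-level scores.
#' @export
collapse_shrna_to_gene <- function(shrna_scores) {
  if (!is.list(shrna_scores)) stop("shrna_scores must be a named list")
  scores <- lapply(shrna_scores, function(x) x[!is.na(x)])
  n <- lengths(scores)
  if (any(n < 2L)) {
    message(sum(n < 2L), " gene(s) excluded: fewer than two hairpin scores")
  }
  keep <- n >= 2L
  vapply(scores[keep], function(x) sort(x)[2L], numeric(1))
}

#' Normalize protein essentiality to \[0, 1\]
#'
#' Maps raw screen scores (more negative = more lethal) to per-cell-line
#' protein essentialities `p` in \[0, 1\] by a negated min-max transform:
#' the most lethal gene gets `p = 1`, the least lethal `p = 0`. A
#' degenerate all-equal profile maps every gene to 0.5 with a warning, so
#' that the exponential dual-edge kernel stays defined.
#'
#' @param raw named numeric vector of gene-level scores.
#' @return named numeric vector of essentialities in \[0, 1\].
#' @export
normalize_protein_essentiality <- function(raw) {
  raw <- raw[!is.na(raw)]
  if (!length(raw)) stop("no gene scores to normalize")
  rng <- range(raw)
  if (rng[1L] == rng[2L]) {
    warning("all raw scores identical; essentiality set to 0.5 for all genes")
    return(stats::setNames(rep(0.5, length(raw)), names(raw)))
  }
  (rng[2L] - raw) / (rng[2L] - rng[1L])
}

#' Per-cell-line gene essentiality profile
#'
#' @param cell_line identifier.
#' @param raw named numeric vector of gene-level screen scores.
#' @return a `gene_essentiality_profile` with `raw` and min-max
#'   `normalized` components.
#' @export
gene_essentiality_profile <- function(cell_line, raw) {
  raw <- raw[!is.na(raw)]
  structure(list(cell_line = cell_line, raw = raw,
                 normalized = normalize_protein_essentiality(raw)),
            class = "gene_essentiality_profile")
}

#' Cell-line alteration context
#'
#' Records which genes are lost in a given cell line (deleterious
#' mutation, homozygous deletion, or no detectable expression) and which
#' genes have essentiality measurements.
#'
#' @param cell_line identifier.
#' @param lost_genes character vector of lost gene symbols.
#' @param measured_genes character vector of genes with screen
#'   measurements.
#' @return a `cell_line_context` object.
#' @export
cell_line_context <- function(cell_line, lost_genes = character(),
                              measured_genes = character()) {
  check_symbols(lost_genes)
  check_symbols(measured_genes)
  structure(list(cell_line = cell_line,
                 lost_genes = unique(as.character(lost_genes)),
                 measured_genes = unique(as.character(measured_genes))),
            class = "cell_line_context")
}

#' Rewire the superpathway for one cell line
#'
#' Removes from the superpathway every node that is lost in the cell line
#' (mutated, deleted, not expressed) or that lacks an essentiality
#' measurement, together with all incident edges, and attaches the
#' normalized essentiality to each remaining node.
#'
#' @param sp a `superpathway`.
#' @param ctx a `cell_line_context` for the same cell line as `profile`.
#' @param profile a `gene_essentiality_profile`.
#' @return a `context_network`: list with `cell_line`, `edges`
#'   (data.frame) and `node_essentiality` (named numeric in \[0, 1\]).
#' @export
apply_context <- function(sp, ctx, profile) {
  stopifnot(inherits(sp, "superpathway"),
            inherits(ctx, "cell_line_context"),
            inherits(profile, "gene_essentiality_profile"))
  if (!identical(ctx$cell_line, profile$cell_line)) {
    stop("context cell line '", ctx$cell_line,
         "' does not match profile cell line '", profile$cell_line, "'")
  }
  measured <- intersect(ctx$measured_genes, names(profile$normalized))
  keep <- setdiff(intersect(sp$nodes, measured), ctx$lost_genes)
  if (!length(keep)) {
    stop("context network for '", ctx$cell_line, "' is empty: ",
         sum(sp$nodes %in% ctx$lost_genes), " node(s) lost, ",
         sum(!sp$nodes %in% measured), " node(s) unmeasured")
  }
  e <- sp$edges
  e <- e[e$protein_1 %in% keep & e$protein_2 %in% keep, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(cell_line = ctx$cell_line,
                 edges = e,
                 node_essentiality = profile$normalized[keep]),
            class = "context_network")
}

#' Construct a context network directly
#'
#' Builds a `context_network` from an explicit edge list and node
#' essentialities, validating the class invariants (every edge endpoint
#' has an essentiality in \[0, 1\], no self-loops). [apply_context()] is
#' the usual constructor; this one serves programmatic construction of
#' small networks.
#'
#' @param cell_line identifier.
#' @param edges data.frame (or two-column matrix) of protein pairs.
#' @param node_essentiality named numeric vector in \[0, 1\] covering at
#'   least every edge endpoint.
#' @return a `context_network`.
#' @export
context_network <- function(cell_line, edges, node_essentiality) {
  em <- as_edge_matrix(edges)
  if (any(em[, 1L] == em[, 2L])) stop("self-loop edges are not allowed")
  if (is.null(names(node_essentiality))) {
    stop("node_essentiality must be named")
  }
  miss <- setdiff(unique(as.vector(em)), names(node_essentiality))
  if (length(miss)) {
    stop("no essentiality value for node(s): ", paste(miss, collapse = ", "))
  }
  if (any(is.na(node_essentiality)) ||
      any(node_essentiality < 0 | node_essentiality > 1)) {
    stop("node essentialities must lie in [0, 1]")
  }
  structure(list(cell_line = cell_line,
                 edges = data.frame(protein_1 = em[, 1L],
                                    protein_2 = em[, 2L],
                                    stringsAsFactors = FALSE),
                 node_essentiality = node_essentiality),
            class = "context_network")
}

#' @export
print.context_network <- function(x, ...) {
  cat("context network [", x$cell_line, "]: ",
      length(x$node_essentiality), " proteins, ", nrow(x$edges),
      " PPIs\n", sep = "")
  invisible(x)
}

#' Derive a not-expressed gene set from an expression matrix
#'
#' The expression-absence criterion of the context model has no canonical
#' cutoff; this helper applies a user-set threshold to a (log-scale)
#' expression matrix and returns, per cell line, the genes at or below
#' it.
#'
#' @param expr numeric matrix, genes x cell lines.
#' @param threshold expression value at or below which a gene is treated
#'   as not expressed (default 0, i.e. non-positive log expression).
#' @return named list mapping cell line to character vector of
#'   not-expressed genes.
#' @export
not_expressed_genes <- function(expr, threshold = 0) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  lapply(stats::setNames(colnames(expr), colnames(expr)),
         function(cl) rownames(expr)[!is.na(expr[, cl]) & expr[, cl] <= threshold])
}
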