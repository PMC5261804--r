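# Readers and writers for the standard input/output formats: SIF edge
# lists, GCT 1.2 screen matrices, GMT gene sets, context / drug /
# patient TSVs and the PPI essentiality matrix TSV. All outputs are
# UTF-8, tab-delimited, LF-terminated.

write_tsv_plain <- function(df, path, ...) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NaN", ...)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NaN", check.names = FALSE, ...)
}

require_file <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  path
}

#' Read a SIF or two-column edge list
#'
#' SIF rows are `nodeA <tab> relation <tab> nodeB`; the relation column
#' is ignored. Two-column files are read as plain edge lists.
#'
#' @param path file path.
#' @return data.frame with columns `protein_1`, `protein_2`.
#' @export
read_sif <- function(path) {
  require_file(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge-list file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L & nfield != 3L)) {
    stop("malformed edge record at line ",
         which(nfield != 2L & nfield != 3L)[1L], " of ", path)
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, function(x) x[[length(x)]], character(1))
  data.frame(protein_1 = a, protein_2 = b, stringsAsFactors = FALSE)
}

#' Write a superpathway as SIF
#'
#' The relation column carries the comma-joined provenance labels.
#'
#' @param sp a `superpathway`.
#' @param path output file path.
#' @export
write_sif <- function(sp, path) {
  stopifnot(inherits(sp, "superpathway"))
  ids <- ppi_id(sp$edges$protein_1, sp$edges$protein_2)
  rel <- vapply(sp$provenance[ids], paste, character(1), collapse = ",")
  df <- data.frame(sp$edges$protein_1, rel, sp$edges$protein_2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a GCT 1.2 matrix
#'
#' Expects the `#1.2` version line, a dimensions line, then a header
#' with `Name`, `Description` and one column per sample. Rows sharing a
#' gene label in `Description` are the hairpins of that gene and can be
#' collapsed with [collapse_shrna_to_gene()].
#'
#' @param path file path.
#' @return list with `matrix` (numeric, rownames = `Name`),
#'   `description` (named character, the gene label per row).
#' @export
read_gct <- function(path) {
  require_file(path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("truncated GCT file: ", path)
  if (trimws(lines[1L]) != "#1.2") {
    stop("unsupported GCT version line '", lines[1L],
         "' (expected '#1.2') in ", path)
  }
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]][1:2]))
  if (any(is.na(dims))) stop("malformed GCT dimensions line in ", path)
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "Name") {
    stop("malformed GCT header line in ", path)
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != dims[1L]) {
    stop("GCT dimension mismatch in ", path, ": declared ", dims[1L],
         " rows, body has ", length(body))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != length(header))) {
    stop("GCT row width mismatch at line ",
         which(lengths(parts) != length(header))[1L] + 3L, " of ", path)
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  samples <- header[-(1:2)]
  if (length(samples) != dims[2L]) {
    stop("GCT dimension mismatch in ", path, ": declared ", dims[2L],
         " samples, header has ", length(samples))
  }
  vals <- matrix(NA_real_, nrow = length(nm), ncol = length(samples),
                 dimnames = list(nm, samples))
  for (r in seq_along(parts)) {
    row_txt <- parts[[r]][-(1:2)]
    row_num <- suppressWarnings(as.numeric(row_txt))
    bad <- is.na(row_num) & !(row_txt %in% c("NA", "NaN", ""))
    if (any(bad)) {
      stop("non-numeric value '", row_txt[which(bad)[1L]],
           "' at line ", r + 3L, " of ", path)
    }
    vals[r, ] <- row_num
  }
  list(matrix = vals, description = stats::setNames(desc, nm))
}

#' Write a GCT 1.2 matrix
#'
#' @param mat numeric matrix with rownames (`Name`) and colnames
#'   (samples).
#' @param description character vector of gene labels per row (defaults
#'   to the rownames).
#' @param path output file path.
#' @export
write_gct <- function(mat, path, description = rownames(mat)) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(mat)),
                   collapse = "\t"), con)
  body <- cbind(rownames(mat), description,
                format(mat, trim = TRUE, digits = 15))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
}

#' Read a cell-line context table
#'
#' TSV with columns `cell_line`, `gene`, `event` where `event` is one
#' of `mutation`, `homozygous_deletion`, `not_expressed`.
#'
#' @param path file path.
#' @param measured_genes optional named list (cell line -> measured
#'   genes) merged into the contexts.
#' @return named list of [cell_line_context()] objects.
#' @export
read_contexts <- function(path, measured_genes = NULL) {
  df <- read_tsv_plain(require_file(path))
  need <- c("cell_line", "gene", "event")
  if (!all(need %in% names(df))) {
    stop("context table must have columns ", paste(need, collapse = ", "))
  }
  bad <- !df$event %in% c("mutation", "homozygous_deletion", "not_expressed")
  if (any(bad)) {
    stop("unknown context event '", df$event[bad][1L], "' in ", path)
  }
  lines <- unique(df$cell_line)
  out <- lapply(stats::setNames(lines, lines), function(cl) {
    cell_line_context(cl,
                      lost_genes = unique(df$gene[df$cell_line == cl]),
                      measured_genes = if (is.null(measured_genes))
                        character() else measured_genes[[cl]])
  })
  out
}

#' Write cell-line contexts to TSV
#'
#' @param contexts named list of contexts; each must carry a
#'   `lost_events` data.frame attribute or the events default to
#'   `"mutation"`.
#' @param path output file path.
#' @export
write_contexts <- function(contexts, path) {
  rows <- lapply(contexts, function(ctx) {
    ev <- attr(ctx, "lost_events")
    if (is.null(ev)) {
      if (!length(ctx$lost_genes)) return(NULL)
      ev <- data.frame(gene = ctx$lost_genes, event = "mutation",
                       stringsAsFactors = FALSE)
    }
    if (!nrow(ev)) return(NULL)
    data.frame(cell_line = ctx$cell_line, gene = ev$gene,
               event = ev$event, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(cell_line = character(), gene = character(),
                     event = character())
  }
  write_tsv_plain(df, path)
}

#' Read/write a PPIs x cell lines essentiality matrix
#'
#' The TSV mirrors the published table layout: first column `ppi` holds
#' the sorted `SYMBOL1_SYMBOL2` key, remaining columns are cell lines,
#' missing values are the literal `NaN`.
#'
#' @param path file path.
#' @return numeric matrix with PPI rownames.
#' @export
read_essentiality_matrix <- function(path) {
  df <- read_tsv_plain(require_file(path))
  if (names(df)[1L] != "ppi") stop("matrix TSV must start with a 'ppi' column")
  parse_ppi_id(df$ppi)  # validates key format
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$ppi
  m
}

#' @rdname read_essentiality_matrix
#' @param matrix numeric matrix with PPI rownames.
#' @export
write_essentiality_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  df <- data.frame(ppi = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Read GMT gene sets (membership filtering only)
#'
#' @param path file path.
#' @return named list of character vectors (set name -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(require_file(path), warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT record at line ", which(bad)[1L])
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Read drug screen inputs
#'
#' `auc_path`: TSV with columns `compound`, `cell_line`, `auc`.
#' `targets_path`: TSV with columns `compound`, `target_gene`.
#'
#' @param auc_path,targets_path file paths.
#' @return list with `auc` (data.frame) and `targets` (named list of
#'   gene vectors).
#' @export
read_drug_screen <- function(auc_path, targets_path) {
  auc <- read_tsv_plain(require_file(auc_path))
  if (!all(c("compound", "cell_line", "auc") %in% names(auc))) {
    stop("AUC table must have columns compound, cell_line, auc")
  }
  tg <- read_tsv_plain(require_file(targets_path))
  if (!all(c("compound", "target_gene") %in% names(tg))) {
    stop("target table must have columns compound, target_gene")
  }
  list(auc = auc,
       targets = split(tg$target_gene, tg$compound))
}

#' Resolved run configuration
#'
#' Flat key-value record of every tunable parameter of a run; written
#' next to outputs so any result can be reproduced.
#'
#' @param ... named scalar parameter values.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == ""))) {
    stop("all run_config entries must be named")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path output file path (`key<TAB>value` lines).
#' @export
write_run_config <- function(cfg, path) {
  keys <- names(cfg)
  vals <- vapply(cfg, function(v) paste(format(v), collapse = ","),
                 character(1))
  writeLines(paste(keys, vals, sep = "\t"), path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(require_file(path), warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  structure(stats::setNames(lapply(parts, `[[`, 2L),
                            vapply(parts, `[[`, character(1), 1L)),
            class = "run_config")
}
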