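# Seed-reproducible synthetic inputs: a hub-structured multi-pathway
# network, hairpin-level essentiality screens, cell-line alteration
# contexts, drug sensitivity with a planted target correlation, and
# patient survival with a planted hazard effect tied to one PPI.

#' Simulation configuration
#'
#' Parameters of the synthetic data generator. The defaults describe a
#' desk-scale analogue of a pooled-screen study: a superpathway built
#' from several overlapping hub-heavy pathways, a screen over a few
#' dozen cell lines in which hub proteins are strongly essential, sparse
#' per-line gene losses, one compound whose sensitivity tracks the
#' planted target's PPI essentialities, and patient survival with a
#' hazard effect tied to the presence of one planted PPI.
#'
#' @param seed mandatory integer seed (< 2^31 - 16); every stage derives
#'   its own stream from it, so stages are independently reproducible.
#' @param n_proteins number of proteins in the name pool.
#' @param n_pathways number of overlapping pathways.
#' @param pathway_size_range two integers, min/max proteins per pathway.
#' @param hub_fraction fraction of proteins designated hubs; hubs are
#'   shared across pathways and attract preferential attachment.
#' @param n_cell_lines number of screened cell lines.
#' @param essential_hub_bias additive shift of hub gene lethality on the
#'   screen scale (negative = more lethal; default -2).
#' @param mutation_rate per-gene, per-cell-line loss probability.
#' @param n_patients number of patients in the survival tables.
#' @param planted_drug_target target gene of the planted compound
#'   (default: the highest-degree hub).
#' @param planted_survival_ppi [ppi_id()] of the PPI with the planted
#'   hazard effect (default: the highest-strength hub PPI).
#' @param hazard_ratio hazard multiplier for patients retaining the
#'   planted PPI (default 3).
#' @param noise_sd per-hairpin replicate noise (screen-scale sd).
#' @param n_compounds number of screened compounds (first is planted).
#' @param n_hairpins hairpins per gene (>= 2).
#' @param target_correlation intended correlation between planted
#'   compound AUC and the target's mean PPI essentiality (default 0.7).
#' @param ppi_absence_rate fraction of patients losing the planted PPI.
#' @param censor_horizon administrative censoring time in days
#'   (default 3000, about 30 percent censoring at the default hazard).
#' @param baseline_hazard baseline exponential hazard per day.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(seed,
                              n_proteins = 150L,
                              n_pathways = 8L,
                              pathway_size_range = c(15L, 40L),
                              hub_fraction = 0.1,
                              n_cell_lines = 30L,
                              essential_hub_bias = -2,
                              mutation_rate = 0.03,
                              n_patients = 200L,
                              planted_drug_target = NULL,
                              planted_survival_ppi = NULL,
                              hazard_ratio = 3,
                              noise_sd = 0.3,
                              n_compounds = 10L,
                              n_hairpins = 4L,
                              target_correlation = 0.7,
                              ppi_absence_rate = 0.4,
                              censor_horizon = 3000,
                              baseline_hazard = 1 / 1500) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed) || seed != floor(seed) || seed >= 2^31 - 16) {
    stop("seed is mandatory and must be an integer below 2^31 - 16")
  }
  if (n_proteins < 3L || n_pathways < 1L || n_cell_lines < 1L ||
      n_patients < 1L || n_hairpins < 2L || n_compounds < 1L) {
    stop("all counts must be positive (and n_hairpins >= 2)")
  }
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1L] < 3L ||
      pathway_size_range[2L] < pathway_size_range[1L] ||
      pathway_size_range[2L] > n_proteins) {
    stop("pathway_size_range must be [min >= 3, max <= n_proteins]")
  }
  for (r in c(hub_fraction, mutation_rate, ppi_absence_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  if (hazard_ratio <= 0 || noise_sd < 0 || censor_horizon <= 0 ||
      baseline_hazard <= 0) {
    stop("hazard_ratio, censor_horizon and baseline_hazard must be positive")
  }
  if (target_correlation <= 0 || target_correlation >= 1) {
    stop("target_correlation must lie in (0, 1)")
  }
  structure(list(seed = as.integer(seed),
                 n_proteins = as.integer(n_proteins),
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 hub_fraction = hub_fraction,
                 n_cell_lines = as.integer(n_cell_lines),
                 essential_hub_bias = essential_hub_bias,
                 mutation_rate = mutation_rate,
                 n_patients = as.integer(n_patients),
                 planted_drug_target = planted_drug_target,
                 planted_survival_ppi = planted_survival_ppi,
                 hazard_ratio = hazard_ratio,
                 noise_sd = noise_sd,
                 n_compounds = as.integer(n_compounds),
                 n_hairpins = as.integer(n_hairpins),
                 target_correlation = target_correlation,
                 ppi_absence_rate = ppi_absence_rate,
                 censor_horizon = censor_horizon,
                 baseline_hazard = baseline_hazard),
            class = "simulation_config")
}

# Fixed offsets give each stage its own reproducible stream.
stage_seed <- function(cfg, stage) {
  offsets <- c(network = 1L, essentiality = 2L, contexts = 3L,
               drugs = 4L, survival = 5L)
  cfg$seed + offsets[[stage]]
}

#' Generate a hub-structured multi-pathway superpathway
#'
#' Builds `n_pathways` preferential-attachment subnetworks over a shared
#' protein pool. A designated hub set (fraction `hub_fraction` of the
#' pool) seeds every pathway's early, high-degree positions, so pathways
#' overlap on hubs and the merged superpathway is hub-heavy. A handful
#' of extra hub-hub edges is merged with provenance `"novel-screen"`.
#'
#' @param cfg a [simulation_config()].
#' @return a `superpathway` with attributes `hub_genes` and `genes`.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(stage_seed(cfg, "network"))
  genes <- sprintf("G%03d", seq_len(cfg$n_proteins))
  n_hub <- max(2L, round(cfg$hub_fraction * cfg$n_proteins))
  hubs <- genes[seq_len(n_hub)]
  others <- setdiff(genes, hubs)
  lists <- vector("list", cfg$n_pathways)
  names(lists) <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  for (k in seq_len(cfg$n_pathways)) {
    sizes <- seq(cfg$pathway_size_range[1L], cfg$pathway_size_range[2L])
    size <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
    n_hub_in <- min(n_hub, max(2L, round(0.3 * size)))
    if (size - n_hub_in > length(others)) {
      stop("infeasible sizes: pathway larger than available protein pool")
    }
    members <- c(sample(hubs, n_hub_in),
                 sample(others, size - n_hub_in))
    g <- igraph::sample_pa(size, power = 1, m = 2, directed = FALSE)
    em <- igraph::as_edgelist(g, names = FALSE)
    lists[[k]] <- data.frame(protein_1 = members[em[, 1L]],
                             protein_2 = members[em[, 2L]],
                             stringsAsFactors = FALSE)
  }
  novel <- t(utils::combn(sample(hubs, min(n_hub, 4L)), 2L))
  novel <- data.frame(protein_1 = novel[, 1L], protein_2 = novel[, 2L],
                      stringsAsFactors = FALSE)
  sp <- merge_pathways(lists, novel_edges = novel)
  attr(sp, "hub_genes") <- intersect(hubs, sp$nodes)
  attr(sp, "genes") <- genes
  sp
}

#' Generate a hairpin-level essentiality screen
#'
#' Every gene of the superpathway gets `n_hairpins` hairpins per cell
#' line. A gene's screen-scale lethality is a standard-normal base value
#' shifted by `essential_hub_bias` for hub genes, plus a small
#' per-cell-line wobble (sd 0.2) and per-hairpin replicate noise
#' (sd `noise_sd`). More negative means more lethal, matching the
#' depletion-score convention of pooled screens.
#'
#' @param cfg a [simulation_config()].
#' @param sp the superpathway from [generate_network()].
#' @return list with `shrna` (hairpins x cell lines matrix),
#'   `description` (gene label per hairpin row), `gene_scores`
#'   (collapsed gene x cell line matrix via the second-most-lethal
#'   rule), and `gene_base` (the noiseless gene lethality).
#' @export
generate_essentiality <- function(cfg, sp) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(sp, "superpathway"))
  set.seed(stage_seed(cfg, "essentiality"))
  genes <- sp$nodes
  hubs <- attr(sp, "hub_genes")
  lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  base <- stats::rnorm(length(genes))
  names(base) <- genes
  base[genes %in% hubs] <- base[genes %in% hubs] + cfg$essential_hub_bias
  cell_wobble <- matrix(stats::rnorm(length(genes) * length(lines), sd = 0.2),
                        nrow = length(genes),
                        dimnames = list(genes, lines))
  hp_names <- as.vector(t(outer(genes, seq_len(cfg$n_hairpins),
                                function(g, j) paste0(g, "-hp", j))))
  desc <- rep(genes, each = cfg$n_hairpins)
  shrna <- matrix(NA_real_, nrow = length(hp_names), ncol = length(lines),
                  dimnames = list(hp_names, lines))
  for (cl in lines) {
    mu <- base + cell_wobble[, cl]
    shrna[, cl] <- rep(mu, each = cfg$n_hairpins) +
      stats::rnorm(length(hp_names), sd = cfg$noise_sd)
  }
  gene_scores <- matrix(NA_real_, nrow = length(genes), ncol = length(lines),
                        dimnames = list(genes, lines))
  for (cl in lines) {
    by_gene <- split(shrna[, cl], desc)
    collapsed <- collapse_shrna_to_gene(by_gene)
    gene_scores[names(collapsed), cl] <- collapsed
  }
  list(shrna = shrna, description = stats::setNames(desc, hp_names),
       gene_scores = gene_scores, gene_base = base)
}

# Default planted survival PPI: the hub-hub edge with the largest
# summed degree, falling back to the top hub's heaviest edge.
default_planted_ppi <- function(sp) {
  g <- as_igraph(sp)
  deg <- igraph::degree(g)
  hubs <- attr(sp, "hub_genes")
  e <- sp$edges
  both_hub <- e$protein_1 %in% hubs & e$protein_2 %in% hubs
  cand <- if (any(both_hub)) e[both_hub, , drop = FALSE] else e
  sums <- deg[cand$protein_1] + deg[cand$protein_2]
  top <- cand[which.max(sums), ]
  ppi_id(top$protein_1, top$protein_2)
}

#' Generate contexts, drug screen and patient survival tables
#'
#' Cell-line contexts lose each gene independently at `mutation_rate`
#' with a random event type. The PPI essentiality matrix is computed
#' from the generated screen; the planted compound's AUC is the planted
#' target's mean PPI essentiality per cell line, standardized and mixed
#' with Gaussian noise calibrated to `target_correlation`; the other
#' compounds get independent AUCs and random non-hub target genes.
#' Patients lose the planted survival PPI (a nonsense/frameshift
#' mutation or homozygous deletion of one partner) at
#' `ppi_absence_rate`; survival is exponential with the hazard
#' multiplied by `hazard_ratio` for patients retaining the PPI, censored
#' administratively at `censor_horizon` days.
#'
#' @param cfg a [simulation_config()].
#' @param sp the superpathway.
#' @param ess the screen from [generate_essentiality()].
#' @param prop_cfg a [propagation_config()] used to score the matrix.
#' @return list with `contexts`, `matrix` (PPI essentiality),
#'   `drug` (`auc` long data.frame, `targets` list), `patients`
#'   (`mutations`, `clinical` data.frames) and `planted` metadata.
#' @export
generate_contexts_drugs_survival <- function(cfg, sp, ess,
                                             prop_cfg = propagation_config()) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(sp, "superpathway"))
  genes <- sp$nodes
  lines <- colnames(ess$gene_scores)
  hubs <- attr(sp, "hub_genes")

  ## contexts -------------------------------------------------------
  set.seed(stage_seed(cfg, "contexts"))
  event_types <- c("mutation", "homozygous_deletion", "not_expressed")
  contexts <- lapply(stats::setNames(lines, lines), function(cl) {
    lost <- genes[stats::runif(length(genes)) < cfg$mutation_rate]
    ctx <- cell_line_context(cl, lost_genes = lost,
                             measured_genes = rownames(ess$gene_scores))
    attr(ctx, "lost_events") <- data.frame(
      gene = lost,
      event = if (length(lost)) sample(event_types, length(lost),
                                       replace = TRUE) else character(),
      stringsAsFactors = FALSE)
    ctx
  })

  mat <- score_matrix(sp, ess$gene_scores, contexts, prop_cfg)

  ## drug screen ----------------------------------------------------
  set.seed(stage_seed(cfg, "drugs"))
  target <- cfg$planted_drug_target
  if (is.null(target)) {
    deg <- igraph::degree(as_igraph(sp))
    target <- names(which.max(deg[hubs]))
  }
  if (!target %in% genes) {
    stop("planted drug target '", target, "' is not in the network")
  }
  compounds <- sprintf("CPD%02d", seq_len(cfg$n_compounds))
  partners <- parse_ppi_id(rownames(mat))
  tgt_rows <- partners[, 1L] == target | partners[, 2L] == target
  z <- colMeans(mat[tgt_rows, , drop = FALSE], na.rm = TRUE)
  usable <- is.finite(z)
  zs <- as.numeric(scale(z[usable]))
  r <- cfg$target_correlation
  noise_sd <- sqrt(1 / r^2 - 1)
  auc_rows <- list(data.frame(
    compound = compounds[1L], cell_line = names(z)[usable],
    auc = 3 + zs + stats::rnorm(sum(usable), sd = noise_sd),
    stringsAsFactors = FALSE))
  targets <- list(target)
  non_hub <- setdiff(genes, hubs)
  for (k in seq_along(compounds)[-1L]) {
    targets[[k]] <- sample(non_hub, 2L)
    auc_rows[[k]] <- data.frame(
      compound = compounds[k], cell_line = lines,
      auc = stats::rnorm(length(lines), mean = 3),
      stringsAsFactors = FALSE)
  }
  names(targets) <- compounds
  drug <- list(auc = do.call(rbind, auc_rows), targets = targets)

  ## patient survival -----------------------------------------------
  set.seed(stage_seed(cfg, "survival"))
  planted_ppi <- cfg$planted_survival_ppi
  if (is.null(planted_ppi)) planted_ppi <- default_planted_ppi(sp)
  pp <- as.vector(parse_ppi_id(planted_ppi))
  if (!all(pp %in% genes)) {
    stop("planted survival PPI '", planted_ppi, "' is not in the network")
  }
  patients <- sprintf("PT%04d", seq_len(cfg$n_patients))
  absent <- stats::runif(cfg$n_patients) < cfg$ppi_absence_rate
  mut_rows <- list()
  for (i in seq_len(cfg$n_patients)) {
    rows <- NULL
    if (absent[i]) {
      kind <- sample(c("nonsense", "frameshift", "homdel"), 1L)
      rows <- data.frame(
        patient = patients[i],
        gene = sample(pp, 1L),
        variant_class = if (kind == "homdel") "wildtype" else kind,
        copy_state = if (kind == "homdel") "homozygous_deletion"
                     else "neutral",
        stringsAsFactors = FALSE)
    }
    n_bg <- stats::rbinom(1L, 4L, 0.4)  # passenger missense mutations
    if (n_bg > 0L) {
      rows <- rbind(rows, data.frame(
        patient = patients[i],
        gene = sample(setdiff(genes, pp), n_bg),
        variant_class = "missense", copy_state = "neutral",
        stringsAsFactors = FALSE))
    }
    mut_rows[[i]] <- rows
  }
  mutations <- do.call(rbind, mut_rows)
  hazard <- cfg$baseline_hazard * ifelse(absent, 1, cfg$hazard_ratio)
  t_event <- stats::rexp(cfg$n_patients, rate = hazard)
  clinical <- data.frame(
    patient = patients,
    time = pmin(t_event, cfg$censor_horizon),
    event = as.integer(t_event <= cfg$censor_horizon),
    stringsAsFactors = FALSE)

  list(contexts = contexts, matrix = mat, drug = drug,
       patients = list(mutations = mutations, clinical = clinical),
       planted = list(drug_target = target, compound = compounds[1L],
                      survival_ppi = planted_ppi,
                      ppi_absent = stats::setNames(absent, patients),
                      hub_genes = hubs))
}

#' Generate and write a complete synthetic dataset
#'
#' Runs all generator stages and writes every file the pipeline
#' consumes: `network.sif`, `essentiality.gct`, `contexts.tsv`,
#' `drug_auc.tsv`, `drug_targets.tsv`, `patient_mutations.tsv`,
#' `clinical.tsv`, the scored `essentiality_matrix.tsv`, and the
#' resolved `sim_config.txt`. Identical configurations produce
#' byte-identical files.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param prop_cfg a [propagation_config()] for matrix scoring.
#' @return (invisibly) list with all generated objects plus `paths`.
#' @export
simulate_dataset <- function(cfg, dir, prop_cfg = propagation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- generate_network(cfg)
  ess <- generate_essentiality(cfg, sp)
  rest <- generate_contexts_drugs_survival(cfg, sp, ess, prop_cfg)
  paths <- list(
    network = file.path(dir, "network.sif"),
    gct = file.path(dir, "essentiality.gct"),
    contexts = file.path(dir, "contexts.tsv"),
    drug_auc = file.path(dir, "drug_auc.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    mutations = file.path(dir, "patient_mutations.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    matrix = file.path(dir, "essentiality_matrix.tsv"),
    config = file.path(dir, "sim_config.txt"))
  write_sif(sp, paths$network)
  write_gct(ess$shrna, paths$gct, description = ess$description)
  write_contexts(rest$contexts, paths$contexts)
  write_tsv_plain(rest$drug$auc, paths$drug_auc)
  tg <- data.frame(
    compound = rep(names(rest$drug$targets),
                   lengths(rest$drug$targets)),
    target_gene = unlist(rest$drug$targets, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv_plain(tg, paths$drug_targets)
  write_tsv_plain(rest$patients$mutations, paths$mutations)
  write_tsv_plain(rest$patients$clinical, paths$clinical)
  write_essentiality_matrix(rest$matrix, paths$matrix)
  write_run_config(run_config(
    seed = cfg$seed, n_proteins = cfg$n_proteins,
    n_pathways = cfg$n_pathways,
    pathway_size_range = paste(cfg$pathway_size_range, collapse = "-"),
    hub_fraction = cfg$hub_fraction, n_cell_lines = cfg$n_cell_lines,
    essential_hub_bias = cfg$essential_hub_bias,
    mutation_rate = cfg$mutation_rate, n_patients = cfg$n_patients,
    hazard_ratio = cfg$hazard_ratio, noise_sd = cfg$noise_sd,
    alpha = prop_cfg$alpha, w = prop_cfg$w, tol = prop_cfg$tol,
    update_mode = prop_cfg$update_mode,
    planted_compound = rest$planted$compound,
    planted_drug_target = rest$planted$drug_target,
    planted_survival_ppi = rest$planted$survival_ppi),
    paths$config)
  invisible(c(list(superpathway = sp, essentiality = ess, paths = paths),
              rest))
}
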