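## Umbrella pipeline: simulate (optional) -> demultiplex -> background
## correction -> preprocess/embed -> CLARA ensemble -> trajectory ->
## connectivity landscape, with TSV intermediates in an output directory.

.log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Marker score per cell
#'
#' Mean `log1p` expression of a gene set per cell, used to mark the primed
#' (root) population when rooting the trajectory.
#'
#' @param counts Genes x cells count matrix.
#' @param genes Marker gene names (missing ones are ignored with a
#'   warning).
#' @return Numeric vector, one score per cell.
#' @export
marker_score <- function(counts, genes) {
  found <- intersect(genes, rownames(counts))
  if (!length(found)) stop("none of the marker genes are in the matrix")
  if (length(found) < length(genes))
    warning(length(genes) - length(found), " marker gene(s) not found")
  colMeans(log1p(as.matrix(counts[found, , drop = FALSE])))
}

#' Run the full connectivity-trajectory pipeline
#'
#' Stages: (1) simulate a synthetic dataset or load counts/tags from disk;
#' (2) optional knee-plot cell calling; (3) hashtag normalisation,
#' assignment and fold-change doublet removal; (4) distribution-based
#' background correction; (5) preprocessing and classical MDS;
#' (6) CLARA ensemble and per-cell connectivity; (7) VRC selection, final
#' MST, root, lineages and pseudotime; (8) connectivity landscape. Each
#' stage writes a TSV intermediate to `out_dir` and logs the seed and the
#' surviving cell/gene counts; with `resume = TRUE`, existing final outputs
#' short-circuit the run.
#'
#' @param config A `run_config` from [read_run_config()], a list, or a
#'   YAML path.
#' @param out_dir Output directory (default `config$out_dir` or
#'   `"conntraj_out"`).
#' @return Invisible list with the main in-memory results (`counts`,
#'   `assignments`, `embedding`, `score`, `selection`, `root`, `lineages`,
#'   `pseudotime`, `landscape`).
#' @export
pipeline_run <- function(config = list(), out_dir = NULL) {
  if (is.character(config) || !inherits(config, "run_config"))
    config <- read_run_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- "conntraj_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  finals <- file.path(out_dir, c("embedding.tsv", "trajectory.tsv",
                                 "mst.tsv", "landscape.tsv"))
  if (isTRUE(config$resume) && all(file.exists(finals))) {
    .log("INFO", "resume: all final outputs present in ", out_dir,
         "; skipping recomputation")
    return(invisible(list(out_dir = out_dir, resumed = TRUE)))
  }

  ## -- stage 1: data ------------------------------------------------------
  truth <- NULL
  if (isTRUE(config$simulate) || is.null(config$counts)) {
    sim_args <- config$sim
    if (!is.null(sim_args)) {
      for (nm in c("n_cells_per_state", "program_sizes", "program_logfc",
                   "tag_depth"))
        if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    }
    sc <- do.call(sim_config, c(sim_args, list(seed = seed)))
    .log("INFO", "simulating ", sum(sc$n_cells_per_state), " cells x ",
         sc$n_genes, " genes (seed ", seed, ")")
    sim <- simulate_counts(sc)
    counts <- sim$counts
    truth <- sim$truth
    tags <- simulate_tags(truth, sc)
    write_sim_dataset(sim, tags, sc, file.path(out_dir, "sim"))
  } else {
    .log("INFO", "loading counts from ", config$counts)
    counts <- read_count_matrix(config$counts)
    tags <- if (!is.null(config$tags)) as.matrix(read_count_matrix(config$tags))
  }

  ## -- stage 2: cell calling ---------------------------------------------
  if (isTRUE(config$cell_calling)) {
    thr <- barcode_rank_inflection(Matrix::colSums(counts))
    keep <- Matrix::colSums(counts) >= thr
    .log("INFO", "cell calling: threshold ", signif(thr, 4), ", ",
         sum(keep), " of ", ncol(counts), " barcodes retained")
    counts <- counts[, keep, drop = FALSE]
    if (!is.null(tags)) tags <- tags[, keep, drop = FALSE]
  }

  ## -- stage 3: demultiplexing -------------------------------------------
  assignments <- NULL
  if (!is.null(tags)) {
    rf <- config$demux$remove_fraction
    if (is.null(rf)) rf <- 0.0382
    assignments <- filter_doublets(assign_tags(normalize_tags(tags)), rf)
    write.table(assignments, file.path(out_dir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    keep <- assignments$status == "singlet"
    .log("INFO", "demux: ", sum(keep), " singlets of ", ncol(counts),
         " cells (removed fraction ", rf, ")")
    counts <- counts[, keep, drop = FALSE]
    if (!is.null(truth)) truth <- truth[keep, , drop = FALSE]
  }

  ## -- stage 4: background correction ------------------------------------
  if (!isFALSE(config$bgcorrect$enabled)) {
    gate_args <- config$bgcorrect[intersect(names(config$bgcorrect),
                                            c("min_gene_max",
                                              "max_first_mean",
                                              "min_component_gap"))]
    gates <- do.call(correction_gates, as.list(gate_args))
    counts <- correct_background(counts, gates, report = TRUE)
    rep <- attr(counts, "report")
    if (!is.null(rep))
      write.table(rep, file.path(out_dir, "bgcorrect_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    .log("INFO", "background correction: ",
         if (is.null(rep)) 0 else sum(rep$gated), " gene(s) gated")
  }

  ## -- stage 5: preprocessing + embedding --------------------------------
  pp <- config$preprocess
  pre <- preprocess_counts(counts,
                           min_counts_per_cell = pp$min_counts_per_cell %||% 200,
                           min_cells_per_gene = pp$min_cells_per_gene %||% 3,
                           n_hvg = pp$n_hvg %||% 500)
  .log("INFO", "preprocess: ", nrow(pre), " cells x ", ncol(pre), " HVGs")
  embedding <- embed_cells(pre)
  write.table(data.frame(barcode = rownames(embedding), embedding),
              file.path(out_dir, "embedding.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) truth <- truth[truth$barcode %in% rownames(embedding), ,
                                      drop = FALSE]

  ## -- stage 6: ensemble + connectivity ----------------------------------
  en <- config$ensemble
  ecfg <- ensemble_config(k_min = en$k_min %||% 3, k_max = en$k_max %||% 20,
                          n_runs = en$n_runs %||% 1000,
                          clara_n_samples = en$clara_n_samples %||% 5,
                          base_seed = seed)
  .log("INFO", "ensemble: ", ecfg$n_runs, " CLARA runs, k in [",
       ecfg$k_min, ", ", ecfg$k_max, "], base seed ", ecfg$base_seed)
  runs <- ensemble_cluster(embedding, ecfg)
  conn <- ensemble_connectivity(embedding, runs)
  write.table(data.frame(run = seq_along(runs),
                         k = vapply(runs, `[[`, 0L, "k"),
                         seed = vapply(runs, `[[`, 0L, "seed"),
                         cost = vapply(runs, `[[`, 0, "cost")),
              file.path(out_dir, "runs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## -- stage 7: trajectory ------------------------------------------------
  sel <- rank_and_select(runs, conn$score,
                         top_n = config$trajectory$top_n %||% 20,
                         pick = config$trajectory$pick %||% 1)
  markers <- NULL
  if (!is.null(config$markers)) {
    ms <- marker_score(counts, unlist(config$markers))
    markers <- ms[match(rownames(embedding), colnames(counts))]
  }
  root <- select_root(sel$selected, conn$score, markers)
  final_graph <- cluster_graph(embedding, sel$selected$labels)
  lineages <- extract_lineages(final_graph$mst_edges, root)
  pt <- lineage_pseudotime(embedding, sel$selected, lineages)
  .log("INFO", "trajectory: selected run k=", sel$selected$k, ", root ",
       root, ", ", length(lineages), " lineage(s)")
  write.table(data.frame(from = final_graph$mst_edges[, 1],
                         to = final_graph$mst_edges[, 2],
                         weight = final_graph$dist[final_graph$mst_edges]),
              file.path(out_dir, "mst.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  traj <- merge(pt, data.frame(barcode = rownames(embedding),
                               connectivity = conn$score), by = "barcode")
  write.table(traj[order(traj$cell, traj$lineage),
                   c("barcode", "cluster", "lineage", "pseudotime",
                     "weight", "connectivity")],
              file.path(out_dir, "trajectory.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## -- stage 8: landscape --------------------------------------------------
  res <- config$landscape$grid_resolution %||% 100
  land <- connectivity_landscape(embedding, conn$score, grid_resolution = res)
  write.table(land$grid, file.path(out_dir, "landscape.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(counts = counts, truth = truth, assignments = assignments,
                 embedding = embedding, runs = runs, score = conn$score,
                 selection = sel, root = root, graph = final_graph,
                 lineages = lineages, pseudotime = pt, landscape = land))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
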