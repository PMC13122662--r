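#' @importFrom Matrix Matrix readMM writeMM colSums rowSums t
#' @importFrom methods as is
#' @importFrom stats rnbinom rpois rmultinom rnorm runif dist cov cmdscale
#'   median var setNames quantile cor
#' @importFrom utils combn read.delim write.table head
NULL

## --- state topology -------------------------------------------------------
##
## The latent structure is a rooted tree of line segments parameterised by a
## lineage coordinate t in [0, 1]:
##
##   naive lineage:     primed [0,.2] -> bridge (.2,.45] ->
##                      intermediate_A (.45,.7] -> naive (.7,1]
##   ectoderm lineage:  primed [0,.2] -> intermediate_B (.2,.55] ->
##                      ectoderm (.55,1]
##   mesoderm lineage:  primed [0,.2] -> mesoderm (.2,1]
##
## primed is shared by all three lineages; the Oct4/Nanog-high bridge lies
## on the naive route only, matching the principal trajectories
## primed -> naive via the bridge, primed -> ectoderm, primed -> mesoderm.

.sim_states <- c("primed", "bridge", "intermediate_A", "intermediate_B",
                 "naive", "ectoderm", "mesoderm")

.sim_programs <- c("pluripotency", "naive", "diff_suppressive", "neural",
                   "metallothionein", "mesoderm", "housekeeping")

.sim_lineages <- list(
  naive    = c("primed", "bridge", "intermediate_A", "naive"),
  ectoderm = c("primed", "intermediate_B", "ectoderm"),
  mesoderm = c("primed", "mesoderm")
)

.state_span <- function(state) {
  switch(state,
    primed         = c(0, 0.2),
    bridge         = c(0.2, 0.45),
    intermediate_A = c(0.45, 0.7),
    intermediate_B = c(0.2, 0.55),
    naive          = c(0.7, 1),
    ectoderm       = c(0.55, 1),
    mesoderm       = c(0.2, 1),
    stop("unknown state: ", state))
}

.state_hashtag <- c(primed = "HT1", bridge = "HT2", intermediate_A = "HT2",
                    intermediate_B = "HT2", naive = "HT3",
                    ectoderm = "HT4", mesoderm = "HT4")

#' Configuration for the branching pluripotency-state simulator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_counts()] and [simulate_tags()]. Defaults describe a desk-scale
#' dataset of 3,000 cells in seven biological states (a primed population, an
#' Oct4/Nanog-high bridge, an intermediate hub split into a naive-fated and a
#' neural-fated subpopulation, a naive terminus, an ectoderm terminus and a
#' mesoderm-like offshoot) with seven gene programs.
#'
#' @param n_cells_per_state Named integer vector of cells per state. Names
#'   must be a subset of the seven canonical states.
#' @param n_genes Total number of genes; genes not belonging to any program
#'   are background genes expressed at `base_mean`.
#' @param program_sizes Named integer vector of genes per program
#'   (pluripotency, naive, diff_suppressive, neural, metallothionein,
#'   mesoderm, housekeeping). Must sum to at most `n_genes`.
#' @param program_logfc Positive per-program natural-log fold change applied
#'   at full activation. A single value is recycled.
#' @param nb_dispersion Negative-binomial size parameter; larger values
#'   approach the Poisson limit.
#' @param base_mean Expected count of an OFF gene.
#' @param branch_noise_sd Gaussian jitter (in lineage-coordinate units)
#'   applied to each cell's position along its branch before activations are
#'   evaluated; 0 gives noise-free data.
#' @param doublet_rate Fraction of output cells that are synthetic doublets,
#'   in [0, 0.5].
#' @param tag_depth Named positive vector of expected hashtag reads per cell
#'   for each hashtag library; unequal by default to exercise normalisation.
#'   A single value is recycled over the four hashtags.
#' @param tag_background_fraction Fraction of a cell's hashtag reads spread
#'   uniformly over the other hashtags, in [0, 0.5].
#' @param discrete_states If `TRUE`, activations are evaluated at each
#'   state's midpoint so states become exchangeable blobs (useful for
#'   discrete-cluster benchmarks); default `FALSE` keeps the latent-time
#'   ramps.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_state = c(primed = 800, bridge = 200,
                                             intermediate_A = 350,
                                             intermediate_B = 250,
                                             naive = 400, ectoderm = 400,
                                             mesoderm = 600),
                       n_genes = 2000,
                       program_sizes = setNames(rep(50L, 7), .sim_programs),
                       program_logfc = 2,
                       nb_dispersion = 2,
                       base_mean = 0.3,
                       branch_noise_sd = 0.05,
                       doublet_rate = 0.05,
                       tag_depth = c(HT1 = 300, HT2 = 500, HT3 = 700,
                                     HT4 = 900),
                       tag_background_fraction = 0.05,
                       discrete_states = FALSE,
                       seed = 1L) {
  if (is.null(names(n_cells_per_state)) ||
      !all(names(n_cells_per_state) %in% .sim_states))
    stop("n_cells_per_state must be named with states among: ",
         paste(.sim_states, collapse = ", "))
  if (any(n_cells_per_state <= 0) || any(n_cells_per_state != round(n_cells_per_state)))
    stop("n_cells_per_state must be positive integers")
  if (is.null(names(program_sizes)))
    names(program_sizes) <- .sim_programs[seq_along(program_sizes)]
  if (!all(names(program_sizes) %in% .sim_programs))
    stop("unknown program in program_sizes")
  if (any(program_sizes < 0)) stop("program_sizes must be non-negative")
  if (sum(program_sizes) > n_genes)
    stop("sum of program_sizes (", sum(program_sizes),
         ") exceeds n_genes (", n_genes, ")")
  if (length(program_logfc) == 1)
    program_logfc <- setNames(rep(program_logfc, length(program_sizes)),
                              names(program_sizes))
  if (any(program_logfc < 0)) stop("program_logfc must be non-negative")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (base_mean <= 0) stop("base_mean must be positive")
  if (branch_noise_sd < 0) stop("branch_noise_sd must be non-negative")
  if (doublet_rate < 0 || doublet_rate > 0.5)
    stop("doublet_rate must be in [0, 0.5]")
  if (length(tag_depth) == 1)
    tag_depth <- c(HT1 = tag_depth, HT2 = tag_depth, HT3 = tag_depth,
                   HT4 = tag_depth)
  if (any(tag_depth <= 0)) stop("tag_depth must be positive")
  if (tag_background_fraction < 0 || tag_background_fraction > 0.5)
    stop("tag_background_fraction must be in [0, 0.5]")
  structure(list(n_cells_per_state = n_cells_per_state,
                 n_genes = as.integer(n_genes),
                 program_sizes = program_sizes,
                 program_logfc = program_logfc,
                 nb_dispersion = nb_dispersion,
                 base_mean = base_mean,
                 branch_noise_sd = branch_noise_sd,
                 doublet_rate = doublet_rate,
                 tag_depth = tag_depth,
                 tag_background_fraction = tag_background_fraction,
                 discrete_states = isTRUE(discrete_states),
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Program activation for one cell. `t` is the (possibly jittered) lineage
## coordinate; returns a named numeric over .sim_programs in [0, 1].
##
## Geometry: the primed population is a large compact mass (constant
## pluripotency) from which the arms radiate in near-orthogonal program
## directions; the bridge is a short connector (partial naive-related
## expression) leading into the intermediate hub, whose naive-fated (A) and
## neural-fated (B) subpopulations share a broad profile (the naive-program
## plateau) and differ in the naive/diff-suppressive/metallothionein versus
## neural ramps; termini lie at the ends of long arms. This mirrors a
## connectivity landscape in which the primed mass is central, the hub is
## an elevated corridor and the termini are peripheral.
.activation <- function(state, lineage, t) {
  a <- setNames(numeric(length(.sim_programs)), .sim_programs)
  a["housekeeping"] <- 1
  ## baseline pluripotency 0.75 everywhere pluripotent; the bridge is the
  ## Oct4/Nanog-high subpopulation — a triangular excursion peaking
  ## mid-bridge — so it hangs off the primed-hub corridor rather than
  ## sitting on its axis
  a["pluripotency"] <- switch(state,
    primed = 0.55 + 0.25 * t,
    bridge = 1,
    intermediate_A = 0.6, naive = 0.6,
    intermediate_B = 0.6,
    ectoderm = 0.6 - 0.2 * (t - 0.55) / 0.45,
    mesoderm = 0.6 * (1 - (t - 0.2) / 0.8))
  ## the neural-fated subpopulation diverges early (low naive plateau), so
  ## the ectoderm arm anchors near the primed junction: the reconstructed
  ## MST then shows a direct primed -> ectoderm trajectory while the
  ## hub-to-ectoderm corridor remains visible only in the connectivity
  ## landscape
  a["naive"] <- switch(state,
    primed = 0,
    bridge = 0.15 * (t - 0.2) / 0.25,
    intermediate_A = 0.15 + 0.5 * (t - 0.45) / 0.25,
    intermediate_B = 0.05,
    naive = 0.65 + 0.35 * (t - 0.7) / 0.3,
    ectoderm = 0.05 * (1 - (t - 0.55) / 0.45),
    mesoderm = 0)
  if (state == "intermediate_A")
    a["metallothionein"] <- 0.5 * (t - 0.45) / 0.25
  if (state == "naive")
    a["metallothionein"] <- 0.5 + 0.5 * (t - 0.7) / 0.3
  if (state == "intermediate_A") {
    ## triangular excursion peaking mid-state: marks the naive-fated
    ## subpopulation without displacing the state's end points
    a["diff_suppressive"] <- 0.5 * (1 - abs(t - 0.575) / 0.125)
  }
  ## multilineage priming: uncommitted states express the neural and
  ## mesoderm programs at a low baseline that is extinguished along the
  ## opposing arms — this makes the three arm directions pairwise
  ## negatively correlated, so the branching structure opens up in a 2-D
  ## embedding instead of collapsing one arm
  a["neural"] <- switch(state,
    primed = 0.25, bridge = 0.25, intermediate_A = 0.25,
    naive = 0.25 * (1 - (t - 0.7) / 0.3),
    intermediate_B = 0.25 + 0.35 * (t - 0.2) / 0.35,
    ectoderm = 0.6 + 0.4 * (t - 0.55) / 0.45,
    mesoderm = 0.25 * (1 - (t - 0.2) / 0.8))
  a["mesoderm"] <- switch(state,
    primed = 0.25, bridge = 0.25,
    intermediate_A = 0.25 * (1 - (t - 0.45) / 0.25),
    naive = 0,
    intermediate_B = 0.25 * (1 - (t - 0.2) / 0.35),
    ectoderm = 0,
    mesoderm = 0.25 + 0.75 * (t - 0.2) / 0.8)
  pmin(pmax(a, 0), 1)
}

.gene_programs <- function(config) {
  sizes <- config$program_sizes
  prog <- rep("background", config$n_genes)
  idx <- 1L
  for (p in names(sizes)) {
    if (sizes[[p]] > 0) {
      prog[idx:(idx + sizes[[p]] - 1L)] <- p
      idx <- idx + sizes[[p]]
    }
  }
  genes <- character(config$n_genes)
  for (p in unique(prog)) {
    w <- which(prog == p)
    genes[w] <- sprintf("%s_%03d", p, seq_along(w))
  }
  data.frame(gene = genes, program = prog, stringsAsFactors = FALSE)
}

#' Simulate a branching pluripotency-state count matrix
#'
#' Draws negative-binomial counts whose log-mean is
#' `log(base_mean) + sum_p logfc_p * membership * activation_p(state, t)`,
#' where activations are piecewise-linear functions of the cell's position
#' `t` along its lineage (see [sim_config()]). Doublets are injected by
#' summing the counts of randomly paired extra cells, so the returned matrix
#' has exactly `sum(n_cells_per_state)` columns.
#'
#' @param config A [sim_config()] object.
#' @return A list with `counts` (sparse genes x cells `dgCMatrix`) and
#'   `truth` (a data frame with one row per cell: `barcode`, `state`,
#'   `lineage`, `latent_time`, `is_doublet`, `hashtag`, plus `state2` /
#'   `hashtag2` for the second parent of a doublet; the per-gene program map
#'   is attached as `attr(truth, "gene_programs")`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$n_cells_per_state)
  n_dbl <- floor(config$doublet_rate * n)

  states <- rep(names(config$n_cells_per_state), config$n_cells_per_state)
  if (n_dbl > 0) {
    extra <- sample(names(config$n_cells_per_state), n_dbl, replace = TRUE,
                    prob = config$n_cells_per_state / n)
    states <- c(states, extra)
  }
  m <- length(states)

  lineage <- vapply(states, function(s) {
    home <- names(.sim_lineages)[vapply(.sim_lineages, function(l) s %in% l,
                                        logical(1))]
    if (length(home) == 1) home else sample(home, 1)
  }, character(1))
  tt <- vapply(states, function(s) {
    sp <- .state_span(s)
    runif(1, sp[1], sp[2])
  }, numeric(1))
  if (config$discrete_states) {
    tt <- vapply(states, function(s) mean(.state_span(s)), numeric(1))
  }
  t_eff <- tt
  if (config$branch_noise_sd > 0 && !config$discrete_states)
    t_eff <- pmin(pmax(tt + rnorm(m, 0, config$branch_noise_sd), 0), 1)

  gp <- .gene_programs(config)
  logfc <- config$program_logfc

  ## programs x cells activation matrix
  act <- vapply(seq_len(m),
                function(i) .activation(states[i], lineage[i], t_eff[i]),
                numeric(length(.sim_programs)))
  ## genes x cells log fold change
  lfc_gene <- setNames(numeric(length(.sim_programs)), .sim_programs)
  lfc_gene[names(logfc)] <- logfc
  gene_fc <- matrix(0, nrow = config$n_genes, ncol = m)
  for (p in .sim_programs) {
    w <- which(gp$program == p)
    if (length(w)) gene_fc[w, ] <- rep(lfc_gene[[p]] * act[p, ],
                                       each = length(w))
  }
  mu <- config$base_mean * exp(gene_fc)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
                   nrow = config$n_genes)
  rownames(counts) <- gp$gene
  colnames(counts) <- sprintf("cell_%05d", seq_len(m))

  truth <- data.frame(barcode = colnames(counts),
                      state = states, lineage = lineage, latent_time = tt,
                      is_doublet = FALSE,
                      hashtag = unname(.state_hashtag[states]),
                      state2 = NA_character_, hashtag2 = NA_character_,
                      parent1 = NA_character_, parent2 = NA_character_,
                      stringsAsFactors = FALSE)
  attr(truth, "gene_programs") <- gp

  counts <- as(Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (n_dbl > 0) {
    out <- inject_doublets(counts, truth, rate = config$doublet_rate,
                           seed = config$seed + 7L, n_doublets = n_dbl)
    counts <- out$counts
    truth <- out$truth
  }
  stopifnot(ncol(counts) == n)
  list(counts = counts, truth = truth)
}

#' Merge random cell pairs into synthetic doublets
#'
#' Selects `floor(rate * ncol(counts))` disjoint cell pairs (unless
#' `n_doublets` overrides the count), sums each pair's gene counts into a
#' single synthetic cell flagged as a doublet, and drops the parents.
#'
#' @param counts Genes x cells count matrix.
#' @param truth Companion truth table (one row per cell).
#' @param rate Doublet fraction in [0, 0.5].
#' @param seed Integer seed.
#' @param n_doublets Optional explicit number of doublets, overriding `rate`.
#' @return List with updated `counts` and `truth`; doublet rows carry both
#'   parents' states and hashtags.
#' @export
inject_doublets <- function(counts, truth, rate, seed = 1L,
                            n_doublets = NULL) {
  if (rate < 0 || rate > 0.5) stop("rate must be in [0, 0.5]")
  n <- ncol(counts)
  d <- if (is.null(n_doublets)) floor(rate * n) else as.integer(n_doublets)
  if (d == 0) return(list(counts = counts, truth = truth))
  if (2L * d > n) stop("not enough cells to form ", d, " doublet pairs")
  set.seed(seed)
  picked <- sample(n, 2L * d)
  p1 <- picked[seq_len(d)]
  p2 <- picked[d + seq_len(d)]
  dbl <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  colnames(dbl) <- sprintf("dblt_%04d", seq_len(d))

  gp <- attr(truth, "gene_programs")
  dbl_truth <- truth[p1, , drop = FALSE]
  dbl_truth$barcode <- colnames(dbl)
  dbl_truth$is_doublet <- TRUE
  dbl_truth$state2 <- truth$state[p2]
  dbl_truth$hashtag2 <- truth$hashtag[p2]
  dbl_truth$parent1 <- truth$barcode[p1]
  dbl_truth$parent2 <- truth$barcode[p2]
  if (is.null(truth$parent1)) {
    truth$parent1 <- NA_character_
    truth$parent2 <- NA_character_
  }
  keep <- setdiff(seq_len(n), picked)
  counts_out <- cbind(counts[, keep, drop = FALSE], dbl)
  truth_out <- rbind(truth[keep, , drop = FALSE], dbl_truth)
  rownames(truth_out) <- NULL
  attr(truth_out, "gene_programs") <- gp
  list(counts = counts_out, truth = truth_out)
}

#' Simulate hashtag (HTO) count libraries
#'
#' Each singlet receives `Poisson(depth)` reads distributed multinomially:
#' fraction `1 - background` on its own hashtag and `background` spread
#' uniformly over the others. A doublet draws
#' `Poisson(depth[h1] + depth[h2])` reads split between its two parents'
#' hashtags in proportion to their library depths. Library depths are
#' deliberately unequal by default so that linear normalisation is exercised.
#'
#' @param truth Truth table from [simulate_counts()].
#' @param config The same [sim_config()] object.
#' @return Hashtags x cells integer matrix (dense), hashtags in rows.
#' @export
simulate_tags <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  tags <- names(config$tag_depth)
  if (length(tags) < 2 && config$doublet_rate > 0)
    stop("need at least 2 hashtags when doublet_rate > 0")
  set.seed(config$seed + 1L)
  bg <- config$tag_background_fraction
  H <- length(tags)
  out <- matrix(0L, nrow = H, ncol = nrow(truth),
                dimnames = list(tags, truth$barcode))
  for (i in seq_len(nrow(truth))) {
    h1 <- truth$hashtag[i]
    if (isTRUE(truth$is_doublet[i]) && !is.na(truth$hashtag2[i])) {
      h2 <- truth$hashtag2[i]
      depth <- config$tag_depth[[h1]] + config$tag_depth[[h2]]
      own <- unique(c(h1, h2))
      w <- setNames(numeric(H), tags)
      if (length(own) == 2) {
        w[h1] <- w[h1] + (1 - bg) * config$tag_depth[[h1]] /
          (config$tag_depth[[h1]] + config$tag_depth[[h2]])
        w[h2] <- w[h2] + (1 - bg) * config$tag_depth[[h2]] /
          (config$tag_depth[[h1]] + config$tag_depth[[h2]])
      } else w[h1] <- 1 - bg
      rest <- setdiff(tags, own)
      if (length(rest)) w[rest] <- bg / length(rest) else w[own] <- w[own] + bg / length(own)
    } else {
      depth <- config$tag_depth[[h1]]
      w <- setNames(rep(bg / max(H - 1, 1), H), tags)
      w[h1] <- if (H > 1) 1 - bg else 1
    }
    total <- rpois(1, depth)
    if (total > 0) out[, i] <- rmultinom(1, total, w)[, 1]
  }
  out
}

#' Inject ambient background counts into bright genes
#'
#' Adds small spurious counts (1 + Poisson(`lambda`)) to a fraction of the
#' cells in which the given genes are effectively silent, emulating ambient
#' RNA / index hopping. Used to benchmark [correct_background()].
#'
#' @param counts Genes x cells count matrix.
#' @param genes Gene names to contaminate.
#' @param rate Fraction of off cells per gene that receive ambient counts.
#' @param lambda Poisson mean of the added counts (plus 1).
#' @param off_below Counts strictly below this value mark a cell as "off"
#'   for the gene.
#' @param seed Integer seed.
#' @return List with `counts` (contaminated matrix) and `injected`, a
#'   two-column matrix of (gene row, cell column) indices that were altered.
#' @export
inject_ambient <- function(counts, genes, rate = 0.2, lambda = 3,
                           off_below = 5, seed = 1L) {
  stopifnot(all(genes %in% rownames(counts)))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  set.seed(seed)
  counts <- as(counts, "CsparseMatrix")
  ij <- list()
  for (g in genes) {
    r <- which(rownames(counts) == g)
    off <- which(counts[r, ] < off_below)
    pick <- off[runif(length(off)) < rate]
    if (length(pick)) {
      counts[r, pick] <- counts[r, pick] + 1L + rpois(length(pick), lambda)
      ij[[g]] <- cbind(rep(r, length(pick)), pick)
    }
  }
  injected <- do.call(rbind, ij)
  list(counts = counts, injected = injected)
}

#' Write a simulated dataset to disk
#'
#' Emits the count matrix as Matrix Market plus `genes.tsv` / `barcodes.tsv`,
#' the hashtag matrix likewise, the truth table as `truth.tsv` and the
#' configuration as `config.yaml`.
#'
#' @param sim Output of [simulate_counts()].
#' @param tags Optional hashtag matrix from [simulate_tags()].
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, tags = NULL, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(sim$counts, file.path(dir, "counts.mtx"))
  truth <- sim$truth
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gp <- attr(truth, "gene_programs")
  if (!is.null(gp))
    write.table(gp, file.path(dir, "gene_programs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(tags))  # own subdirectory so label files cannot collide
    write_count_matrix(Matrix(tags, sparse = TRUE),
                       file.path(dir, "tags", "tags.mtx"))
  cfg <- config
  class(cfg) <- NULL
  cfg$n_cells_per_state <- as.list(cfg$n_cells_per_state)
  cfg$program_sizes <- as.list(cfg$program_sizes)
  cfg$program_logfc <- as.list(cfg$program_logfc)
  cfg$tag_depth <- as.list(cfg$tag_depth)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
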