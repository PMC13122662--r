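# Shared helpers: small configurations, the primed marker contrast used to
# root benchmark trajectories, and independent oracles (Pruefer-sequence MST
# enumeration, brute-force k-medoids).

small_sizes <- c(primed = 80, bridge = 20, intermediate_A = 35,
                 intermediate_B = 25, naive = 40, ectoderm = 40,
                 mesoderm = 60)

# 20 genes per program (140 total) for configs with few genes
small_programs <- setNames(rep(20L, 7),
                           c("pluripotency", "naive", "diff_suppressive",
                             "neural", "metallothionein", "mesoderm",
                             "housekeeping"))

# Primed-state score: pluripotency-marker expression penalised by
# naive-related (incl. metallothionein) expression; operationally primed
# cells are the naive-marker-negative pluripotent ones.
primed_marker <- function(counts) {
  marker_score(counts, sprintf("pluripotency_%03d", 1:50)) -
    2 * (marker_score(counts, sprintf("naive_%03d", 1:50)) +
         marker_score(counts, sprintf("metallothionein_%03d", 1:50)))
}

# Full trajectory reconstruction on one simulated dataset; returns the
# pieces needed by the recovery checks.
run_trajectory <- function(seed, n_runs = 200, config = sim_config(seed = seed)) {
  sim <- simulate_counts(config)
  pre <- preprocess_counts(sim$counts)
  emb <- embed_cells(pre)
  runs <- ensemble_cluster(emb, ensemble_config(n_runs = n_runs,
                                                base_seed = seed))
  conn <- ensemble_connectivity(emb, runs)
  sel <- rank_and_select(runs, conn$score)
  root <- select_root(sel$selected, conn$score, primed_marker(sim$counts))
  graph <- cluster_graph(emb, sel$selected$labels)
  lineages <- extract_lineages(graph$mst_edges, root)
  labels <- sel$selected$labels
  majority <- vapply(seq_len(max(labels)), function(j)
    names(which.max(table(sim$truth$state[labels == j]))), character(1))
  leaves <- vapply(lineages, function(l) majority[l[length(l)]], character(1))
  list(sim = sim, truth = sim$truth, embedding = emb, runs = runs,
       score = conn$score, selected = sel$selected, root = root,
       graph = graph, lineages = lineages, labels = labels,
       majority = majority, leaves = leaves)
}

# Did the reconstruction recover the primed-rooted three-trajectory tree?
lineage_recovery_ok <- function(r) {
  root_ok <- r$majority[r$root] == "primed"
  term_ok <- all(c("naive", "ectoderm", "mesoderm") %in% r$leaves)
  nl <- which(r$leaves == "naive")
  via_ok <- FALSE
  if (length(nl)) {
    path_clusters <- unique(unlist(r$lineages[nl]))
    hub <- which(r$truth$state %in% c("bridge", "intermediate_A") &
                   !r$truth$is_doublet)
    via_ok <- mean(r$labels[hub] %in% path_clusters) > 0.5
  }
  root_ok && term_ok && via_ok
}

# Spearman correlation between reconstructed pseudotime and true latent
# time for the cells of each true lineage, evaluated on the reconstructed
# lineage ending in the matching terminus.
pseudotime_recovery <- function(r) {
  pt <- lineage_pseudotime(r$embedding, r$selected, r$lineages)
  vapply(c("naive", "ectoderm", "mesoderm"), function(target) {
    li <- which(r$leaves == target)[1]
    if (is.na(li)) return(NA_real_)
    sub <- pt[pt$lineage == li, ]
    m <- match(sub$barcode, r$truth$barcode)
    keep <- r$truth$lineage[m] == target
    cor(sub$pseudotime[keep], r$truth$latent_time[m][keep],
        method = "spearman")
  }, numeric(1))
}

# Independent MST oracle: enumerate all labelled spanning trees on k nodes
# via Pruefer sequences and return the minimum total weight.
prufer_tree_edges <- function(prufer, k) {
  degree <- rep(1L, k)
  for (p in prufer) degree[p] <- degree[p] + 1L
  edges <- matrix(0L, k - 1, 2)
  ptr <- 1L
  for (i in seq_along(prufer)) {
    leaf <- which(degree == 1L)[1]
    edges[ptr, ] <- c(leaf, prufer[i])
    ptr <- ptr + 1L
    degree[leaf] <- 0L
    degree[prufer[i]] <- degree[prufer[i]] - 1L
  }
  edges[ptr, ] <- which(degree == 1L)
  edges
}

min_spanning_weight_bruteforce <- function(d) {
  k <- nrow(d)
  if (k == 1) return(0)
  if (k == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- prufer_tree_edges(seqs[i, ], k)
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

# Brute-force k-medoids: minimum cost over all C(n, k) medoid sets.
pam_cost_bruteforce <- function(d, k) {
  n <- nrow(d)
  sets <- combn(n, k)
  best <- Inf
  for (i in seq_len(ncol(sets))) {
    cost <- sum(apply(d[, sets[, i], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

random_symmetric_distance <- function(k) {
  m <- matrix(runif(k * k, 0.1, 10), k, k)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  d
}
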