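## Preprocessing, classical MDS embedding and the CLARA k-medoids ensemble.

#' Normalise, filter and select highly variable genes
#'
#' Removes cells with total counts below `min_counts_per_cell` and genes
#' detected in fewer than `min_cells_per_gene` cells, scales every cell to
#' the median surviving cell total, applies `log1p`, and keeps the
#' `n_hvg` genes with the highest variance of the log-normalised values.
#'
#' @param counts Genes x cells count matrix.
#' @param min_counts_per_cell Minimum total counts per cell (default 200).
#' @param min_cells_per_gene Minimum number of cells a gene must be
#'   detected in (default 3).
#' @param n_hvg Number of highly variable genes to keep (default 500).
#' @return Dense cells x HVGs matrix of log-normalised expression, with
#'   barcodes as row names.
#' @export
preprocess_counts <- function(counts, min_counts_per_cell = 200,
                              min_cells_per_gene = 3, n_hvg = 500) {
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  totals <- Matrix::colSums(counts)
  keep_cells <- totals >= min_counts_per_cell
  detected <- Matrix::rowSums(counts[, keep_cells, drop = FALSE] > 0)
  keep_genes <- detected >= min_cells_per_gene
  if (!any(keep_cells) || !any(keep_genes))
    stop("preprocessing removed everything: ", sum(keep_cells), " of ",
         ncol(counts), " cells and ", sum(keep_genes), " of ",
         nrow(counts), " genes survive the thresholds")
  m <- counts[keep_genes, keep_cells, drop = FALSE]
  totals <- totals[keep_cells]
  target <- median(totals)
  norm <- Matrix::t(m) * (target / totals)  # cells x genes
  lognorm <- as.matrix(log1p(norm))
  v <- apply(lognorm, 2, var)
  n_hvg <- min(n_hvg, ncol(lognorm))
  hvg <- order(v, decreasing = TRUE)[seq_len(n_hvg)]
  lognorm[, sort(hvg), drop = FALSE]
}

#' Classical (Torgerson) multidimensional scaling to two dimensions
#'
#' Double-centres -D^2/2 and projects onto the top two eigenpairs. The sign
#' of each axis is fixed so that its first non-zero coordinate is positive,
#' making the embedding deterministic.
#'
#' @param dissimilarity Square symmetric non-negative matrix with zero
#'   diagonal (or a `dist` object).
#' @return Cells x 2 coordinate matrix, row names preserved.
#' @export
classical_mds <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  if (any(d < 0)) stop("dissimilarity matrix must be non-negative")
  if (max(abs(d - Matrix::t(d))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("dissimilarity matrix must have zero diagonal")
  n <- nrow(d)
  if (n <= 500) {
    xy <- cmdscale(d, k = 2)
  } else {
    ## large inputs: only the top eigenpairs of the double-centred matrix
    ## are needed; deterministic subspace iteration is much cheaper than a
    ## full eigendecomposition
    D2 <- d^2
    rmns <- rowMeans(D2)
    B <- -0.5 * (sweep(sweep(D2, 1, rmns), 2, rmns) + mean(D2))
    p <- 6L
    V <- qr.Q(qr(cbind(sin(outer(seq_len(n), seq_len(p) * 0.7)))))
    lam_old <- rep(Inf, 2)
    for (it in seq_len(300)) {
      V <- qr.Q(qr(B %*% V))
      if (it %% 10 == 0) {
        Tm <- crossprod(V, B %*% V)
        lam <- sort(eigen((Tm + t(Tm)) / 2, symmetric = TRUE,
                          only.values = TRUE)$values, decreasing = TRUE)[1:2]
        if (max(abs(lam - lam_old)) < 1e-9 * max(abs(lam), 1)) break
        lam_old <- lam
      }
    }
    Tm <- crossprod(V, B %*% V)
    e <- eigen((Tm + t(Tm)) / 2, symmetric = TRUE)
    keep <- order(e$values, decreasing = TRUE)[1:2]
    lam <- pmax(e$values[keep], 0)
    xy <- (V %*% e$vectors[, keep, drop = FALSE]) %*% diag(sqrt(lam), 2)
  }
  if (ncol(xy) < 2) xy <- cbind(xy, matrix(0, nrow(d), 2 - ncol(xy)))
  for (j in 1:2) {
    nz <- which(abs(xy[, j]) > 1e-12)
    if (length(nz) && xy[nz[1], j] < 0) xy[, j] <- -xy[, j]
  }
  rownames(xy) <- rownames(d)
  colnames(xy) <- c("mds1", "mds2")
  xy
}

#' Embed preprocessed cells with classical MDS
#'
#' Convenience wrapper: Euclidean distances on the preprocessed HVG matrix,
#' then [classical_mds()].
#'
#' @param pre Cells x genes matrix from [preprocess_counts()].
#' @return Cells x 2 embedding.
#' @export
embed_cells <- function(pre) {
  classical_mds(as.matrix(dist(pre)))
}

#' Configuration for the CLARA clustering ensemble
#'
#' @param k_min,k_max Range of cluster numbers cycled over (defaults 3 and
#'   20).
#' @param n_runs Number of CLARA runs (desk-scale default 1000; the
#'   reference analysis used 10000).
#' @param clara_sample_size Subsample size per CLARA sampling; `NULL` means
#'   the classical default `min(n, 40 + 2k)`.
#' @param clara_n_samples Number of subsamplings per run (default 5).
#' @param base_seed Seed of run 0; run r uses `base_seed + r`.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(k_min = 3, k_max = 20, n_runs = 1000,
                            clara_sample_size = NULL, clara_n_samples = 5,
                            base_seed = 1L) {
  stopifnot(k_min >= 2, k_max >= k_min, n_runs >= 1, clara_n_samples >= 1)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_runs = as.integer(n_runs),
                 clara_sample_size = clara_sample_size,
                 clara_n_samples = as.integer(clara_n_samples),
                 base_seed = as.integer(base_seed)),
            class = "ensemble_config")
}

.run_cost <- function(embedding, labels, medoids) {
  sum(sqrt(rowSums((embedding - embedding[medoids[labels], , drop = FALSE])^2)))
}

#' k-medoids (PAM) on a dissimilarity matrix
#'
#' Deterministic k-medoids. For small problems (at most `exact_limit`
#' candidate medoid sets) the optimal medoid set is found by exhaustive
#' enumeration, so the cost provably equals the brute-force optimum; larger
#' problems use greedy BUILD followed by first-improvement SWAP passes
#' until no single medoid exchange lowers the cost (ties broken toward the
#' lowest index). Labels always satisfy the nearest-medoid rule.
#'
#' @param dissimilarity Square symmetric dissimilarity matrix or `dist`.
#' @param k Number of clusters, `k < n`.
#' @param seed Recorded in the result for provenance (the search itself is
#'   deterministic).
#' @param exact_limit Maximum number of medoid sets to enumerate
#'   exhaustively (default 10000).
#' @return A `clustering_run` list: `k`, `labels`, `medoids` (indices),
#'   `seed`, `cost` (total dissimilarity to assigned medoids).
#' @export
pam_medoids <- function(dissimilarity, k, seed = 0L, exact_limit = 10000) {
  dm <- as.matrix(stats::as.dist(dissimilarity))
  n <- nrow(dm)
  if (k >= n) stop("k must be smaller than the number of observations")
  set_cost <- function(med) sum(apply(dm[, med, drop = FALSE], 1, min))
  if (choose(n, k) <= exact_limit) {
    sets <- combn(n, k)
    costs <- apply(sets, 2, set_cost)
    med <- sets[, which.min(costs)]
  } else {
    ## BUILD: greedy medoid addition
    med <- which.min(rowSums(dm))
    while (length(med) < k) {
      cur <- apply(dm[, med, drop = FALSE], 1, min)
      gains <- vapply(seq_len(n), function(j) {
        if (j %in% med) -Inf else sum(pmax(cur - dm[, j], 0))
      }, numeric(1))
      med <- c(med, which.max(gains))
    }
    ## SWAP: first-improvement passes until no exchange lowers the cost
    cur_cost <- set_cost(med)
    repeat {
      improved <- FALSE
      for (mi in seq_along(med)) {
        for (j in seq_len(n)) {
          if (j %in% med) next
          cand <- med
          cand[mi] <- j
          cc <- set_cost(cand)
          if (cc < cur_cost - 1e-12) {
            med <- cand
            cur_cost <- cc
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  med <- sort(med)
  labels <- apply(dm[, med, drop = FALSE], 1, which.min)
  structure(list(k = as.integer(k), labels = as.integer(labels),
                 medoids = as.integer(med), seed = as.integer(seed),
                 cost = set_cost(med)),
            class = "clustering_run")
}

#' One CLARA k-medoids run on an embedding
#'
#' Runs `cluster::clara` (PAM on subsamples, best full-data assignment
#' kept) with Euclidean distances on the 2-D embedding, seeded through R's
#' RNG for bit-reproducibility.
#'
#' @param embedding Cells x 2 coordinate matrix.
#' @param k Number of clusters.
#' @param config An [ensemble_config()] (supplies sample size / samplings).
#' @param seed Integer seed for the subsampling.
#' @return A `clustering_run` list (see [pam_medoids()]).
#' @export
clara_run <- function(embedding, k, config = ensemble_config(), seed = 1L) {
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells")
  sampsize <- config$clara_sample_size
  if (is.null(sampsize)) sampsize <- min(n, 40 + 2 * k)
  sampsize <- max(sampsize, k + 2)
  if (sampsize > n) sampsize <- n
  if (sampsize <= k) stop("clara sample size must exceed k")
  set.seed(seed)
  fit <- cluster::clara(embedding, k = k, metric = "euclidean",
                        samples = config$clara_n_samples,
                        sampsize = sampsize, rngR = TRUE, pamLike = TRUE,
                        medoids.x = FALSE, keep.data = FALSE)
  labels <- as.integer(fit$clustering)
  medoids <- as.integer(fit$i.med)
  structure(list(k = as.integer(k), labels = labels, medoids = medoids,
                 seed = as.integer(seed),
                 cost = .run_cost(embedding, labels, medoids)),
            class = "clustering_run")
}

#' Run the CLARA clustering ensemble
#'
#' Executes `n_runs` CLARA runs on the embedding; run `r` (0-based) uses
#' `k = k_min + (r mod (k_max - k_min + 1))` and seed `base_seed + r`, so
#' the k range is cycled evenly and the whole ensemble is reproducible from
#' `base_seed`.
#'
#' @param embedding Cells x 2 coordinate matrix.
#' @param config An [ensemble_config()].
#' @return List of `clustering_run` objects, length `n_runs`.
#' @export
ensemble_cluster <- function(embedding, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  if (config$k_max >= nrow(embedding))
    stop("k_max must be smaller than the number of cells")
  n_k <- config$k_max - config$k_min + 1L
  lapply(seq_len(config$n_runs) - 1L, function(r) {
    k <- config$k_min + (r %% n_k)
    clara_run(embedding, k, config, seed = config$base_seed + r)
  })
}
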