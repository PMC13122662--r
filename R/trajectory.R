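## MST connectivity trajectory reconstruction: Mahalanobis-like
## inter-cluster distances, per-run MSTs, ensemble cell-connectivity
## scores, VRC ranking, root selection, lineages and pseudotime.

#' Mahalanobis-like distances between clusters
#'
#' `d^2(i, j) = (mu_i - mu_j)' [(S_i + S_j)/2 + eps I]^-1 (mu_i - mu_j)`
#' with cluster centroids `mu`, covariances `S`, and ridge
#' `eps = 1e-6 x mean coordinate variance` (singleton clusters contribute
#' the ridge alone). Reduces to Euclidean distance for identity
#' covariances.
#'
#' @param embedding Cells x 2 coordinate matrix.
#' @param labels Integer cluster labels in `1..k`.
#' @return Symmetric k x k distance matrix with zero diagonal.
#' @export
intercluster_distances <- function(embedding, labels) {
  k <- max(labels)
  if (!all(seq_len(k) %in% labels)) stop("empty cluster in labels")
  eps <- 1e-6 * mean(apply(embedding, 2, var))
  mus <- vector("list", k)
  covs <- vector("list", k)
  for (j in seq_len(k)) {
    pts <- embedding[labels == j, , drop = FALSE]
    mus[[j]] <- colMeans(pts)
    covs[[j]] <- if (nrow(pts) > 1) cov(pts) else matrix(0, 2, 2)
  }
  d <- matrix(0, k, k)
  I2 <- diag(2)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    S <- (covs[[i]] + covs[[j]]) / 2 + eps * I2
    delta <- mus[[i]] - mus[[j]]
    d2 <- drop(crossprod(delta, solve(S, delta)))
    d[i, j] <- d[j, i] <- sqrt(max(d2, 0))
  }
  d
}

#' Minimum spanning tree by Prim's algorithm
#'
#' Deterministic: ties are broken by the lexicographically smallest
#' `(i, j)` vertex pair.
#'
#' @param d Symmetric distance matrix.
#' @return `(k-1) x 2` integer matrix of edges, each row `i < j`; zero rows
#'   for `k = 1`.
#' @export
minimum_spanning_tree <- function(d) {
  k <- nrow(d)
  if (k == 1) return(matrix(integer(0), 0, 2))
  in_tree <- c(TRUE, rep(FALSE, k - 1))
  edges <- matrix(0L, k - 1, 2)
  for (e in seq_len(k - 1)) {
    best <- NULL
    best_w <- Inf
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      w <- d[i, j]
      cand <- c(min(i, j), max(i, j))
      if (w < best_w ||
          (w == best_w && (cand[1] < best[1] ||
                           (cand[1] == best[1] && cand[2] < best[2])))) {
        best_w <- w
        best <- cand
        nxt <- j
      }
    }
    edges[e, ] <- best
    in_tree[nxt] <- TRUE
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

#' Per-cluster connectivity from an MST
#'
#' Connectivity of cluster j is its MST degree divided by the number of
#' clusters, so values lie in `[1/k, (k-1)/k]` and sum to `2(k-1)/k`.
#'
#' @param mst_edges Edge matrix from [minimum_spanning_tree()].
#' @param k Number of clusters.
#' @return Numeric vector of length k.
#' @export
cluster_connectivity <- function(mst_edges, k) {
  deg <- tabulate(c(mst_edges[, 1], mst_edges[, 2]), nbins = k)
  deg / k
}

#' Cluster graph for one clustering
#'
#' Bundles centroids, covariances, the Mahalanobis-like distance matrix and
#' the MST for a single clustering of the embedding.
#'
#' @param embedding Cells x 2 coordinate matrix.
#' @param labels Integer cluster labels in `1..k`.
#' @return A `cluster_graph` list: `k`, `dist`, `mst_edges`,
#'   `connectivity` (per cluster).
#' @export
cluster_graph <- function(embedding, labels) {
  k <- max(labels)
  d <- intercluster_distances(embedding, labels)
  mst <- minimum_spanning_tree(d)
  structure(list(k = k, dist = d, mst_edges = mst,
                 connectivity = cluster_connectivity(mst, k)),
            class = "cluster_graph")
}

#' Ensemble cell-connectivity score
#'
#' For every run, each cell inherits its cluster's connectivity; the
#' per-cell score is the mean over runs (order-invariant, equal weights).
#'
#' @param runs List of `clustering_run` objects.
#' @param graphs List of matching [cluster_graph()] objects.
#' @return Numeric vector, one score per cell.
#' @export
cell_connectivity <- function(runs, graphs) {
  if (length(runs) == 0) stop("need at least one run")
  if (length(runs) != length(graphs)) stop("runs and graphs differ in length")
  n <- length(runs[[1]]$labels)
  acc <- numeric(n)
  for (r in seq_along(runs)) {
    if (max(runs[[r]]$labels) != graphs[[r]]$k)
      stop("run ", r, " and its graph disagree on k")
    acc <- acc + graphs[[r]]$connectivity[runs[[r]]$labels]
  }
  acc / length(runs)
}

#' Per-run MSTs and the averaged cell-connectivity score
#'
#' Convenience driver: builds a [cluster_graph()] for every run of the
#' ensemble and averages cluster connectivity into per-cell scores.
#'
#' @param embedding Cells x 2 coordinate matrix.
#' @param runs Ensemble from [ensemble_cluster()].
#' @return List with `graphs` and `score` (per-cell connectivity).
#' @export
ensemble_connectivity <- function(embedding, runs) {
  graphs <- lapply(runs, function(r) cluster_graph(embedding, r$labels))
  list(graphs = graphs, score = cell_connectivity(runs, graphs))
}

#' Calinski-Harabasz variance-ratio criterion on a 1-D vector
#'
#' `VRC = [SSB / (k - 1)] / [SSW / (n - k)]` of the values grouped by the
#' labels. Zero within-cluster variance returns `Inf` with attribute
#' `degenerate = TRUE` so that ranking still works.
#'
#' @param labels Integer cluster labels in `1..k`, `k >= 2`.
#' @param values Finite numeric vector (here: cell-connectivity scores).
#' @return VRC value.
#' @export
vrc <- function(labels, values) {
  k <- max(labels)
  n <- length(values)
  if (k < 2) stop("vrc needs at least 2 clusters")
  if (n <= k) stop("vrc needs more observations than clusters")
  if (!all(is.finite(values))) stop("values must be finite")
  gm <- mean(values)
  means <- tapply(values, labels, mean)
  sizes <- tabulate(labels, nbins = k)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[labels])^2)
  if (ssw < .Machine$double.eps) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Rank ensemble runs by VRC and select a clustering
#'
#' Computes the VRC of every run's labels on the one-dimensional ensemble
#' connectivity vector, ranks runs in decreasing order and returns the
#' `pick`-th ranked run (default the top one) together with the top-n
#' report, mirroring a manual choice among the best candidates.
#'
#' @param runs Ensemble from [ensemble_cluster()].
#' @param cell_conn Per-cell connectivity score from
#'   [ensemble_connectivity()].
#' @param top_n Number of runs in the report (default 20).
#' @param pick 1-based index into the ranked report (default 1).
#' @return List with `selected` (a `clustering_run`), `rank` (data frame
#'   run / k / seed / vrc for the top n) and `pick`.
#' @export
rank_and_select <- function(runs, cell_conn, top_n = 20, pick = 1) {
  if (length(runs) == 0) stop("empty ensemble")
  scores <- vapply(runs, function(r) as.numeric(vrc(r$labels, cell_conn)),
                   numeric(1))
  ord <- order(scores, decreasing = TRUE)
  top_n <- min(top_n, length(runs))
  if (pick < 1 || pick > top_n) stop("pick must be in 1..", top_n)
  rank <- data.frame(run = ord[seq_len(top_n)],
                     k = vapply(runs[ord[seq_len(top_n)]], `[[`, 0L, "k"),
                     seed = vapply(runs[ord[seq_len(top_n)]], `[[`, 0L, "seed"),
                     vrc = scores[ord[seq_len(top_n)]])
  list(selected = runs[[ord[pick]]], rank = rank, pick = pick)
}

#' Choose the root cluster of the final tree
#'
#' Among clusters whose mean marker score exceeds the across-cluster median
#' (when marker scores are supplied), picks the cluster with the highest
#' mean cell connectivity; without markers, the global connectivity argmax.
#' Ties go to the lowest cluster id.
#'
#' @param run Selected `clustering_run`.
#' @param cell_conn Per-cell connectivity scores.
#' @param marker_scores Optional per-cell score (e.g. mean log-expression
#'   of primed/pluripotency marker genes).
#' @return Root cluster id (integer).
#' @export
select_root <- function(run, cell_conn, marker_scores = NULL) {
  k <- max(run$labels)
  conn_mean <- tapply(cell_conn, run$labels, mean)
  cand <- seq_len(k)
  if (!is.null(marker_scores)) {
    mk <- tapply(marker_scores, run$labels, mean)
    enriched <- which(mk > median(mk))
    if (length(enriched)) cand <- enriched
  }
  as.integer(unname(cand[which.max(conn_mean[cand])]))
}

#' Root-to-leaf lineages of an MST
#'
#' One lineage per leaf (degree-1 cluster other than the root), each the
#' unique path from the root, ordered by increasing leaf id. A
#' single-cluster tree yields one trivial lineage.
#'
#' @param mst_edges Edge matrix from [minimum_spanning_tree()].
#' @param root Root cluster id.
#' @return List of integer vectors (ordered cluster ids, root first).
#' @export
extract_lineages <- function(mst_edges, root) {
  if (nrow(mst_edges) == 0) return(list(as.integer(root)))
  k <- max(mst_edges)
  adj <- lapply(seq_len(k), function(i) integer(0))
  for (e in seq_len(nrow(mst_edges))) {
    i <- mst_edges[e, 1]; j <- mst_edges[e, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  parent <- rep(NA_integer_, k)
  parent[root] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(parent[w])) {
      parent[w] <- v
      queue <- c(queue, w)
    }
  }
  deg <- lengths(adj)
  leaves <- sort(setdiff(which(deg == 1), root))
  lapply(leaves, function(leaf) {
    path <- leaf
    while (parent[path[1]] != 0L) path <- c(parent[path[1]], path)
    as.integer(path)
  })
}

#' Arc-length pseudotime along piecewise-linear lineage curves
#'
#' Each lineage defines a piecewise-linear curve through its ordered
#' cluster centroids. A cell is assigned to every lineage containing its
#' cluster (weight `1 / n_lineages`); its pseudotime is the arc length of
#' its orthogonal projection onto the curve, clamped to
#' `[0, total length]`, in the units of the embedding.
#'
#' @param embedding Cells x 2 coordinate matrix.
#' @param run Selected `clustering_run`.
#' @param lineages List of ordered cluster paths from [extract_lineages()].
#' @return Data frame with one row per (cell, lineage): `cell` (index),
#'   `barcode`, `cluster`, `lineage`, `pseudotime`, `weight`.
#' @export
lineage_pseudotime <- function(embedding, run, lineages) {
  labels <- run$labels
  k <- max(labels)
  centroids <- t(vapply(seq_len(k),
                        function(j) colMeans(embedding[labels == j, ,
                                                       drop = FALSE]),
                        numeric(2)))
  barcodes <- rownames(embedding)
  if (is.null(barcodes)) barcodes <- as.character(seq_len(nrow(embedding)))
  curves <- lapply(lineages, function(path) {
    pts <- centroids[path, , drop = FALSE]
    seglen <- if (nrow(pts) > 1)
      sqrt(rowSums((pts[-1, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)) else numeric(0)
    list(pts = pts, cum = c(0, cumsum(seglen)))
  })
  membership <- lapply(seq_len(nrow(embedding)), function(i)
    which(vapply(lineages, function(p) labels[i] %in% p, logical(1))))
  rows <- vector("list", nrow(embedding))
  for (i in seq_len(nrow(embedding))) {
    lin <- membership[[i]]
    if (!length(lin)) {
      rows[[i]] <- data.frame(cell = i, barcode = barcodes[i],
                              cluster = labels[i], lineage = NA_integer_,
                              pseudotime = NA_real_, weight = NA_real_)
      next
    }
    w <- 1 / length(lin)
    x <- embedding[i, ]
    rows[[i]] <- do.call(rbind, lapply(lin, function(l) {
      cv <- curves[[l]]
      pts <- cv$pts
      if (nrow(pts) == 1) {
        pt <- 0
      } else {
        best_d <- Inf
        pt <- 0
        for (s in seq_len(nrow(pts) - 1)) {
          a <- pts[s, ]; b <- pts[s + 1, ]
          ab <- b - a
          len2 <- sum(ab^2)
          tt <- if (len2 > 0) min(max(sum((x - a) * ab) / len2, 0), 1) else 0
          proj <- a + tt * ab
          dd <- sum((x - proj)^2)
          if (dd < best_d - 1e-12) {
            best_d <- dd
            pt <- cv$cum[s] + tt * sqrt(len2)
          }
        }
      }
      data.frame(cell = i, barcode = barcodes[i], cluster = labels[i],
                 lineage = l, pseudotime = pt, weight = w)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
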