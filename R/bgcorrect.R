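## Distribution-based error correction: per-gene two-component decomposition
## of log2(count + 1) values, zeroing the low (background) component in
## genes that pass three gates on the log2 scale.

#' Gates for distribution-based background correction
#'
#' A gene is corrected only if (1) its maximum `log2(count + 1)` exceeds
#' `min_gene_max`, (2) the fitted first-component (background) mean is at
#' most `max_first_mean`, and (3) the two component means are separated by
#' at least `min_component_gap`. All thresholds are on the log2(x + 1)
#' scale.
#'
#' @param min_gene_max Gate 1 threshold (default 8).
#' @param max_first_mean Gate 2 threshold (default 5.5).
#' @param min_component_gap Gate 3 threshold (default 5).
#' @return An object of class `correction_gates`.
#' @export
correction_gates <- function(min_gene_max = 8, max_first_mean = 5.5,
                             min_component_gap = 5) {
  stopifnot(is.finite(min_gene_max), is.finite(max_first_mean),
            is.finite(min_component_gap), min_component_gap > 0)
  structure(list(min_gene_max = min_gene_max,
                 max_first_mean = max_first_mean,
                 min_component_gap = min_component_gap),
            class = "correction_gates")
}

#' Fit a two-component equal-variance Gaussian mixture in one dimension
#'
#' Plain EM on the supplied values: means initialised at the minimum and
#' maximum, equal mixing weights, a single shared variance, at most
#' `max_iter` iterations or until the log-likelihood changes by less than
#' `tol`. Components are ordered by mean. With fewer than 4 values, or a
#' degenerate (constant) input, a single-component fallback is returned.
#'
#' @param values Numeric vector (typically positive log2(x+1) values).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @return List with `means` (length 2, increasing), `sd`, `weights`,
#'   `responsibility` (per-value posterior probability of component 1) and
#'   `converged`; or a list with `fallback = TRUE` when no two-component
#'   fit is possible.
#' @export
fit_two_components <- function(values, max_iter = 100, tol = 1e-6) {
  x <- values[is.finite(values)]
  if (length(x) < 4 || diff(range(x)) < .Machine$double.eps^0.5)
    return(list(fallback = TRUE, means = rep(mean(x), 2), sd = stats::sd(x),
                weights = c(1, 0), responsibility = rep(1, length(x)),
                converged = FALSE))
  mu <- c(min(x), max(x))
  sigma <- max(stats::sd(x) / 2, 1e-3)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sigma)
    d2 <- w[2] * stats::dnorm(x, mu[2], sigma)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    n1 <- sum(r1); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # one component emptied out
    mu[1] <- sum(r1 * x) / n1
    mu[2] <- sum((1 - r1) * x) / n2
    sigma <- sqrt((sum(r1 * (x - mu[1])^2) + sum((1 - r1) * (x - mu[2])^2)) /
                    length(x))
    sigma <- max(sigma, 1e-4)
    w <- c(n1, n2) / length(x)
  }
  if (mu[1] > mu[2]) {  # keep components ordered by mean
    mu <- rev(mu); w <- rev(w); r1 <- 1 - r1
  }
  list(fallback = FALSE, means = mu, sd = sigma, weights = w,
       responsibility = r1, converged = converged)
}

#' Zero the background component of gated genes
#'
#' For each gene passing all three [correction_gates()] on the
#' `log2(count + 1)` scale, counts of the cells assigned (posterior > 0.5)
#' to the low-mean component are set to zero. Counts never increase; genes
#' failing any gate, all-zero genes and genes whose mixture fit falls back
#' to one component are untouched. The operation is idempotent.
#'
#' @param counts Genes x cells count matrix (sparse or dense, integer).
#' @param gates A [correction_gates()] object.
#' @param report If `TRUE`, attach a per-gene data frame (`gene`, `gated`,
#'   `mean1`, `mean2`, `n_zeroed`) as attribute `"report"`.
#' @return Corrected count matrix of the same class and dimensions.
#' @export
correct_background <- function(counts, gates = correction_gates(),
                               report = FALSE) {
  stopifnot(inherits(gates, "correction_gates"))
  ## iterate genes as columns of the transpose for fast sparse access
  tc <- as(Matrix::t(as(counts, "CsparseMatrix")), "CsparseMatrix")
  p <- tc@p
  xvals <- tc@x
  n_genes <- ncol(tc)
  rep_rows <- if (report)
    data.frame(gene = colnames(tc), gated = FALSE, mean1 = NA_real_,
               mean2 = NA_real_, n_zeroed = 0L, stringsAsFactors = FALSE)
  for (g in seq_len(n_genes)) {
    idx <- if (p[g + 1] > p[g]) (p[g] + 1L):p[g + 1] else integer(0)
    if (!length(idx)) next
    vals <- xvals[idx]
    lg <- log2(vals + 1)
    if (max(lg) <= gates$min_gene_max) next
    fit <- fit_two_components(lg)
    if (isTRUE(fit$fallback)) next
    if (report) {
      rep_rows$mean1[g] <- fit$means[1]
      rep_rows$mean2[g] <- fit$means[2]
    }
    if (fit$means[1] > gates$max_first_mean) next
    if ((fit$means[2] - fit$means[1]) < gates$min_component_gap) next
    zero <- idx[fit$responsibility > 0.5]
    if (length(zero)) xvals[zero] <- 0
    if (report) {
      rep_rows$gated[g] <- TRUE
      rep_rows$n_zeroed[g] <- length(zero)
    }
  }
  tc@x <- xvals
  out <- Matrix::drop0(Matrix::t(tc))
  if (report) attr(out, "report") <- rep_rows
  out
}
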