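## Hashtag demultiplexing: cell calling from barcode totals, linear
## normalisation to the smallest library, fold-change sample assignment,
## rank-based doublet removal and the Poisson doublet-rate estimator.

#' Knee-plot inflection threshold for cell calling
#'
#' Finds the inflection of the log10(total) vs log10(rank) barcode-rank
#' curve: totals are sorted decreasingly, consecutive log-log slopes are
#' smoothed with a centred moving average, and the threshold is placed at
#' the steepest negative smoothed slope (geometric midpoint of the totals on
#' either side of that segment). Barcodes with totals strictly below the
#' returned threshold are considered empty.
#'
#' @param per_barcode_totals Named or unnamed vector of per-barcode total
#'   counts; zeros are ignored.
#' @param window Moving-average window for slope smoothing (default 5).
#' @return The threshold total count (numeric scalar).
#' @export
barcode_rank_inflection <- function(per_barcode_totals, window = 5) {
  totals <- per_barcode_totals[per_barcode_totals > 0]
  if (length(totals) < 10)
    stop("need at least 10 barcodes with positive totals, got ",
         length(totals))
  srt <- sort(as.numeric(totals), decreasing = TRUE)
  lrank <- log10(seq_along(srt))
  ltot <- log10(srt)
  dy <- diff(ltot)
  dx <- diff(lrank)
  slope <- ifelse(dx > 0, dy / dx, 0)
  if (all(slope >= 0) || length(unique(srt)) == 1) {
    warning("barcode-rank curve has no interior slope minimum; ",
            "returning the minimum positive total")
    return(min(srt))
  }
  w <- max(1L, as.integer(window))
  kern <- rep(1 / w, w)
  sm <- stats::filter(slope, kern, sides = 2)
  sm[is.na(sm)] <- slope[is.na(sm)]
  i <- which.min(sm)
  ## refine to the steepest raw slope inside the smoothing window so the
  ## threshold lands on the actual cliff, not at its smoothed shoulder
  win <- max(1, i - w %/% 2):min(length(slope), i + w %/% 2)
  i <- win[which.min(slope[win])]
  sqrt(srt[i] * srt[i + 1])
}

#' Linearly normalise hashtag libraries to the smallest total
#'
#' Each hashtag row is scaled by `min(totals) / total(hashtag)` so that all
#' hashtag totals are equal after scaling. Idempotent and rank-preserving
#' within a hashtag.
#'
#' @param tags Hashtags x cells count matrix (integer or real).
#' @return Real-valued matrix of the same shape.
#' @export
normalize_tags <- function(tags) {
  totals <- rowSums(tags)
  if (any(totals == 0))
    stop("hashtag(s) with zero total reads: ",
         paste(rownames(tags)[totals == 0], collapse = ", "))
  tags * (min(totals) / totals)
}

#' Assign cells to hashtags by first/second fold-change
#'
#' Each cell is assigned to its most abundant (normalised) hashtag; the
#' fold-change is `(first + 1) / (second + 1)` with a pseudocount of 1 so
#' that a zero second count stays finite. Exact first/second ties are
#' labelled ambiguous. With a single hashtag every cell is assigned to it
#' with infinite fold-change.
#'
#' @param norm_tags Hashtags x cells matrix, normally from
#'   [normalize_tags()].
#' @return Data frame with one row per cell: `barcode`, `hashtag`, `fc`,
#'   `status` (singlet / ambiguous).
#' @export
assign_tags <- function(norm_tags) {
  if (nrow(norm_tags) == 0 || ncol(norm_tags) == 0)
    stop("empty hashtag matrix")
  barcodes <- colnames(norm_tags)
  if (is.null(barcodes)) barcodes <- sprintf("cell_%05d", seq_len(ncol(norm_tags)))
  if (nrow(norm_tags) == 1) {
    return(data.frame(barcode = barcodes,
                      hashtag = rownames(norm_tags)[1],
                      fc = Inf, status = "singlet",
                      stringsAsFactors = FALSE))
  }
  m <- as.matrix(norm_tags)
  res <- apply(m, 2, function(v) {
    v <- unname(v)
    o <- order(v, decreasing = TRUE)
    c(first = v[o[1]], second = v[o[2]], which = o[1])
  })
  fc <- (res["first", ] + 1) / (res["second", ] + 1)
  tied <- res["first", ] == res["second", ]
  data.frame(barcode = barcodes,
             hashtag = ifelse(tied, NA_character_,
                              rownames(norm_tags)[res["which", ]]),
             fc = unname(fc),
             status = ifelse(tied, "ambiguous", "singlet"),
             stringsAsFactors = FALSE)
}

#' Flag the lowest fold-change cells as doublets
#'
#' Cells are ordered by increasing fold-change (a doublet carries two
#' hashtags, so its first/second fold-change is close to 1) and the first
#' `floor(n * remove_fraction)` are relabelled as doublets. Ties at the cut
#' are broken by barcode lexicographic order for determinism.
#'
#' @param assignments Output of [assign_tags()].
#' @param remove_fraction Fraction of cells to flag, in [0, 1).
#' @return The assignment table with `status` updated to "doublet" for the
#'   flagged cells.
#' @export
filter_doublets <- function(assignments, remove_fraction) {
  if (remove_fraction < 0 || remove_fraction >= 1)
    stop("remove_fraction must be in [0, 1)")
  n <- nrow(assignments)
  d <- floor(n * remove_fraction)
  if (d > 0) {
    o <- order(assignments$fc, assignments$barcode)
    assignments$status[o[seq_len(d)]] <- "doublet"
  }
  assignments
}

#' Poisson doublet-rate estimate from loading counts
#'
#' With `lambda = n_loaded / n_wells` cells per well, the expected doublet
#' fraction among occupied wells is
#' `P(>= 2 | >= 1) = (1 - exp(-lambda) - lambda * exp(-lambda)) /
#' (1 - exp(-lambda))`.
#'
#' @param n_loaded Number of cells loaded.
#' @param n_wells Number of capture wells.
#' @return Expected doublet fraction among captured cells.
#' @export
poisson_doublet_fraction <- function(n_loaded, n_wells) {
  if (n_loaded <= 0 || n_wells <= 0)
    stop("n_loaded and n_wells must be positive")
  lambda <- n_loaded / n_wells
  (1 - exp(-lambda) - lambda * exp(-lambda)) / (1 - exp(-lambda))
}
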