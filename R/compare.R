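#' Compare a motif against a library
#'
#' Column-alignment motif similarity in the style of TomTom: for every
#' library motif, both orientations and every offset with at least
#' `min_overlap` overlapping columns are scored; the per-column score is
#' the chosen metric between regularized frequency columns (Pearson
#' correlation, or negative Euclidean distance so that larger is always
#' better), and the alignment score is the sum over overlapping columns.
#'
#' Significance is empirical: the null distribution of the column metric is
#' built from all ordered pairs of distinct columns pooled across the
#' library, discretized into `n_bins` bins; the null distribution of an
#' alignment score over `k` columns is the k-fold convolution of that
#' binned null (dynamic programming), giving
#' `P(null sum >= observed sum)`. That p-value is Bonferroni-corrected by
#' the number of offset/orientation alignments tested for the target.
#' Libraries with fewer than 10 motifs give too few columns to calibrate
#' the null, so the analytic Pearson null is used instead (for 4-point
#' columns the null correlation is uniform on `[-1, 1]`); the Euclidean
#' metric requires the empirical null.
#'
#' @param query a frequency `Motif`.
#' @param library list of frequency `Motif`s.
#' @param min_overlap minimum overlapping columns (>= 3).
#' @param column_metric `"pearson"` or `"euclidean"`.
#' @param n_bins discretization bins for the null.
#' @param pseudo_weight regularization applied to all frequency columns
#'   (uniform background) before comparison.
#' @return Data frame of class `ComparisonResult`, one row per target,
#'   ranked by `combined_p`: columns `query`, `target`, `offset` (target
#'   start minus query start), `orientation` (`same`/`revcomp`), `overlap`,
#'   `score`, `combined_p`.
#' @export
compare_motifs <- function(query, library, min_overlap = 5,
                           column_metric = c("pearson", "euclidean"),
                           n_bins = 100, pseudo_weight = 0.01) {
  column_metric <- match.arg(column_metric)
  stopifnot(inherits(query, "Motif"), min_overlap >= 3)
  if (length(library) == 0) stop("empty motif library")
  ubg <- background(NULL)
  reg <- function(m) regularize_motif(m, ubg, pseudo_weight)$mat
  qm <- reg(query)
  lib_mats <- lapply(library, reg)
  metric <- if (column_metric == "pearson") {
    # a constant column carries no shape information: score it as 0
    function(a, b) {
      r <- suppressWarnings(stats::cor(a, b))
      if (is.na(r)) 0 else r
    }
  } else {
    function(a, b) -sqrt(sum((a - b)^2))
  }
  ## null pmf over binned column-metric values
  pool <- do.call(cbind, lib_mats)
  rng <- if (column_metric == "pearson") c(-1, 1) else c(-sqrt(2), 0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                                  1L), n_bins)
  if (length(library) >= 10 || column_metric == "euclidean") {
    if (length(library) < 10 && column_metric == "euclidean")
      warning("small library: empirical Euclidean null is poorly calibrated")
    nc <- ncol(pool)
    vals <- numeric(nc * (nc - 1) / 2); k <- 0L
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
      k <- k + 1L; vals[k] <- metric(pool[, i], pool[, j])
    }
    pmf <- tabulate(bin_of(vals), nbins = n_bins)
    pmf <- pmf / sum(pmf)
  } else {
    ## analytic Pearson null for 4-point columns: uniform on [-1, 1]
    pmf <- rep(1 / n_bins, n_bins)
  }
  rows <- vector("list", length(library))
  for (ti in seq_along(library)) {
    tm_f <- lib_mats[[ti]]
    Wq <- ncol(qm)
    best <- NULL; n_align <- 0L
    for (orient in c("same", "revcomp")) {
      tm <- if (orient == "same") tm_f else rc_mat(tm_f)
      Wt <- ncol(tm)
      for (off in (-Wt + min_overlap):(Wq - min_overlap)) {
        qcols <- max(1, off + 1):min(Wq, off + Wt)
        if (length(qcols) < min_overlap) next
        tcols <- qcols - off
        n_align <- n_align + 1L
        colsc <- vapply(seq_along(qcols),
                        function(i) metric(qm[, qcols[i]], tm[, tcols[i]]),
                        numeric(1))
        sc <- sum(colsc)
        obs_bin <- sum(bin_of(colsc))
        p <- conv_tail_p(pmf, length(colsc), obs_bin)
        if (is.null(best) || p < best$p - 1e-15 ||
            (abs(p - best$p) <= 1e-15 && sc > best$score)) {
          best <- list(p = p, score = sc, offset = off, orientation = orient,
                       overlap = length(colsc), column_scores = colsc)
        }
      }
    }
    if (is.null(best)) next
    rows[[ti]] <- data.frame(
      query = query$name, target = library[[ti]]$name, offset = best$offset,
      orientation = best$orientation, overlap = best$overlap,
      score = best$score,
      combined_p = max(min(best$p * n_align, 1), .Machine$double.xmin),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    stop("no alignment with the required overlap; lower min_overlap")
  res <- do.call(rbind, rows)
  res <- res[order(res$combined_p, -res$score, res$target), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ComparisonResult", "data.frame")
  res
}

## P(sum of k iid draws of bin indices >= obs_bin) by DP convolution.
conv_tail_p <- function(pmf, k, obs_bin) {
  nb <- length(pmf)
  dist <- pmf
  if (k > 1) for (i in 2:k) {
    new <- rep(0, length(dist) + nb - 1)
    for (b in seq_len(nb)) if (pmf[b] > 0)
      new[(b):(b + length(dist) - 1)] <- new[(b):(b + length(dist) - 1)] + pmf[b] * dist
    dist <- new
  }
  ## dist[i] = P(sum of indices = i + k - 1)
  sums <- seq_along(dist) + k - 1
  sum(dist[sums >= obs_bin])
}
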