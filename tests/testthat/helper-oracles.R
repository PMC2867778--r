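# Shared independent oracles and small fixture builders. Everything here is
# deliberately naive (per-base vectors, per-word sums, explicit enumeration)
# so that agreement with the package's vectorized implementations is
# meaningful.

rand_location_set <- function(n, seq_len_ = 10000, sid = "s1", seed = NULL,
                              max_width = 200) {
  if (!is.null(seed)) set.seed(seed)
  start <- floor(runif(n) * (seq_len_ - max_width))
  width <- 1 + floor(runif(n) * max_width)
  location_set(sid, start, pmin(start + width, seq_len_), name = "rand")
}

# Per-base boolean membership vector of a LocationSet on one sequence.
membership <- function(x, sid = "s1", L = 10000) {
  v <- rep(FALSE, L)
  xs <- x[x$sequence_id == sid, , drop = FALSE]
  for (i in seq_len(nrow(xs))) v[(xs$start[i] + 1):xs$end[i]] <- TRUE
  v
}

# Re-assemble a boolean per-base vector into maximal intervals.
vector_to_intervals <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  cbind(start = starts[r$values] - 1, end = ends[r$values])
}

# Naive per-word LOD: explicit per-position sum.
oracle_lod <- function(pssm, word) {
  code <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(code)) return(NA_real_)
  sum(vapply(seq_along(code), function(i) pssm$mat[code[i], i], numeric(1)))
}

# Naive exhaustive score distribution: enumerate all 4^W words with the
# first position slowest (matching lexicographic expansion), score each by
# left-to-right summation and weight by the product of background
# probabilities.
oracle_exhaustive <- function(pssm) {
  W <- ncol(pssm$mat)
  scores <- 0; probs <- 1
  for (j in seq_len(W)) {
    scores <- as.vector(vapply(scores, function(s) s + pssm$mat[, j],
                               numeric(4)))
    probs <- as.vector(vapply(probs, function(p) p * pssm$bg$probs, numeric(4)))
  }
  o <- order(scores)
  list(scores = scores[o], probs = probs[o],
       tail = function(t) sum(probs[o][scores[o] >= t]))
}

# All words of width W as character vectors (A fastest), used by small
# brute-force enumerations.
all_words <- function(W) {
  do.call(expand.grid, rep(list(c("A", "C", "G", "T")), W))
}

# Brute-force scan of one sequence: score every window on both strands by
# string extraction and per-word scoring.
oracle_scan <- function(s, pssm, threshold) {
  W <- ncol(pssm$mat)
  out <- list()
  for (x in seq_len(nchar(s) - W + 1)) {
    word <- substr(s, x, x + W - 1)
    if (grepl("N", word)) next
    fs <- oracle_lod(pssm, word)
    rs <- oracle_lod(pssm, revcomp_str(word))
    if (!is.na(fs) && fs >= threshold)
      out[[length(out) + 1L]] <- data.frame(start = x - 1, strand = "+", score = fs)
    if (!is.na(rs) && rs >= threshold)
      out[[length(out) + 1L]] <- data.frame(start = x - 1, strand = "-", score = rs)
  }
  if (length(out) == 0)
    return(data.frame(start = numeric(0), strand = character(0), score = numeric(0)))
  do.call(rbind, out)
}

# Reverse complement by hand, IUPAC-aware (independent of Biostrings).
revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s), "")[[1]]),
        collapse = "")
}

# Exhaustive segmentation enumeration for the two-state sequence model:
# sums, over every tiling of the sequence by single background bases and
# width-W motif blocks, the product of emission and transition
# probabilities. Exponential; for short sequences only.
oracle_segmentation_lik <- function(code, W, w, bgp, fp) {
  bgp <- unname(bgp)
  rec <- function(i) {
    if (i == 0) return(1)
    tot <- (1 - w) * bgp[code[i]] * rec(i - 1)
    if (i >= W) {
      win <- code[(i - W + 1):i]
      tot <- tot + w * prod(fp[cbind(win, seq_len(W))]) * rec(i - W)
    }
    tot
  }
  rec(length(code))
}

# A sharp 10-bp motif (about 1.6 bits per column): consensus base 0.95,
# others 0.05/3. Used wherever a strong planted signal is needed.
sharp_motif <- function(consensus = "TTGACGTCAA", major = 0.95) {
  ch <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - major) / 3, 4, length(ch),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(ch)) mat[ch[j], j] <- major
  motif(mat, name = paste0("sharp_", consensus))
}

# Best column correlation between a discovered motif and a truth motif over
# all offsets with >= min_overlap columns, both orientations.
best_column_correlation <- function(found, truth, min_overlap = 8) {
  fmats <- list(found$mat, revcomp_motif(found)$mat)
  best <- -1
  for (fm in fmats) {
    Wf <- ncol(fm); Wt <- ncol(truth$mat)
    for (off in (-Wf + min_overlap):(Wt - min_overlap)) {
      tc <- max(1, off + 1):min(Wt, off + Wf)
      fc <- tc - off
      if (length(tc) < min_overlap) next
      r <- suppressWarnings(cor(as.vector(fm[, fc]), as.vector(truth$mat[, tc])))
      if (!is.na(r)) best <- max(best, r)
    }
  }
  best
}

# Fraction of truth sites recovered within +/- tol bp by discovered sites
# (sites$seq indexes sequences; truth_starts is a list per sequence).
site_recovery <- function(sites, truth_starts, tol = 1) {
  hit <- 0
  for (i in seq_along(truth_starts)) {
    ts <- truth_starts[[i]]
    if (length(ts) == 0) next
    ds <- sites$start[sites$seq == i]
    hit <- hit + sum(vapply(ts, function(t) any(abs(ds - t) <= tol), logical(1)))
  }
  hit / sum(lengths(truth_starts))
}

# Closed-form two-sided Fisher p for a 2x2 table (a, n1-a; b, n2-b):
# hypergeometric sum over tables with point probability <= observed.
oracle_fisher2 <- function(a, n1, b, n2) {
  K <- a + b; N <- n1 + n2
  lo <- max(0, K - n2); hi <- min(K, n1)
  d <- dhyper(lo:hi, n1, n2, K)
  sum(d[d <= d[a - lo + 1] * (1 + 1e-7)])
}
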