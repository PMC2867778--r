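#' LOD score of a single word
#'
#' The logarithm-of-odds score of a word under a PSSM is the sum of the
#' per-position log2 odds `s(i, word_i)`. Words containing `N` get no score
#' (`NA`): an unknown base never matches.
#'
#' @param pssm a `PSSM`.
#' @param word character string of the PSSM's width over `{A,C,G,T,N}`.
#' @return LOD score in bits, or `NA` if the word contains `N`.
#' @export
lod_score <- function(pssm, word) {
  stopifnot(inherits(pssm, "PSSM"))
  code <- encode_seq(toupper(word))
  if (length(code) != ncol(pssm$mat)) stop("word length != motif width")
  if (any(code == 5L)) return(NA_real_)
  sum(pssm$mat[cbind(code, seq_along(code))])
}

#' Affinity score of a word
#'
#' For affinity motifs (normalized binding-weight matrices) the score of a
#' word is the product of its per-position weights, a value in `[0, 1]`
#' with 1 for the optimal word.
#'
#' @param m an affinity `Motif`.
#' @param word character string of the motif's width.
#' @return Product score in `[0, 1]`, or `NA` if the word contains `N`.
#' @export
affinity_score <- function(m, word) {
  stopifnot(inherits(m, "Motif"))
  if (m$kind != "affinity") stop("affinity_score needs an affinity motif")
  code <- encode_seq(toupper(word))
  if (length(code) != ncol(m$mat)) stop("word length != motif width")
  if (any(code == 5L)) return(NA_real_)
  prod(m$mat[cbind(code, seq_along(code))])
}

## Window scores of an encoded sequence under a 4 x W score matrix,
## combined additively left-to-right. Windows containing N score NA.
## Returns numeric vector of length L - W + 1 (length 0 when W > L).
score_windows <- function(code, smat) {
  W <- ncol(smat); L <- length(code)
  if (W > L) return(numeric(0))
  n <- L - W + 1L
  m5 <- rbind(smat, NA_real_)           # row 5 poisons N-containing windows
  tot <- m5[(0L * 5L) + code[1:n]]
  if (W > 1) for (j in 2:W)
    tot <- tot + m5[((j - 1L) * 5L) + code[j:(j + n - 1L)]]
  tot
}

## Reverse-complement a 4 x W score (or frequency) matrix.
rc_mat <- function(mat) {
  out <- mat[c(4, 3, 2, 1), rev(seq_len(ncol(mat))), drop = FALSE]
  rownames(out) <- BASES
  out
}

#' Score distribution of a PSSM under an i.i.d. background
#'
#' Gives `P(score >= t)` for a single W-mer drawn from the order-0
#' background: the null used for per-match p-values.
#'
#' Two methods are available. `exhaustive` enumerates all `4^W` words
#' (widths up to 10) and is exact. `importance_sampling` draws words from a
#' compound proposal, the defensive 50/50 mixture of the background and the
#' PSSM-tilted product distribution `q0(word) = prod f'(i, word_i)`; the
#' estimator averages `b(word)/q(word)` over sampled words with
#' `score >= t` and reports its standard error. Because
#' `f'(i,b) = bg(b) 2^{s(i,b)}`, the weight reduces to
#' `1 / (0.5 + 0.5 * 2^{score})`, which is bounded above by 2 (variance
#' control) and concentrates sampling on high-scoring words where the tail
#' lives.
#'
#' @param pssm a `PSSM` (its embedded order-0 background is used).
#' @param method `"exhaustive"` or `"importance_sampling"`.
#' @param n_samples number of proposal draws (>= 100) for sampling.
#' @param seed integer seed for sampling (required for reproducibility).
#' @return An object of class `ScoreDistribution`.
#' @seealso [tail_prob()]
#' @export
score_distribution <- function(pssm, method = c("exhaustive", "importance_sampling"),
                               n_samples = 1e5, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(pssm, "PSSM"))
  W <- ncol(pssm$mat)
  bgp <- pssm$bg$probs
  if (method == "exhaustive") {
    if (W > 10) stop("exhaustive enumeration limited to width <= 10")
    scores <- 0; probs <- 1
    for (j in seq_len(W)) {
      scores <- rep(scores, each = 4) + unname(pssm$mat[, j])
      probs <- rep(probs, each = 4) * unname(bgp)
    }
    o <- order(scores)
    structure(list(method = method, scores = scores[o], probs = probs[o],
                   weights = NULL, n_samples = NULL, seed = NULL,
                   min_score = pssm$min_score, max_score = pssm$max_score),
              class = "ScoreDistribution")
  } else {
    if (n_samples < 100) stop("n_samples must be >= 100")
    fp <- bgp * 2^pssm$mat               # regularized frequencies, columns sum to 1
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    from_motif <- stats::runif(n_samples) < 0.5
    codes <- matrix(0L, n_samples, W)
    for (j in seq_len(W)) {
      codes[, j] <- ifelse(from_motif,
                           sample.int(4, n_samples, replace = TRUE, prob = fp[, j]),
                           sample.int(4, n_samples, replace = TRUE, prob = bgp))
    }
    sc <- rep(0, n_samples)
    for (j in seq_len(W)) sc <- sc + pssm$mat[cbind(codes[, j], j)]
    wts <- 1 / (0.5 + 0.5 * 2^sc)
    o <- order(sc)
    structure(list(method = method, scores = sc[o], probs = NULL,
                   weights = wts[o], n_samples = n_samples, seed = seed,
                   min_score = pssm$min_score, max_score = pssm$max_score),
              class = "ScoreDistribution")
  }
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ScoreDistribution <- function(x, ...) {
  cat("ScoreDistribution (", x$method, ") over [",
      round(x$min_score, 3), ",", round(x$max_score, 3), "] bits\n")
  invisible(x)
}

#' Tail probability of a score distribution
#'
#' @param dist a `ScoreDistribution`.
#' @param t score threshold(s).
#' @return Data frame with columns `t`, `p` and (for sampling) `se`.
#' @export
tail_prob <- function(dist, t) {
  stopifnot(inherits(dist, "ScoreDistribution"))
  if (dist$method == "exhaustive") {
    p <- vapply(t, function(tt) sum(dist$probs[dist$scores >= tt]), numeric(1))
    data.frame(t = t, p = p)
  } else {
    n <- dist$n_samples
    res <- t(vapply(t, function(tt) {
      x <- dist$weights * (dist$scores >= tt)
      c(mean(x), stats::sd(x) / sqrt(n))
    }, numeric(2)))
    data.frame(t = t, p = res[, 1], se = res[, 2])
  }
}

## Smallest achieved score whose tail probability is <= p (score cutoff
## equivalent to a p-value threshold); Inf when even the best word exceeds p.
score_cutoff_for_pvalue <- function(dist, p) {
  s <- dist$scores                       # ascending
  pr <- if (dist$method == "exhaustive") dist$probs else dist$weights / dist$n_samples
  tail <- rev(cumsum(rev(pr)))
  first <- !duplicated(s)                # tail at first occurrence = P(score >= s)
  u <- s[first]; tp <- tail[first]
  ok <- which(tp <= p)
  if (length(ok) == 0) Inf else u[min(ok)]
}

#' Scan a genome or location set for motif matches
#'
#' Scores every window of the motif's width on the requested strands and
#' reports windows at or above the threshold. Windows containing `N` are
#' skipped. A minus-strand match at `[x, x+W)` is the LOD score of the
#' reverse complement of the forward-strand word, reported at the same
#' coordinates with strand `-`.
#'
#' Thresholds can be given as a score (bits) or as a per-window p-value
#' under the background (`threshold_type = "pvalue"`), in which case the
#' score cutoff is the smallest achievable score with
#' `P(score >= t) <= threshold` (exhaustive null for widths <= 10,
#' importance sampling otherwise).
#'
#' @param target a `Genome`, or a `LocationSet` (then `genome` is required;
#'   matches are reported in genome coordinates).
#' @param m a frequency `Motif` or a `PSSM`.
#' @param threshold score (bits) or p-value per `threshold_type`.
#' @param threshold_type `"score"` or `"pvalue"`.
#' @param strands `"+"`, `"-"` or `"both"`.
#' @param genome bound `Genome` when `target` is a `LocationSet`.
#' @param bg,pseudo_weight PSSM construction parameters when `m` is a
#'   `Motif`; `bg = NULL` estimates an order-0 background from the genome.
#' @param n_samples,seed importance-sampling controls for p-value
#'   thresholds at widths > 10.
#' @return A `LocationSet` of matches with `value` = LOD score, `label` =
#'   matched forward-strand word, sorted by (sequence_id, start, strand).
#' @export
scan_motif <- function(target, m, threshold, threshold_type = c("score", "pvalue"),
                       strands = c("both", "+", "-"), genome = NULL,
                       bg = NULL, pseudo_weight = 0.01,
                       n_samples = 1e5, seed = 1) {
  threshold_type <- match.arg(threshold_type)
  strands <- match.arg(strands)
  if (inherits(target, "Genome") && is.null(genome)) genome <- target
  if (inherits(target, "LocationSet") && is.null(genome))
    stop("scanning a LocationSet requires a bound genome")
  pssm <- as_pssm(m, genome, bg, pseudo_weight)
  dist <- NULL
  if (threshold_type == "pvalue") {
    dist <- score_distribution(pssm,
      method = if (ncol(pssm$mat) <= 10) "exhaustive" else "importance_sampling",
      n_samples = n_samples, seed = seed)
    threshold <- score_cutoff_for_pvalue(dist, threshold)
  }
  regions <- if (inherits(target, "Genome")) {
    sl <- seq_lengths(target)
    data.frame(sequence_id = names(sl), start = 0, end = as.numeric(sl),
               stringsAsFactors = FALSE)
  } else as.data.frame(target)[c("sequence_id", "start", "end")]
  want <- if (strands == "both") c("+", "-") else strands
  smat_rc <- rc_mat(pssm$mat)
  W <- ncol(pssm$mat)
  res <- list()
  for (i in seq_len(nrow(regions))) {
    s <- get_seq(genome, regions$sequence_id[i], regions$start[i], regions$end[i])
    code <- encode_seq(s)
    for (st in want) {
      sc <- score_windows(code, if (st == "+") pssm$mat else smat_rc)
      hit <- which(!is.na(sc) & sc >= threshold)
      if (length(hit) == 0) next
      res[[length(res) + 1L]] <- data.frame(
        sequence_id = regions$sequence_id[i],
        start = regions$start[i] + hit - 1,
        end = regions$start[i] + hit - 1 + W,
        strand = st, value = sc[hit],
        label = substring(s, hit, hit + W - 1L),
        flag = NA_character_, stringsAsFactors = FALSE)
    }
  }
  nm <- paste0("matches:", pssm$name)
  if (length(res) == 0) return(location_set(name = nm))
  df <- do.call(rbind, res)
  df <- df[!duplicated(df[c("sequence_id", "start", "strand")]), , drop = FALSE]
  df <- df[order(df$sequence_id, df$start, df$strand), , drop = FALSE]
  out <- as_location_set(df, name = nm)
  if (!is.null(dist)) attr(out, "score_cutoff") <- threshold
  out
}

as_pssm <- function(m, genome = NULL, bg = NULL, pseudo_weight = 0.01) {
  if (inherits(m, "PSSM")) return(m)
  if (!inherits(m, "Motif")) stop("need a Motif or PSSM")
  if (is.null(bg)) bg <- if (!is.null(genome)) background(genome) else background()
  to_pssm(m, bg, pseudo_weight)
}

#' Cumulative LOD score of a sequence
#'
#' A whole-sequence motif-enrichment score: the sum, over all windows on
#' both strands, of the window LOD in excess of `floor`
#' (`sum max(lod - floor, 0)`). With the default floor of 0 only
#' better-than-background windows contribute, so a single strong site or
#' many weak sites can both raise the score.
#'
#' @param sequence DNA string.
#' @param m a frequency `Motif` or `PSSM`.
#' @param floor baseline LOD subtracted from each window (default 0).
#' @param bg,pseudo_weight PSSM construction parameters.
#' @return Cumulative LOD in bits (0 when the sequence is shorter than the
#'   motif).
#' @export
cumulative_lod <- function(sequence, m, floor = 0, bg = background(),
                           pseudo_weight = 0.01) {
  pssm <- as_pssm(m, bg = bg, pseudo_weight = pseudo_weight)
  code <- encode_seq(toupper(sequence))
  fwd <- score_windows(code, pssm$mat)
  rev <- score_windows(code, rc_mat(pssm$mat))
  sum(pmax(c(fwd, rev) - floor, 0), na.rm = TRUE)
}

#' HMM-based whole-sequence motif score (w-score)
#'
#' Models the sequence as emitted by a two-state generative process: at
#' each step, with probability `w` a motif state emits a full W-mer from
#' the regularized motif frequencies, otherwise a background state emits a
#' single base. The forward recursion over prefix likelihoods is
#'
#' `F(i) = (1-w) b(x_i) F(i-1) + w M(x_{i-W+1..i}) F(i-W)`
#'
#' and the w-score is `log2 L(w_hat) / L(0)` with `w_hat` chosen to
#' maximize the likelihood by golden-section search on `log10 w` over
#' `[1e-6, 0.5]`. The score is >= 0 by construction (`w = 0` recovers the
#' background-only model); it grows with the number and strength of motif
#' occurrences. Motif emission is evaluated on the forward strand; scan the
#' reverse complement of the sequence to score the other strand. Windows
#' containing `N` are excluded from the motif state and `N` bases emit with
#' probability 1 under both models.
#'
#' @param sequence DNA string, length >= motif width.
#' @param m a frequency `Motif`.
#' @param bg a `Background` (order-0 used).
#' @param pseudo_weight motif regularization weight.
#' @param fixed_w evaluate at this transition weight instead of optimizing
#'   (diagnostic use); the attribute `loglik` then holds the model
#'   log-likelihood (natural log).
#' @return w-score in bits, with the fitted transition weight in attribute
#'   `w_hat`.
#' @export
w_score <- function(sequence, m, bg = background(), pseudo_weight = 0.01,
                    fixed_w = NULL) {
  stopifnot(inherits(m, "Motif"), m$kind == "frequency")
  code <- encode_seq(toupper(sequence))
  W <- motif_width(m)
  if (length(code) < W) stop("sequence shorter than motif width")
  fp <- regularize_motif(m, bg, pseudo_weight)$mat
  logb <- c(log(bg$probs), 0)            # N emits with probability 1
  lb <- logb[code]
  logM <- score_windows(code, log(fp))   # log motif emission per window
  L <- length(code)
  ll <- function(w) {
    lw <- log(w); l1w <- log1p(-w)
    f <- rep(-Inf, L + 1L); f[1] <- 0
    for (i in seq_len(L)) {
      v <- l1w + lb[i] + f[i]
      if (i >= W && !is.na(logM[i - W + 1L])) {
        v2 <- lw + logM[i - W + 1L] + f[i - W + 1L]
        mx <- max(v, v2)
        v <- if (is.finite(mx)) mx + log(exp(v - mx) + exp(v2 - mx)) else -Inf
      }
      f[i + 1L] <- v
    }
    f[L + 1L]
  }
  ll0 <- sum(lb)
  if (!is.null(fixed_w)) {
    lw <- if (fixed_w > 0) ll(fixed_w) else ll0
    return(structure((lw - ll0) / log(2), w_hat = fixed_w, loglik = lw))
  }
  opt <- stats::optimize(function(u) ll(10^u), interval = c(-6, log10(0.5)),
                         maximum = TRUE, tol = 1e-6)
  score <- max(0, (opt$objective - ll0) / log(2))
  w_hat <- if (score > 0) 10^opt$maximum else 0
  structure(score, w_hat = w_hat)
}

#' Filter motif matches by conservation across aligned genomes
#'
#' Phylogenetic footprinting: a match is kept only if, in the alignment
#' block covering it, at least `min_other_genomes` non-reference rows
#' contain a window (within the aligned span padded by one motif width on
#' each side, after gap removal) scoring at least
#' `score_fraction * reference match score` on either strand. Matches not
#' covered by any block are dropped in strict mode (default) or kept with
#' `lenient = TRUE`.
#'
#' @param matches a `LocationSet` from [scan_motif()] (`value` holds the
#'   reference LOD score).
#' @param blocks list of `AlignmentBlock`.
#' @param m the `Motif` or `PSSM` that produced the matches.
#' @param min_other_genomes minimum number of non-reference rows that must
#'   support the match.
#' @param score_fraction fraction of the reference score required, in
#'   `(0, 1]`.
#' @param lenient keep matches outside any block.
#' @param bg,pseudo_weight PSSM construction parameters.
#' @return The filtered `LocationSet`.
#' @export
filter_conserved <- function(matches, blocks, m, min_other_genomes = 1,
                             score_fraction = 0.8, lenient = FALSE,
                             bg = background(), pseudo_weight = 0.01) {
  stopifnot(inherits(matches, "LocationSet"),
            score_fraction > 0, score_fraction <= 1)
  pssm <- as_pssm(m, bg = bg, pseudo_weight = pseudo_weight)
  W <- ncol(pssm$mat)
  smat_rc <- rc_mat(pssm$mat)
  keep <- logical(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    blk <- NULL
    for (b in blocks)
      if (b$sequence_id == matches$sequence_id[i] &&
          b$start <= matches$start[i] && matches$end[i] <= b$end) { blk <- b; break }
    if (is.null(blk)) { keep[i] <- lenient; next }
    ref <- strsplit(blk$rows[[1]], "")[[1]]
    refpos <- cumsum(ref != "-")         # genome offset (1-based) per column
    c1 <- which(refpos == matches$start[i] - blk$start + 1 & ref != "-")[1]
    c2 <- which(refpos == matches$end[i] - blk$start & ref != "-")[1]
    span <- seq(max(1, c1 - W), min(length(ref), c2 + W))
    need <- score_fraction * matches$value[i]
    n_ok <- 0L
    for (r in seq_along(blk$rows)[-1]) {
      frag <- gsub("-", "", paste(strsplit(blk$rows[[r]], "")[[1]][span],
                                  collapse = ""), fixed = TRUE)
      if (nchar(frag) < W) next
      code <- encode_seq(frag)
      best <- suppressWarnings(max(c(score_windows(code, pssm$mat),
                                     score_windows(code, smat_rc)), na.rm = TRUE))
      if (is.finite(best) && best >= need) n_ok <- n_ok + 1L
    }
    keep[i] <- n_ok >= min_other_genomes
  }
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, name = ls_name(matches), class = class(matches))
}
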