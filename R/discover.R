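#' Configuration for Gibbs motif discovery
#'
#' @param width motif width W (>= 4).
#' @param n_motifs number of motifs to report; sites of each reported motif
#'   are masked before searching for the next.
#' @param iterations Gibbs sweeps per restart (>= 100).
#' @param n_restarts independent restarts; restart `r` seeds its RNG stream
#'   with `seed + r - 1`.
#' @param seed base RNG seed (mandatory for reproducibility).
#' @param bg_order Markov order (0-3) of the background estimated from the
#'   input sequences.
#' @param zoops_prob prior probability that a sequence contains no site
#'   (ZOOPS model), in `[0, 1)`.
#' @param both_strands consider candidate sites on both strands.
#' @return A list of class `GibbsConfig`.
#' @export
gibbs_config <- function(width, n_motifs = 1, iterations = 1000,
                         n_restarts = 5, seed = 1, bg_order = 0,
                         zoops_prob = 0.1, both_strands = TRUE) {
  stopifnot(width >= 4, iterations >= 100, n_restarts >= 1,
            zoops_prob >= 0, zoops_prob < 1, bg_order %in% 0:3)
  structure(list(width = as.integer(width), n_motifs = as.integer(n_motifs),
                 iterations = as.integer(iterations),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 bg_order = as.integer(bg_order), zoops_prob = zoops_prob,
                 both_strands = both_strands),
            class = "GibbsConfig")
}

#' De novo motif discovery by Gibbs sampling
#'
#' Searches a set of sequences for a shared over-represented motif with a
#' ZOOPS (zero-or-one occurrence per sequence) Gibbs sampler. Each restart
#' initializes one random site per sequence, then repeatedly holds out one
#' sequence, builds the regularized count matrix `f'` from the remaining
#' sites (one background-proportional pseudo-observation in total), and
#' re-samples the held-out sequence's site among all N-free windows (both
#' strands by default) with probability proportional to
#' `prod_i f'(i, b_i) / P_bg(word)`, or no site with prior `zoops_prob`.
#' After the sampling sweeps, deterministic argmax sweeps run to a fixed
#' point (the predictive-update maximum). Restarts are compared by motif
#' score = total information content (bits, vs the order-0 marginal of the
#' background) times the number of sites. For multiple motifs, the sites of
#' each reported motif are masked to `N` before the next search.
#'
#' With a fixed seed the output is reproducible bit-for-bit.
#'
#' @param sequences character vector of DNA sequences, or a `LocationSet`
#'   with `genome` supplied.
#' @param config a [gibbs_config()].
#' @param genome bound `Genome` when `sequences` is a `LocationSet`.
#' @return A list of length `n_motifs`; each element has `motif` (the count
#'   `Motif`, `nsites` set), `sites` (data frame `seq`, `start`, `strand`,
#'   `word`; `start` is 0-based within the input sequence), and `score`.
#' @export
gibbs_discover <- function(sequences, config, genome = NULL) {
  stopifnot(inherits(config, "GibbsConfig"))
  if (inherits(sequences, "LocationSet")) {
    if (is.null(genome)) stop("LocationSet input requires a bound genome")
    sequences <- location_seqs(sequences, genome)
  }
  sequences <- toupper(as.character(sequences))
  W <- config$width
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (all(nchar(sequences) < W)) stop("all sequences shorter than the motif width")
  bg <- background(sequences, order = config$bg_order)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  work <- sequences
  out <- vector("list", config$n_motifs)
  for (k in seq_len(config$n_motifs)) {
    best <- NULL
    for (r in seq_len(config$n_restarts)) {
      set.seed(config$seed + (k - 1L) * config$n_restarts + r - 1L)
      fit <- gibbs_one_restart(work, W, bg, config)
      if (!is.null(fit) && (is.null(best) || fit$score > best$score)) best <- fit
    }
    if (is.null(best)) stop("no valid site configuration found")
    out[[k]] <- best
    if (k < config$n_motifs)
      work <- mask_sites(work, data.frame(seq = best$sites$seq,
                                          start = best$sites$start,
                                          end = best$sites$start + W))
  }
  out
}

## One seeded restart of the sampler on pre-masked sequences.
gibbs_one_restart <- function(seqs, W, bg, config) {
  n <- length(seqs)
  z <- config$zoops_prob
  ## Per-sequence candidate table: encoded windows and their background
  ## log-probabilities, on each requested strand.
  prep <- lapply(seqs, function(s) {
    code <- encode_seq(s)
    L <- length(code)
    if (L < W) return(NULL)
    nw <- L - W + 1L
    hasN <- !is.na(score_windows(code, matrix(0, 4, W)))
    valid <- which(hasN)
    if (length(valid) == 0) return(NULL)
    strands <- "+"
    if (config$both_strands) strands <- c("+", "-")
    cand_start <- rep(valid, length(strands))
    cand_strand <- rep(strands, each = length(valid))
    wc <- t(vapply(valid, function(j) code[j:(j + W - 1L)], integer(W)))
    wcodes <- wc
    if (config$both_strands) {
      comp <- c(4L, 3L, 2L, 1L)
      wcodes <- rbind(wc, matrix(comp[wc[, W:1, drop = FALSE]], ncol = W))
    }
    list(code = code, start = cand_start, strand = cand_strand,
         wcodes = wcodes, logbg = bg_word_logprob(bg, wcodes))
  })
  usable <- which(!vapply(prep, is.null, logical(1)))
  if (length(usable) < 2) return(NULL)
  ## counts: 4 x W matrix over current sites; site[s] = candidate row or 0
  counts <- matrix(0, 4, W)
  site <- rep(0L, n)
  for (s in usable) {
    site[s] <- sample.int(nrow(prep[[s]]$wcodes), 1L)
    counts <- counts + word_counts(prep[[s]]$wcodes[site[s], ])
  }
  bgp <- bg$probs
  update <- function(s, sample_it) {
    if (site[s] > 0L) counts <<- counts - word_counts(prep[[s]]$wcodes[site[s], ])
    nn <- sum(site[usable] > 0L) - (site[s] > 0L)
    fp <- (counts + bgp) / (nn + 1)
    lf <- log(fp)
    idx <- sweep(prep[[s]]$wcodes, 2, (seq_len(W) - 1L) * 4L, "+")
    logA <- rowSums(matrix(lf[idx], ncol = W)) - prep[[s]]$logbg
    nc <- length(logA)
    mx <- max(logA, 0)
    wj <- (1 - z) / nc * exp(logA - mx)
    w0 <- z * exp(-mx)
    if (sample_it) {
      pick <- sample.int(nc + 1L, 1L, prob = c(w0, wj))
    } else {
      pick <- which.max(c(w0, wj))
    }
    site[s] <<- pick - 1L
    if (site[s] > 0L) counts <<- counts + word_counts(prep[[s]]$wcodes[site[s], ])
    invisible(NULL)
  }
  ## column-shift move: slide every placed site by d if that raises the
  ## configuration score (counters the phase-shift local optima Gibbs
  ## samplers are prone to)
  cand_index <- function(s, j, st) {
    hit <- which(prep[[s]]$start == j & prep[[s]]$strand == st)
    if (length(hit)) hit[1] else NA_integer_
  }
  config_score <- function(cnts, nsit) {
    f <- (cnts + bgp) / (nsit + 1)
    nsit * sum(f * log2(f / bgp))
  }
  try_shift <- function() {
    placed <- usable[site[usable] > 0L]
    if (length(placed) < 2) return(invisible(NULL))
    best_d <- 0L
    best_sc <- config_score(counts, length(placed))
    best_idx <- NULL
    for (d in c(-2L, -1L, 1L, 2L)) {
      idx <- vapply(placed, function(s) {
        j <- prep[[s]]$start[site[s]]
        st <- prep[[s]]$strand[site[s]]
        cand_index(s, j + (if (st == "+") d else -d), st)
      }, integer(1))
      if (anyNA(idx)) next
      cnts <- matrix(0, 4, W)
      for (k in seq_along(placed))
        cnts <- cnts + word_counts(prep[[placed[k]]]$wcodes[idx[k], ])
      sc <- config_score(cnts, length(placed))
      if (sc > best_sc + 1e-12) { best_sc <- sc; best_d <- d; best_idx <- idx }
    }
    if (best_d != 0L) {
      for (k in seq_along(placed)) site[placed[k]] <<- best_idx[k]
      counts <<- matrix(0, 4, W)
      for (s in placed) counts <<- counts + word_counts(prep[[s]]$wcodes[site[s], ])
    }
    invisible(NULL)
  }
  for (it in seq_len(config$iterations)) {
    for (s in usable) update(s, TRUE)
    if (it %% 50L == 0L) try_shift()
  }
  ## deterministic predictive-update sweeps to a fixed point
  for (pass in seq_len(100L)) {
    prev <- site
    for (s in usable) update(s, FALSE)
    try_shift()
    if (identical(prev, site)) break
  }
  placed <- usable[site[usable] > 0L]
  if (length(placed) < 2) return(NULL)
  words <- vapply(placed, function(s) decode_seq(prep[[s]]$wcodes[site[s], ]),
                  character(1))
  m <- motif(words_to_counts(words), name = sprintf("gibbs_w%d", W),
             nsites = length(words))
  ic_bg <- information_content(m, bg = structure(
    list(order = 0L, probs = bg$probs, cond = NULL), class = "Background"))
  sites <- data.frame(
    seq = placed,
    start = vapply(placed, function(s) prep[[s]]$start[site[s]] - 1L, integer(1)),
    strand = vapply(placed, function(s) prep[[s]]$strand[site[s]], character(1)),
    word = words, stringsAsFactors = FALSE)
  list(motif = m, sites = sites, score = ic_bg$total * length(words))
}

word_counts <- function(wcode) {
  W <- length(wcode)
  m <- matrix(0, 4, W)
  m[cbind(wcode, seq_len(W))] <- 1
  m
}

#' Mask site spans with N
#'
#' Replaces each site span with `N` so the bases are excluded from further
#' motif searches (used between successive motifs in [gibbs_discover()]).
#'
#' @param sequences character vector of sequences.
#' @param sites data frame with columns `seq` (sequence index), `start`
#'   (0-based) and `end` (exclusive).
#' @return The masked character vector.
#' @export
mask_sites <- function(sequences, sites) {
  for (i in seq_len(nrow(sites))) {
    s <- sites$seq[i]
    if (sites$start[i] < 0 || sites$end[i] > nchar(sequences[s]))
      stop("site out of bounds")
    substr(sequences[s], sites$start[i] + 1L, sites$end[i]) <-
      strrep("N", sites$end[i] - sites$start[i])
  }
  sequences
}
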