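# Scoring and scanning: LOD/affinity scores, match p-values, whole-sequence
# scores and the conservation filter, each against an independent oracle.

test_that("LOD scoring is additive and rejects N words", {
  bg <- background(NULL)
  zero <- to_pssm(motif(matrix(0.25, 4, 4)), bg)
  expect_equal(lod_score(zero, "ACGT"), 0)
  expect_equal(lod_score(zero, "TTTT"), 0)

  a1 <- to_pssm(motif_from_degenerate("A"), bg, pseudo_weight = 1e-9)
  expect_equal(lod_score(a1, "A"), 2, tolerance = 1e-6)

  set.seed(100)
  m <- motif(matrix(runif(24) + 0.02, 4, 6))
  ps <- to_pssm(m, bg)
  for (i in 1:100) {
    w <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
    expect_equal(lod_score(ps, w), oracle_lod(ps, w))
  }
  expect_true(is.na(lod_score(ps, "ACGNTA")))
})

test_that("affinity scores are per-position products in [0, 1]", {
  ones <- motif(matrix(1, 4, 5), kind = "affinity")
  expect_equal(affinity_score(ones, "ACGTA"), 1)
  zero_col <- motif(matrix(c(1, 0, 0, 0), 4, 3), kind = "affinity")
  expect_equal(affinity_score(zero_col, "ACA"), 0)
  set.seed(101)
  aff <- motif(matrix(runif(20), 4, 5), kind = "affinity")
  for (i in 1:50) {
    w <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
    code <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    expect_equal(affinity_score(aff, w),
                 prod(vapply(1:5, function(j) aff$mat[code[j], j], numeric(1))))
    expect_gte(affinity_score(aff, w), 0)
    expect_lte(affinity_score(aff, w), 1)
  }
  expect_error(affinity_score(motif(matrix(1, 4, 3)), "ACG"), "affinity")
})

test_that("exhaustive score distribution equals naive enumeration", {
  set.seed(102)
  for (i in 1:5) {
    W <- sample(3:5, 1)
    ps <- to_pssm(motif(matrix(runif(4 * W) + 0.01, 4, W)),
                  background(genome(c(s = paste(sample(c("A","C","G","T"), 500,
                                                       TRUE, prob = runif(4) + 0.2),
                                                collapse = "")))))
    d <- score_distribution(ps, "exhaustive")
    o <- oracle_exhaustive(ps)
    expect_identical(d$scores, o$scores)
    expect_identical(d$probs, o$probs)
    expect_equal(sum(d$probs), 1)
    # boundary behaviour
    expect_equal(tail_prob(d, ps$min_score - 1)$p, 1)
    expect_equal(tail_prob(d, ps$min_score - 1e-9)$p, 1)
    expect_equal(tail_prob(d, ps$max_score + 1e-9)$p, 0)
    # non-increasing step function
    ts <- seq(ps$min_score, ps$max_score, length.out = 30)
    expect_true(all(diff(tail_prob(d, ts)$p) <= 0))
  }
})

test_that("importance sampling agrees with the exhaustive tail within 3 SE", {
  set.seed(103)
  ps <- to_pssm(motif(matrix(runif(20) + 0.01, 4, 5)), background(NULL))
  ex <- score_distribution(ps, "exhaustive")
  samp <- score_distribution(ps, "importance_sampling", n_samples = 1e5, seed = 11)
  for (q in c(0.90, 0.99)) {
    t <- stats::quantile(ex$scores, q, names = FALSE)
    truth <- tail_prob(ex, t)$p
    est <- tail_prob(samp, t)
    expect_lt(abs(est$p - truth), 3 * est$se)
  }
  expect_error(score_distribution(ps, "importance_sampling", n_samples = 50),
               "100")
})

test_that("importance sampling is unbiased over seeded replicates", {
  set.seed(104)
  ps <- to_pssm(motif(matrix(runif(20) + 0.05, 4, 5)), background(NULL))
  ex <- score_distribution(ps, "exhaustive")
  t <- stats::quantile(ex$scores, 0.95, names = FALSE)
  truth <- tail_prob(ex, t)$p
  ests <- vapply(1:200, function(s)
    tail_prob(score_distribution(ps, "importance_sampling", n_samples = 2000,
                                 seed = s), t)$p, numeric(1))
  se_mean <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 2 * se_mean)
})

test_that("genome scanning equals the brute-force window oracle", {
  g <- make_genome(2000, 0.5, seed = 105)
  # inject some N to exercise skipping
  s <- unclass(g)[["s1"]]
  substr(s, 500, 520) <- strrep("N", 21)
  g <- genome(c(s1 = s))
  set.seed(106)
  m <- motif(matrix(runif(24) + 0.01, 4, 6))
  bg <- background(g)
  ps <- to_pssm(m, bg)
  thr <- stats::quantile(c(ps$min_score, ps$max_score), 0.7, names = FALSE)
  got <- scan_motif(g, ps, threshold = thr)
  want <- oracle_scan(s, ps, thr)
  want <- want[order(want$start, want$strand), ]
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$value, want$score)
  # no window overlapping the N run
  expect_false(any(got$start >= 494 & got$start <= 519))
  # threshold extremes
  expect_equal(nrow(scan_motif(g, ps, threshold = ps$max_score + 1)), 0)
  all_hits <- scan_motif(g, ps, threshold = ps$min_score)
  nfree <- sum(!is.na(regmotif:::score_windows(regmotif:::encode_seq(s), ps$mat)))
  expect_equal(sum(all_hits$strand == "+"), nfree)
})

test_that("scanning has strand symmetry under genome reverse complement", {
  g <- make_genome(1000, 0.5, seed = 107)
  set.seed(108)
  m <- motif(matrix(runif(20) + 0.05, 4, 5))
  ps <- to_pssm(m, background(NULL))
  thr <- 0.6 * ps$max_score
  fwd <- scan_motif(g, ps, threshold = thr)
  grc <- genome(c(s1 = revcomp(unclass(g)[["s1"]])))
  rcv <- scan_motif(grc, ps, threshold = thr)
  L <- 1000; W <- 5
  # a + match at x on the revcomp genome is a - match at L - x - W
  expect_equal(sort(L - rcv$start[rcv$strand == "+"] - W),
               sort(fwd$start[fwd$strand == "-"]))
  expect_equal(sort(L - rcv$start[rcv$strand == "-"] - W),
               sort(fwd$start[fwd$strand == "+"]))
})

test_that("p-value thresholds select the matching score cutoff", {
  g <- make_genome(5000, 0.5, seed = 109)
  m <- sharp_motif("ACGTTGCA", major = 0.9)
  ps <- to_pssm(m, background(g))
  d <- score_distribution(ps, "exhaustive")
  pthr <- 1e-3
  hits <- scan_motif(g, ps, threshold = pthr, threshold_type = "pvalue")
  cutoff <- attr(hits, "score_cutoff")
  expect_lte(tail_prob(d, cutoff)$p, pthr)
  # every reported match scores at or above the cutoff, and the cutoff is
  # the loosest achievable one
  if (nrow(hits) > 0) expect_true(all(hits$value >= cutoff))
  below <- max(d$scores[d$scores < cutoff])
  expect_gt(tail_prob(d, below)$p, pthr)
})

test_that("scanning a LocationSet reports genome coordinates", {
  g <- make_genome(1000, 0.5, seed = 110)
  m <- sharp_motif("TTGACGTCAA")
  pl <- plant_sites(g, m, 3, seed = 111, mode = "consensus")
  regions <- location_set("s1", pl$sites$start - 10, pl$sites$end + 10,
                          genome = pl$genome)
  ps <- to_pssm(m, background(NULL))
  hits <- scan_motif(regions, ps, threshold = 0.9 * ps$max_score,
                     genome = pl$genome)
  expect_true(all(pl$sites$start %in% hits$start))
})

test_that("cumulative LOD equals the double-strand window sum oracle", {
  set.seed(112)
  m <- motif(matrix(runif(20) + 0.05, 4, 5))
  bg <- background(NULL)
  ps <- to_pssm(m, bg)
  # shorter than the motif: no windows
  expect_equal(cumulative_lod("ACG", m, bg = bg), 0)
  # single-window sequence
  w <- "ACGTA"
  expect_equal(cumulative_lod(w, m, floor = -100, bg = bg),
               oracle_lod(ps, w) + oracle_lod(ps, revcomp_str(w)) + 200)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    want <- 0
    for (x in 1:(60 - 4)) {
      word <- substr(s, x, x + 4)
      want <- want + max(oracle_lod(ps, word), 0) +
        max(oracle_lod(ps, revcomp_str(word)), 0)
    }
    expect_equal(cumulative_lod(s, m, bg = bg), want)
  }
})

test_that("w-score forward recursion equals segmentation enumeration", {
  set.seed(113)
  m <- motif(matrix(runif(12) + 0.05, 4, 3))
  bg <- background(NULL)
  fp <- regularize_motif(m, bg, 0.01)$mat
  # all sequences of lengths 3..5, plus random length 6-8 sequences
  seqs <- character(0)
  for (L in 3:5) {
    words <- all_words(L)
    seqs <- c(seqs, apply(words, 1, paste, collapse = ""))
  }
  seqs <- c(seqs, vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(6:8, 1), TRUE), collapse = ""),
    character(1)))
  for (w in c(0.1, 0.37)) {
    for (s in sample(seqs, 120)) {
      got <- attr(w_score(s, m, bg, fixed_w = w), "loglik")
      want <- log(oracle_segmentation_lik(
        match(strsplit(s, "")[[1]], c("A", "C", "G", "T")), 3, w, bg$probs, fp))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("w-score is zero iff the motif adds nothing", {
  bg <- background(NULL)
  atbg <- motif(matrix(0.25, 4, 4))
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  expect_equal(as.numeric(w_score(s, atbg, bg, pseudo_weight = 0)), 0)
  # tandem consensus repeats of a sharp motif score strictly positive
  m <- sharp_motif()
  tandem <- strrep(motif_consensus(m), 6)
  expect_gt(as.numeric(w_score(tandem, m, bg)), 0)
})

test_that("w-score grows with the number of planted sites (in expectation)", {
  m <- sharp_motif()
  bg <- background(NULL)
  mean_score <- function(k) {
    mean(vapply(1:5, function(s) {
      g <- make_genome(300, 0.5, seed = 7000 + 10 * k + s)
      pl <- if (k > 0) plant_sites(g, m, k, seed = 7500 + 10 * k + s,
                                   mode = "consensus")$genome else g
      as.numeric(w_score(unclass(pl)[["s1"]], m, bg))
    }, numeric(1)))
  }
  scores <- vapply(c(0, 2, 5), mean_score, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("conservation filter matches a brute-force rescoring oracle", {
  m <- sharp_motif()
  bg <- background(NULL)
  ps <- to_pssm(m, bg)
  g <- make_genome(600, 0.5, seed = 114)
  pl <- plant_sites(g, m, 6, seed = 115, mode = "consensus")
  matches <- scan_motif(pl$genome, ps, threshold = 0.8 * ps$max_score)
  expect_gte(nrow(matches), 6)
  blocks <- make_alignment(pl$genome, location_set("s1", 0, 600),
                           n_species = 3, sub_rate = 0.25, seed = 116)
  frac <- 0.9
  kept <- filter_conserved(matches, blocks, ps, min_other_genomes = 2,
                           score_fraction = frac, bg = bg)
  # oracle: rescore each non-reference row around the aligned span
  blk <- blocks[[1]]
  W <- 10
  want_keep <- vapply(seq_len(nrow(matches)), function(i) {
    n_ok <- 0
    for (r in names(blk$rows)[-1]) {
      row <- blk$rows[[r]]       # no gaps in simulated blocks
      lo <- max(1, matches$start[i] - W + 1)
      hi <- min(600, matches$end[i] + W)
      frag <- substr(row, lo, hi)
      best <- -Inf
      for (x in 1:(nchar(frag) - W + 1)) {
        wd <- substr(frag, x, x + W - 1)
        best <- max(best, oracle_lod(ps, wd), oracle_lod(ps, revcomp_str(wd)),
                    na.rm = TRUE)
      }
      if (best >= frac * matches$value[i]) n_ok <- n_ok + 1
    }
    n_ok >= 2
  }, logical(1))
  expect_equal(matches$start[want_keep], kept$start)

  # all-gap rows at the match drop it
  g2 <- genome(c(s1 = "ACGTTTGACGTCAAACGTAC"))
  m2 <- scan_motif(g2, ps, threshold = 0.8 * ps$max_score, strands = "+")
  expect_equal(nrow(m2), 1)
  gapblk <- alignment_block("s1", 0, 20,
                            c(ref = unclass(g2)[["s1"]],
                              sp1 = paste0(substr(unclass(g2)[["s1"]], 1, 2),
                                           strrep("-", 16),
                                           substr(unclass(g2)[["s1"]], 19, 20))))
  expect_equal(nrow(filter_conserved(m2, list(gapblk), ps,
                                     min_other_genomes = 1, bg = bg)), 0)
  # matches outside any block: dropped strict, kept lenient
  expect_equal(nrow(filter_conserved(m2, list(), ps, bg = bg)), 0)
  expect_equal(nrow(filter_conserved(m2, list(), ps, lenient = TRUE, bg = bg)), 1)
})
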