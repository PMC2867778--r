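# Enrichment, positional-distribution, spacing and GO statistics.

test_that("identical target and control sets give flat enrichment", {
  g <- make_genome(3000, 0.5, seed = 150)
  regions <- location_set("s1", seq(0, 2900, by = 100), seq(50, 2950, by = 100),
                          genome = g)
  m <- sharp_motif("ACGTACGT", major = 0.9)
  res <- motif_enrichment(m, regions, regions, g, cutoffs = c(2, 5, 8))
  expect_true(all(res$p == 1))
  expect_true(all(is.na(res$ratio) | res$ratio == 1))
  # cutoff above max_score: no matches anywhere, p = 1
  ps <- to_pssm(m, background(g))
  res2 <- motif_enrichment(m, regions, regions, g, cutoffs = ps$max_score + 1)
  expect_equal(res2$n_target_with_match, 0)
  expect_equal(res2$p, 1)
  expect_error(motif_enrichment(m, regions, regions, g, cutoffs = c(5, 2)),
               "increasing")
})

test_that("planted enrichment counts match and Fisher equals the closed form", {
  m <- sharp_motif()
  g <- make_genome(10000, 0.5, seed = 151)
  width <- 60
  starts <- seq(0, 9900, by = 100)[1:100]
  regions <- location_set("s1", starts, starts + width)
  # plant consensus in target regions 1..30 of 50; controls 51..100 untouched
  seqs <- unclass(g)[["s1"]]
  for (i in 1:30)
    substr(seqs, starts[i] + 20 + 1, starts[i] + 30) <- motif_consensus(m)
  g2 <- genome(c(s1 = seqs))
  targets <- as_location_set(as.data.frame(regions)[1:50, ])
  controls <- as_location_set(as.data.frame(regions)[51:100, ])
  bg <- background(NULL)
  ps <- to_pssm(m, bg)
  cut <- 0.9 * ps$max_score
  res <- motif_enrichment(m, targets, controls, g2, cutoffs = cut, bg = bg)
  expect_equal(res$n_target_with_match, 30)
  expect_equal(res$n_control_with_match, 0)
  expect_equal(res$p, oracle_fisher2(30, 50, 0, 50))
})

test_that("Fisher p equals the hypergeometric closed form over many tables", {
  set.seed(152)
  for (i in 1:200) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    expect_equal(stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2))$p.value,
                 oracle_fisher2(a, n1, b, n2), tolerance = 1e-12,
                 info = paste(a, n1, b, n2))
  }
})

test_that("shuffled-sequence controls preserve dinucleotide counts", {
  g <- make_genome(2000, 0.4, seed = 153)
  s <- unclass(g)[["s1"]]
  set.seed(1)
  sh <- regmotif:::dinuc_shuffle_one(s)
  expect_equal(nchar(sh), nchar(s))
  dinucs <- function(x) table(substring(x, 1:(nchar(x) - 1), 2:nchar(x)))
  expect_equal(dinucs(sh), dinucs(s))
  # control-free enrichment runs and returns sane output
  m <- sharp_motif("ACGTACGT")
  regions <- location_set("s1", c(0, 500, 1000), c(200, 700, 1200))
  res <- motif_enrichment(m, regions, NULL, g, cutoffs = 5, shuffle_seed = 2)
  expect_equal(res$n_control, 3)
})

test_that("library enrichment ranks a planted motif first by q-value", {
  set.seed(154)
  planted <- sharp_motif()
  decoys <- lapply(1:9, function(i)
    motif(matrix(runif(40) + 0.02, 4, 10), name = paste0("decoy", i)))
  library <- c(list(planted), decoys)
  g <- make_genome(8000, 0.5, seed = 155)
  starts <- seq(0, by = 80, length.out = 100)
  seqs <- unclass(g)[["s1"]]
  for (i in 1:40) substr(seqs, starts[i] + 11, starts[i] + 20) <-
    motif_consensus(planted)
  g2 <- genome(c(s1 = seqs))
  targets <- location_set("s1", starts[1:50], starts[1:50] + 60)
  controls <- location_set("s1", starts[51:100], starts[51:100] + 60)
  bg <- background(NULL)
  res <- library_enrichment(library, targets, controls, g2, cutoffs = 12,
                            bg = bg)
  expect_equal(res$motif[which.min(res$q)], planted$name)
  # single-motif library: q equals p
  solo <- library_enrichment(list(planted), targets, controls, g2,
                             cutoffs = 12, bg = bg)
  expect_equal(solo$q, solo$p)
})

test_that("positional concentration at anchor midpoints is detected", {
  anchors <- location_set("s1", seq(0, 9900, by = 100), seq(0, 9900, by = 100) + 100)
  # 100 matches exactly at anchor midpoints
  mstart <- seq(0, 9900, by = 100) + 48
  matches <- location_set("s1", mstart, mstart + 4)
  res <- positional_distribution(matches, anchors)
  expect_lt(res$p, 1e-6)
  expect_equal(res$n, 100)
  expect_error(positional_distribution(location_set("s1", 1, 5), anchors),
               "at least 2")
})

test_that("uniform match placement is not flagged as non-uniform", {
  set.seed(156)
  anchors <- location_set("s1", seq(0, 49500, by = 500),
                          seq(0, 49500, by = 500) + 400)
  ps <- vapply(1:30, function(rep) {
    set.seed(1000 + rep)
    aidx <- sample(100, 1000, replace = TRUE)
    off <- floor(runif(1000) * 396)
    mm <- location_set("s1", anchors$start[aidx] + off,
                       anchors$start[aidx] + off + 4)
    positional_distribution(mm, anchors)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("planted 30 bp spacing is detected and self-pairs are excluded", {
  mA <- sharp_motif("TTGACGTCAA")
  mB <- sharp_motif("GGGTACCGGG")
  g <- make_genome(30000, 0.5, seed = 157)
  pp <- plant_site_pairs(g, mA, mB, n_pairs = 100, gap = 30, seed = 158,
                         mode = "consensus")
  res <- spacing_analysis(pp$sitesA, pp$sitesB, seq_lengths = g,
                          max_gap = 100, window = 5, n_permutations = 500,
                          seed = 3)
  w <- res$windows
  hot <- w[w$gap_lo <= 30 & 30 < w$gap_hi, ]
  expect_equal(which.min(w$p_adj), which(w$gap_lo == hot$gap_lo))
  expect_lte(hot$p_adj, 0.05)
  expect_gte(res$n_pairs, 100)   # planted pairs plus chance co-occurrences

  # A = B with a single match: no pairs
  one <- location_set("s1", 10, 20)
  r2 <- spacing_analysis(one, one, seq_lengths = c(s1 = 1000), max_gap = 50,
                         window = 5, n_permutations = 10, seed = 1)
  expect_equal(r2$n_pairs, 0)
  expect_match(r2$flagged, "no co-occurring")
})

test_that("random spacing stays below the detection threshold", {
  set.seed(159)
  flags <- vapply(1:10, function(rep) {
    g <- make_genome(20000, 0.5, seed = 2000 + rep)
    set.seed(3000 + rep)
    sa <- sort(sample(0:19900, 60)); sb <- sort(sample(0:19900, 60))
    A <- location_set("s1", sa, sa + 10)
    B <- location_set("s1", sb, sb + 10)
    res <- spacing_analysis(A, B, seq_lengths = g, max_gap = 100, window = 5,
                            n_permutations = 199, seed = 4000 + rep)
    if (is.null(res$windows)) FALSE else any(res$windows$p_adj <= 0.05)
  }, logical(1))
  expect_gte(mean(!flags), 0.9)
})

test_that("GO enrichment reproduces the hypergeometric closed form", {
  genes <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene = genes[1:5], term = "T1")
  dag <- data.frame(term = "T1", parent = "ROOT")
  res <- go_enrichment(genes[1:5], ann, dag, genes)
  r1 <- res[res$term == "T1", ]
  expect_equal(r1$k, 5); expect_equal(r1$K, 5)
  expect_equal(r1$p, 1 / choose(20, 5))
  expect_equal(r1$p, 1 / 15504, tolerance = 1e-12)
  # a term annotated to every universe gene is uninformative
  ann2 <- rbind(ann, data.frame(gene = genes, term = "Tall"))
  res2 <- go_enrichment(genes[1:5], ann2, dag, genes)
  expect_equal(res2$p[res2$term == "Tall"], 1)
  # no annotated study genes -> empty result
  ann3 <- data.frame(gene = genes[6:8], term = "T2")
  expect_equal(nrow(go_enrichment(genes[1:2], ann3, dag, genes)), 0)
  expect_error(go_enrichment("nope", ann, dag, genes), "absent")
})

test_that("annotation propagation is monotone along ancestry", {
  set.seed(160)
  for (rep in 1:5) {
    terms <- paste0("t", 1:12)
    # random DAG: each term gets 0-2 parents among lower-numbered terms
    edges <- list()
    for (i in 2:12) {
      np <- sample(0:min(2, i - 1), 1)
      if (np > 0)
        for (p in sample(seq_len(i - 1), np))
          edges[[length(edges) + 1L]] <- data.frame(term = terms[i],
                                                    parent = terms[p])
    }
    dag <- do.call(rbind, edges)
    genes <- sprintf("g%02d", 1:30)
    ann <- data.frame(gene = sample(genes, 40, replace = TRUE),
                      term = sample(terms, 40, replace = TRUE))
    res <- go_enrichment(sample(genes, 10), ann, dag, genes)
    anc <- regmotif:::ancestors_table(dag)
    for (t in res$term) for (a in intersect(anc[[t]], res$term)) {
      expect_gte(res$k[res$term == a], res$k[res$term == t])
      expect_gte(res$K[res$term == a], res$K[res$term == t])
    }
  }
  expect_error(regmotif:::ancestors_table(
    data.frame(term = c("a", "b"), parent = c("b", "a"))), "cyclic")
})

test_that("upstream windows truncate at edges and neighbors", {
  g <- genome(c(s1 = strrep("ACGT", 500)))   # 2000 bp
  genes <- gene_models(c("g1", "g2", "g3"), "s1",
                       start = c(0, 600, 1500), end = c(400, 1000, 1900),
                       strand = c("+", "+", "-"))
  ups <- regmotif:::upstream_regions(genes, g, upstream_bp = 300)
  expect_true(is.na(ups$start[1]))                 # no room at sequence start
  expect_equal(c(ups$start[2], ups$end[2]), c(400, 600))  # clipped at g1
  expect_equal(c(ups$start[3], ups$end[3]), c(1900, 2000)) # minus strand, edge
  ups2 <- regmotif:::upstream_regions(genes, g, 300, truncate_at_neighbor = FALSE)
  expect_equal(c(ups2$start[2], ups2$end[2]), c(300, 600))
})

test_that("best upstream scores equal a brute-force window maximum", {
  m <- sharp_motif("ACGTTGCA", major = 0.9)
  g <- make_genome(4000, 0.5, seed = 161)
  starts <- seq(500, 3700, by = 400)
  genes <- gene_models(paste0("g", seq_along(starts)), "s1", starts,
                       starts + 200, rep(c("+", "-"), length.out = length(starts)))
  bg <- background(NULL)
  ps <- to_pssm(m, bg)
  tab <- best_upstream_scores(list(m), genes, g, upstream_bp = 150, bg = bg)
  ups <- regmotif:::upstream_regions(genes, g, 150)
  for (i in seq_len(nrow(genes))) {
    s <- substr(unclass(g)[["s1"]], ups$start[i] + 1, ups$end[i])
    best <- -Inf
    for (x in seq_len(nchar(s) - 7)) {
      wd <- substr(s, x, x + 7)
      best <- max(best, oracle_lod(ps, wd), oracle_lod(ps, revcomp_str(wd)),
                  na.rm = TRUE)
    }
    expect_equal(tab[i, 1], best, info = paste("gene", i))
  }
  # a gene flush at the sequence start has no upstream window
  g0 <- gene_models("g0", "s1", 0, 100, "+")
  tab0 <- best_upstream_scores(list(m), g0, g, upstream_bp = 150, bg = bg)
  expect_equal(tab0[1, 1], -Inf)
})

test_that("motif-GO association recovers the annotated upstream term", {
  m <- sharp_motif()
  g <- make_genome(20000, 0.5, seed = 162)
  gg <- make_genes_and_go(g, n_genes = 20, n_terms = 4,
                          enriched_term_size = 10, seed = 163)
  # plant the consensus upstream of exactly the enriched genes
  seqs <- unclass(g)[["s1"]]
  ups <- regmotif:::upstream_regions(gg$genes, g, 150)
  for (i in which(gg$genes$gene_id %in% gg$enriched_genes)) {
    # plant next to the TSS, the part of the window no neighbor shares
    pos <- if (gg$genes$strand[i] == "+") ups$end[i] - 15 else ups$start[i] + 5
    substr(seqs, pos + 1, pos + 10) <- motif_consensus(m)
  }
  g2 <- genome(c(s1 = seqs))
  bg <- background(NULL)
  res <- motif_go_association(m, gg$genes, g2, upstream_bp = 150,
                              score_cutoff = 15,
                              annotations = gg$annotations,
                              ancestry = gg$ancestry, bg = bg)
  expect_equal(res$term[1], gg$enriched_term)
  expect_setequal(attr(res, "study_genes"), gg$enriched_genes)
  # an unreachable cutoff empties the study set
  ps <- to_pssm(m, bg)
  res0 <- motif_go_association(m, gg$genes, g2, upstream_bp = 150,
                               score_cutoff = ps$max_score + 1,
                               annotations = gg$annotations,
                               ancestry = gg$ancestry, bg = bg)
  expect_equal(nrow(res0), 0)
  expect_error(motif_go_association(m, gg$genes, g2, upstream_bp = 5,
                                    score_cutoff = 1,
                                    annotations = gg$annotations,
                                    ancestry = gg$ancestry, bg = bg),
               "width")
})
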