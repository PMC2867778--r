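#' Motif enrichment in target vs control locations
#'
#' For each score cutoff, counts how many target and control locations
#' contain at least one motif match (any window on either strand scoring
#' >= cutoff) and tests the 2x2 table with a two-sided Fisher exact test.
#' Incremental cutoffs show how enrichment sharpens as the match
#' definition tightens.
#'
#' When `controls` is omitted, a control set is built by dinucleotide
#' shuffling each target sequence (Altschul-Erikson shuffle, seeded), a
#' composition-preserving null.
#'
#' @param m a frequency `Motif` or `PSSM`.
#' @param targets,controls `LocationSet`s; `controls = NULL` enables the
#'   shuffled-sequence control.
#' @param genome bound `Genome`.
#' @param cutoffs strictly increasing score cutoffs (bits).
#' @param bg,pseudo_weight PSSM construction parameters (`bg = NULL`
#'   estimates from the genome).
#' @param shuffle_seed seed for the dinucleotide-shuffle control.
#' @return Data frame of class `EnrichmentResult`: one row per cutoff with
#'   counts, `ratio` (target fraction / control fraction) and Fisher `p`.
#' @export
motif_enrichment <- function(m, targets, controls = NULL, genome,
                             cutoffs, bg = NULL, pseudo_weight = 0.01,
                             shuffle_seed = 1) {
  stopifnot(inherits(targets, "LocationSet"), nrow(targets) > 0)
  if (is.unsorted(cutoffs, strictly = TRUE)) stop("cutoffs must be strictly increasing")
  pssm <- as_pssm(m, genome, bg, pseudo_weight)
  tseq <- location_seqs(targets, genome)
  cseq <- if (is.null(controls)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(shuffle_seed)
    vapply(tseq, dinuc_shuffle_one, character(1), USE.NAMES = FALSE)
  } else {
    stopifnot(inherits(controls, "LocationSet"), nrow(controls) > 0)
    location_seqs(controls, genome)
  }
  tmax <- best_scores(tseq, pssm)
  cmax <- best_scores(cseq, pssm)
  rows <- lapply(cutoffs, function(cut) {
    a <- sum(tmax >= cut, na.rm = TRUE); n1 <- length(tmax)
    b <- sum(cmax >= cut, na.rm = TRUE); n2 <- length(cmax)
    p <- stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2))$p.value
    data.frame(motif = pssm$name, cutoff = cut,
               n_target_with_match = a, n_target = n1,
               n_control_with_match = b, n_control = n2,
               ratio = if (b > 0) (a / n1) / (b / n2) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

## Best window LOD per sequence, both strands; -Inf when no N-free window.
best_scores <- function(seqs, pssm) {
  rcm <- rc_mat(pssm$mat)
  vapply(seqs, function(s) {
    code <- encode_seq(s)
    sc <- c(score_windows(code, pssm$mat), score_windows(code, rcm))
    if (all(is.na(sc)) || length(sc) == 0) -Inf else max(sc, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

## Altschul-Erikson dinucleotide shuffle of one sequence (exact
## dinucleotide counts preserved). N breaks the sequence into independently
## shuffled segments.
dinuc_shuffle_one <- function(s) {
  segs <- strsplit(s, "N+")[[1]]
  gaps <- regmatches(s, gregexpr("N+", s))[[1]]
  sh <- vapply(segs, function(seg) {
    if (nchar(seg) < 3) return(seg)
    code <- encode_seq(seg)
    L <- length(code)
    last <- code[L]
    edges <- lapply(1:4, function(b) code[which(code[-L] == b) + 1L])
    repeat {
      ## choose a random last edge per vertex (except the terminal vertex)
      le <- rep(NA_integer_, 4)
      for (b in 1:4) if (b != last && length(edges[[b]]) > 0)
        le[b] <- edges[[b]][sample.int(length(edges[[b]]), 1L)]
      ## the chosen last-edge graph must connect every used vertex to `last`
      ok <- TRUE
      for (b in 1:4) {
        if (b == last || length(edges[[b]]) == 0) next
        v <- b; steps <- 0L
        while (v != last && steps < 8L) { v <- le[v]; steps <- steps + 1L
          if (is.na(v)) break }
        if (is.na(v) || v != last) { ok <- FALSE; break }
      }
      if (ok) break
    }
    ## shuffle remaining edges, append the chosen last edge
    elist <- lapply(1:4, function(b) {
      e <- edges[[b]]
      if (!is.na(le[b])) {
        drop <- which(e == le[b])[1]
        e <- e[-drop]
      }
      if (length(e) > 1) e <- e[sample.int(length(e))]
      c(e, if (!is.na(le[b])) le[b])
    })
    ptr <- rep(1L, 4)
    out <- integer(L); out[1] <- code[1]
    for (i in 2:L) {
      v <- out[i - 1L]
      out[i] <- elist[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
    }
    decode_seq(out)
  }, character(1))
  ## reassemble with original N runs
  res <- character(0)
  for (i in seq_along(sh)) {
    res <- c(res, sh[i], if (i <= length(gaps)) gaps[i])
  }
  paste(res, collapse = "")
}

#' Library-wide motif enrichment
#'
#' Runs [motif_enrichment()] for every motif in a library and adds
#' Benjamini-Hochberg q-values across motifs at each cutoff.
#'
#' @inheritParams motif_enrichment
#' @param library list of `Motif`s.
#' @return Data frame (class `EnrichmentResult`) with an added `q` column.
#' @export
library_enrichment <- function(library, targets, controls = NULL, genome,
                               cutoffs, bg = NULL, pseudo_weight = 0.01,
                               shuffle_seed = 1) {
  if (length(library) == 0) stop("empty motif library")
  res <- do.call(rbind, lapply(library, function(m)
    motif_enrichment(m, targets, controls, genome, cutoffs, bg,
                     pseudo_weight, shuffle_seed)))
  res$q <- NA_real_
  for (cut in unique(res$cutoff)) {
    i <- res$cutoff == cut
    res$q[i] <- stats::p.adjust(res$p[i], method = "BH")
  }
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Test motif matches for non-uniform positional distribution
#'
#' Tests whether matches distribute non-randomly relative to anchor
#' locations (e.g. whether a motif sits under ChIP peak centers). Each
#' match is assigned to its nearest anchor on the same sequence (midpoint
#' distance; ties to the leftmost anchor). In `relative_in_region` mode the
#' match midpoint is scaled to `[0, 1]` across its anchor's span (matches
#' with midpoints outside the anchor are dropped); in `distance_to_point`
#' mode the signed bp distance from the anchor midpoint is used over
#' `support`. The primary test is a chi-square goodness-of-fit against
#' uniform over `n_bins` equal bins; a Kolmogorov-Smirnov test against the
#' uniform is reported as secondary.
#'
#' @param matches,anchors `LocationSet`s.
#' @param mode `"relative_in_region"` or `"distance_to_point"`.
#' @param n_bins bins for the chi-square test.
#' @param support numeric length-2 support for `distance_to_point`
#'   (defaults to symmetric around 0 at the largest observed distance).
#' @param min_n matches below this count are flagged underpowered.
#' @return List of class `DistributionResult`: `n`, `positions`,
#'   `statistic`, `p` (chi-square), `p_ks`, `method`, `underpowered`.
#' @export
positional_distribution <- function(matches, anchors,
                                    mode = c("relative_in_region",
                                             "distance_to_point"),
                                    n_bins = 10, support = NULL, min_n = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(matches, "LocationSet"), inherits(anchors, "LocationSet"))
  if (nrow(matches) < 2) stop("need at least 2 matches")
  if (nrow(anchors) < 1) stop("need at least 1 anchor")
  mids <- (matches$start + matches$end) / 2
  amids <- (anchors$start + anchors$end) / 2
  idx <- rep(NA_integer_, nrow(matches))
  for (sid in unique(matches$sequence_id)) {
    mrows <- which(matches$sequence_id == sid)
    arows <- which(anchors$sequence_id == sid)
    if (length(arows) == 0) next
    o <- arows[order(amids[arows])]
    am <- amids[o]
    j <- findInterval(mids[mrows], am)
    j1 <- pmax(j, 1L); j2 <- pmin(j + 1L, length(am))
    d1 <- abs(mids[mrows] - am[j1]); d2 <- abs(mids[mrows] - am[j2])
    idx[mrows] <- o[ifelse(d1 <= d2, j1, j2)]   # ties -> leftmost anchor
  }
  ok <- !is.na(idx)
  pos <- if (mode == "relative_in_region") {
    p <- (mids[ok] - anchors$start[idx[ok]]) /
      (anchors$end[idx[ok]] - anchors$start[idx[ok]])
    p[p >= 0 & p <= 1]
  } else {
    mids[ok] - amids[idx[ok]]
  }
  if (mode == "distance_to_point") {
    if (is.null(support)) support <- c(-1, 1) * max(abs(pos), 1)
    pos <- pos[pos >= support[1] & pos <= support[2]]
  } else support <- c(0, 1)
  n <- length(pos)
  if (n < 2) stop("fewer than 2 usable match positions")
  u <- (pos - support[1]) / (support[2] - support[1])
  cnt <- tabulate(pmin(pmax(ceiling(u * n_bins), 1L), n_bins), nbins = n_bins)
  expd <- n / n_bins
  stat <- sum((cnt - expd)^2 / expd)
  p_chi <- stats::pchisq(stat, df = n_bins - 1, lower.tail = FALSE)
  p_ks <- suppressWarnings(stats::ks.test(u, "punif")$p.value)
  structure(list(n = n, positions = pos, statistic = stat, p = p_chi,
                 p_ks = p_ks, method = "chi_square_bins", n_bins = n_bins,
                 mode = mode, support = support, underpowered = n < min_n),
            class = "DistributionResult")
}

#' @export
print.DistributionResult <- function(x, ...) {
  cat(sprintf("Positional distribution (%s): n = %d, chi2 = %.3f, p = %.3g (KS p = %.3g)%s\n",
              x$mode, x$n, x$statistic, x$p, x$p_ks,
              if (x$underpowered) " [underpowered]" else ""))
  invisible(x)
}

#' Test for non-random spacing between two sets of motif matches
#'
#' Computes the gap (distance between facing edges) of every A,B match
#' pair on the same sequence with gap in `[0, max_gap]`, bins the gaps into
#' windows of `window` bp, and compares each window's count to a
#' permutation null in which B's matches are re-placed uniformly at random
#' within their sequences (lengths preserved). Per-window empirical
#' p-values `(1 + #{null >= observed}) / (1 + n_permutations)` are BH
#' adjusted. Use this to detect, e.g., two motifs typically separated by a
#' 30-50 bp gap.
#'
#' When A and B are the same set, self-pairs (identical interval and
#' strand) are excluded.
#'
#' @param matchesA,matchesB `LocationSet`s of motif matches.
#' @param seq_lengths named vector of sequence lengths (or a `Genome`).
#' @param max_gap maximum gap considered (bp).
#' @param window histogram window width (bp), `1 <= window <= max_gap`.
#' @param n_permutations number of null permutations.
#' @param seed RNG seed.
#' @return List of class `SpacingResult`: `histogram` (per-bp gap counts),
#'   `windows` (data frame with `gap_lo`, `gap_hi`, `observed`,
#'   `expected`, `p`, `p_adj`), `n_pairs`.
#' @export
spacing_analysis <- function(matchesA, matchesB, seq_lengths, max_gap = 100,
                             window = 5, n_permutations = 1000, seed = 1) {
  stopifnot(max_gap >= window, window >= 1, n_permutations >= 1)
  if (inherits(seq_lengths, "Genome")) seq_lengths <- seq_lengths(seq_lengths)
  self <- identical(matchesA[c("sequence_id", "start", "end", "strand")],
                    matchesB[c("sequence_id", "start", "end", "strand")])
  gaps_of <- function(A, B) {
    out <- numeric(0)
    for (sid in intersect(unique(A$sequence_id), unique(B$sequence_id))) {
      a <- A[A$sequence_id == sid, , drop = FALSE]
      b <- B[B$sequence_id == sid, , drop = FALSE]
      gf <- outer(a$end, b$start, function(ae, bs) bs - ae)   # B after A
      gb <- outer(a$start, b$end, function(as_, be) as_ - be) # B before A
      g <- ifelse(gf >= 0, gf, ifelse(gb >= 0, gb, -1))       # overlap: -1
      if (self)
        g[outer(a$start, b$start, "==") & outer(a$end, b$end, "==") &
            outer(a$strand, b$strand, "==")] <- -1
      out <- c(out, g[g >= 0 & g <= max_gap])
    }
    out
  }
  obs <- gaps_of(matchesA, matchesB)
  brk <- seq(0, ceiling(max_gap / window) * window, by = window)
  bin_counts <- function(g) tabulate(findInterval(g, brk, rightmost.closed = FALSE),
                                     nbins = length(brk) - 1)
  if (length(obs) == 0) {
    return(structure(list(histogram = integer(0), windows = NULL, n_pairs = 0,
                          flagged = "no co-occurring pairs"),
                     class = "SpacingResult"))
  }
  obs_w <- bin_counts(obs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  widthsB <- matchesB$end - matchesB$start
  null_w <- matrix(0, n_permutations, length(obs_w))
  for (p in seq_len(n_permutations)) {
    B2 <- matchesB
    L <- seq_lengths[B2$sequence_id]
    ns <- floor(stats::runif(nrow(B2)) * (L - widthsB + 1))
    B2$start <- ns; B2$end <- ns + widthsB
    null_w[p, ] <- bin_counts(gaps_of(matchesA, B2))
  }
  pvals <- vapply(seq_along(obs_w), function(i)
    (1 + sum(null_w[, i] >= obs_w[i])) / (1 + n_permutations), numeric(1))
  windows <- data.frame(gap_lo = brk[-length(brk)], gap_hi = brk[-1],
                        observed = obs_w, expected = colMeans(null_w),
                        p = pvals, p_adj = stats::p.adjust(pvals, "BH"))
  hist <- tabulate(obs + 1L, nbins = max_gap + 1)
  names(hist) <- 0:max_gap
  structure(list(histogram = hist, windows = windows, n_pairs = length(obs),
                 flagged = NULL),
            class = "SpacingResult")
}

#' @export
print.SpacingResult <- function(x, ...) {
  if (!is.null(x$flagged)) { cat("Spacing analysis:", x$flagged, "\n"); return(invisible(x)) }
  cat("Spacing analysis:", x$n_pairs, "co-occurring pairs\n")
  print(utils::head(x$windows[order(x$windows$p_adj), ], 5))
  invisible(x)
}

#' Gene Ontology term enrichment
#'
#' GO-TermFinder-style enrichment: gene annotations are propagated to all
#' ancestor terms, then each term with at least one study gene is tested
#' with the hypergeometric upper tail
#' `p = P(X >= k)` for `k` study genes among `n` drawn from a universe of
#' `N` genes of which `K` carry the term. Correction is Bonferroni over
#' the number of tested terms.
#'
#' @param study_genes character vector of study gene ids (must be a subset
#'   of the universe).
#' @param annotations data frame `(gene, term)` of direct annotations.
#' @param ancestry data frame `(term, parent)`; must be acyclic. Terms
#'   absent from `ancestry` are roots.
#' @param universe_genes character vector of universe gene ids.
#' @return Data frame of class `GOResult`, one row per tested term, ordered
#'   by `p`: columns `term`, `k`, `n`, `K`, `N`, `p`, `p_corrected`.
#' @export
go_enrichment <- function(study_genes, annotations, ancestry, universe_genes) {
  study_genes <- unique(as.character(study_genes))
  universe_genes <- unique(as.character(universe_genes))
  if (!all(study_genes %in% universe_genes))
    stop("study genes absent from universe: ",
         paste(utils::head(setdiff(study_genes, universe_genes)), collapse = ", "))
  anc <- ancestors_table(ancestry)
  ## propagate: gene annotated to term => annotated to every ancestor
  gene2terms <- tapply(as.character(annotations$term),
                       as.character(annotations$gene), function(terms) {
    unique(unlist(c(terms, lapply(terms, function(t) anc[[t]]))))
  })
  gene2terms <- gene2terms[names(gene2terms) %in% universe_genes]
  term_genes <- list()
  for (g in names(gene2terms)) for (t in gene2terms[[g]])
    term_genes[[t]] <- c(term_genes[[t]], g)
  N <- length(universe_genes); n <- length(study_genes)
  rows <- list()
  for (t in names(term_genes)) {
    gs <- unique(term_genes[[t]])
    K <- length(gs)
    k <- length(intersect(gs, study_genes))
    if (k < 1) next
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(term = t, k = k, n = n, K = K,
                                            N = N, p = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(structure(data.frame(term = character(0), k = integer(0),
                                n = integer(0), K = integer(0), N = integer(0),
                                p = numeric(0), p_corrected = numeric(0)),
                     class = c("GOResult", "data.frame")))
  res <- do.call(rbind, rows)
  res$p_corrected <- pmin(res$p * nrow(res), 1)
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("GOResult", "data.frame")
  res
}

## term -> character vector of all ancestors; errors on cycles.
ancestors_table <- function(ancestry) {
  parents <- split(as.character(ancestry$parent), as.character(ancestry$term))
  memo <- new.env(parent = emptyenv())
  walk <- function(t, path) {
    if (t %in% path) stop("cyclic term ancestry at ", t)
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- parents[[t]]
    res <- character(0)
    for (p in ps) res <- c(res, p, walk(p, c(path, t)))
    memo[[t]] <- unique(res)
    memo[[t]]
  }
  out <- list()
  for (t in names(parents)) out[[t]] <- walk(t, character(0))
  out
}

#' Associate a motif with GO terms via upstream matches
#'
#' Builds the study set of genes whose strand-aware upstream window
#' (`upstream_bp` before the TSS, truncated at sequence edges and, by
#' default, at the nearest neighboring gene) contains at least one motif
#' match scoring >= `score_cutoff` on either strand, then runs
#' [go_enrichment()] with all genes as the universe.
#'
#' @param m a frequency `Motif` or `PSSM`.
#' @param genes a `GeneModelSet`.
#' @param genome bound `Genome`.
#' @param upstream_bp upstream window size (must be >= motif width).
#' @param score_cutoff LOD cutoff in bits.
#' @param annotations,ancestry as in [go_enrichment()].
#' @param truncate_at_neighbor clip the window at the closest neighboring
#'   gene boundary (default `TRUE`, appropriate for compact genomes).
#' @param bg,pseudo_weight PSSM construction parameters.
#' @return A `GOResult` data frame (empty when no gene qualifies), with the
#'   study set in attribute `study_genes`.
#' @export
motif_go_association <- function(m, genes, genome, upstream_bp, score_cutoff,
                                 annotations, ancestry,
                                 truncate_at_neighbor = TRUE,
                                 bg = NULL, pseudo_weight = 0.01) {
  pssm <- as_pssm(m, genome, bg, pseudo_weight)
  if (upstream_bp < ncol(pssm$mat)) stop("upstream_bp smaller than motif width")
  ups <- upstream_regions(genes, genome, upstream_bp, truncate_at_neighbor)
  sc <- rep(-Inf, nrow(genes))
  nonempty <- which(!is.na(ups$start) & ups$end - ups$start >= ncol(pssm$mat))
  if (length(nonempty) > 0) {
    seqs <- vapply(nonempty, function(i)
      get_seq(genome, ups$sequence_id[i], ups$start[i], ups$end[i]), character(1))
    sc[nonempty] <- best_scores(seqs, pssm)
  }
  study <- genes$gene_id[sc >= score_cutoff]
  if (length(study) == 0)
    return(structure(data.frame(term = character(0), k = integer(0),
                                n = integer(0), K = integer(0), N = integer(0),
                                p = numeric(0), p_corrected = numeric(0)),
                     class = c("GOResult", "data.frame"),
                     study_genes = character(0)))
  res <- go_enrichment(study, annotations, ancestry, genes$gene_id)
  attr(res, "study_genes") <- study
  res
}

## Strand-aware upstream windows, truncated at sequence edges and
## (optionally) at the nearest neighboring gene boundary.
upstream_regions <- function(genes, genome, upstream_bp,
                             truncate_at_neighbor = TRUE) {
  sl <- seq_lengths(genome)
  out <- data.frame(sequence_id = genes$sequence_id,
                    start = NA_real_, end = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    sid <- genes$sequence_id[i]
    if (genes$strand[i] == "+") {
      e <- genes$start[i]
      s <- max(0, e - upstream_bp)
      if (truncate_at_neighbor) {
        nb <- genes$end[genes$sequence_id == sid & genes$end <= e &
                          genes$gene_id != genes$gene_id[i]]
        if (length(nb) > 0) s <- max(s, max(nb))
      }
    } else {
      s <- genes$end[i]
      e <- min(sl[[sid]], s + upstream_bp)
      if (truncate_at_neighbor) {
        nb <- genes$start[genes$sequence_id == sid & genes$start >= s &
                            genes$gene_id != genes$gene_id[i]]
        if (length(nb) > 0) e <- min(e, min(nb))
      }
    }
    if (s < e) { out$start[i] <- s; out$end[i] <- e }
  }
  out
}

#' Best upstream motif score per gene and motif
#'
#' For each gene and each library motif, the maximum window LOD (both
#' strands) within the gene's upstream region; `-Inf` when the region has
#' no N-free window.
#'
#' @param library list of `Motif`s (or `PSSM`s).
#' @param genes a `GeneModelSet`.
#' @param genome bound `Genome`.
#' @param upstream_bp upstream window size.
#' @param truncate_at_neighbor clip at neighboring genes.
#' @param bg,pseudo_weight PSSM construction parameters.
#' @return Numeric matrix, genes x motifs.
#' @export
best_upstream_scores <- function(library, genes, genome, upstream_bp,
                                 truncate_at_neighbor = TRUE,
                                 bg = NULL, pseudo_weight = 0.01) {
  ups <- upstream_regions(genes, genome, upstream_bp, truncate_at_neighbor)
  seqs <- rep(NA_character_, nrow(genes))
  ok <- which(!is.na(ups$start))
  seqs[ok] <- vapply(ok, function(i)
    get_seq(genome, ups$sequence_id[i], ups$start[i], ups$end[i]), character(1))
  out <- matrix(-Inf, nrow(genes), length(library),
                dimnames = list(genes$gene_id,
                                vapply(library, function(m)
                                  if (inherits(m, "PSSM")) m$name else m$name,
                                  character(1))))
  for (j in seq_along(library)) {
    pssm <- as_pssm(library[[j]], genome, bg, pseudo_weight)
    usable <- which(!is.na(seqs) & nchar(seqs) >= ncol(pssm$mat))
    if (length(usable) > 0)
      out[usable, j] <- best_scores(seqs[usable], pssm)
  }
  out
}
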