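#' Generate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`; fully determined by the seed.
#'
#' @param length sequence length (>= 100) for each sequence.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed RNG seed (mandatory: fixtures are pure functions of their
#'   parameters and seed).
#' @param n_sequences number of sequences (`s1`, `s2`, ...).
#' @param name genome name.
#' @return A `Genome`.
#' @export
make_genome <- function(length, gc = 0.5, seed, n_sequences = 1,
                        name = "synthetic") {
  stopifnot(length >= 100, gc >= 0, gc <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(seq_len(n_sequences), function(i)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = ""),
    character(1))
  genome(stats::setNames(seqs, paste0("s", seq_len(n_sequences))), name = name)
}

## Sample one site sequence from a motif's frequency columns.
sample_site <- function(m) {
  paste(vapply(seq_len(motif_width(m)), function(j)
    sample(BASES, 1, prob = m$mat[, j]), character(1)), collapse = "")
}

## Choose n non-overlapping starts of width w in [0, L - w], uniformly.
place_nonoverlapping <- function(L, w, n, max_tries = 10000L) {
  starts <- numeric(0)
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("cannot place ", n, " non-overlapping sites")
    cand <- floor(stats::runif(1) * (L - w + 1))
    if (all(abs(cand - starts) >= w)) starts <- c(starts, cand)
  }
  sort(starts)
}

#' Plant motif sites into a genome
#'
#' Splices `n_sites` site sequences (sampled from the motif's frequency
#' columns, or the consensus word with `mode = "consensus"`) into
#' non-overlapping uniform-random positions, and returns the modified
#' genome together with the truth set of planted locations.
#'
#' @param g a `Genome`.
#' @param m a frequency `Motif`.
#' @param n_sites number of sites to plant: genome-wide (spread across
#'   sequences in proportion to their lengths) or, with
#'   `scatter = "per_sequence"`, exactly `n_sites` in every sequence (the
#'   one-site-per-sequence regime motif-discovery fixtures use).
#' @param seed RNG seed.
#' @param mode `"sampled"` or `"consensus"`.
#' @param scatter `"genome_wide"` or `"per_sequence"`.
#' @return List with elements `genome` and `sites` (a `LocationSet`; the
#'   `label` column holds each planted word).
#' @export
plant_sites <- function(g, m, n_sites, seed, mode = c("sampled", "consensus"),
                        scatter = c("genome_wide", "per_sequence")) {
  mode <- match.arg(mode)
  scatter <- match.arg(scatter)
  stopifnot(inherits(g, "Genome"), inherits(m, "Motif"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- motif_width(m)
  if (n_sites == 0)
    return(list(genome = g, sites = location_set(name = "planted")))
  sl <- seq_lengths(g)
  sid <- if (scatter == "per_sequence") rep(names(sl), each = n_sites)
  else sample(names(sl), n_sites, replace = TRUE, prob = sl)
  seqs <- unclass(g)
  rows <- list()
  for (id in unique(sid)) {
    k <- sum(sid == id)
    starts <- place_nonoverlapping(sl[[id]], W, k)
    for (st in starts) {
      word <- if (mode == "consensus") motif_consensus(m) else sample_site(m)
      substr(seqs[[id]], st + 1, st + W) <- word
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = id, start = st, end = st + W, strand = "+",
        value = NA_real_, label = word, flag = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  g2 <- genome(seqs, name = attr(g, "name"))
  list(genome = g2,
       sites = as_location_set(do.call(rbind, rows), name = "planted"))
}

#' Plant pairs of motif sites at a fixed gap
#'
#' Plants `n_pairs` A-site/B-site pairs with exactly `gap` bp between the
#' facing edges (B downstream of A), at non-overlapping uniform-random
#' positions. Used to exercise spacing statistics.
#'
#' @param g a `Genome`.
#' @param mA,mB frequency `Motif`s.
#' @param n_pairs number of pairs.
#' @param gap gap in bp between A's end and B's start.
#' @param seed RNG seed.
#' @param mode `"sampled"` or `"consensus"`.
#' @return List with `genome`, `sitesA`, `sitesB`.
#' @export
plant_site_pairs <- function(g, mA, mB, n_pairs, gap, seed,
                             mode = c("sampled", "consensus")) {
  mode <- match.arg(mode)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  wA <- motif_width(mA); wB <- motif_width(mB)
  unit <- wA + gap + wB
  sl <- seq_lengths(g)
  sid <- sample(names(sl), n_pairs, replace = TRUE, prob = sl)
  seqs <- unclass(g)
  rowsA <- list(); rowsB <- list()
  for (id in unique(sid)) {
    k <- sum(sid == id)
    starts <- place_nonoverlapping(sl[[id]], unit, k)
    for (st in starts) {
      wa <- if (mode == "consensus") motif_consensus(mA) else sample_site(mA)
      wb <- if (mode == "consensus") motif_consensus(mB) else sample_site(mB)
      substr(seqs[[id]], st + 1, st + wA) <- wa
      bstart <- st + wA + gap
      substr(seqs[[id]], bstart + 1, bstart + wB) <- wb
      rowsA[[length(rowsA) + 1L]] <- data.frame(
        sequence_id = id, start = st, end = st + wA, strand = "+",
        value = NA_real_, label = wa, flag = NA_character_)
      rowsB[[length(rowsB) + 1L]] <- data.frame(
        sequence_id = id, start = bstart, end = bstart + wB, strand = "+",
        value = NA_real_, label = wb, flag = NA_character_)
    }
  }
  list(genome = genome(seqs, name = attr(g, "name")),
       sitesA = as_location_set(do.call(rbind, rowsA), name = "plantedA"),
       sitesB = as_location_set(do.call(rbind, rowsB), name = "plantedB"))
}

#' Simulate a ChIP-style enrichment track
#'
#' Baseline 0 plus a triangular bump of the given height and width centered
#' on each truth site, plus i.i.d. Gaussian noise; one value per base.
#'
#' @param g a `Genome` (defines sequence lengths).
#' @param sites a `LocationSet` of truth sites (bump centers at site
#'   midpoints).
#' @param peak_width bump base width in bp.
#' @param height bump peak height.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return A `DataTrack` with one run per base.
#' @export
make_chip_track <- function(g, sites, peak_width, height, noise_sd, seed) {
  stopifnot(peak_width >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sl <- seq_lengths(g)
  rows <- list()
  for (id in names(sl)) {
    v <- rep(0, sl[[id]])
    ss <- sites[sites$sequence_id == id, , drop = FALSE]
    half <- peak_width / 2
    for (i in seq_len(nrow(ss))) {
      ctr <- floor((ss$start[i] + ss$end[i]) / 2)
      pos <- max(0, ctr - ceiling(half)):min(sl[[id]] - 1, ctr + ceiling(half))
      bump <- height * pmax(0, 1 - abs(pos - ctr) / half)
      v[pos + 1] <- v[pos + 1] + bump
    }
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    rows[[id]] <- data.frame(sequence_id = id, start = 0:(sl[[id]] - 1),
                             end = 1:sl[[id]], value = v,
                             stringsAsFactors = FALSE)
  }
  data_track(do.call(rbind, rows))
}

#' Simulate multiple-genome alignment blocks
#'
#' For each region, emits an alignment block whose non-reference rows are
#' the reference sequence with i.i.d. substitutions at `sub_rate`, except
#' within `conserve_sites` (substitution rate 0 there) when given. No
#' indels are simulated, which keeps conservation-filter expectations
#' analytic; gapped parsing is exercised with hand-written blocks.
#'
#' @param g reference `Genome`.
#' @param regions `LocationSet` of reference intervals to align.
#' @param n_species number of non-reference rows.
#' @param sub_rate per-base substitution probability in `[0, 0.75]`.
#' @param conserve_sites optional `LocationSet` of truth sites kept
#'   substitution-free in all rows.
#' @param seed RNG seed.
#' @return List of `AlignmentBlock`.
#' @export
make_alignment <- function(g, regions, n_species, sub_rate,
                           conserve_sites = NULL, seed) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.75)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  refname <- attr(g, "name") %||% "ref"
  blocks <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    sid <- regions$sequence_id[i]
    ref <- get_seq(g, sid, regions$start[i], regions$end[i])
    code <- encode_seq(ref)
    protected <- rep(FALSE, length(code))
    if (!is.null(conserve_sites)) {
      cs <- conserve_sites[conserve_sites$sequence_id == sid, , drop = FALSE]
      for (j in seq_len(nrow(cs))) {
        lo <- max(cs$start[j], regions$start[i]); hi <- min(cs$end[j], regions$end[i])
        if (lo < hi) protected[(lo - regions$start[i] + 1):(hi - regions$start[i])] <- TRUE
      }
    }
    rows <- stats::setNames(ref, refname)
    for (sp in seq_len(n_species)) {
      mut <- code
      hit <- stats::runif(length(code)) < sub_rate & !protected & code <= 4L
      if (any(hit)) {
        ## substitute with a uniformly chosen *different* base
        shift <- sample.int(3, sum(hit), replace = TRUE)
        mut[hit] <- ((code[hit] - 1L + shift) %% 4L) + 1L
      }
      rows[paste0("species", sp)] <- decode_seq(mut)
    }
    blocks[[i]] <- alignment_block(sid, regions$start[i], regions$end[i], rows)
  }
  blocks
}

#' Generate gene models and a toy GO annotation
#'
#' Places `n_genes` non-overlapping genes on alternating strands with at
#' least `gap` bp between them, builds `n_terms` GO-like terms under a
#' common root (a shallow 2-level DAG), and annotates a designated subset
#' of genes (size `enriched_term_size`) to the first term; remaining genes
#' are annotated to the other terms round-robin.
#'
#' @param g a `Genome`.
#' @param n_genes number of genes.
#' @param n_terms number of leaf terms.
#' @param enriched_term_size genes annotated to the designated term `T1`.
#' @param seed RNG seed.
#' @param gene_width gene body width in bp.
#' @param gap minimum intergenic gap in bp.
#' @return List with `genes` (`GeneModelSet`), `annotations` (gene, term),
#'   `ancestry` (term, parent), `enriched_term`, `enriched_genes`.
#' @export
make_genes_and_go <- function(g, n_genes, n_terms, enriched_term_size, seed,
                              gene_width = 500, gap = 200) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sl <- seq_lengths(g)
  sid <- names(sl)[1]
  need <- n_genes * (gene_width + gap)
  if (need > sl[[sid]]) stop("genome too short for ", n_genes, " genes")
  starts <- gap + (seq_len(n_genes) - 1) * (gene_width + gap)
  genes <- gene_models(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    sequence_id = sid, start = starts, end = starts + gene_width,
    strand = rep(c("+", "-"), length.out = n_genes))
  terms <- sprintf("T%d", seq_len(n_terms))
  enriched <- sample(genes$gene_id, enriched_term_size)
  ann <- data.frame(gene = enriched, term = terms[1], stringsAsFactors = FALSE)
  rest <- setdiff(genes$gene_id, enriched)
  if (length(rest) > 0 && n_terms > 1)
    ann <- rbind(ann, data.frame(
      gene = rest, term = terms[1 + (seq_along(rest) - 1) %% (n_terms - 1) + 1],
      stringsAsFactors = FALSE))
  ancestry <- data.frame(term = terms, parent = "ROOT", stringsAsFactors = FALSE)
  list(genes = genes, annotations = ann, ancestry = ancestry,
       enriched_term = terms[1], enriched_genes = sort(enriched))
}
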