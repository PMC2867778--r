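#' Set algebra on location sets
#'
#' Union, intersection and subtraction of two location sets with per-base
#' semantics: the result is the set of bases in `A op B`, re-assembled into
#' maximal intervals and sorted. Record-level annotation (value, label,
#' flag) is not propagated; strand is ignored unless `stranded = TRUE`,
#' in which case the operation is applied within each strand separately.
#'
#' Typical ChIP uses: merge binding-region calls from replicates (union),
#' restrict binding regions to promoters (intersection), or remove regions
#' also enriched in a control experiment (subtraction).
#'
#' @param op one of `"union"`, `"intersection"`, `"subtraction"`.
#' @param A,B `LocationSet`s on the same genome.
#' @param stranded apply the operation per strand.
#' @return A `LocationSet` of maximal merged intervals.
#' @examples
#' a <- location_set("chr1", 10, 20)
#' b <- location_set("chr1", 15, 30)
#' set_operation("union", a, b)  # single [10,30)
#' @export
set_operation <- function(op = c("union", "intersection", "subtraction"), A, B,
                          stranded = FALSE) {
  op <- match.arg(op)
  stopifnot(inherits(A, "LocationSet"), inherits(B, "LocationSet"))
  ga <- ls_to_granges(A, ignore_strand = !stranded)
  gb <- ls_to_granges(B, ignore_strand = !stranded)
  gr <- switch(op,
    union = GenomicRanges::union(ga, gb, ignore.strand = !stranded),
    intersection = GenomicRanges::intersect(ga, gb, ignore.strand = !stranded),
    subtraction = GenomicRanges::setdiff(ga, gb, ignore.strand = !stranded)
  )
  granges_to_ls(gr, name = paste0(op, "(", ls_name(A), ",", ls_name(B), ")"))
}

#' Gene models
#'
#' Builds a gene-model table from per-gene stranded locations. The TSS is
#' the strand-aware 5' end: `start` for `+` genes, `end - 1` for `-` genes.
#'
#' @param gene_id character vector of gene ids.
#' @param sequence_id,start,end,strand gene body intervals (0-based
#'   half-open); strand must be `+` or `-`.
#' @return A data frame of class `GeneModelSet` with a computed `tss`
#'   column.
#' @export
gene_models <- function(gene_id, sequence_id, start, end, strand) {
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (anyDuplicated(gene_id)) stop("duplicate gene ids")
  df <- data.frame(gene_id = as.character(gene_id),
                   sequence_id = as.character(sequence_id),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("empty gene interval")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  structure(df, class = c("GeneModelSet", "data.frame"))
}

#' Assign binding regions to genes
#'
#' A gene is assigned to a region if the region overlaps the gene body
#' (relation `overlapping`, distance 0), or lies on the gene's upstream side
#' within `max_upstream` bp of its TSS (relation `upstream`), or past the
#' gene's 3' end within `max_downstream` bp (relation `downstream`).
#' Distances are measured from the region's nearest edge and are >= 1 for
#' non-overlapping assignments (an adjacent region has distance 1). With
#' `allow_multiple = FALSE` only the nearest gene(s) are kept; equal-distance
#' ties keep all tied genes.
#'
#' @param regions a `LocationSet`.
#' @param genes a `GeneModelSet`.
#' @param max_upstream,max_downstream maximum assignment distances in bp
#'   (>= 0; 0 disables that side).
#' @param allow_multiple keep all qualifying genes rather than nearest only.
#' @return A data frame with columns `region` (row index into the sorted
#'   `regions`), `sequence_id`, `start`, `end`, `gene_id`, `distance`,
#'   `relation`.
#' @export
assign_to_genes <- function(regions, genes, max_upstream = 1000,
                            max_downstream = 0, allow_multiple = TRUE) {
  stopifnot(inherits(regions, "LocationSet"), inherits(genes, "GeneModelSet"),
            max_upstream >= 0, max_downstream >= 0)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rs <- regions$start[i]; re <- regions$end[i]; rc <- regions$sequence_id[i]
    g <- genes[genes$sequence_id == rc, , drop = FALSE]
    if (nrow(g) == 0) next
    overlap <- g$start < re & rs < g$end
    # upstream side of the TSS, strand-aware; distance from nearest region edge
    d_up <- ifelse(g$strand == "+", g$tss - re + 1, rs - g$tss)
    up <- !overlap & d_up >= 1 & d_up <= max_upstream
    # past the 3' end of the gene body
    d_dn <- ifelse(g$strand == "+", rs - g$end + 1, g$start - re + 1)
    dn <- !overlap & !up & d_dn >= 1 & d_dn <= max_downstream
    hit <- overlap | up | dn
    if (!any(hit)) next
    dist <- ifelse(overlap, 0, ifelse(up, d_up, d_dn))[hit]
    rel <- ifelse(overlap, "overlapping", ifelse(up, "upstream", "downstream"))[hit]
    gid <- g$gene_id[hit]
    if (!allow_multiple) {
      keep <- dist == min(dist)
      dist <- dist[keep]; rel <- rel[keep]; gid <- gid[keep]
    }
    out[[length(out) + 1L]] <- data.frame(
      region = i, sequence_id = rc, start = rs, end = re,
      gene_id = gid, distance = dist, relation = rel,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(region = integer(0), sequence_id = character(0),
                      start = numeric(0), end = numeric(0),
                      gene_id = character(0), distance = numeric(0),
                      relation = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract peaks from a numeric track
#'
#' Finds maximal runs of bases with value >= `threshold`; runs separated by
#' at most `merge_gap` uncalled bases are merged; merged runs shorter than
#' `min_width` are dropped. Each peak's `value` is the maximum over the run
#' and its `label` records the summit, the leftmost base attaining that
#' maximum.
#'
#' This is a deliberately limited extraction/refinement utility, not a
#' peak caller with a background model.
#'
#' @param track a `DataTrack`.
#' @param threshold minimum per-base value.
#' @param min_width minimum peak width in bp (>= 1).
#' @param merge_gap maximum gap to bridge between runs (>= 0).
#' @return A `LocationSet`; `label` holds the summit position.
#' @export
extract_peaks <- function(track, threshold, min_width = 1, merge_gap = 0) {
  stopifnot(inherits(track, "DataTrack"), min_width >= 1, merge_gap >= 0)
  res <- list()
  for (sid in unique(track$sequence_id)) {
    t <- track[track$sequence_id == sid, , drop = FALSE]
    lo <- min(t$start); hi <- max(t$end)
    v <- rep(-Inf, hi - lo)
    for (r in seq_len(nrow(t)))
      v[(t$start[r] - lo + 1):(t$end[r] - lo)] <- t$value[r]
    above <- v >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- cbind(starts[r$values], ends[r$values])  # 1-based inclusive in v
    # merge runs separated by <= merge_gap
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
      if (runs[k, 1] - merged[nrow(merged), 2] - 1 <= merge_gap)
        merged[nrow(merged), 2] <- runs[k, 2]
      else merged <- rbind(merged, runs[k, ])
    }
    w <- merged[, 2] - merged[, 1] + 1
    merged <- merged[w >= min_width, , drop = FALSE]
    if (nrow(merged) == 0) next
    pk_val <- numeric(nrow(merged)); summit <- numeric(nrow(merged))
    for (k in seq_len(nrow(merged))) {
      vv <- v[merged[k, 1]:merged[k, 2]]
      pk_val[k] <- max(vv)
      summit[k] <- lo + merged[k, 1] - 1 + which.max(vv) - 1
    }
    res[[length(res) + 1L]] <- data.frame(
      sequence_id = sid, start = lo + merged[, 1] - 1, end = lo + merged[, 2],
      strand = "*", value = pk_val, label = as.character(summit),
      flag = NA_character_, stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(location_set(name = "peaks"))
  as_location_set(do.call(rbind, res), name = "peaks")
}
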