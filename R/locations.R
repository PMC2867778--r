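#' Location sets: strand-aware genomic intervals
#'
#' A `LocationSet` is a data frame of 0-based half-open intervals with the
#' columns `sequence_id`, `start`, `end`, `strand` (`+`, `-` or `*` for
#' unstranded) and the optional per-location columns `value` (numeric),
#' `label` (character) and `flag` (tri-state curation marker: `"true"`,
#' `"false"` or `"undecided"`). Rows are kept sorted by
#' `(sequence_id, start, end)`.
#'
#' @param sequence_id,start,end,strand interval columns (recycled as usual).
#' @param value,label,flag optional per-location annotation columns.
#' @param name name of the set.
#' @param genome optional `Genome`; when supplied, every interval is checked
#'   against the sequence lengths.
#' @return An object of class `LocationSet` (also a `data.frame`).
#' @examples
#' ls1 <- location_set("chr1", c(0, 15), c(10, 30), name = "peaks")
#' @export
location_set <- function(sequence_id = character(0), start = integer(0),
                         end = integer(0), strand = "*",
                         value = NA_real_, label = NA_character_,
                         flag = NA_character_, name = "locations",
                         genome = NULL) {
  n <- max(length(sequence_id), length(start), length(end))
  if (length(sequence_id) == 0) n <- 0L
  df <- data.frame(
    sequence_id = rep_len(as.character(sequence_id), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    value = rep_len(as.numeric(value), n),
    label = rep_len(as.character(label), n),
    flag = rep_len(as.character(flag), n),
    stringsAsFactors = FALSE
  )
  as_location_set(df, name = name, genome = genome)
}

#' Coerce a data frame to a LocationSet
#' @param df data frame with at least `sequence_id`, `start`, `end`.
#' @inheritParams location_set
#' @return A `LocationSet`.
#' @export
as_location_set <- function(df, name = "locations", genome = NULL) {
  need <- c("sequence_id", "start", "end")
  if (!all(need %in% names(df))) stop("need columns: ", paste(need, collapse = ", "))
  for (col in c("strand", "value", "label", "flag"))
    if (is.null(df[[col]]))
      df[[col]] <- switch(col, strand = "*", value = NA_real_,
                          label = NA_character_, flag = NA_character_)
  df <- df[c("sequence_id", "start", "end", "strand", "value", "label", "flag")]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(df$start != floor(df$start) | df$end != floor(df$end)))
    stop("non-integer coordinates")
  if (any(df$start < 0)) stop("negative start coordinate")
  if (any(df$start >= df$end)) stop("empty or inverted interval (start >= end)")
  if (!all(df$strand %in% c("+", "-", "*"))) stop("strand must be +, - or *")
  okflag <- is.na(df$flag) | df$flag %in% c("true", "false", "undecided")
  if (!all(okflag)) stop("flag must be true/false/undecided or NA")
  if (!is.null(genome)) {
    sl <- seq_lengths(genome)
    if (!all(df$sequence_id %in% names(sl)))
      stop("sequence ids absent from genome: ",
           paste(setdiff(df$sequence_id, names(sl)), collapse = ", "))
    if (any(df$end > sl[df$sequence_id])) stop("interval extends past sequence end")
  }
  o <- order(df$sequence_id, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, name = name, class = c("LocationSet", "data.frame"))
}

#' @export
print.LocationSet <- function(x, ...) {
  cat("LocationSet:", attr(x, "name"), "|", nrow(x), "location(s)\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

ls_name <- function(x) attr(x, "name") %||% "locations"

`%||%` <- function(a, b) if (is.null(a)) b else a

## LocationSet <-> GRanges (internal). GRanges is 1-based closed, so
## start+1 on the way in and start-1 on the way out.
ls_to_granges <- function(x, ignore_strand = TRUE) {
  GenomicRanges::GRanges(
    seqnames = x$sequence_id,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (ignore_strand) rep("*", nrow(x)) else x$strand
  )
}

granges_to_ls <- function(gr, name = "locations") {
  location_set(
    sequence_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = name
  )
}

#' Filter a location set by its tri-state curation flag
#'
#' Curation flags mark locations as `"true"`, `"false"` or `"undecided"`
#' (e.g. hand-reviewed ChIP binding regions); this keeps the subset whose
#' flag is in `keep`, preserving order.
#'
#' @param x a `LocationSet`.
#' @param keep character vector of flag states to keep; `NA` entries in the
#'   set are treated as `"undecided"`.
#' @return A `LocationSet`.
#' @export
filter_by_flag <- function(x, keep) {
  stopifnot(inherits(x, "LocationSet"))
  keep <- match.arg(keep, c("true", "false", "undecided"), several.ok = TRUE)
  fl <- ifelse(is.na(x$flag), "undecided", x$flag)
  out <- x[fl %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, name = ls_name(x), class = class(x))
}

#' Extract the DNA sequence of each location
#'
#' Minus-strand locations are reverse complemented.
#' @param x a `LocationSet`.
#' @param genome a `Genome`.
#' @return Character vector of sequences, one per location.
#' @export
location_seqs <- function(x, genome) {
  stopifnot(inherits(x, "LocationSet"), inherits(genome, "Genome"))
  if (nrow(x) == 0) return(character(0))
  out <- vapply(seq_len(nrow(x)), function(i)
    get_seq(genome, x$sequence_id[i], x$start[i], x$end[i]), character(1))
  neg <- x$strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  out
}
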