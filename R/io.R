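#' Per-base numeric data tracks
#'
#' A `DataTrack` stores per-base numeric values (e.g. ChIP enrichment) as a
#' data frame of non-overlapping 0-based half-open runs with columns
#' `sequence_id`, `start`, `end`, `value`: every base in `[start, end)`
#' carries `value`. Bases not covered by any run have no value.
#'
#' @param df data frame with columns `sequence_id`, `start`, `end`, `value`.
#' @return An object of class `DataTrack` (also a `data.frame`).
#' @export
data_track <- function(df = data.frame(sequence_id = character(0),
                                       start = numeric(0), end = numeric(0),
                                       value = numeric(0))) {
  need <- c("sequence_id", "start", "end", "value")
  if (!all(need %in% names(df))) stop("need columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (any(!is.finite(df$value))) stop("track values must be finite")
  if (any(df$start >= df$end)) stop("empty run (start >= end)")
  o <- order(df$sequence_id, df$start)
  df <- df[o, , drop = FALSE]
  ovl <- df$sequence_id[-1] == df$sequence_id[-nrow(df)] &
    df$start[-1] < df$end[-nrow(df)]
  if (nrow(df) > 1 && any(ovl)) stop("overlapping runs within track")
  rownames(df) <- NULL
  structure(df, class = c("DataTrack", "data.frame"))
}

#' @export
print.DataTrack <- function(x, ...) {
  cat("DataTrack |", nrow(x), "run(s),", sum(x$end - x$start), "bases covered\n")
  print(utils::head(as.data.frame(x), 8))
  invisible(x)
}

#' Look up per-base track values
#' @param track a `DataTrack`.
#' @param sequence_id sequence name.
#' @param pos 0-based base positions.
#' @return Numeric vector of values (`NA` where uncovered).
#' @export
value_at <- function(track, sequence_id, pos) {
  t <- track[track$sequence_id == sequence_id, , drop = FALSE]
  out <- rep(NA_real_, length(pos))
  if (nrow(t) == 0) return(out)
  i <- findInterval(pos, t$start)
  hit <- i >= 1 & pos < t$end[pmax(i, 1L)]
  out[hit] <- t$value[i[hit]]
  out
}

# ---- FASTA ----------------------------------------------------------------

#' Read a genome from FASTA
#'
#' Sequences are uppercased; `U` is converted to `T`; other non-ACGTN
#' characters are mapped to `N` with a warning (or rejected with
#' `strict = TRUE`).
#'
#' @param path FASTA file.
#' @param name genome name (defaults to the file name).
#' @param strict reject non-ACGTN characters instead of mapping to N.
#' @return A `Genome`.
#' @export
read_fasta <- function(path, name = basename(path), strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) stop("not a FASTA file (must begin with '>')")
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate FASTA header ids")
  genome(stats::setNames(as.character(ss), ids), name = name, strict = strict)
}

#' Write a genome to FASTA
#' @param g a `Genome`.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "Genome"))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(g)) {
    writeLines(paste0(">", names(g)[i]), con)
    s <- unclass(g)[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- BED ------------------------------------------------------------------

#' Read a BED file as a LocationSet
#'
#' BED is already 0-based half-open, so coordinates are kept verbatim.
#' Column 4 maps to `label`, 5 to `value`, 6 to `strand`.
#'
#' @param path BED file (3-6 tab-separated columns; `track`/`browser`/`#`
#'   lines are skipped).
#' @param name set name.
#' @param genome optional bound `Genome` for validation.
#' @return A `LocationSet`.
#' @export
read_bed <- function(path, name = basename(path), genome = NULL) {
  lines <- read_data_lines(path)
  if (length(lines) == 0)
    return(location_set(name = name))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 3)) stop("BED line with fewer than 3 columns")
  get <- function(i) vapply(f, function(x) if (length(x) >= i) x[[i]] else NA_character_,
                            character(1))
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates")
  if (any(start != floor(start))) stop("non-integer BED coordinates")
  strand <- get(6); strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "*"
  value <- suppressWarnings(as.numeric(get(5)))
  label <- get(4); label[label == "."] <- NA_character_
  location_set(get(1), start, end, strand = strand, value = value,
               label = label, name = name, genome = genome)
}

#' Write a LocationSet as BED
#'
#' Always writes 6 columns (`.`/`0` placeholders for missing label/value).
#' @param x a `LocationSet`.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "LocationSet"))
  lab <- ifelse(is.na(x$label), ".", x$label)
  val <- ifelse(is.na(x$value), "0", format(x$value, digits = 17, trim = TRUE,
                                            scientific = FALSE))
  strand <- ifelse(x$strand == "*", ".", x$strand)
  lines <- paste(x$sequence_id, format_coord(x$start), format_coord(x$end),
                 lab, val, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, trim = TRUE, scientific = FALSE)

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  drop <- startsWith(lines, "#") | startsWith(lines, "track") |
    startsWith(lines, "browser")
  lines[!drop]
}

# ---- GFF ------------------------------------------------------------------

#' Read a GFF file as a LocationSet
#'
#' GFF coordinates are 1-based inclusive; internally they become 0-based
#' half-open (`start - 1`, `end`). Column 3 (feature type) maps to `label`,
#' column 6 (score) to `value`; the attributes column is kept opaque.
#'
#' @inheritParams read_bed
#' @return A `LocationSet`.
#' @export
read_gff <- function(path, name = basename(path), genome = NULL) {
  lines <- read_data_lines(path)
  if (length(lines) == 0) return(location_set(name = name))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) stop("GFF line without 9 columns")
  m <- do.call(rbind, f)
  start1 <- suppressWarnings(as.numeric(m[, 4]))
  end1 <- suppressWarnings(as.numeric(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) stop("non-numeric GFF coordinates")
  if (any(start1 > end1)) stop("GFF start > end")
  strand <- m[, 7]; strand[!(strand %in% c("+", "-"))] <- "*"
  value <- suppressWarnings(as.numeric(m[, 6]))
  label <- m[, 3]; label[label == "."] <- NA_character_
  location_set(m[, 1], start1 - 1, end1, strand = strand, value = value,
               label = label, name = name, genome = genome)
}

#' Write a LocationSet as GFF
#' @param x a `LocationSet`.
#' @param path output file.
#' @param source value for GFF column 2.
#' @export
write_gff <- function(x, path, source = "regmotif") {
  stopifnot(inherits(x, "LocationSet"))
  lab <- ifelse(is.na(x$label), ".", x$label)
  val <- ifelse(is.na(x$value), ".", format(x$value, digits = 17, trim = TRUE,
                                            scientific = FALSE))
  strand <- ifelse(x$strand == "*", ".", x$strand)
  lines <- paste(x$sequence_id, source, lab, format_coord(x$start + 1),
                 format_coord(x$end), val, strand, ".", ".", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---- WIG ------------------------------------------------------------------

#' Read a WIG file as a DataTrack
#'
#' Supports `fixedStep` and `variableStep` declarations with `step`/`span`
#' semantics. WIG positions are 1-based; internal runs are 0-based
#' half-open.
#'
#' @param path WIG file.
#' @return A `DataTrack`.
#' @export
read_wig <- function(path) {
  lines <- read_data_lines(path)
  mode <- NULL; chrom <- NULL; step <- 1; span <- 1; nextstart <- NA
  rows <- vector("list", length(lines)); k <- 0L
  for (ln in lines) {
    if (startsWith(ln, "fixedStep") || startsWith(ln, "variableStep")) {
      kv <- parse_decl(ln)
      mode <- if (startsWith(ln, "fixed")) "fixed" else "variable"
      chrom <- kv[["chrom"]]
      if (is.null(chrom)) stop("WIG declaration without chrom")
      span <- as.numeric(kv[["span"]] %||% "1")
      if (mode == "fixed") {
        if (is.null(kv[["start"]])) stop("fixedStep declaration without start")
        nextstart <- as.numeric(kv[["start"]]) - 1  # to 0-based
        step <- as.numeric(kv[["step"]] %||% "1")
      }
    } else {
      if (is.null(mode)) stop("WIG value line before any declaration")
      if (mode == "fixed") {
        v <- suppressWarnings(as.numeric(ln))
        if (is.na(v)) stop("non-numeric WIG value: ", ln)
        k <- k + 1L
        rows[[k]] <- c(nextstart, nextstart + span, v)
        nextstart <- nextstart + step
      } else {
        parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
        if (length(parts) != 2) stop("malformed variableStep line: ", ln)
        p <- suppressWarnings(as.numeric(parts[1]))
        v <- suppressWarnings(as.numeric(parts[2]))
        if (is.na(p) || is.na(v)) stop("non-numeric WIG value: ", ln)
        k <- k + 1L
        rows[[k]] <- c(p - 1, p - 1 + span, v)
      }
      names(rows)[k] <- chrom
    }
  }
  rows <- rows[seq_len(k)]
  if (k == 0L) return(data_track())
  m <- do.call(rbind, rows)
  data_track(data.frame(sequence_id = names(rows), start = m[, 1],
                        end = m[, 2], value = m[, 3],
                        stringsAsFactors = FALSE))
}

parse_decl <- function(ln) {
  toks <- strsplit(trimws(ln), "[ \t]+")[[1]][-1]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

#' Write a DataTrack as WIG
#'
#' Emits `variableStep` sections; a new declaration is written whenever the
#' sequence or the run span changes.
#' @param track a `DataTrack`.
#' @param path output file.
#' @export
write_wig <- function(track, path) {
  stopifnot(inherits(track, "DataTrack"))
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(track) > 0) {
    span <- track$end - track$start
    decl <- c(TRUE, track$sequence_id[-1] != track$sequence_id[-nrow(track)] |
                span[-1] != span[-nrow(track)])
    for (i in seq_len(nrow(track))) {
      if (decl[i])
        writeLines(sprintf("variableStep chrom=%s span=%s",
                           track$sequence_id[i], format_coord(span[i])), con)
      writeLines(paste(format_coord(track$start[i] + 1),
                       format(track$value[i], digits = 17, trim = TRUE,
                              scientific = FALSE)), con)
    }
  }
  invisible(path)
}

# ---- Alignment blocks -----------------------------------------------------

#' Multiple-alignment blocks
#'
#' An `AlignmentBlock` holds a reference interval plus gapped aligned rows
#' from other genomes. All rows have equal length; the reference row with
#' gaps removed must equal the reference genome subsequence when a genome is
#' bound. The first row is the reference.
#'
#' The on-disk format is one header line `=block <seq_id> <start> <end>`
#' (0-based half-open) followed by one `name<TAB>gapped_seq` line per
#' genome.
#'
#' @param sequence_id,start,end reference interval (0-based half-open).
#' @param rows named character vector of gapped rows (alphabet + `-`);
#'   first entry is the reference row.
#' @return An object of class `AlignmentBlock`.
#' @export
alignment_block <- function(sequence_id, start, end, rows) {
  if (length(rows) < 1 || is.null(names(rows))) stop("rows must be named")
  rows <- toupper(rows)
  if (length(unique(nchar(rows))) != 1) stop("alignment rows differ in length")
  bad <- gsub("[ACGTN-]", "", rows)
  if (any(nchar(bad) > 0)) stop("illegal characters in alignment rows")
  ref_degap <- gsub("-", "", rows[[1]], fixed = TRUE)
  if (nchar(ref_degap) != end - start)
    stop("reference row length (degapped) does not match interval width")
  structure(list(sequence_id = sequence_id, start = start, end = end,
                 rows = rows), class = "AlignmentBlock")
}

#' @export
print.AlignmentBlock <- function(x, ...) {
  cat("AlignmentBlock", x$sequence_id, paste0("[", x$start, ",", x$end, ")"),
      "|", length(x$rows), "rows\n")
  invisible(x)
}

#' Read alignment blocks
#' @param path block-format file.
#' @param genome optional bound `Genome`: the degapped reference row of each
#'   block must match the genome subsequence.
#' @return List of `AlignmentBlock`.
#' @export
read_alignment_blocks <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^=block ", lines)
  if (length(heads) == 0) return(list())
  ends <- c(heads[-1] - 1L, length(lines))
  blocks <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    hd <- strsplit(lines[heads[i]], "[ \t]+")[[1]]
    if (length(hd) != 4) stop("malformed block header: ", lines[heads[i]])
    body <- lines[(heads[i] + 1L):ends[i]]
    kv <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(kv) != 2)) stop("malformed alignment row")
    rows <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    b <- alignment_block(hd[2], as.numeric(hd[3]), as.numeric(hd[4]), rows)
    if (!is.null(genome)) {
      ref <- gsub("-", "", b$rows[[1]], fixed = TRUE)
      if (ref != get_seq(genome, b$sequence_id, b$start, b$end))
        stop("reference row does not match bound genome at block ", i)
    }
    blocks[[i]] <- b
  }
  blocks
}

#' Write alignment blocks
#' @param blocks list of `AlignmentBlock`.
#' @param path output file.
#' @export
write_alignment_blocks <- function(blocks, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (b in blocks) {
    writeLines(sprintf("=block %s %s %s", b$sequence_id,
                       format_coord(b$start), format_coord(b$end)), con)
    writeLines(paste(names(b$rows), b$rows, sep = "\t"), con)
  }
  invisible(path)
}
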