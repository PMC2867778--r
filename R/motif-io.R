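#' Read motifs from text formats
#'
#' Supported formats:
#' \describe{
#'   \item{`matrix`}{The package's own bit-exact text format: a `>name`
#'     header line (optionally `>name kind=affinity`), then one line per
#'     motif position holding 4 whitespace-separated values in the order
#'     A C G T. Count matrices are normalized column-wise.}
#'   \item{`meme`}{MEME minimal format: `MOTIF name` headers followed by a
#'     `letter-probability matrix:` declaration and one A/C/G/T probability
#'     row per position.}
#'   \item{`bioprospector`}{BioProspector-style output: `Motif #k` block
#'     headers; within a block, every line whose last whitespace-separated
#'     token is a DNA word of the block's constant width is taken as an
#'     aligned site, and the sites are stacked into a count matrix.}
#'   \item{`degenerate_list`}{One IUPAC string per line, optionally
#'     preceded by a name (`name<TAB>pattern`).}
#' }
#'
#' @param path input file.
#' @param format one of `"matrix"`, `"meme"`, `"bioprospector"`,
#'   `"degenerate_list"`.
#' @return A list of `Motif` objects.
#' @export
read_motifs <- function(path, format = c("matrix", "meme", "bioprospector",
                                         "degenerate_list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  switch(format,
         matrix = parse_matrix_motifs(lines),
         meme = parse_meme_motifs(lines),
         bioprospector = parse_bioprospector_motifs(lines),
         degenerate_list = parse_degenerate_list(lines))
}

parse_matrix_motifs <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) {
    if (length(lines) > 0) stop("matrix format requires '>name' headers")
    return(list())
  }
  ends <- c(heads[-1] - 1L, length(lines))
  out <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    hd <- trimws(sub("^>", "", lines[heads[i]]))
    kind <- if (grepl("kind=affinity", hd)) "affinity" else "frequency"
    nm <- trimws(sub("\\s*kind=\\w+", "", hd))
    if (ends[i] < heads[i] + 1L) stop("motif block without rows: ", nm)
    body <- lines[(heads[i] + 1L):ends[i]]
    vals <- lapply(strsplit(trimws(body), "[ \t]+"), as.numeric)
    if (any(lengths(vals) != 4) || anyNA(unlist(vals)))
      stop("matrix rows must hold 4 numeric values (A C G T): ", nm)
    mat <- t(do.call(rbind, vals))
    if (any(mat < 0)) stop("negative matrix entry in motif ", nm)
    out[[i]] <- motif(mat, name = nm, kind = kind)
  }
  out
}

parse_meme_motifs <- function(lines) {
  heads <- grep("^MOTIF\\b", lines)
  out <- list()
  for (h in heads) {
    nm <- strsplit(trimws(lines[h]), "[ \t]+")[[1]][2]
    decl <- grep("^letter-probability matrix", lines)
    decl <- decl[decl > h][1]
    if (is.na(decl)) stop("MOTIF without letter-probability matrix: ", nm)
    kv <- regmatches(lines[decl], gregexpr("\\w+= *[0-9.eE+-]+", lines[decl]))[[1]]
    w <- NA_integer_; nsites <- NULL
    for (tok in kv) {
      p <- strsplit(gsub(" ", "", tok), "=")[[1]]
      if (p[1] == "w") w <- as.integer(p[2])
      if (p[1] == "nsites") nsites <- as.numeric(p[2])
    }
    if (is.na(w)) stop("letter-probability matrix without w=: ", nm)
    body <- lines[(decl + 1L):(decl + w)]
    vals <- lapply(strsplit(trimws(body), "[ \t]+"), as.numeric)
    if (any(lengths(vals) != 4) || anyNA(unlist(vals)))
      stop("malformed MEME probability rows for motif ", nm)
    out[[length(out) + 1L]] <- motif(t(do.call(rbind, vals)), name = nm,
                                     nsites = nsites)
  }
  out
}

parse_bioprospector_motifs <- function(lines) {
  heads <- grep("^Motif #", lines)
  if (length(heads) == 0) return(list())
  ends <- c(heads[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(heads)) {
    nm <- sub("[:(].*$", "", trimws(lines[heads[i]]))
    nm <- gsub("[# ]", "", nm)
    body <- lines[(heads[i] + 1L):ends[i]]
    last_tok <- vapply(strsplit(trimws(body), "[ \t]+"),
                       function(x) if (length(x)) x[length(x)] else "",
                       character(1))
    words <- toupper(last_tok[grepl("^[ACGTacgt]{4,}$", last_tok)])
    if (length(words) == 0) next
    w <- as.integer(names(sort(table(nchar(words)), decreasing = TRUE))[1])
    words <- words[nchar(words) == w]
    out[[length(out) + 1L]] <- motif(words_to_counts(words), name = nm,
                                     nsites = length(words))
  }
  out
}

words_to_counts <- function(words) {
  W <- nchar(words[1])
  mat <- matrix(0, 4, W, dimnames = list(BASES, NULL))
  for (wd in words) {
    ch <- strsplit(wd, "")[[1]]
    for (j in seq_len(W)) mat[ch[j], j] <- mat[ch[j], j] + 1
  }
  mat
}

parse_degenerate_list <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    out[[i]] <- if (length(parts) >= 2)
      motif_from_degenerate(parts[2], name = parts[1])
    else motif_from_degenerate(parts[1])
  }
  out
}

#' Write motifs to text formats
#'
#' `matrix` writes the package's bit-exact matrix format (17 significant
#' digits, round-trips through [read_motifs()]); `meme` writes MEME minimal
#' format; `logo` writes a TSV table of IC-scaled letter heights
#' (`name`, `position`, `base`, `height` in bits), the numeric content of a
#' sequence logo.
#'
#' @param motifs list of `Motif` objects.
#' @param path output file.
#' @param format `"matrix"`, `"meme"` or `"logo"`.
#' @param bg `Background` used for `logo` letter heights.
#' @export
write_motifs <- function(motifs, path, format = c("matrix", "meme", "logo"),
                         bg = background()) {
  format <- match.arg(format)
  con <- file(path, "w"); on.exit(close(con))
  if (format == "meme") {
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "",
                 "Background letter frequencies",
                 paste(sprintf("%s %.5f", BASES, bg$probs), collapse = " "), ""),
               con)
  }
  if (format == "logo")
    writeLines("name\tposition\tbase\theight", con)
  for (m in motifs) {
    stopifnot(inherits(m, "Motif"))
    if (format == "matrix") {
      hd <- paste0(">", m$name, if (m$kind == "affinity") " kind=affinity")
      writeLines(hd, con)
      writeLines(apply(m$mat, 2, function(col)
        paste(sprintf("%.17g", col), collapse = " ")), con)
    } else if (format == "meme") {
      writeLines(paste("MOTIF", m$name), con)
      writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         motif_width(m),
                         as.integer(m$nsites %||% 20)), con)
      writeLines(apply(m$mat, 2, function(col)
        paste(sprintf("%.6f", col), collapse = " ")), con)
      writeLines("", con)
    } else {
      ic <- information_content(m, bg)$per_column
      for (j in seq_len(motif_width(m)))
        writeLines(sprintf("%s\t%d\t%s\t%.6g", m$name, j, BASES,
                           ic[j] * m$mat[, j]), con)
    }
  }
  invisible(path)
}
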