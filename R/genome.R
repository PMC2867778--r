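#' Genome: a named set of DNA sequences
#'
#' A `Genome` is a named character vector of DNA sequences over the alphabet
#' `{A,C,G,T,N}`, uppercased on construction. All coordinates used against a
#' genome are 0-based half-open; conversions to 1-based formats happen only
#' at file-format boundaries.
#'
#' Normalization rules: lowercase is uppercased; `U` becomes `T`; other IUPAC
#' ambiguity codes become `N` with a warning, or raise an error in strict
#' mode. `N` never matches anything during scoring or pattern search.
#'
#' @param sequences named character vector of DNA sequences.
#' @param name optional genome name.
#' @param strict if `TRUE`, characters outside `{A,C,G,T,N}` (after case/U
#'   normalization) are an error instead of being mapped to `N`.
#' @return An object of class `Genome`.
#' @examples
#' g <- genome(c(chr1 = "acgtn", chr2 = "TTTT"))
#' seq_lengths(g)
#' @export
genome <- function(sequences, name = "genome", strict = FALSE) {
  if (length(sequences) == 0) stop("genome needs at least one sequence")
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named")
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  s <- toupper(sequences)
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (any(nchar(bad) > 0)) {
    chars <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
    if (strict) stop("illegal characters in sequence: ", paste(chars, collapse = " "))
    warning("mapping non-ACGTN characters to N: ", paste(chars, collapse = " "))
    for (ch in chars) s <- gsub(ch, "N", s, fixed = TRUE)
  }
  if (any(nchar(s) == 0)) stop("empty sequence: ",
                               paste(ids[nchar(s) == 0], collapse = ", "))
  structure(s, name = name, class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome:", attr(x, "name"), "|", length(x), "sequence(s),",
      sum(nchar(x)), "bp\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n))
    cat(" ", names(x)[i], nchar(x[[i]]), "bp\n")
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Sequence lengths of a genome
#' @param g a `Genome`.
#' @return Named integer vector of sequence lengths.
#' @export
seq_lengths <- function(g) {
  stopifnot(inherits(g, "Genome"))
  stats::setNames(nchar(unclass(g)), names(g))
}

## Extract genome subsequence, 0-based half-open coordinates.
get_seq <- function(g, sequence_id, start, end) {
  s <- unclass(g)[[sequence_id]]
  if (is.null(s) || is.na(s)) stop("unknown sequence id: ", sequence_id)
  if (start < 0 || end > nchar(s) || start >= end)
    stop("coordinates [", start, ",", end, ") out of range for ", sequence_id)
  substr(s, start + 1L, end)
}

#' Reverse complement of DNA strings
#'
#' `N` complements to `N`.
#' @param x character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Integer base coding used throughout: A=1 C=2 G=3 T=4 N=5.
BASES <- c("A", "C", "G", "T")

.code_lut <- local({
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  lut
})

encode_seq <- function(s) {
  code <- .code_lut[utf8ToInt(s)]
  if (anyNA(code)) stop("sequence contains characters outside {A,C,G,T,N}")
  code
}

decode_seq <- function(code) {
  paste(c(BASES, "N")[code], collapse = "")
}

#' Estimate a background base-composition model
#'
#' Order-0 backgrounds are the mononucleotide frequencies of the input
#' (ignoring `N`); orders 1-3 add conditional tables
#' `P(base | previous k bases)` estimated from overlapping (k+1)-mers, with
#' one pseudo-observation per cell so all probabilities stay positive.
#'
#' @param x a `Genome` or character vector of DNA sequences; `NULL` gives the
#'   uniform background.
#' @param order Markov order, 0-3.
#' @return An object of class `Background` with elements `order`, `probs`
#'   (length-4 named base probabilities) and, for `order > 0`, `cond`, a
#'   `4^k x 4` row-stochastic matrix indexed by context.
#' @export
background <- function(x = NULL, order = 0) {
  stopifnot(order %in% 0:3)
  if (is.null(x)) {
    probs <- stats::setNames(rep(0.25, 4), BASES)
    return(structure(list(order = 0L, probs = probs, cond = NULL),
                     class = "Background"))
  }
  seqs <- if (inherits(x, "Genome")) unclass(x) else as.character(x)
  codes <- lapply(seqs, encode_seq)
  all1 <- unlist(codes, use.names = FALSE)
  cnt <- tabulate(all1[all1 <= 4L], nbins = 4L) + 1
  probs <- stats::setNames(cnt / sum(cnt), BASES)
  cond <- NULL
  if (order > 0) {
    k <- order
    tab <- matrix(1, nrow = 4L^k, ncol = 4L)  # +1 pseudo-observation per cell
    for (cd in codes) {
      L <- length(cd)
      if (L <= k) next
      pos <- seq_len(L - k)
      ctx <- rep(0L, L - k)
      ok <- rep(TRUE, L - k)
      for (j in seq_len(k)) {
        bj <- cd[pos + j - 1L]
        ok <- ok & bj <= 4L
        ctx <- ctx * 4L + (pmin(bj, 4L) - 1L)
      }
      nxt <- cd[pos + k]
      ok <- ok & nxt <= 4L
      if (!any(ok)) next
      idx <- cbind(ctx[ok] + 1L, nxt[ok])
      for (r in seq_len(nrow(idx))) tab[idx[r, 1L], idx[r, 2L]] <-
          tab[idx[r, 1L], idx[r, 2L]] + 1
    }
    cond <- tab / rowSums(tab)
    colnames(cond) <- BASES
  }
  structure(list(order = as.integer(order), probs = probs, cond = cond),
            class = "Background")
}

#' @export
print.Background <- function(x, ...) {
  cat("Background model, order", x$order, "\n")
  print(round(x$probs, 4))
  invisible(x)
}

## Log probability of words under a background.
## `codes`: integer matrix, one row per word, entries 1..4. For order-k
## backgrounds the first k positions use the marginal base probabilities.
bg_word_logprob <- function(bg, codes) {
  if (is.vector(codes)) codes <- matrix(codes, nrow = 1L)
  W <- ncol(codes)
  lp <- rep(0, nrow(codes))
  k <- bg$order
  logp0 <- log(bg$probs)
  for (j in seq_len(min(k, W))) lp <- lp + logp0[codes[, j]]
  if (W > k) {
    if (k == 0L) {
      for (j in seq_len(W)) lp <- lp + logp0[codes[, j]]
    } else {
      logc <- log(bg$cond)
      for (j in (k + 1L):W) {
        ctx <- rep(0L, nrow(codes))
        for (t in seq_len(k)) ctx <- ctx * 4L + (codes[, j - k + t - 1L] - 1L)
        lp <- lp + logc[cbind(ctx + 1L, codes[, j])]
      }
    }
  }
  lp
}
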