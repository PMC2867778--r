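#' DNA motif objects
#'
#' A motif is a set of short DNA sequences summarized as a position-specific
#' weight matrix: a `4 x W` matrix (rows A, C, G, T) of column frequencies.
#' Two kinds are supported: `"frequency"` motifs, whose columns are
#' probability distributions (each column sums to 1), and `"affinity"`
#' motifs (as produced by biophysical models such as MatrixREDUCE), whose
#' entries are relative binding weights in `[0, 1]` with column maximum 1.
#'
#' @param mat `4 x W` numeric matrix, rows in order A, C, G, T. Count
#'   matrices are accepted for frequency motifs and normalized column-wise.
#' @param name motif name.
#' @param kind `"frequency"` or `"affinity"`.
#' @param nsites optional number of sites the matrix was built from.
#' @return An object of class `Motif`.
#' @examples
#' m <- motif(matrix(c(2, 0, 0, 2), 4, 3, dimnames = list(c("A","C","G","T"), NULL)))
#' @export
motif <- function(mat, name = "motif", kind = c("frequency", "affinity"),
                  nsites = NULL) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("motif matrix must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 1) stop("motif width must be >= 1")
  if (any(!is.finite(mat)) || any(mat < 0)) stop("motif entries must be finite and >= 0")
  if (kind == "frequency") {
    cs <- colSums(mat)
    if (any(cs <= 0)) stop("zero-sum motif column")
    mat <- sweep(mat, 2, cs, "/")
  } else {
    cm <- apply(mat, 2, max)
    if (any(cm <= 0)) stop("zero-max affinity column")
    mat <- sweep(mat, 2, cm, "/")
  }
  dimnames(mat) <- list(BASES, NULL)
  structure(list(name = name, mat = mat, kind = kind, nsites = nsites),
            class = "Motif")
}

#' @export
print.Motif <- function(x, ...) {
  cat("Motif:", x$name, "|", x$kind, "| width", motif_width(x), "\n")
  print(round(x$mat, 3))
  invisible(x)
}

#' Motif width
#' @param m a `Motif` or `PSSM`.
#' @return Integer number of columns.
#' @export
motif_width <- function(m) ncol(m$mat)

#' Build a motif from a degenerate IUPAC string
#'
#' Each column is the uniform distribution over the symbol's base set
#' (e.g. `R` gives A = G = 0.5).
#'
#' @param iupac string over the 15 IUPAC codes.
#' @param name motif name.
#' @return A frequency `Motif`.
#' @export
motif_from_degenerate <- function(iupac, name = iupac) {
  syms <- strsplit(toupper(iupac), "")[[1]]
  if (length(syms) == 0) stop("empty pattern")
  if (!all(syms %in% names(IUPAC_SETS)))
    stop("illegal IUPAC symbol: ", paste(setdiff(syms, names(IUPAC_SETS)), collapse = " "))
  mat <- vapply(syms, function(sym) {
    col <- rep(0, 4); names(col) <- BASES
    col[IUPAC_SETS[[sym]]] <- 1 / length(IUPAC_SETS[[sym]])
    col
  }, numeric(4))
  motif(matrix(mat, nrow = 4), name = name)
}

#' Regularize a frequency motif against a background
#'
#' Mixes each column with the background:
#' `f'(i, b) = (1 - p) f(i, b) + p bg(b)`. Columns remain probability
#' distributions; with `p > 0` all entries are positive, keeping log-odds
#' finite. The default `p = 0.01` barely perturbs strong motifs.
#'
#' @param m a frequency `Motif`.
#' @param bg a `Background` (order-0 probabilities are used).
#' @param pseudo_weight mixing weight `p` in `[0, 1)`.
#' @return A regularized frequency `Motif`.
#' @export
regularize_motif <- function(m, bg = background(), pseudo_weight = 0.01) {
  stopifnot(inherits(m, "Motif"), m$kind == "frequency",
            pseudo_weight >= 0, pseudo_weight < 1)
  mat <- (1 - pseudo_weight) * m$mat + pseudo_weight * bg$probs
  motif(mat, name = m$name, nsites = m$nsites)
}

#' Derive the log-odds scoring matrix (PSSM) of a motif
#'
#' The position-specific scoring matrix holds
#' `s(i, b) = log2( f'(i, b) / bg(b) )` where `f'` is the
#' pseudocount-regularized frequency matrix. The LOD score of a word is the
#' sum of its per-position entries.
#'
#' @param m a frequency `Motif`.
#' @param bg a `Background`; order-0 probabilities are used.
#' @param pseudo_weight regularization weight passed to
#'   [regularize_motif()].
#' @return An object of class `PSSM` with elements `mat` (4 x W log-odds,
#'   bits), `bg`, `max_score`, `min_score`.
#' @export
to_pssm <- function(m, bg = background(), pseudo_weight = 0.01) {
  stopifnot(inherits(m, "Motif"))
  if (m$kind != "frequency")
    stop("affinity motifs are scored with affinity_score(), not a PSSM")
  f <- regularize_motif(m, bg, pseudo_weight)$mat
  s <- log2(f / bg$probs)
  if (any(!is.finite(s))) stop("non-finite log-odds; use pseudo_weight > 0")
  structure(list(name = m$name, mat = s, bg = bg,
                 max_score = sum(apply(s, 2, max)),
                 min_score = sum(apply(s, 2, min))),
            class = "PSSM")
}

#' @export
print.PSSM <- function(x, ...) {
  cat("PSSM:", x$name, "| width", ncol(x$mat),
      sprintf("| score range [%.3f, %.3f] bits\n", x$min_score, x$max_score))
  print(round(x$mat, 3))
  invisible(x)
}

#' Information content of a motif
#'
#' Per-column relative entropy versus the background, in bits:
#' `IC(i) = sum_b f(i,b) log2( f(i,b) / bg(b) )` with `0 log 0 = 0`.
#' This is the quantity sequence logos display as letter-stack heights.
#'
#' @param m a frequency `Motif`.
#' @param bg a `Background`.
#' @return List with `per_column` (numeric vector) and `total`.
#' @export
information_content <- function(m, bg = background()) {
  stopifnot(inherits(m, "Motif"), m$kind == "frequency")
  f <- m$mat
  term <- ifelse(f > 0, f * log2(f / bg$probs), 0)
  per <- colSums(term)
  list(per_column = per, total = sum(per))
}

#' Reverse complement a motif
#'
#' Reverses the column order and swaps A with T and C with G.
#' @param m a `Motif`.
#' @return A `Motif`.
#' @export
revcomp_motif <- function(m) {
  stopifnot(inherits(m, "Motif"))
  mat <- m$mat[c(4, 3, 2, 1), rev(seq_len(ncol(m$mat))), drop = FALSE]
  dimnames(mat) <- list(BASES, NULL)
  out <- m
  out$mat <- mat
  out
}

#' Consensus string of a motif
#' @param m a `Motif`.
#' @return The per-column argmax bases (ties broken by A<C<G<T order).
#' @export
motif_consensus <- function(m) {
  paste(BASES[apply(m$mat, 2, which.max)], collapse = "")
}
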