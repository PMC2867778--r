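## IUPAC degenerate-base alphabet: each symbol names a set of bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## 15 symbols x 5 base codes (A C G T N): does symbol match the base?
## An N in the *genome* matches nothing.
.iupac_match <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_SETS), ncol = 5,
              dimnames = list(names(IUPAC_SETS), c(BASES, "N")))
  for (sym in names(IUPAC_SETS)) m[sym, IUPAC_SETS[[sym]]] <- TRUE
  m
})

#' Find matches to a degenerate (IUPAC) DNA pattern
#'
#' Reports every position where each pattern symbol's base set contains the
#' genome base. `N` in the genome matches nothing. Minus-strand hits are
#' matches of the reverse-complement pattern on the forward sequence,
#' reported with strand `-`. Overlapping hits are all reported.
#'
#' @param g a `Genome`.
#' @param pattern non-empty string over the 15 IUPAC codes.
#' @param strands `"+"`, `"-"` or `"both"`.
#' @return A `LocationSet` with `label` = the matched genomic word.
#' @examples
#' g <- genome(c(s = "GGAATTCC"))
#' find_pattern(g, "GAATTC", "both")
#' @export
find_pattern <- function(g, pattern, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  stopifnot(inherits(g, "Genome"), nchar(pattern) >= 1)
  pat <- strsplit(toupper(pattern), "")[[1]]
  if (!all(pat %in% names(IUPAC_SETS)))
    stop("illegal IUPAC symbol: ",
         paste(setdiff(pat, names(IUPAC_SETS)), collapse = " "))
  want <- if (strands == "both") c("+", "-") else strands
  res <- list()
  for (sid in names(g)) {
    code <- encode_seq(unclass(g)[[sid]])
    for (st in want) {
      p <- if (st == "+") pat else strsplit(revcomp(paste(pat, collapse = "")), "")[[1]]
      hits <- match_positions(code, p)
      if (length(hits) == 0) next
      res[[length(res) + 1L]] <- data.frame(
        sequence_id = sid, start = hits - 1, end = hits - 1 + length(p),
        strand = st,
        label = substring(unclass(g)[[sid]], hits, hits + length(p) - 1L),
        value = NA_real_, flag = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) return(location_set(name = paste0("pattern:", pattern)))
  as_location_set(do.call(rbind, res), name = paste0("pattern:", pattern))
}

## 1-based start positions where pattern symbols all match.
match_positions <- function(code, pat) {
  W <- length(pat); L <- length(code)
  if (W > L) return(integer(0))
  n <- L - W + 1L
  ok <- rep(TRUE, n)
  for (j in seq_len(W))
    ok <- ok & .iupac_match[pat[j], ][code[j:(j + n - 1L)]]
  which(ok)
}

#' Find direct and inverted repeats
#'
#' Searches for pairs of equal-length arms `arm1 = [i, i+a)` and
#' `arm2 = [j, j+a)` on the forward sequence with gap `g = j - (i+a)`,
#' where for a direct repeat the arm sequences are equal and for an
#' inverted repeat arm2 is the reverse complement of arm1. `N` never
#' matches. All hits within the parameter box are reported, subject to
#' maximality: a hit is suppressed if its arms can be extended (preserving
#' the repeat property, a non-negative gap and `arm <= arm_max`).
#' Overlapping hits at different gaps/centers are all reported.
#'
#' @param g a `Genome`.
#' @param kind `"direct"` or `"inverted"`.
#' @param arm_min,arm_max arm length range (bp), `1 <= arm_min <= arm_max`.
#' @param gap_min,gap_max gap range (bp), `0 <= gap_min <= gap_max`.
#' @return A data frame with columns `sequence_id`, `start1`, `end1`,
#'   `start2`, `end2`, `arm`, `gap`, `kind`, `arm1_seq`, `arm2_seq`.
#' @examples
#' g <- genome(c(s = "GAATTC"))
#' find_repeats(g, "inverted", 3, 3, 0, 0)
#' @export
find_repeats <- function(g, kind = c("direct", "inverted"),
                         arm_min, arm_max, gap_min = 0, gap_max = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(g, "Genome"), arm_min >= 1, arm_min <= arm_max,
            gap_min >= 0, gap_min <= gap_max)
  out <- list()
  for (sid in names(g)) {
    s <- unclass(g)[[sid]]
    code <- encode_seq(s)
    hits <- if (kind == "direct")
      direct_repeats(code, arm_min, arm_max, gap_min, gap_max)
    else
      inverted_repeats(code, arm_min, arm_max, gap_min, gap_max)
    if (nrow(hits) == 0) next
    hits <- data.frame(sequence_id = sid, hits, kind = kind,
                       stringsAsFactors = FALSE)
    hits$arm1_seq <- substring(s, hits$start1 + 1, hits$end1)
    hits$arm2_seq <- substring(s, hits$start2 + 1, hits$end2)
    out[[length(out) + 1L]] <- hits
  }
  if (length(out) == 0)
    return(data.frame(sequence_id = character(0), start1 = numeric(0),
                      end1 = numeric(0), start2 = numeric(0), end2 = numeric(0),
                      arm = numeric(0), gap = numeric(0), kind = character(0),
                      arm1_seq = character(0), arm2_seq = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$sequence_id, res$start1, res$start2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Direct repeats: for each offset d = arm + gap, positions x with
## s[x] == s[x+d] (x 0-based) form runs; within a run the maximal arm is
## min(run length, arm_max, d) -- capped arms admit every placement.
direct_repeats <- function(code, arm_min, arm_max, gap_min, gap_max) {
  L <- length(code)
  rows <- list()
  for (d in (arm_min + gap_min):(arm_max + gap_max)) {
    if (d + arm_min > L) break
    n <- L - d
    m <- code[1:n] == code[(1 + d):(d + n)] & code[1:n] <= 4L
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      rl <- r$lengths[k]
      a <- min(rl, arm_max, d)
      gp <- d - a
      if (a < arm_min || gp < gap_min || gp > gap_max) next
      xs <- if (a < rl) starts[k]:(ends[k] - a + 1) else starts[k]
      for (x in xs)
        rows[[length(rows) + 1L]] <-
          c(start1 = x - 1, end1 = x - 1 + a, start2 = x - 1 + a + gp,
            end2 = x - 1 + 2 * a + gp, arm = a, gap = gp)
    }
  }
  as.data.frame(do.call(rbind, rows) %||% matrix(numeric(0), ncol = 6,
    dimnames = list(NULL, c("start1", "end1", "start2", "end2", "arm", "gap"))))
}

## Inverted repeats: for each center sum S (0-based: x pairs with S - x),
## matched positions x <= (S-1)/2 with s[x] == comp(s[S-x]) form runs in x;
## arms grow outward (decreasing x) from a chosen inner edge x_end with
## gap = S - 2*x_end - 1.
inverted_repeats <- function(code, arm_min, arm_max, gap_min, gap_max) {
  L <- length(code)
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rows <- list()
  for (S in (2 * arm_min + gap_min - 1):(2 * L)) {
    x_in <- (S - 1) %/% 2              # innermost left position
    x_max <- min(x_in, L - 1)
    x_lo <- max(0, S - L + 1)          # need S - x <= L - 1
    if (x_max < x_lo) next
    xs <- x_lo:x_max
    m <- code[xs + 1] == comp[code[S - xs + 1]] & code[xs + 1] <= 4L
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run_lo <- xs[starts[k]]; run_hi <- xs[ends[k]]  # matched x in [run_lo, run_hi]
      # candidate inner edges: run_hi (full-run arm), plus every placement
      # when the arm is capped at arm_max
      rl <- run_hi - run_lo + 1
      if (rl <= arm_max) {
        cand <- run_hi; arms <- rl
      } else {
        cand <- (run_lo + arm_max - 1):run_hi; arms <- rep(arm_max, length(cand))
      }
      for (ci in seq_along(cand)) {
        x_end <- cand[ci]; a <- arms[ci]
        gp <- S - 2 * x_end - 1
        if (a < arm_min || gp < gap_min || gp > gap_max) next
        # inner extension (x_end+1 matched, gap-2 >= 0) would violate
        # maximality; only possible if x_end+1 <= x_in and is matched
        if (a < arm_max && gp >= 2 && x_end + 1 <= min(x_in, run_hi)) next
        rows[[length(rows) + 1L]] <-
          c(start1 = x_end - a + 1, end1 = x_end + 1, start2 = S - x_end,
            end2 = S - x_end + a, arm = a, gap = gp)
      }
    }
  }
  as.data.frame(do.call(rbind, rows) %||% matrix(numeric(0), ncol = 6,
    dimnames = list(NULL, c("start1", "end1", "start2", "end2", "arm", "gap"))))
}
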