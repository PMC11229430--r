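# Exact parsimony scoring. One postorder sweep per tree evaluates every
# character simultaneously with vectorised integer bit operations on the
# state masks, so exhaustive placement over all branches stays cheap even
# for simulation studies with hundreds of characters.

#' Weighting scheme for parsimony scoring
#'
#' Equal weights minimise the total step count; implied weights minimise
#' Goloboff's concave fit `sum(es / (es + k))` over characters, where `es`
#' is a character's extra steps (observed minus minimum) and `k` the
#' concavity constant. Larger `k` discounts homoplasy more gently and
#' converges to equal weights; the default `k = 12` follows current practice
#' for morphological matrices.
#'
#' @param mode `"equal"` or `"implied"`.
#' @param k concavity constant, positive; ignored under equal weights.
#' @export
weighting_scheme <- function(mode = c("implied", "equal"), k = 12) {
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("concavity constant k must be a positive number")
  }
  structure(list(mode = mode, k = as.numeric(k)), class = "weighting_scheme")
}

IW_TOL <- 1e-9

# Map tree leaves onto matrix rows, erroring on absentees.
leaf_rows <- function(pt, cm) {
  labs <- leaf_labels(pt)
  rows <- match(labs, cm$taxa)
  if (anyNA(rows)) {
    stop(sprintf("leaf '%s' absent from character matrix", labs[is.na(rows)][1L]))
  }
  stats::setNames(rows, labs)
}

# Per-character Fitch/Hartigan lengths for the selected characters.
# Binary nodes use classic Fitch (intersection if non-empty else union, +1);
# polytomies use Hartigan's frequency rule: keep the states present in the
# maximal number of child sets K, adding (degree - K) steps. MISSING leaves
# carry the character's full observed state set and so never force steps.
fitch_lengths <- function(pt, cm, chars = NULL) {
  if (is.null(chars)) chars <- seq_len(ncol(cm$bits))
  nc <- length(chars)
  N <- length(pt$parent)
  po <- postorder_nodes(pt)
  rows <- leaf_rows(pt, cm)

  full <- rep(0L, nc)
  for (i in rows) full <- bitwOr(full, cm$bits[i, chars])
  full[full == 0L] <- 1L  # character uncoded on this tree: inert

  S <- matrix(0L, N, nc)
  steps <- integer(nc)
  for (v in po) {
    kids <- pt$children[[v]]
    d <- length(kids)
    if (d == 0L) {
      x <- cm$bits[rows[[pt$label[v]]], chars]
      miss <- x == 0L
      x[miss] <- full[miss]
      S[v, ] <- x
    } else if (d == 1L) {
      S[v, ] <- S[kids, ]
    } else if (d == 2L) {
      a <- S[kids[1L], ]; b <- S[kids[2L], ]
      I <- bitwAnd(a, b)
      z <- I == 0L
      steps[z] <- steps[z] + 1L
      I[z] <- bitwOr(a, b)[z]
      S[v, ] <- I
    } else {
      cnt <- matrix(0L, MAX_STATES, nc)
      for (kd in kids) {
        x <- S[kd, ]
        for (s in seq_len(MAX_STATES) - 1L) {
          cnt[s + 1L, ] <- cnt[s + 1L, ] + bitwAnd(bitwShiftR(x, s), 1L)
        }
      }
      K <- cnt[1L, ]
      for (s in 2:MAX_STATES) K <- pmax(K, cnt[s, ])
      set <- rep(0L, nc)
      for (s in seq_len(MAX_STATES) - 1L) {
        hit <- cnt[s + 1L, ] == K
        set[hit] <- bitwOr(set[hit], bitwShiftL(1L, s))
      }
      S[v, ] <- set
      steps <- steps + (d - K)
    }
  }
  steps
}

#' Parsimony length of one character on a tree
#'
#' The minimum number of state changes over all internal assignments
#' (Fitch's algorithm; Hartigan's generalisation at polytomies). Missing
#' cells carry the character's full state set; multi-state cells carry their
#' set (standard ambiguity semantics).
#'
#' @param tree a `phylotree`; every leaf must appear in `matrix`.
#' @param matrix a `char_matrix`.
#' @param char 1-based character index.
#' @export
fitch_length <- function(tree, matrix, char) {
  if (char < 1L || char > ncol(matrix$bits)) stop("character index out of range")
  as.integer(fitch_lengths(tree, matrix, chars = char))
}

resolve_character_filter <- function(cm, character_filter) {
  if (is.null(character_filter)) return(seq_len(ncol(cm$bits)))
  if (is.numeric(character_filter)) {
    chars <- as.integer(character_filter)
    if (any(chars < 1L | chars > ncol(cm$bits))) stop("character index out of range")
    return(chars)
  }
  keep <- cm$partitions %in% character_filter
  if (!any(keep)) {
    stop(sprintf("unknown partition(s): %s",
                 paste(setdiff(character_filter, cm$partitions), collapse = ",")))
  }
  which(keep)
}

#' Score a tree under equal and implied weights
#'
#' Computes per-character Fitch lengths `s`, minimum steps `m` (over the
#' taxa actually on the tree), extra steps `es = s - m`, the equal-weights
#' total `sum(s)` and the implied-weights fit `sum(es / (es + k))`. Both
#' objectives are always reported; `weighting` supplies `k` and the mode
#' used by optimisers.
#'
#' @inheritParams fitch_length
#' @param weighting a [weighting_scheme()].
#' @param character_filter `NULL` (all characters), a vector of partition
#'   labels, or integer character indices.
#' @return a `tree_score`: `total_steps`, `total_extra_steps`, `iw_score`,
#'   `k`, and a `per_character` data frame (char, partition, s, m, es, fit).
#' @export
score_tree <- function(tree, matrix, weighting = weighting_scheme(),
                       character_filter = NULL) {
  chars <- resolve_character_filter(matrix, character_filter)
  s <- fitch_lengths(tree, matrix, chars)
  m <- min_steps_vec(matrix, chars, taxa = leaf_labels(tree))
  es <- s - m
  if (any(es < 0L)) stop("internal error: s < m")  # invariant s_i >= m_i
  fit <- es / (es + weighting$k)
  structure(list(
    total_steps = sum(s),
    total_extra_steps = sum(es),
    iw_score = sum(fit),
    k = weighting$k,
    mode = weighting$mode,
    per_character = data.frame(char = chars,
                               partition = matrix$partitions[chars],
                               s = s, m = m, es = es, fit = fit)),
    class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat(sprintf("tree_score: steps=%d extra=%d iw=%.6f (k=%g, %d characters)\n",
              x$total_steps, x$total_extra_steps, x$iw_score, x$k,
              nrow(x$per_character)))
  invisible(x)
}

#' Write the per-character score table as TSV
#' @param ts a `tree_score`.
#' @param file output path.
#' @export
write_score_table <- function(ts, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fossilplace %s\tk=%g\tweights=%s",
                     as.character(utils::packageVersion("fossilplace")),
                     ts$k, ts$mode), con)
  utils::write.table(ts$per_character, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# Lean objective pair used inside placement loops: m is precomputed once per
# leaf set since it does not depend on topology.
objectives_with_m <- function(tree, cm, chars, m, k) {
  s <- fitch_lengths(tree, cm, chars)
  es <- s - m
  c(ew = sum(s), iw = sum(es / (es + k)))
}
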