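# Independent oracles and random-instance generators shared by the suite.
# The brute-force parsimony oracle enumerates every internal-node state
# assignment; it shares no code path with fitch_lengths().

brute_force_length <- function(pt, cm, char) {
  N <- length(pt$parent)
  leaf <- vapply(seq_len(N), function(v) length(pt$children[[v]]) == 0L,
                 logical(1L))
  rows <- match(pt$label[leaf], cm$taxa)
  full <- Reduce(bitwOr, cm$bits[rows, char], 0L)
  if (full == 0L) return(0L)
  states <- fossilplace:::mask_states(full)
  leafmask <- integer(N)
  leafmask[leaf] <- ifelse(cm$bits[rows, char] == 0L, full,
                           cm$bits[rows, char])
  internals <- which(!leaf)
  grid <- as.matrix(expand.grid(rep(list(states), length(internals))))
  cost <- integer(nrow(grid))
  for (v in setdiff(seq_len(N), pt$root)) {
    p <- grid[, match(pt$parent[v], internals)]
    cost <- cost + if (leaf[v]) {
      as.integer(bitwAnd(leafmask[v], bitwShiftL(1L, p)) == 0L)
    } else {
      as.integer(grid[, match(v, internals)] != p)
    }
  }
  as.integer(min(cost))
}

# minimum steps of one character by enumerating every resolution of its
# polymorphic cells and every topology (trees are irrelevant for the bound,
# but resolving over them honours the definition)
brute_force_min_steps <- function(cells) {
  # cells: list of integer state vectors (empty = missing)
  coded <- cells[lengths(cells) > 0L]
  if (length(coded) == 0L) return(0L)
  grids <- expand.grid(coded)
  min(apply(grids, 1L, function(r) length(unique(r)) - 1L))
}

random_tree <- function(n, poly_prob = 0, seed = NULL) {
  gen <- function() {
    phy <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    if (poly_prob > 0) {
      phy$edge.length <- ifelse(stats::runif(nrow(phy$edge)) < poly_prob,
                                0, phy$edge.length)
      phy <- ape::di2multi(phy, tol = 1e-8)
    }
    as_phylotree(phy)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

random_cell <- function(n_states, p_missing, p_poly) {
  u <- stats::runif(1)
  if (u < p_missing) return(sample(c("?", "-"), 1L))
  if (u < p_missing + p_poly && n_states >= 2L) {
    st <- sort(sample(0:(n_states - 1L), 2L))
    return(sprintf("[%d%d]", st[1L], st[2L]))
  }
  as.character(sample(0:(n_states - 1L), 1L))
}

random_matrix <- function(taxa, n_char, n_states = 2L, p_missing = 0.15,
                          p_poly = 0.1, seed = NULL) {
  gen <- function() {
    rows <- vapply(taxa, function(tx) {
      paste(replicate(n_char, random_cell(n_states, p_missing, p_poly)),
            collapse = "")
    }, character(1L))
    char_matrix(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# the fixed 8-leaf recovery world used by the acceptance suite
recovery_world_tree <- function() {
  parse_newick(paste0(
    "(((t1:0.15,t2:0.15):0.15,(t3:0.15,Fossil:0.15):0.15):0.15,",
    "((t4:0.15,t5:0.15):0.15,(t6:0.15,t7:0.15):0.15):0.15);"))
}

extdata <- function(f) system.file("extdata", f, package = "fossilplace")

# rankings are equivalent up to ties: every strictly ordered pair under `a`
# is strictly ordered the same way under `b` (at tolerance tol), and ties
# under `a` are ties under `b`
ranking_equivalent <- function(a, b, tol = 1e-9) {
  all(outer(a, a, `<`) == outer(b, b, function(x, y) x < y - tol))
}
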