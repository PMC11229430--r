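# Mk-model generator for validation: unordered characters evolved on a known
# tree with branch lengths in expected changes per character, plus the
# fossil-style missingness the placement analysis must cope with (whole
# partitions uncodable, partial coding elsewhere). No ascertainment
# correction: the consumer is parsimony, not a likelihood estimator.

#' Simulation configuration
#'
#' @param tree a `phylotree` (or Newick string / ape phylo) with
#'   non-negative branch lengths in expected substitutions per character.
#' @param n_characters number of characters to simulate (>= 1).
#' @param n_states number of states r (at least 2); along a branch of length `t`
#'   a lineage keeps its state with probability
#'   `1/r + (1 - 1/r) * exp(-r * t / (r - 1))` and otherwise changes to a
#'   uniformly chosen different state (the Mk transition probability).
#' @param missing_fraction fraction of maskable cells set to MISSING,
#'   in `[0, 1)`; applied as an exact count (`round(f * n)`) so census
#'   numbers are deterministic.
#' @param designated_taxon taxon receiving the missingness mask (fossil
#'   style); `NULL` masks uniformly across the whole matrix.
#' @param partitions optional partition specification (see [char_matrix()]).
#' @param missing_partitions partition labels that are entirely MISSING for
#'   the designated taxon (the "larval block" situation); requires
#'   `designated_taxon`. At least one partition must stay maskable.
#' @param seed integer seed making the simulation deterministic.
#' @export
sim_config <- function(tree, n_characters, n_states = 2L,
                       missing_fraction = 0, designated_taxon = NULL,
                       partitions = NULL, missing_partitions = character(0),
                       seed = 1L) {
  tree <- as_phylotree(tree)
  if (any(!is.na(tree$edge_len) & tree$edge_len < 0)) {
    stop("branch lengths must be non-negative")
  }
  if (n_characters < 1L) stop("n_characters must be >= 1")
  if (n_states < 2L || n_states > MAX_STATES) {
    stop(sprintf("n_states must be in 2..%d", MAX_STATES))
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  part <- resolve_partitions(partitions, as.integer(n_characters))
  if (length(missing_partitions)) {
    if (is.null(designated_taxon)) {
      stop("missing_partitions requires a designated_taxon")
    }
    if (!all(missing_partitions %in% part)) stop("unknown missing partition")
    if (all(unique(part) %in% missing_partitions)) {
      stop("at least one partition must remain maskable (some signal must remain)")
    }
  }
  if (!is.null(designated_taxon) &&
      !designated_taxon %in% leaf_labels(tree)) {
    stop(sprintf("designated taxon '%s' not on tree", designated_taxon))
  }
  structure(list(tree = tree, n_characters = as.integer(n_characters),
                 n_states = as.integer(n_states),
                 missing_fraction = missing_fraction,
                 designated_taxon = designated_taxon,
                 partitions = part,
                 missing_partitions = missing_partitions,
                 seed = as.integer(seed)),
            class = "sim_config")
}

mk_stay_prob <- function(t, r) 1 / r + (1 - 1 / r) * exp(-r * t / (r - 1))

#' Simulate a morphological character matrix under the Mk model
#'
#' Each character evolves independently: the root state is uniform over the
#' `r` states, and each branch resamples the state with the Mk transition
#' probability (see [sim_config()]). The missingness mask is applied after
#' simulation. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return a `char_matrix` over the tree's leaves.
#' @export
simulate_matrix <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  pt <- config$tree
  nc <- config$n_characters
  r <- config$n_states
  withr::with_seed(config$seed, {
    N <- length(pt$parent)
    state <- matrix(NA_integer_, N, nc)
    pre <- rev(postorder_nodes(pt))
    state[pt$root, ] <- sample.int(r, nc, replace = TRUE) - 1L
    for (v in pre) {
      if (v == pt$root) next
      t <- pt$edge_len[v]
      if (is.na(t)) t <- 0
      p_stay <- mk_stay_prob(t, r)
      stay <- stats::runif(nc) < p_stay
      par <- state[pt$parent[v], ]
      jump <- (par + sample.int(r - 1L, nc, replace = TRUE)) %% r
      state[v, ] <- ifelse(stay, par, jump)
    }
    leaves <- which(vapply(seq_len(N), function(v) is_leaf(pt, v), logical(1L)))
    bits <- matrix(0L, length(leaves), nc)
    for (i in seq_along(leaves)) {
      bits[i, ] <- bitwShiftL(1L, state[leaves[i], ])
    }
    rownames(bits) <- pt$label[leaves]
    # missingness mask
    if (!is.null(config$designated_taxon)) {
      i <- match(config$designated_taxon, rownames(bits))
      block <- config$partitions %in% config$missing_partitions
      bits[i, block] <- 0L
      maskable <- which(!block)
      n_mask <- round(config$missing_fraction * length(maskable))
      if (n_mask > 0L) bits[i, sample(maskable, n_mask)] <- 0L
    } else if (config$missing_fraction > 0) {
      cells <- length(bits)
      n_mask <- round(config$missing_fraction * cells)
      if (n_mask > 0L) bits[sample.int(cells, n_mask)] <- 0L
    }
    poly <- matrix(FALSE, nrow(bits), nc)
    rownames(poly) <- rownames(bits)
    new_char_matrix(bits, poly, partitions = config$partitions,
                    symbols = 0:(r - 1L))
  })
}

#' Simulate a dataset for a placement-recovery experiment
#'
#' Simulates a matrix on the true tree, prunes the designated taxon from
#' the tree, and records the branch on the pruned backbone where the taxon
#' truly attaches.
#'
#' @param config a [sim_config()] with a `designated_taxon`.
#' @return list with `config`, `matrix`, `pruned_taxon`, `backbone`
#'   (a `phylotree`) and `true_branch` (branch id on the backbone).
#' @export
simulate_dataset <- function(config) {
  if (is.null(config$designated_taxon)) {
    stop("simulate_dataset needs a designated_taxon to prune")
  }
  cm <- simulate_matrix(config)
  pr <- prune_leaf(config$tree, config$designated_taxon)
  list(config = config, matrix = cm,
       pruned_taxon = config$designated_taxon,
       backbone = pr$tree, true_branch = pr$branch)
}

#' Placement recovery rate over simulated replicates
#'
#' For each replicate the designated taxon's characters are re-simulated
#' (replicate `i` uses seed `seed + i`), the taxon is pruned, and
#' [exhaustive_placement()] is run on the backbone; the replicate counts as
#' a success iff the true attachment branch is in the optimum set of the
#' requested weighting mode.
#'
#' @param config a [sim_config()] with a `designated_taxon`; the tree needs
#'   at least 5 leaves.
#' @param n_replicates number of replicates (>= 1).
#' @param weighting a [weighting_scheme()]; its mode selects which optimum
#'   set defines success.
#' @param seed integer; drives the per-replicate seed sequence.
#' @return recovery rate in `[0, 1]`.
#' @export
recovery_experiment <- function(config, n_replicates,
                                weighting = weighting_scheme("equal"),
                                seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (n_leaves(config$tree) < 5L) stop("recovery experiment needs >= 5 leaves")
  pr <- prune_leaf(config$tree, config$designated_taxon)
  successes <- 0L
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seed + i
    cm <- simulate_matrix(cfg)
    ps <- exhaustive_placement(pr$tree, cm, config$designated_taxon, weighting)
    opt <- if (weighting$mode == "equal") ps$optima$equal else ps$optima$implied
    if (pr$branch %in% opt) successes <- successes + 1L
  }
  successes / n_replicates
}
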