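# The decisive analysis: one floating fossil, every backbone branch tried,
# both objectives mapped onto the tree. The multi-taxon constrained search
# is a deterministic-seeded stepwise-addition + leaf-SPR hill climb whose
# single-taxon behaviour is provably identical to exhaustive enumeration.

#' Exhaustive single-taxon placement on a backbone
#'
#' Inserts `fossil` on every scorable branch of `backbone` (see
#' [enumerate_branches()]) and scores each resulting tree. Equal-weights
#' steps and the implied-weights fit are both reported for every branch
#' regardless of the requested mode, and the argmin sets of both columns
#' are retained in full (all ties).
#'
#' @param backbone a `phylotree`; all its leaves must be in `matrix`.
#' @param matrix a `char_matrix` containing `fossil`.
#' @param fossil taxon label present in `matrix` but not on `backbone`.
#' @param weighting a [weighting_scheme()] (supplies `k`).
#' @param character_filter optional partition labels / character indices.
#' @return a `placement_scores`: `fossil`, `backbone`, `k`, `rows` (data
#'   frame branch / ew_steps / iw_score in branch enumeration order) and
#'   `optima` (list with `equal` and `implied` branch-id vectors).
#' @export
exhaustive_placement <- function(backbone, matrix, fossil,
                                 weighting = weighting_scheme(),
                                 character_filter = NULL) {
  if (fossil %in% leaf_labels(backbone)) {
    stop(sprintf("fossil '%s' is already on the backbone", fossil))
  }
  taxon_row(matrix, fossil)  # lookup error if absent
  chars <- resolve_character_filter(matrix, character_filter)
  branches <- enumerate_branches(backbone)
  m <- min_steps_vec(matrix, chars, taxa = c(leaf_labels(backbone), fossil))
  k <- weighting$k
  sc <- vapply(branches, function(b) {
    objectives_with_m(insert_leaf(backbone, b, fossil), matrix, chars, m, k)
  }, c(ew = 0, iw = 0))
  rows <- data.frame(branch = branches,
                     ew_steps = as.integer(sc["ew", ]),
                     iw_score = sc["iw", ],
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    fossil = fossil, backbone = backbone, k = k, rows = rows,
    optima = list(
      equal = rows$branch[rows$ew_steps == min(rows$ew_steps)],
      implied = rows$branch[rows$iw_score <= min(rows$iw_score) + IW_TOL])),
    class = "placement_scores")
}

#' @export
print.placement_scores <- function(x, ...) {
  cat(sprintf("placement_scores for '%s' on %d branches (k=%g)\n",
              x$fossil, nrow(x$rows), x$k))
  cat(sprintf("  equal-weights optimum: %d steps at {%s}\n",
              min(x$rows$ew_steps), paste(x$optima$equal, collapse = "; ")))
  cat(sprintf("  implied-weights optimum: %.6f at {%s}\n",
              min(x$rows$iw_score), paste(x$optima$implied, collapse = "; ")))
  invisible(x)
}

#' Write per-branch placement scores as TSV
#'
#' One row per backbone branch: branch id (smaller-side leaf list),
#' equal-weights steps, implied-weights score, and optimum flags. The
#' header comment names `k` and the weighting mode so outputs are
#' self-describing.
#'
#' @param ps a `placement_scores`.
#' @param file output path.
#' @param mode label recorded in the header (default `"both"`).
#' @export
write_placement_tsv <- function(ps, file, mode = "both") {
  df <- ps$rows
  df$is_optimum_ew <- df$branch %in% ps$optima$equal
  df$is_optimum_iw <- df$branch %in% ps$optima$implied
  df$iw_score <- sprintf("%.6f", df$iw_score)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fossilplace %s\tk=%g\tweights=%s\tfossil=%s",
                     as.character(utils::packageVersion("fossilplace")),
                     ps$k, mode, ps$fossil), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Map placement scores onto the backbone
#'
#' Returns a copy of the backbone whose branches carry the requested score
#' as an annotation (integer for equal weights, 6-decimal fixed for
#' implied); optimal branches get a `*` suffix. Write with
#' [write_newick()], re-read with [read_annotated_newick()].
#'
#' @param scores a `placement_scores`.
#' @param mode `"equal"` or `"implied"`.
#' @export
map_scores <- function(scores, mode = c("equal", "implied")) {
  mode <- match.arg(mode)
  pt <- scores$backbone
  tab <- branch_table(pt)
  rows <- scores$rows
  opt <- scores$optima[[mode]]
  lab <- if (mode == "equal") sprintf("%d", rows$ew_steps)
         else sprintf("%.6f", rows$iw_score)
  lab[rows$branch %in% opt] <- paste0(lab[rows$branch %in% opt], "*")
  note <- rep(NA_character_, length(pt$parent))
  note[tab$node[match(rows$branch, tab$id)]] <- lab
  pt$note <- note
  pt
}

## ---- constrained heuristic search -------------------------------------

search_objective <- function(obj, weighting) {
  if (weighting$mode == "equal") obj[["ew"]] else obj[["iw"]]
}

topology_key <- function(pt) paste(sort(bipartition_set(pt)), collapse = "|")

best_insertion <- function(tree, cm, chars, m, k, label, weighting) {
  branches <- enumerate_branches(tree)
  best <- NULL; best_val <- Inf; best_obj <- NULL
  for (b in branches) {
    cand <- insert_leaf(tree, b, label)
    obj <- objectives_with_m(cand, cm, chars, m, k)
    val <- search_objective(obj, weighting)
    if (val < best_val - IW_TOL) {  # ties keep the first branch in order
      best <- cand; best_val <- val; best_obj <- obj
    }
  }
  list(tree = best, val = best_val, obj = best_obj)
}

#' Constrained parsimony search with floating taxa
#'
#' Taxa with molecular data keep their backbone interrelationships fixed;
#' the `floating` taxa (fossils and unsequenced extant taxa) may attach
#' anywhere. Each restart adds the floating taxa by stepwise insertion in a
#' seeded random order, each at its currently best branch, then hill-climbs
#' with single-leaf subtree-prune-regraft moves restricted to floating
#' leaves until a full pass yields no strict improvement. A final plateau
#' sweep collects every equal-score single-leaf reattachment so that all
#' tied optima are reported. Deterministic given `seed`.
#'
#' @param backbone a `phylotree`.
#' @param matrix a `char_matrix` covering backbone leaves and floating taxa.
#' @param floating character vector of taxon labels, disjoint from the
#'   backbone leaves (may be empty: the backbone itself is returned).
#' @param weighting a [weighting_scheme()]; its `mode` is the objective.
#' @param n_restarts number of random-order restarts (>= 1).
#' @param seed integer seed; restart r uses `seed + r`.
#' @param character_filter optional partition labels / character indices.
#' @return a `constrained_search_result`: `best_trees` (all distinct tied
#'   topologies), `best_score` (a `tree_score`), `floating`, and `log`
#'   (one row per restart: seed, addition order, final scores).
#' @export
constrained_search <- function(backbone, matrix, floating,
                               weighting = weighting_scheme(),
                               n_restarts = 3L, seed = 1L,
                               character_filter = NULL) {
  floating <- as.character(floating)
  if (length(intersect(floating, leaf_labels(backbone)))) {
    stop("floating taxa overlap the backbone leaves")
  }
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  chars <- resolve_character_filter(matrix, character_filter)
  k <- weighting$k
  all_taxa <- c(leaf_labels(backbone), floating)
  m <- min_steps_vec(matrix, chars, taxa = all_taxa)

  if (length(floating) == 0L) {
    ts <- score_tree(backbone, matrix, weighting, character_filter)
    log <- data.frame(restart = integer(0), seed = integer(0),
                      order = character(0), ew_steps = integer(0),
                      iw_score = numeric(0))
    return(structure(list(best_trees = list(backbone), best_score = ts,
                          floating = floating, log = log),
                     class = "constrained_search_result"))
  }

  best_val <- Inf
  best_trees <- list(); best_keys <- character(0)
  log <- vector("list", n_restarts)

  for (r in seq_len(n_restarts)) {
    ord <- withr::with_seed(seed + r, sample(floating))
    tree <- backbone
    for (lab in ord) {
      tree <- best_insertion(tree, matrix, chars, m, k, lab, weighting)$tree
    }
    obj <- objectives_with_m(tree, matrix, chars, m, k)
    val <- search_objective(obj, weighting)
    # leaf-SPR hill climbing over floating leaves
    repeat {
      improved <- FALSE
      for (lab in sort(floating)) {
        pr <- prune_leaf(tree, lab)
        cand <- best_insertion(pr$tree, matrix, chars, m, k, lab, weighting)
        if (cand$val < val - IW_TOL) {
          tree <- cand$tree; val <- cand$val; obj <- cand$obj
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    log[[r]] <- data.frame(restart = r, seed = seed + r,
                           order = paste(ord, collapse = ","),
                           ew_steps = as.integer(obj[["ew"]]),
                           iw_score = obj[["iw"]])
    if (val < best_val - IW_TOL) {
      best_val <- val
      best_trees <- list(tree); best_keys <- topology_key(tree)
    } else if (val <= best_val + IW_TOL) {
      key <- topology_key(tree)
      if (!key %in% best_keys) {
        best_trees <- c(best_trees, list(tree)); best_keys <- c(best_keys, key)
      }
    }
  }

  # plateau sweep: record every equal-score single-leaf reattachment
  frontier <- best_trees
  while (length(frontier)) {
    nxt <- list()
    for (tree in frontier) {
      for (lab in sort(floating)) {
        pr <- prune_leaf(tree, lab)
        for (b in enumerate_branches(pr$tree)) {
          cand <- insert_leaf(pr$tree, b, lab)
          obj <- objectives_with_m(cand, matrix, chars, m, k)
          if (search_objective(obj, weighting) <= best_val + IW_TOL) {
            key <- topology_key(cand)
            if (!key %in% best_keys) {
              best_trees <- c(best_trees, list(cand))
              best_keys <- c(best_keys, key)
              nxt <- c(nxt, list(cand))
            }
          }
        }
      }
    }
    frontier <- nxt
  }

  structure(list(
    best_trees = best_trees,
    best_score = score_tree(best_trees[[1L]], matrix, weighting,
                            character_filter),
    floating = floating,
    log = do.call(rbind, log)),
    class = "constrained_search_result")
}

#' @export
print.constrained_search_result <- function(x, ...) {
  cat(sprintf("constrained_search_result: %d floating taxa, %d best tree(s)\n",
              length(x$floating), length(x$best_trees)))
  print(x$best_score)
  invisible(x)
}
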