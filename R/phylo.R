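# Per-domain phylogenies and their incongruence. Trees are ape `phylo`
# objects; numeric `node.label` carries percentage branch supports (NA =
# unknown). Inference is distance-based (saturation-corrected p-distance +
# neighbor joining) with column-resampling bootstrap supports; externally
# computed trees can be supplied instead via read_newick().

#' Saturation-corrected pairwise distances from a protein alignment
#'
#' For each pair, the mismatch fraction `p` is computed over the columns
#' where both sequences are non-gap, then corrected for multiple hits under
#' an equal-input model: `d = -p_max * ln(1 - p / p_max)` with
#' `p_max = 0.95`, the equilibrium mismatch probability for 20 equally
#' likely residues. `p` at or above the cap is clamped just below it.
#' Pairs sharing fewer than 20 columns are unreliable: their distance is set
#' to the matrix maximum and a warning is emitted; a pair with zero shared
#' columns is an error.
#'
#' @param aln Aligned sequence tibble (ideally trimmed).
#' @return A symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
pairwise_distance <- function(aln) {
  aln <- validate_seqs(aln, aligned = TRUE, min_records = 3L)
  m <- aln_matrix(aln)
  n <- nrow(m)
  p_max <- 0.95
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  shared <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      ns <- sum(ok)
      if (ns == 0L) {
        stop("sequences '", aln$id[i], "' and '", aln$id[j],
             "' share no aligned columns", call. = FALSE)
      }
      shared[i, j] <- ns
      p <- sum(m[i, ok] != m[j, ok]) / ns
      p <- min(p, p_max * (1 - 1e-6))
      d[i, j] <- d[j, i] <- -p_max * log(1 - p / p_max)
    }
  }
  few <- which(shared > 0L & shared < 20L, arr.ind = TRUE)
  if (nrow(few) > 0L) {
    dmax <- max(d)
    for (r in seq_len(nrow(few))) {
      i <- few[r, 1L]; j <- few[r, 2L]
      d[i, j] <- d[j, i] <- dmax
    }
    warning(nrow(few), " pair(s) share fewer than 20 columns; their ",
            "distance was set to the matrix maximum", call. = FALSE)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via [ape::nj()]) on a validated symmetric
#' matrix. The result is unrooted with no supports; see
#' [bootstrap_support()] to attach them.
#'
#' @param dm Symmetric non-negative matrix with zero diagonal and ids as
#'   dimnames; at least 3 taxa.
#' @return A `phylo` object.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(!is.finite(dm)) || any(dm < 0) || any(diag(dm) != 0)) {
    stop("distances must be finite, non-negative, with zero diagonal",
         call. = FALSE)
  }
  tr <- ape::nj(dm)
  tr$node.label <- rep(NA_real_, tr$Nnode)
  tr
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Infers the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree each
#' time, and labels every internal edge of the point tree with the
#' percentage of replicates containing the same bipartition.
#'
#' @param aln Aligned (trimmed) sequence tibble.
#' @param n_reps Number of bootstrap replicates (>= 10).
#' @param seed Integer seed for the resampling.
#' @return A `phylo` object with numeric percentage `node.label` (root `NA`).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L) {
  aln <- validate_seqs(aln, aligned = TRUE, min_records = 4L)
  n_reps <- as.integer(n_reps)
  if (n_reps < 10L) stop("n_reps must be >= 10", call. = FALSE)
  m <- aln_matrix(aln)
  build <- function(mat) {
    suppressWarnings(nj_tree(pairwise_distance(matrix_aln(mat))))
  }
  point <- build(m)
  L <- ncol(m)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      build(m[, sample.int(L, L, replace = TRUE), drop = FALSE])
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- 100 * counts / n_reps
  sup[1L] <- NA_real_  # root "bipartition" is trivial for an unrooted tree
  point$node.label <- sup
  point
}

# ---- nested-list tree representation -------------------------------------
# Used for support collapsing and tanglegram rotation, where child order and
# splicing are easier to manipulate than ape's edge matrix.
# A node is list(leaf = label or NULL, support, length, children = list()).

phylo_to_nested <- function(tree) {
  ntip <- length(tree$tip.label)
  sup <- tree$node.label
  if (is.null(sup)) sup <- rep(NA_real_, tree$Nnode)
  sup <- suppressWarnings(as.numeric(sup))
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(tree$edge))
  len_of <- numeric(ntip + tree$Nnode)
  len_of[tree$edge[, 2L]] <- elen
  build <- function(node) {
    if (node <= ntip) {
      list(leaf = tree$tip.label[node], support = NA_real_,
           length = len_of[node], children = NULL)
    } else {
      list(leaf = NULL, support = sup[node - ntip], length = len_of[node],
           children = lapply(kids[[as.character(node)]], build))
    }
  }
  build(ntip + 1L)
}

nested_to_newick <- function(node) {
  rec <- function(x) {
    if (is.null(x$children)) {
      sprintf("%s:%.10f", x$leaf, x$length)
    } else {
      sup <- if (is.na(x$support)) "" else format(x$support)
      sprintf("(%s)%s:%.10f",
              paste(vapply(x$children, rec, ""), collapse = ","),
              sup, x$length)
    }
  }
  paste0(rec(node), ";")
}

nested_to_phylo <- function(node) {
  normalize_supports(ape::read.tree(text = nested_to_newick(node)))
}

nested_leaves <- function(node) {
  if (is.null(node$children)) return(node$leaf)
  unlist(lapply(node$children, nested_leaves))
}

count_internal <- function(node) {
  if (is.null(node$children)) return(0L)
  1L + sum(vapply(node$children, count_internal, 0L))
}

is_binary_nested <- function(node) {
  if (is.null(node$children)) return(TRUE)
  length(node$children) == 2L &&
    all(vapply(node$children, is_binary_nested, TRUE))
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal edge whose support is below `threshold`; the
#' contracted edge's length is added to its children so leaf-to-leaf path
#' lengths are preserved. Leaves are never removed. Internal edges with
#' unknown (`NA`) support are retained with a warning rather than collapsed.
#'
#' @param tree A `phylo` with numeric percentage `node.label`.
#' @param threshold Support percentage below which edges are contracted.
#' @return A `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold = 70) {
  stopifnot(inherits(tree, "phylo"))
  nested <- phylo_to_nested(tree)
  unknown <- 0L
  contract <- function(node) {
    if (is.null(node$children)) return(node)
    node$children <- lapply(node$children, contract)
    out <- list()
    for (child in node$children) {
      if (!is.null(child$children) && is.na(child$support)) {
        unknown <<- unknown + 1L
        out <- c(out, list(child))
      } else if (!is.null(child$children) && child$support < threshold) {
        spliced <- lapply(child$children, function(gc) {
          gc$length <- gc$length + child$length
          gc
        })
        out <- c(out, spliced)
      } else {
        out <- c(out, list(child))
      }
    }
    node$children <- out
    node
  }
  nested <- contract(nested)
  if (unknown > 0L) {
    warning(unknown, " internal edge(s) with unknown support were retained",
            call. = FALSE)
  }
  nested_to_phylo(nested)
}

# ---- tanglegram ordering --------------------------------------------------

# Inversion count of the permutation mapping order1 onto order2 = number of
# crossing connector lines in the side-by-side layout.
count_crossings <- function(order1, order2) {
  p <- match(order1, order2)
  n <- length(p)
  if (n < 2L) return(0L)
  s <- 0L
  for (i in seq_len(n - 1L)) {
    s <- s + sum(p[seq.int(i + 1L, n)] < p[i])
  }
  s
}

# One barycenter pass: reorder every internal node's children by the mean
# position of their leaves in the facing order (stable, so ties keep the
# current order). Returns the reordered nested tree.
barycenter_pass <- function(node, pos) {
  if (is.null(node$children)) return(node)
  node$children <- lapply(node$children, barycenter_pass, pos = pos)
  b <- vapply(node$children, function(ch) {
    mean(pos[nested_leaves(ch)])
  }, 0)
  node$children <- node$children[order(b)]
  node
}

# Reverse the child order of the internal node addressed by a child-index
# path from the root (empty path = root itself).
flip_at <- function(node, path) {
  if (length(path) == 0L) {
    node$children <- rev(node$children)
    return(node)
  }
  k <- path[1L]
  node$children[[k]] <- flip_at(node$children[[k]], path[-1L])
  node
}

# Child-index paths of every internal node, preorder.
internal_paths <- function(node) {
  paths <- list()
  collect <- function(x, path) {
    if (is.null(x$children)) return(invisible(NULL))
    paths[[length(paths) + 1L]] <<- path
    for (k in seq_along(x$children)) collect(x$children[[k]], c(path, k))
  }
  collect(node, integer(0))
  paths
}

# Greedy hill climbing: reverse any internal node's children whenever that
# strictly reduces crossings against the fixed facing order; repeat to a
# local optimum.
flip_improve <- function(node, facing_order) {
  eval_cr <- function(t) count_crossings(nested_leaves(t), facing_order)
  cur <- eval_cr(node)
  repeat {
    improved <- FALSE
    # a flip at an ancestor re-indexes the paths below it, so restart the
    # path enumeration after every accepted flip
    for (p in internal_paths(node)) {
      cand <- flip_at(node, p)
      cr <- eval_cr(cand)
      if (cr < cur) {
        node <- cand
        cur <- cr
        improved <- TRUE
        break
      }
    }
    if (!improved) return(node)
  }
}

# All leaf orders reachable by rotating internal nodes of a binary tree.
all_leaf_orders <- function(node) {
  if (is.null(node$children)) return(list(node$leaf))
  kid_orders <- lapply(node$children, all_leaf_orders)
  out <- list()
  for (perm in list(seq_along(kid_orders), rev(seq_along(kid_orders)))) {
    combos <- list(character(0))
    for (k in perm) {
      combos <- unlist(lapply(combos, function(pre) {
        lapply(kid_orders[[k]], function(o) c(pre, o))
      }), recursive = FALSE)
    }
    out <- c(out, combos)
  }
  unique(out)
}

#' Order two trees as a tanglegram with few crossings
#'
#' Finds leaf orders for two trees on the same leaf set that minimise the
#' number of crossing connector lines. Small binary problems (at most 16
#' internal nodes in total) are solved exactly by enumerating all rotation
#' states; larger ones use alternating barycenter passes plus greedy
#' single-node flips until no improvement. The returned layout is never
#' worse than the input orders.
#'
#' @param tree1,tree2 `phylo` objects on identical leaf sets.
#' @return A list with `order1`, `order2` (character vectors of leaf labels)
#'   and `crossings` (integer crossing count of the final layout).
#' @export
tanglegram_order <- function(tree1, tree2) {
  stopifnot(inherits(tree1, "phylo"), inherits(tree2, "phylo"))
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    only1 <- setdiff(tree1$tip.label, tree2$tip.label)
    only2 <- setdiff(tree2$tip.label, tree1$tip.label)
    stop("leaf sets differ; only in tree1: ",
         paste(only1, collapse = ", "), "; only in tree2: ",
         paste(only2, collapse = ", "), call. = FALSE)
  }
  n1 <- phylo_to_nested(tree1)
  n2 <- phylo_to_nested(tree2)
  exact_ok <- is_binary_nested(n1) && is_binary_nested(n2) &&
    (count_internal(n1) + count_internal(n2)) <= 16L
  if (exact_ok) {
    o1s <- all_leaf_orders(n1)
    o2s <- all_leaf_orders(n2)
    best <- list(order1 = o1s[[1L]], order2 = o2s[[1L]],
                 crossings = count_crossings(o1s[[1L]], o2s[[1L]]))
    for (o1 in o1s) {
      for (o2 in o2s) {
        cr <- count_crossings(o1, o2)
        if (cr < best$crossings) {
          best <- list(order1 = o1, order2 = o2, crossings = cr)
        }
        if (best$crossings == 0L) break
      }
      if (best$crossings == 0L) break
    }
    return(best)
  }
  best1 <- n1
  best2 <- n2
  best_cr <- count_crossings(nested_leaves(n1), nested_leaves(n2))
  repeat {
    pos2 <- stats::setNames(seq_along(nested_leaves(best2)),
                            nested_leaves(best2))
    cand1 <- barycenter_pass(best1, pos2)
    cand1 <- flip_improve(cand1, nested_leaves(best2))
    pos1 <- stats::setNames(seq_along(nested_leaves(cand1)),
                            nested_leaves(cand1))
    cand2 <- barycenter_pass(best2, pos1)
    cand2 <- flip_improve(cand2, nested_leaves(cand1))
    cr <- count_crossings(nested_leaves(cand1), nested_leaves(cand2))
    if (cr < best_cr) {
      best1 <- cand1
      best2 <- cand2
      best_cr <- cr
    } else {
      break
    }
  }
  list(order1 = nested_leaves(best1), order2 = nested_leaves(best2),
       crossings = best_cr)
}

# ---- leaf displacement ----------------------------------------------------

# Neighborhood of one leaf in one tree: root the tree at the leaf farthest
# from it (ties: alphabetically first), then walk up from the leaf to the
# smallest ancestral clade containing at least `min_other` other leaves.
leaf_neighborhood <- function(tree, leaf, min_other, pathd) {
  others <- setdiff(tree$tip.label, leaf)
  far <- others[pathd[leaf, others] == max(pathd[leaf, others])]
  far <- sort(far)[1L]
  rooted <- ape::root(tree, outgroup = far, resolve.root = TRUE)
  tip <- match(leaf, rooted$tip.label)
  anc <- phangorn::Ancestors(rooted, tip, "all")
  for (node in anc) {
    tips <- rooted$tip.label[phangorn::Descendants(rooted, node, "tips")[[1L]]]
    nb <- setdiff(tips, leaf)
    if (length(nb) >= min_other) return(nb)
  }
  others
}

#' Per-leaf displacement between two domain trees
#'
#' For every leaf, compares its local neighborhood (the smallest clade, on
#' the tree rooted at the leaf's farthest point, containing at least
#' `neighborhood_min` other leaves) between the two trees. The displacement
#' is one minus the Jaccard similarity of the two neighborhoods: 0 when the
#' leaf sits among the same taxa in both trees, near 1 when its domain has
#' moved across clades. Leaves with displacement above the threshold are
#' flagged as phylogenetically incongruent — the reproducible surrogate for
#' spotting taxa whose positions differ between the two sides of a
#' tanglegram. Both trees should already be collapsed at the support
#' threshold so weakly supported placements do not drive the statistic.
#'
#' @param tree_nuclease,tree_helicase `phylo` objects on identical leaf sets.
#' @param neighborhood_min Minimum number of other leaves in a neighborhood.
#' @param displacement_threshold Flagging threshold on the displacement.
#' @return A tibble with columns `id`, `displacement`, `flagged` and
#'   list-columns `neighborhood_nuclease`, `neighborhood_helicase`.
#' @export
leaf_displacement <- function(tree_nuclease, tree_helicase,
                              neighborhood_min = 5L,
                              displacement_threshold = 0.8) {
  stopifnot(inherits(tree_nuclease, "phylo"),
            inherits(tree_helicase, "phylo"))
  if (!setequal(tree_nuclease$tip.label, tree_helicase$tip.label)) {
    stop("leaf sets differ between the two trees", call. = FALSE)
  }
  n <- length(tree_nuclease$tip.label)
  if (n - 1L < neighborhood_min) {
    stop("tree too small for neighborhood_min = ", neighborhood_min,
         call. = FALSE)
  }
  with_lengths <- function(tr) {
    if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
    tr
  }
  t1 <- with_lengths(tree_nuclease)
  t2 <- with_lengths(tree_helicase)
  d1 <- ape::cophenetic.phylo(t1)
  d2 <- ape::cophenetic.phylo(t2)
  ids <- sort(t1$tip.label)
  rows <- lapply(ids, function(leaf) {
    nb1 <- leaf_neighborhood(t1, leaf, neighborhood_min, d1)
    nb2 <- leaf_neighborhood(t2, leaf, neighborhood_min, d2)
    jac <- length(intersect(nb1, nb2)) / length(union(nb1, nb2))
    tibble::tibble(id = leaf, displacement = 1 - jac,
                   flagged = (1 - jac) > displacement_threshold,
                   neighborhood_nuclease = list(sort(nb1)),
                   neighborhood_helicase = list(sort(nb2)))
  })
  dplyr::bind_rows(rows)
}
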