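# Branching-based grouping schemes for rooted airway trees. All three label
# segments from the tree topology alone and serve as the comparison baseline
# for the morphology-based clustering.
#
# Conventions (single-child "pass-through" segments, which arise from cutting
# the tree at the terminal bronchioles, inherit their neighbour's label in all
# three schemes; junctions of three or more branches are treated like
# bifurcations):
#   generations    root = 0, incremented below every branch point
#   orders         terminals = 1, parent = max(children) + 1 at every junction
#   Strahler       terminals = 1, parent increments only when the maximal
#                  child order is attained by two or more children

new_grouping <- function(method, labels) {
  structure(list(method = method, labels = labels,
                 n_groups = length(unique(labels))),
            class = "airway_grouping")
}

#' @export
print.airway_grouping <- function(x, ...) {
  cat(sprintf("Airway grouping by %s: %d segments, %d groups (labels %d..%d)\n",
              x$method, length(x$labels), x$n_groups, min(x$labels), max(x$labels)))
  invisible(x)
}

check_groupable <- function(tree) {
  v <- validate_tree(tree)
  if (length(v) > 0)
    stop_validation("cannot label an invalid tree: %s", paste(v, collapse = "; "))
}

#' Generation labels (counting bifurcations from the root)
#'
#' Generations count airway bifurcations from the trachea down to the
#' periphery: the root segment is generation 0 and a child's generation
#' exceeds its parent's by one exactly when the parent is a branch point
#' (two or more children). Pass-through segments keep their parent's
#' generation.
#'
#' @param tree a valid [airway_tree()].
#' @return an `airway_grouping` with integer labels per segment id.
#' @export
assign_generations <- function(tree) {
  check_groupable(tree)
  kids <- tree_children(tree)
  nkid <- lengths(kids)
  ord <- topological_order(tree)
  lab <- setNames(integer(length(ord)), ord)
  parent <- setNames(tree$segments$parent_id, tree$segments$segment_id)
  lab[tree$root_id] <- 0L
  for (id in ord[-1]) {
    p <- parent[[id]]
    lab[id] <- lab[[p]] + (if (nkid[[p]] >= 2L) 1L else 0L)
  }
  new_grouping("generations", lab)
}

# shared bottom-up recursion for orders and Strahler orders
centripetal_labels <- function(tree, combine) {
  kids <- tree_children(tree)
  ord <- rev(topological_order(tree))
  lab <- setNames(integer(length(ord)), ord)
  for (id in ord) {
    ch <- kids[[id]]
    lab[id] <- if (length(ch) == 0) 1L
    else if (length(ch) == 1) lab[[ch]]
    else combine(lab[ch])
  }
  lab
}

#' Order labels (Horsfield-style, counting inward from the periphery)
#'
#' Orders count from the periphery inward: terminal segments have order 1 and
#' the order increases at each point where two or more branches meet, to one
#' more than the largest child order. Single-child segments inherit.
#'
#' @inheritParams assign_generations
#' @return an `airway_grouping` with integer labels per segment id.
#' @export
assign_orders <- function(tree) {
  check_groupable(tree)
  new_grouping("orders", centripetal_labels(tree, function(ch) max(ch) + 1L))
}

#' Strahler order labels
#'
#' Strahler orders count from the periphery inward like orders, but increase
#' only where two or more children of the same (maximal) order meet;
#' otherwise the parent takes the maximal child order. This compresses
#' monopodial trees - a long trunk with small lateral branches stays at a low
#' order regardless of its length - which is precisely why Strahler orders
#' outperform generations on asymmetric airway trees.
#'
#' @inheritParams assign_generations
#' @return an `airway_grouping` with integer labels per segment id.
#' @export
assign_strahler_orders <- function(tree) {
  check_groupable(tree)
  new_grouping("strahler", centripetal_labels(tree, function(ch) {
    m <- max(ch)
    if (sum(ch == m) >= 2L) m + 1L else m
  }))
}

#' All branching-based groupings of a tree
#'
#' @param tree a valid [airway_tree()].
#' @param methods subset of `c("generations", "orders", "strahler")`.
#' @return named list of `airway_grouping` objects.
#' @export
assign_groupings <- function(tree, methods = c("generations", "orders", "strahler")) {
  methods <- match.arg(methods, several.ok = TRUE)
  fns <- list(generations = assign_generations, orders = assign_orders,
              strahler = assign_strahler_orders)
  setNames(lapply(methods, function(m) fns[[m]](tree)), methods)
}
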