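# Independent oracles and tree builders used across the suite. These are
# deliberately naive (plain recursion, double loops, full enumeration) and
# written against the definitions, not against the package implementation.

# build an airway_tree from an edge list: ids, parents (NA for root)
make_tree <- function(ids, parents, lumen = NULL, wall = NULL,
                      subject = "S", group = "NOX", validate = TRUE) {
  n <- length(ids)
  if (is.null(lumen)) lumen <- rep(100, n)
  if (is.null(wall)) wall <- rep(10, n)
  airway_tree(subject, group,
              data.frame(segment_id = ids, parent_id = parents,
                         lumen_diameter = lumen, wall_thickness = wall,
                         stringsAsFactors = FALSE),
              validate = validate)
}

# caterpillar: trunk of `trunk_len` nodes, each with one terminal lateral,
# the trunk continuing into a terminal tip segment beyond the last node
caterpillar_tree <- function(trunk_len) {
  ids <- c(paste0("T", seq_len(trunk_len)), "TIP",
           paste0("L", seq_len(trunk_len)))
  parents <- c(NA, paste0("T", seq_len(trunk_len - 1)),   # trunk chain
               paste0("T", trunk_len),                    # tip
               paste0("T", seq_len(trunk_len)))           # laterals
  make_tree(ids, parents)
}

# perfect binary tree of given depth (depth 0 = single root segment)
binary_tree <- function(depth) {
  ids <- "1"; parents <- NA_character_
  for (d in seq_len(depth)) {
    prev <- ids[nchar(ids) == d]
    for (p in prev) {
      ids <- c(ids, paste0(p, "0"), paste0(p, "1"))
      parents <- c(parents, p, p)
    }
  }
  make_tree(ids, parents)
}

# random rooted tree: each new segment attaches to a uniformly chosen
# existing one, so single-child chains and multifurcations both occur
random_tree <- function(n, seed) {
  set.seed(seed)
  parents <- c(NA_character_, paste0("N", sapply(2:n, function(i)
    sample.int(i - 1, 1))))
  make_tree(paste0("N", 1:n), parents,
            lumen = runif(n, 20, 600), wall = runif(n, 2, 30))
}

# --- naive recursive grouping oracles (definition-level implementations) ---

oracle_children <- function(tree) {
  seg <- tree$segments
  lapply(setNames(seg$segment_id, seg$segment_id), function(id)
    seg$segment_id[!is.na(seg$parent_id) & seg$parent_id == id])
}

oracle_generations <- function(tree) {
  kids <- oracle_children(tree)
  lab <- c()
  rec <- function(id, g) {
    lab[id] <<- g
    ch <- kids[[id]]
    for (c in ch) rec(c, if (length(ch) >= 2) g + 1L else g)
  }
  rec(tree$root_id, 0L)
  lab[tree$segments$segment_id]
}

oracle_orders <- function(tree) {
  kids <- oracle_children(tree)
  rec <- function(id) {
    ch <- kids[[id]]
    if (length(ch) == 0) return(setNames(1L, id))
    sub <- lapply(ch, rec)
    vals <- vapply(seq_along(ch), function(i) sub[[i]][[ch[i]]], 1L)
    own <- if (length(ch) == 1) vals else max(vals) + 1L
    c(setNames(own, id), unlist(sub))
  }
  lab <- rec(tree$root_id)
  lab[tree$segments$segment_id]
}

oracle_strahler <- function(tree) {
  kids <- oracle_children(tree)
  rec <- function(id) {
    ch <- kids[[id]]
    if (length(ch) == 0) return(setNames(1L, id))
    sub <- lapply(ch, rec)
    vals <- vapply(seq_along(ch), function(i) sub[[i]][[ch[i]]], 1L)
    own <- if (length(ch) == 1) vals
           else if (sum(vals == max(vals)) >= 2) max(vals) + 1L else max(vals)
    c(setNames(own, id), unlist(sub))
  }
  lab <- rec(tree$root_id)
  lab[tree$segments$segment_id]
}

# --- brute-force validity indices (double loops over points) --------------

bf_davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  lev <- unique(labels)
  k <- length(lev)
  cent <- S <- list()
  for (g in lev) {
    pts <- x[labels == g, , drop = FALSE]
    cent[[g]] <- colMeans(pts)
    S[[g]] <- mean(apply(pts, 1, function(p) sqrt(sum((p - cent[[g]])^2))))
  }
  db <- 0
  for (i in lev) {
    worst <- -Inf
    for (j in lev) {
      if (identical(i, j)) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (S[[i]] + S[[j]]) / d)
    }
    db <- db + worst
  }
  db / k
}

bf_dunn <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  sep <- Inf; diam <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (labels[i] == labels[j]) diam <- max(diam, d) else sep <- min(sep, d)
  }
  sep / diam
}

# --- exact Mann-Whitney null enumeration (tie-free samples) ---------------

bf_mann_whitney_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  N <- n_a + n_b
  splits <- combn(N, n_a)
  allr <- seq_len(N)
  Us <- apply(splits, 2, function(idx) sum(allr[idx]) - n_a * (n_a + 1) / 2)
  mu <- n_a * n_b / 2
  # two-sided: total probability of U at least as extreme on either side
  dev <- abs(U_obs - mu)
  mean(abs(Us - mu) >= dev - 1e-9)
}
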