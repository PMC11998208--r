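# Cluster-validity indices and the benchmark comparing branching-based
# grouping schemes with the morphology-based mixture partition.

check_index_input <- function(x, labels) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop_validation("features must be finite")
  labels <- as.vector(labels)
  if (length(labels) != nrow(x))
    stop_validation("labels length (%d) does not match rows (%d)",
                    length(labels), nrow(x))
  groups <- split(seq_len(nrow(x)), labels)
  if (length(groups) < 2)
    stop_validation("validity indices need at least 2 non-empty groups")
  list(x = x, groups = groups)
}

#' Davies-Bouldin cluster validity index
#'
#' Average, over groups, of the worst-case ratio of summed within-group
#' dispersions to between-centroid distance:
#' \deqn{DB = \frac{1}{k}\sum_i \max_{j \ne i} \frac{S_i + S_j}{d(c_i, c_j)}}
#' with \eqn{S_i} the mean Euclidean distance of group-\eqn{i} points to
#' their centroid \eqn{c_i}. Lower values indicate better-separated groups;
#' a single-point group contributes dispersion 0.
#'
#' @param x numeric feature matrix (one row per observation).
#' @param labels group label per row (at least two non-empty groups).
#' @return the index value (non-negative).
#' @export
davies_bouldin <- function(x, labels) {
  inp <- check_index_input(x, labels)
  x <- inp$x; groups <- inp$groups
  k <- length(groups)
  cent <- do.call(rbind, lapply(groups, function(idx)
    colMeans(x[idx, , drop = FALSE])))
  S <- vapply(seq_len(k), function(i) {
    idx <- groups[[i]]
    mean(sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2, cent[i, ])^2)))
  }, 0)
  D <- as.matrix(dist(cent))
  if (any(D[upper.tri(D)] == 0))
    stop_validation("two groups share an identical centroid; the Davies-Bouldin ratio is undefined")
  R <- outer(S, S, "+") / D
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Dunn cluster validity index
#'
#' Ratio of the smallest between-group separation (single linkage: minimum
#' inter-point distance over all group pairs) to the largest within-group
#' diameter (complete diameter: maximum pairwise distance within a group).
#' Larger values indicate better separation; the index reflects only the
#' worst-case pair, not an average.
#'
#' @inheritParams davies_bouldin
#' @return the index value (non-negative).
#' @export
dunn_index <- function(x, labels) {
  inp <- check_index_input(x, labels)
  x <- inp$x; groups <- inp$groups
  D <- as.matrix(dist(x))
  gi <- rep(seq_along(groups), lengths(groups))
  ord <- unlist(groups, use.names = FALSE)
  gl <- integer(nrow(x)); gl[ord] <- gi
  same <- outer(gl, gl, "==")
  diam <- max(D[same & upper.tri(D)], 0)
  if (diam == 0)
    stop_validation("all groups are singletons (zero diameter); the Dunn ratio is undefined")
  sep <- min(D[!same])
  sep / diam
}

#' Benchmark grouping schemes by cluster-validity indices
#'
#' Scores every requested grouping of the cohort with the Davies-Bouldin and
#' Dunn indices computed on the two morphological features (lumen diameter,
#' wall thickness). Branching-based schemes are defined per tree, so they are
#' evaluated on each tree's own segments and reported as mean and standard
#' deviation over trees; the pooled mixture model is evaluated once on the
#' complete feature matrix of all trees and carries no SD.
#'
#' @param cohort an [airway_cohort()].
#' @param model optional [airway_gmm()] fit on the same cohort; adds the
#'   pooled `gmm` row.
#' @param methods branching-based schemes to score.
#' @return a `data.frame` of class `quality_report` with one row per method:
#'   `method`, `protocol`, `db_mean`, `db_sd`, `dunn_mean`, `dunn_sd`,
#'   `n_groups_mean`, `n_groups_sd`, `n_trees`.
#' @export
evaluate_groupings <- function(cohort, model = NULL,
                               methods = c("generations", "orders", "strahler")) {
  stopifnot(inherits(cohort, "airway_cohort"))
  rows <- list()
  for (m in methods) {
    db <- dunn <- ng <- numeric(0)
    for (tr in cohort) {
      g <- assign_groupings(tr, m)[[1]]
      x <- tr$segments[, c("lumen_diameter", "wall_thickness")]
      lab <- g$labels[tr$segments$segment_id]
      if (length(unique(lab)) < 2) {
        warning(sprintf("tree '%s': method %s yields < 2 groups; excluded",
                        tr$subject_id, m))
        next
      }
      db <- c(db, davies_bouldin(x, lab))
      dunn <- c(dunn, dunn_index(x, lab))
      ng <- c(ng, g$n_groups)
    }
    rows[[m]] <- data.frame(
      method = m, protocol = "per-tree",
      db_mean = mean(db), db_sd = if (length(db) > 1) sd(db) else NA_real_,
      dunn_mean = mean(dunn), dunn_sd = if (length(dunn) > 1) sd(dunn) else NA_real_,
      n_groups_mean = mean(ng), n_groups_sd = if (length(ng) > 1) sd(ng) else NA_real_,
      n_trees = length(db), stringsAsFactors = FALSE)
  }
  if (!is.null(model)) {
    stopifnot(inherits(model, "airway_gmm"))
    lab <- as.integer(model$classification)
    rows$gmm <- data.frame(
      method = "gmm", protocol = "pooled",
      db_mean = davies_bouldin(model$data, lab), db_sd = NA_real_,
      dunn_mean = dunn_index(model$data, lab), dunn_sd = NA_real_,
      n_groups_mean = model$k, n_groups_sd = NA_real_,
      n_trees = length(cohort), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("quality_report", "data.frame")
  out
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Grouping-scheme benchmark (Davies-Bouldin: lower is better;",
      "Dunn: higher is better)\n")
  fmt <- function(m, s) ifelse(is.na(s), sprintf("%.3g", m),
                               sprintf("%.3g (%.2g)", m, s))
  print(data.frame(method = x$method, protocol = x$protocol,
                   `DB (SD)` = fmt(x$db_mean, x$db_sd),
                   `Dunn (SD)` = fmt(x$dunn_mean, x$dunn_sd),
                   `groups (SD)` = fmt(x$n_groups_mean, x$n_groups_sd),
                   check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}
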