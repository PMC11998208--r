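# The central fitting function: BIC-selected Gaussian mixture on the
# (lumen diameter, wall thickness) plane, pooled over all trees of a cohort,
# with canonical CL1..CLk relabeling by descending lumen diameter.

#' Feature matrix for morphological clustering
#'
#' Extracts the two clustering features - lumen diameter and wall thickness,
#' both in micrometres and deliberately left on their raw scales - as one row
#' per segment, pooled over all trees of the cohort.
#'
#' @param cohort an [airway_cohort()] (or a single [airway_tree()]).
#' @return numeric matrix with columns `lumen_diameter`, `wall_thickness` and
#'   a `keys` attribute (`data.frame` of subject and segment ids).
#' @export
feature_matrix <- function(cohort) {
  if (inherits(cohort, "airway_tree")) cohort <- airway_cohort(list(cohort))
  stopifnot(inherits(cohort, "airway_cohort"))
  tab <- do.call(rbind, lapply(cohort, function(tr)
    data.frame(subject_id = tr$subject_id, segment_id = tr$segments$segment_id,
               lumen_diameter = tr$segments$lumen_diameter,
               wall_thickness = tr$segments$wall_thickness,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  if (any(is.na(tab$lumen_diameter)) || any(is.na(tab$wall_thickness)))
    stop_validation("feature matrix must not contain missing values")
  x <- as.matrix(tab[, c("lumen_diameter", "wall_thickness")])
  rownames(x) <- paste(tab$subject_id, tab$segment_id, sep = ":")
  attr(x, "keys") <- tab[, c("subject_id", "segment_id")]
  x
}

#' Morphology-based Gaussian-mixture clustering of airway segments
#'
#' Fits Gaussian mixture models on the pooled (lumen diameter, wall
#' thickness) feature matrix of a whole cohort for every combination of
#' component count in `k` and covariance family in `families`, scores each
#' with the Bayesian information criterion (convention
#' \eqn{2\log L - m\ln n}; higher is better) and returns the highest-scoring
#' model. Ties are broken toward fewer components, then toward the simpler
#' family. Components are then relabeled CL1..CLk in descending order of
#' mean lumen diameter, so CL1 is always the large central airway cluster and
#' CLk the smallest, most distal one.
#'
#' The mixture is fit once on the pooled segments of all trees; cluster
#' labels then map back to the individual trees. Clustering per tree (or per
#' treatment group, for pathologies that destroy the shared morphology) is
#' possible by passing a subset cohort.
#'
#' @param x an [airway_cohort()], [airway_tree()], or a two-column numeric
#'   matrix/data.frame of (lumen diameter, wall thickness) in micrometres.
#' @param k integer vector of component counts to scan (default 1..9).
#' @param families covariance families to scan (default all five, see
#'   [airway_families()]; ellipsoids of variable volume, shape and
#'   orientation are the `"full-free"` family).
#' @param standardize standardize features to unit variance before fitting
#'   (default `FALSE`: the model operates on raw micrometre scales).
#' @param seed integer seed; all EM restarts derive from it.
#' @param n_restarts EM restarts per (k, family) fit.
#' @param ... further arguments passed to [fit_gmm()].
#' @return an object of class `airway_gmm` with components `k`, `family`,
#'   `weights`, `means`, `covariances`, `loglik`, `n_params`, `bic`,
#'   `bic_table` (score of every scanned pair), `posterior`,
#'   `classification` (factor CL1..CLk), `data`, `keys`, `seed`.
#' @seealso [predict.airway_gmm()], [plot.airway_gmm()], [evaluate_groupings()]
#' @examples
#' \donttest{
#' coh <- generate_cohort(synthetic_config(seed = 1))
#' fit <- airway_gmm(coh$cohort, k = 1:6, families = "full-free", seed = 1)
#' summary(fit)
#' }
#' @export
airway_gmm <- function(x, k = 1:9, families = airway_families(),
                       standardize = FALSE, seed = 1, n_restarts = 10, ...) {
  keys <- NULL
  if (inherits(x, c("airway_cohort", "airway_tree"))) {
    x <- feature_matrix(x)
    keys <- attr(x, "keys")
  }
  x <- as.matrix(x)
  if (ncol(x) != 2) stop_validation("feature matrix must have two columns")
  if (nrow(x) < 2) stop_validation("need at least 2 segments to cluster")
  if (is.null(colnames(x))) colnames(x) <- c("lumen_diameter", "wall_thickness")
  scale_sd <- c(1, 1)
  if (standardize) {
    scale_sd <- apply(x, 2, sd)
    x <- sweep(x, 2, scale_sd, "/")
  }
  families <- match.arg(families, airway_families(), several.ok = TRUE)
  k <- sort(unique(as.integer(k)))
  if (length(k) == 0) stop_validation("k range must be nonempty")
  grid <- expand.grid(k = k, family = families, stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  errs <- character()
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- tryCatch(
      fit_gmm(x, grid$k[i], grid$family[i], seed = seed,
              n_restarts = n_restarts, ...),
      error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok))
    stop_validation("all (k, family) fits failed: %s", errs[1])
  bic_table <- data.frame(
    k = grid$k, family = grid$family,
    loglik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$loglik, 0),
    n_params = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$n_params, 0),
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, 0))
  # highest BIC wins; ties toward smaller k, then simpler (earlier) family
  fam_rank <- match(grid$family, airway_families())
  o <- order(-bic_table$bic, grid$k, fam_rank, na.last = TRUE)
  best <- fits[[o[1]]]
  obj <- structure(
    c(best[c("k", "family", "weights", "means", "covariances", "loglik",
             "n_params", "bic", "converged", "seed")],
      list(bic_table = bic_table, posterior = best$responsibilities,
           data = x, keys = keys, standardize = standardize,
           scale_sd = scale_sd, trace = best$trace,
           n = nrow(x), call = match.call())),
    class = "airway_gmm")
  canonical_relabel(obj)
}

#' Canonical CL1..CLk relabeling of mixture components
#'
#' Renames the components of a fitted mixture in strictly descending order of
#' their mean lumen diameter: CL1 is the cluster of the largest (central)
#' airways and CLk the smallest, most distal one. Exact ties in mean lumen
#' are broken by descending mean wall thickness, then by component index.
#' Idempotent and invariant to the order in which EM happened to produce the
#' components.
#'
#' @param object an `airway_gmm` fit.
#' @return the same fit with components reordered and named CL1..CLk.
#' @export
canonical_relabel <- function(object) {
  stopifnot(inherits(object, "airway_gmm"))
  m <- object$means
  o <- order(-m[, 1], -m[, 2], seq_len(object$k))
  lab <- paste0("CL", seq_len(object$k))
  object$weights <- object$weights[o]
  object$means <- object$means[o, , drop = FALSE]
  rownames(object$means) <- lab
  colnames(object$means) <- colnames(object$data)
  object$covariances <- object$covariances[, , o, drop = FALSE]
  dimnames(object$covariances) <- list(colnames(object$data),
                                       colnames(object$data), lab)
  names(object$weights) <- lab
  object$posterior <- object$posterior[, o, drop = FALSE]
  colnames(object$posterior) <- lab
  object$classification <- factor(lab[max.col(object$posterior)], levels = lab)
  object
}

# bivariate normal log-density with closed-form 2x2 inverse
dmvnorm2_log <- function(x, mu, sigma) {
  d1 <- x[, 1] - mu[1]; d2 <- x[, 2] - mu[2]
  s11 <- sigma[1, 1]; s22 <- sigma[2, 2]; s12 <- sigma[1, 2]
  det <- s11 * s22 - s12 * s12
  q <- (s22 * d1 * d1 - 2 * s12 * d1 * d2 + s11 * d2 * d2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Posterior responsibilities and cluster labels for new segments
#'
#' @param object an `airway_gmm` fit.
#' @param newdata two-column matrix/data.frame of (lumen diameter, wall
#'   thickness); defaults to the training data.
#' @param type `"classification"` (factor of CL labels) or `"posterior"`
#'   (matrix of responsibilities).
#' @param ... unused.
#' @return factor or matrix according to `type`.
#' @export
predict.airway_gmm <- function(object, newdata = NULL,
                               type = c("classification", "posterior"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data else {
    x <- as.matrix(newdata)
    if (object$standardize) x <- sweep(x, 2, object$scale_sd, "/")
    x
  }
  lg <- sapply(seq_len(object$k), function(j)
    log(object$weights[j]) + dmvnorm2_log(x, object$means[j, ],
                                          object$covariances[, , j]))
  lg <- matrix(lg, nrow = nrow(x))
  m <- lg[cbind(seq_len(nrow(x)), max.col(lg))]
  z <- exp(lg - m)
  z <- z / rowSums(z)
  colnames(z) <- rownames(object$means)
  if (type == "posterior") z
  else factor(rownames(object$means)[max.col(z)], levels = rownames(object$means))
}

#' @export
print.airway_gmm <- function(x, ...) {
  cat(sprintf("Airway GMM: %d components, '%s' covariance family\n",
              x$k, x$family))
  cat(sprintf("  n = %d segments, logLik = %.2f, BIC = %.2f (of %d scanned models)\n",
              x$n, x$loglik, x$bic, nrow(x$bic_table)))
  cat("  mean lumen diameter per cluster (um): ",
      paste(sprintf("%s=%.1f", rownames(x$means), x$means[, 1]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.airway_gmm <- function(object, ...) {
  comp <- data.frame(
    cluster = rownames(object$means),
    weight = object$weights,
    mean_lumen = object$means[, 1], mean_wall = object$means[, 2],
    sd_lumen = sqrt(object$covariances[1, 1, ]),
    sd_wall = sqrt(object$covariances[2, 2, ]),
    n_segments = as.vector(table(object$classification)),
    row.names = NULL)
  structure(list(k = object$k, family = object$family, n = object$n,
                 loglik = object$loglik, bic = object$bic,
                 components = comp, bic_table = object$bic_table,
                 seed = object$seed),
            class = "summary.airway_gmm")
}

#' @export
print.summary.airway_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture over %d airway segments\n", x$n))
  cat(sprintf("Selected by BIC: k = %d, family '%s' (BIC = %.2f, logLik = %.2f)\n\n",
              x$k, x$family, x$bic, x$loglik))
  print(x$components, digits = 4)
  cat("\nTop of the BIC table:\n")
  bt <- x$bic_table[order(-x$bic_table$bic), ]
  print(head(bt, 5), digits = 6, row.names = FALSE)
  invisible(x)
}

#' @export
coef.airway_gmm <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       covariances = object$covariances)
}

#' @export
logLik.airway_gmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Draw segments from a fitted mixture
#'
#' @param object an `airway_gmm` fit.
#' @param nsim number of segments to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return a `data.frame` with the two features and the generating cluster.
#' @export
simulate.airway_gmm <- function(object, nsim = 1, seed = 1, ...) {
  with_seed(seed, {
    comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
    out <- t(vapply(comp, function(j) {
      L <- chol(object$covariances[, , j])
      object$means[j, ] + as.vector(t(L) %*% rnorm(2))
    }, numeric(2)))
    colnames(out) <- colnames(object$data)
    data.frame(out, cluster = rownames(object$means)[comp])
  })
}

# ellipse polygon at a given Mahalanobis radius
cov_ellipse <- function(mu, sigma, radius = sqrt(qchisq(0.68, 2)), n = 120) {
  ang <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(cos(ang), sin(ang)) * radius
  t(mu + t(circ %*% chol(sigma)))
}

#' Scatter plot of the clustered morphology plane
#'
#' Plots all segments in the (lumen diameter, wall thickness) plane, colored
#' by assigned cluster, with an ellipse per component marking the center and
#' orientation of the underlying Gaussian.
#'
#' @param x an `airway_gmm` fit.
#' @param ellipse_level probability mass enclosed by each ellipse.
#' @param pch,cex plotting parameters for the points.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @importFrom graphics lines legend points
#' @importFrom stats qchisq
#' @importFrom grDevices hcl.colors
#' @export
plot.airway_gmm <- function(x, ellipse_level = 0.68, pch = 16, cex = 0.5, ...) {
  cols <- grDevices::hcl.colors(max(x$k, 2), "Dark 3")[seq_len(x$k)]
  ci <- as.integer(x$classification)
  graphics::plot(x$data[, 1], x$data[, 2], col = cols[ci], pch = pch, cex = cex,
                 xlab = "Lumen diameter (um)", ylab = "Wall thickness (um)", ...)
  r <- sqrt(qchisq(ellipse_level, 2))
  for (j in seq_len(x$k)) {
    e <- cov_ellipse(x$means[j, ], x$covariances[, , j], r)
    lines(e[, 1], e[, 2], col = cols[j], lwd = 2)
    points(x$means[j, 1], x$means[j, 2], col = cols[j], pch = 3, cex = 1.4)
  }
  legend("topright", legend = rownames(x$means), col = cols, pch = pch, bty = "n")
  invisible(x)
}
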