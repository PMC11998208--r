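# Gaussian-mixture machinery: covariance families, BIC, seeded multi-restart
# EM (inner loop in C++, see src/em.cpp).

#' Covariance families of the mixture model
#'
#' The scanned model grid approximates the classical mixture-model family
#' hierarchy for bivariate data:
#' \describe{
#'   \item{spherical-shared}{one spherical covariance for all components}
#'   \item{spherical-free}{per-component spherical covariance}
#'   \item{diagonal-free}{per-component diagonal covariance}
#'   \item{full-shared}{one unrestricted covariance for all components}
#'   \item{full-free}{per-component unrestricted covariance - ellipsoids of
#'     variable volume, shape and orientation}
#' }
#' Families are ordered from simplest to most flexible; BIC ties are broken
#' toward the simpler family.
#'
#' @return character vector of family names.
#' @export
airway_families <- function() {
  c("spherical-shared", "spherical-free", "diagonal-free",
    "full-shared", "full-free")
}

family_code <- function(family) {
  match(match.arg(family, airway_families()), airway_families())
}

# free parameters of a k-component bivariate mixture under a family
gmm_n_parameters <- function(k, family, d = 2) {
  cov_pars <- switch(match.arg(family, airway_families()),
    "spherical-shared" = 1,
    "spherical-free"   = k,
    "diagonal-free"    = k * d,
    "full-shared"      = d * (d + 1) / 2,
    "full-free"        = k * d * (d + 1) / 2)
  (k - 1) + k * d + cov_pars
}

#' Bayesian information criterion score
#'
#' Uses the convention \eqn{\mathrm{BIC} = 2\,\log L - m\,\ln n} under which
#' the best model attains the \emph{highest} score.
#'
#' @param log_likelihood maximized log-likelihood of the model.
#' @param n_parameters number of free parameters \eqn{m}.
#' @param n_observations number of observations \eqn{n} (must be at least 2).
#' @return the BIC score (higher is better).
#' @export
bic_score <- function(log_likelihood, n_parameters, n_observations) {
  if (n_observations < 2)
    stop_validation("BIC needs at least 2 observations")
  2 * log_likelihood - n_parameters * log(n_observations)
}

# deterministic RNG scope: runs expr under a seed, restores the RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a stream of sub-seeds below 2^31 from one seed
sub_seed <- function(seed, i) {
  (as.double(seed %% 2147483647L) * 48271 + i * 8191) %% 2147483647
}

# hard-assignment one-hot responsibilities from integer cluster labels
one_hot <- function(cl, k, n) {
  z <- matrix(0, n, k)
  z[cbind(seq_len(n), cl)] <- 1
  z
}

# initial responsibilities for one restart: the first restart uses k-means,
# later restarts assign points to k randomly chosen distinct rows
gmm_init <- function(x, k, restart, seed) {
  n <- nrow(x)
  if (k == 1) return(matrix(1, n, 1))
  with_seed(sub_seed(seed, restart), {
    km <- if (restart == 1)
      tryCatch(suppressWarnings(kmeans(x, centers = k, nstart = 1, iter.max = 20)),
               error = function(e) NULL) # fewer distinct points than centers
    else NULL
    if (!is.null(km)) {
      one_hot(km$cluster, k, n)
    } else {
      centers <- x[sample.int(n, k), , drop = FALSE]
      d2 <- sapply(seq_len(k), function(j)
        (x[, 1] - centers[j, 1])^2 + (x[, 2] - centers[j, 2])^2)
      cl <- max.col(-d2)
      # every component must start non-empty
      for (j in seq_len(k)) if (!any(cl == j)) cl[which.max(d2[, j] == min(d2[, j]))] <- j
      one_hot(cl, k, n)
    }
  })
}

#' Fit one Gaussian mixture by seeded multi-restart EM
#'
#' Fits a `k`-component bivariate Gaussian mixture to the feature matrix by
#' expectation-maximization, restarted `n_restarts` times from different
#' seeded initializations (k-means for the first restart, random centers
#' after that); the restart with the highest log-likelihood is kept. A
#' covariance floor of `floor_factor` times each feature's variance prevents
#' singular (degenerate) solutions. Deterministic given `seed`.
#'
#' @param x numeric matrix with two columns (lumen diameter and wall
#'   thickness, micrometres).
#' @param k number of mixture components (at least 1, at most `nrow(x)`).
#' @param family covariance family, see [airway_families()].
#' @param seed integer seed controlling all restarts.
#' @param n_restarts number of EM restarts (default 10).
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood improvement below which EM stops.
#' @param floor_factor covariance floor as a fraction of feature variance.
#' @return a list with elements `k`, `family`, `weights`, `means` (k x 2),
#'   `covariances` (2 x 2 x k), `loglik`, `trace` (per-iteration
#'   log-likelihood of the winning restart), `responsibilities`, `n_params`,
#'   `bic`, `converged`, `seed`.
#' @export
fit_gmm <- function(x, k, family = "full-free", seed = 1, n_restarts = 10,
                    max_iter = 500, tol = 1e-8, floor_factor = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k < 1) stop_validation("k must be at least 1")
  if (k > n) stop_validation("k = %d exceeds the number of rows (%d)", k, n)
  fam <- match.arg(family, airway_families())
  code <- family_code(fam)
  # variance floor; the additive term keeps degenerate (zero-variance) data
  # fittable without crashing
  floor_diag <- pmax(floor_factor * apply(x, 2, var),
                     1e-10 * (1 + colMeans(x)^2))
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    z0 <- gmm_init(x, k, r, seed)
    fit <- em_gmm_cpp(x, z0, code, as.integer(max_iter), tol, floor_diag)
    if (fit$status != 0) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop_validation("EM failed for k = %d, family '%s' (degenerate data?)", k, fam)
  if (!best$converged)
    warning(sprintf("EM did not converge within %d iterations (k = %d, %s); best iterate returned",
                    max_iter, k, fam))
  m <- gmm_n_parameters(k, fam)
  list(k = k, family = fam, weights = as.vector(best$weights),
       means = t(best$means), covariances = best$covariances,
       loglik = best$loglik, trace = as.vector(best$trace),
       responsibilities = best$responsibilities,
       n_params = m, bic = bic_score(best$loglik, m, n),
       converged = best$converged, seed = seed)
}
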