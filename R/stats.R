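# Two-group nonparametric comparisons: Mann-Whitney U with exact small-sample
# p-values, rank-based effect size r with Cohen interpretation, significance
# stars, and the global + per-cluster comparison tables.

#' Mann-Whitney U test for two independent samples
#'
#' Computes the U statistic of the first sample from rank sums with midranks
#' for ties. For small tie-free samples (both sizes at most 8) the two-sided
#' p-value is exact (from the full null distribution of U); otherwise the
#' normal approximation with tie-corrected variance and continuity correction
#' is used. The standardized statistic Z is always computed from the
#' tie-corrected normal approximation \emph{without} continuity correction,
#' because it feeds the rank-based effect size \eqn{r = |Z|/\sqrt{N}}.
#'
#' @param a,b numeric samples (both nonempty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   `NULL` (default) chooses exact when both sizes are at most 8 and there
#'   are no ties.
#' @return a list with `U` (for sample `a`), `Z`, `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`), `n_a`, `n_b`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0)
    stop_validation("both samples must be nonempty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  N <- n_a + n_b
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  mu <- n_a * n_b / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n_a * n_b / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) { # all observations identical in both samples
    return(list(U = mu, Z = 0, p = 1, method = "degenerate",
                n_a = n_a, n_b = n_b))
  }
  sigma <- sqrt(sigma2)
  Z <- (U - mu) / sigma
  use_exact <- if (is.null(exact)) (n_a <= 8 && n_b <= 8 && !has_ties) else exact
  if (use_exact && has_ties)
    stop_validation("exact p-values are only available without ties")
  if (use_exact) {
    p <- 2 * min(pwilcox(U, n_a, n_b), 1 - pwilcox(U - 1, n_a, n_b))
    method <- "exact"
  } else {
    cc <- max(abs(U - mu) - 0.5, 0) # continuity correction
    p <- 2 * pnorm(-cc / sigma)
    method <- "normal"
  }
  list(U = U, Z = Z, p = min(p, 1), method = method, n_a = n_a, n_b = n_b)
}

#' Rank-based effect size r
#'
#' The correlation-scaled effect size for rank tests,
#' \eqn{r = |Z| / \sqrt{N}} with \eqn{N} the total number of observations,
#' clipped to \[0, 1\].
#'
#' @param Z standardized test statistic.
#' @param n_total total number of observations across both groups (at
#'   least 2).
#' @return effect size r in \[0, 1\].
#' @export
effect_r <- function(Z, n_total) {
  if (n_total < 2) stop_validation("effect size needs at least 2 observations")
  min(abs(Z) / sqrt(n_total), 1)
}

#' Cohen interpretation of effect size r
#'
#' Benchmarks 0.1 / 0.3 / 0.5 with half-open intervals: r below 0.1 is "none"
#' (no effect), then "small" below 0.3, "medium" below 0.5, and "large" from
#' 0.5 upward. Boundary values belong to the higher category (r = 0.3 is
#' "medium").
#'
#' @param r effect size in \[0, 1\].
#' @return one of `"none"`, `"small"`, `"medium"`, `"large"`.
#' @export
cohen_category <- function(r) {
  if (is.na(r) || r < 0 || r > 1)
    stop_validation("effect size r must lie in [0, 1]")
  if (r < 0.1) "none" else if (r < 0.3) "small" else if (r < 0.5) "medium" else "large"
}

#' Significance stars for a p-value
#'
#' The star code used in the figures and tables: `ns` for p > 0.05, `*` for
#' p <= 0.05, `**` for p <= 0.01, `***` for p <= 0.001 and `****` for
#' p <= 0.0001 (boundaries inclusive).
#'
#' @param p p-value in \[0, 1\] (`NA` yields `"-"`).
#' @return character star code.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("-")
    stopifnot(pi >= 0, pi <= 1)
    if (pi > 0.05) "ns"
    else if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 1e-2) "**"
    else "*"
  }, "")
}

#' Global and per-cluster two-group comparisons
#'
#' For each requested parameter, compares the two treatment groups globally
#' (all segments pooled) and within every cluster scope, using the
#' Mann-Whitney U test with the rank-based effect size r. Group summaries
#' report mean, SD, median and n. Observations enter as collected - no
#' outlier removal - and segments with a missing parameter value are skipped
#' (counts reported via `n_skipped`). Effect categories are reported only for
#' significant rows (p <= 0.05); non-significant rows carry `"-"`, matching
#' the table convention of the underlying study design. No multiple-testing
#' correction is applied by default (raw per-scope p-values); set
#' `p_adjust = "holm"` to adjust within each parameter.
#'
#' @param data a segment table ([segment_table()]) or any `data.frame` with a
#'   `group` column, the parameter columns, and a cluster-label column.
#' @param parameters character vector of parameter column names to compare.
#' @param cluster name of the cluster-label column (default `"cluster"`), or
#'   a vector of labels with one entry per row of `data`.
#' @param groups length-2 character vector naming the two groups, first the
#'   treated group; defaults to `c("HYX", "NOX")` when present, otherwise the
#'   sorted group levels.
#' @param scopes scopes to compare; default `"Global"` plus every cluster
#'   label.
#' @param p_adjust `"none"` (default) or a method of [stats::p.adjust()]
#'   applied per parameter across scopes.
#' @param verbose log skipped-observation counts per parameter.
#' @return a `data.frame` of class `airway_comparison`: one row per
#'   (parameter, scope) with group summaries, `U`, `Z`, `p`, `effect_r`,
#'   `effect_category`, `stars`, `computable`, `n_skipped`.
#' @export
compare_groups <- function(data, parameters, cluster = "cluster",
                           groups = NULL, scopes = NULL, p_adjust = "none",
                           verbose = FALSE) {
  stopifnot(is.data.frame(data), "group" %in% names(data))
  lab <- if (length(cluster) == 1 && is.character(cluster) &&
               cluster %in% names(data)) data[[cluster]]
         else if (length(cluster) == nrow(data)) as.vector(cluster)
         else stop_validation("cluster labels not found")
  lab <- as.character(lab)
  if (is.null(groups)) {
    lev <- sort(unique(as.character(data$group)))
    groups <- if (all(c("HYX", "NOX") %in% lev)) c("HYX", "NOX") else lev
  }
  if (length(groups) != 2)
    stop_validation("compare_groups needs exactly two groups (got %d)",
                    length(groups))
  if (is.null(scopes))
    scopes <- c("Global", sort(unique(lab[!is.na(lab)])))
  missing_par <- setdiff(parameters, names(data))
  if (length(missing_par) > 0)
    stop_validation("parameter column(s) not in data: %s",
                    paste(missing_par, collapse = ", "))
  rows <- list()
  for (par in parameters) {
    v <- data[[par]]
    if (verbose) {
      n_na <- sum(is.na(v))
      if (n_na > 0)
        message(sprintf("compare_groups: %s: skipping %d segments with missing values",
                        par, n_na))
    }
    for (sc in scopes) {
      in_scope <- if (sc == "Global") rep(TRUE, nrow(data)) else !is.na(lab) & lab == sc
      va <- v[in_scope & data$group == groups[1]]
      vb <- v[in_scope & data$group == groups[2]]
      n_skipped <- sum(is.na(va)) + sum(is.na(vb))
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      row <- data.frame(parameter = par, scope = sc,
                        group_a = groups[1], group_b = groups[2],
                        n_a = length(va), n_b = length(vb),
                        mean_a = NA_real_, sd_a = NA_real_, median_a = NA_real_,
                        mean_b = NA_real_, sd_b = NA_real_, median_b = NA_real_,
                        U = NA_real_, Z = NA_real_, p = NA_real_,
                        effect_r = NA_real_, effect_category = "-",
                        stars = "-", computable = FALSE,
                        n_skipped = n_skipped, stringsAsFactors = FALSE)
      if (length(va) > 0) {
        row$mean_a <- mean(va); row$sd_a <- sd(va); row$median_a <- median(va)
      }
      if (length(vb) > 0) {
        row$mean_b <- mean(vb); row$sd_b <- sd(vb); row$median_b <- median(vb)
      }
      if (length(va) >= 1 && length(vb) >= 1) {
        mw <- mann_whitney_u(va, vb)
        row$U <- mw$U; row$Z <- mw$Z; row$p <- mw$p
        row$effect_r <- effect_r(mw$Z, length(va) + length(vb))
        row$computable <- TRUE
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    for (par in parameters) {
      i <- out$parameter == par
      out$p[i] <- stats::p.adjust(out$p[i], method = p_adjust)
    }
  }
  out$stars <- significance_stars(out$p)
  sig <- !is.na(out$p) & out$p <= 0.05
  out$effect_category[sig] <- vapply(out$effect_r[sig], cohen_category, "")
  rownames(out) <- NULL
  class(out) <- c("airway_comparison", "data.frame")
  out
}

#' @export
print.airway_comparison <- function(x, ...) {
  need <- c("parameter", "scope", "group_a", "group_b", "mean_a", "sd_a",
            "mean_b", "sd_b", "stars", "effect_category")
  if (!all(need %in% names(x))) return(print.data.frame(x, ...))
  cat(sprintf("Two-group comparison: %s vs %s (Mann-Whitney U, effect size r)\n",
              x$group_a[1], x$group_b[1]))
  tab <- data.frame(
    Parameter = x$parameter, Cluster = x$scope,
    `Mean A (SD)` = sprintf("%.2f (%.2f)", x$mean_a, x$sd_a),
    `Mean B (SD)` = sprintf("%.2f (%.2f)", x$mean_b, x$sd_b),
    `p` = x$stars, `Effect` = x$effect_category, check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}
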