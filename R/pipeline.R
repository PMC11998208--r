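# End-to-end workflow: ingest or simulate a cohort, assign branching-based
# groupings, fit the BIC-selected mixture, benchmark the schemes, and run the
# global + per-cluster group comparisons. All outputs are deterministic given
# (configuration, seed).

#' Run the full airway-compartment analysis
#'
#' Executes the complete workflow: read a segment table (or generate a
#' synthetic cohort), assign generations / orders / Strahler orders per tree,
#' fit the pooled Gaussian mixture with BIC model selection and canonical
#' relabeling, score all grouping schemes with the Davies-Bouldin and Dunn
#' indices, and compare the two treatment groups globally and per cluster for
#' every morphometric and epithelial parameter present.
#'
#' @param input path to a delimited segment table; `NULL` to simulate.
#' @param config a [synthetic_config()] used when `input` is `NULL`; default
#'   `synthetic_config(seed = seed)`.
#' @param out_dir directory for report files (created); `NULL` writes
#'   nothing.
#' @param seed master seed for simulation and model fitting.
#' @param k,families model-selection grid, see [airway_gmm()].
#' @param methods branching-based baselines to score.
#' @param parameters parameter columns to compare; default: all morphometric
#'   and epithelial parameters with data.
#' @param dialect column map for `input`, see [default_dialect()].
#' @param n_restarts EM restarts per model fit.
#' @param figures write figures (scatter with ellipses, per-parameter
#'   boxplots) when exporting.
#' @param verbose log per-stage progress and row counts.
#' @return an object of class `airway_run`: `cohort`, `truth` (synthetic
#'   only), `fit` (the [airway_gmm()]), `table` (segment table with labels),
#'   `quality`, `comparisons`, `seed`, `version`, `config_hash`.
#' @export
run_pipeline <- function(input = NULL, config = NULL, out_dir = NULL,
                         seed = 1, k = 1:9, families = airway_families(),
                         methods = c("generations", "orders", "strahler"),
                         parameters = NULL, dialect = default_dialect(),
                         n_restarts = 10, figures = TRUE, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  truth <- NULL
  if (is.null(input)) {
    if (is.null(config)) config <- synthetic_config(seed = seed)
    say("stage simulate: generating synthetic cohort (seed %d)", config$seed)
    gen <- generate_cohort(config)
    cohort <- gen$cohort; truth <- gen$truth
  } else {
    say("stage read: %s", input)
    cohort <- read_segment_table(input, dialect)
    config <- NULL
  }
  nseg <- sum(vapply(cohort, function(tr) nrow(tr$segments), 0L))
  say("stage read/simulate: %d trees, %d segments", length(cohort), nseg)

  say("stage grouping: generations, orders, Strahler orders per tree")
  for (sid in names(cohort)) {
    gr <- assign_groupings(cohort[[sid]], methods)
    for (m in names(gr)) {
      lab <- gr[[m]]$labels[cohort[[sid]]$segments$segment_id]
      col <- c(generations = "generation", orders = "order",
               strahler = "strahler")[[m]]
      cohort[[sid]]$segments[[col]] <- unname(lab)
    }
  }

  say("stage clustering: GMM grid k = %s, %d families",
      paste(range(k), collapse = ".."), length(families))
  fit <- airway_gmm(cohort, k = k, families = families, seed = seed,
                    n_restarts = n_restarts)
  say("stage clustering: selected k = %d, family '%s'", fit$k, fit$family)

  say("stage quality: validity indices per grouping scheme")
  quality <- evaluate_groupings(cohort, fit, methods)

  tab <- segment_table(cohort)
  for (col in intersect(c("generation", "order", "strahler"), names(cohort[[1]]$segments)))
    tab[[col]] <- unlist(lapply(cohort, function(tr) tr$segments[[col]]),
                         use.names = FALSE)
  stopifnot(identical(paste(tab$subject_id, tab$segment_id),
                      paste(fit$keys$subject_id, fit$keys$segment_id)))
  tab$cluster <- as.character(fit$classification)
  if (is.null(parameters)) {
    cand <- c("lumen_diameter", "wall_thickness", "epithelium_height",
              "cilium_length", "density", "pct_ciliated", "pct_goblet",
              "pct_basal", "pct_club", "pct_other")
    parameters <- cand[vapply(cand, function(p)
      p %in% names(tab) && any(!is.na(tab[[p]])), TRUE)]
  }
  say("stage comparison: %d parameters x %d scopes", length(parameters),
      1L + fit$k)
  comparisons <- compare_groups(tab, parameters, cluster = "cluster",
                                verbose = verbose)

  run <- structure(
    list(cohort = cohort, truth = truth, fit = fit, table = tab,
         quality = quality, comparisons = comparisons,
         parameters = parameters, seed = seed, config = config,
         version = as.character(packageVersion("airwayclust")),
         config_hash = if (is.null(config)) NA_character_ else config_hash(config)),
    class = "airway_run")
  if (!is.null(out_dir)) export_report(run, out_dir, figures = figures)
  run
}

#' @export
print.airway_run <- function(x, ...) {
  cat(sprintf("Airway analysis run (airwayclust %s, seed %d)\n", x$version,
              x$seed))
  print(x$fit)
  cat("\n")
  print(x$quality)
  invisible(x)
}

provenance_line <- function(run) {
  sprintf("# airwayclust %s | seed %d | config %s", run$version, run$seed,
          ifelse(is.na(run$config_hash), "external-input", run$config_hash))
}

write_csv_stamped <- function(df, path, run) {
  con <- file(path, open = "wb") # binary mode: identical bytes on any OS
  on.exit(close(con))
  writeLines(provenance_line(run), con)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) {
    v <- sprintf("%.12g", df[[j]])
    v[is.na(df[[j]])] <- "NA"
    df[[j]] <- v
  }
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the tables, model and figures of a run
#'
#' Writes `segments.csv` (per-segment table with all labels),
#' `quality.csv` (validity-index benchmark in the method-per-row layout),
#' `comparisons.csv` (global and per-cluster group comparison in the
#' parameter/cluster/means/p/effect layout), `model.json` (mixture
#' parameters and the full BIC table) and `run_info.json`. With
#' `figures = TRUE` also writes `scatter_clusters.png` (feature plane with
#' cluster ellipses) and one `boxplot_<parameter>.png` per compared
#' parameter (1.5 IQR whiskers, significance stars per scope). Every file
#' carries the package version, seed and configuration hash; reruns with the
#' same configuration are byte-identical for all text outputs.
#'
#' @param run an `airway_run` from [run_pipeline()].
#' @param out_dir output directory (created recursively).
#' @param figures write PNG figures as well?
#' @return `out_dir`, invisibly.
#' @export
export_report <- function(run, out_dir, figures = TRUE) {
  stopifnot(inherits(run, "airway_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_stamped(run$table, file.path(out_dir, "segments.csv"), run)

  q <- run$quality
  qual <- data.frame(Algorithm = q$method, Protocol = q$protocol,
                     `Davies-Bouldin index` = q$db_mean, `DB SD` = q$db_sd,
                     `Dunn index` = q$dunn_mean, `Dunn SD` = q$dunn_sd,
                     Clusters = q$n_groups_mean, `Clusters SD` = q$n_groups_sd,
                     check.names = FALSE)
  write_csv_stamped(qual, file.path(out_dir, "quality.csv"), run)

  cm <- run$comparisons
  comp <- data.frame(Parameter = cm$parameter, Cluster = cm$scope,
                     `Mean A` = cm$mean_a, `SD A` = cm$sd_a,
                     `Median A` = cm$median_a, `n A` = cm$n_a,
                     `Mean B` = cm$mean_b, `SD B` = cm$sd_b,
                     `Median B` = cm$median_b, `n B` = cm$n_b,
                     U = cm$U, Z = cm$Z, `p-value` = cm$p,
                     `Effect r` = cm$effect_r,
                     `Effect strength` = cm$effect_category,
                     Significance = cm$stars, check.names = FALSE)
  names(comp) <- sub("A$", cm$group_a[1], names(comp))
  names(comp) <- sub("B$", cm$group_b[1], names(comp))
  write_csv_stamped(comp, file.path(out_dir, "comparisons.csv"), run)

  fit <- run$fit
  model <- list(package = "airwayclust", version = run$version,
                seed = run$seed, config_hash = run$config_hash,
                k = fit$k, family = fit$family, loglik = fit$loglik,
                bic = fit$bic, weights = as.list(fit$weights),
                means = apply(fit$means, 1, as.list),
                covariances = lapply(seq_len(fit$k), function(j)
                  fit$covariances[, , j]),
                bic_table = fit$bic_table)
  jsonlite::write_json(model, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  info <- list(package = "airwayclust", version = run$version,
               seed = run$seed, config_hash = run$config_hash,
               n_trees = length(run$cohort),
               n_segments = nrow(run$table),
               groups = as.list(table(run$table$group)),
               parameters = run$parameters)
  if (!is.null(run$config))
    info$config <- unclass_recursive(run$config)
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (figures) {
    grDevices::png(file.path(out_dir, "scatter_clusters.png"),
                   width = 900, height = 700)
    plot(fit, main = "Morphological clusters (pooled cohort)")
    grDevices::dev.off()
    for (par in run$parameters) {
      grDevices::png(file.path(out_dir, sprintf("boxplot_%s.png", par)),
                     width = 1000, height = 600)
      plot_group_boxes(run$table, par, run$comparisons)
      grDevices::dev.off()
    }
  }
  invisible(out_dir)
}

# Global + per-cluster grouped boxplot with significance stars
plot_group_boxes <- function(tab, parameter, comparisons) {
  cm <- comparisons[comparisons$parameter == parameter, ]
  scopes <- cm$scope
  groups <- c(cm$group_a[1], cm$group_b[1])
  vals <- list(); at <- numeric(0); cols <- character(0); pos <- 0
  for (sc in scopes) {
    keep <- if (sc == "Global") rep(TRUE, nrow(tab)) else tab$cluster == sc
    for (gi in 1:2) {
      pos <- pos + 1
      vals[[pos]] <- tab[[parameter]][keep & tab$group == groups[gi]]
      at[pos] <- pos + (match(sc, scopes) - 1) # gap between scope blocks
      cols[pos] <- c("#D55E00", "#0072B2")[gi]
    }
  }
  ylim <- range(unlist(vals), na.rm = TRUE)
  ylim[2] <- ylim[2] + 0.12 * diff(ylim)
  graphics::boxplot(vals, at = at, col = cols, range = 1.5, outline = TRUE,
                    pch = 16, cex = 0.4, names = NA, ylim = ylim,
                    ylab = parameter, xaxt = "n",
                    main = sprintf("%s by scope (%s vs %s)", parameter,
                                   groups[1], groups[2]))
  centers <- tapply(at, rep(scopes, each = 2), mean)[scopes]
  graphics::axis(1, at = centers, labels = scopes)
  for (i in seq_along(scopes)) {
    graphics::text(centers[i], ylim[2] - 0.04 * diff(ylim), cm$stars[i],
                   cex = 1.1)
  }
  graphics::legend("topright", legend = groups, fill = c("#D55E00", "#0072B2"),
                   bty = "n")
}
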