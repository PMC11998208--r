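# Seeded generator of synthetic monopodial airway cohorts with known
# morphological archetypes and known treatment effects. The generator is the
# validation bed for the clustering and comparison machinery: every segment
# carries its generating archetype, so cluster recovery, method ranking and
# effect recovery can be scored against ground truth.

#' Default morphological archetypes of the synthetic cohort
#'
#' Five archetypes mirror the canonical cluster characterization of a
#' monopodial airway tree, in descending lumen diameter: CL1 the large
#' central (trunk) airway, CL2 medium airways distal of the large ones, CL3
#' small airways with larger diameter and the thinnest walls of the small
#' group, CL4 small airways of medium diameter, and CL5 the smallest, most
#' distal segments with the highest spread in wall thickness. Lumen/wall
#' moments are free modelling parameters (no published per-cluster values
#' exist) chosen once so that the five clusters form overlapping but
#' recoverable ellipses on the micrometre scale; epithelium parameters
#' follow the magnitudes reported for healthy (normoxic) rabbit airways.
#' Goblet-cell probability is nonzero only for the two large-airway
#' archetypes, where goblet cells are actually observed in rabbits.
#'
#' @return a `data.frame` with one row per archetype: morphology moments
#'   (means, SDs, lumen-wall correlation), epithelium parameters (height,
#'   cilium length, nuclear density per mm) and cell-category probabilities.
#' @export
default_archetypes <- function() {
  a <- data.frame(
    name = paste0("CL", 1:5),
    role = c("trunk", "medium", "small-a", "small-b", "small-terminal"),
    lumen_mean = c(500, 240, 120, 80, 38),
    wall_mean = c(24, 14, 6.5, 9.0, 8.6),
    lumen_sd = c(120, 55, 16, 9.5, 6.5),
    wall_sd = c(6, 3.4, 0.9, 1.0, 2.8),
    cor = c(0.10, 0.15, 0.20, 0.20, 0.10),
    height_mean = c(9.6, 8.4, 7.5, 7.4, 7.8),
    height_sd = c(1.6, 1.4, 1.2, 1.3, 1.2),
    cilium_mean = c(7.2, 6.2, 5.6, 5.2, 5.3),
    cilium_sd = c(1.3, 1.3, 1.2, 1.2, 1.0),
    density = c(136, 117, 116, 111, 108),
    p_ciliated = c(0.540, 0.480, 0.460, 0.450, 0.420),
    p_goblet = c(0.006, 0.001, 0.000, 0.000, 0.000),
    p_basal = c(0.036, 0.025, 0.017, 0.013, 0.012),
    p_club = c(0.410, 0.490, 0.520, 0.535, 0.565),
    p_other = c(0.008, 0.004, 0.003, 0.002, 0.001),
    stringsAsFactors = FALSE)
  pc <- c("p_ciliated", "p_goblet", "p_basal", "p_club", "p_other")
  a[pc] <- a[pc] / rowSums(a[pc])
  a
}

#' Default treatment (hyperoxia-style) effect structure
#'
#' Multiplicative shifts applied to the treated group's archetype parameters
#' before sampling, reproducing the qualitative effect pattern of the
#' hyperoxia disease model: smaller lumen and thicker walls confined to the
#' large-airway archetypes (CL1, CL2), taller epithelium and shorter cilia
#' across all airways, and a mildly lower nuclear density everywhere.
#'
#' @param lumen_mult,wall_mult,height_mult,cilium_mult,density_mult named (or
#'   recycled) per-archetype multipliers.
#' @return an object of class `group_effect`.
#' @export
default_group_effect <- function(lumen_mult = c(0.8, 0.8, 1, 1, 1),
                                 wall_mult = c(1.2, 1.2, 1, 1, 1),
                                 height_mult = rep(1.3, 5),
                                 cilium_mult = rep(0.85, 5),
                                 density_mult = rep(0.9, 5)) {
  expand <- function(v) {
    v <- rep_len(v, 5)
    names(v) <- paste0("CL", 1:5)
    v
  }
  structure(list(lumen_mult = expand(lumen_mult), wall_mult = expand(wall_mult),
                 height_mult = expand(height_mult),
                 cilium_mult = expand(cilium_mult),
                 density_mult = expand(density_mult)),
            class = "group_effect")
}

#' Configuration of the synthetic cohort generator
#'
#' The default configuration emulates a typical small-animal hyperoxia
#' experiment: two subjects per group (normoxia NOX vs hyperoxia HYX), one
#' monopodial tree
#' per subject with a long central trunk of `trunk_length` segments whose
#' lateral daughters root progressively smaller monopodial subtrees, for a
#' total on the order of 700 segments per group.
#'
#' @param n_subjects trees per group.
#' @param groups the two group labels.
#' @param treated which group receives the `effect`.
#' @param trunk_length number of segments of the central (CL1) trunk.
#' @param branch_q length-2 numeric `(q0, q1)`: a lateral at relative trunk
#'   position `p` roots a subtree whose caliber is one step smaller than its
#'   trunk's plus `Binomial(2, q0 + q1 p)` extra steps, so proximal laterals
#'   carry deep subtrees and distal laterals shallow ones - the hallmark of
#'   monopodial branching.
#' @param archetypes archetype table, see [default_archetypes()].
#' @param effect a [default_group_effect()] or `NULL` for a null cohort.
#' @param epithelium sample epithelium profiles for every segment?
#' @param ruler_length epithelium counting-ruler length, micrometres.
#' @param seed mandatory integer seed; the generator is fully deterministic
#'   given the configuration.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 2, groups = c("NOX", "HYX"),
                             treated = "HYX", trunk_length = 26,
                             branch_q = c(0.35, 0.5),
                             archetypes = default_archetypes(),
                             effect = default_group_effect(),
                             epithelium = TRUE, ruler_length = 100,
                             seed = 1) {
  stopifnot(n_subjects >= 1, trunk_length >= 2, length(groups) == 2,
            treated %in% groups, length(branch_q) == 2,
            is.numeric(seed), length(seed) == 1, !is.na(seed))
  stopifnot(all(archetypes$lumen_sd > 0), all(archetypes$wall_sd > 0),
            all(abs(archetypes$cor) < 1))
  structure(list(n_subjects = as.integer(n_subjects), groups = groups,
                 treated = treated, trunk_length = as.integer(trunk_length),
                 branch_q = branch_q,
                 archetypes = archetypes, effect = effect,
                 epithelium = epithelium, ruler_length = ruler_length,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# trunk lengths per caliber 1..4; caliber 5 segments are terminal leaves
trunk_lengths <- function(config) c(config$trunk_length, 6, 4, 2)

#' Generate one monopodial airway tree (topology and archetype tags)
#'
#' Builds a rooted monopodial tree: a central trunk whose every segment
#' spawns one lateral daughter subtree, itself a smaller monopodial trunk,
#' down to terminal segments. Lateral subtree depth decreases stochastically
#' toward the trunk tip (see `branch_q` in [synthetic_config()]). Each
#' segment is tagged with the archetype of its caliber class (trunk = CL1,
#' first-level laterals = CL2, ..., terminals = CL5). Morphology is not yet
#' sampled; see [sample_morphology()].
#'
#' @param config a [synthetic_config()].
#' @param subject_id subject identifier for the tree.
#' @param group treatment-group label.
#' @param seed integer seed (deterministic topology given the seed).
#' @return an [airway_tree()] with `archetype` tags and unit placeholder
#'   morphology.
#' @export
generate_tree <- function(config, subject_id, group, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- trunk_lengths(config)
  q0 <- config$branch_q[1]; q1 <- config$branch_q[2]
  ids <- character(0); parents <- character(0); calibers <- integer(0)
  n <- 0L
  add <- function(parent, caliber) {
    n <<- n + 1L
    id <- sprintf("S%04d", n)
    ids[n] <<- id; parents[n] <<- parent; calibers[n] <<- caliber
    id
  }
  gen_trunk <- function(parent, caliber) {
    if (caliber >= 5L) {
      add(parent, 5L)
      return(invisible(NULL))
    }
    len <- L[caliber]
    pos <- (seq_len(len) - 1) / max(len - 1, 1)
    extra <- rbinom(len, 2, pmin(0.95, q0 + q1 * pos))
    prev <- parent
    nodes <- character(len)
    for (i in seq_len(len)) nodes[i] <- prev <- add(prev, caliber)
    for (i in seq_len(len - 1L))
      gen_trunk(nodes[i], min(5L, caliber + 1L + extra[i]))
    # the trunk tip ends by splitting into two terminal daughters
    add(nodes[len], 5L)
    add(nodes[len], 5L)
    invisible(NULL)
  }
  with_seed(seed, gen_trunk(NA_character_, 1L))
  segments <- data.frame(segment_id = ids, parent_id = parents,
                         lumen_diameter = 1, wall_thickness = 0,
                         archetype = paste0("CL", calibers),
                         stringsAsFactors = FALSE)
  airway_tree(subject_id, group, segments)
}

# draw n strictly positive values from N(mean, sd) by resampling
rnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Sample segment morphology from archetype distributions
#'
#' Draws (lumen diameter, wall thickness) for every segment from the
#' bivariate Gaussian of its archetype, truncated at zero by resampling.
#' For a treated-group tree the effect multipliers are applied to the
#' archetype means \emph{before} sampling, so recovery tests have
#' analytically known targets.
#'
#' @param tree an archetype-tagged [airway_tree()] from [generate_tree()].
#' @param archetypes archetype table.
#' @param effect a `group_effect` to apply, or `NULL`.
#' @param seed integer seed.
#' @return the tree with `lumen_diameter` and `wall_thickness` filled in.
#' @export
sample_morphology <- function(tree, archetypes = default_archetypes(),
                              effect = NULL, seed = 1) {
  seg <- tree$segments
  if (any(is.na(seg$archetype)))
    stop_validation("every segment must carry an archetype tag")
  with_seed(seed, {
    for (i in seq_len(nrow(archetypes))) {
      a <- archetypes[i, ]
      idx <- which(seg$archetype == a$name)
      if (length(idx) == 0) next
      mu <- c(a$lumen_mean, a$wall_mean)
      if (!is.null(effect)) {
        mu[1] <- mu[1] * effect$lumen_mult[[a$name]]
        mu[2] <- mu[2] * effect$wall_mult[[a$name]]
      }
      cv <- a$cor * a$lumen_sd * a$wall_sd
      S <- matrix(c(a$lumen_sd^2, cv, cv, a$wall_sd^2), 2)
      R <- chol(S)
      draw <- function(m) {
        z <- matrix(rnorm(2 * m), m, 2) %*% R
        sweep(z, 2, mu, "+")
      }
      x <- draw(length(idx))
      while (any(bad <- x[, 1] <= 0 | x[, 2] <= 0))
        x[bad, ] <- draw(sum(bad))
      seg$lumen_diameter[idx] <- x[, 1]
      seg$wall_thickness[idx] <- x[, 2]
    }
  })
  tree$segments <- seg
  tree
}

#' Sample one epithelium profile from archetype parameters
#'
#' The total nuclei count along the ruler is Poisson with mean
#' `density * ruler_length / 1000`; category counts are multinomial from the
#' archetype's (possibly effect-shifted) probability vector. Epithelial
#' height and cilium length are positive-truncated Gaussians.
#'
#' @param archetype one row of the archetype table.
#' @param effect a `group_effect` or `NULL`.
#' @param ruler_length counting-ruler length in micrometres.
#' @param seed integer seed.
#' @return a list with the epithelium fields of a segment row.
#' @export
sample_epithelium <- function(archetype, effect = NULL, ruler_length = 100,
                              seed = 1) {
  with_seed(seed,
    as.list(sample_epithelium_n(1L, archetype, effect, ruler_length)))
}

# vectorized internal version: n profiles of one archetype (no seed scope)
sample_epithelium_n <- function(n, archetype, effect = NULL,
                                ruler_length = 100) {
  a <- archetype
  hm <- a$height_mean; cm <- a$cilium_mean; dm <- a$density
  if (!is.null(effect)) {
    hm <- hm * effect$height_mult[[a$name]]
    cm <- cm * effect$cilium_mult[[a$name]]
    dm <- dm * effect$density_mult[[a$name]]
  }
  p <- c(a$p_ciliated, a$p_goblet, a$p_basal, a$p_club, a$p_other)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop_validation("cell-category probabilities must be a probability vector")
  total <- rpois(n, dm * ruler_length / 1000)
  counts <- matrix(0, n, 5)
  pos <- total > 0
  if (any(pos))
    counts[pos, ] <- t(vapply(total[pos],
                              function(tt) rmultinom(1, tt, p)[, 1],
                              numeric(5)))
  data.frame(ruler_length = ruler_length,
             n_ciliated = counts[, 1], n_goblet = counts[, 2],
             n_basal = counts[, 3], n_club = counts[, 4],
             n_other = counts[, 5],
             epithelium_height = rnorm_pos(n, hm, a$height_sd),
             cilium_length = rnorm_pos(n, cm, a$cilium_sd))
}

#' Generate a full synthetic cohort with ground truth
#'
#' Generates `n_subjects` trees per group, samples morphology (and, if
#' configured, epithelium profiles) for every segment, applies the effect
#' structure to the treated group, and returns the cohort together with the
#' ground-truth archetype of every segment. Fully deterministic given the
#' configuration (which includes the seed).
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `cohort` (an [airway_cohort()]), `truth`
#'   (`data.frame`: subject_id, segment_id, archetype) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  trees <- list(); idx <- 0L
  for (g in config$groups) {
    eff <- if (g == config$treated) config$effect else NULL
    for (s in seq_len(config$n_subjects)) {
      idx <- idx + 1L
      sid <- paste0(g, s)
      tr <- generate_tree(config, sid, g, seed = sub_seed(config$seed, idx))
      tr <- sample_morphology(tr, config$archetypes, eff,
                              seed = sub_seed(config$seed, 1000 + idx))
      if (config$epithelium) {
        with_seed(sub_seed(config$seed, 2000 + idx), {
          for (i in seq_len(nrow(config$archetypes))) {
            a <- config$archetypes[i, ]
            rows <- which(tr$segments$archetype == a$name)
            if (length(rows) == 0) next
            prof <- sample_epithelium_n(length(rows), a, eff,
                                        config$ruler_length)
            tr$segments[rows, names(prof)] <- prof
          }
        })
      }
      trees[[sid]] <- tr
    }
  }
  cohort <- airway_cohort(trees)
  truth <- do.call(rbind, lapply(cohort, function(tr)
    data.frame(subject_id = tr$subject_id, segment_id = tr$segments$segment_id,
               archetype = tr$segments$archetype, stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  list(cohort = cohort, truth = truth, config = config)
}
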