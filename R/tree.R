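#' @useDynLib airwayclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate complete.cases cor cov dwilcox kmeans mahalanobis
#'   median pnorm pwilcox quantile rbinom rmultinom rnorm rpois sd setNames var
#' @importFrom utils read.table write.table packageVersion head
"_PACKAGE"

# classed error helpers ------------------------------------------------------

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("airway_format_error", "error")))
}
stop_integrity <- function(...) {
  stop(errorCondition(sprintf(...), class = c("airway_integrity_error", "error")))
}
stop_validation <- function(...) {
  stop(errorCondition(sprintf(...), class = c("airway_validation_error", "error")))
}

# canonical segment-table columns; epithelium fields are NA when the profile
# was not measured for a segment
EPI_COUNT_COLS <- c("n_ciliated", "n_goblet", "n_basal", "n_club", "n_other")
EPI_COLS <- c("ruler_length", EPI_COUNT_COLS, "epithelium_height", "cilium_length")
SEGMENT_COLS <- c("segment_id", "parent_id", "lumen_diameter", "wall_thickness",
                  "archetype", EPI_COLS)

empty_epithelium <- function(n) {
  out <- as.data.frame(setNames(rep(list(rep(NA_real_, n)), length(EPI_COLS)), EPI_COLS))
  out
}

#' Construct an airway tree
#'
#' An airway tree is a rooted collection of branch segments (the portion of an
#' airway between two bifurcations), each measured by its averaged lumen
#' diameter and wall thickness in micrometres. Topology is stored as parent
#' pointers; exactly one segment (the root, typically at the hilum) has no
#' parent.
#'
#' @param subject_id identifier of the animal/lung the tree belongs to.
#' @param group treatment-group label (e.g. `"NOX"` or `"HYX"`).
#' @param segments a `data.frame` with columns `segment_id`, `parent_id`
#'   (`NA` for the root), `lumen_diameter` and `wall_thickness` (micrometres);
#'   optionally `archetype` and the epithelium columns `ruler_length`,
#'   `n_ciliated`, `n_goblet`, `n_basal`, `n_club`, `n_other`,
#'   `epithelium_height`, `cilium_length`.
#' @param validate if `TRUE` (default), reject trees violating the invariants
#'   (see [validate_tree()]).
#' @return an object of class `airway_tree`.
#' @seealso [validate_tree()], [terminal_segments()], [read_segment_table()]
#' @export
airway_tree <- function(subject_id, group, segments, validate = TRUE) {
  stopifnot(is.data.frame(segments))
  segments$segment_id <- as.character(segments$segment_id)
  segments$parent_id <- as.character(segments$parent_id)
  segments$parent_id[!is.na(segments$parent_id) & segments$parent_id == ""] <- NA_character_
  if (is.null(segments$archetype)) segments$archetype <- NA_character_
  for (col in EPI_COLS) if (is.null(segments[[col]])) segments[[col]] <- NA_real_
  segments <- segments[, SEGMENT_COLS]
  rownames(segments) <- NULL
  tree <- structure(
    list(subject_id = as.character(subject_id), group = as.character(group),
         segments = segments,
         root_id = segments$segment_id[is.na(segments$parent_id)][1]),
    class = "airway_tree")
  if (validate) {
    v <- validate_tree(tree)
    if (length(v) > 0)
      stop_integrity("invalid airway tree for subject '%s': %s",
                     subject_id, paste(v, collapse = "; "))
  }
  tree
}

#' Validate an airway-tree structure
#'
#' Checks the structural invariants of a rooted segment tree: unique segment
#' ids, exactly one root, no self-parenting, all parent pointers resolvable,
#' every segment reachable from the root (connected, acyclic), positive lumen
#' diameters and non-negative wall thicknesses.
#'
#' @param tree an [airway_tree()] (or a bare list with the same fields).
#' @return a character vector of human-readable violations; empty when the
#'   tree is valid. Violations name the offending segment and the broken rule.
#' @export
validate_tree <- function(tree) {
  seg <- tree$segments
  out <- character()
  dup <- seg$segment_id[duplicated(seg$segment_id)]
  if (length(dup) > 0)
    out <- c(out, sprintf("duplicate segment id '%s'", unique(dup)))
  roots <- seg$segment_id[is.na(seg$parent_id)]
  if (length(roots) == 0) out <- c(out, "no root segment (every segment has a parent)")
  if (length(roots) > 1)
    out <- c(out, sprintf("multiple roots: %s", paste(roots, collapse = ", ")))
  self <- !is.na(seg$parent_id) & seg$parent_id == seg$segment_id
  if (any(self))
    out <- c(out, sprintf("segment '%s' is its own parent", seg$segment_id[self]))
  known <- seg$parent_id %in% seg$segment_id | is.na(seg$parent_id)
  if (any(!known))
    out <- c(out, sprintf("segment '%s' cites nonexistent parent '%s'",
                          seg$segment_id[!known], seg$parent_id[!known]))
  # reachability from the root by breadth-first traversal over parent pointers
  if (length(roots) >= 1 && all(known) && length(dup) == 0) {
    kids <- split(seg$segment_id, factor(seg$parent_id, levels = seg$segment_id))
    seen <- character(); frontier <- roots
    while (length(frontier) > 0) {
      seen <- c(seen, frontier)
      frontier <- unlist(kids[frontier], use.names = FALSE)
    }
    miss <- setdiff(seg$segment_id, seen)
    if (length(miss) > 0)
      out <- c(out, sprintf("segment '%s' unreachable from the root (cycle or orphan)", miss))
  }
  bad_lumen <- !is.na(seg$lumen_diameter) & seg$lumen_diameter <= 0
  if (any(bad_lumen))
    out <- c(out, sprintf("segment '%s' has nonpositive lumen diameter", seg$segment_id[bad_lumen]))
  bad_wall <- !is.na(seg$wall_thickness) & seg$wall_thickness < 0
  if (any(bad_wall))
    out <- c(out, sprintf("segment '%s' has negative wall thickness", seg$segment_id[bad_wall]))
  out
}

# children of every segment, as a list keyed by segment_id
tree_children <- function(tree) {
  seg <- tree$segments
  split(seg$segment_id[!is.na(seg$parent_id)],
        factor(seg$parent_id[!is.na(seg$parent_id)], levels = seg$segment_id))
}

# segments ordered root-first so that every parent precedes its children
topological_order <- function(tree) {
  kids <- tree_children(tree)
  ord <- character(nrow(tree$segments)); i <- 0L
  frontier <- tree$root_id
  while (length(frontier) > 0) {
    ord[i + seq_along(frontier)] <- frontier
    i <- i + length(frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  ord
}

#' Terminal segments of an airway tree
#'
#' The terminal segments are the leaves of the conducting tree: in the imaging
#' workflow these correspond to the terminal bronchioles at which the
#' segmentation was cut.
#'
#' @param tree a valid [airway_tree()].
#' @return character vector of segment ids with no children.
#' @export
terminal_segments <- function(tree) {
  v <- validate_tree(tree)
  if (length(v) > 0)
    stop_validation("cannot compute terminals of an invalid tree: %s",
                    paste(v, collapse = "; "))
  seg <- tree$segments
  setdiff(seg$segment_id, seg$parent_id[!is.na(seg$parent_id)])
}

#' Construct a cohort of airway trees
#'
#' @param trees a list of [airway_tree()] objects, one per subject.
#' @return an object of class `airway_cohort`. Trees are named by subject id.
#' @export
airway_cohort <- function(trees) {
  stopifnot(length(trees) > 0, all(vapply(trees, inherits, TRUE, "airway_tree")))
  names(trees) <- vapply(trees, `[[`, "", "subject_id")
  if (anyDuplicated(names(trees)))
    stop_integrity("duplicate subject ids in cohort: %s",
                   paste(unique(names(trees)[duplicated(names(trees))]), collapse = ", "))
  structure(trees, class = "airway_cohort")
}

#' @export
print.airway_tree <- function(x, ...) {
  cat(sprintf("Airway tree: subject '%s' (group %s), %d segments, %d terminals\n",
              x$subject_id, x$group, nrow(x$segments), length(terminal_segments(x))))
  invisible(x)
}

#' @export
print.airway_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, "", "group")
  nseg <- vapply(x, function(t) nrow(t$segments), 0L)
  cat(sprintf("Airway cohort: %d trees, %d segments\n", length(x), sum(nseg)))
  for (g in unique(groups))
    cat(sprintf("  group %s: %d trees, %d segments\n", g, sum(groups == g),
                sum(nseg[groups == g])))
  invisible(x)
}

#' Flatten a cohort into one segment table
#'
#' Returns one row per segment across all trees, with the derived epithelium
#' summaries appended: `density` (nuclei per mm along the counting ruler) and
#' the cell-type percentages `pct_ciliated`, `pct_goblet`, `pct_basal`,
#' `pct_club`, `pct_other`. Percentages are `NA` where no profile was
#' measured or no nuclei were counted.
#'
#' @param cohort an [airway_cohort()].
#' @return a `data.frame` with columns `subject_id`, `group`, the segment
#'   fields, and the derived epithelium summaries.
#' @export
segment_table <- function(cohort) {
  stopifnot(inherits(cohort, "airway_cohort"))
  tabs <- lapply(cohort, function(tr) {
    cbind(data.frame(subject_id = tr$subject_id, group = tr$group,
                     stringsAsFactors = FALSE), tr$segments)
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  counts <- as.matrix(tab[, EPI_COUNT_COLS])
  total <- rowSums(counts)
  tab$density <- ifelse(is.na(total) | is.na(tab$ruler_length), NA_real_,
                        total / tab$ruler_length * 1000)
  frac <- counts / total * 100
  frac[is.na(total) | total == 0, ] <- NA_real_
  colnames(frac) <- sub("^n_", "pct_", EPI_COUNT_COLS)
  cbind(tab, as.data.frame(frac))
}

# I/O ------------------------------------------------------------------------

#' Default column-name dialect for segment tables
#'
#' No standard file format exists for per-segment airway morphometry tables,
#' so [read_segment_table()] resolves columns through a dialect map from
#' logical field names to the column names used in a particular file. The
#' default maps each logical name to itself.
#'
#' @return named list mapping logical field names to column names.
#' @export
default_dialect <- function() {
  nm <- c("subject_id", "group", "segment_id", "parent_id", "image_index",
          "inner_diameter", "outer_diameter", "lumen_diameter",
          "wall_thickness", "archetype", EPI_COLS)
  as.list(setNames(nm, nm))
}

#' Read a per-segment morphometry table into a cohort
#'
#' Reads a delimited text file (comma default, tab accepted) with one row per
#' raw (segment, image) measurement, or one row per segment if measurements
#' were pre-averaged. Raw rows carry `inner_diameter` and `outer_diameter`
#' (micrometres); the wall thickness of each image is `(outer - inner) / 2`
#' and rows of the same segment appearing in multiple consecutive images are
#' averaged. Pre-averaged rows carry `lumen_diameter` and `wall_thickness`
#' directly. Epithelium columns are optional; absent fields yield segments
#' without profiles.
#'
#' @param path path to the delimited text file (UTF-8, header row required).
#' @param dialect a column-name map as produced by [default_dialect()];
#'   entries may be overridden to match the file's headers.
#' @param sep field separator; `NULL` (default) chooses tab when the header
#'   contains one, comma otherwise.
#' @return an [airway_cohort()].
#' @export
read_segment_table <- function(path, dialect = default_dialect(), sep = NULL) {
  if (!file.exists(path)) stop_format("file does not exist: '%s'", path)
  d <- utils::modifyList(default_dialect(), dialect)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#", quote = "\"",
                    fileEncoding = "UTF-8")
  col <- function(field) {
    nm <- d[[field]]
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  for (field in c("subject_id", "group", "segment_id", "parent_id"))
    if (is.null(col(field)))
      stop_format("required column '%s' (field %s) missing in '%s'",
                  d[[field]], field, path)
  has_raw <- !is.null(col("inner_diameter")) && !is.null(col("outer_diameter"))
  has_avg <- !is.null(col("lumen_diameter")) && !is.null(col("wall_thickness"))
  if (!has_raw && !has_avg)
    stop_format(paste0("need either columns '%s'+'%s' or '%s'+'%s' in '%s'"),
                d$inner_diameter, d$outer_diameter, d$lumen_diameter,
                d$wall_thickness, path)
  tab <- data.frame(subject_id = as.character(col("subject_id")),
                    group = as.character(col("group")),
                    segment_id = as.character(col("segment_id")),
                    parent_id = as.character(col("parent_id")),
                    stringsAsFactors = FALSE)
  tab$image_index <- if (!is.null(col("image_index"))) col("image_index") else 1L
  key <- paste(tab$subject_id, tab$segment_id, tab$image_index, sep = "\r")
  if (anyDuplicated(key))
    stop_integrity("duplicate (subject, segment, image) key: %s",
                   gsub("\r", "/", key[duplicated(key)][1]))
  if (has_raw) {
    inner <- as.numeric(col("inner_diameter"))
    outer <- as.numeric(col("outer_diameter"))
    bad <- which(!is.na(inner) & inner <= 0)
    if (length(bad) > 0)
      stop_validation("nonpositive inner diameter in row %d", bad[1] + 1L)
    bad <- which(!is.na(outer) & !is.na(inner) & outer < inner)
    if (length(bad) > 0)
      stop_validation("outer diameter smaller than inner diameter in row %d",
                      bad[1] + 1L)
    tab$lumen_diameter <- inner
    tab$wall_thickness <- wall_thickness(outer, inner)
  } else {
    tab$lumen_diameter <- as.numeric(col("lumen_diameter"))
    tab$wall_thickness <- as.numeric(col("wall_thickness"))
    bad <- which(!is.na(tab$lumen_diameter) & tab$lumen_diameter <= 0)
    if (length(bad) > 0)
      stop_validation("nonpositive lumen diameter in row %d", bad[1] + 1L)
  }
  tab$archetype <- if (!is.null(col("archetype"))) as.character(col("archetype")) else NA_character_
  for (field in EPI_COLS)
    tab[[field]] <- if (!is.null(col(field))) as.numeric(col(field)) else NA_real_

  # aggregate per-image rows per (subject, segment): arithmetic mean of the
  # per-image lumen diameters and per-image wall thicknesses
  skey <- paste(tab$subject_id, tab$segment_id, sep = "\r")
  first <- tab[!duplicated(skey), ]
  o <- match(paste(first$subject_id, first$segment_id, sep = "\r"), skey)
  agg_num <- function(v) {
    s <- rowsum(ifelse(is.na(v), 0, v), skey)
    n <- rowsum(as.numeric(!is.na(v)), skey)
    out <- as.vector(s / n)[match(unique(skey), rownames(s))]
    out[is.nan(out)] <- NA_real_
    out
  }
  ukey <- unique(skey)
  agg <- first[match(ukey, skey), ]
  for (field in c("lumen_diameter", "wall_thickness", EPI_COLS))
    agg[[field]] <- agg_num(tab[[field]])

  trees <- lapply(split(agg, agg$subject_id), function(s) {
    if (length(unique(s$group)) > 1)
      stop_integrity("subject '%s' appears with multiple group labels",
                     s$subject_id[1])
    airway_tree(s$subject_id[1], s$group[1], s[, !(names(s) %in%
      c("subject_id", "group", "image_index"))])
  })
  airway_cohort(trees[order(names(trees))])
}

#' Write a cohort back to a delimited segment table
#'
#' One row per (already averaged) segment. Numeric fields are written with
#' full precision so that write-then-read round-trips reproduce all values
#' exactly.
#'
#' @param cohort an [airway_cohort()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(cohort, path, sep = ",") {
  tabs <- lapply(cohort, function(tr)
    cbind(data.frame(subject_id = tr$subject_id, group = tr$group,
                     stringsAsFactors = FALSE), tr$segments))
  tab <- do.call(rbind, tabs)
  num <- vapply(tab, is.numeric, TRUE)
  for (j in which(num)) {
    v <- sprintf("%.17g", tab[[j]])
    v[is.na(tab[[j]])] <- NA
    tab[[j]] <- v
  }
  write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Export one tree as nested JSON
#'
#' Parent-to-children nesting with per-segment attributes, intended for
#' external tree viewers.
#'
#' @param tree an [airway_tree()].
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  kids <- tree_children(tree)
  seg <- tree$segments
  rownames(seg) <- seg$segment_id
  build <- function(id) {
    row <- seg[id, ]
    node <- list(segment_id = id,
                 lumen_diameter = row$lumen_diameter,
                 wall_thickness = row$wall_thickness)
    if (!is.na(row$archetype)) node$archetype <- row$archetype
    ch <- kids[[id]]
    if (length(ch) > 0) node$children <- lapply(ch, build)
    node
  }
  js <- jsonlite::toJSON(build(tree$root_id), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
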