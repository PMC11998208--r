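# Derived morphometric quantities: wall thickness, per-image averaging,
# epithelium density and cell-type fractions. All lengths in micrometres.

#' Airway wall thickness from inner and outer diameter
#'
#' The wall (mucosal and muscular tissue) thickness of an airway cross
#' section is half the difference between the outer and the inner (lumen)
#' diameter:
#' \deqn{\mathrm{wall} = (\varnothing_{outer} - \varnothing_{inner}) / 2.}
#'
#' @param outer_diameter outer diameter(s), micrometres.
#' @param inner_diameter inner (lumen) diameter(s), micrometres; must be
#'   positive and no larger than the outer diameter.
#' @return wall thickness in micrometres (vectorized).
#' @examples
#' wall_thickness(30, 20) # 5
#' @export
wall_thickness <- function(outer_diameter, inner_diameter) {
  if (any(!is.na(inner_diameter) & inner_diameter <= 0))
    stop_validation("inner diameter must be positive")
  if (any(!is.na(outer_diameter) & !is.na(inner_diameter) &
            outer_diameter < inner_diameter))
    stop_validation("outer diameter must not be smaller than inner diameter")
  (outer_diameter - inner_diameter) / 2
}

#' Average repeated per-image measurements of one segment
#'
#' A branch segment visible in multiple consecutive microscopy images yields
#' one (inner, outer) diameter pair per image; its morphometry is the
#' arithmetic mean over images. The wall thickness is computed per image via
#' [wall_thickness()] and then averaged (identical, by linearity, to applying
#' the formula to the averaged diameters).
#'
#' @param records a `data.frame` with columns `inner_diameter` and
#'   `outer_diameter` (one row per image), optionally `segment_id` (must then
#'   be constant).
#' @return a list with elements `lumen_diameter` and `wall_thickness`.
#' @examples
#' aggregate_measurements(data.frame(inner_diameter = c(20, 22),
#'                                   outer_diameter = c(30, 30)))
#' @export
aggregate_measurements <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_validation("aggregate_measurements needs at least one record")
  if (!is.null(records$segment_id) && length(unique(records$segment_id)) > 1)
    stop_validation("records mix segment ids: %s",
                    paste(unique(records$segment_id), collapse = ", "))
  w <- wall_thickness(records$outer_diameter, records$inner_diameter)
  list(lumen_diameter = mean(records$inner_diameter), wall_thickness = mean(w))
}

#' Nuclear density along the epithelium counting ruler
#'
#' Cell nuclei are counted along a digital ruler (default length 100
#' micrometres) placed on the airway epithelium; density is reported per
#' millimetre.
#'
#' @param counts nuclei counts (a vector of per-category counts, or a single
#'   total).
#' @param ruler_length ruler length in micrometres (default 100).
#' @return nuclei per mm.
#' @examples
#' nuclei_density(12) # 120 nuclei/mm on a 100 um ruler
#' @export
nuclei_density <- function(counts, ruler_length = 100) {
  if (length(ruler_length) != 1 || is.na(ruler_length) || ruler_length <= 0)
    stop_validation("ruler length must be a single positive value")
  if (any(counts < 0, na.rm = TRUE))
    stop_validation("nuclei counts must be non-negative")
  sum(counts) / ruler_length * 1000
}

#' Cell-type composition of the epithelium as percentages
#'
#' Converts per-category nuclei counts into percentages of all observed
#' nuclei. When no nuclei were observed the composition is undefined and all
#' percentages are returned as `NA` (never `NaN`).
#'
#' @param counts named or unnamed non-negative counts per cell category
#'   (ciliated, goblet, basal, club, other).
#' @return numeric vector of percentages summing to 100 (or all-`NA`).
#' @examples
#' cell_fractions(c(ciliated = 5, goblet = 0, basal = 0, club = 5, other = 0))
#' @export
cell_fractions <- function(counts) {
  if (any(counts < 0, na.rm = TRUE))
    stop_validation("cell counts must be non-negative")
  total <- sum(counts)
  if (is.na(total) || total == 0)
    return(setNames(rep(NA_real_, length(counts)), names(counts)))
  counts / total * 100
}
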