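# Small shared utilities.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items: 1 for
#' identical partitions (up to label permutation), about 0 for independent
#' ones. Used to score recovery of generating archetypes by the fitted
#' clusters.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

# deterministic md5 of a configuration (for output provenance stamps)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

unclass_recursive <- function(x) {
  if (is.list(x) && !is.data.frame(x)) lapply(unclass(x), unclass_recursive)
  else if (is.data.frame(x)) as.data.frame(unclass(x))
  else x
}
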