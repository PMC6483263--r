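#' Chromosome map: an ordering and orientation of scaffolds
#'
#' A map in the sense used throughout this package is an ordered list of
#' scaffolds, each carried forward (`+1`) or reverse-complemented (`-1`).
#' Rates (intra-scaffold and junction recombination fractions) are attached
#' by the fitting functions; the bare object is just the order/orientation.
#'
#' @param scaffold Character vector of scaffold ids (unique).
#' @param orientation Integer vector of +1 / -1 (default all forward).
#' @return Object of class `chrom_map`.
#' @export
chrom_map <- function(scaffold, orientation = rep(1L, length(scaffold))) {
  scaffold <- as.character(scaffold)
  if (anyDuplicated(scaffold)) stop("duplicated scaffold in map", call. = FALSE)
  if (length(orientation) != length(scaffold) || !all(orientation %in% c(-1L, 1L))) {
    stop("`orientation` must be +1/-1, one per scaffold", call. = FALSE)
  }
  structure(list(scaffold = scaffold, orientation = as.integer(orientation)),
            class = "chrom_map")
}

#' @export
print.chrom_map <- function(x, ...) {
  cat("<chrom_map> ", length(x$scaffold), " scaffolds\n  ", sep = "")
  cat(paste0(ifelse(x$orientation > 0, "", "-"), x$scaffold), sep = " ")
  cat("\n")
  invisible(x)
}

#' @export
length.chrom_map <- function(x) length(x$scaffold)

#' Full reversal of a chromosome map
#'
#' Reverses the scaffold order and flips every orientation. A map and its
#' full reversal induce the same marker sequence read in opposite directions
#' and therefore have identical likelihood.
#'
#' @param map A [chrom_map()].
#' @return The reversed [chrom_map()].
#' @export
reverse_map <- function(map) {
  chrom_map(rev(map$scaffold), -rev(map$orientation))
}

.encode_map <- function(map) {
  paste(ifelse(map$orientation > 0, map$scaffold, paste0("-", map$scaffold)),
        collapse = "|")
}

#' Canonical signature of a map
#'
#' A string key identical for a map and its full reversal (the
#' lexicographically smaller of the two encodings), used to cache fitness
#' evaluations and to break ties deterministically.
#'
#' @param map A [chrom_map()].
#' @return Character scalar.
#' @export
map_signature <- function(map) {
  min(.encode_map(map), .encode_map(reverse_map(map)))
}

#' Canonical form of a map
#'
#' Returns whichever of the map or its full reversal has the smaller
#' encoding, so that map-equivalent pairs compare equal.
#'
#' @param map A [chrom_map()].
#' @return A [chrom_map()].
#' @export
canonical_map <- function(map) {
  r <- reverse_map(map)
  if (.encode_map(map) <= .encode_map(r)) map else r
}

#' Randomly permute and reorient a map
#'
#' Draws a uniform random permutation of the scaffolds and independent
#' uniform orientations -- the deliberately uninformative starting point for
#' the genetic algorithm. With `identity = TRUE` the input is returned
#' unchanged (no-op mode).
#'
#' @param map A [chrom_map()].
#' @param identity Return the input unchanged.
#' @return A [chrom_map()] with attributes `n_fixed` (scaffolds left in
#'   place) and `perm_distance` (scaffolds moved).
#' @export
scramble_map <- function(map, identity = FALSE) {
  if (identity) {
    out <- map
    attr(out, "n_fixed") <- length(map)
    attr(out, "perm_distance") <- 0L
    return(out)
  }
  L <- length(map$scaffold)
  perm <- sample.int(L)
  ori <- sample(c(-1L, 1L), L, replace = TRUE)
  if (L == 1L) perm <- 1L
  out <- chrom_map(map$scaffold[perm], ori)
  attr(out, "n_fixed") <- sum(perm == seq_len(L))
  attr(out, "perm_distance") <- sum(perm != seq_len(L))
  out
}

#' Tidy a chromosome map
#'
#' @param x A [chrom_map()], possibly carrying fitted rates (as returned in
#'   a `map_fit`).
#' @param ... Unused.
#' @return Tibble with columns `rank`, `scaffold`, `orientation`.
#' @export
tidy.chrom_map <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$scaffold), scaffold = x$scaffold,
                 orientation = ifelse(x$orientation > 0, "+", "-"))
}
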