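#' Recombination fractions from physical distance at a fixed rate
#'
#' The homogeneous-rate model used while estimating genotyping error rates:
#' the genetic distance between adjacent markers on a scaffold is their
#' midpoint-to-midpoint physical distance times a fixed genomic-average rate
#' (5.0 cM/Mb for F2 populations, 10.0 cM/Mb for F3 and RIL populations),
#' Haldane-transformed to a recombination fraction and floored at `r_min`.
#'
#' @param markers Marker tibble for one scaffold (columns `index`, `start`,
#'   `end`), ordered by coordinate.
#' @param rate_cm_per_mb Fixed rate in cM/Mb (> 0).
#' @param r_min Lower floor on recombination fractions.
#' @return Numeric vector of length `nrow(markers) - 1`.
#' @examples
#' w <- define_windows(c(s1 = 3e5))
#' physical_r_vector(w, 5.0)  # two gaps of 100 kb -> r ~ 0.004975
#' @export
physical_r_vector <- function(markers, rate_cm_per_mb, r_min = 1e-6) {
  stopifnot(rate_cm_per_mb > 0)
  if (is.unsorted(markers$index) || is.unsorted(markers$start)) {
    stop("markers must be ordered by coordinate", call. = FALSE)
  }
  if (nrow(markers) < 2) return(numeric(0))
  mid <- (markers$start + markers$end) / 2
  pmax(haldane_r(diff(mid) / 1e6 * rate_cm_per_mb), r_min)
}

#' Intra-scaffold recombination rate MLE
#'
#' Maximizes the summed per-individual chain likelihood within each scaffold
#' with respect to the recombination fractions between all adjacent markers
#' (cyclic coordinate-wise Brent ascent). These estimates feed the genetic
#' algorithm, where they are held fixed.
#'
#' @param calls A [geno_calls()] object.
#' @param errors Error-rate tibble from [estimate_error_rates()].
#' @param design A [cross_design()].
#' @param rate_cm_per_mb Fixed rate used for starting values (defaults to
#'   the design's genomic average).
#' @param r_min,r_max Bounds on each recombination fraction.
#' @param ... Passed to the coordinate-ascent engine.
#' @return Tibble with columns `scaffold`, `gap` (1-based gap index within
#'   the scaffold), `marker_from`, `marker_to`, `r`, `loglik` (per-scaffold
#'   attained log-likelihood). Single-marker scaffolds contribute no rows.
#' @export
estimate_intra_rates <- function(calls, errors, design, rate_cm_per_mb = NULL,
                                 r_min = 1e-6, r_max = 0.5, ...) {
  ctx <- .lk_context(calls, errors, design)
  rate0 <- rate_cm_per_mb %||% .default_fixed_rate(design)
  start <- .physical_intra_list(ctx$markers, rate0, r_min)
  out <- lapply(names(ctx$scaffold_markers), function(sc) {
    idx <- ctx$scaffold_markers[[sc]]
    if (length(idx) < 2) return(NULL)
    E <- ctx$E[, , idx, drop = FALSE]
    res <- .coord_ascent(E, start[[sc]], design,
                         free = rep(TRUE, length(idx) - 1L),
                         r_min = r_min, r_max = r_max, ...)
    mk <- ctx$markers$marker[idx]
    tibble::tibble(scaffold = sc, gap = seq_len(length(idx) - 1L),
                   marker_from = mk[-length(mk)], marker_to = mk[-1],
                   r = res$rates, loglik = res$loglik)
  })
  dplyr::bind_rows(out)
}

#' Flag scaffolds whose internal rates suggest a mis-join
#'
#' An intra-scaffold recombination fraction far above the genomic average
#' over at most one window length is evidence that the scaffold spans a
#' structural breakpoint (for example an inversion edge) and should be split
#' into independent pieces before map search.
#'
#' @param intra Tibble from [estimate_intra_rates()].
#' @param threshold Flag gaps with `r` above this (default 0.2).
#' @return Tibble of flagged `(scaffold, gap, r)` rows.
#' @export
flag_split_candidates <- function(intra, threshold = 0.2) {
  dplyr::filter(intra, .data$r > threshold)[, c("scaffold", "gap", "r")]
}

#' Split scaffolds at flagged gaps
#'
#' Each flagged scaffold is cut after the marker preceding the flagged gap;
#' the pieces are renamed with letter suffixes (`13` becomes `13a`, `13b`),
#' their windows renumbered from the start of each piece and coordinates
#' re-based, so they re-enter the pipeline as independent scaffolds.
#'
#' @param calls A [geno_calls()] object.
#' @param flags Tibble from [flag_split_candidates()].
#' @return A new [geno_calls()] object.
#' @export
split_scaffolds <- function(calls, flags) {
  if (!nrow(flags)) return(calls)
  mk <- calls$markers
  new_sc <- mk$scaffold
  new_index <- mk$index
  new_start <- mk$start; new_end <- mk$end
  for (sc in unique(flags$scaffold)) {
    gaps <- sort(flags$gap[flags$scaffold == sc])
    rows <- which(mk$scaffold == sc)
    rows <- rows[order(mk$index[rows])]
    piece <- findInterval(seq_along(rows) - 1L, gaps) + 1L
    new_sc[rows] <- paste0(sc, letters[piece])
    for (p in unique(piece)) {
      pr <- rows[piece == p]
      new_index[pr] <- seq_along(pr)
      off <- new_start[pr[1]]
      new_start[pr] <- new_start[pr] - off
      new_end[pr] <- new_end[pr] - off
    }
  }
  mk$scaffold <- new_sc; mk$index <- new_index
  mk$start <- new_start; mk$end <- new_end
  mk$marker <- sprintf("%s:%d-%d", mk$scaffold, as.integer(mk$start),
                       as.integer(mk$end))
  geno_calls(calls$calls, mk, depth = calls$depth)
}

#' Fit recombination rates to a fixed scaffold order
#'
#' Computes the maximum-likelihood recombination fractions for a given map.
#' In `"junction"` mode only the `L - 1` inter-scaffold rates are free
#' (intra-scaffold rates held at their [estimate_intra_rates()] values) --
#' this log-likelihood is the genetic algorithm's fitness. In `"full"` mode
#' all `L - 1 + K` rates are re-estimated jointly, which is applied to the
#' final map and also when imposing one cross's map on another. Bad joins
#' are absorbed by junction rates rising toward 0.5.
#'
#' @param map A [chrom_map()].
#' @param calls A [geno_calls()] object.
#' @param errors Error-rate tibble ([estimate_error_rates()]).
#' @param design A [cross_design()].
#' @param intra Intra-rate tibble ([estimate_intra_rates()]) or named list;
#'   `NULL` falls back to the fixed physical-rate model as starting values.
#' @param mode `"junction"` or `"full"`.
#' @param posterior Also compute genotype posteriors under the fitted map.
#' @param init_inter Starting value for junction rates.
#' @param ... Passed to the coordinate-ascent engine.
#' @return Object of class `map_fit`: the map, attained `loglik`, the rate
#'   vector along the induced marker sequence, marker bookkeeping, and
#'   optionally `posterior` (individuals x 3 x markers array).
#' @export
fit_map <- function(map, calls, errors, design, intra = NULL,
                    mode = c("junction", "full"), posterior = FALSE,
                    init_inter = 0.05, ...) {
  mode <- match.arg(mode)
  ctx <- .lk_context(calls, errors, design)
  fit <- .fit_map_ctx(ctx, map, .intra_as_list(intra, ctx$markers), mode,
                      init_inter = init_inter, posterior = posterior, ...)
  fit
}

.fit_map_ctx <- function(ctx, map, intra_list, mode, init_inter = 0.05,
                         posterior = FALSE, ops = NULL, ...) {
  ms <- .map_sequence(ctx, map)
  if (is.null(intra_list)) {
    intra_list <- .physical_intra_list(ctx$markers,
                                       .default_fixed_rate(ctx$design))
  }
  M <- length(ms$seq)
  if (mode == "junction") {
    # coarse chain over scaffold transfer operators (exact, much faster)
    if (is.null(ops)) ops <- .scaffold_ops(ctx, intra_list)
    chain <- lapply(seq_along(map$scaffold), function(i) {
      ops[[map$scaffold[i]]][[if (map$orientation[i] > 0) "fwd" else "rev"]]
    })
    cres <- .coarse_junction_fit(chain, ctx$design,
                                 inter = rep(init_inter,
                                             length(map$scaffold) - 1L), ...)
    res <- list(
      rates = .assemble_rates(map, ms, intra_list, inter = cres$rates,
                              init_inter = init_inter),
      loglik = cres$loglik, cycles = cres$cycles)
  } else {
    rates <- .assemble_rates(map, ms, intra_list, init_inter = init_inter)
    free <- rep(TRUE, max(M - 1L, 0L))
    E <- ctx$E[, , ms$seq, drop = FALSE]
    res <- .coord_ascent(E, rates, ctx$design, free, ...)
  }
  out <- structure(list(
    map = map, loglik = res$loglik, rates = res$rates,
    junctions = ms$junctions, seq = ms$seq,
    markers = ctx$markers[ms$seq, , drop = FALSE],
    scaffold_lens = ms$lens, design = ctx$design,
    n_individuals = ctx$n, mode = mode, cycles = res$cycles), class = "map_fit")
  if (posterior) {
    E <- ctx$E[, , ms$seq, drop = FALSE]
    post <- .fb_posterior(E, res$rates, ctx$design)$posterior
    dimnames(post) <- list(ctx$individuals, c("AA", "AB", "BB"),
                           ctx$markers$marker[ms$seq])
    out$posterior <- post
  }
  out
}

#' @export
print.map_fit <- function(x, ...) {
  cat("<map_fit> ", length(x$map$scaffold), " scaffolds, ",
      length(x$seq), " markers, ", x$n_individuals, " individuals\n",
      "  mode: ", x$mode, ";  lnLk = ", sprintf("%.3f", x$loglik),
      ";  length = ", sprintf("%.1f cM", sum(haldane_cm(pmin(x$rates, 0.5 - 1e-12)))),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted map
#'
#' One row per marker in map order, with the recombination fraction and
#' genetic distance to the next marker and the cumulative map position.
#'
#' @param x A `map_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.map_fit <- function(x, ...) {
  M <- length(x$seq)
  r_next <- c(x$rates, NA_real_)
  cm_next <- c(haldane_cm(pmin(x$rates, 0.5 - 1e-12)), NA_real_)
  ori <- rep(x$map$orientation, x$scaffold_lens)
  tibble::tibble(
    position = seq_len(M),
    marker = x$markers$marker,
    scaffold = x$markers$scaffold,
    orientation = ifelse(ori > 0, "+", "-"),
    junction = c(seq_len(max(M - 1, 0)) %in% x$junctions, NA),
    r_next = r_next,
    cm_next = cm_next,
    cum_cm = c(0, cumsum(cm_next[-M])))
}

#' @export
glance.map_fit <- function(x, ...) {
  tibble::tibble(
    n_scaffolds = length(x$map$scaffold),
    n_markers = length(x$seq),
    n_individuals = x$n_individuals,
    loglik = x$loglik,
    length_cm = sum(haldane_cm(pmin(x$rates, 0.5 - 1e-12))),
    mode = x$mode)
}

#' Genotype posteriors and final rates for an optimized map
#'
#' Convenience wrapper for the last pipeline stage: re-estimates all
#' `L - 1 + K` rates jointly under `map` and emits genotype posteriors.
#'
#' @inheritParams fit_map
#' @return A `map_fit` with `posterior` attached.
#' @export
finalize_map <- function(map, calls, errors, design, intra = NULL, ...) {
  fit_map(map, calls, errors, design, intra, mode = "full",
          posterior = TRUE, ...)
}

#' Per-marker interval recombination rates
#'
#' For every interior marker of a scaffold, defines the interval from the
#' midpoint of the preceding marker to the midpoint of the following one
#' (200 kb for standard 100 kb windows) and reports the summed genetic
#' length of the two flanking gaps as a rate in cM/Mb. Scaffold-end markers
#' and inter-scaffold gaps are excluded, as the interceding DNA there is
#' unknown. Supply `exclude` (marker ids) to mask regions where
#' recombination is suppressed by segregating inversions.
#'
#' @param fit A `map_fit` (typically from [finalize_map()]).
#' @param exclude Optional character vector of marker ids to drop.
#' @return Tibble with `scaffold`, `marker`, `interval_start`,
#'   `interval_end`, `cm`, `rate_cm_per_mb`.
#' @export
extract_interval_rates <- function(fit, exclude = NULL) {
  out <- list()
  pos <- 0L
  for (i in seq_along(fit$map$scaffold)) {
    k <- fit$scaffold_lens[i]
    if (k >= 3L) {
      chunk <- fit$rates[(pos + 1L):(pos + k - 1L)]
      rows <- fit$markers[(pos + 1L):(pos + k), , drop = FALSE]
      if (fit$map$orientation[i] < 0) {
        chunk <- rev(chunk)
        rows <- rows[rev(seq_len(k)), , drop = FALSE]
      }
      mid <- (rows$start + rows$end) / 2
      j <- 2:(k - 1L)
      cm <- haldane_cm(pmin(chunk[j - 1L], 0.5 - 1e-12)) +
        haldane_cm(pmin(chunk[j], 0.5 - 1e-12))
      out[[length(out) + 1L]] <- tibble::tibble(
        scaffold = fit$map$scaffold[i],
        marker = rows$marker[j],
        interval_start = mid[j - 1L],
        interval_end = mid[j + 1L],
        cm = cm,
        rate_cm_per_mb = cm / ((mid[j + 1L] - mid[j - 1L]) / 1e6))
    }
    pos <- pos + k
  }
  res <- dplyr::bind_rows(out)
  if (!is.null(exclude) && nrow(res)) {
    res <- dplyr::filter(res, !(.data$marker %in% exclude))
  }
  res
}

#' Consensus interval rates across crosses
#'
#' Standardizes each cross's interval rates by that cross's total map length
#' and averages across crosses with the supplied reciprocal-variance
#' weights. Intervals scored by no cross are absent from the output.
#'
#' @param rates Long tibble with columns `cross`, `marker`,
#'   `rate_cm_per_mb` (one row per cross x interval).
#' @param weights Tibble with columns `cross`, `weight` (weights in (0, 1],
#'   maximum 1).
#' @param map_lengths Named numeric vector: total map length (cM) per cross.
#' @return Tibble with `marker`, `consensus_rate` (standardized scale) and
#'   `n_crosses`.
#' @export
weighted_mean_rates <- function(rates, weights, map_lengths) {
  stopifnot(all(c("cross", "marker", "rate_cm_per_mb") %in% names(rates)),
            all(c("cross", "weight") %in% names(weights)))
  d <- dplyr::left_join(rates, weights, by = "cross")
  if (anyNA(d$weight)) stop("missing weight for some cross", call. = FALSE)
  d$std_rate <- d$rate_cm_per_mb / map_lengths[d$cross]
  d |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      consensus_rate = sum(.data$weight * .data$std_rate) / sum(.data$weight),
      n_crosses = dplyr::n(), .groups = "drop")
}

#' Reciprocal-variance cross weights used in the original five-cross study
#'
#' Shipped as a worked-example fixture for [weighted_mean_rates()].
#'
#' @return Tibble with columns `cross`, `weight`.
#' @export
default_cross_weights <- function() {
  tibble::tibble(
    cross = c("IMPR", "IMSWC", "IMNAS", "DUNTIL", "IMF3"),
    weight = c(1.0, 0.899, 0.790, 0.677, 0.380))
}
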